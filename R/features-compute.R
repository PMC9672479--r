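# Per-family feature computations. Texture formulas follow the standard
# IBSI-style definitions over merged-direction matrices; gray levels are
# the 1-based discretized levels produced by discretize_gray().

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

firstorder_features <- function(x, gray, ngray, voxel_volume) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  robust <- x[x >= q[1] & x <= q[5]]
  p <- tabulate(gray, nbins = ngray) / n
  sk <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = entropy_bits(p),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = sk,
    Kurtosis = ku,
    Variance = m2,
    Uniformity = sum(p^2))
}

# Largest pairwise Euclidean distance among a set of points (rows), done
# in chunks to bound memory.
max_pairwise_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  sq <- rowSums(pts^2)
  best <- 0
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    cp <- pts[s:e, , drop = FALSE] %*% t(pts)
    d2 <- outer(sq[s:e], sq, `+`) - 2 * cp
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

# Surface voxels: mask voxels with at least one 6-neighbour outside.
surface_voxels <- function(mask) {
  dm <- dim(mask)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
  core <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  nb <- pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  core & !nb
}

# Shape features depend on the mask and voxel spacing only. spacing_mm is
# (z, y, x).
shape_features <- function(mask, spacing_mm) {
  dm <- dim(mask)
  vz <- spacing_mm[1]; vy <- spacing_mm[2]; vx <- spacing_mm[3]
  voxvol <- vz * vy * vx
  n <- sum(mask)
  vol <- n * voxvol
  # surface area from exposed faces
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
  faces_z <- sum(mask & !pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)]) +
    sum(mask & !pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)])
  faces_y <- sum(mask & !pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)]) +
    sum(mask & !pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)])
  faces_x <- sum(mask & !pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]]) +
    sum(mask & !pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)])
  sa <- faces_z * vy * vx + faces_y * vz * vx + faces_x * vz * vy
  sphericity <- if (sa > 0) (36 * pi * vol^2)^(1 / 3) / sa else 0

  surf <- which(surface_voxels(mask), arr.ind = TRUE)
  pts <- cbind(surf[, 1] * vz, surf[, 2] * vy, surf[, 3] * vx)
  d3 <- max_pairwise_dist(pts)
  plane_diam <- function(axis) {
    keep <- setdiff(1:3, axis)
    best <- 0
    for (lev in unique(surf[, axis])) {
      p <- pts[surf[, axis] == lev, keep, drop = FALSE]
      best <- max(best, max_pairwise_dist(p))
    }
    best
  }
  d_slice <- plane_diam(1L)   # within an axial slice (y, x)
  d_col <- plane_diam(2L)     # within a coronal plane (z, x)
  d_row <- plane_diam(3L)     # within a sagittal plane (z, y)

  all_idx <- which(mask, arr.ind = TRUE)
  P <- cbind(all_idx[, 1] * vz, all_idx[, 2] * vy, all_idx[, 3] * vx)
  if (nrow(P) > 1L) {
    ev <- sort(pmax(eigen(stats::cov(P), symmetric = TRUE,
                          only.values = TRUE)$values, 0), decreasing = TRUE)
  } else {
    ev <- c(0, 0, 0)
  }
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  c(MeshVolume = vol, VoxelVolume = vol, SurfaceArea = sa,
    SurfaceVolumeRatio = if (vol > 0) sa / vol else 0,
    Sphericity = sphericity, Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d_slice, Maximum2DDiameterColumn = d_col,
    Maximum2DDiameterRow = d_row, MajorAxisLength = major,
    MinorAxisLength = minor, LeastAxisLength = least,
    Elongation = elong, Flatness = flat)
}

glcm_features <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  k_diff <- 0:(ng - 1)
  pxmy <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  pxpy <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(k_diff * pxmy)
  hx <- entropy_bits(px); hy <- entropy_bits(py)
  hxy <- entropy_bits(p)
  eps <- .Machine$double.eps
  hxy1 <- -sum(p * log2(outer(px, py) + eps))
  pq <- outer(px, py)
  hxy2 <- -sum(pq[pq > 0] * log2(pq[pq > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sx > 0 && sy > 0) {
    (sum(i * j * p) - mux * muy) / (sx * sy)
  } else 1
  # MCC: sqrt of the second-largest eigenvalue of Q
  mcc <- if (ng > 1) {
    Q <- matrix(0, ng, ng)
    pos <- px > 0 & py > 0
    sub <- p[pos, pos, drop = FALSE] / py[pos][col(p[pos, pos, drop = FALSE])]
    Qs <- (p[pos, pos, drop = FALSE] / px[pos]) %*% t(sub)
    evq <- sort(Re(eigen(Qs, only.values = TRUE)$values), decreasing = TRUE)
    if (length(evq) > 1) sqrt(max(0, min(1, evq[2]))) else 1
  } else 1
  c(Autocorrelation = sum(i * j * p),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy_bits(pxmy),
    DifferenceVariance = sum((k_diff - da)^2 * pxmy),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1, Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * pxpy),
    SumEntropy = entropy_bits(pxpy),
    SumSquares = sum((i - mux)^2 * p),
    MCC = mcc)
}

# Shared run-length / size-zone style statistics over a gray x size count
# matrix. `n_vox` is the number of mask voxels for the percentage feature.
rl_style_features <- function(P, n_vox, prefix) {
  nr <- sum(P)
  p <- P / nr
  i <- row(p); j <- col(p)
  ri <- rowSums(p); cj <- colSums(p)
  mu_i <- sum(seq_len(nrow(p)) * ri)
  mu_j <- sum(seq_len(ncol(p)) * cj)
  list(gln = sum(rowSums(P)^2) / nr,
       glnn = sum(rowSums(P)^2) / nr^2,
       glv = sum(p * (i - mu_i)^2),
       high = sum(p * i^2),
       low = sum(p / i^2),
       long = sum(p * j^2),
       short = sum(p / j^2),
       long_high = sum(p * i^2 * j^2),
       long_low = sum(p * j^2 / i^2),
       short_high = sum(p * i^2 / j^2),
       short_low = sum(p / (i^2 * j^2)),
       sizen = sum(colSums(P)^2) / nr,
       sizenn = sum(colSums(P)^2) / nr^2,
       sizev = sum(p * (j - mu_j)^2),
       entropy = entropy_bits(p),
       percentage = nr / n_vox)
}

glrlm_features <- function(P, n_vox) {
  s <- rl_style_features(P, n_vox * 13, "run")
  c(GrayLevelNonUniformity = s$gln,
    GrayLevelNonUniformityNormalized = s$glnn,
    GrayLevelVariance = s$glv,
    HighGrayLevelRunEmphasis = s$high,
    LongRunEmphasis = s$long,
    LongRunHighGrayLevelEmphasis = s$long_high,
    LongRunLowGrayLevelEmphasis = s$long_low,
    LowGrayLevelRunEmphasis = s$low,
    RunEntropy = s$entropy,
    RunLengthNonUniformity = s$sizen,
    RunLengthNonUniformityNormalized = s$sizenn,
    RunPercentage = s$percentage,
    RunVariance = s$sizev,
    ShortRunEmphasis = s$short,
    ShortRunHighGrayLevelEmphasis = s$short_high,
    ShortRunLowGrayLevelEmphasis = s$short_low)
}

glszm_features <- function(zones, ngray, n_vox) {
  if (nrow(zones) == 0L) stop("degenerate mask for glszm")
  maxsize <- max(zones[, 2])
  P <- matrix(0, ngray, maxsize)
  for (k in seq_len(nrow(zones))) {
    P[zones[k, 1], zones[k, 2]] <- P[zones[k, 1], zones[k, 2]] + 1
  }
  s <- rl_style_features(P, n_vox, "zone")
  c(GrayLevelNonUniformity = s$gln,
    GrayLevelNonUniformityNormalized = s$glnn,
    GrayLevelVariance = s$glv,
    HighGrayLevelZoneEmphasis = s$high,
    LargeAreaEmphasis = s$long,
    LargeAreaHighGrayLevelEmphasis = s$long_high,
    LargeAreaLowGrayLevelEmphasis = s$long_low,
    LowGrayLevelZoneEmphasis = s$low,
    SizeZoneNonUniformity = s$sizen,
    SizeZoneNonUniformityNormalized = s$sizenn,
    SmallAreaEmphasis = s$short,
    SmallAreaHighGrayLevelEmphasis = s$short_high,
    SmallAreaLowGrayLevelEmphasis = s$short_low,
    ZoneEntropy = s$entropy,
    ZonePercentage = s$percentage,
    ZoneVariance = s$sizev)
}

gldm_features <- function(P) {
  s <- rl_style_features(P, sum(P), "dep")
  c(DependenceEntropy = s$entropy,
    DependenceNonUniformity = s$sizen,
    DependenceNonUniformityNormalized = s$sizenn,
    DependenceVariance = s$sizev,
    GrayLevelNonUniformity = s$gln,
    GrayLevelVariance = s$glv,
    HighGrayLevelEmphasis = s$high,
    LargeDependenceEmphasis = s$long,
    LargeDependenceHighGrayLevelEmphasis = s$long_high,
    LargeDependenceLowGrayLevelEmphasis = s$long_low,
    LowGrayLevelEmphasis = s$low,
    SmallDependenceEmphasis = s$short,
    SmallDependenceHighGrayLevelEmphasis = s$short_high,
    SmallDependenceLowGrayLevelEmphasis = s$short_low)
}

ngtdm_features <- function(ns) {
  n_i <- ns[, 1]; s_i <- ns[, 2]
  N <- sum(n_i)
  p_i <- n_i / N
  lev <- seq_len(nrow(ns))
  act <- p_i > 0
  ngp <- sum(act)
  psum <- sum(p_i * s_i)
  coarse <- if (psum > 0) min(1 / psum, 1e6) else 1e6
  if (ngp > 1) {
    li <- lev[act]; pi_ <- p_i[act]; si <- s_i[act]
    dif2 <- outer(li, li, function(a, b) (a - b)^2)
    contrast <- sum(outer(pi_, pi_) * dif2) / (ngp * (ngp - 1)) * sum(s_i) / N
    denom_busy <- sum(abs(outer(li * pi_, li * pi_, `-`)))
    busy <- if (denom_busy > 0) psum / denom_busy else 0
    num_cplx <- outer(pi_ * si, pi_ * si, `+`) / outer(pi_, pi_, `+`)
    cplx <- sum(abs(outer(li, li, `-`)) * num_cplx) / N
    strength <- if (sum(s_i) > 0) {
      sum(outer(pi_, pi_, `+`) * dif2) / sum(s_i)
    } else 0
  } else {
    contrast <- 0; busy <- 0; cplx <- 0; strength <- 0
  }
  c(Busyness = busy, Coarseness = coarse, Complexity = cplx,
    Contrast = contrast, Strength = strength)
}
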