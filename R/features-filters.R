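# Separable 3D convolution with replicate edge handling, used for the
# Laplacian-of-Gaussian and wavelet filter banks. Kernels are applied per
# axis via a banded matrix multiply (BLAS), which is fast at the volume
# sizes this package targets.

# Convolve along one axis of a 3D array. `origin` is the (1-based) index
# of the kernel tap aligned with the output voxel; centred for odd kernels.
conv_axis <- function(arr, kernel, axis, origin = (length(kernel) + 1L) %/% 2L) {
  dm <- dim(arr)
  d <- dm[axis]
  K <- length(kernel)
  B <- matrix(0, d, d)
  for (m in seq_len(K)) {
    src <- pmin(pmax(seq_len(d) + (m - origin), 1L), d)  # replicate edges
    B[cbind(seq_len(d), src)] <- B[cbind(seq_len(d), src)] + kernel[m]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  out <- B %*% matrix(a, nrow = d)
  out <- array(out, dim = dm[perm])
  aperm(out, order(perm))
}

conv3_sep <- function(arr, kz, ky, kx) {
  conv_axis(conv_axis(conv_axis(arr, kz, 1L), ky, 2L), kx, 3L)
}

# Sampled 1D Gaussian and its second derivative (sigma in voxels).
gauss_kernel <- function(sigma, deriv2 = FALSE) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (!deriv2) return(g)
  (x^2 / sigma^4 - 1 / sigma^2) * g
}

# Laplacian of Gaussian of a 3D (z, y, x) array; sigma in mm, spacing_mm
# per axis (z, y, x).
log_filter <- function(arr, sigma_mm, spacing_mm) {
  sv <- sigma_mm / spacing_mm  # per-axis sigma in voxels
  g <- lapply(sv, gauss_kernel)
  g2 <- lapply(sv, gauss_kernel, deriv2 = TRUE)
  # scale-normalised LoG (multiply second derivatives by sigma^2)
  s2 <- sigma_mm^2
  s2 * (conv3_sep(arr, g2[[1]], g[[2]], g[[3]]) +
          conv3_sep(arr, g[[1]], g2[[2]], g[[3]]) +
          conv3_sep(arr, g[[1]], g[[2]], g2[[3]]))
}

# One-level undecimated 3D Haar decomposition: 8 sub-band images of the
# input size, named by the (x, y, z) filter sequence, e.g. "HLL" = high-
# pass along x, low-pass along y and z.
wavelet_bands <- function(arr) {
  lo <- c(1, 1) / sqrt(2)
  hi <- c(1, -1) / sqrt(2)
  pick <- function(ch) if (ch == "L") lo else hi
  grid <- expand.grid(c("L", "H"), c("L", "H"), c("L", "H"),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  nm <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    bx <- grid[i, 3]; by <- grid[i, 2]; bz <- grid[i, 1]
    nm[i] <- paste0(bx, by, bz)
    out[[i]] <- conv3_sep(arr, pick(bz), pick(by), pick(bx))
  }
  names(out) <- nm
  out
}

# All filtered images implied by a config, cropped to the mask bounding
# box plus a filter-sized margin (values at mask voxels are unaffected by
# the crop as long as the margin covers the kernel radius).
filtered_images <- function(image, mask, cfg, spacing_mm = c(1, 1, 1)) {
  dm <- dim(image)
  pad <- 2L
  if (length(cfg$log_sigmas)) {
    pad <- max(pad, ceiling(4 * max(cfg$log_sigmas) / min(spacing_mm)) + 1L)
  }
  bb <- apply(which(mask, arr.ind = TRUE), 2, range)
  lo <- pmax(bb[1, ] - pad, 1L)
  hi <- pmin(bb[2, ] + pad, dm)
  crop <- image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mcrop <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  imgs <- list(original = crop)
  for (s in cfg$log_sigmas) {
    tag <- sprintf("log-sigma-%s-mm-3D",
                   gsub(".", "-", format(as.numeric(s), nsmall = 1, trim = TRUE),
                        fixed = TRUE))
    imgs[[tag]] <- log_filter(crop, s, spacing_mm)
  }
  if (cfg$wavelet) {
    wb <- wavelet_bands(crop)
    names(wb) <- paste0("wavelet-", names(wb))
    imgs <- c(imgs, wb)
  }
  list(images = imgs, mask = mcrop)
}

# Discretize masked intensities into equal-width gray levels (1..n).
# Default width = ROI range / n_levels; an absolute bin_width may override.
discretize_gray <- function(values, cfg) {
  rng <- range(values)
  if (diff(rng) <= 0) {
    stop("degenerate mask: fewer than 2 distinct gray levels after discretization")
  }
  if (!is.null(cfg$bin_width)) {
    g <- floor((values - rng[1]) / cfg$bin_width) + 1L
  } else {
    step <- diff(rng) / cfg$n_levels
    g <- pmin(floor((values - rng[1]) / step) + 1L, cfg$n_levels)
  }
  as.integer(g)
}
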