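#' Acquisition geometry of a simulated DSC-PWI series
#'
#' Describes the grid on which a synthetic 4D perfusion series is generated.
#' The defaults follow a typical 1.5T stroke protocol (50 dynamic
#' measurements over 20 slices) but use a 64x64 in-plane matrix so that
#' test-scale phantoms stay cheap; 256x256 is supported.
#'
#' @param n_timepoints Number of dynamic measurements (default 50).
#' @param n_slices Number of axial slices (default 20).
#' @param height,width In-plane matrix size in voxels (default 64).
#' @param slice_thickness_mm Slice spacing in mm (default 6.5).
#' @param spacing_mm In-plane voxel spacing in mm (default 0.9).
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_timepoints = 50L, n_slices = 20L,
                             height = 64L, width = 64L,
                             slice_thickness_mm = 6.5, spacing_mm = 0.9) {
  n_timepoints <- as.integer(n_timepoints)
  n_slices <- as.integer(n_slices)
  height <- as.integer(height)
  width <- as.integer(width)
  if (n_timepoints < 4L) stop("n_timepoints must be >= 4")
  if (n_slices < 8L || height < 8L || width < 8L) {
    stop("all spatial dimensions must be >= 8")
  }
  if (slice_thickness_mm <= 0 || spacing_mm <= 0) stop("spacing must be > 0")
  structure(list(n_timepoints = n_timepoints, n_slices = n_slices,
                 height = height, width = width,
                 slice_thickness_mm = slice_thickness_mm,
                 spacing_mm = spacing_mm),
            class = "acquisition_spec")
}

#' Contrast-bolus signal model
#'
#' Parameters of the gamma-variate bolus passage and of the susceptibility
#' signal-loss relation `I(t) = baseline * exp(-contrast_k * C(t))`. The
#' concentration curve is peak-normalised: its maximum equals `amplitude`
#' and occurs at `arrival_t0 + shape_alpha * scale_beta` timepoints.
#'
#' @param baseline Pre-bolus signal intensity, > 0.
#' @param arrival_t0 Bolus arrival time, in timepoints.
#' @param shape_alpha,scale_beta Gamma-variate shape and scale, both > 0.
#' @param amplitude Peak concentration (arbitrary units), >= 0.
#' @param contrast_k Signal-loss coefficient, >= 0.
#' @return An object of class `bolus_model`.
#' @export
bolus_model <- function(baseline = 100, arrival_t0 = 8, shape_alpha = 3,
                        scale_beta = 1.5, amplitude = 1, contrast_k = 0.5) {
  if (baseline <= 0) stop("baseline must be > 0")
  if (shape_alpha <= 0 || scale_beta <= 0) {
    stop("shape_alpha and scale_beta must be > 0")
  }
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(baseline = baseline, arrival_t0 = arrival_t0,
                 shape_alpha = shape_alpha, scale_beta = scale_beta,
                 amplitude = amplitude, contrast_k = contrast_k),
            class = "bolus_model")
}

#' Hypoperfusion lesion specification
#'
#' A lesion is grown inside one hemisphere of the brain mask until a target
#' fraction of that hemisphere's brain voxels is reached. Lesion voxels get
#' an attenuated, delayed bolus: with `attenuation = 1` and `delay = 0`
#' lesion voxels are statistically indistinguishable from normal tissue.
#'
#' @param hemisphere `"left"` or `"right"` (left = lower x indices).
#' @param target_fraction Fraction of hemisphere brain voxels in \[0, 0.7].
#' @param attenuation Bolus amplitude multiplier in \[0, 1] inside the lesion.
#' @param delay Extra arrival delay in timepoints, >= 0.
#' @param geometry_seed Integer seed controlling lesion placement.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(hemisphere = c("left", "right"), target_fraction = 0.3,
                        attenuation = 0.4, delay = 2, geometry_seed = 1L) {
  hemisphere <- match.arg(hemisphere)
  if (target_fraction < 0 || target_fraction > 0.7) {
    stop("target_fraction must be in [0, 0.7]")
  }
  if (attenuation < 0 || attenuation > 1) stop("attenuation must be in [0, 1]")
  if (delay < 0) stop("delay must be >= 0")
  structure(list(hemisphere = hemisphere, target_fraction = target_fraction,
                 attenuation = attenuation, delay = delay,
                 geometry_seed = as.integer(geometry_seed)),
            class = "lesion_spec")
}

#' Gamma-variate concentration curve
#'
#' Peak-normalised gamma-variate bolus model:
#' `C(t) = A * ((t - t0) / (alpha*beta))^alpha * exp(alpha - (t - t0)/beta)`
#' for `t >= t0` and 0 before arrival. The mode is at `t0 + alpha*beta`,
#' where the curve equals `A`.
#'
#' @param t Ascending numeric time grid (timepoint units).
#' @param model A [bolus_model()].
#' @return Numeric vector of concentrations, same length as `t`.
#' @export
gamma_variate_curve <- function(t, model) {
  stopifnot(inherits(model, "bolus_model"))
  if (is.unsorted(t)) stop("t must be ascending")
  dt <- t - model$arrival_t0
  C <- numeric(length(t))
  pos <- dt > 0
  a <- model$shape_alpha
  b <- model$scale_beta
  C[pos] <- model$amplitude * (dt[pos] / (a * b))^a * exp(a - dt[pos] / b)
  C
}

#' Signal intensity from concentration
#'
#' DSC signal-loss relation `I(t) = baseline * exp(-contrast_k * C(t))`:
#' the signal dips where concentration peaks, and never exceeds baseline.
#'
#' @param C Non-negative concentration sequence.
#' @param model A [bolus_model()].
#' @return Intensity sequence, same length as `C`.
#' @export
signal_from_concentration <- function(C, model) {
  stopifnot(inherits(model, "bolus_model"))
  if (any(C < 0)) stop("C must be >= 0")
  model$baseline * exp(-model$contrast_k * C)
}

# Axis-aligned ellipsoidal brain mask on the (z, y, x) grid.
make_brain_mask <- function(acq) {
  Z <- acq$n_slices; H <- acq$height; W <- acq$width
  cz <- (Z + 1) / 2; cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rz <- 0.48 * Z; ry <- 0.42 * H; rx <- 0.42 * W
  z <- ((seq_len(Z) - cz) / rz)^2
  y <- ((seq_len(H) - cy) / ry)^2
  x <- ((seq_len(W) - cx) / rx)^2
  d <- outer(outer(z, y, `+`), x, `+`)
  array(d <= 1, dim = c(Z, H, W))
}

# Indices of the x-columns belonging to each hemisphere; an odd midline
# column belongs to neither.
hemisphere_columns <- function(W) {
  half <- W %/% 2
  list(left = seq_len(half), right = seq.int(W - half + 1L, W))
}

# Grow a 6-connected lesion from a random seed voxel inside one hemisphere
# until `target_fraction` of the hemisphere's brain voxels is reached.
grow_lesion <- function(brain_mask, hemisphere, target_fraction, seed) {
  dm <- dim(brain_mask)
  Z <- dm[1]; H <- dm[2]; W <- dm[3]
  cols <- hemisphere_columns(W)[[hemisphere]]
  hemi <- array(FALSE, dm)
  hemi[, , cols] <- brain_mask[, , cols]
  n_hemi <- sum(hemi)
  target_n <- round(target_fraction * n_hemi)
  lesion <- array(FALSE, dm)
  if (target_n == 0L) return(lesion)
  idx <- which(hemi)
  set.seed(seed)
  # seed voxel away from the hemisphere boundary where possible: prefer the
  # inner half of candidate voxels by distance to the hemisphere centroid
  ar <- arrayInd(idx, dm)
  ctr <- colMeans(ar)
  d2 <- rowSums((sweep(ar, 2, ctr))^2)
  pool <- idx[d2 <= stats::quantile(d2, 0.25)]
  start <- pool[sample.int(length(pool), 1L)]
  lesion[start] <- TRUE
  frontier <- start
  n <- 1L
  off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
               c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  while (n < target_n) {
    if (length(frontier) == 0L) {
      stop("lesion growth exhausted the hemisphere before reaching target_fraction")
    }
    fa <- arrayInd(frontier, dm)
    cand <- do.call(rbind, lapply(seq_len(nrow(off)), function(k) {
      sweep(fa, 2, off[k, ], `+`)
    }))
    ok <- cand[, 1] >= 1 & cand[, 1] <= Z & cand[, 2] >= 1 & cand[, 2] <= H &
      cand[, 3] >= 1 & cand[, 3] <= W
    cand <- cand[ok, , drop = FALSE]
    ci <- unique(cand[, 1] + (cand[, 2] - 1L) * Z + (cand[, 3] - 1L) * Z * H)
    ci <- ci[hemi[ci] & !lesion[ci]]
    if (length(ci) == 0L) {
      stop("lesion growth exhausted the hemisphere before reaching target_fraction")
    }
    ci <- ci[sample.int(length(ci))]
    take <- min(length(ci), target_n - n)
    lesion[ci[seq_len(take)]] <- TRUE
    frontier <- ci
    n <- n + take
  }
  lesion
}

#' Generate a synthetic 4D DSC-PWI phantom
#'
#' Builds an ellipsoidal brain on the acquisition grid, grows a
#' hypoperfusion lesion (HA) in one hemisphere, mirrors it about the
#' midsagittal plane to define the normal-area (NA) reference region, and
#' synthesises per-voxel time-intensity curves: a gamma-variate bolus
#' converted to signal loss, with per-voxel jitter of arrival time and
#' amplitude (+/- 5%) so texture is non-degenerate, and additive Gaussian
#' noise. Lesion voxels receive an attenuated, delayed bolus, reproducing
#' the hallmark of hypoperfused tissue: a much smaller signal drop than in
#' the mirrored normal region.
#'
#' @param acq An [acquisition_spec()].
#' @param bolus A [bolus_model()].
#' @param lesion A [lesion_spec()].
#' @param noise_sd Additive Gaussian noise standard deviation, signal units.
#' @param seed Integer seed; the phantom is a deterministic function of its
#'   arguments and this seed.
#' @return An object of class `phantom4d`: a list with `volume`
#'   (t, z, y, x array), `brain_mask`, `ha_mask`, `na_mask` (z, y, x logical
#'   arrays), `achieved_fraction`, `noise_sd`, `seed`, and the input specs.
#' @export
generate_phantom <- function(acq = acquisition_spec(), bolus = bolus_model(),
                             lesion = lesion_spec(), noise_sd = 1, seed = 1L) {
  stopifnot(inherits(acq, "acquisition_spec"), inherits(bolus, "bolus_model"),
            inherits(lesion, "lesion_spec"))
  seed <- as.integer(seed)
  brain <- make_brain_mask(acq)
  ha <- grow_lesion(brain, lesion$hemisphere, lesion$target_fraction,
                    seed = lesion$geometry_seed + seed)
  na <- mirror_roi(ha)
  cols <- hemisphere_columns(acq$width)[[lesion$hemisphere]]
  n_hemi <- sum(brain[, , cols])
  achieved <- if (n_hemi > 0) sum(ha) / n_hemi else 0

  Tn <- acq$n_timepoints
  t_grid <- seq_len(Tn) - 1
  nb <- sum(brain)
  set.seed(seed + 1L)
  # per-voxel heterogeneity: +/-5% jitter on arrival and amplitude
  jit_t0 <- stats::runif(nb, -0.05, 0.05) * max(bolus$arrival_t0, 1)
  jit_amp <- 1 + stats::runif(nb, -0.05, 0.05)
  idx <- which(brain)
  in_ha <- ha[idx]
  amp <- bolus$amplitude * jit_amp * ifelse(in_ha, lesion$attenuation, 1)
  t0 <- bolus$arrival_t0 + jit_t0 + ifelse(in_ha, lesion$delay, 0)

  a <- bolus$shape_alpha; b <- bolus$scale_beta
  dt <- outer(t0, t_grid, function(t0v, tv) tv - t0v)  # nb x T
  Cm <- matrix(0, nb, Tn)
  pos <- dt > 0
  Cm[pos] <- (dt[pos] / (a * b))^a * exp(a - dt[pos] / b)
  Cm <- Cm * amp
  Im <- bolus$baseline * exp(-bolus$contrast_k * Cm)
  Im <- Im + matrix(stats::rnorm(nb * Tn, sd = noise_sd), nb, Tn)
  Im <- pmax(Im, 1e-6)

  vol <- array(0, dim = c(Tn, acq$n_slices, acq$height, acq$width))
  nvox <- prod(dim(brain))
  for (n in seq_len(Tn)) {
    sl <- numeric(nvox)
    sl[idx] <- Im[, n]
    vol[n, , , ] <- sl
  }
  structure(list(volume = vol, brain_mask = brain, ha_mask = ha, na_mask = na,
                 achieved_fraction = achieved, noise_sd = noise_sd,
                 seed = seed, acq = acq, bolus = bolus, lesion = lesion),
            class = "phantom4d")
}

#' @export
print.phantom4d <- function(x, ...) {
  dm <- dim(x$volume)
  cat(sprintf("<phantom4d> %d timepoints, %dx%dx%d (z,y,x)\n",
              dm[1], dm[2], dm[3], dm[4]))
  cat(sprintf("  brain %d voxels; HA %d; NA %d; lesion fraction %.3f\n",
              sum(x$brain_mask), sum(x$ha_mask), sum(x$na_mask),
              x$achieved_fraction))
  invisible(x)
}

#' Generate a cohort of phantoms
#'
#' Draws one phantom per subject with lesion fractions sampled from
#' `fraction_range` (uniform) and a random lesioned hemisphere. Per-subject
#' seeds are derived deterministically from the cohort seed, so the same
#' seed reproduces the cohort bit for bit.
#'
#' @param n_subjects Number of phantoms, >= 1.
#' @param acq,bolus Acquisition and bolus models shared by all subjects.
#' @param fraction_range Length-2 range for uniform lesion fractions.
#' @param attenuation,delay Lesion bolus parameters shared by all subjects.
#' @param noise_sd Additive noise standard deviation.
#' @param seed Cohort seed.
#' @return List of `n_subjects` [generate_phantom()] results.
#' @export
generate_cohort <- function(n_subjects, acq = acquisition_spec(),
                            bolus = bolus_model(),
                            fraction_range = c(0.02, 0.5),
                            attenuation = 0.4, delay = 2,
                            noise_sd = 1, seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max %/% 4L, n_subjects)
  fractions <- stats::runif(n_subjects, fraction_range[1], fraction_range[2])
  sides <- sample(c("left", "right"), n_subjects, replace = TRUE)
  lapply(seq_len(n_subjects), function(i) {
    generate_phantom(acq, bolus,
                     lesion_spec(hemisphere = sides[i],
                                 target_fraction = fractions[i],
                                 attenuation = attenuation, delay = delay,
                                 geometry_seed = 0L),
                     noise_sd = noise_sd, seed = sub_seeds[i])
  })
}

#' Write a phantom to NIfTI-1 files
#'
#' The 4D volume is written as (x, y, z, t) NIfTI (the on-disk convention),
#' the three masks as 3D uint8 images, and a JSON manifest records seed,
#' fractions and file paths.
#'
#' @param phantom A `phantom4d`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the manifest list.
#' @export
write_phantom_nifti <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "phantom4d"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # (t,z,y,x) -> (x,y,z,t) for NIfTI
  vol <- aperm(phantom$volume, c(4, 3, 2, 1))
  sp <- c(phantom$acq$spacing_mm, phantom$acq$spacing_mm,
          phantom$acq$slice_thickness_mm)
  paths <- list(volume = file.path(dir, paste0(prefix, "_4d.nii.gz")),
                brain = file.path(dir, paste0(prefix, "_brain.nii.gz")),
                ha = file.path(dir, paste0(prefix, "_ha.nii.gz")),
                na = file.path(dir, paste0(prefix, "_na.nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(sp, 1)), paths$volume)
  for (m in c("brain", "ha", "na")) {
    msk <- aperm(phantom[[paste0(m, "_mask")]], c(3, 2, 1))
    storage.mode(msk) <- "integer"
    RNifti::writeNifti(RNifti::asNifti(msk, pixdim = sp, datatype = "uint8"),
                       paths[[m]])
  }
  manifest <- list(seed = phantom$seed,
                   achieved_fraction = phantom$achieved_fraction,
                   noise_sd = phantom$noise_sd, files = paths)
  jsonlite::write_json(manifest,
                       file.path(dir, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
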