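#' Decompose a 4D series into per-timepoint 3D images
#'
#' @param volume 4D (t, z, y, x) array.
#' @return List of T 3D (z, y, x) arrays; element `n + 1` is the image at
#'   0-based time index `n`.
#' @export
decompose_4d <- function(volume) {
  dm <- dim(volume)
  if (is.null(dm) || length(dm) != 4L) stop("volume must be a 4D array")
  lapply(seq_len(dm[1]), function(n) {
    array(volume[n, , , ], dim = dm[2:4])
  })
}

# Texture + first-order features for one (already filtered) image over a
# cropped mask. Returns the 93-element non-shape vector (or a family
# subset).
intensity_features <- function(img, mask, cfg, families, voxel_volume) {
  x <- img[mask]
  gray <- tryCatch(discretize_gray(x, cfg), error = function(e) {
    stop(sprintf("%s (families: %s)", conditionMessage(e),
                 paste(families, collapse = ",")), call. = FALSE)
  })
  ngray <- max(gray)
  dims <- dim(mask)
  gvol <- integer(length(mask))
  gvol[which(mask)] <- gray
  out <- numeric(0)
  if ("firstorder" %in% families) {
    out <- c(out, stats::setNames(
      firstorder_features(x, gray, ngray, voxel_volume),
      paste0("firstorder_", .firstorder_features)))
  }
  if ("glcm" %in% families) {
    P <- .cpp_glcm(gvol, as.logical(mask), dims, ngray)
    out <- c(out, stats::setNames(glcm_features(P),
                                  paste0("glcm_", .glcm_features)))
  }
  if ("glrlm" %in% families) {
    P <- .cpp_glrlm(gvol, as.logical(mask), dims, ngray)
    out <- c(out, stats::setNames(glrlm_features(P, sum(mask)),
                                  paste0("glrlm_", .glrlm_features)))
  }
  if ("glszm" %in% families) {
    z <- .cpp_glszm_zones(gvol, as.logical(mask), dims)
    out <- c(out, stats::setNames(glszm_features(z, ngray, sum(mask)),
                                  paste0("glszm_", .glszm_features)))
  }
  if ("ngtdm" %in% families) {
    ns <- .cpp_ngtdm(gvol, as.logical(mask), dims, ngray)
    out <- c(out, stats::setNames(ngtdm_features(ns),
                                  paste0("ngtdm_", .ngtdm_features)))
  }
  if ("gldm" %in% families) {
    P <- .cpp_gldm(gvol, as.logical(mask), dims, ngray, 0L)
    out <- c(out, stats::setNames(gldm_features(P),
                                  paste0("gldm_", .gldm_features)))
  }
  out
}

#' Radiomics features of one 3D timepoint image
#'
#' Computes the configured feature families on the original image and, for
#' the non-shape families, on every Laplacian-of-Gaussian and wavelet
#' sub-band image. With the default configuration this yields exactly
#' 1,316 named values (107 original + 5 x 93 LoG + 8 x 93 wavelet). Shape
#' features depend on the mask (and voxel spacing) only.
#'
#' @param image 3D (z, y, x) numeric array.
#' @param mask 3D logical array, >= 2 voxels with >= 2 distinct gray
#'   levels after discretization.
#' @param cfg An [extraction_config()].
#' @param spacing_mm Voxel spacing (z, y, x) in mm.
#' @param time_index Optional 0-based time index appended to names; `NULL`
#'   leaves names unsuffixed.
#' @param .shape Optional precomputed shape vector (mask-only, so it is
#'   identical across timepoints and can be reused).
#' @return Named numeric vector.
#' @export
extract_timepoint_features <- function(image, mask, cfg = extraction_config(),
                                       spacing_mm = c(1, 1, 1),
                                       time_index = NULL, .shape = NULL) {
  stopifnot(inherits(cfg, "extraction_config"))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (sum(mask) < 2L) stop("degenerate mask: fewer than 2 voxels (shape)")
  voxel_volume <- prod(spacing_mm)
  nonshape <- intersect(cfg$families, .texture_families)
  out <- numeric(0)
  if ("shape" %in% cfg$families) {
    sh <- if (is.null(.shape)) shape_features(mask, spacing_mm) else .shape
    out <- c(out, stats::setNames(sh, paste0("original_shape_",
                                             .shape_features)))
  }
  if (length(nonshape)) {
    fi <- filtered_images(image, mask, cfg, spacing_mm)
    for (tag in names(fi$images)) {
      v <- intensity_features(fi$images[[tag]], fi$mask, cfg, nonshape,
                              voxel_volume)
      names(v) <- paste0(tag, "_", names(v))
      out <- c(out, v)
    }
  }
  if (!is.null(time_index)) {
    names(out) <- paste0(names(out), "_", as.integer(time_index))
  }
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)][1]
    stop("non-finite feature value: ", bad)
  }
  out
}

#' Radiomics features of a full 4D series
#'
#' Concatenates [extract_timepoint_features()] over all timepoints, with
#' 0-based time-index suffixes. At the default configuration and T = 50
#' this yields 65,800 features.
#'
#' @inheritParams extract_timepoint_features
#' @param volume 4D (t, z, y, x) array.
#' @return Named numeric vector of length T x (per-timepoint count).
#' @export
extract_series_features <- function(volume, mask, cfg = extraction_config(),
                                    spacing_mm = c(1, 1, 1)) {
  imgs <- decompose_4d(volume)
  mask <- array(as.logical(mask), dim = dim(mask))
  shape <- if ("shape" %in% cfg$families) shape_features(mask, spacing_mm)
  out <- vector("list", length(imgs))
  for (n in seq_along(imgs)) {
    out[[n]] <- tryCatch(
      extract_timepoint_features(imgs[[n]], mask, cfg, spacing_mm,
                                 time_index = n - 1L, .shape = shape),
      error = function(e) {
        stop(sprintf("timepoint %d: %s", n - 1L, conditionMessage(e)),
             call. = FALSE)
      })
  }
  unlist(out)
}

#' Extract a named subset of features
#'
#' Recomputes only the timepoints, filters and families needed to produce
#' the requested feature names (used by the lesion-proportion experiment,
#' which re-extracts a small selected set on slab masks).
#'
#' @param volume 4D (t, z, y, x) array.
#' @param mask 3D logical array.
#' @param names Character vector of rendered feature names.
#' @param cfg An [extraction_config()] (controls discretization).
#' @param spacing_mm Voxel spacing (z, y, x) in mm.
#' @return Named numeric vector in the order of `names`.
#' @export
extract_named_features <- function(volume, mask, names,
                                   cfg = extraction_config(),
                                   spacing_mm = c(1, 1, 1)) {
  p <- parse_feature_name(names)
  dm <- dim(volume)
  if (any(p$time_index >= dm[1])) stop("time_index beyond series length")
  mask <- array(as.logical(mask), dim = dim(mask))
  out <- stats::setNames(numeric(length(names)), names)
  shape_cache <- NULL
  for (n in sort(unique(p$time_index))) {
    sel <- p$time_index == n
    fams <- unique(p$family[sel])
    tags <- unique(p$filter_tag[sel])
    sub <- extraction_config(
      families = fams,
      log_sigmas = as.numeric(gsub("-", ".", fixed = TRUE,
                                   sub("^log-sigma-(.*)-mm-3D$", "\\1",
                                       grep("^log-sigma-", tags, value = TRUE)))),
      wavelet = any(startsWith(tags, "wavelet-")),
      n_levels = cfg$n_levels, bin_width = cfg$bin_width)
    if ("shape" %in% fams && is.null(shape_cache)) {
      shape_cache <- shape_features(mask, spacing_mm)
    }
    img <- array(volume[n + 1L, , , ], dim = dm[2:4])
    v <- extract_timepoint_features(img, mask, sub, spacing_mm,
                                    time_index = n, .shape = shape_cache)
    hit <- intersect(names[sel], base::names(v))
    if (length(hit) < sum(sel)) {
      stop("could not recompute feature(s): ",
           paste(setdiff(names[sel], hit), collapse = ", "))
    }
    out[hit] <- v[hit]
  }
  out
}
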