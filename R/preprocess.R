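#' Temporal smoothing configuration
#'
#' The DSC-PWI series is smoothed voxel-by-voxel with a triple moving
#' average: three successive passes of a centred length-3 mean filter with
#' replicate (repeat-pad) edge handling, which leaves constant series
#' unchanged.
#'
#' @param window Kernel length; only the odd value 3 is supported.
#' @param passes Number of successive passes, >= 1 (default 3).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(window = 3L, passes = 3L) {
  if (window != 3L) stop("only a 1x3 kernel is supported")
  if (passes < 1L) stop("passes must be >= 1")
  structure(list(window = 3L, passes = as.integer(passes),
                 edge_mode = "repeat-pad"),
            class = "smoothing_config")
}

#' Smooth every voxel's time-intensity curve
#'
#' Applies the triple moving average along the time axis (first dimension)
#' of a 4D (t, z, y, x) array.
#'
#' @param volume 4D numeric array (t, z, y, x) with >= 3 timepoints.
#' @param cfg A [smoothing_config()].
#' @return Array of the same shape.
#' @export
smooth_time_series <- function(volume, cfg = smoothing_config()) {
  stopifnot(inherits(cfg, "smoothing_config"))
  dm <- dim(volume)
  if (is.null(dm) || length(dm) != 4L) stop("volume must be a 4D array")
  Tn <- dm[1]
  if (Tn < 3L) stop("volume must have >= 3 timepoints")
  m <- matrix(volume, nrow = Tn)
  for (p in seq_len(cfg$passes)) {
    pad <- rbind(m[1, , drop = FALSE], m, m[Tn, , drop = FALSE])
    m <- (pad[seq_len(Tn), , drop = FALSE] +
            pad[seq_len(Tn) + 1L, , drop = FALSE] +
            pad[seq_len(Tn) + 2L, , drop = FALSE]) / 3
  }
  array(m, dim = dm)
}

#' Mirror a mask about the midsagittal plane
#'
#' Reflects a 3D (z, y, x) mask about the mid-x plane `x = (W + 1) / 2`
#' (1-based). The mirrored hypoperfusion mask defines the normal-area
#' reference region in the contralateral hemisphere. Mirroring is an
#' involution and preserves voxel count.
#'
#' @param mask 3D logical (or 0/1) array in (z, y, x) order.
#' @return Logical array of the same shape.
#' @export
mirror_roi <- function(mask) {
  dm <- dim(mask)
  if (is.null(dm) || length(dm) != 3L) stop("mask must be a 3D array")
  out <- mask[, , rev(seq_len(dm[3])), drop = FALSE]
  storage.mode(out) <- "logical"
  out
}

#' Split a brain into hemisphere samples
#'
#' Divides the x axis in two. With even width the split is exact; with odd
#' width the midline column is assigned to neither hemisphere (so the two
#' samples cover the brain minus at most one column and never overlap).
#' This is how 80 subjects yield 160 hemisphere samples.
#'
#' @param volume 4D (t, z, y, x) array.
#' @param brain_mask 3D (z, y, x) logical array.
#' @return List with elements `left` and `right`, each a list holding
#'   `volume` (the full 4D array), `mask` (the hemisphere-restricted brain
#'   mask) and `side`.
#' @export
split_hemispheres <- function(volume, brain_mask) {
  dm <- dim(brain_mask)
  if (length(dm) != 3L) stop("brain_mask must be 3D")
  W <- dm[3]
  cols <- hemisphere_columns(W)
  out <- lapply(c(left = "left", right = "right"), function(side) {
    m <- array(FALSE, dm)
    m[, , cols[[side]]] <- brain_mask[, , cols[[side]]]
    list(volume = volume, mask = m, side = side)
  })
  out
}

#' Build a feature table
#'
#' A light container for a samples x features numeric matrix with sample
#' identifiers and sample roles (e.g. `"HA"` / `"NA"` or hemisphere sides).
#'
#' @param values Numeric matrix with feature names as column names.
#' @param sample_ids Character vector, one id per row.
#' @param roles Character vector, one role per row.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          roles = rep(NA_character_, nrow(values))) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have feature names")
  if (anyDuplicated(colnames(values))) stop("duplicate feature names")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  rownames(values) <- sample_ids
  structure(list(values = values, sample_ids = sample_ids, roles = roles),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Accept a feature_table or a plain named matrix.
ft_values <- function(table) {
  if (inherits(table, "feature_table")) table$values else as.matrix(table)
}

#' Mean-centred range normalisation of features
#'
#' Normalises each feature column as `(x - mean(x)) / (max(x) - min(x))`,
#' so every non-constant column has range exactly 1 (this is deliberately
#' the mean-centred variant, not min-max scaling; `method = "min_max"`
#' gives `(x - min) / range` instead). Constant columns cannot be scaled
#' and are dropped with a warning.
#'
#' @param table A [feature_table()] or named numeric matrix.
#' @param method `"mean_range"` (default) or `"min_max"`.
#' @return Same class as the input, with constant columns removed.
#' @export
normalize_features <- function(table, method = c("mean_range", "min_max")) {
  method <- match.arg(method)
  x <- ft_values(table)
  rng <- apply(x, 2, function(v) diff(range(v)))
  const <- rng == 0 | !is.finite(rng)
  if (any(const)) {
    warning(sprintf("dropping %d constant feature column(s)", sum(const)))
    x <- x[, !const, drop = FALSE]
    rng <- rng[!const]
  }
  ctr <- if (method == "mean_range") colMeans(x) else apply(x, 2, min)
  out <- sweep(sweep(x, 2, ctr), 2, rng, `/`)
  if (inherits(table, "feature_table")) {
    feature_table(out, table$sample_ids, table$roles)
  } else {
    out
  }
}
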