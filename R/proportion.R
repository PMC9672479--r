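#' Middle-S slab of a mask or volume
#'
#' Selects the S central slices along z. With 0-based slice indices the
#' slab covers `[floor((Z - S) / 2), floor((Z - S) / 2) + S)`.
#'
#' @param x 3D (z, y, x) or 4D (t, z, y, x) array.
#' @param S Slab height in slices, `S <= Z`.
#' @return Array of the same kind with Z replaced by S.
#' @export
middle_slab <- function(x, S) {
  dm <- dim(x)
  zaxis <- if (length(dm) == 4L) 2L else 1L
  Z <- dm[zaxis]
  if (S > Z) stop("slab height exceeds number of slices")
  start <- floor((Z - S) / 2) + 1L   # 1-based
  idx <- seq.int(start, start + S - 1L)
  if (length(dm) == 4L) {
    x[, idx, , , drop = FALSE]
  } else {
    x[idx, , , drop = FALSE]
  }
}

#' Lesion-proportion label
#'
#' The fraction of slab brain voxels that are ischemic; the sample is
#' positive when that fraction strictly exceeds the reference threshold
#' RT.
#'
#' @param ha_slab 3D logical lesion slab.
#' @param brain_slab 3D logical brain slab (non-empty).
#' @param RT Reference threshold in \[0, 1).
#' @return Integer 0/1.
#' @export
proportion_label <- function(ha_slab, brain_slab, RT) {
  nb <- sum(brain_slab)
  if (nb == 0L) stop("empty brain slab")
  frac <- sum(ha_slab & brain_slab) / nb
  as.integer(frac > RT)
}

# Hemisphere samples of a cohort: per phantom, the left and right
# hemisphere (volume + hemisphere brain mask + lesion mask restricted to
# that hemisphere).
cohort_hemispheres <- function(cohort) {
  out <- list()
  for (i in seq_along(cohort)) {
    ph <- cohort[[i]]
    hs <- split_hemispheres(ph$volume, ph$brain_mask)
    for (side in c("left", "right")) {
      h <- hs[[side]]
      out[[length(out) + 1L]] <- list(
        subject = i, side = side, volume = h$volume, mask = h$mask,
        ha = ph$ha_mask & h$mask)
    }
  }
  out
}

#' Lesion-proportion classification sweep
#'
#' The proportion experiment: every phantom is split into hemisphere
#' samples; for each slab height S the features named in the top-6 union
#' are recomputed on the hemisphere's middle-S slab mask; for each
#' reference threshold RT the samples are labelled by whether their slab
#' lesion fraction exceeds RT, the Lasso selector re-selects a subset
#' F'_RT_S from the recomputed features, and the classifier bank is
#' cross-validated on it. The composite score multiplies the set's mean
#' metric by a family-style coefficient: the mean metric of the full
#' recomputed top-6 union under the same configuration's labels.
#'
#' @param cohort List of phantoms from [generate_cohort()].
#' @param top6_features Character vector of feature names (the top-6
#'   union), or a `feature_set`.
#' @param S_values Slab heights (default `c(3, 4, 5)`).
#' @param RT_grid Reference thresholds (default `seq(0, 0.39, 0.01)`).
#' @param extraction Extraction config used for the slab recomputation.
#' @param selector A [selector_config()].
#' @param models A [model_bank()] (subset allowed); `NULL` skips model
#'   fitting and produces labels and selections only.
#' @param k,seed Cross-validation folds and seed.
#' @param label_only If TRUE, build the configurations and labels without
#'   feature extraction or model fitting.
#' @return Data frame with one row per (S, RT) configuration: label
#'   counts, degeneracy flag, selected-feature count, mean metrics and CS;
#'   the selections are attached as attribute `"selected"` and the
#'   per-model metric rows as attribute `"metrics"`.
#' @export
sweep_rt <- function(cohort, top6_features, S_values = c(3, 4, 5),
                     RT_grid = seq(0, 0.39, by = 0.01),
                     extraction = extraction_config(),
                     selector = selector_config(),
                     models = model_bank(), k = 10L, seed = 1L,
                     label_only = FALSE) {
  nms <- if (inherits(top6_features, "feature_set")) {
    top6_features$members$name
  } else {
    as.character(top6_features)
  }
  if (!length(nms)) stop("top-6 union is empty")
  hemis <- cohort_hemispheres(cohort)
  rows <- list()
  selections <- list()
  metric_rows <- list()
  metric_names <- c("Acc", "Pre", "Auc", "F1", "Recall")
  for (S in S_values) {
    fracs <- vapply(hemis, function(h) {
      bs <- middle_slab(h$mask, S)
      hs <- middle_slab(h$ha, S)
      if (sum(bs) == 0L) return(0)
      sum(hs & bs) / sum(bs)
    }, numeric(1))
    feats <- NULL
    if (!label_only) {
      feats <- t(vapply(hemis, function(h) {
        extract_named_features(middle_slab(h$volume, S),
                               middle_slab(h$mask, S), nms, extraction)
      }, numeric(length(nms))))
      colnames(feats) <- nms
      feats <- normalize_features(feats)
    }
    for (RT in RT_grid) {
      labels <- as.integer(fracs > RT)
      degenerate <- length(unique(labels)) < 2L ||
        min(table(labels)) < max(2L, if (is.null(models)) 0L else k)
      row <- data.frame(S = S, RT = RT, n = length(labels),
                        n_pos = sum(labels), degenerate = degenerate,
                        n_selected = NA_integer_, cs = NA_real_)
      for (mn in metric_names) row[[paste0("m", mn)]] <- NA_real_
      key <- sprintf("S%d_RT%.2f", S, RT)
      if (!label_only && !degenerate) {
        fsel <- select_features("Lasso", feats, labels, selector,
                                attributes = FALSE)
        if (nrow(fsel$members) == 0L) {
          # fall back to the full recomputed top-6 union for this config
          fsel$members <- data.frame(name = colnames(ft_values(feats)),
                                     score = 0)
        }
        selections[[key]] <- fsel$members$name
        row$n_selected <- nrow(fsel$members)
        if (!is.null(models)) {
          mm <- crossval_metrics(fsel, feats, labels, models, k = k,
                                 seed = seed)
          h_cfg <- mean(crossval_metrics(colnames(ft_values(feats)),
                                         feats, labels, models, k = k,
                                         seed = seed))
          for (mn in metric_names) row[[paste0("m", mn)]] <- mean(mm[, mn])
          row$cs <- h_cfg * mean(mm)
          metric_rows[[key]] <- data.frame(S = S, RT = RT,
                                           model = rownames(mm),
                                           as.data.frame(mm),
                                           row.names = NULL)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "selected") <- selections
  attr(out, "metrics") <- if (length(metric_rows)) {
    do.call(rbind, metric_rows)
  }
  rownames(out) <- NULL
  out
}
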