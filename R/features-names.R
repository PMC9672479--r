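# Base feature names per family. The per-family cardinalities are part of
# the package contract: Shape 14, FirstOrder 18, GLCM 24, GLRLM 16,
# GLSZM 16, NGTDM 5, GLDM 14 (107 on the original image; the 93 non-shape
# features recur on every filtered image).

.shape_features <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
  "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
  "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness")

.firstorder_features <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

.glcm_features <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares", "MCC")

.glrlm_features <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

.glszm_features <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")

.ngtdm_features <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                     "Strength")

.gldm_features <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

.family_features <- list(shape = .shape_features,
                         firstorder = .firstorder_features,
                         glcm = .glcm_features,
                         glrlm = .glrlm_features,
                         glszm = .glszm_features,
                         ngtdm = .ngtdm_features,
                         gldm = .gldm_features)

.all_families <- names(.family_features)
.texture_families <- setdiff(.all_families, "shape")

#' Feature extraction configuration
#'
#' Controls which radiomics families and image filters are computed. With
#' the defaults a single 3D timepoint yields exactly 1,316 features:
#' 107 on the original image (14 shape + 93 intensity/texture), plus the
#' 93 non-shape features on each of 5 Laplacian-of-Gaussian images
#' (sigma 1..5 mm) and 8 one-level 3D wavelet sub-bands.
#'
#' @param families Character subset of
#'   `c("shape","firstorder","glcm","glrlm","glszm","ngtdm","gldm")`.
#' @param log_sigmas Numeric vector of LoG sigmas in mm (default `1:5`);
#'   `NULL` or empty disables LoG images.
#' @param wavelet Logical; compute the 8 one-level 3D Haar sub-bands.
#' @param n_levels Number of equal-width gray levels the ROI intensity
#'   range is divided into before texture-matrix computation (default 25,
#'   i.e. bin width = ROI range / 25, invariant to intensity units).
#' @param bin_width Optional absolute bin width overriding `n_levels`.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(families = .all_families, log_sigmas = 1:5,
                              wavelet = TRUE, n_levels = 25L,
                              bin_width = NULL) {
  families <- match.arg(families, .all_families, several.ok = TRUE)
  if (!is.null(log_sigmas) && length(log_sigmas) &&
      any(log_sigmas <= 0)) stop("log_sigmas must be > 0")
  if (n_levels < 2L) stop("n_levels must be >= 2")
  structure(list(families = families,
                 log_sigmas = if (is.null(log_sigmas)) numeric(0) else log_sigmas,
                 wavelet = isTRUE(wavelet),
                 n_levels = as.integer(n_levels),
                 bin_width = bin_width),
            class = "extraction_config")
}

# Filter tags implied by a config, in canonical order.
config_filter_tags <- function(cfg) {
  tags <- "original"
  for (s in cfg$log_sigmas) {
    tags <- c(tags, sprintf("log-sigma-%s-mm-3D",
                            gsub(".", "-",
                                 format(as.numeric(s), nsmall = 1, trim = TRUE),
                                 fixed = TRUE)))
  }
  if (cfg$wavelet) {
    bands <- apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")), 1,
                   function(r) paste0(r[3], r[2], r[1]))
    tags <- c(tags, paste0("wavelet-", bands))
  }
  tags
}

# Number of features one timepoint yields under a config.
config_feature_count <- function(cfg) {
  base <- sum(lengths(.family_features[cfg$families]))
  nonshape <- sum(lengths(.family_features[setdiff(cfg$families, "shape")]))
  n_filtered <- length(config_filter_tags(cfg)) - 1L
  base + n_filtered * nonshape
}

#' Render a feature name
#'
#' Feature names follow `<filter>_<family>_<base>_<n>`, e.g.
#' `"log-sigma-1-0-mm-3D_firstorder_Skewness_17"`: the radiomics feature of
#' the 3D image at (0-based) time index 17. [parse_feature_name()] is the
#' exact inverse.
#'
#' @param filter_tag Filter tag (`"original"`, `"log-sigma-<s>-mm-3D"`,
#'   `"wavelet-<band>"`).
#' @param family Lower-case family tag (e.g. `"firstorder"`).
#' @param base Base feature name (e.g. `"Skewness"`).
#' @param time_index 0-based time index.
#' @return Character name.
#' @export
render_feature_name <- function(filter_tag, family, base, time_index) {
  paste(filter_tag, family, base, time_index, sep = "_")
}

#' Parse a feature name
#'
#' @param name Character vector of rendered feature names.
#' @return Data frame with columns `filter_tag`, `family`, `base`,
#'   `time_index`.
#' @seealso [render_feature_name()]
#' @export
parse_feature_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("unparseable feature name(s): ", paste(head(name[bad], 3), collapse = ", "))
  }
  m <- do.call(rbind, parts)
  fam_ok <- m[, 2] %in% .all_families
  tag_ok <- m[, 1] == "original" | startsWith(m[, 1], "log-sigma-") |
    startsWith(m[, 1], "wavelet-")
  ti <- suppressWarnings(as.integer(m[, 4]))
  if (any(!fam_ok | !tag_ok | is.na(ti) | ti < 0)) {
    stop("invalid feature name component")
  }
  data.frame(filter_tag = m[, 1], family = m[, 2], base = m[, 3],
             time_index = ti, stringsAsFactors = FALSE)
}

#' Radiomics group of a feature
#'
#' Maps a feature name to one of the nine reported groups. The filter tag
#' dominates: any feature computed on a Laplacian-of-Gaussian image belongs
#' to the Log-sigma group and any feature on a wavelet sub-band to the
#' Wavelet group; original-image features fall back to their family group
#' (Shape, First-order, GLCM, GLRLM, GLSZM, NGTDM, GLDM).
#'
#' @param name Character vector of feature names.
#' @return Character vector of group labels.
#' @export
group_of <- function(name) {
  p <- parse_feature_name(name)
  fam_group <- c(shape = "Shape", firstorder = "First-order", glcm = "GLCM",
                 glrlm = "GLRLM", glszm = "GLSZM", ngtdm = "NGTDM",
                 gldm = "GLDM")
  out <- unname(fam_group[p$family])
  out[startsWith(p$filter_tag, "log-sigma-")] <- "Log-sigma"
  out[startsWith(p$filter_tag, "wavelet-")] <- "Wavelet"
  out
}

#' The nine radiomics group labels
#' @return Character vector of length 9.
#' @export
radiomics_groups <- function() {
  c("Shape", "First-order", "GLCM", "GLRLM", "GLSZM", "NGTDM", "GLDM",
    "Log-sigma", "Wavelet")
}
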