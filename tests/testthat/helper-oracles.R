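# Independent brute-force oracles used across the suite. These are written
# as literal loops over the defining formulas and share no code with the
# package implementations they check.

# Plug-in mutual information by explicit double loop, bits.
naive_mi <- function(x, y) {
  x <- as.integer(as.factor(x)); y <- as.integer(as.factor(y))
  n <- length(x)
  out <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        out <- out + pab * log2(pab / (sum(x == a) / n * sum(y == b) / n))
      }
    }
  }
  out
}

# I(X;Y|Z) = sum_z p(z) I(X;Y | Z = z), by explicit conditioning.
naive_cmi <- function(x, y, z) {
  out <- 0
  for (c in unique(z)) {
    sel <- z == c
    if (sum(sel) > 1L) out <- out + mean(sel) * naive_mi(x[sel], y[sel])
  }
  out
}

# Brute-force greedy forward selection for the mutual-information family,
# evaluating each method's objective literally at every step.
naive_greedy_scores <- function(D, y, method, beta = 0.5) {
  p <- ncol(D)
  nm <- colnames(D)
  scores <- rep(NA_real_, p)
  names(scores) <- nm
  S <- integer(0)
  remaining <- seq_len(p)
  while (length(remaining)) {
    obj <- vapply(remaining, function(i) {
      if (!length(S)) return(naive_mi(D[, i], y))
      switch(method,
        MIFS = naive_mi(D[, i], y) -
          beta * sum(vapply(S, function(s) naive_mi(D[, i], D[, s]),
                            numeric(1))),
        MRMR = naive_mi(D[, i], y) -
          mean(vapply(S, function(s) naive_mi(D[, i], D[, s]), numeric(1))),
        JMI = naive_mi(D[, i], y) -
          mean(vapply(S, function(s) {
            naive_mi(D[, i], y) - naive_cmi(D[, i], y, D[, s])
          }, numeric(1))),
        CMIM = min(vapply(S, function(s) naive_cmi(D[, i], y, D[, s]),
                          numeric(1))))
    }, numeric(1))
    ord <- order(-obj, nm[remaining])
    pick <- remaining[ord[1]]
    scores[pick] <- obj[ord[1]]
    S <- c(S, pick)
    remaining <- setdiff(remaining, pick)
  }
  scores
}

# Small labelled toy table with a perfect predictor and weak distractors.
toy_table <- function(n = 60, p_noise = 7, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(lab = y, sapply(seq_len(p_noise), function(j) 0.3 * y + rnorm(n)))
  colnames(x) <- c("lab", paste0("d", seq_len(p_noise)))
  list(x = suppressWarnings(normalize_features(x)), y = y)
}

# A small phantom acquisition used throughout the unit tests.
tiny_acq <- function(Tn = 12L) {
  acquisition_spec(n_timepoints = Tn, n_slices = 8L, height = 16L,
                   width = 16L)
}

tiny_phantom <- function(seed = 3, attenuation = 0.4, delay = 2,
                         noise_sd = 0.5, fraction = 0.3, Tn = 12L) {
  generate_phantom(tiny_acq(Tn), bolus_model(),
                   lesion_spec(target_fraction = fraction,
                               attenuation = attenuation, delay = delay),
                   noise_sd = noise_sd, seed = seed)
}

# Time x voxel matrix of the series restricted to a 3D mask.
series_matrix <- function(volume, mask) {
  matrix(volume, nrow = dim(volume)[1])[, which(mask), drop = FALSE]
}
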