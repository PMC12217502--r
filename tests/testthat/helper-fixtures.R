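# Shared fixtures: audiogram builders and small phantom/cohort helpers.

# Audiogram from six AC thresholds in 0.25-8 kHz order.
ag <- function(th, ...) {
  names(th) <- AUDIO_FREQS
  audiogram(th, ...)
}

# Audiogram pair differing by a delta vector (prior flat at `base`).
ag_pair <- function(delta, base = 30) {
  list(prior = ag(rep(base, 6)), current = ag(base + delta))
}

# Small, fast noise-free vestibule phantom.
clean_vestibule <- function(target_tv = 62.5, target_ep = 0.25, voxel = 0.5) {
  generate_phantom(phantom_spec("vestibule", target_tv = target_tv,
                                target_ep = target_ep, voxel_size = voxel,
                                blur_fwhm = 0, noise_sigma = 0))
}

# Direct enumeration of the quoted hearing-stability rules, written
# independently of classify_stability: a visit is unstable if any |delta| is
# at least 20 dB, or two adjacent frequencies both shift by at least 15 dB;
# the cumulative shift sums signed deltas strictly larger than 10 dB in
# magnitude.
oracle_stability <- function(delta) {
  unstable <- FALSE
  for (i in seq_along(delta)) {
    if (abs(delta[i]) >= 20) unstable <- TRUE
  }
  for (i in seq_len(length(delta) - 1)) {
    if (abs(delta[i]) >= 15 && abs(delta[i + 1]) >= 15) unstable <- TRUE
  }
  shift <- 0
  for (d in delta) if (abs(d) > 10) shift <- shift + d
  list(unstable = unstable, shift = shift)
}

# Exhaustive two-sided Fisher exact p by enumeration over all tables with
# the observed margins (probability-mass rule).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  amin <- max(0, c1 - (n - r1)); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(a) stats::dhyper(a, r1, n - r1, c1),
                  numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
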