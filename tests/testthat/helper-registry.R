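# shared fixtures: the packaged registry and shape builders
registry <- load_parameter_table()

shapes_at <- function(set, coherence, n = 1) {
  st <- isi_stats(registry[[set]], coherence)
  list(pref = lognormal_shape(st$preferred, n),
       null = lognormal_shape(st$null, n),
       stats = st)
}

# numeric quadrature of the KL divergence in bits (independent oracle)
kl_quadrature_bits <- function(pref, null) {
  f <- function(x) {
    stats::dlnorm(x, pref$kappa, sqrt(pref$theta2)) *
      (stats::dlnorm(x, pref$kappa, sqrt(pref$theta2), log = TRUE) -
         stats::dlnorm(x, null$kappa, sqrt(null$theta2), log = TRUE)) / log(2)
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# a nearly-information-free variant of a parameter set (null moved onto the
# preferred channel up to a vanishing divergence)
near_degenerate_set <- function(set = "Omega", coherence = 25.6,
                                K_bits = 1e-10) {
  src <- registry[[set]]
  targets <- stats::setNames(rep(K_bits, nrow(src)),
                             rownames(src))
  deplete_parameter_set(src, targets, label = "near_degenerate")
}

# an exactly information-free two-channel set: both channels share the
# preferred statistics, so g1 = g2 = 0 and posteriors never move
equal_stats_set <- function(coherence = 12.8) {
  src <- registry$Omega
  out <- src
  out$null_mean <- out$pref_mean
  out$null_sd <- out$pref_sd
  attr(out, "label") <- "equal_stats"
  out
}

# Wald's lower bound on the expected sample size of a two-hypothesis
# sequential test at symmetric error rate eps, in observations. The
# per-step discrimination information is that of the full observation
# vector: with two independent channels whose roles swap between the
# hypotheses, it is the symmetrized divergence
# KL(f*||f0) + KL(f0||f*) in bits.
wald_bound_T <- function(eps, pref_shape, null_shape) {
  I_bits <- ((1 - eps) * log((1 - eps) / eps) +
               eps * log(eps / (1 - eps))) / log(2)
  K12 <- kl_divergence_bits(pref_shape, null_shape) +
    kl_divergence_bits(null_shape, pref_shape)
  I_bits / K12
}
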