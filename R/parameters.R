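#' Inter-spike-interval statistics for one evidence channel
#'
#' Bundles the mean and standard deviation (both in ms) of the inter-spike
#' intervals (ISIs) produced by an MT-like sensory channel. The preferred
#' channel of a condition fires faster than the null channel, so its mean
#' ISI is shorter.
#'
#' @param mean_isi Positive mean ISI in ms.
#' @param sd_isi Positive ISI standard deviation in ms.
#' @return An object of class `isi_statistics`.
#' @examples
#' isi_statistics(29.9, 26.0)
#' @export
isi_statistics <- function(mean_isi, sd_isi) {
  if (!is.numeric(mean_isi) || length(mean_isi) != 1L || !is.finite(mean_isi) ||
      mean_isi <= 0) {
    stop("`mean_isi` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sd_isi) || length(sd_isi) != 1L || !is.finite(sd_isi) ||
      sd_isi <= 0) {
    stop("`sd_isi` must be a single positive number", call. = FALSE)
  }
  structure(list(mean_isi = as.numeric(mean_isi), sd_isi = as.numeric(sd_isi)),
            class = "isi_statistics")
}

#' @export
print.isi_statistics <- function(x, ...) {
  cat(sprintf("ISI statistics: mean %.2f ms, sd %.2f ms\n", x$mean_isi, x$sd_isi))
  invisible(x)
}

# canonical decimal-string keys for the packaged coherences; avoids
# floating-point key lookup pitfalls
.coherence_key <- function(coherence) {
  format(as.numeric(coherence), trim = TRUE, drop0trailing = TRUE)
}

#' Coherence levels of the packaged registry
#'
#' @return Numeric vector of motion-coherence percentages covered by the
#'   packaged MT statistics table.
#' @export
coherence_levels <- function() c(3.2, 6.4, 12.8, 25.6, 51.2)

.registry_labels <- c("Omega", "Omega_d_N2", "Omega_d_N4")

#' Load the MT inter-spike-interval statistics registry
#'
#' Reads a delimited table of per-coherence ISI means and standard deviations
#' for the preferred and null channels and builds the three parameter sets
#' used throughout the package: `Omega` (statistics measured in MT) and the
#' two information-depleted sets `Omega_d_N2`, `Omega_d_N4` (null channels
#' moved towards the preferred one so that the pair carries the reduced
#' discrimination information estimated from monkey behaviour). All three
#' sets share the same preferred-channel columns.
#'
#' @param source Path to a CSV with columns `coherence`, `n_neurons`,
#'   `pref_mean`, `pref_sd`, `omega_null_mean`, `omega_null_sd`,
#'   `omegad_n2_null_mean`, `omegad_n2_null_sd`, `omegad_n4_null_mean`,
#'   `omegad_n4_null_sd`. Defaults to the table packaged with the package.
#' @return A named list of three `isi_parameter_set` objects
#'   (`Omega`, `Omega_d_N2`, `Omega_d_N4`).
#' @examples
#' reg <- load_parameter_table()
#' isi_stats(reg$Omega, 51.2)
#' @export
load_parameter_table <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "mt_isi_statistics.csv", package = "rmsprt")
  }
  if (!file.exists(source)) stop("registry file not found: ", source, call. = FALSE)
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  needed <- c("coherence", "n_neurons", "pref_mean", "pref_sd",
              "omega_null_mean", "omega_null_sd",
              "omegad_n2_null_mean", "omegad_n2_null_sd",
              "omegad_n4_null_mean", "omegad_n4_null_sd")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  want <- .coherence_key(coherence_levels())
  have <- .coherence_key(tab$coherence)
  if (!setequal(have, want) || anyDuplicated(have) > 0) {
    stop("registry must contain exactly one row per coherence in {",
         paste(want, collapse = ", "), "}; found {",
         paste(have, collapse = ", "), "}", call. = FALSE)
  }
  tab <- tab[match(want, have), ]
  stat_cols <- setdiff(needed, c("coherence", "n_neurons"))
  for (cl in stat_cols) {
    bad <- !is.finite(tab[[cl]]) | tab[[cl]] <= 0
    if (any(bad)) {
      stop(sprintf("non-positive statistic in column '%s' at coherence %s",
                   cl, .coherence_key(tab$coherence[bad][1])), call. = FALSE)
    }
  }
  make_set <- function(label, null_mean, null_sd) {
    df <- data.frame(
      coherence = as.numeric(tab$coherence),
      n_neurons = as.integer(tab$n_neurons),
      pref_mean = tab$pref_mean, pref_sd = tab$pref_sd,
      null_mean = null_mean, null_sd = null_sd,
      stringsAsFactors = FALSE
    )
    rownames(df) <- .coherence_key(df$coherence)
    structure(df, label = label, class = c("isi_parameter_set", "data.frame"))
  }
  sets <- list(
    Omega      = make_set("Omega", tab$omega_null_mean, tab$omega_null_sd),
    Omega_d_N2 = make_set("Omega_d_N2", tab$omegad_n2_null_mean, tab$omegad_n2_null_sd),
    Omega_d_N4 = make_set("Omega_d_N4", tab$omegad_n4_null_mean, tab$omegad_n4_null_sd)
  )
  for (s in sets) .validate_parameter_set(s)
  # depleted null means must lie between the preferred and Omega null means
  # at each coherence (equal to the Omega null when a condition was not
  # depleted, e.g. in partially depleted user-produced registries)
  for (lbl in c("Omega_d_N2", "Omega_d_N4")) {
    d <- sets[[lbl]]
    o <- sets$Omega
    ok <- d$null_mean > d$pref_mean & d$null_mean <= o$null_mean
    if (!all(ok)) {
      stop(sprintf("depleted set %s violates betweenness at coherence %s",
                   lbl, .coherence_key(d$coherence[!ok][1])), call. = FALSE)
    }
  }
  sets
}

.validate_parameter_set <- function(set) {
  if (!all(set$pref_mean < set$null_mean)) {
    bad <- which(set$pref_mean >= set$null_mean)[1]
    stop(sprintf(
      "parameter set %s: preferred mean ISI must be shorter than null at coherence %s",
      attr(set, "label"), .coherence_key(set$coherence[bad])), call. = FALSE)
  }
  invisible(set)
}

#' Look up the ISI statistics of a parameter set at one coherence
#'
#' @param set An `isi_parameter_set` from [load_parameter_table()].
#' @param coherence One of the packaged coherence percentages.
#' @return A list with elements `preferred` and `null`, both `isi_statistics`.
#' @export
isi_stats <- function(set, coherence) {
  stopifnot(inherits(set, "isi_parameter_set"))
  key <- .coherence_key(coherence)
  if (!key %in% rownames(set)) {
    stop("coherence ", key, " not in parameter set ", attr(set, "label"),
         call. = FALSE)
  }
  row <- set[key, ]
  list(preferred = isi_statistics(row$pref_mean, row$pref_sd),
       null = isi_statistics(row$null_mean, row$null_sd))
}

#' Lognormal shape parameters from ISI moments
#'
#' Moment-matches a lognormal distribution to the given ISI mean and
#' standard deviation, after dividing both by the hypothesis-independent
#' data scaling factor `n`. The squared log-scale is
#' `theta2 = log(sd^2/mean^2 + 1)` (invariant to `n`) and the log-location
#' is `kappa = log(mean/n) - theta2/2`, so the implied lognormal has exactly
#' the requested first two moments.
#'
#' @param stats An `isi_statistics` object (or a list with `mean_isi`,
#'   `sd_isi`).
#' @param n Positive scaling factor applied to the raw statistics
#'   (default 1). Scaling shifts `kappa` by `-log(n)` and leaves `theta2`
#'   unchanged; it never affects inference.
#' @return An object of class `lognormal_shape` with fields `kappa`,
#'   `theta2`.
#' @examples
#' lognormal_shape(isi_statistics(29.9, 26.0))
#' @export
lognormal_shape <- function(stats, n = 1) {
  if (!is.list(stats) || is.null(stats$mean_isi) || is.null(stats$sd_isi)) {
    stop("`stats` must be an isi_statistics object", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("`n` must be a single positive number", call. = FALSE)
  }
  mu <- stats$mean_isi / n
  sg <- stats$sd_isi / n
  if (mu <= 0 || sg <= 0) stop("non-positive ISI statistics", call. = FALSE)
  theta2 <- log(sg^2 / mu^2 + 1)
  kappa <- log(mu) - theta2 / 2
  structure(list(kappa = kappa, theta2 = theta2), class = "lognormal_shape")
}

#' @export
print.lognormal_shape <- function(x, ...) {
  cat(sprintf("lognormal shape: kappa %.4f, theta2 %.4f\n", x$kappa, x$theta2))
  invisible(x)
}

#' Back-convert a lognormal shape to its implied ISI moments
#'
#' Closed-form inverse of [lognormal_shape()]: the mean is
#' `exp(kappa + theta2/2)` and the standard deviation is
#' `mean * sqrt(exp(theta2) - 1)`.
#'
#' @param shape A `lognormal_shape`.
#' @return An `isi_statistics` with the implied mean and SD (on the scaled
#'   axis, i.e. already divided by whatever `n` built the shape).
#' @export
shape_moments <- function(shape) {
  stopifnot(inherits(shape, "lognormal_shape"))
  m <- exp(shape$kappa + shape$theta2 / 2)
  s <- m * sqrt(exp(shape$theta2) - 1)
  isi_statistics(m, s)
}

#' Discrimination information between preferred and null ISI distributions
#'
#' Kullback-Leibler divergence, in bits per ISI, from the preferred-channel
#' lognormal `f*` to the null-channel lognormal `f0`. Because the log of a
#' lognormal variate is normal, the divergence has the Gaussian closed form
#' `K = [log(T0/T*) + (T*^2 + (k* - k0)^2) / (2 T0^2) - 1/2] / log(2)`
#' with `T = sqrt(theta2)` and `k = kappa`. It is invariant to the data
#' scaling factor `n` used to build the shapes.
#'
#' @param pref `lognormal_shape` of the preferred channel.
#' @param null `lognormal_shape` of the null channel.
#' @return Nonnegative divergence in bits per ISI.
#' @examples
#' reg <- load_parameter_table()
#' st <- isi_stats(reg$Omega, 51.2)
#' kl_divergence_bits(lognormal_shape(st$preferred), lognormal_shape(st$null))
#' @export
kl_divergence_bits <- function(pref, null) {
  stopifnot(inherits(pref, "lognormal_shape"), inherits(null, "lognormal_shape"))
  t2p <- pref$theta2
  t2n <- null$theta2
  dk <- pref$kappa - null$kappa
  nats <- 0.5 * log(t2n / t2p) + (t2p + dk^2) / (2 * t2n) - 0.5
  nats / log(2)
}

#' Discrimination information of a parameter set at one coherence
#'
#' Convenience wrapper: builds the preferred and null lognormal shapes of a
#' parameter set at the given coherence and returns their KL divergence in
#' bits per ISI.
#'
#' @inheritParams isi_stats
#' @param n Data scaling factor; the result does not depend on it.
#' @return Divergence in bits per ISI.
#' @export
set_discrimination_bits <- function(set, coherence, n = 1) {
  st <- isi_stats(set, coherence)
  kl_divergence_bits(lognormal_shape(st$preferred, n), lognormal_shape(st$null, n))
}
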