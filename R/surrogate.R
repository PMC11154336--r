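#' Surrogate count for a two-sided Chebyshev test
#'
#' Number of random-shuffle surrogates needed for a two-sided test at miss
#' probability `alpha`: \eqn{N_S = \lceil 2/\alpha \rceil - 1}. With the
#' 6-Sigma default (`alpha = 1/36`) this gives 71 surrogates.
#'
#' @param alpha miss probability in (0, 1).
#' @return Integer surrogate count.
#' @export
n_surrogates_for <- function(alpha) {
  stop_if_not_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  as.integer(ceiling(2 / alpha) - 1)
}

#' Configuration for surrogate significance testing
#'
#' Bundles the Chebyshev parameter, surrogate count, master seed, and the
#' decision threshold on the significance level lambda. By Chebyshev's
#' inequality a deviation of `chebyshev_k` ensemble standard deviations has
#' probability at most `alpha = 1/chebyshev_k^2` under the shuffled null,
#' regardless of the null distribution's shape; the default `chebyshev_k = 6`
#' (the 6-Sigma rule) carries confidence `1 - 1/36 = 97.2%`, and 4.47 is the
#' 95% practical floor.
#'
#' @param chebyshev_k positive Chebyshev parameter (ensemble-sd units).
#' @param n_surrogates ensemble size; default [n_surrogates_for()] of
#'   `1/chebyshev_k^2`.
#' @param seed master RNG seed; every surrogate draws a deterministic
#'   sub-seed from it.
#' @param decision_threshold lambda cutoff for declaring significance
#'   (default 6).
#' @param shuffle for UID ensembles: shuffle `"both"` series (the default)
#'   or the `"source"` only.
#' @return Object of class `significance_config`.
#' @export
significance_config <- function(chebyshev_k = 6, n_surrogates = NULL, seed = 1L,
                                decision_threshold = 6,
                                shuffle = c("both", "source")) {
  stop_if_not_scalar_number(chebyshev_k, "chebyshev_k")
  if (chebyshev_k <= 1) stop("`chebyshev_k` must exceed 1", call. = FALSE)
  alpha <- 1 / chebyshev_k^2
  if (is.null(n_surrogates)) n_surrogates <- n_surrogates_for(alpha)
  if (n_surrogates < 1L) stop("`n_surrogates` must be >= 1", call. = FALSE)
  structure(list(chebyshev_k = chebyshev_k, alpha = alpha,
                 n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed),
                 decision_threshold = decision_threshold,
                 shuffle = match.arg(shuffle)),
            class = "significance_config")
}

#' @export
print.significance_config <- function(x, ...) {
  cat(sprintf(
    "<significance_config> chebyshev_k = %.4g (alpha = %.4g, confidence %.4g%%), N_S = %d, seed = %d, threshold = %.4g, shuffle = %s\n",
    x$chebyshev_k, x$alpha, 100 * (1 - x$alpha), x$n_surrogates, x$seed,
    x$decision_threshold, x$shuffle))
  invisible(x)
}

#' Confidence level of a Chebyshev significance threshold
#'
#' `1 - 1/k^2`: the distribution-free confidence attached to declaring
#' significance at `lambda > k`.
#'
#' @param chebyshev_k threshold in ensemble-sd units.
#' @return Confidence in \[0, 1).
#' @export
chebyshev_confidence <- function(chebyshev_k) {
  stopifnot(all(chebyshev_k > 0))
  1 - 1 / chebyshev_k^2
}

#' Chebyshev significance threshold for a confidence level
#'
#' Inverse of [chebyshev_confidence()]: the lambda cutoff needed for
#' distribution-free confidence `confidence`; 95% gives 4.47.
#'
#' @param confidence desired confidence in (0, 1).
#' @return Threshold in ensemble-sd units.
#' @export
chebyshev_significance <- function(confidence) {
  stopifnot(all(confidence > 0 & confidence < 1))
  sqrt(1 / (1 - confidence))
}

#' Random-shuffle surrogate of a symbol series
#'
#' Uniformly random permutation of the sample order: temporal structure (and
#' hence any directed coupling) is destroyed while the symbol multiset — the
#' marginal distribution — is preserved exactly. Deterministic given `seed`.
#'
#' @param series a [symbol_series()].
#' @param seed RNG seed for the permutation.
#' @return A [symbol_series()] with permuted symbols.
#' @export
shuffle_surrogate <- function(series, seed) {
  series <- as_symbols(series)
  n <- length(series$symbols)
  perm <- with_seed(seed, sample.int(n))
  out <- series
  out$symbols <- series$symbols[perm]
  out
}

make_ensemble <- function(label, values, seed) {
  structure(list(statistic_label = label, values = values,
                 mu = mean(values), sigma = stats::sd(values), seed = seed),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %s: N_S = %d, mu = %.6g, sigma = %.6g (seed %d)\n",
              x$statistic_label, length(x$values), x$mu, x$sigma, x$seed))
  invisible(x)
}

#' Surrogate ensemble of the UID statistic
#'
#' For each of `cfg$n_surrogates` surrogates, shuffles the head series and
#' (by default) the eye series with fresh deterministic sub-seeds of
#' `cfg$seed`, and records the unidirectional information difference
#' \eqn{UID = TE_{head \to eye} - TE_{eye \to head}} between the surrogate
#' pair. The ensemble mean and standard deviation form the null against which
#' an observed UID is scored.
#'
#' @param eye,head [symbol_series()] for the eye (X) and head (Y) channels.
#' @param cfg a [significance_config()]; `cfg$shuffle = "source"` shuffles
#'   the head series only.
#' @param l,k history lengths passed to [transfer_entropy()].
#' @return A `surrogate_ensemble` (values, `mu`, `sigma`, seed).
#' @export
uid_surrogate_ensemble <- function(eye, head, cfg = significance_config(),
                                   l = 1L, k = 1L) {
  eye <- as_symbols(eye, "eye"); head <- as_symbols(head, "head")
  ns <- cfg$n_surrogates
  seeds <- derive_subseeds(cfg$seed, 2L * ns)
  vals <- vapply(seq_len(ns), function(i) {
    head_s <- shuffle_surrogate(head, seeds[2L * i - 1L])
    eye_s <- if (cfg$shuffle == "both") shuffle_surrogate(eye, seeds[2L * i]) else eye
    transfer_entropy(head_s, eye_s, l, k)$value -
      transfer_entropy(eye_s, head_s, l, k)$value
  }, numeric(1))
  make_ensemble("UID(head->eye)", vals, cfg$seed)
}

#' Surrogate ensemble of a single-direction transfer entropy
#'
#' Shuffles the source series only and records TE(shuffled source ->
#' original target) for each surrogate. This is the null ensemble used both
#' to test a single TE direction for significance and as the bias term
#' subtracted in the normalized transfer entropy.
#'
#' @param source,target [symbol_series()].
#' @param cfg a [significance_config()]. Sub-seeds depend only on `cfg$seed`
#'   and the surrogate index, never on channel labels, so the two directions
#'   of a pair are corrected with identical permutation streams.
#' @param l,k history lengths.
#' @return A `surrogate_ensemble`.
#' @export
te_surrogate_ensemble <- function(source, target, cfg = significance_config(),
                                  l = 1L, k = 1L) {
  source <- as_symbols(source, "source"); target <- as_symbols(target, "target")
  seeds <- derive_subseeds(cfg$seed, cfg$n_surrogates)
  vals <- vapply(seeds, function(s) {
    transfer_entropy(shuffle_surrogate(source, s), target, l, k)$value
  }, numeric(1))
  make_ensemble("TE(shuffled source -> target)", vals, cfg$seed)
}

#' Score an observed statistic against a surrogate ensemble
#'
#' The significance level is the z-like score
#' \eqn{\lambda = (\mathrm{observed} - \mu) / \sigma} of the observed
#' statistic against the surrogate null; significance is declared when
#' lambda exceeds `cfg$decision_threshold`, with distribution-free
#' Chebyshev confidence `1 - 1/chebyshev_k^2`. A zero-sigma ensemble is
#' flagged degenerate (lambda `+Inf`, `0`, or `-Inf` as the observation
#' sits above, at, or below `mu`).
#'
#' @param observed observed statistic value.
#' @param ens a `surrogate_ensemble`.
#' @param cfg a [significance_config()].
#' @return Object of class `significance_result`: `observed`, `lambda`,
#'   `confidence`, `significant`, `degenerate`, plus the ensemble `mu` and
#'   `sigma`.
#' @export
significance <- function(observed, ens, cfg = significance_config()) {
  stop_if_not_scalar_number(observed, "observed")
  stopifnot(inherits(ens, "surrogate_ensemble"))
  degenerate <- ens$sigma == 0 || is.na(ens$sigma)
  lambda <- if (!degenerate) {
    (observed - ens$mu) / ens$sigma
  } else if (observed > ens$mu) Inf else if (observed == ens$mu) 0 else -Inf
  structure(list(observed = observed, mu = ens$mu, sigma = ens$sigma,
                 lambda = lambda,
                 confidence = chebyshev_confidence(cfg$chebyshev_k),
                 significant = lambda > cfg$decision_threshold,
                 degenerate = degenerate),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("<significance_result> observed %.6g vs null (mu %.6g, sigma %.6g): lambda = %.4g -> %s%s\n",
              x$observed, x$mu, x$sigma, x$lambda,
              if (x$significant) "significant" else "not significant",
              if (x$degenerate) " [degenerate ensemble]" else ""))
  invisible(x)
}
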