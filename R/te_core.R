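#' Construct a symbol series
#'
#' Wraps an integer-coded series (codes in `[0, alphabet_size)`) as produced
#' by [discretize()] or by the binary simulator. Plug-in transfer entropy is
#' computed on these codes.
#'
#' @param symbols integer vector of codes in `[0, alphabet_size)`.
#' @param alphabet_size number of symbols B.
#' @param bin_edges optional numeric vector of bin edges (degrees) that
#'   produced the codes.
#' @param scheme discretization scheme label.
#' @return Object of class `symbol_series`.
#' @export
symbol_series <- function(symbols, alphabet_size, bin_edges = NULL,
                          scheme = c("equal_width", "quantile", "none")) {
  scheme <- match.arg(scheme)
  symbols <- as.integer(symbols)
  alphabet_size <- as.integer(alphabet_size)
  if (alphabet_size < 1L) stop("`alphabet_size` must be at least 1", call. = FALSE)
  if (anyNA(symbols) || any(symbols < 0L) || any(symbols >= alphabet_size)) {
    stop("symbol codes must lie in [0, alphabet_size)", call. = FALSE)
  }
  structure(list(symbols = symbols, alphabet_size = alphabet_size,
                 bin_edges = bin_edges, scheme = scheme),
            class = "symbol_series")
}

#' @export
print.symbol_series <- function(x, ...) {
  cat(sprintf("<symbol_series> n = %d, B = %d, scheme = %s\n",
              length(x$symbols), x$alphabet_size, x$scheme))
  invisible(x)
}

as_symbols <- function(x, name = "series") {
  if (inherits(x, "symbol_series")) return(x)
  if (is.numeric(x) && !anyNA(x) && all(x == floor(x)) && all(x >= 0)) {
    return(symbol_series(x, max(x) + 1L, scheme = "none"))
  }
  stop(sprintf("`%s` must be a symbol_series or a non-negative integer vector", name),
       call. = FALSE)
}

#' Discretize a continuous series into symbols
#'
#' Histogram discretization, the first step of the plug-in (maximum
#' likelihood) entropy estimator. `equal_width` splits `[min, max]` into B
#' equal bins (right-open, last bin closed); `quantile` places edges at
#' empirical quantiles, merging duplicate edges (B then shrinks accordingly).
#' A constant series collapses to a single symbol, B = 1.
#'
#' @param series numeric vector (degrees), length >= 2, all finite.
#' @param alphabet_size requested number of bins B >= 2.
#' @param scheme `"equal_width"` (default) or `"quantile"`.
#' @return A [symbol_series()].
#' @export
discretize <- function(series, alphabet_size = 8L,
                       scheme = c("equal_width", "quantile")) {
  scheme <- match.arg(scheme)
  if (length(series) < 2L) stop("`series` must have length >= 2", call. = FALSE)
  if (!all(is.finite(series))) stop("`series` contains non-finite values", call. = FALSE)
  if (alphabet_size < 2L) stop("`alphabet_size` must be >= 2", call. = FALSE)
  rng <- range(series)
  if (rng[1] == rng[2]) {
    return(symbol_series(rep(0L, length(series)), 1L,
                         bin_edges = rng, scheme = scheme))
  }
  edges <- switch(scheme,
    equal_width = seq(rng[1], rng[2], length.out = alphabet_size + 1L),
    quantile = unique(stats::quantile(series, probs = seq(0, 1, length.out = alphabet_size + 1L),
                                      names = FALSE, type = 7))
  )
  if (length(edges) < 3L) {  # quantile edges all collapsed
    return(symbol_series(rep(0L, length(series)), 1L, bin_edges = rng, scheme = scheme))
  }
  codes <- findInterval(series, edges, rightmost.closed = TRUE, all.inside = TRUE) - 1L
  symbol_series(codes, length(edges) - 1L, bin_edges = edges, scheme = scheme)
}

#' Joint distribution of (target now, target past, source past)
#'
#' Plug-in joint distribution over the tuple
#' \eqn{(x_t, x_{t-k..t-1}, y_{t-l..t-1})}: one count per time index from
#' `max(l, k) + 1` to the series end, probabilities = counts / n. This is the
#' sufficient statistic for transfer entropy with source history `l` and
#' target history `k`.
#'
#' @param target,source [symbol_series()] (or integer-code vectors) of equal
#'   length.
#' @param l source history length (samples), >= 1.
#' @param k target history length (samples), >= 1.
#' @return Object of class `joint_distribution`: a `cells` data frame
#'   (`target_now`, `target_past`, `source_past` composite codes, `count`,
#'   `prob`) plus `n_samples` and the history lengths.
#' @export
joint_distribution <- function(target, source, l = 1L, k = 1L) {
  target <- as_symbols(target, "target"); source <- as_symbols(source, "source")
  x <- target$symbols; y <- source$symbols
  n <- length(x)
  if (length(y) != n) stop("`target` and `source` must have equal length", call. = FALSE)
  l <- as.integer(l); k <- as.integer(k)
  if (l < 1L || k < 1L) stop("history lengths must be >= 1", call. = FALSE)
  m <- max(l, k)
  if (n <= m) stop("series length must exceed max(l, k)", call. = FALSE)
  Bt <- target$alphabet_size; Bs <- source$alphabet_size
  t_idx <- (m + 1L):n
  now <- x[t_idx]
  past <- 0
  for (j in seq_len(k)) past <- past + x[t_idx - j] * Bt^(j - 1L)
  src <- 0
  for (j in seq_len(l)) src <- src + y[t_idx - j] * Bs^(j - 1L)
  n_past <- Bt^k; n_src <- Bs^l
  if (Bt * n_past * n_src > 5e7) {
    stop("state space too large for histories (l, k) at these alphabet sizes", call. = FALSE)
  }
  key <- 1 + now + Bt * (past + n_past * src)
  counts <- tabulate(key, nbins = Bt * n_past * n_src)
  keep <- which(counts > 0L)
  z <- keep - 1L
  cells <- data.frame(
    target_now = z %% Bt,
    target_past = (z %/% Bt) %% n_past,
    source_past = z %/% (Bt * n_past),
    count = counts[keep]
  )
  cells$prob <- cells$count / length(t_idx)
  structure(list(cells = cells, n_samples = length(t_idx),
                 alphabet_target = Bt, alphabet_source = Bs, l = l, k = k),
            class = "joint_distribution")
}

#' Plug-in conditional entropy from a joint distribution
#'
#' \eqn{H(\mathrm{target\_now} \mid \mathrm{margin})} in bits, where the
#' margin is any subset of the past coordinates; zero-probability cells
#' contribute nothing (0 log 0 := 0).
#'
#' @param joint a [joint_distribution()].
#' @param conditioning character vector naming the conditioning margin:
#'   `"target_past"`, `"source_past"`, or both.
#' @return Conditional entropy in bits (non-negative scalar).
#' @export
conditional_entropy <- function(joint, conditioning = "target_past") {
  stopifnot(inherits(joint, "joint_distribution"))
  ok <- c("target_past", "source_past")
  if (length(conditioning) < 1L || !all(conditioning %in% ok)) {
    stop("`conditioning` must be a non-empty subset of {target_past, source_past}",
         call. = FALSE)
  }
  cells <- joint$cells
  cond_key <- do.call(paste, c(cells[conditioning], list(sep = ":")))
  joint_key <- paste(cells$target_now, cond_key, sep = "|")
  h_joint <- entropy_bits(rowsum(cells$count, joint_key))
  h_cond <- entropy_bits(rowsum(cells$count, cond_key))
  max(h_joint - h_cond, 0)
}

#' Plug-in transfer entropy between symbol series
#'
#' Directed information flow from `source` to `target` in bits:
#' \deqn{TE = H(X_t | X_{t-1}^{(k)}) - H(X_t | X_{t-1}^{(k)}, Y_{t-1}^{(l)}),}
#' estimated by plug-in conditional entropies from the empirical
#' [joint_distribution()]. The first term is also the attainable maximum
#' ("ceiling") of the estimate, returned alongside. History lengths default
#' to `l = k = 1`, the convention for head-eye rotation series.
#'
#' @param source,target [symbol_series()] (or integer-code vectors) of equal
#'   length, longer than `max(l, k) + 1`.
#' @param l,k source and target history lengths (samples).
#' @param source_label,target_label names recorded in the result.
#' @return Object of class `te_estimate` with fields `value` (bits),
#'   `ceiling` (bits), `l`, `k`, `n_samples`, labels.
#' @export
transfer_entropy <- function(source, target, l = 1L, k = 1L,
                             source_label = "source", target_label = "target") {
  source <- as_symbols(source, "source"); target <- as_symbols(target, "target")
  if (length(target$symbols) <= max(l, k) + 1L) {
    stop("series too short for transfer entropy at these history lengths", call. = FALSE)
  }
  jd <- joint_distribution(target, source, l = l, k = k)
  ceiling_bits <- conditional_entropy(jd, "target_past")
  h_full <- conditional_entropy(jd, c("target_past", "source_past"))
  structure(list(source_label = source_label, target_label = target_label,
                 l = jd$l, k = jd$k,
                 value = max(ceiling_bits - h_full, 0),
                 ceiling = ceiling_bits,
                 n_samples = jd$n_samples),
            class = "te_estimate")
}

#' @export
print.te_estimate <- function(x, ...) {
  cat(sprintf("<te_estimate> TE %s -> %s (l = %d, k = %d): %.6g bits (ceiling %.6g, n = %d)\n",
              x$source_label, x$target_label, x$l, x$k, x$value, x$ceiling, x$n_samples))
  invisible(x)
}
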