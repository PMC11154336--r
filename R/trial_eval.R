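#' Driving performance from a speed trace
#'
#' The task is to hold a constant speed, so performance is the inverse of the
#' average (absolute) acceleration: speed is converted from km/h to m/s,
#' acceleration taken as first differences over the timestamp deltas, and
#' \eqn{1/\mathrm{AvgAcc}} returned in s^2/m — larger is smoother driving. A
#' signed mean would cancel over a closed course, hence the absolute value;
#' an RMS variant is available via `method`.
#'
#' @param speed numeric vector, km/h.
#' @param timestamps numeric vector, seconds, strictly increasing, same
#'   length as `speed`, length >= 3.
#' @param method `"abs"` (mean absolute acceleration, default) or `"rms"`.
#' @param cap value returned (with a `degenerate` attribute) when the average
#'   acceleration is below 1e-9 m/s^2, where the inverse blows up.
#' @return Performance in s^2/m, with attributes `avg_acc` (m/s^2) and
#'   `degenerate`.
#' @export
driving_performance <- function(speed, timestamps, method = c("abs", "rms"),
                                cap = 1e9) {
  method <- match.arg(method)
  if (length(speed) != length(timestamps)) {
    stop("`speed` and `timestamps` must have equal length", call. = FALSE)
  }
  if (length(speed) < 3L) stop("speed trace too short (need >= 3 samples)", call. = FALSE)
  if (any(diff(timestamps) <= 0)) stop("non-monotone timestamps", call. = FALSE)
  ok <- !is.na(speed)
  v <- speed[ok] / 3.6
  ts <- timestamps[ok]
  if (length(v) < 3L) stop("speed trace too short after removing missing samples", call. = FALSE)
  acc <- diff(v) / diff(ts)
  avg <- switch(method, abs = mean(abs(acc)), rms = sqrt(mean(acc^2)))
  if (avg < 1e-9) {
    return(structure(cap, avg_acc = avg, degenerate = TRUE))
  }
  structure(1 / avg, avg_acc = avg, degenerate = FALSE)
}

#' One-way ANOVA between two groups
#'
#' Standard one-way analysis of variance (via [stats::aov()]) comparing two
#' value vectors, as used to contrast the two transfer-entropy directions
#' across a cohort; `df_between = 1`, `df_within = n_a + n_b - 2`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return Object of class `anova_result`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`.
#' @export
anova_two_group <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  d <- data.frame(value = c(group_a, group_b),
                  group = factor(rep(c("a", "b"), c(length(group_a), length(group_b)))))
  tab <- stats::anova(stats::aov(value ~ group, data = d))
  structure(list(f_statistic = tab[["F value"]][1],
                 df_between = tab[["Df"]][1],
                 df_within = tab[["Df"]][2],
                 p_value = tab[["Pr(>F)"]][1]),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' Pearson, Kendall and Spearman correlation report
#'
#' Runs the three standard association tests via [stats::cor.test()]:
#' Pearson on values, Kendall tau-b (tie-corrected), and Spearman on average
#' ranks; rank tests use the asymptotic two-sided p-value, which handles the
#' ties typical of rounded table data. Zero-variance input yields `NA`
#' coefficients and a `degenerate` flag.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Object of class `correlation_report`: `plcc`, `kendall`,
#'   `spearman`, their p-values, `n`, `degenerate`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; correlations undefined")
    return(structure(list(plcc = NA_real_, kendall = NA_real_, spearman = NA_real_,
                          p_plcc = NA_real_, p_kendall = NA_real_, p_spearman = NA_real_,
                          n = length(x), degenerate = TRUE),
                     class = "correlation_report"))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  ke <- stats::cor.test(x, y, method = "kendall", exact = FALSE)
  sp <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  structure(list(plcc = unname(pe$estimate), kendall = unname(ke$estimate),
                 spearman = unname(sp$estimate),
                 p_plcc = pe$p.value, p_kendall = ke$p.value, p_spearman = sp$p.value,
                 n = length(x), degenerate = FALSE),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> n = %d: PLCC %.3g (p %.3g), KROCC %.3g (p %.3g), SROCC %.3g (p %.3g)\n",
              x$n, x$plcc, x$p_plcc, x$kendall, x$p_kendall, x$spearman, x$p_spearman))
  invisible(x)
}

#' Assemble per-trial metrics into a cohort report
#'
#' Takes per-trial metric rows (as produced by [analyze_trials()], or any
#' data frame with `te_head_to_eye`, `te_eye_to_head`, `nuid`, `performance`
#' columns in bits / dimensionless / s^2/m) and produces: a display table
#' with the information measures scaled by 10^2 and rounded to 2 decimals
#' (the conventional printing scale), a two-group ANOVA contrasting the TE
#' directions, and the NUID-vs-performance [correlate()] report. With fewer
#' than 3 trials the statistics are withheld with a warning.
#'
#' @param trials data frame of per-trial metrics.
#' @return List with `table` (display-scaled data frame), `anova`
#'   (`anova_result` or `NULL`), `correlations` (`correlation_report` or
#'   `NULL`).
#' @export
assemble_cohort <- function(trials) {
  trials <- as.data.frame(trials)
  tab <- trials
  for (col in intersect(c("te_head_to_eye", "te_eye_to_head", "uid", "nuid"), names(tab))) {
    tab[[paste0(col, "_x100")]] <- round(100 * tab[[col]], 2)
    tab[[col]] <- NULL
  }
  if (nrow(trials) < 3L) {
    warning("fewer than 3 trials; cohort statistics withheld")
    return(list(table = tab, anova = NULL, correlations = NULL))
  }
  an <- NULL
  if (all(c("te_head_to_eye", "te_eye_to_head") %in% names(trials))) {
    an <- anova_two_group(trials$te_head_to_eye, trials$te_eye_to_head)
  }
  co <- NULL
  if (all(c("nuid", "performance") %in% names(trials)) &&
      !anyNA(trials$performance)) {
    co <- correlate(trials$nuid, trials$performance)
  }
  list(table = tab, anova = an, correlations = co)
}
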