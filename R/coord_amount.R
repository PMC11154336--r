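#' Decibel signal-match measure of head-eye coordination
#'
#' PSNR-style score of how closely the head and eye rotation traces match in
#' value:
#' \deqn{\mathrm{CoordAmount} = 10 \log_{10}\!\frac{360^2}{\mathrm{Diff}},
#' \qquad \mathrm{Diff} = \frac{1}{n}\sum_t (y_t - x_t)^2,}
#' with 360 degrees the largest possible absolute difference between two
#' rotation samples. Higher values mean tighter magnitude coordination. The
#' measure carries no temporal ordering, so it can attest that coordination
#' exists but cannot tell which of head or eye leads — use
#' [compute_uid()] / [compute_nuid()] for direction.
#'
#' When `Diff` falls below `epsilon` (identical traces) the value is capped
#' at `10 log10(360^2 / epsilon)` and flagged degenerate.
#'
#' @param eye,head numeric rotation vectors (degrees), equal length >= 1,
#'   finite.
#' @param epsilon lower cap on `Diff` keeping the decibel value finite.
#' @return Object of class `coord_amount_result`: `diff` (mean squared
#'   difference, squared degrees), `scale_factor` (360), `num`, `value_db`,
#'   `degenerate`.
#' @export
coord_amount <- function(eye, head, epsilon = 1e-12) {
  if (length(eye) != length(head)) stop("`eye` and `head` must have equal length", call. = FALSE)
  if (length(eye) < 1L) stop("empty input", call. = FALSE)
  if (!all(is.finite(eye)) || !all(is.finite(head))) {
    stop("inputs must be finite", call. = FALSE)
  }
  scale_factor <- 360
  d <- mean((head - eye)^2)
  degenerate <- d < epsilon
  structure(list(diff = d, scale_factor = scale_factor, num = length(eye),
                 value_db = 10 * log10(scale_factor^2 / max(d, epsilon)),
                 degenerate = degenerate),
            class = "coord_amount_result")
}

#' @export
print.coord_amount_result <- function(x, ...) {
  cat(sprintf("<coord_amount_result> %.4g dB (mean squared difference %.6g deg^2 over %d samples)%s\n",
              x$value_db, x$diff, x$num,
              if (x$degenerate) " [degenerate: traces identical]" else ""))
  invisible(x)
}
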