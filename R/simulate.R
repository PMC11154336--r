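#' Specification of a synthetic coupled pair
#'
#' Describes a pair of series with known directional coupling from the
#' "head" channel to the "eye" channel, used for null calibration, power
#' analysis, and direction-recovery checks. Models:
#'
#' * `binary_copy` — source i.i.d. uniform binary, target a `lag`-shifted
#'   copy: transfer entropy in the coupled direction tends to 1 bit, the
#'   reverse to 0;
#' * `gaussian_ar` — source AR(1), target AR(1) plus `coupling` times the
#'   lagged source plus Gaussian noise;
#' * `headeye_like` — a smooth, slowly wandering "head" yaw (near-unit-root
#'   AR(1)) with an "eye" yaw that follows it at a lag through a gain, plus
#'   Poisson-timed saccade-like step offsets (bounded at +/-30 degrees) and
#'   measurement noise.
#'
#' The default length is 16,200 samples — 3 minutes at 90 Hz, one driving
#' trial.
#'
#' @param model one of `"gaussian_ar"`, `"binary_copy"`, `"headeye_like"`.
#' @param n series length in samples (`n >= lag + 2`).
#' @param self_coeff_source,self_coeff_target AR(1) coefficients, absolute
#'   value below 1.
#' @param coupling lag-coupling coefficient from head to eye.
#' @param lag coupling lag in samples, >= 1.
#' @param noise_sd innovation standard deviation (model units).
#' @param seed RNG seed; simulation is deterministic given the spec.
#' @return Object of class `coupling_spec`.
#' @export
coupling_spec <- function(model = c("gaussian_ar", "binary_copy", "headeye_like"),
                          n = 16200L, self_coeff_source = 0.5,
                          self_coeff_target = 0.5, coupling = 0.8,
                          lag = 1L, noise_sd = 0.2, seed = 1L) {
  model <- match.arg(model)
  n <- as.integer(n); lag <- as.integer(lag)
  if (lag < 1L) stop("`lag` must be >= 1", call. = FALSE)
  if (n < lag + 2L) stop("`n` must be at least lag + 2", call. = FALSE)
  if (abs(self_coeff_source) >= 1 || abs(self_coeff_target) >= 1) {
    stop("AR(1) self coefficients must have absolute value below 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(model = model, n = n,
                 self_coeff_source = self_coeff_source,
                 self_coeff_target = self_coeff_target,
                 coupling = coupling, lag = lag, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "coupling_spec")
}

ar1_series <- function(n, a, noise_sd) {
  e <- stats::rnorm(n, sd = noise_sd)
  as.numeric(stats::filter(e, a, method = "recursive"))
}

#' Simulate a coupled head/eye recording
#'
#' Generates the pair described by `spec` with ground-truth coupling from
#' head to eye, packaged as a [trial_recording()] at 90 Hz with the coupled
#' channels in yaw (pitch channels are zero). Deterministic given
#' `spec$seed`.
#'
#' @param spec a [coupling_spec()].
#' @return A [trial_recording()] with attribute `true_direction =
#'   "head->eye"` (or `"none"` at zero coupling).
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  n <- spec$n; lag <- spec$lag
  out <- with_seed(spec$seed, {
    switch(spec$model,
      binary_copy = {
        head <- sample(0:1, n, replace = TRUE)
        eye <- c(sample(0:1, lag, replace = TRUE), head[seq_len(n - lag)])
        list(head = as.numeric(head), eye = as.numeric(eye))
      },
      gaussian_ar = {
        head <- ar1_series(n, spec$self_coeff_source, spec$noise_sd)
        e <- stats::rnorm(n, sd = spec$noise_sd)
        eye <- numeric(n)
        for (t in 2:n) {
          drive <- if (t > lag) spec$coupling * head[t - lag] else 0
          eye[t] <- spec$self_coeff_target * eye[t - 1] + drive + e[t]
        }
        list(head = head, eye = eye)
      },
      headeye_like = {
        head <- ar1_series(n, 0.995, 0.5)          # slow, smooth yaw drift, sd ~ 5 deg
        head <- pmax(pmin(head, 170), -170)
        jumps <- stats::rbinom(n, 1L, 1 / 90) *     # ~1 saccade-like step per second
          stats::runif(n, -10, 10)
        offset <- numeric(n)
        for (t in 2:n) offset[t] <- max(min(offset[t - 1] + jumps[t], 30), -30)
        lagged <- c(rep(head[1], lag), head[seq_len(n - lag)])
        eye <- spec$coupling * lagged + offset + stats::rnorm(n, sd = spec$noise_sd)
        eye <- pmax(pmin(eye, 170), -170)
        list(head = head, eye = eye)
      })
  })
  rec <- trial_recording(
    timestamps = (seq_len(n) - 1L) / 90,
    eye_yaw = out$eye, eye_pitch = numeric(n),
    head_yaw = out$head, head_pitch = numeric(n),
    sample_rate = 90,
    participant_id = "sim",
    trial_id = sprintf("%s_c%g_lag%d_seed%d", spec$model, spec$coupling, lag, spec$seed)
  )
  truth <- if (spec$model != "binary_copy" && spec$coupling == 0) "none" else "head->eye"
  attr(rec, "true_direction") <- truth
  rec
}

#' Direction-recovery power analysis over a grid of coupling specs
#'
#' For each spec, repeatedly simulates the pair (fresh sub-seeds of the
#' spec's seed), runs the full UID pipeline — discretize, observed UID,
#' surrogate ensemble, significance level — and optionally NUID, and
#' summarizes the detection rate (fraction of runs with lambda above the
#' decision threshold in the true head-to-eye direction), the mean lambda,
#' and the mean NUID.
#'
#' @param grid list of [coupling_spec()] objects (a single spec is
#'   accepted).
#' @param cfg a [significance_config()]; each run derives its own surrogate
#'   master seed from `cfg$seed`.
#' @param n_seeds simulated runs per spec.
#' @param alphabet_size,scheme discretization settings (see [discretize()]).
#' @param include_nuid compute mean NUID per spec (roughly doubles the
#'   cost).
#' @return Data frame with one row per spec: model, coupling, lag, n,
#'   `detection_rate`, `mean_lambda`, `mean_nuid`, `nuid_positive_rate`
#'   (the NUID columns are `NA` when not computed).
#' @export
recovery_suite <- function(grid, cfg = significance_config(), n_seeds = 30L,
                           alphabet_size = 8L, scheme = "equal_width",
                           include_nuid = TRUE) {
  if (inherits(grid, "coupling_spec")) grid <- list(grid)
  if (length(grid) < 1L) stop("need at least one coupling spec", call. = FALSE)
  rows <- lapply(grid, function(spec) {
    sim_seeds <- derive_subseeds(spec$seed, n_seeds)
    cfg_seeds <- derive_subseeds(cfg$seed + spec$seed, n_seeds)
    lambdas <- numeric(n_seeds)
    nuids <- rep(NA_real_, n_seeds)
    for (i in seq_len(n_seeds)) {
      spec_i <- spec; spec_i$seed <- sim_seeds[i]
      rec <- simulate_pair(spec_i)
      pair <- select_axis(rec, "yaw")
      eye <- discretize(pair$eye, alphabet_size, scheme)
      head <- discretize(pair$head, alphabet_size, scheme)
      cfg_i <- cfg; cfg_i$seed <- cfg_seeds[i]
      obs <- compute_uid(transfer_entropy(head, eye), transfer_entropy(eye, head))
      ens <- uid_surrogate_ensemble(eye, head, cfg_i)
      lambdas[i] <- significance(obs$uid, ens, cfg_i)$lambda
      if (include_nuid) nuids[i] <- compute_nuid(eye, head, cfg_i)$nuid
    }
    data.frame(model = spec$model, coupling = spec$coupling, lag = spec$lag,
               n = spec$n,
               detection_rate = mean(lambdas > cfg$decision_threshold),
               mean_lambda = mean(lambdas),
               mean_nuid = mean(nuids),
               nuid_positive_rate = if (include_nuid) mean(nuids > 0) else NA_real_)
  })
  do.call(rbind, rows)
}
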