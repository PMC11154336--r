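#' Analysis run configuration
#'
#' One declarative object holding every tunable of the per-trial pipeline,
#' validated up front and embedded in all outputs so runs are reproducible
#' from their reports alone. All randomness flows from the single `seed`.
#'
#' @param axis rotation axis analyzed, `"yaw"` (default) or `"pitch"`.
#' @param alphabet_size histogram bins B for [discretize()].
#' @param scheme binning scheme, `"equal_width"` or `"quantile"`.
#' @param l,k source/target history lengths for [transfer_entropy()].
#' @param chebyshev_k,n_surrogates,decision_threshold,shuffle see
#'   [significance_config()].
#' @param seed master RNG seed.
#' @param max_gap gap-fill limit in seconds for [clean_gaps()].
#' @param unwrap treat input rotations as continuity-corrected.
#' @param acceleration `"abs"` or `"rms"`, see [driving_performance()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(axis = "yaw", alphabet_size = 8L,
                       scheme = "equal_width", l = 1L, k = 1L,
                       chebyshev_k = 6, n_surrogates = NULL,
                       decision_threshold = 6, shuffle = "both", seed = 1L,
                       max_gap = 0.1, unwrap = FALSE, acceleration = "abs") {
  axis <- match.arg(axis, c("yaw", "pitch"))
  scheme <- match.arg(scheme, c("equal_width", "quantile"))
  acceleration <- match.arg(acceleration, c("abs", "rms"))
  if (alphabet_size < 2L) stop("`alphabet_size` must be >= 2", call. = FALSE)
  if (l < 1L || k < 1L) stop("history lengths must be >= 1", call. = FALSE)
  if (max_gap < 0) stop("`max_gap` must be non-negative", call. = FALSE)
  sig <- significance_config(chebyshev_k = chebyshev_k,
                             n_surrogates = n_surrogates, seed = seed,
                             decision_threshold = decision_threshold,
                             shuffle = shuffle)
  structure(list(axis = axis, alphabet_size = as.integer(alphabet_size),
                 scheme = scheme, l = as.integer(l), k = as.integer(k),
                 significance = sig, seed = as.integer(seed),
                 max_gap = max_gap, unwrap = isTRUE(unwrap),
                 acceleration = acceleration),
            class = "run_config")
}

config_string <- function(config) {
  sig <- config$significance
  sprintf("axis=%s B=%d scheme=%s l=%d k=%d chebyshev_k=%g N_S=%d threshold=%g shuffle=%s seed=%d max_gap=%g acceleration=%s",
          config$axis, config$alphabet_size, config$scheme, config$l, config$k,
          sig$chebyshev_k, sig$n_surrogates, sig$decision_threshold,
          sig$shuffle, config$seed, config$max_gap, config$acceleration)
}

#' Run the full coordination pipeline on one recording
#'
#' Gap-cleans the recording, extracts the configured axis, discretizes both
#' channels, and computes the directed transfer entropies, UID with its
#' surrogate significance level, NUID, the decibel coordination amount, and
#' (when a speed trace is present) driving performance.
#'
#' @param rec a [trial_recording()].
#' @param config a [run_config()]; the per-trial surrogate seed is derived
#'   deterministically from `config$seed` and the trial identifiers.
#' @return One-row data frame of class `trial_metrics`.
#' @export
analyze_trial <- function(rec, config = run_config()) {
  stopifnot(inherits(rec, "trial_recording"), inherits(config, "run_config"))
  rec <- clean_gaps(rec, config$max_gap)
  pair <- select_axis(rec, config$axis)
  eye <- discretize(pair$eye, config$alphabet_size, config$scheme)
  head <- discretize(pair$head, config$alphabet_size, config$scheme)
  trial_seed <- with_seed(
    sum(utf8ToInt(paste(rec$participant_id, rec$trial_id))) + config$seed,
    sample.int(.Machine$integer.max - 1L, 1L))
  cfg <- config$significance
  cfg$seed <- trial_seed
  te_fwd <- transfer_entropy(head, eye, config$l, config$k, "head", "eye")
  te_rev <- transfer_entropy(eye, head, config$l, config$k, "eye", "head")
  uid <- compute_uid(te_fwd, te_rev)
  ens <- uid_surrogate_ensemble(eye, head, cfg, config$l, config$k)
  sig <- significance(uid$uid, ens, cfg)
  nuid <- compute_nuid(eye, head, cfg, config$l, config$k)
  ca <- coord_amount(pair$eye, pair$head)
  perf <- if (!is.null(rec$speed)) {
    driving_performance(rec$speed[!rec$missing_mask], pair$timestamps,
                        method = config$acceleration)
  } else NA_real_
  out <- data.frame(
    participant_id = rec$participant_id, trial_id = rec$trial_id,
    n_samples = length(pair$eye),
    te_head_to_eye = te_fwd$value, te_eye_to_head = te_rev$value,
    uid = uid$uid, lambda = sig$lambda, significant = sig$significant,
    nuid = nuid$nuid, coord_amount_db = ca$value_db,
    performance = as.numeric(perf),
    alphabet_size = config$alphabet_size, scheme = config$scheme,
    l = config$l, k = config$k, n_surrogates = cfg$n_surrogates,
    seed = trial_seed)
  class(out) <- c("trial_metrics", class(out))
  out
}

#' Analyze a set of trial files and write the cohort report
#'
#' Loads each trial file, runs [analyze_trial()], and assembles the cohort
#' table, two-direction TE ANOVA and NUID-performance correlations. When
#' `output_dir` is given, writes `metrics.tsv` (per-trial rows) and
#' `report.txt` (configuration, seeds, and cohort statistics).
#'
#' @param paths character vector of trial file paths (at least one).
#' @param config a [run_config()].
#' @param output_dir optional output directory (created if needed).
#' @param schema column mapping for [load_trial()].
#' @return Invisibly, a list: `metrics` (data frame), `cohort` (see
#'   [assemble_cohort()]), `config`.
#' @export
analyze_trials <- function(paths, config = run_config(), output_dir = NULL,
                           schema = trial_schema()) {
  if (length(paths) < 1L) stop("no trial files given", call. = FALSE)
  metrics <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    rec <- tryCatch(load_trial(paths[i], schema = schema, unwrapped = config$unwrap),
                    error = function(e) {
                      stop(sprintf("failed to read '%s': %s", paths[i], conditionMessage(e)),
                           call. = FALSE)
                    })
    metrics[[i]] <- analyze_trial(rec, config)
  }
  metrics <- do.call(rbind, metrics)
  cohort <- suppressWarnings(assemble_cohort(metrics))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(metrics, file.path(output_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rpt <- file.path(output_dir, "report.txt")
    lines <- c("coordte cohort report",
               paste("config:", config_string(config)),
               sprintf("trials analyzed: %d", nrow(metrics)))
    if (!is.null(cohort$anova)) {
      a <- cohort$anova
      lines <- c(lines, sprintf("TE direction ANOVA: F(%d, %d) = %.4f, p = %.3g",
                                a$df_between, a$df_within, a$f_statistic, a$p_value))
    }
    if (!is.null(cohort$correlations)) {
      co <- cohort$correlations
      lines <- c(lines, sprintf(
        "NUID vs performance: PLCC %.4f (p %.3g), KROCC %.4f (p %.3g), SROCC %.4f (p %.3g)",
        co$plcc, co$p_plcc, co$kendall, co$p_kendall, co$spearman, co$p_spearman))
    }
    writeLines(lines, rpt)
  }
  invisible(list(metrics = metrics, cohort = cohort, config = config))
}

#' Simulate a grid of coupled trials to disk
#'
#' Writes one standard-format trial file per [coupling_spec()] plus a
#' `manifest.tsv` recording the ground-truth coupling of each file, so a
#' later [analyze_trials()] run can be scored for direction recovery.
#' Sub-seeds are derived per spec, so specs sharing a seed still produce
#' distinct data.
#'
#' @param specs list of [coupling_spec()] objects.
#' @param output_dir output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
simulate_trials <- function(specs, output_dir) {
  if (inherits(specs, "coupling_spec")) specs <- list(specs)
  if (length(specs) < 1L) stop("no coupling specs given", call. = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_subseeds(sum(vapply(specs, `[[`, 0L, "seed")) + length(specs),
                           length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    spec$seed <- seeds[i]
    rec <- simulate_pair(spec)
    fname <- sprintf("sim_%02d_%s.tsv", i, spec$model)
    write_trial(rec, file.path(output_dir, fname))
    rows[[i]] <- data.frame(file = fname, model = spec$model, n = spec$n,
                            coupling = spec$coupling, lag = spec$lag,
                            noise_sd = spec$noise_sd, seed = spec$seed,
                            true_direction = attr(rec, "true_direction"))
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(output_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Recompute the reference cohort's published statistics
#'
#' From the packaged fixtures, recomputes the 48 UID values out of the two
#' TE columns, the eye-to-head TE column mean, the two-direction ANOVA, and
#' the three NUID-performance correlations, and compares each against the
#' published value at its printing precision. The Spearman row is expected
#' to fail by 0.01: the published 0.41 is not reproducible from the printed
#' (2-decimal) cohort values, which give 0.40.
#'
#' @return Data frame with columns `check`, `expected`, `actual`,
#'   `tolerance`, `pass`; attribute `all_pass`.
#' @export
fixture_check <- function() {
  te <- cohort_te(); uid <- cohort_uid(); nu <- cohort_nuid()
  uid_re <- te$te_head_to_eye_x100 - te$te_eye_to_head_x100
  an <- anova_two_group(te$te_head_to_eye_x100, te$te_eye_to_head_x100)
  co <- correlate(nu$nuid_x100, nu$performance_s2_per_m)
  rows <- rbind(
    data.frame(check = "max |UID - (TE_fwd - TE_rev)| over 48 trials (x10^-2)",
               expected = 0, actual = max(abs(uid_re - uid$uid_x100)),
               tolerance = 0.010000001),
    data.frame(check = "mean TE eye->head (x10^-2)",
               expected = 1.9, actual = mean(te$te_eye_to_head_x100),
               tolerance = 0.05),
    data.frame(check = "TE direction ANOVA F(1,94)",
               expected = 80.25, actual = an$f_statistic, tolerance = 0.02 * 80.25),
    data.frame(check = "ANOVA df_within", expected = 94, actual = an$df_within,
               tolerance = 0),
    data.frame(check = "NUID-performance PLCC", expected = 0.32,
               actual = co$plcc, tolerance = 0.005),
    data.frame(check = "NUID-performance KROCC", expected = 0.27,
               actual = co$kendall, tolerance = 0.005),
    data.frame(check = "NUID-performance SROCC", expected = 0.41,
               actual = co$spearman, tolerance = 0.005)
  )
  rows$pass <- abs(rows$actual - rows$expected) <= rows$tolerance
  attr(rows, "all_pass") <- all(rows$pass)
  rows
}
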