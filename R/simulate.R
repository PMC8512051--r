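# Synthetic waist-worn accelerometer trials.
#
# The generator emulates the structure of public fall corpora recorded at
# 200 Hz on the waist: activities of daily living (ADL) whose signal
# magnitude vector (SMV) stays near 1 g, and falls showing the two-stage
# free-fall/impact signature -- the SMV dips toward zero during free fall
# and spikes well above the ADL range at ground contact. Peak ranges for
# the two classes are disjoint by construction, so simulated corpora are
# separable in SMVmax the way the real classes are.

# fraction of the ADL peak range each activity kind occupies, plus its
# dominant oscillation frequency (Hz)
.adl_kind_table <- function() {
  list(
    standing = list(frac = c(0.00, 0.15), freq = 0.3),
    sitting  = list(frac = c(0.00, 0.20), freq = 0.4),
    walking  = list(frac = c(0.25, 0.55), freq = 2.0),
    jogging  = list(frac = c(0.55, 0.90), freq = 2.8)
  )
}

.fall_kinds_default <- c("forward_fall", "backward_fall", "lateral_fall")

#' Simulation configuration for a synthetic trial corpus
#'
#' Collects the knobs of the trial generator: class counts (hence the
#' imbalance ratio of the corpus), sampling rate, activity kind sets,
#' per-axis noise level and the class-specific SMV-peak ranges. The default
#' peak ranges are disjoint (`adl_peak_range` high end below
#' `impact_peak_range` low end) so ADL and fall trials are separable in
#' SMVmax, mirroring the separation reported for real waist-worn corpora.
#'
#' @param n_adl,n_fall number of ADL and fall trials.
#' @param fs sampling rate in Hz (default 200, the rate of the reference
#'   corpus).
#' @param adl_kinds,fall_kinds activity label sets to cycle through.
#' @param noise_sd per-axis sensor noise standard deviation, m/s^2.
#' @param adl_peak_range,impact_peak_range `(lo, hi)` target ranges for the
#'   per-trial maximum SMV, m/s^2. `impact_peak_range[1]` must exceed
#'   `adl_peak_range[2]`.
#' @param adl_duration_s,fall_duration_s trial durations in seconds; falls
#'   must last at least 3 s so a peak-centered 3 s segment exists.
#' @param master_seed integer seed from which every per-trial seed is
#'   derived.
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_adl = 100, n_fall = 10, fs = 200,
                       adl_kinds = names(.adl_kind_table()),
                       fall_kinds = .fall_kinds_default,
                       noise_sd = 0.3,
                       adl_peak_range = c(10, 25),
                       impact_peak_range = c(30, 50),
                       adl_duration_s = 10, fall_duration_s = 12,
                       master_seed = 0L) {
  if (n_adl < 0 || n_fall < 0 || n_adl + n_fall < 1)
    stop_imbfall("need n_adl >= 0, n_fall >= 0 and at least one trial",
                 "imbfall_config_error")
  if (n_adl > 0 && length(adl_kinds) == 0)
    stop_imbfall("n_adl > 0 but `adl_kinds` is empty", "imbfall_config_error")
  if (n_fall > 0 && length(fall_kinds) == 0)
    stop_imbfall("n_fall > 0 but `fall_kinds` is empty", "imbfall_config_error")
  if (impact_peak_range[1] <= adl_peak_range[2])
    stop_imbfall(
      "impact_peak_range must lie strictly above adl_peak_range (disjoint SMVmax classes)",
      "imbfall_config_error")
  structure(list(
    n_adl = as.integer(n_adl), n_fall = as.integer(n_fall), fs = fs,
    adl_kinds = adl_kinds, fall_kinds = fall_kinds, noise_sd = noise_sd,
    adl_peak_range = adl_peak_range, impact_peak_range = impact_peak_range,
    adl_duration_s = adl_duration_s, fall_duration_s = fall_duration_s,
    master_seed = as.integer(master_seed),
    imbalance_ratio = if (n_fall > 0) n_adl / n_fall else Inf
  ), class = "sim_config")
}

new_sensor_trial <- function(data, fs, activity_class, is_fall, trial_id,
                             seed = NA_integer_, unit = "m/s2") {
  structure(list(data = data, fs = fs, unit = unit,
                 activity_class = activity_class, is_fall = is_fall,
                 trial_id = trial_id, seed = seed),
            class = "sensor_trial")
}

#' @export
print.sensor_trial <- function(x, ...) {
  cat(sprintf("<sensor_trial> %s  [%s, %s]\n", x$trial_id, x$activity_class,
              if (x$is_fall) "fall" else "ADL"))
  cat(sprintf("  %d samples x %d channels @ %g Hz (%s), SMVmax = %.2f\n",
              nrow(x$data), ncol(x$data), x$fs, x$unit,
              smv_max(x)$value))
  invisible(x)
}

# local RNG scope: generators never disturb the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one activity-of-daily-living trial
#'
#' Generates a tri-axial accelerometer trace for a non-fall activity:
#' gravity along the vertical axis plus a rectified periodic activity
#' component whose amplitude is scaled so the trial's maximum SMV lands
#' inside `adl_peak_range`, plus i.i.d. Gaussian sensor noise on every
#' axis. The SMV therefore oscillates about 1 g and never approaches the
#' free-fall regime.
#'
#' @param kind one of the configured ADL kinds (default table: `standing`,
#'   `sitting`, `walking`, `jogging`).
#' @param duration_s trial duration, seconds.
#' @param fs sampling rate, Hz.
#' @param seed integer seed; the same call with the same seed is
#'   bit-identical.
#' @param noise_sd per-axis noise SD, m/s^2.
#' @param adl_peak_range target `(lo, hi)` range for the trial's SMVmax.
#' @param trial_id identifier stored in the trial.
#' @param n_channels total channel count; channels beyond the first three
#'   are zero-filled (placeholders for extra sensors).
#' @return a `sensor_trial`.
#' @export
sim_adl_trial <- function(kind, duration_s, fs, seed,
                          noise_sd = 0.3, adl_peak_range = c(10, 25),
                          trial_id = sprintf("adl_%s_%d", kind, seed),
                          n_channels = 3L) {
  table <- .adl_kind_table()
  if (!kind %in% names(table))
    stop_imbfall(sprintf("unknown ADL kind '%s' (known: %s)", kind,
                         paste(names(table), collapse = ", ")),
                 "imbfall_kind_error")
  assert_scalar_pos(duration_s, "duration_s", "imbfall_value_error")
  assert_scalar_pos(fs, "fs", "imbfall_value_error")
  spec <- table[[kind]]
  n <- round(duration_s * fs)
  with_seed(seed, {
    # target peak drawn inside the kind's slice of the ADL range, with a
    # small margin so additive noise cannot push SMVmax out of range
    w <- diff(adl_peak_range)
    lo <- adl_peak_range[1] + spec$frac[1] * w
    hi <- adl_peak_range[1] + spec$frac[2] * w
    margin <- min(4 * noise_sd, 0.4 * (hi - lo))
    target <- stats::runif(1, lo + margin, hi - margin)
    amp <- target - GRAVITY          # peak ranges sit above 1 g by design
    t <- (seq_len(n) - 1) / fs
    phase <- stats::runif(1, 0, 2 * pi)
    # rectified oscillation: activity only ever adds magnitude, so the SMV
    # floor stays at ~1 g (no spurious free-fall dips in ADL data)
    act <- amp * (1 + sin(2 * pi * spec$freq * t + phase)) / 2
    az <- GRAVITY + act
    ax <- stats::rnorm(n, 0, noise_sd)
    ay <- stats::rnorm(n, 0, noise_sd)
    az <- az + stats::rnorm(n, 0, noise_sd)
    data <- cbind(ax, ay, az)
    if (n_channels > 3L)
      data <- cbind(data, matrix(0, n, n_channels - 3L))
    colnames(data) <- NULL
    new_sensor_trial(data, fs, kind, FALSE, trial_id, seed)
  })
}

#' Simulate one fall trial with the free-fall/impact signature
#'
#' Generates, in order: pre-fall walking, a free-fall interval in which all
#' axes decay toward zero (SMV < 3 m/s^2), a single dominant half-sine
#' impact whose peak SMV lands inside `impact_peak_range`, and low-motion
#' rest in a lying orientation. The impact peak is the trial's unique
#' global SMV maximum.
#'
#' @inheritParams sim_adl_trial
#' @param kind fall-kind label (stored; kinds share one phenomenology and
#'   differ in impact direction).
#' @param impact_peak_range target `(lo, hi)` range for the impact SMV peak.
#' @param adl_peak_range ADL SMVmax range; the pre-fall walking phase is
#'   drawn from the same amplitude law as ADL walking, so windows that
#'   precede the fall are statistically indistinguishable from ordinary
#'   walking (as in real recordings, where the activity before a fall is
#'   just activity).
#' @return a `sensor_trial`.
#' @export
sim_fall_trial <- function(kind, duration_s, fs, seed,
                           noise_sd = 0.3, impact_peak_range = c(30, 50),
                           adl_peak_range = c(10, 25),
                           trial_id = sprintf("fall_%s_%d", kind, seed),
                           n_channels = 3L) {
  assert_scalar_pos(fs, "fs", "imbfall_value_error")
  if (!is.numeric(duration_s) || duration_s < 3)
    stop_imbfall("fall trials must last at least 3 s so a 3 s peak-centered segment exists",
                 "imbfall_value_error")
  n <- round(duration_s * fs)
  with_seed(seed, {
    t_free <- 0.35                      # free-fall duration, s
    t_impact <- 0.08                    # impact pulse width, s
    n_free <- max(round(t_free * fs), 2L)
    n_imp <- max(round(t_impact * fs), 3L)
    if (n_imp %% 2L == 0L) n_imp <- n_imp + 1L  # odd width: unique peak sample
    # impact centered near 60% of the trial (jittered), away from the edges
    frac <- stats::runif(1, 0.45, 0.7)
    i_peak <- round(frac * n)
    i_imp0 <- i_peak - (n_imp - 1L) %/% 2L
    i_free0 <- i_imp0 - n_free
    n_pre <- i_free0 - 1L

    w <- diff(impact_peak_range)
    margin <- min(4 * noise_sd, 0.2 * w)
    peak <- stats::runif(1, impact_peak_range[1] + margin,
                         impact_peak_range[2] - margin)

    ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
    # pre-fall: ordinary walking, same amplitude law as ADL walking so
    # pre-impact windows carry no artificial fall cue
    walk <- .adl_kind_table()$walking
    wlk_w <- diff(adl_peak_range)
    wlk_lo <- adl_peak_range[1] + walk$frac[1] * wlk_w
    wlk_hi <- adl_peak_range[1] + walk$frac[2] * wlk_w
    wamp <- stats::runif(1, wlk_lo, wlk_hi) - GRAVITY
    tp <- (seq_len(n_pre) - 1) / fs
    phase <- stats::runif(1, 0, 2 * pi)
    az[seq_len(n_pre)] <- GRAVITY +
      wamp * (1 + sin(2 * pi * walk$freq * tp + phase)) / 2
    # free fall: exponential decay of the measured acceleration toward zero
    idx_free <- i_free0:(i_imp0 - 1L)
    decay <- exp(-((seq_along(idx_free) - 1) / fs) / 0.12)
    az[idx_free] <- GRAVITY * decay
    # impact: half-sine pulse along a kind-dependent direction
    idx_imp <- i_imp0:(i_imp0 + n_imp - 1L)
    pulse <- peak * sin(pi * (seq_len(n_imp) - 0.5) / n_imp)
    dir <- switch(kind,
                  forward_fall  = c(0.8, 0.1, 0.6),
                  backward_fall = c(-0.8, 0.1, 0.6),
                  lateral_fall  = c(0.1, 0.8, 0.6),
                  c(0.5, 0.5, 0.7))
    dir <- dir / sqrt(sum(dir^2))
    ax[idx_imp] <- dir[1] * pulse
    ay[idx_imp] <- dir[2] * pulse
    az[idx_imp] <- dir[3] * pulse
    # rest: lying, gravity now along x
    idx_rest <- (i_imp0 + n_imp):n
    ax[idx_rest] <- GRAVITY
    az[idx_rest] <- 0
    data <- cbind(ax + stats::rnorm(n, 0, noise_sd),
                  ay + stats::rnorm(n, 0, noise_sd),
                  az + stats::rnorm(n, 0, noise_sd))
    # keep the analytic impact sample the exact global argmax: noise is
    # small relative to the class separation but could otherwise retune
    # which in-pulse sample wins
    data[i_peak, ] <- dir * peak
    if (n_channels > 3L)
      data <- cbind(data, matrix(0, n, n_channels - 3L))
    colnames(data) <- NULL
    new_sensor_trial(data, fs, kind, TRUE, trial_id, seed)
  })
}

#' Simulate a corpus of labeled trials with a controlled imbalance ratio
#'
#' Generates `n_adl` ADL and `n_fall` fall trials, cycling through the
#' configured kind sets. Per-trial seeds are derived deterministically from
#' `master_seed`, so the same configuration always yields a byte-identical
#' corpus.
#'
#' @param config a [sim_config()].
#' @return an object of class `trial_corpus`: a list with `trials` (list of
#'   `sensor_trial`) and `manifest` (data frame with trial_id, class,
#'   fall flag, seed, sample count) plus the generating `config`.
#' @export
sim_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  trials <- vector("list", config$n_adl + config$n_fall)
  i <- 0L
  for (j in seq_len(config$n_adl)) {
    kind <- config$adl_kinds[[(j - 1L) %% length(config$adl_kinds) + 1L]]
    i <- i + 1L
    trials[[i]] <- sim_adl_trial(
      kind, config$adl_duration_s, config$fs,
      seed = derive_seed(config$master_seed, i),
      noise_sd = config$noise_sd, adl_peak_range = config$adl_peak_range,
      trial_id = sprintf("adl_%04d_%s", j, kind))
  }
  for (j in seq_len(config$n_fall)) {
    kind <- config$fall_kinds[[(j - 1L) %% length(config$fall_kinds) + 1L]]
    i <- i + 1L
    trials[[i]] <- sim_fall_trial(
      kind, config$fall_duration_s, config$fs,
      seed = derive_seed(config$master_seed, i),
      noise_sd = config$noise_sd,
      impact_peak_range = config$impact_peak_range,
      adl_peak_range = config$adl_peak_range,
      trial_id = sprintf("fall_%04d_%s", j, kind))
  }
  manifest <- data.frame(
    trial_id = vapply(trials, `[[`, "", "trial_id"),
    activity_class = vapply(trials, `[[`, "", "activity_class"),
    is_fall = vapply(trials, `[[`, NA, "is_fall"),
    n_samples = vapply(trials, function(tr) nrow(tr$data), 0L),
    fs = config$fs,
    seed = vapply(trials, `[[`, NA_integer_, "seed"),
    stringsAsFactors = FALSE)
  structure(list(trials = trials, manifest = manifest, config = config),
            class = "trial_corpus")
}

#' @export
print.trial_corpus <- function(x, ...) {
  n_fall <- sum(x$manifest$is_fall)
  n_adl <- nrow(x$manifest) - n_fall
  cat(sprintf("<trial_corpus> %d trials: %d ADL, %d fall (imbalance ratio %s)\n",
              nrow(x$manifest), n_adl, n_fall,
              if (n_fall > 0) sprintf("%.2f", n_adl / n_fall) else "Inf"))
  invisible(x)
}

#' Write / read a trial corpus in the plain-text trial dialect
#'
#' One headerless CSV per trial (rows = timesteps, columns = channels,
#' first three = accelerometer x, y, z) plus a `manifest.csv` sidecar with
#' trial_id, file, activity_class, fall flag, sampling rate and unit.
#'
#' @param corpus a `trial_corpus`.
#' @param dir output directory (created if missing).
#' @return `write_corpus` returns the manifest path invisibly;
#'   `read_corpus` returns a `trial_corpus` (without the simulation
#'   config).
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "trial_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(corpus$trials))
  for (i in seq_along(corpus$trials)) {
    tr <- corpus$trials[[i]]
    files[i] <- paste0(tr$trial_id, ".csv")
    utils::write.table(format(tr$data, digits = 10, trim = TRUE,
                              scientific = FALSE),
                       file.path(dir, files[i]), sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  man <- corpus$manifest
  man$file <- files
  man$unit <- vapply(corpus$trials, `[[`, "", "unit")
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  trials <- lapply(seq_len(nrow(man)), function(i) {
    data <- as.matrix(utils::read.table(file.path(dir, man$file[i]),
                                        sep = ",", header = FALSE))
    dimnames(data) <- NULL
    new_sensor_trial(data, man$fs[i], man$activity_class[i],
                     as.logical(man$is_fall[i]), man$trial_id[i],
                     if ("seed" %in% names(man)) man$seed[i] else NA_integer_,
                     unit = if ("unit" %in% names(man)) man$unit[i] else "m/s2")
  })
  structure(list(trials = trials, manifest = man[setdiff(names(man), c("file", "unit"))],
                 config = NULL),
            class = "trial_corpus")
}
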