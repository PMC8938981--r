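# External drives: homogeneous Poisson background per population, the
# rate-modulated transient cortical stimulus, trial schedules, and the
# calibration routines that tune them.

#' Generate independent homogeneous Poisson spike trains
#'
#' @param rate Rate in spikes/s (>= 0).
#' @param n_sources Number of independent trains.
#' @param duration Duration (ms).
#' @param seed Optional integer seed.
#' @return List of numeric vectors of spike times (ms), one per source.
#' @export
poisson_trains <- function(rate, n_sources, duration, seed = NULL) {
  if (rate < 0) stop("rate must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_sources), function(i) {
    n <- stats::rpois(1, rate * duration / 1000)
    sort(stats::runif(n, 0, duration))
  })
}

#' Background Poisson drive
#'
#' Per-population rate (spikes/s) and synaptic weight (nS) of the uncorrelated
#' excitatory Poisson input every neuron receives.  Each neuron gets its own
#' realization.  The weight is a fixed nominal EPSG per population; only rates
#' are tuned by [calibrate_background()].
#'
#' @param rate Named list/vector of rates (Hz) per population.
#' @param weight Named list/vector of weights (nS) per population (default
#'   1 nS everywhere).
#' @return A `bg_background` object.
#' @export
background_drive <- function(rate, weight = NULL) {
  rate <- as.list(rate)
  if (is.null(weight))
    weight <- stats::setNames(as.list(rep(1, length(rate))), names(rate))
  weight <- as.list(weight)
  stopifnot(all(unlist(rate) >= 0))
  structure(list(rate = rate, weight = weight), class = "bg_background")
}

#' Load the shipped calibrated background drive for a condition
#'
#' The packaged rates are the outcome of [calibrate_background()] run against
#' each condition's baseline-rate targets; they serve as the default drive
#' and as the starting point when recalibration is requested.
#'
#' @param condition Condition name.
#' @return A `bg_background`.
#' @export
default_background <- function(condition = c("normal", "PD-biphasic",
                                             "PD-triphasic")) {
  condition <- match.arg(condition)
  path <- system.file("extdata",
                      paste0("background_", condition, ".yaml"),
                      package = "bgnet")
  obj <- yaml::read_yaml(path)
  background_drive(obj$rate, obj$weight)
}

#' Write a background drive as a YAML artifact
#'
#' @param background A `bg_background`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_background <- function(background, path) {
  yaml::write_yaml(list(rate = background$rate, weight = background$weight),
                   path, precision = 15L)
  invisible(path)
}

#' Calibrate background rates against baseline firing-rate targets
#'
#' Tunes each population's background Poisson rate until the simulated
#' baseline mean rates fall inside the condition's target intervals.  The
#' population's own rate is monotone in its own drive, so calibration is a
#' per-population line search: the drive is first stepped geometrically until
#' it brackets the target, then bisected in log space; an outer loop over the
#' populations (upstream nuclei first: striatum and STN, then GPe, then SNr)
#' repeats until joint convergence.  The strong coupling between STN, GPe-TI
#' and SNr makes the network's response to a single drive very steep, which
#' is why bracketing/bisection is used rather than joint gradient-style
#' updates.  Measurement discards the first 500 ms of each run.
#'
#' @param network A `bg_network`.
#' @param init A `bg_background` with starting rates (and the fixed weights).
#' @param targets Per-population target intervals; defaults to the network
#'   condition's `rate_targets`.
#' @param duration Simulated ms per evaluation (the first 500 ms are
#'   discarded).
#' @param max_rounds Maximum outer rounds over the population sequence.
#' @param max_evals Cap on per-population simulations within one line search.
#' @param order Population tuning order; defaults to upstream-first.
#' @param seed Integer seed.
#' @return A `bg_background` with tuned rates; attributes `achieved` (measured
#'   rates), `converged`, and `residual` (distance to interval, Hz).
#' @export
calibrate_background <- function(network, init, targets = NULL,
                                 duration = 2500, max_rounds = 3,
                                 max_evals = 9, order = NULL, seed = 1L) {
  stopifnot(inherits(network, "bg_network"))
  if (is.null(targets)) targets <- network$condition$rate_targets
  pops <- names(targets)
  if (is.null(order))
    order <- intersect(c("D1-SPN", "D2-SPN", "FSI", "STN",
                         "GPe-TA", "GPe-TI", "SNr"), pops)
  bg <- init
  network <- prepare_network(network)
  seed_i <- 0L

  measure <- function(bg) {
    seed_i <<- seed_i + 1L
    ras <- simulate_trial(network, background = bg, duration = duration,
                          seed = seed + seed_i)
    population_rates(ras, window = c(500, duration))
  }
  ok_one <- function(measured, p) {
    tr <- targets[[p]]
    measured[[p]] >= tr[1] && measured[[p]] <= tr[2]
  }

  measured <- measure(bg)
  for (round in seq_len(max_rounds)) {
    if (all(vapply(pops, ok_one, TRUE, measured = measured))) break
    for (p in order) {
      if (ok_one(measured, p)) next
      tr <- targets[[p]]
      evals <- 0L
      # bracket: lo drives below the interval, hi drives above it
      lo <- NULL; hi <- NULL
      cur <- max(bg$rate[[p]], 10)
      if (measured[[p]] > tr[2]) hi <- list(r = cur) else lo <- list(r = cur)
      while (evals < max_evals && (is.null(lo) || is.null(hi))) {
        cur <- if (is.null(hi)) cur * 1.4 else cur / 1.4
        bg$rate[[p]] <- cur
        measured <- measure(bg)
        evals <- evals + 1L
        if (ok_one(measured, p)) break
        if (measured[[p]] > tr[2]) hi <- list(r = cur) else lo <- list(r = cur)
      }
      # bisect in log space until inside the interval
      while (evals < max_evals && !ok_one(measured, p) &&
             !is.null(lo) && !is.null(hi)) {
        cur <- exp((log(lo$r) + log(hi$r)) / 2)
        bg$rate[[p]] <- cur
        measured <- measure(bg)
        evals <- evals + 1L
        if (measured[[p]] > tr[2]) hi <- list(r = cur) else lo <- list(r = cur)
      }
    }
  }
  resid <- vapply(pops, function(p) {
    tr <- targets[[p]]
    max(0, tr[1] - measured[[p]], measured[[p]] - tr[2])
  }, 0)
  attr(bg, "achieved") <- measured
  attr(bg, "converged") <- all(resid == 0)
  attr(bg, "residual") <- resid
  if (!all(resid == 0))
    warning("background calibration did not reach all targets; residuals (Hz): ",
            paste(sprintf("%s=%.2f", pops[resid > 0], resid[resid > 0]),
                  collapse = ", "))
  bg
}

#' Transient cortical stimulus profile
#'
#' The stimulus is a rate-modulated Poisson spike train delivered to a
#' fraction of the striatal and STN populations: a rectangular excitatory
#' pulse (`pulse_rate` spikes/s for `pulse_dur` ms) followed by a rectangular
#' suppression of the stimulated neurons' cortical background to a fraction
#' `supp_frac` of its baseline for `supp_dur` ms, emulating the brief
#' excitation-then-suppression cortical response to stimulation.  The rate
#' profile is identical across trials; spike realizations differ.
#'
#' `weight` gives the healthy-condition stimulus synapse weight per target
#' population; in a given condition the effective weight is scaled by the
#' cortical dopamine sensitivities (`stim_scale` of the condition bundle).
#' `delay` is the cortex-to-target conduction delay per population.
#'
#' @param pulse_rate Pulse amplitude (spikes/s).
#' @param pulse_dur Pulse duration (ms).
#' @param supp_frac Background factor during suppression (0..1).
#' @param supp_dur Suppression duration (ms).
#' @param plateau_rate,plateau_dur Optional second pulse segment (spikes/s,
#'   ms) between the peak and the suppression: a lower sustained plateau,
#'   emulating a cortical response whose sharp onset decays into a weaker
#'   tail before the sub-baseline suppression.
#' @param shape `"rect"` for a rectangular pulse or `"cos2"` for a smooth
#'   raised-cosine bump of the same peak rate and duration (the smooth shape
#'   disperses the evoked volleys and avoids artificial millisecond-scale
#'   synchronization of the stimulated populations).
#' @param weight Named vector, stimulus weight (nS) per target population.
#' @param delay Named vector, conduction delay (ms) per target population.
#' @param targets Populations receiving the stimulus.
#' @return A `bg_stimulus_profile`.
#' @export
stimulus_profile <- function(pulse_rate, pulse_dur, supp_frac, supp_dur,
                             weight, delay,
                             targets = c("D1-SPN", "D2-SPN", "STN"),
                             plateau_rate = 0, plateau_dur = 0,
                             shape = c("rect", "cos2")) {
  shape <- match.arg(shape)
  stopifnot(pulse_rate >= 0, supp_frac >= 0, supp_frac <= 1,
            plateau_rate >= 0, plateau_dur >= 0)
  structure(list(pulse_rate = pulse_rate, pulse_dur = pulse_dur,
                 supp_frac = supp_frac, supp_dur = supp_dur,
                 plateau_rate = plateau_rate, plateau_dur = plateau_dur,
                 shape = shape,
                 weight = weight, delay = delay, targets = targets),
            class = "bg_stimulus_profile")
}

#' Load the calibrated default stimulus profile
#'
#' The shipped profile was fitted once, in the healthy condition, so that the
#' nigral transient response reproduces the early-excitation latency/duration
#' and early-inhibition latency anchors; it is then frozen and reused
#' unchanged for all conditions and experiments.
#'
#' @return A `bg_stimulus_profile`.
#' @export
default_stimulus_profile <- function() {
  path <- system.file("extdata", "stimulus_profile.yaml", package = "bgnet")
  obj <- yaml::read_yaml(path)
  stimulus_profile(obj$pulse_rate, obj$pulse_dur, obj$supp_frac, obj$supp_dur,
                   weight = unlist(obj$weight), delay = unlist(obj$delay),
                   targets = obj$targets)
}

#' Trial schedule for transient-response experiments
#'
#' @param n_trials Number of trials (default 100).
#' @param duration Recorded ms per trial (default 1200).
#' @param onset_window Stimulation onset drawn uniformly in this window (ms;
#'   default \[700, 900\], which also discards the startup transient).
#' @param seed Integer seed for the onset draws.
#' @return A `bg_schedule` with per-trial `onsets`.
#' @export
trial_schedule <- function(n_trials = 100, duration = 1200,
                           onset_window = c(700, 900), seed = 1L) {
  set.seed(seed)
  onsets <- stats::runif(n_trials, onset_window[1], onset_window[2])
  structure(list(n_trials = n_trials, duration = duration,
                 onset_window = onset_window, onsets = onsets),
            class = "bg_schedule")
}

#' Draw the stimulated subsets and assemble a per-trial stimulus
#'
#' Chooses the stimulated fraction of each target population (fixed across
#' trials for a given build seed) and returns a function of the trial onset
#' producing the `bg_stimulus_trial` consumed by [simulate_trial()].  The
#' stimulus weight onto each target population is the profile's healthy
#' weight scaled by the condition's cortical dopamine factor.
#'
#' @param network A `bg_network`.
#' @param profile A `bg_stimulus_profile`.
#' @param fraction Stimulated fraction of each target population (0..1].
#' @param seed Seed for the subset draw.
#' @param stn_only If `TRUE`, only the STN receives the stimulus.
#' @return A function `f(onset_ms)` returning a `bg_stimulus_trial`.
#' @export
transient_stimulus <- function(network, profile, fraction = 0.5, seed = 1L,
                               stn_only = FALSE) {
  stopifnot(inherits(network, "bg_network"),
            inherits(profile, "bg_stimulus_profile"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  targets <- profile$targets
  if (stn_only) targets <- intersect(targets, "STN")
  set.seed(seed)
  ids <- integer(0); weights <- numeric(0); shifts_ms <- numeric(0)
  scale <- network$condition$stim_scale
  for (pop in targets) {
    pid <- population_ids(network, pop)
    k <- round(fraction * length(pid))
    sel <- sort(sample(pid, k))
    ids <- c(ids, sel)
    weights <- c(weights, rep(profile$weight[[pop]] * scale[[pop]], k))
    shifts_ms <- c(shifts_ms, rep(profile$delay[[pop]], k))
  }
  force(profile)
  function(onset) {
    structure(list(
      ids = ids, weights = weights, shifts_ms = shifts_ms, onset = onset,
      rate_fn = function(n_steps, dt) {
        r <- numeric(n_steps)
        i0 <- round(onset / dt)
        i1 <- min(n_steps, i0 + round(profile$pulse_dur / dt))
        if (i0 < n_steps) {
          if (identical(profile$shape, "cos2")) {
            tt <- (seq.int(i0 + 1, i1) - i0 - 0.5) * dt
            r[(i0 + 1):i1] <-
              profile$pulse_rate * sin(pi * tt / profile$pulse_dur)^2
          } else {
            r[(i0 + 1):i1] <- profile$pulse_rate
          }
        }
        if (profile$plateau_dur > 0 && i1 < n_steps) {
          i2 <- min(n_steps, i1 + round(profile$plateau_dur / dt))
          r[(i1 + 1):i2] <- profile$plateau_rate
        }
        r
      },
      mod_fn = function(n_steps, dt) {
        m <- rep(1, n_steps)
        s0 <- round((onset + profile$pulse_dur + profile$plateau_dur) / dt)
        s1 <- min(n_steps, s0 + round(profile$supp_dur / dt))
        if (s0 < n_steps) m[(s0 + 1):s1] <- profile$supp_frac
        m
      }),
      class = "bg_stimulus_trial")
  }
}

#' Fit the free stimulus parameters against healthy-condition anchors
#'
#' One-time calibration: adjusts the pulse amplitude (and optionally the
#' stimulus weights) of a starting profile so that the healthy-condition SNr
#' response attains early-excitation latency 7 ms, duration 4 ms and
#' early-inhibition latency 11 ms at 1-ms binning.  The returned profile is
#' meant to be frozen (see [default_stimulus_profile()]) and reused for every
#' condition; low-dopamine runs must not re-tune it.
#'
#' @param network Healthy-condition `bg_network`.
#' @param background Calibrated `bg_background`.
#' @param start Starting `bg_stimulus_profile`.
#' @param amp_grid Multiplicative factors applied to `pulse_rate`.
#' @param n_trials Trials per evaluation.
#' @param seed Integer seed.
#' @return The best-fitting `bg_stimulus_profile`, with attribute `anchors`
#'   (achieved EE latency/duration and EI latency) and `score`.
#' @export
calibrate_stimulus <- function(network, background, start,
                               amp_grid = c(0.75, 1, 1.25), n_trials = 10,
                               seed = 1L) {
  best <- NULL
  for (f in amp_grid) {
    prof <- start
    prof$pulse_rate <- start$pulse_rate * f
    res <- run_transient_experiment(network, background, prof,
                                    n_trials = n_trials, seed = seed)
    z <- res$zones$SNr
    ee <- z[z$zone == "EE", ]
    ei <- z[z$zone == "EI", ]
    lat_ee <- if (nrow(ee) && ee$detected) ee$L else NA
    dur_ee <- if (nrow(ee) && ee$detected) ee$D else NA
    lat_ei <- if (nrow(ei) && ei$detected) ei$L else NA
    score <- sum(abs(c(lat_ee - 7, dur_ee - 4, lat_ei - 11)), na.rm = TRUE) +
      50 * sum(is.na(c(lat_ee, dur_ee, lat_ei)))
    if (is.null(best) || score < best$score)
      best <- list(profile = prof, score = score,
                   anchors = c(EE_latency = lat_ee, EE_duration = dur_ee,
                               EI_latency = lat_ei))
  }
  out <- best$profile
  attr(out, "anchors") <- best$anchors
  attr(out, "score") <- best$score
  out
}

#' Onset times locked to a target phase of the nigral beta oscillation
#'
#' Runs stimulus-free preview trials of the (low-dopamine) network, extracts
#' the 12-30 Hz Hilbert phase of the SNr population rate, and for each trial
#' picks an onset inside the scheduling window at which the instantaneous
#' phase equals the requested `phi` (radians; peak = 0, trough = pi by the
#' cosine convention of the analytic signal).  Delivering the stimulus in a
#' re-run of the same trial seed reproduces the pre-onset trajectory exactly,
#' so the stimulus arrives at the requested phase.
#'
#' @param network A `bg_network` in a low-dopamine condition.
#' @param background Calibrated `bg_background`.
#' @param phi Target phase (radians in \[0, 2*pi)); presets used by the
#'   experiments: `1.20*pi` (trough), `1.61*pi`, `1.81*pi` (rising/peak),
#'   `0.23*pi` (falling edge).
#' @param n_trials Number of trials (default 48).
#' @param duration Trial duration (ms).
#' @param onset_window Window the onset may fall in (ms).
#' @param tol Phase tolerance (radians).
#' @param seed Integer seed; trial `i` uses seed `seed + i`.
#' @param min_oi Minimum beta-band oscillation index required of the preview
#'   activity.
#' @return Data frame with `trial`, `seed`, `onset` (ms) and the realized
#'   `phase`.
#' @export
phase_locked_onsets <- function(network, background, phi, n_trials = 48,
                                duration = 1200, onset_window = c(700, 900),
                                tol = 0.1 * pi, seed = 1L, min_oi = 0.05) {
  network <- prepare_network(network)
  out <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    ras <- simulate_trial(network, background = background,
                          duration = duration, seed = seed + i)
    sp <- population_spikes(ras, "SNr")
    rate <- spike_rate_series(sp$t, duration, bin = 1) / sp$n * 1000
    oi <- oscillation_index(rate[-(1:500)], bin = 1)
    if (oi < min_oi)
      stop("insufficient beta-band power in preview trial ", i,
           " (OI = ", signif(oi, 3), ")")
    ph <- instantaneous_phase(rate, fs = 1000, band = c(12, 30))
    idx <- seq.int(onset_window[1], onset_window[2])
    d <- abs(((ph[idx] - phi + pi) %% (2 * pi)) - pi)
    j <- which(d <= tol)
    if (!length(j)) j <- which.min(d)
    pick <- j[ceiling(stats::runif(1) * length(j))]
    out[[i]] <- data.frame(trial = i, seed = seed + i,
                           onset = idx[pick], phase = ph[idx[pick]])
  }
  do.call(rbind, out)
}
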