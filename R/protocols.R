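# Scripted end-to-end experiment protocols: transient-response runs, the
# stimulated-fraction sweep, six-connection weight sweeps, restoration and
# lesion experiments, dopamine-level sweeps and phase-conditioned
# stimulation.  Every protocol is reproducible from its arguments and seed.

#' Run a transient-stimulation experiment
#'
#' Simulates `n_trials` trials with the calibrated background and the frozen
#' transient stimulus delivered to a fraction of the striatal and STN
#' populations (onset drawn uniformly in the schedule window per trial),
#' builds per-population PSTHs and segments the SNr response into zones.
#'
#' @param network A `bg_network`.
#' @param background Calibrated `bg_background`.
#' @param profile A `bg_stimulus_profile` (default: the shipped calibrated
#'   profile).
#' @param fraction Stimulated fraction (default 0.5).
#' @param n_trials Trials (100 for headline runs; smaller for fast runs).
#' @param duration Trial length in ms (default 1200).
#' @param seed Master seed (controls subsets, onsets and realizations).
#' @param stn_only Deliver the stimulus to the STN only.
#' @param pops Populations for which PSTHs are returned.
#' @return A `bg_transient`: list with `psth` (per population), `zones` (per
#'   population), `signature` (SNr), `onsets`, `counts` (per-neuron binned
#'   counts per population), `condition`, `seed`.
#' @export
run_transient_experiment <- function(network, background,
                                     profile = default_stimulus_profile(),
                                     fraction = 0.5, n_trials = 20,
                                     duration = 1200, seed = 1L,
                                     stn_only = FALSE,
                                     pops = c("GPe-TA", "GPe-TI", "STN", "SNr")) {
  stopifnot(inherits(network, "bg_network"))
  network <- prepare_network(network)
  sched <- trial_schedule(n_trials = n_trials, duration = duration,
                          seed = seed)
  stim_fn <- transient_stimulus(network, profile, fraction = fraction,
                                seed = seed, stn_only = stn_only)
  rasters <- vector("list", n_trials)
  for (i in seq_len(n_trials))
    rasters[[i]] <- simulate_trial(network, background = background,
                                   stimulus = stim_fn(sched$onsets[i]),
                                   duration = duration, seed = seed + 1000L + i)
  counts <- lapply(stats::setNames(pops, pops), function(p)
    psth_counts(rasters, sched$onsets, p))
  psth <- lapply(counts, psth_from_counts, n_trials = n_trials)
  zones <- lapply(psth, detect_zones)
  structure(list(psth = psth, zones = zones,
                 signature = extract_signature(zones$SNr),
                 onsets = sched$onsets, counts = counts,
                 condition = network$condition$name, fraction = fraction,
                 seed = seed),
            class = "bg_transient")
}

#' @export
print.bg_transient <- function(x, ...) {
  cat("Transient experiment (", x$condition, ", fraction ", x$fraction,
      ", ", length(x$onsets), " trials)\nSNr zones:\n", sep = "")
  print(x$zones$SNr, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sweep the stimulated fraction of the striatal and STN populations
#'
#' @inheritParams run_transient_experiment
#' @param fractions Fractions to test (default 0.1 to 1 in steps of 0.1).
#' @return List (one element per fraction) of SNr zone tables; attribute
#'   `fractions`.
#' @export
run_fraction_sweep <- function(network, background,
                               profile = default_stimulus_profile(),
                               fractions = seq(0.1, 1, by = 0.1),
                               n_trials = 20, seed = 1L) {
  out <- lapply(fractions, function(f) {
    res <- run_transient_experiment(network, background, profile,
                                    fraction = f, n_trials = n_trials,
                                    seed = seed, pops = "SNr")
    res$zones$SNr
  })
  attr(out, "fractions") <- fractions
  out
}

#' Seven-point weight grid for one projection
#'
#' For a projection with healthy weight `v` and low-dopamine scaling factor
#' `m` (the dopamine factor `1 + beta * phi` at dopamine level 0), builds the
#' seven geometric steps from `v/m` to `m*v` including `v`: three steps
#' toward the high-dopamine side, the normal value, and three toward the
#' low-dopamine side.
#'
#' @param name Projection key, e.g. `"D2-SPN->GPe-TI"`.
#' @param family `"biphasic"` or `"triphasic"` low-dopamine tuning.
#' @return List with `name`, `v`, `m` and the seven `values` (nS).
#' @export
sweep_grid <- function(name, family = c("biphasic", "triphasic")) {
  family <- match.arg(family)
  prj <- projection_table()[[name]]
  if (is.null(prj)) stop("unknown projection: ", name)
  beta <- if (family == "triphasic") prj$beta_tri else prj$beta_bi
  v <- prj$weight
  m <- 1 + beta * (0 - 0.8)
  values <- v * m^(seq(-3, 3) / 3)
  list(name = name, v = v, m = m, values = values)
}

SWEEP_CONNECTIONS <- c("D1-SPN->SNr", "D2-SPN->GPe-TI", "GPe-TA->GPe-TI",
                       "GPe-TI->GPe-TA", "STN->GPe-TI", "GPe-TI->STN")

#' Six-connection weight sweep
#'
#' Varies each of the six connections that shape the transient response over
#' its seven-point grid (all other parameters at their healthy values), runs
#' the transient experiment at each grid point, and summarizes each zone's
#' duration and area-per-unit-time by the coefficient of variation (SD/mean)
#' across the seven grid points.
#'
#' @param network Healthy-condition `bg_network`.
#' @param background Calibrated healthy background.
#' @param profile Frozen stimulus profile.
#' @param connections Projection keys to sweep.
#' @param n_trials Trials per grid point.
#' @param seed Integer seed.
#' @return A `bg_sweep`: list with `zones` (per connection, per grid point),
#'   `grids`, and `cv` (data.frame: connection, zone, cv_duration,
#'   cv_area_time).
#' @export
run_weight_sweep <- function(network, background,
                             profile = default_stimulus_profile(),
                             connections = SWEEP_CONNECTIONS,
                             n_trials = 10, seed = 1L) {
  stopifnot(inherits(network, "bg_network"))
  family <- network$condition$family
  grids <- lapply(stats::setNames(connections, connections), sweep_grid,
                  family = family)
  zones <- list()
  for (cn in connections) {
    zl <- vector("list", 7L)
    for (g in seq_len(7L)) {
      net_g <- network
      net_g$projections[[cn]]$weight <- grids[[cn]]$values[g]
      res <- run_transient_experiment(net_g, background, profile,
                                      n_trials = n_trials, seed = seed,
                                      pops = "SNr")
      zl[[g]] <- res$zones$SNr
    }
    zones[[cn]] <- zl
  }
  cv <- do.call(rbind, lapply(connections, function(cn) {
    do.call(rbind, lapply(ZONE_ORDER, function(zn) {
      dur <- vapply(zones[[cn]], function(z) z$D[z$zone == zn], 0)
      at <- vapply(zones[[cn]],
                   function(z) (z$A / z$D)[z$zone == zn], 0)
      cv_of <- function(x) {
        x <- x[!is.na(x)]
        if (length(x) < 2 || mean(x) == 0) return(NA_real_)
        stats::sd(x) / abs(mean(x))
      }
      data.frame(connection = cn, zone = zn, cv_duration = cv_of(dur),
                 cv_area_time = cv_of(at))
    }))
  }))
  structure(list(zones = zones, grids = grids, cv = cv), class = "bg_sweep")
}

#' Pooled response-diversity statistics over sweep grid points
#'
#' Pools the zone features over sweep grid points, emulating recordings from
#' animals/regions with heterogeneous synaptic strengths: the healthy pool
#' uses the grid points one step either side of the normal value, the
#' low-dopamine pool the three steps toward the low-dopamine extreme.
#'
#' @param sweep A `bg_sweep` from [run_weight_sweep()].
#' @param condition `"normal"` or `"pd"`: which sub-range to pool.
#' @return Data frame: zone, feature (`D`, `H_dev`, ...), mean, sd over the
#'   pooled grid points and connections.
#' @export
pool_sweep_features <- function(sweep, condition = c("normal", "pd")) {
  condition <- match.arg(condition)
  idx <- if (condition == "normal") 3:5 else 5:7  # grid point 4 = normal
  rows <- list()
  for (cn in names(sweep$zones))
    for (g in idx)
      rows[[length(rows) + 1L]] <- sweep$zones[[cn]][[g]]
  pooled <- do.call(rbind, rows)
  feats <- c("L", "D", "A", "H_mu", "H_sigma", "H_p", "H_dev")
  do.call(rbind, lapply(ZONE_ORDER, function(zn) {
    sub <- pooled[pooled$zone == zn & pooled$detected, , drop = FALSE]
    do.call(rbind, lapply(feats, function(f)
      data.frame(zone = zn, feature = f,
                 mean = if (nrow(sub)) mean(sub[[f]]) else NA_real_,
                 sd = if (nrow(sub) > 1) stats::sd(sub[[f]]) else NA_real_)))
  }))
}

#' Restoration experiment
#'
#' Starting from the low-dopamine (triphasic) network, restores one
#' projection (or loop) at a time to its healthy weight and delay,
#' recalibrates the background so baseline rates match the healthy targets,
#' reruns the transient experiment, and measures the Euclidean distance of
#' the 24-dimensional response signature to the healthy and to the
#' low-dopamine reference signatures.
#'
#' @param pd_network Low-dopamine `bg_network` (triphasic preset).
#' @param pd_background Its calibrated background.
#' @param normal_signature,pd_signature Reference signatures from transient
#'   runs of the healthy and low-dopamine networks.
#' @param profile Frozen stimulus profile.
#' @param restorations Projection/loop names to restore one at a time.
#' @param normal Healthy condition bundle (for weights, delays and targets).
#' @param n_trials Trials per run.
#' @param recal_iter Background recalibration rounds per restoration.
#' @param seed Integer seed.
#' @return Data frame: restoration, dist_normal, dist_pd.
#' @export
run_restoration <- function(pd_network, pd_background, normal_signature,
                            pd_signature, profile = default_stimulus_profile(),
                            restorations = c("D2-SPN->GPe-TI", "STN<->GPe-TI",
                                             "GPe-TA<->GPe-TI", "D1-SPN->SNr"),
                            normal = build_condition("normal"),
                            n_trials = 20, recal_iter = 2, seed = 1L) {
  out <- lapply(restorations, function(nm) {
    net <- restore_projection(pd_network, nm, normal = normal)
    bg <- calibrate_background(net, pd_background,
                               targets = normal$rate_targets,
                               max_rounds = recal_iter, duration = 2500,
                               seed = seed)
    res <- run_transient_experiment(net, bg, profile, n_trials = n_trials,
                                    seed = seed, pops = "SNr")
    data.frame(restoration = nm,
               dist_normal = signature_distance(res$signature,
                                                normal_signature,
                                                strict = FALSE),
               dist_pd = signature_distance(res$signature, pd_signature,
                                            strict = FALSE))
  })
  do.call(rbind, out)
}

#' Lesion battery: oscillation metrics after disconnecting pathways
#'
#' Removes each listed projection (or loop) from the low-dopamine network and
#' measures the steady-state Fano factor and oscillation index per
#' population.  No background recalibration is applied: the battery measures
#' the raw consequence of each disconnection.
#'
#' @param network Low-dopamine `bg_network`.
#' @param background Its calibrated background.
#' @param lesions Names of projections/loops to remove one at a time.
#' @param pops Populations to measure.
#' @param n_trials,duration,seed Steady-state run parameters.
#' @return Data frame: lesion (including `"none"`), population, FF, OI.
#' @export
run_lesion_battery <- function(network, background,
                               lesions = c("D2-SPN->GPe-TI", "STN<->GPe-TI",
                                           "GPe-TA<->GPe-TI", "GPe-TI->FSI"),
                               pops = c("GPe-TA", "GPe-TI", "STN", "SNr"),
                               n_trials = 5, duration = 3000, seed = 1L) {
  run_one <- function(net, label) {
    om <- oscillation_metrics(net, background, pops = pops,
                              n_trials = n_trials, duration = duration,
                              seed = seed)
    cbind(lesion = label, om$metrics)
  }
  out <- list(run_one(network, "none"))
  for (nm in lesions)
    out[[length(out) + 1L]] <- run_one(apply_lesion(network, nm), nm)
  do.call(rbind, out)
}

#' Dopamine-level sweep of the transient response
#'
#' Rebuilds the network at each dopamine level (keeping the preset's
#' low-dopamine synaptic sensitivities), linearly interpolates the background
#' rates between the calibrated low-dopamine (level 0) and healthy (level
#' 0.8) drives, and reports each zone's duration and area-per-unit-time.
#'
#' @param preset `"PD-biphasic"` or `"PD-triphasic"`.
#' @param pd_background Calibrated background at dopamine level 0.
#' @param normal_background Calibrated background at level 0.8.
#' @param profile Frozen stimulus profile.
#' @param levels Dopamine levels to test.
#' @param build_seed Seed for network builds.
#' @param n_trials,seed Transient run parameters.
#' @return Data frame: level, zone, detected, merged, D, area_time.
#' @export
run_dopamine_sweep <- function(preset = c("PD-biphasic", "PD-triphasic"),
                               pd_background, normal_background,
                               profile = default_stimulus_profile(),
                               levels = seq(0, 1, by = 0.2), build_seed = 1L,
                               n_trials = 20, seed = 1L) {
  preset <- match.arg(preset)
  out <- list()
  for (lev in levels) {
    cond <- build_condition(preset, alpha_dop = lev)
    net <- build_network(cond, seed = build_seed)
    a <- min(max(lev / 0.8, 0), 1.25)
    rate <- mapply(function(p, q) (1 - min(a, 1)) * p + min(a, 1) * q,
                   pd_background$rate[names(pd_background$rate)],
                   normal_background$rate[names(pd_background$rate)],
                   SIMPLIFY = FALSE)
    bg <- background_drive(rate, pd_background$weight)
    res <- run_transient_experiment(net, bg, profile, n_trials = n_trials,
                                    seed = seed, pops = "SNr")
    z <- res$zones$SNr
    out[[length(out) + 1L]] <-
      data.frame(level = lev, zone = z$zone, detected = z$detected,
                 merged = z$merged, D = z$D, area_time = z$A / z$D)
  }
  do.call(rbind, out)
}

#' Phase-conditioned stimulation
#'
#' For each requested beta phase, finds per-trial onsets at which the SNr
#' oscillation attains that phase (via stimulus-free preview runs re-run with
#' identical seeds), delivers the stimulus at those onsets, and reports the
#' pooled SNr zone table per phase plus the grand average across all phases.
#'
#' @param network Low-dopamine (biphasic) `bg_network`.
#' @param background Calibrated background.
#' @param profile Frozen stimulus profile.
#' @param phis Target phases (radians).
#' @param n_trials Trials per phase (default 48).
#' @param fraction Stimulated fraction.
#' @param seed Integer seed.
#' @return List with `per_phase` (zone table per phase), `grand` (zone table
#'   over all trials pooled), `onsets` (data frame per phase).
#' @export
run_phase_conditioned <- function(network, background,
                                  profile = default_stimulus_profile(),
                                  phis = c(1.20, 1.61, 1.81, 0.23) * pi,
                                  n_trials = 48, fraction = 0.5, seed = 1L) {
  network <- prepare_network(network)
  stim_fn <- transient_stimulus(network, profile, fraction = fraction,
                                seed = seed)
  per_phase <- list()
  onset_tabs <- list()
  all_rasters <- list()
  all_onsets <- numeric(0)
  for (k in seq_along(phis)) {
    tab <- phase_locked_onsets(network, background, phis[k],
                               n_trials = n_trials, seed = seed + 10000L * k)
    rasters <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab)))
      rasters[[i]] <- simulate_trial(network, background = background,
                                     stimulus = stim_fn(tab$onset[i]),
                                     duration = 1200, seed = tab$seed[i])
    ps <- compute_psth(rasters, tab$onset, pop = "SNr")
    per_phase[[sprintf("%.2fpi", phis[k] / pi)]] <- detect_zones(ps)
    onset_tabs[[k]] <- tab
    all_rasters <- c(all_rasters, rasters)
    all_onsets <- c(all_onsets, tab$onset)
  }
  grand <- detect_zones(compute_psth(all_rasters, all_onsets, pop = "SNr"))
  list(per_phase = per_phase, grand = grand, onsets = onset_tabs)
}
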