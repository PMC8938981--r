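# R-side simulation driver: flattens a bg_network into the arrays consumed by
# the C++ core, runs one or more trials, and wraps the emitted spikes as a
# bg_raster object.

#' @useDynLib bgnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Flatten per-population neuron parameters into per-neuron vectors and the
# projections into a CSR structure indexed by source neuron (out-edges).
flatten_network <- function(network, dt) {
  pops <- network$populations
  n <- sum(pops$size)
  fields <- c("C_m", "g_L", "E_L", "V_th", "V_reset", "E_ex", "E_in",
              "tau_syn_ex", "tau_syn_in", "I_e", "t_ref")
  adex_fields <- c("a", "b", "Delta_T", "tau_w", "V_peak")
  vecs <- lapply(c(fields, adex_fields), function(f) numeric(n))
  names(vecs) <- c(fields, adex_fields)
  is_adex <- integer(n)
  for (k in seq_len(nrow(pops))) {
    idx <- seq.int(pops$offset[k] + 1L, pops$offset[k] + pops$size[k])
    prm <- network$condition$neurons[[pops$name[k]]]
    for (f in fields) vecs[[f]][idx] <- prm[[f]]
    if (prm$model == "adex") {
      is_adex[idx] <- 1L
      for (f in adex_fields) vecs[[f]][idx] <- prm[[f]]
    } else {
      vecs$tau_w[idx] <- 1  # unused, keep positive
      vecs$Delta_T[idx] <- 1
    }
  }

  # out-edge CSR
  offs <- stats::setNames(pops$offset, pops$name)
  src_all <- integer(0); tgt_all <- integer(0)
  w_all <- numeric(0); d_all <- integer(0)
  for (pr in network$projections) {
    dstep <- pr$delay / dt
    if (abs(dstep - round(dstep)) > 1e-9)
      stop("projection delay ", pr$delay, " ms is not a multiple of dt = ", dt)
    n_tgt <- ncol(pr$sources)
    src_all <- c(src_all, as.vector(pr$sources) - 1L + offs[[pr$source]])
    tgt_all <- c(tgt_all, rep(seq_len(n_tgt) - 1L + offs[[pr$target]],
                              each = pr$K))
    w_all <- c(w_all, rep(pr$weight, pr$K * n_tgt))
    d_all <- c(d_all, rep(as.integer(round(dstep)), pr$K * n_tgt))
  }
  ord <- order(src_all)
  src_all <- src_all[ord]; tgt_all <- tgt_all[ord]
  w_all <- w_all[ord]; d_all <- d_all[ord]
  out_ptr <- c(0L, cumsum(tabulate(src_all + 1L, nbins = n)))

  list(n = n, vecs = vecs, is_adex = is_adex,
       out_ptr = as.integer(out_ptr), out_tgt = as.integer(tgt_all),
       out_w = w_all, out_dstep = as.integer(d_all))
}

#' Simulate the network for one trial
#'
#' Integrates the coupled membrane and synapse equations over `duration` ms
#' with time step `dt` (default 0.1 ms).  External drive is composed of (i) a
#' per-population homogeneous Poisson background (from [background_drive()] or
#' a calibration), (ii) an optional rate-modulated Poisson stimulus delivered
#' to a subset of neurons (see [transient_stimulus()]), and (iii) optional
#' explicit spike trains.
#'
#' The trial is exactly reproducible given (`network`, drives, `seed`, `dt`).
#'
#' @param network A `bg_network`.
#' @param background A `bg_background` (per-population Poisson rate and
#'   weight), or `NULL` for none.
#' @param stimulus A `bg_stimulus_trial` for this trial (or `NULL`).
#' @param ext_spikes Optional list with vectors `id` (1-based global neuron
#'   id), `t` (ms) and `w` (signed nS): explicit input spikes.
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms).
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @param record_traces Global id of a neuron whose membrane potential and
#'   conductances are recorded every step (0 = none).
#' @return A `bg_raster`: list with `id`, `t` (spike events), `duration`,
#'   `populations`, and optional `V`, `g_ex`, `g_in` traces.
#' @export
simulate_trial <- function(network, background = NULL, stimulus = NULL,
                           ext_spikes = NULL, duration = 1200, dt = 0.1,
                           seed = NULL, record_traces = 0L) {
  stopifnot(inherits(network, "bg_network"))
  flat <- flatten_cached(network, dt)
  n <- flat$n
  n_steps <- as.integer(round(duration / dt))

  bg_rate <- numeric(n); bg_w <- numeric(n)
  if (!is.null(background)) {
    for (pop in names(background$rate)) {
      idx <- population_ids(network, pop)
      bg_rate[idx] <- background$rate[[pop]]
      bg_w[idx] <- background$weight[[pop]]
    }
  }

  stim_mask <- integer(n); stim_w <- numeric(n); stim_shift <- integer(n)
  stim_rate <- numeric(0); bg_mod <- numeric(0)
  if (!is.null(stimulus)) {
    stim_mask[stimulus$ids] <- 1L
    stim_w[stimulus$ids] <- stimulus$weights
    stim_shift[stimulus$ids] <- as.integer(round(stimulus$shifts_ms / dt))
    stim_rate <- stimulus$rate_fn(n_steps, dt)
    bg_mod <- stimulus$mod_fn(n_steps, dt)
  }

  if (is.null(ext_spikes)) {
    ext_step <- integer(0); ext_tgt <- integer(0); ext_w <- numeric(0)
  } else {
    stp <- as.integer(floor(ext_spikes$t / dt))
    ord <- order(stp)
    ext_step <- stp[ord]
    ext_tgt <- as.integer(ext_spikes$id[ord]) - 1L
    ext_w <- rep_len(ext_spikes$w, length(stp))[ord]
  }

  if (!is.null(seed)) set.seed(seed)
  v <- flat$vecs
  res <- .sim_core(v$C_m, v$g_L, v$E_L, v$V_th, v$V_reset, v$E_ex, v$E_in,
                   v$tau_syn_ex, v$tau_syn_in, v$I_e, v$t_ref, flat$is_adex,
                   v$a, v$b, v$Delta_T, v$tau_w, v$V_peak,
                   flat$out_ptr, flat$out_tgt, flat$out_w, flat$out_dstep,
                   bg_rate, bg_w, stim_mask, stim_w, stim_shift,
                   stim_rate, bg_mod,
                   ext_step, ext_tgt, ext_w, duration, dt,
                   as.integer(record_traces))
  structure(list(id = res$id, t = res$t, duration = duration, dt = dt,
                 populations = network$populations,
                 V = res$V, g_ex = res$g_ex, g_in = res$g_in),
            class = "bg_raster")
}

# Per-network flattening cache: rebuilding the CSR for every trial would
# dominate runtime for multi-trial protocols.
flatten_cached <- function(network, dt) {
  cache <- attr(network, ".flat", exact = TRUE)
  if (!is.null(cache) && identical(cache$dt, dt)) return(cache$flat)
  flatten_network(network, dt)
}

#' Pre-flatten a network for repeated simulation
#'
#' Attaches the internal flattened representation to the network object so
#' repeated [simulate_trial()] calls skip the edge-list flattening.
#'
#' @param network A `bg_network`.
#' @param dt Integration step the cache is valid for.
#' @return The network with the cache attached.
#' @export
prepare_network <- function(network, dt = 0.1) {
  attr(network, ".flat") <- list(dt = dt, flat = flatten_network(network, dt))
  network
}

#' @export
print.bg_raster <- function(x, ...) {
  cat("Spike raster:", length(x$t), "spikes over", x$duration, "ms\n")
  invisible(x)
}

#' Mean firing rates per population from a raster
#'
#' @param raster A `bg_raster`.
#' @param window Optional `c(t0, t1)` ms analysis window (default: whole run).
#' @return Named numeric vector of population mean rates (Hz per neuron).
#' @export
population_rates <- function(raster, window = NULL) {
  if (is.null(window)) window <- c(0, raster$duration)
  keep <- raster$t > window[1] & raster$t <= window[2]
  id <- raster$id[keep]
  pops <- raster$populations
  out <- numeric(nrow(pops))
  names(out) <- pops$name
  dur_s <- (window[2] - window[1]) / 1000
  for (k in seq_len(nrow(pops))) {
    cnt <- sum(id > pops$offset[k] & id <= pops$offset[k] + pops$size[k])
    out[k] <- cnt / pops$size[k] / dur_s
  }
  out
}

#' Extract one population's spikes with population-local ids
#'
#' @param raster A `bg_raster`.
#' @param pop Population name.
#' @return List with `id` (1-based within the population), `t` (ms) and `n`
#'   (population size).
#' @export
population_spikes <- function(raster, pop) {
  pops <- raster$populations
  row <- pops[pops$name == pop, ]
  if (nrow(row) != 1L) stop("unknown population: ", pop)
  keep <- raster$id > row$offset & raster$id <= row$offset + row$size
  list(id = raster$id[keep] - row$offset, t = raster$t[keep], n = row$size)
}

#' Write a raster as a delimited event file
#'
#' Tab-separated columns `trial`, `id`, `t_ms`; a populations manifest is
#' written alongside.
#'
#' @param rasters A `bg_raster` or list of them (one per trial).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_raster <- function(rasters, path) {
  if (inherits(rasters, "bg_raster")) rasters <- list(rasters)
  df <- do.call(rbind, lapply(seq_along(rasters), function(i)
    data.frame(trial = i, id = rasters[[i]]$id, t_ms = rasters[[i]]$t)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(rasters[[1]]$populations,
                     paste0(path, ".populations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
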