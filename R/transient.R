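# Transient-response analysis: onset-aligned PSTHs, segmentation of the
# response into the four significance zones (EE, EI, LE, LI), zone features,
# the 24-dimensional response signature and its Euclidean distance, and
# subpopulation resampling statistics.

PSTH_PRE <- 100L   # ms before onset
PSTH_POST <- 250L  # ms after onset
Z_CRIT <- stats::qnorm(0.95)  # one-tailed p < 0.05

# Per-neuron x per-bin spike-count matrix, aligned to each trial's own onset.
psth_counts <- function(rasters, onsets, pop) {
  if (inherits(rasters, "bg_raster")) rasters <- list(rasters)
  stopifnot(length(rasters) == length(onsets))
  n_bins <- PSTH_PRE + PSTH_POST
  n <- population_spikes(rasters[[1]], pop)$n
  acc <- integer(n * n_bins)
  for (i in seq_along(rasters)) {
    sp <- population_spikes(rasters[[i]], pop)
    rel <- sp$t - onsets[i]
    keep <- rel >= -PSTH_PRE & rel < PSTH_POST
    if (!any(keep)) next
    bin <- floor(rel[keep]) + PSTH_PRE + 1L  # bin 1 = [-100, -99) ms
    lin <- (bin - 1L) * n + sp$id[keep]
    acc <- acc + tabulate(lin, nbins = n * n_bins)
  }
  matrix(acc, nrow = n, ncol = n_bins)
}

#' Onset-aligned peristimulus time histogram
#'
#' 1-ms rectangular bins over a window of 100 ms before to 250 ms after each
#' trial's stimulation onset; rates averaged over trials and over the analyzed
#' neuron set.  The baseline statistics (mean and SD) are computed from the
#' 100 pre-stimulus bins only.
#'
#' @param rasters A `bg_raster` or list of them (one per trial).
#' @param onsets Numeric vector of per-trial onsets (ms).
#' @param pop Population to analyze (default `"SNr"`).
#' @param neurons Optional integer subset of population-local neuron ids.
#' @return A `bg_psth`: list with `rate` (350 bins, spikes/s), `time` (bin
#'   start, ms relative to onset), `baseline` (`mean`, `sd`), `n_trials`,
#'   `n_neurons`.
#' @export
compute_psth <- function(rasters, onsets, pop = "SNr", neurons = NULL) {
  counts <- psth_counts(rasters, onsets, pop)
  psth_from_counts(counts, n_trials = length(onsets), neurons = neurons)
}

psth_from_counts <- function(counts, n_trials, neurons = NULL) {
  if (!is.null(neurons)) {
    if (!length(neurons)) stop("empty neuron subset")
    counts <- counts[neurons, , drop = FALSE]
  }
  n_neurons <- nrow(counts)
  rate <- colSums(counts) / (n_trials * n_neurons * 1e-3)
  pre <- rate[seq_len(PSTH_PRE)]
  structure(list(rate = rate,
                 time = seq.int(-PSTH_PRE, PSTH_POST - 1L),
                 baseline = list(mean = mean(pre), sd = stats::sd(pre)),
                 n_trials = n_trials, n_neurons = n_neurons),
            class = "bg_psth")
}

#' @export
print.bg_psth <- function(x, ...) {
  cat("PSTH:", length(x$rate), "x 1-ms bins,", x$n_trials, "trials,",
      x$n_neurons, "neurons; baseline", sprintf("%.2f", x$baseline$mean),
      "+/-", sprintf("%.2f", x$baseline$sd), "spikes/s\n")
  invisible(x)
}

# Scan the post-onset bins for significance episodes of alternating polarity.
# An episode opens at the first of >= 2 consecutive bins beyond the one-tailed
# critical value and closes when two consecutive bins fall below it (end time
# = last significant bin).  Consecutive same-polarity episodes with no
# opposite-polarity episode between them are merged (the merged-excitation
# convention of the biphasic low-dopamine response).
find_episodes <- function(sig) {
  n <- length(sig)
  episodes <- list()
  i <- 1L
  while (i < n) {
    if (sig[i] != 0L && sig[i + 1L] == sig[i]) {
      p <- sig[i]
      last_sig <- i
      j <- i + 1L
      while (j <= n) {
        if (sig[j] == p) {
          last_sig <- j
        } else if (j < n && sig[j + 1L] != p) {
          break  # two consecutive bins below significance for this polarity
        }
        j <- j + 1L
      }
      episodes[[length(episodes) + 1L]] <-
        list(polarity = p, start = i, end = last_sig, merged = FALSE)
      i <- last_sig + 1L
    } else {
      i <- i + 1L
    }
  }
  # merge same-polarity neighbours
  merged <- list()
  for (ep in episodes) {
    k <- length(merged)
    if (k > 0L && merged[[k]]$polarity == ep$polarity) {
      merged[[k]]$end <- ep$end
      merged[[k]]$merged <- TRUE
    } else {
      merged[[k + 1L]] <- ep
    }
  }
  merged
}

#' Segment a PSTH into the four response zones
#'
#' Applies a one-tailed Z-test per bin against the pre-stimulus baseline
#' (p < 0.05, i.e. |Z| > 1.645 in the appropriate tail) over t in \[0, 250)
#' ms, requiring at least two consecutive significant bins to open a zone.
#' Zones are labelled in temporal order with alternating polarity: early
#' excitation (EE), early inhibition (EI), late excitation (LE), late
#' inhibition (LI).  When no inhibitory episode separates two excitatory
#' episodes they are reported as a single merged excitation under EE (the
#' biphasic convention); a single inhibition that follows the final
#' excitation is LI.  Zones that are not detected are returned with
#' `detected = FALSE`.
#'
#' @param psth A `bg_psth`.
#' @param baseline Optional list with `mean`, `sd` overriding the PSTH's own
#'   pre-stimulus baseline.
#' @return A data.frame with one row per zone (EE, EI, LE, LI): `detected`,
#'   `merged`, latency `L` (ms), duration `D` (ms), absolute area `A`
#'   (spikes/s x bins), `H_mu`, `H_sigma` (mean, SD of bin heights), peak
#'   `H_p` and its deviation from baseline `H_dev`.
#' @export
detect_zones <- function(psth, baseline = NULL) {
  stopifnot(inherits(psth, "bg_psth"))
  if (is.null(baseline)) baseline <- psth$baseline
  if (!isTRUE(baseline$sd > 0)) stop("baseline SD must be positive")
  post <- psth$rate[(PSTH_PRE + 1L):(PSTH_PRE + PSTH_POST)]
  z <- (post - baseline$mean) / baseline$sd
  sig <- integer(length(z))
  sig[z > Z_CRIT] <- 1L
  sig[z < -Z_CRIT] <- -1L
  eps <- find_episodes(sig)
  if (length(eps) > 4L) {
    warning("more than four significance episodes; ignoring episodes beyond ",
            "the fourth")
    eps <- eps[seq_len(4L)]
  }

  labels <- character(length(eps))
  pols <- vapply(eps, function(e) e$polarity, 0L)
  exc_idx <- which(pols == 1L)
  inh_idx <- which(pols == -1L)
  if (length(exc_idx)) labels[exc_idx] <- c("EE", "LE")[seq_along(exc_idx)]
  if (length(inh_idx) == 2L) {
    labels[inh_idx] <- c("EI", "LI")
  } else if (length(inh_idx) == 1L) {
    after_last_exc <- length(exc_idx) > 0L && inh_idx > max(exc_idx)
    labels[inh_idx] <- if (after_last_exc) "LI" else "EI"
  }

  out <- data.frame(zone = c("EE", "EI", "LE", "LI"), detected = FALSE,
                    merged = FALSE, L = NA_real_, D = NA_real_, A = NA_real_,
                    H_mu = NA_real_, H_sigma = NA_real_, H_p = NA_real_,
                    H_dev = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(eps)) {
    if (!nzchar(labels[k]) || is.na(labels[k])) next
    e <- eps[[k]]
    h <- post[e$start:e$end]
    row <- match(labels[k], out$zone)
    peak <- if (e$polarity > 0L) max(h) else min(h)
    out[row, c("detected", "merged")] <- c(TRUE, e$merged)
    # bin index i covers [i-1, i) ms after onset; latency is the start time
    out[row, c("L", "D", "A", "H_mu", "H_sigma", "H_p", "H_dev")] <-
      c(e$start - 1L, e$end - e$start + 1L, sum(abs(h - baseline$mean)),
        mean(h), if (length(h) > 1L) stats::sd(h) else 0, peak,
        peak - baseline$mean)
  }
  attr(out, "baseline") <- baseline
  out
}

ZONE_ORDER <- c("EE", "EI", "LE", "LI")
FEATURE_ORDER <- c("L", "D", "A", "H_mu", "H_sigma", "H_p")

#' Pack zone features into the 24-dimensional response signature
#'
#' Concatenates the six features (latency, duration, area, mean, SD, peak of
#' bin heights) of the four zones in the fixed order EE, EI, LE, LI.  Zones
#' that were not detected contribute zeros, and the signature carries a
#' missing-zone marker; two signatures can only be compared when their
#' markers agree.
#'
#' @param zones Zone table from [detect_zones()].
#' @return A `bg_signature`: numeric vector of length 24 with attribute
#'   `missing` (logical, per zone).
#' @export
extract_signature <- function(zones) {
  v <- numeric(0)
  missing <- logical(length(ZONE_ORDER))
  names(missing) <- ZONE_ORDER
  for (zn in ZONE_ORDER) {
    row <- zones[zones$zone == zn, ]
    if (isTRUE(row$detected)) {
      v <- c(v, as.numeric(row[1, FEATURE_ORDER]))
    } else {
      v <- c(v, numeric(length(FEATURE_ORDER)))
      missing[zn] <- TRUE
    }
  }
  names(v) <- paste(rep(ZONE_ORDER, each = length(FEATURE_ORDER)),
                    FEATURE_ORDER, sep = ".")
  structure(v, missing = missing, class = "bg_signature")
}

#' Euclidean distance between two response signatures
#'
#' @param f_test,f_ref `bg_signature` vectors from [extract_signature()],
#'   built under the same missing-zone policy.
#' @param strict Error when the missing-zone markers differ (default); with
#'   `strict = FALSE` undetected zones simply contribute their zero features
#'   (used by restoration experiments where a zone may appear or vanish).
#' @return Square root of the summed squared differences over the 24
#'   components.
#' @export
signature_distance <- function(f_test, f_ref, strict = TRUE) {
  stopifnot(inherits(f_test, "bg_signature"), inherits(f_ref, "bg_signature"))
  if (strict && !identical(attr(f_test, "missing"), attr(f_ref, "missing")))
    stop("signatures have mismatched missing-zone markers")
  sqrt(sum((as.numeric(f_test) - as.numeric(f_ref))^2))
}

#' Subpopulation resampling statistics of the zone features
#'
#' Repeats the feature extraction over `O_S` observations, each using a
#' random subset of `N_S` (fraction) of the population's neurons, and returns
#' the mean and SD of every zone feature over the observations.
#'
#' @param rasters List of `bg_raster` (one per trial).
#' @param onsets Per-trial onsets (ms).
#' @param pop Population (default `"SNr"`).
#' @param N_S Fraction of neurons per observation (default 0.5; the
#'   experiment tables also use 0.2).
#' @param O_S Number of observations (default 100).
#' @param seed Integer seed for the subset draws.
#' @return Data frame with columns `zone`, `feature`, `mean`, `sd` (features
#'   `L`, `D`, `A`, `H_mu`, `H_sigma`, `H_p`, `H_dev`; undetected zones give
#'   NA), plus attribute `detect_frac`, the fraction of observations in which
#'   each zone was detected.
#' @export
subsample_features <- function(rasters, onsets, pop = "SNr", N_S = 0.5,
                               O_S = 100, seed = 1L) {
  counts <- psth_counts(rasters, onsets, pop)
  n <- nrow(counts)
  k <- round(N_S * n)
  if (k < 1) stop("subset smaller than one neuron")
  set.seed(seed)
  feats <- c(FEATURE_ORDER, "H_dev")
  arr <- array(NA_real_, dim = c(O_S, length(ZONE_ORDER), length(feats)),
               dimnames = list(NULL, ZONE_ORDER, feats))
  for (o in seq_len(O_S)) {
    sub <- sample.int(n, k)
    ps <- psth_from_counts(counts, n_trials = length(onsets), neurons = sub)
    zs <- detect_zones(ps)
    for (zn in ZONE_ORDER) {
      row <- zs[zs$zone == zn, ]
      if (isTRUE(row$detected))
        arr[o, zn, ] <- as.numeric(row[1, feats])
    }
  }
  out <- expand.grid(zone = ZONE_ORDER, feature = feats,
                     stringsAsFactors = FALSE)
  out$mean <- mapply(function(z, f) mean(arr[, z, f], na.rm = TRUE),
                     out$zone, out$feature)
  out$sd <- mapply(function(z, f) stats::sd(arr[, z, f], na.rm = TRUE),
                   out$zone, out$feature)
  attr(out, "detect_frac") <-
    apply(!is.na(arr[, , 1, drop = FALSE]), 2, mean)
  out
}

#' Write a zone-feature table as a delimited file
#'
#' @param features Data frame as returned by [subsample_features()] (with a
#'   `condition` column added by the caller if desired).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
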