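# Network instantiation: fixed in-degree random connectivity over the seven
# populations, plus lesion and restoration surgery on a built network.

#' Build the basal-ganglia network
#'
#' Instantiates all 6539 neurons and the 22 projections of the model as fixed
#' in-degree random connectivity: every target neuron of a projection draws
#' exactly `K` distinct presynaptic partners uniformly at random from the
#' source population (no self-connections, no multapses).  Connectivity is
#' deterministic given `seed`; each projection uses its own seed derived from
#' the master seed, so removing one projection never reshuffles another.
#'
#' @param condition A `bg_condition` from [build_condition()].
#' @param seed Master integer seed for the connectivity.
#' @return An object of class `bg_network`: list with `populations`
#'   (data.frame: name, size, model, offset of the zero-based global id
#'   range), `condition`, `seed`, and `projections`, each carrying a `K x
#'   n_target` integer matrix `sources` of 1-based source-local neuron ids.
#' @export
build_network <- function(condition, seed = 1L) {
  stopifnot(inherits(condition, "bg_condition"))
  sizes <- bg_population_sizes()
  pops <- data.frame(name = names(sizes), size = as.integer(sizes),
                     model = vapply(condition$neurons[names(sizes)],
                                    function(p) p$model, ""),
                     offset = cumsum(c(0L, unname(sizes)))[seq_along(sizes)],
                     stringsAsFactors = FALSE)
  projections <- condition$projections
  for (i in seq_along(projections)) {
    pr <- projections[[i]]
    n_src <- sizes[[pr$source]]
    n_tgt <- sizes[[pr$target]]
    if (pr$K > n_src)
      stop("in-degree K exceeds source population size for ",
           names(projections)[i])
    # dedicated substream per projection
    set.seed((seed + 7919L * i) %% .Machine$integer.max)
    recurrent <- identical(pr$source, pr$target)
    src <- matrix(0L, nrow = pr$K, ncol = n_tgt)
    for (j in seq_len(n_tgt)) {
      pool_n <- if (recurrent) n_src - 1L else n_src
      s <- sample.int(pool_n, pr$K)
      if (recurrent) s <- ifelse(s >= j, s + 1L, s)  # exclude autapse
      src[, j] <- s
    }
    pr$sources <- src
    projections[[i]] <- pr
  }
  structure(list(populations = pops, condition = condition, seed = seed,
                 projections = projections),
            class = "bg_network")
}

#' @export
print.bg_network <- function(x, ...) {
  cat("Basal-ganglia network (", sum(x$populations$size), " neurons, ",
      length(x$projections), " projections), condition ",
      x$condition$name, "\n", sep = "")
  print(x$populations, row.names = FALSE)
  invisible(x)
}

# Expand a lesion / restoration name into the projection keys it covers.
# The loop names "STN<->GPe-TI" and "GPe-TA<->GPe-TI" cover both directions.
resolve_projection_names <- function(network, name) {
  keys <- names(network$projections)
  if (name %in% keys) return(name)
  both <- switch(name,
    "STN<->GPe-TI" = c("STN->GPe-TI", "GPe-TI->STN"),
    "GPe-TA<->GPe-TI" = c("GPe-TA->GPe-TI", "GPe-TI->GPe-TA"),
    "GPe-TI<->GPe-TA" = c("GPe-TA->GPe-TI", "GPe-TI->GPe-TA"),
    stop("unknown projection: ", name))
  stopifnot(all(both %in% keys))
  both
}

#' Remove a projection from a built network
#'
#' Deletes every edge of the named projection; all other projections keep the
#' exact edge sets of the original build.  Bidirectional lesion names
#' (`"STN<->GPe-TI"`, `"GPe-TA<->GPe-TI"`) remove both directions.
#'
#' @param network A `bg_network`.
#' @param name Projection name, e.g. `"D2-SPN->GPe-TI"`.
#' @return The lesioned `bg_network`.
#' @export
apply_lesion <- function(network, name) {
  stopifnot(inherits(network, "bg_network"))
  for (key in resolve_projection_names(network, name))
    network$projections[[key]] <- NULL
  network
}

#' Restore a projection of a low-dopamine network to its healthy strength
#'
#' Sets the named projection's weight and delay back to the normal-condition
#' values (the edge sets are untouched).  Bidirectional names restore both
#' directions.  The returned network carries a `recalibrate` attribute naming
#' the restored projection; restoration experiments re-tune the background
#' drive so baseline rates match the healthy state.
#'
#' @param network A `bg_network` built from a PD condition.
#' @param name Projection (or loop) name.
#' @param normal A `bg_condition` for the healthy state (default
#'   `build_condition("normal")`).
#' @return The modified `bg_network`.
#' @export
restore_projection <- function(network, name, normal = build_condition("normal")) {
  stopifnot(inherits(network, "bg_network"))
  for (key in resolve_projection_names(network, name)) {
    network$projections[[key]]$weight <- normal$projections[[key]]$weight
    network$projections[[key]]$delay <- normal$projections[[key]]$delay
  }
  attr(network, "recalibrate") <- c(attr(network, "recalibrate"), name)
  network
}

# Hand-built miniature network for unit tests and single-neuron experiments:
# arbitrary populations (name -> list(size, params)) and explicit projections
# (list(source, target, weight, delay, sources = K x n_tgt matrix)).
make_test_network <- function(pops, projections = list()) {
  sizes <- vapply(pops, function(p) as.integer(p$size), 0L)
  popdf <- data.frame(name = names(pops), size = sizes,
                      model = vapply(pops, function(p) p$params$model, ""),
                      offset = cumsum(c(0L, unname(sizes)))[seq_along(sizes)],
                      stringsAsFactors = FALSE)
  neurons <- lapply(pops, function(p) p$params)
  for (i in seq_along(projections)) {
    pr <- projections[[i]]
    if (is.null(pr$K)) projections[[i]]$K <- nrow(pr$sources)
  }
  cond <- structure(list(name = "test", family = "biphasic",
                         dopamine = dopamine_state(0.8), neurons = neurons,
                         projections = projections,
                         stim_scale = c("D1-SPN" = 1, "D2-SPN" = 1,
                                        "STN" = 1, "FSI" = 1),
                         rate_targets = list()),
                    class = "bg_condition")
  structure(list(populations = popdf, condition = cond, seed = 0L,
                 projections = projections),
            class = "bg_network")
}

# Global (1-based) id range of a population.
population_ids <- function(network, pop) {
  row <- network$populations[network$populations$name == pop, ]
  if (nrow(row) != 1L) stop("unknown population: ", pop)
  seq.int(row$offset + 1L, row$offset + row$size)
}

#' Export a network as per-projection edge lists
#'
#' Writes one tab-separated file per projection (columns `source`, `target`
#' as zero-based global neuron ids) plus a `populations.tsv` manifest.
#'
#' @param network A `bg_network`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
export_edge_lists <- function(network, dir) {
  stopifnot(inherits(network, "bg_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(network$populations, file.path(dir, "populations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  offs <- stats::setNames(network$populations$offset, network$populations$name)
  for (nm in names(network$projections)) {
    pr <- network$projections[[nm]]
    n_tgt <- ncol(pr$sources)
    df <- data.frame(
      source = as.vector(pr$sources) - 1L + offs[[pr$source]],
      target = rep(seq_len(n_tgt) - 1L + offs[[pr$target]], each = pr$K))
    fn <- gsub("[^A-Za-z0-9]+", "_", nm)
    utils::write.table(df, file.path(dir, paste0(fn, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
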