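# Model parameters: neuron constants, connectivity, dopamine modulation and
# condition presets for the reduced basal-ganglia network (6539 neurons).

#' Population names of the basal-ganglia network
#'
#' @return Character vector of the seven population names in canonical order.
#' @export
bg_populations <- function() {
  c("D1-SPN", "D2-SPN", "FSI", "STN", "GPe-TA", "GPe-TI", "SNr")
}

#' Population sizes of the reduced basal-ganglia network
#'
#' @return Named integer vector of population sizes (total 6539 neurons).
#' @export
bg_population_sizes <- function() {
  c("D1-SPN" = 2000L, "D2-SPN" = 2000L, "FSI" = 80L, "STN" = 388L,
    "GPe-TA" = 329L, "GPe-TI" = 988L, "SNr" = 754L)
}

#' Reference neuron parameters per population
#'
#' LIF populations carry the membrane, threshold and synaptic-kinetics
#' constants; AdEx populations add the exponential spike-initiation term and
#' the adaptation current.  Units: pF, nS, mV, ms, pA.  `beta_EL` /
#' `beta_Vth` are the dimensionless dopamine sensitivities of the leak
#' reversal and spike threshold.  Two printed oddities are kept as printed:
#' the STN excitatory reversal potential of -10 mV, and the distinct
#' excitatory/inhibitory synaptic time constants of the two pallidal
#' populations.
#'
#' @return Named list of per-population parameter lists.
#' @export
neuron_params_table <- function() {
  list(
    "D1-SPN" = list(
      model = "lif", C_m = 192, g_L = 8.04, E_L = -87.2, V_th = -45,
      V_reset = -87.2, E_ex = 0, E_in = -64, tau_syn_ex = 0.3,
      tau_syn_in = 2, I_e = 128, t_ref = 2,
      beta_EL = 0.05, beta_Vth = 0.205),
    "D2-SPN" = list(
      model = "lif", C_m = 157, g_L = 6.46, E_L = -85.4, V_th = -45,
      V_reset = -85.4, E_ex = 0, E_in = -64, tau_syn_ex = 0.3,
      tau_syn_in = 2, I_e = 0, t_ref = 2,
      beta_EL = 0, beta_Vth = 0),
    "FSI" = list(
      model = "lif", C_m = 700, g_L = 16.67, E_L = -65, V_th = -54,
      V_reset = -65, E_ex = 0, E_in = -76, tau_syn_ex = 0.3,
      tau_syn_in = 2, I_e = 0, t_ref = 2,
      beta_EL = -0.078, beta_Vth = 0),
    "STN" = list(
      model = "lif", C_m = 60, g_L = 10, E_L = -80.2, V_th = -64,
      V_reset = -70, E_ex = -10, E_in = -84, tau_syn_ex = 0.33,
      tau_syn_in = 1.5, I_e = 1, t_ref = 2,
      beta_EL = 0, beta_Vth = 0),
    "GPe-TA" = list(
      model = "adex", C_m = 60, g_L = 1, E_L = -55.1, V_th = -54.7,
      V_reset = -60, E_ex = 0, E_in = -65, tau_syn_ex = 1,
      tau_syn_in = 5.5, I_e = 1, t_ref = 2,
      a = 2.5, b = 105, Delta_T = 2.55, tau_w = 20, V_peak = 0,
      beta_EL = -0.181, beta_Vth = 0),
    "GPe-TI" = list(
      model = "adex", C_m = 40, g_L = 1, E_L = -55.1, V_th = -54.7,
      V_reset = -60, E_ex = 0, E_in = -65, tau_syn_ex = 4.8,
      tau_syn_in = 1, I_e = 12, t_ref = 2,
      a = 2.5, b = 70, Delta_T = 1.7, tau_w = 20, V_peak = 0,
      beta_EL = -0.181, beta_Vth = 0),
    "SNr" = list(
      model = "adex", C_m = 80, g_L = 3, E_L = -55.8, V_th = -55.2,
      V_reset = -65, E_ex = 0, E_in = -80, tau_syn_ex = 5.7,
      tau_syn_in = 2.04, I_e = 0, t_ref = 2,
      a = 3, b = 200, Delta_T = 1.6, tau_w = 20, V_peak = 0,
      beta_EL = -0.0896, beta_Vth = 0)
  )
}

# The 22 weighted/delayed pathways of the network in healthy condition:
# in-degree K (connections per target neuron), signed peak conductance
# weight (nS; negative = inhibitory, routed through the E_in channel),
# conduction delay (ms), and the dopamine sensitivity beta of the weight
# for each condition family ("biphasic" / "triphasic" low-dopamine tuning).
projection_table <- function() {
  p <- function(source, target, K, weight, delay, beta_bi = 0, beta_tri = beta_bi) {
    list(source = source, target = target, K = as.integer(K),
         weight = weight, delay = delay,
         beta_bi = beta_bi, beta_tri = beta_tri)
  }
  prj <- list(
    p("D1-SPN", "D1-SPN", 364, -0.15, 1.7, beta_bi = 0.88),
    p("D1-SPN", "D2-SPN",  84, -0.375, 1.7, beta_bi = 0.88),
    p("D2-SPN", "D1-SPN", 392, -0.45, 1.7, beta_bi = 0.88),
    p("D2-SPN", "D2-SPN", 504, -0.35, 1.7, beta_bi = 0.88),
    p("FSI",    "D1-SPN",  16, -2.6, 1.7, beta_bi = 0),
    p("FSI",    "D2-SPN",  11, -2.6, 1.7, beta_bi = -0.90),
    p("GPe-TA", "D1-SPN",  10, -0.02, 7, beta_bi = -1.22),
    p("GPe-TA", "D2-SPN",  10, -0.04, 7, beta_bi = -1.15),
    p("FSI",    "FSI",     10, -0.4, 1.7, beta_bi = -1.27),
    p("GPe-TA", "FSI",     10, -0.25, 7, beta_bi = -0.53),
    p("GPe-TI", "FSI",     10, -1.0, 7, beta_bi = -0.53),
    p("GPe-TI", "SNr",     32, -52.5, 3, beta_bi = 0),
    p("D1-SPN", "SNr",    500, -15, 7, beta_bi = 0.42, beta_tri = 0.56),
    p("STN",    "SNr",     30, 4.78, 4, beta_bi = 0),
    p("D2-SPN", "GPe-TI", 500, -1.08, 7, beta_bi = -1.00, beta_tri = -0.48),
    p("STN",    "GPe-TA",  30, 0.24, 2, beta_bi = -0.3),
    p("STN",    "GPe-TI",  30, 0.175, 2, beta_bi = -0.3),
    p("GPe-TA", "GPe-TA",   5, -0.11, 1, beta_bi = -0.83),
    p("GPe-TA", "GPe-TI",   5, -1.3, 1, beta_bi = -0.83),
    p("GPe-TI", "GPe-TA",  25, -0.35, 1, beta_bi = -0.83),
    p("GPe-TI", "GPe-TI",  25, -1.3, 1, beta_bi = -0.83),
    p("GPe-TI", "STN",     30, -0.3, 1, beta_bi = -0.54, beta_tri = -0.24)
  )
  names(prj) <- vapply(prj, function(x) paste0(x$source, "->", x$target), "")
  prj
}

# Dopamine sensitivities of the cortical (stimulus) pathway weights.
cortical_beta <- function(family = c("biphasic", "triphasic")) {
  family <- match.arg(family)
  c("D1-SPN" = 1.04, "D2-SPN" = -0.26, "STN" = -1.15, "FSI" = 0)
}

#' Dopamine state
#'
#' Encodes the tonic dopamine level `alpha_dop` in \[0, 1\] (0 = fully
#' dopamine-depleted / parkinsonian, 1 = high dopamine) together with the
#' reference level `alpha_normal` = 0.8 to which the healthy condition is
#' mapped.  All dopamine effects are linear in `phi = alpha_dop - alpha_normal`.
#'
#' @param alpha_dop Dopamine level in \[0, 1\].
#' @param alpha_normal Reference level (default 0.8).
#' @return An object of class `dopamine_state` with fields `alpha_dop`,
#'   `alpha_normal` and `phi`.
#' @export
dopamine_state <- function(alpha_dop, alpha_normal = 0.8) {
  stopifnot(is.numeric(alpha_dop), length(alpha_dop) == 1L)
  if (alpha_dop < 0 || alpha_dop > 1)
    stop("alpha_dop must lie in [0, 1]")
  structure(list(alpha_dop = alpha_dop, alpha_normal = alpha_normal,
                 phi = alpha_dop - alpha_normal),
            class = "dopamine_state")
}

#' Apply dopamine modulation to one population's neuron parameters
#'
#' The spike threshold is scaled as `V_th * (1 + beta_Vth * phi)` (non-zero
#' beta_Vth only for D1-SPN) and the leak reversal as `E_L * (1 + beta_EL *
#' phi)` (D1-SPN, FSI, GPe-TA, GPe-TI, SNr).  D2-SPN and STN neurons are not
#' dopamine-modulated by default; set `modulate_d2 = TRUE` to apply the
#' D1-type excitability scaling to D2-SPN as a control experiment.
#'
#' @param params Neuron parameter list for one population.
#' @param population Population name.
#' @param dopamine A [dopamine_state()].
#' @param modulate_d2 Logical; also modulate D2-SPN excitability (off by
#'   default).
#' @return The modulated parameter list.
#' @export
modulate_neuron <- function(params, population, dopamine, modulate_d2 = FALSE) {
  if (!population %in% bg_populations())
    stop("unknown population: ", population)
  phi <- dopamine$phi
  beta_EL <- params$beta_EL
  beta_Vth <- params$beta_Vth
  if (population == "D2-SPN" && modulate_d2) {
    # control experiment: give D2-SPN the D1-type excitability sensitivity
    beta_EL <- 0.05
    beta_Vth <- 0.205
  }
  params$E_L <- params$E_L * (1 + beta_EL * phi)
  params$V_th <- params$V_th * (1 + beta_Vth * phi)
  params
}

#' Apply dopamine modulation to a synaptic weight
#'
#' Scales a weight as `w * (1 + beta * phi)`.  The sign of the weight is
#' preserved for all parameter combinations used by the model; if a
#' combination would flip the sign a warning is raised.
#'
#' @param weight Signed peak conductance (nS).
#' @param beta Dimensionless dopamine sensitivity.
#' @param dopamine A [dopamine_state()].
#' @return Modulated weight (nS).
#' @export
modulate_weight <- function(weight, beta, dopamine) {
  f <- 1 + beta * dopamine$phi
  if (any(f < 0 & weight != 0))
    warning("dopamine modulation flips synapse polarity (factor ", f, ")")
  weight * f
}

# Per-population baseline firing-rate target intervals (Hz) used by the
# background calibration.  Point targets with a printed SD are represented as
# mean +/- SD intervals.
background_targets <- function(condition = c("normal", "pd")) {
  condition <- match.arg(condition)
  if (condition == "normal") {
    list("D1-SPN" = c(0.01, 2.0), "D2-SPN" = c(0.01, 2.0),
         "FSI" = c(10, 20), "STN" = c(10, 13),
         "GPe-TA" = c(10.7, 12.9), "GPe-TI" = c(23.5, 24.9),
         "SNr" = c(20, 35))
  } else {
    list("D1-SPN" = c(0.1, 0.5), "D2-SPN" = c(1, 2),
         "FSI" = c(10, 20), "STN" = c(26, 29),
         "GPe-TA" = c(12, 16), "GPe-TI" = c(17, 20),
         "SNr" = c(20, 35))
  }
}

#' Build a complete condition parameter bundle
#'
#' Assembles all neuron parameters, projections (with dopamine-modulated
#' weights), cortical-stimulus weight scaling factors and baseline-rate
#' targets for one of the three study conditions:
#'
#' * `"normal"`: healthy state, dopamine level 0.8;
#' * `"PD-biphasic"`: dopamine-depleted state (level 0) with the default
#'   low-dopamine synaptic sensitivities, in which the nigral transient
#'   response is biphasic;
#' * `"PD-triphasic"`: the same depleted state with three altered synaptic
#'   sensitivities (D2-SPN->GPe-TI, D1-SPN->SNr, GPe-TI->STN) that recover a
#'   triphasic transient response.
#'
#' @param name Condition name.
#' @param alpha_dop Optional dopamine level overriding the preset's default
#'   (used by dopamine-sweep experiments).
#' @param modulate_d2 Also apply dopamine modulation to D2-SPN excitability
#'   (control experiment; off by default).
#' @return An object of class `bg_condition`: a list with elements `name`,
#'   `dopamine`, `neurons` (modulated per-population parameter lists),
#'   `projections` (each with `K`, `weight` (modulated), `weight_normal`,
#'   `delay`, `beta`), `stim_scale` (per-target cortical weight factors),
#'   and `rate_targets`.
#' @export
build_condition <- function(name = c("normal", "PD-biphasic", "PD-triphasic"),
                            alpha_dop = NULL, modulate_d2 = FALSE) {
  name <- match.arg(name)
  family <- if (name == "PD-triphasic") "triphasic" else "biphasic"
  if (is.null(alpha_dop))
    alpha_dop <- if (name == "normal") 0.8 else 0.0
  dop <- dopamine_state(alpha_dop)

  neurons <- neuron_params_table()
  for (pop in names(neurons))
    neurons[[pop]] <- modulate_neuron(neurons[[pop]], pop, dop,
                                      modulate_d2 = modulate_d2)

  projections <- projection_table()
  for (nm in names(projections)) {
    pr <- projections[[nm]]
    beta <- if (family == "triphasic") pr$beta_tri else pr$beta_bi
    pr$beta <- beta
    pr$weight_normal <- pr$weight
    pr$weight <- modulate_weight(pr$weight, beta, dop)
    projections[[nm]] <- pr
  }

  cb <- cortical_beta(family)
  stim_scale <- 1 + cb * dop$phi
  targets <- background_targets(if (name == "normal") "normal" else "pd")

  structure(list(name = name, family = family, dopamine = dop,
                 neurons = neurons, projections = projections,
                 stim_scale = stim_scale, rate_targets = targets),
            class = "bg_condition")
}

#' @export
print.bg_condition <- function(x, ...) {
  cat("Basal-ganglia condition bundle:", x$name, "\n")
  cat("  dopamine level:", x$dopamine$alpha_dop,
      "(phi =", format(x$dopamine$phi), ")\n")
  cat("  populations:", paste(names(x$neurons), collapse = ", "), "\n")
  cat("  projections:", length(x$projections), "\n")
  invisible(x)
}

#' Tabulate a condition's projections
#'
#' One row per projection: source, target, in-degree, healthy weight, dopamine
#' sensitivity, effective (modulated) weight and delay.  Useful as an audit
#' dump.
#'
#' @param condition A `bg_condition`.
#' @return A data.frame.
#' @export
projection_summary <- function(condition) {
  stopifnot(inherits(condition, "bg_condition"))
  do.call(rbind, lapply(condition$projections, function(p)
    data.frame(source = p$source, target = p$target, K = p$K,
               weight_normal = p$weight_normal, beta = p$beta,
               weight = p$weight, delay = p$delay)))
}

#' Write / read a condition bundle as a YAML file
#'
#' Round-trips all fields of a condition bundle through a structured
#' plain-text representation.
#'
#' @param condition A `bg_condition`.
#' @param path File path.
#' @return `write_condition` returns `path` invisibly; `read_condition`
#'   returns the reconstructed `bg_condition`.
#' @export
write_condition <- function(condition, path) {
  stopifnot(inherits(condition, "bg_condition"))
  obj <- unclass(condition)
  obj$dopamine <- unclass(obj$dopamine)
  obj$stim_scale <- as.list(obj$stim_scale)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_condition
#' @export
read_condition <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$dopamine <- structure(obj$dopamine, class = "dopamine_state")
  obj$stim_scale <- unlist(obj$stim_scale)
  obj$rate_targets <- lapply(obj$rate_targets, unlist)
  structure(obj, class = "bg_condition")
}
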