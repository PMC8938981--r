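# Shared fixtures: miniature neuron parameter sets and synthetic PSTHs.

lif_test_params <- function(...) {
  p <- list(model = "lif", C_m = 200, g_L = 10, E_L = -70, V_th = -55,
            V_reset = -70, E_ex = 0, E_in = -80, tau_syn_ex = 0.5,
            tau_syn_in = 2, I_e = 0, t_ref = 2)
  mods <- list(...)
  p[names(mods)] <- mods
  p
}

single_neuron_net <- function(params) {
  bgnet:::make_test_network(list(X = list(size = 1, params = params)))
}

# Synthetic PSTH: pre-stimulus baseline with a tiny deterministic jitter
# (mean `base`, small positive SD) and a caller-supplied post-onset profile.
synthetic_psth <- function(post, base = 30, jitter = 0.1) {
  pre <- base + rep_len(c(-jitter, jitter), 100)
  rate <- c(pre, rep_len(post, 250))
  structure(list(rate = rate, time = seq.int(-100, 249),
                 baseline = list(mean = mean(pre), sd = stats::sd(pre)),
                 n_trials = 1L, n_neurons = 1L),
            class = "bg_psth")
}

# Post-onset profile with zones at given times (ms) and amplitudes (in
# baseline-SD units around `base`).  The SD matches the deterministic
# pre-stimulus jitter of synthetic_psth().
zone_profile <- function(base = 30, sd = NULL, spans = list()) {
  if (is.null(sd)) sd <- stats::sd(rep_len(c(-0.1, 0.1), 100))
  post <- rep(base, 250)
  for (s in spans) post[(s$from + 1):(s$to + 1)] <- base + s$z * sd
  post
}
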