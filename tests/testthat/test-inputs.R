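# External drive generation: Poisson trains, stimulus subsets, schedules.

test_that("Poisson trains have the right count statistics", {
  trains <- poisson_trains(100, n_sources = 500, duration = 10000, seed = 4)
  counts <- lengths(trains)
  expect_equal(mean(counts), 1000, tolerance = 0.01)
  expect_equal(stats::var(counts) / mean(counts), 1, tolerance = 0.15)
  # rate 0 gives empty trains; negative rate errors
  expect_true(all(lengths(poisson_trains(0, 5, 1000, seed = 1)) == 0))
  expect_error(poisson_trains(-1, 5, 1000), "non-negative")
  # different seeds give different realizations
  t1 <- poisson_trains(50, 3, 1000, seed = 1)
  t2 <- poisson_trains(50, 3, 1000, seed = 2)
  expect_false(identical(t1, t2))
  # pairwise count correlation of independent sources is near zero
  m <- vapply(poisson_trains(200, 60, 20000, seed = 9), function(tt)
    tabulate(ceiling(tt / 250), nbins = 80), numeric(80))
  cors <- stats::cor(m)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.5)
  expect_lt(abs(mean(cors[upper.tri(cors)])), 0.02)
})

test_that("the in-simulator background drive is Poisson with the requested rate", {
  # a leak-free integrator neuron is not available, so count background
  # events indirectly: a neuron with enormous threshold never spikes, and
  # the conductance trace integrates the alpha kernels; compare the mean
  # conductance with the analytic expectation rate * J * e * tau
  p <- lif_test_params(V_th = 100, tau_syn_ex = 1)
  net <- single_neuron_net(p)
  bg <- background_drive(rate = list(X = 2000), weight = list(X = 1))
  ras <- simulate_trial(net, background = bg, duration = 3000, seed = 8,
                        record_traces = 1)
  g_mean <- mean(ras$g_ex[10000:30000])
  expect_equal(g_mean, 2000 * 1 * exp(1) * 1e-3, tolerance = 0.05)
})

test_that("stimulated subsets have the exact size and honour STN-only mode", {
  net <- build_network(build_condition("normal"), seed = 2)
  prof <- default_stimulus_profile()
  stim_fn <- transient_stimulus(net, prof, fraction = 0.5, seed = 1)
  st <- stim_fn(800)
  stn_ids <- population_ids(net, "STN")
  expect_equal(sum(st$ids %in% stn_ids), 194L)  # half of 388
  expect_equal(sum(st$ids %in% population_ids(net, "D1-SPN")), 1000L)
  expect_equal(sum(st$ids %in% population_ids(net, "D2-SPN")), 1000L)

  only <- transient_stimulus(net, prof, fraction = 0.5, seed = 1,
                             stn_only = TRUE)(800)
  expect_true(all(only$ids %in% stn_ids))
  expect_equal(length(only$ids), 194L)
  expect_error(transient_stimulus(net, prof, fraction = 0), "fraction")

  # the same seed redraws the same subset; the subset is onset-independent
  st2 <- transient_stimulus(net, prof, fraction = 0.5, seed = 1)(850)
  expect_identical(st$ids, st2$ids)

  # rate profile: pulse of the right height and length at the onset
  r <- st$rate_fn(12000, 0.1)
  expect_equal(sum(r > 0) * 0.1, prof$pulse_dur)
  expect_equal(max(r), prof$pulse_rate)
  expect_equal(which(r > 0)[1], 800 / 0.1 + 1)
  m <- st$mod_fn(12000, 0.1)
  expect_equal(sum(m < 1) * 0.1, prof$supp_dur)
  expect_equal(min(m), prof$supp_frac)
})

test_that("stimulus weights are scaled by the condition's cortical dopamine factors", {
  prof <- default_stimulus_profile()
  pd <- build_network(build_condition("PD-biphasic"), seed = 2)
  nor <- build_network(build_condition("normal"), seed = 2)
  st_pd <- transient_stimulus(pd, prof, fraction = 1, seed = 1)(800)
  st_no <- transient_stimulus(nor, prof, fraction = 1, seed = 1)(800)
  stn <- population_ids(pd, "STN")
  w_pd <- unique(st_pd$weights[st_pd$ids %in% stn])
  w_no <- unique(st_no$weights[st_no$ids %in% stn])
  # cortico-STN weight is 1.92x stronger at dopamine 0 (beta = -1.15)
  expect_equal(w_pd / w_no, 1.92, tolerance = 1e-10)
  d1 <- population_ids(pd, "D1-SPN")
  w1_pd <- unique(st_pd$weights[st_pd$ids %in% d1])
  w1_no <- unique(st_no$weights[st_no$ids %in% d1])
  # cortico-D1 weight is weakened at low dopamine (beta = +1.04)
  expect_equal(w1_pd / w1_no, 1 - 1.04 * 0.8, tolerance = 1e-10)
})

test_that("trial schedules draw onsets uniformly inside the window", {
  sch <- trial_schedule(n_trials = 200, seed = 5)
  expect_length(sch$onsets, 200L)
  expect_true(all(sch$onsets >= 700 & sch$onsets <= 900))
  expect_gt(stats::sd(sch$onsets), 30)  # spread, not clustered
  expect_identical(trial_schedule(n_trials = 200, seed = 5)$onsets, sch$onsets)
})

test_that("background calibration updates rates toward the targets monotonically", {
  # single self-driven population with an analytic-ish response: more drive,
  # more spikes; calibration must land inside the interval
  p <- lif_test_params(I_e = 0)
  net <- bgnet:::make_test_network(list(X = list(size = 20, params = p)))
  init <- background_drive(rate = list(X = 2000), weight = list(X = 1))
  bg <- calibrate_background(net, init, targets = list(X = c(20, 30)),
                             duration = 2000, max_rounds = 6,
                             order = "X", seed = 3)
  expect_true(attr(bg, "converged"))
  ach <- attr(bg, "achieved")
  expect_true(ach[["X"]] >= 20 && ach[["X"]] <= 30)
  # idempotence: recalibrating from the calibrated state ends immediately
  bg2 <- calibrate_background(net, bg, targets = list(X = c(20, 30)),
                              duration = 2000, max_rounds = 6,
                              order = "X", seed = 3)
  expect_equal(unlist(bg2$rate), unlist(bg$rate))
})
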