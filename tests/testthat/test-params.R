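# Parameter tables, dopamine modulation and condition presets.

test_that("dopamine modulation of neuron excitability matches the printed scalings", {
  tab <- neuron_params_table()
  low <- dopamine_state(0)
  high <- dopamine_state(1)

  # FSI leak reversal: 5 mV lower at zero dopamine than at high dopamine
  fsi_lo <- modulate_neuron(tab$FSI, "FSI", low)$E_L
  fsi_hi <- modulate_neuron(tab$FSI, "FSI", high)$E_L
  expect_equal(fsi_hi - fsi_lo, 65 * 0.078, tolerance = 1e-10)
  expect_equal(fsi_hi - fsi_lo, 5, tolerance = 0.05)

  # GPe-TI leak reversal: 10 mV lower at zero dopamine
  ti_lo <- modulate_neuron(tab$`GPe-TI`, "GPe-TI", low)$E_L
  ti_hi <- modulate_neuron(tab$`GPe-TI`, "GPe-TI", high)$E_L
  expect_equal(ti_hi - ti_lo, 55.1 * 0.181, tolerance = 1e-10)
  expect_equal(ti_hi - ti_lo, 10, tolerance = 0.03)

  # SNr: 5 mV lower at zero dopamine
  snr_lo <- modulate_neuron(tab$SNr, "SNr", low)$E_L
  snr_hi <- modulate_neuron(tab$SNr, "SNr", high)$E_L
  expect_equal(snr_hi - snr_lo, 5, tolerance = 0.01)

  # identity at the reference level (phi = 0)
  ref <- dopamine_state(0.8)
  for (pop in bg_populations())
    expect_identical(modulate_neuron(tab[[pop]], pop, ref), tab[[pop]])

  # only D1-SPN has a threshold effect; D2-SPN and STN are unmodulated
  expect_equal(modulate_neuron(tab$`D1-SPN`, "D1-SPN", low)$V_th,
               -45 * (1 + 0.205 * -0.8))
  expect_identical(modulate_neuron(tab$`D2-SPN`, "D2-SPN", low), tab$`D2-SPN`)
  expect_identical(modulate_neuron(tab$STN, "STN", low), tab$STN)
  expect_error(modulate_neuron(tab$STN, "nucleus-x", low), "unknown")
})

test_that("dopamine modulation of weights is linear in phi and matches hand arithmetic", {
  low <- dopamine_state(0)
  # D2-SPN -> GPe-TI at full depletion, biphasic sensitivity
  expect_equal(modulate_weight(-1.08, -1.00, low), -1.944)
  # cortico-STN scaling factor at full depletion
  expect_equal(modulate_weight(1, -1.15, low), 1.92)
  # unchanged at phi = 0
  expect_equal(modulate_weight(-0.35, -0.83, dopamine_state(0.8)), -0.35)
  # linearity in phi
  b <- -0.7; w <- 2.5
  phis <- c(-0.8, -0.4, 0, 0.2)
  vals <- vapply(phis, function(p)
    modulate_weight(w, b, dopamine_state(p + 0.8)), 0)
  expect_equal(vals, w * (1 + b * phis))
  # sign flip is flagged
  expect_warning(modulate_weight(-1, 1.5, low), "polarity")
})

test_that("condition presets carry the printed projection table and overrides", {
  nor <- build_condition("normal")
  bip <- build_condition("PD-biphasic")
  tri <- build_condition("PD-triphasic")

  expect_equal(length(nor$projections), 22L)
  expect_equal(nor$projections[["D2-SPN->GPe-TI"]]$weight, -1.08)
  expect_equal(nor$dopamine$alpha_dop, 0.8)
  expect_equal(bip$dopamine$alpha_dop, 0)

  # the three boldfaced overrides distinguish the triphasic preset
  expect_equal(tri$projections[["D1-SPN->SNr"]]$beta, 0.56)
  expect_equal(tri$projections[["D2-SPN->GPe-TI"]]$beta, -0.48)
  expect_equal(tri$projections[["GPe-TI->STN"]]$beta, -0.24)
  overridden <- c("D1-SPN->SNr", "D2-SPN->GPe-TI", "GPe-TI->STN")
  for (nm in names(bip$projections)) {
    if (nm %in% overridden) {
      expect_false(isTRUE(all.equal(bip$projections[[nm]]$beta,
                                    tri$projections[[nm]]$beta)), info = nm)
    } else {
      expect_identical(bip$projections[[nm]], tri$projections[[nm]], info = nm)
    }
  }
  expect_identical(bip$neurons, tri$neurons)
  expect_error(build_condition("PD-quadriphasic"))
})

test_that("condition bundles round-trip through the YAML representation", {
  cond <- build_condition("PD-triphasic")
  path <- tempfile(fileext = ".yaml")
  write_condition(cond, path)
  back <- read_condition(path)
  expect_equal(back$neurons, cond$neurons)
  expect_equal(back$projections, cond$projections)
  expect_equal(back$stim_scale, cond$stim_scale)
  expect_equal(back$dopamine$phi, cond$dopamine$phi)
  unlink(path)
})

test_that("shipped condition files load back into identical bundles", {
  for (nm in c("normal", "PD-biphasic", "PD-triphasic")) {
    path <- system.file("extdata", paste0("condition_", nm, ".yaml"),
                        package = "bgnet")
    back <- read_condition(path)
    fresh <- build_condition(nm)
    expect_equal(back$projections, fresh$projections, info = nm)
    expect_equal(back$neurons, fresh$neurons, info = nm)
  }
})

test_that("projection audit table exposes effective weights", {
  tab <- projection_summary(build_condition("PD-biphasic"))
  expect_equal(nrow(tab), 22L)
  row <- tab[tab$source == "D2-SPN" & tab$target == "GPe-TI", ]
  expect_equal(row$weight, -1.944)
  expect_equal(row$weight_normal, -1.08)
  # delays are never dopamine-modulated
  nor <- projection_summary(build_condition("normal"))
  expect_equal(tab$delay, nor$delay)
})
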