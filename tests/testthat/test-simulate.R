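test_that("the null model produces an identically zero retract after pull-off", {
  cfg <- sim_config(bond = bond_model(lambda = 0),
                    tether = tether_model(lambda = 0),
                    noise = noise_model(deflection_sd = 0, drift_slope = 0),
                    seed = 1)
  out <- simulate_retract_curve(cfg)
  expect_equal(nrow(out$truth), 0)
  ret <- out$curve$segment == "retract"
  d <- out$curve$deflection[ret]
  n_contact <- ceiling((cfg$metadata$max_load / cfg$contact_stiffness) /
                         (3000 / cfg$metadata$sampling_rate))
  expect_true(all(d[(n_contact + 2):length(d)] == 0))
  expect_equal(d[1] * cfg$metadata$spring_constant_k, cfg$metadata$max_load)
})

test_that("identical configurations reproduce identical curves", {
  cfg <- preset_condition("NF-NF", seed = 9)
  a <- simulate_retract_curve(cfg)
  b <- simulate_retract_curve(cfg)
  expect_identical(a$curve$deflection, b$curve$deflection)
  expect_identical(a$truth, b$truth)
})

test_that("any map curve can be regenerated alone from its child seed", {
  cfg <- preset_condition("SF-SF", seed = 21)
  sim <- simulate_force_map(cfg, n_curves = 8, map_id = "mapA")
  i <- 7
  solo_cfg <- cfg
  solo_cfg$seed <- scfs:::.child_seed(cfg$seed, "mapA", i)
  solo_cfg$metadata$curve_id <- sprintf("mapA_c%02d", i)
  solo <- simulate_retract_curve(solo_cfg)
  expect_identical(solo$curve$deflection, sim$map$curves[[i]]$deflection)
})

test_that("ground-truth event counts follow the configured Poisson rates", {
  counts <- vapply(1:300, function(s) {
    out <- simulate_retract_curve(preset_condition("NF-NF", seed = 4000 + s))
    sum(out$truth$class == "jump")
  }, numeric(1))
  # lambda = 3; the mean over 300 curves should sit within a few standard
  # errors (losses to the record boundary are rare at these force scales)
  expect_gt(mean(counts), 2.5)
  expect_lt(mean(counts), 3.5)
})

test_that("generated events respect the minimum spacing, contact included", {
  for (s in 1:50) {
    out <- simulate_retract_curve(preset_benchmark(seed = 500 + s))
    pos <- sort(out$truth$separation_nm)
    if (length(pos) >= 1) expect_gte(pos[1], 60 - 1e-9)
    if (length(pos) >= 2) expect_true(all(diff(pos) >= 60 - 1e-9))
  }
})

test_that("noise-free truth equals an exact finite-difference scan of the trace", {
  hits <- 0
  for (s in 1:25) {
    cfg <- preset_benchmark(seed = 600 + s, noise_sd = 0)
    cfg$noise$drift_slope <- 0
    out <- simulate_retract_curve(cfg)
    osc <- oracle_step_scan(out$curve)
    expect_identical(sort(out$truth$index), osc)
    hits <- hits + length(osc)
  }
  expect_gt(hits, 0)
})

test_that("thermal records obey equipartition at long record lengths", {
  rec <- simulate_thermal_deflection(k = 60, duration = 50, seed = 11)
  ratio <- var(rec$deflection) * 60 / kBT()
  expect_gt(ratio, 0.98)
  expect_lt(ratio, 1.02)
})

test_that("doubling the spring constant halves the thermal variance exactly", {
  r1 <- simulate_thermal_deflection(k = 60, duration = 2, seed = 5)
  r2 <- simulate_thermal_deflection(k = 120, duration = 2, seed = 5)
  expect_equal(var(r1$deflection) / var(r2$deflection), 2, tolerance = 1e-10)
})

test_that("thermal synthesis rejects an unresolvable resonance", {
  expect_error(simulate_thermal_deflection(k = 60, f0 = 2000, fs = 3000),
               "twice the resonance")
})
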