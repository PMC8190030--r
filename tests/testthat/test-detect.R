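test_that("baseline correction removes offset and linear drift", {
  # drift-only curve: 0.01 pN/nm tilt over 10 um of piezo travel, no events
  cfg <- sim_config(bond = bond_model(lambda = 0),
                    tether = tether_model(lambda = 0),
                    noise = noise_model(deflection_sd = 0, drift_slope = 0.01),
                    seed = 1)
  out <- simulate_retract_curve(cfg)
  cv <- out$curve
  ret <- cv$segment == "retract"
  z <- cv$z_position[ret]; d <- cv$deflection[ret]
  n <- length(z); base <- (n - floor(n * 0.25) + 1):n
  slope <- coef(lm(d[base] ~ z[base]))[[2]]
  recovered <- -slope * cv$metadata$spring_constant_k   # pN per nm of travel
  expect_equal(recovered, 0.01, tolerance = 0.01)

  p <- correct_baseline(cv)
  expect_equal(mean(p$force[base]), 0, tolerance = 1e-9)  # lm residual mean
  off <- p$force[(n %/% 2):(n - 1)]                       # off-contact region
  expect_lt(max(abs(off)), 1e-6)
  expect_error(correct_baseline(make_retract_curve(rnorm(100))),
               "fewer than 50 samples")
})

test_that("contact point is found near the truth and shifts with the z axis", {
  cfg <- preset_benchmark(seed = 31)
  cv <- simulate_retract_curve(cfg)$curve
  p <- correct_baseline(cv)
  ci <- find_contact_point(p)
  true_z_contact <- max(cv$z_position) -
    cfg$metadata$max_load / cfg$contact_stiffness
  ds <- 1.5                                   # nm of travel per sample
  expect_lt(abs(p$z[ci] - true_z_contact), 15 * ds)
  expect_false(attr(ci, "flagged"))

  shifted <- cv
  shifted$z_position <- cv$z_position + 100
  p2 <- correct_baseline(shifted)
  ci2 <- find_contact_point(p2)
  expect_identical(as.integer(ci2), as.integer(ci))
  expect_equal(p2$z[ci2] - p$z[ci], 100)
})

test_that("a curve with no repulsive region falls back to a flagged contact", {
  cv <- make_retract_curve(rep(0, 1000))
  p <- correct_baseline(cv)
  ci <- find_contact_point(p)
  expect_identical(as.integer(ci), 1L)
  expect_true(attr(ci, "flagged"))
})

test_that("a noise-free step is localized exactly with its exact height", {
  d <- c(rep(-1, 1000), rep(0, 1000))   # 1.0 nm deflection step
  p <- correct_baseline(make_retract_curve(d))
  cand <- detect_steps(p)
  expect_equal(nrow(cand), 1)
  expect_identical(cand$index, 1001L)
  expect_equal(cand$step_height_nm, 1.0, tolerance = 1e-12)
  expect_equal(cand$step_force_pN, 60, tolerance = 1e-10)
})

test_that("two noise-free steps three windows apart are both localized", {
  d <- c(rep(-2, 900), rep(-1, 45), rep(0, 1055))   # steps at 901 and 946
  p <- correct_baseline(make_retract_curve(d))
  cand <- detect_steps(p)
  expect_identical(cand$index, c(901L, 946L))
  expect_equal(cand$step_height_nm, c(1, 1), tolerance = 1e-12)
})

test_that("pure noise yields no candidates in at least 99% of seeds", {
  clean <- 0
  for (s in 1:1000) {
    set.seed(s)
    p <- correct_baseline(make_retract_curve(rnorm(1e4, 0, 0.1)))
    if (nrow(detect_steps(p)) == 0) clean <- clean + 1
  }
  expect_gte(clean, 990)
})

test_that("short curves are rejected by the step detector", {
  p <- correct_baseline(make_retract_curve(rnorm(220, 0, 0.1)))
  p$force <- p$force[1:50]
  expect_error(detect_steps(p), "4 \\* window_w")
})

test_that("reported force is exactly spring constant times step height", {
  out <- simulate_retract_curve(preset_benchmark(seed = 13))
  ev <- process_curve(out$curve)$events
  expect_gt(nrow(ev), 0)
  expect_identical(ev$force_pN, ev$step_height_nm * 60)
})

test_that("scaling the spring constant scales forces, not indices", {
  out <- simulate_retract_curve(preset_benchmark(seed = 17))
  cv <- out$curve
  cv2 <- cv
  cv2$metadata$spring_constant_k <- 3 * cv$metadata$spring_constant_k
  e1 <- process_curve(cv)$events
  e2 <- process_curve(cv2)$events
  expect_identical(e2$index, e1$index)
  expect_equal(e2$force_pN, 3 * e1$force_pN, tolerance = 1e-9)
})

test_that("a loaded ramp is classified as a jump with the expected loading rate", {
  # single bond through k_eff = 0.2 pN/nm, rupture at 90 pN, no noise
  ds <- 1.5; n <- 2000; k <- 60; k_eff <- 0.2
  g <- (seq_len(n) - 1) * ds
  f <- numeric(n)
  ramp <- g >= 150 & g < 150 + 90 / k_eff
  f[ramp] <- -k_eff * (g[ramp] - 150)
  p <- correct_baseline(make_retract_curve(f / k))
  p <- scfs:::.add_separation(p)
  ev <- classify_events(p, detect_steps(p))
  expect_equal(nrow(ev), 1)
  expect_identical(ev$class, "jump")
  expect_equal(ev$force_pN, 90, tolerance = 0.02)
  expect_equal(ev$loading_rate_pN_per_s, 600, tolerance = 0.01)
})

test_that("a flat plateau is classified as a tether", {
  ds <- 1.5; n <- 2000; k <- 60
  g <- (seq_len(n) - 1) * ds
  f <- ifelse(g < 900, -30, 0)             # 30 pN plateau, detach at 900 nm
  p <- correct_baseline(make_retract_curve(f / k))
  p <- scfs:::.add_separation(p)
  ev <- classify_events(p, detect_steps(p))
  expect_equal(nrow(ev), 1)
  expect_identical(ev$class, "tether")
  expect_equal(ev$force_pN, 30, tolerance = 1e-9)
  expect_lt(abs(ev$pre_slope_pN_per_nm), 0.05)
})

test_that("event-free curves process to an empty event table", {
  cfg <- sim_config(bond = bond_model(lambda = 0),
                    tether = tether_model(lambda = 0), seed = 23)
  res <- process_curve(simulate_retract_curve(cfg)$curve)
  expect_equal(nrow(res$events), 0)
  expect_s3_class(res$events, "rupture_events")
})

test_that("processing errors carry the curve id", {
  cv <- make_retract_curve(rnorm(120, 0, 0.1),
                           meta = curve_metadata(curve_id = "shorty"))
  expect_error(process_curve(cv), "shorty")
})

test_that("high-SNR maps are recovered nearly completely with small force error", {
  tr <- list(); ev <- list()
  for (s in 1:20) {
    cfg <- preset_benchmark(seed = 700 + s)
    cfg$metadata$curve_id <- sprintf("c%02d", s)
    out <- simulate_retract_curve(cfg)
    tr[[s]] <- out$truth
    ev[[s]] <- process_curve(out$curve)$events
  }
  bm <- detection_benchmark(do.call(rbind, tr), do.call(rbind, ev))
  expect_gte(bm$recall, 0.95)
  expect_gte(bm$precision, 0.95)
  expect_lte(bm$force_rmse_pN, 3)
})

test_that("benchmark scoring handles empty inputs", {
  tr <- data.frame(curve_id = "a", separation_nm = 100, force_pN = 50,
                   stringsAsFactors = FALSE)
  de <- data.frame(curve_id = character(0), separation_nm = numeric(0),
                   force_pN = numeric(0), stringsAsFactors = FALSE)
  out <- detection_benchmark(tr, de)
  expect_equal(out$recall, 0)
  expect_equal(out$n_matched, 0)
  both <- detection_benchmark(tr[0, ], de)
  expect_true(is.na(both$recall))
})
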