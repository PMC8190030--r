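test_that("curve_metadata applies protocol defaults and validates inputs", {
  m <- curve_metadata()
  expect_equal(m$spring_constant_k, 60)
  expect_equal(m$velocity_v, 3)
  expect_equal(m$max_load, 3000)
  expect_equal(m$dwell_time, 2)
  expect_equal(m$temperature, 310.15)
  expect_equal(m$treatment_label, "none")
  expect_error(curve_metadata(spring_constant_k = -1))
  expect_error(curve_metadata(velocity_v = 0))
  expect_error(curve_metadata(treatment_label = "aspirin"))
})

test_that("force_curve enforces its structural invariants", {
  m <- curve_metadata()
  t5 <- (0:4) / 10
  z5 <- c(5, 4, 3, 2, 1)
  expect_error(force_curve(t5, z5[1:4], rep(0, 5), rep("retract", 5), m),
               "equal length")
  expect_error(force_curve(c(0, 0.1, 0.1, 0.3, 0.4), z5, rep(0, 5),
                           rep("retract", 5), m),
               "strictly increasing")
  expect_error(force_curve(t5, z5, rep(0, 5), rep("approach", 5), m),
               "retract segment is empty")
  expect_error(force_curve(t5, c(1, 2, 3, 4, 5), rep(0, 5),
                           rep("retract", 5), m),
               "non-increasing")
  expect_error(force_curve(t5, z5, rep(0, 5), rep("landing", 5), m),
               "segment labels")
  cv <- force_curve(t5, z5, rep(0, 5), rep("retract", 5), m)
  expect_s3_class(cv, "force_curve")
})

test_that("force_map requires a shared condition label", {
  a <- make_retract_curve(rep(0, 100),
                          meta = curve_metadata(condition_label = "NF-NF"))
  b <- make_retract_curve(rep(0, 100),
                          meta = curve_metadata(condition_label = "DF-DF"))
  expect_error(force_map(list(a, b)), "share one condition label")
  mp <- force_map(list(a, a), map_id = "m1")
  expect_equal(length(mp$curves), 2)
})

test_that("pool_condition keeps jump forces only and allows empty pools", {
  ev <- data.frame(class = c("jump", "tether", "jump", "tether", "jump"),
                   force_pN = c(40, 30, 55, 30, 62))
  ds <- pool_condition(ev, "NF-NF")
  expect_equal(ds$rupture_forces, c(40, 55, 62))
  empty <- pool_condition(ev[ev$class == "none", ], "NF-NF")
  expect_length(empty$rupture_forces, 0)
  expect_error(pool_condition(data.frame(class = "jump", force_pN = -3), "x"),
               "positive")
  # identical list pooled twice gives the identical multiset
  expect_identical(pool_condition(ev, "NF-NF")$rupture_forces,
                   ds$rupture_forces)
})

test_that("curve TSV files round-trip data and metadata", {
  cfg <- sim_config(metadata = curve_metadata(condition_label = "NF-NF",
                                              curve_id = "rt1"),
                    seed = 5)
  cv <- simulate_retract_curve(cfg)$curve
  path <- tempfile(fileext = ".tsv")
  write_force_curve(cv, path)
  back <- read_force_curve(path)
  expect_equal(back$deflection, cv$deflection, tolerance = 1e-8)
  expect_equal(back$z_position, cv$z_position, tolerance = 1e-8)
  expect_identical(back$segment, cv$segment)
  expect_equal(back$metadata$spring_constant_k, cv$metadata$spring_constant_k)
  expect_identical(back$metadata$curve_id, "rt1")
  expect_identical(back$metadata$condition_label, "NF-NF")
  # writing the same curve twice is byte-identical
  path2 <- tempfile(fileext = ".tsv")
  write_force_curve(cv, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  unlink(c(path, path2))
})

test_that("curve reader rejects malformed input naming the offending line", {
  cv <- make_retract_curve(rnorm(100, 0, 0.1))
  path <- tempfile(fileext = ".tsv")
  write_force_curve(cv, path)
  lines <- readLines(path)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("# spring constant sixty", lines[-1]), bad)
  expect_error(read_force_curve(bad), "spring constant sixty")

  writeLines(c("# mystery_key: 1", lines[-1]), bad)
  expect_error(read_force_curve(bad), "unknown header key")

  writeLines(sub("^# spring_constant_pN_per_nm: .*",
                 "# spring_constant_pN_per_nm: soft", lines), bad)
  expect_error(read_force_curve(bad), "non-numeric")

  writeLines(lines[startsWith(lines, "#")], bad)
  expect_error(read_force_curve(bad), "column header")
  unlink(c(path, bad))
})

test_that("event tables round-trip doubles exactly", {
  out <- simulate_retract_curve(preset_benchmark(seed = 3))
  ev <- process_curve(out$curve)$events
  expect_gt(nrow(ev), 0)
  path <- tempfile(fileext = ".tsv")
  write_event_table(ev, path)
  back <- read_event_table(path)
  expect_identical(back$force_pN, ev$force_pN)
  expect_identical(back$step_height_nm, ev$step_height_nm)
  expect_identical(back$index, ev$index)
  expect_identical(back$class, ev$class)
  # empty table: header-only file, zero rows on re-read
  write_event_table(ev[0, ], path)
  expect_equal(nrow(read_event_table(path)), 0)
  unlink(path)
})

test_that("thermal energy follows the Boltzmann constant in pN nm", {
  expect_equal(kB_pN_nm, 1.380649e-2)
  expect_equal(kBT(310.15), 1.380649e-2 * 310.15)
  expect_equal(kBT(310.15), 4.282, tolerance = 1e-3)
  expect_equal(kBT(620.3) / kBT(310.15), 2)
  expect_error(kBT(-1))
})

test_that("child seeds are deterministic, distinct and within the RNG range", {
  s1 <- scfs:::.child_seed(1, "map1", 7)
  expect_identical(s1, scfs:::.child_seed(1, "map1", 7))
  expect_false(s1 == scfs:::.child_seed(1, "map1", 8))
  expect_false(s1 == scfs:::.child_seed(2, "map1", 7))
  seeds <- vapply(1:500, function(i) scfs:::.child_seed(1, "m", i), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0)
})
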