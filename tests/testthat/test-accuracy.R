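test_that("TEP arithmetic and band membership behave at the boundaries", {
  expect_equal(compute_tep(5.0, 5.0), 0.0)
  expect_equal(compute_tep(9.2, 10.0), -0.8)
  expect_equal(compute_tep(-20.5, -20.0), -0.5)
  band <- accuracy_band()
  expect_true(is_accurate(0, band))
  expect_true(is_accurate(1.0, band))    # closed interval: endpoint counts
  expect_true(is_accurate(-1.0, band))
  expect_false(is_accurate(-1.2, band))
  expect_false(is_accurate(1.0, accuracy_band(inclusive = FALSE)))
})

test_that("accuracy-volume range extracts extremes, counts and gap flags", {
  band <- accuracy_band()
  sweep <- tibble::tibble(volume_mL = c(0, 0.5, 1.0, 1.5, 2.0),
                          tep_cmH2O = c(-3.0, -0.5, 0.2, 0.9, 2.5))
  r <- accuracy_volume_range(sweep, band)
  expect_equal(r$v_accuracy_min, 0.5)
  expect_equal(r$v_accuracy_max, 1.5)
  expect_equal(r$v_working, 1.0)
  expect_equal(r$n_in_band, 3L)
  expect_false(r$has_gaps)

  # all out of band: absent range, zero count
  none <- accuracy_volume_range(
    tibble::tibble(volume_mL = c(0, 0.5), tep_cmH2O = c(-5, 4)), band)
  expect_true(is.na(none$v_accuracy_min))
  expect_true(is.na(none$v_working))
  expect_equal(none$n_in_band, 0L)

  # exactly one in-band step: range collapses, working volume absent
  one <- accuracy_volume_range(
    tibble::tibble(volume_mL = c(0, 0.5, 1.0), tep_cmH2O = c(-2, 0.3, 1.4)),
    band)
  expect_equal(one$v_accuracy_min, 0.5)
  expect_equal(one$v_accuracy_max, 0.5)
  expect_true(is.na(one$v_working))
  expect_equal(one$n_in_band, 1L)

  # an interior excursion out of band is flagged but does not split the range
  gap <- accuracy_volume_range(
    tibble::tibble(volume_mL = c(0, 0.5, 1.0, 1.5),
                   tep_cmH2O = c(0.2, 1.6, 0.1, -0.2)), band)
  expect_equal(gap$v_accuracy_min, 0)
  expect_equal(gap$v_accuracy_max, 1.5)
  expect_true(gap$has_gaps)
  expect_equal(gap$n_in_band, 3L)
})

test_that("working volume and accuracy percentages reproduce printed arithmetic", {
  expect_equal(working_volume(0.5, 1.5), 1.0)
  expect_equal(working_volume(0.00, 0.66), 0.66)
  expect_equal(working_volume(2.0, 2.0), 0.0)
  expect_error(working_volume(1.5, 0.5), "v_max")

  expect_equal(accuracy_percent(10, 27), 37.0)
  expect_equal(accuracy_percent(16, 27), 59.3)
  expect_equal(accuracy_percent(0, 12), 0.0)
  # half-up, not banker's: 0.25 of 200 teps would be 12.5%, stays 12.5;
  # a .x5 percent rounds up
  expect_equal(accuracy_percent(1, 8), 12.5)
  expect_equal(accuracy_percent(5, 8), 62.5)
  expect_equal(accuracy_percent(3, 8), 37.5)

  r <- accuracy_rate(c(0, 0.5, -1.5, 2.0), accuracy_band())
  expect_equal(r$n_in_band, 2L)
  expect_equal(r$n_total, 4L)
  expect_equal(r$percent, 50.0)
  expect_error(accuracy_rate(numeric(0)), "value")
})

test_that("range extraction equals a 0.01-mL brute-force scan of the model", {
  eso <- toy_eso()
  cfg <- noise_free_cfg()
  for (p_box in c(-20, -10, 0, 10, 20)) {
    cath <- toy_catheter()
    sw <- simulate_chamber_sweep(cath, eso, p_box, cfg)
    got <- accuracy_volume_range(sw)
    iv <- oracle_band_scan(cath, eso, p_box, v_max = max(sw$volume_mL))
    in_grid <- sw$volume_mL[sw$volume_mL >= iv[1] - 1e-9 &
                              sw$volume_mL <= iv[2] + 1e-9]
    expect_equal(got$v_accuracy_min, min(in_grid))
    expect_equal(got$v_accuracy_max, max(in_grid))
    expect_equal(got$n_in_band, length(in_grid))
  }
})

test_that("mean working volume is the difference of mean extremes over a test set", {
  set.seed(5)
  eso <- toy_eso()
  cfg <- bench_config(noise_sd = 0.1, replicates = 3)
  grid <- run_study_grid(list(toy_catheter()), eso, cfg, seed = 9)
  rng <- accuracy_ranges(grid)
  both <- !is.na(rng$v_working)
  expect_gt(sum(both), 2)
  expect_equal(mean(rng$v_working[both]),
               mean(rng$v_accuracy_max[both]) - mean(rng$v_accuracy_min[both]))
  # a present working volume is at least one volume step
  expect_true(all(rng$v_working[both] >= cfg$volume_step))
})

test_that("recommended-volume accuracy filters steps and skips absent ranges", {
  eso <- toy_eso(e_es = 2)
  cfg <- noise_free_cfg(p_box_levels = 0, replicates = 1)
  # recommended range covering exactly the accuracy plateau: 100%
  cath <- toy_catheter(name = "OnPlateau", v_u0 = 0.5, v_o0 = 1.5,
                       recommended_min = 0.5, recommended_max = 1.5)
  sw <- run_study_grid(list(cath), eso, cfg, seed = 1)
  got <- recommended_volume_accuracy(sw, list(OnPlateau = cath))
  expect_equal(got$percent, 100.0)
  expect_false(got$skipped)

  # no stated range: skipped with a message
  cath_na <- toy_catheter(name = "NoRange", recommended_min = NA,
                          recommended_max = NA)
  sw_na <- run_study_grid(list(cath_na), eso, cfg, seed = 1)
  expect_message(
    got_na <- recommended_volume_accuracy(sw_na, list(NoRange = cath_na)),
    "skipped")
  expect_true(got_na$skipped)
  expect_true(is.na(got_na$percent))

  # range entirely below the underfill threshold at p_box = +20: 0%
  cath_low <- toy_catheter(name = "Underfilled", v_u0 = 3.5, c_u = 0.05,
                           k_u = 2, v_o0 = 4.5,
                           recommended_min = 0.5, recommended_max = 2.0)
  sw_low <- run_study_grid(list(cath_low), eso,
                           noise_free_cfg(p_box_levels = 20, replicates = 1),
                           seed = 1)
  got_low <- recommended_volume_accuracy(sw_low, list(Underfilled = cath_low))
  expect_equal(got_low$percent, 0.0)

  # range with no simulated steps inside it: explicit 0-of-0 flag
  cath_far <- toy_catheter(name = "FarRange", recommended_min = 8.6,
                           recommended_max = 8.9)
  sw_far <- run_study_grid(list(cath_far), eso, cfg, seed = 1)
  got_far <- recommended_volume_accuracy(sw_far, list(FarRange = cath_far))
  expect_true(got_far$empty)
  expect_equal(got_far$n_total, 0L)
})

test_that("per-catheter summary pools sweeps and mirrors the summary layout", {
  eso <- toy_eso()
  cfg <- bench_config(noise_sd = 0.05, replicates = 2,
                      p_box_levels = c(-10, 0, 10))
  grid <- run_study_grid(list(toy_catheter(name = "A"),
                              toy_catheter(name = "B", v_o0 = 2.5)),
                         eso, cfg, seed = 4)
  t2 <- table2_summary(accuracy_ranges(grid))
  expect_equal(t2$catheter, c("A", "B"))
  expect_true(all(c("v_accuracy_min_mean", "v_accuracy_min_sd",
                    "v_accuracy_max_median", "v_working_q1",
                    "v_working_q3") %in% names(t2)))
  # wider plateau means a larger mean working volume
  expect_gt(t2$v_working_mean[2], t2$v_working_mean[1])
})
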