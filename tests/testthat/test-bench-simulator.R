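test_that("forward TEP model matches hand-evaluated piecewise cases", {
  cath <- toy_catheter()          # v_u0 0.5, c_u 0.05, k_u 2, v_o0 1.5, c_o 0.03
  eso <- toy_eso(e_es = 2)        # with e_b = 2 the series elastance is 1

  # underfilled at v = 0, p_box = +20: V_min = 0.5 + 0.05*20 = 1.5, gain 2
  expect_equal(tep_model(0, 20, cath, eso), -3.0)
  # plateau is exactly zero everywhere between the thresholds
  v_min <- v_underfill_threshold(5, cath)
  v_ov <- v_overfill_threshold(5, cath)
  v_plateau <- seq(v_min, v_ov, length.out = 7)
  expect_equal(tep_model(v_plateau, 5, cath, eso), rep(0, 7))
  # 1 mL past the overfill threshold with E_ser = 1 overestimates by +1
  expect_equal(tep_model(v_ov + 1, 5, cath, eso), 1.0)
  expect_equal(series_elastance(cath, eso), 1.0)
  expect_error(tep_model(-0.5, 0, cath, eso), "volume")
})

test_that("TEP model is monotone in volume and thresholds move with pressure", {
  cath <- toy_catheter()
  eso <- toy_eso()
  for (p_box in c(-20, -5, 0, 5, 20)) {
    v <- seq(0, 8, by = 0.05)
    tep <- tep_model(v, p_box, cath, eso)
    expect_true(all(diff(tep) >= -1e-12))
  }
  # positive pressure raises the underfill threshold (c_u >= 0)
  expect_gte(v_underfill_threshold(20, cath), v_underfill_threshold(0, cath))
  # negative pressure lowers the overfill threshold
  expect_lt(v_overfill_threshold(-20, cath), v_overfill_threshold(0, cath))
  # overfill threshold never drops below the underfill threshold
  for (p in seq(-20, 20, by = 5))
    expect_gte(v_overfill_threshold(p, cath), v_underfill_threshold(p, cath))
})

test_that("noise-free elastance sweep is exactly two-segment and stops at the cap", {
  cath <- toy_catheter(v_res = 0.5, e_b = 15.7)
  cfg <- noise_free_cfg()
  curve <- simulate_elastance_sweep(cath, cfg)
  expect_equal(curve$pressure_cmH2O[1:4], c(0, 0, 7.85, 15.7))
  n <- nrow(curve)
  expect_gte(curve$pressure_cmH2O[n], 40)
  expect_true(all(curve$pressure_cmH2O[-n] < 40))
  expect_equal(curve$volume_mL, seq(0, by = 0.5, length.out = n))
  # exact piecewise structure: flat at 0 up to v_res, slope e_b after
  expect_equal(curve$pressure_cmH2O,
               15.7 * pmax(0, curve$volume_mL - 0.5))

  # v_res = 0 rises from the first increment
  curve0 <- simulate_elastance_sweep(toy_catheter(v_res = 0, e_b = 10), cfg)
  expect_equal(curve0$pressure_cmH2O[1:3], c(0, 5, 10))
})

test_that("sweeps are reproducible for a fixed seed", {
  cath <- toy_catheter()
  eso <- toy_eso()
  cfg <- bench_config(noise_sd = 0.1)
  a <- simulate_elastance_sweep(cath, cfg, seed = 42)
  b <- simulate_elastance_sweep(cath, cfg, seed = 42)
  expect_identical(a, b)
  s1 <- simulate_chamber_sweep(cath, eso, 10, cfg, seed = 7)
  s2 <- simulate_chamber_sweep(cath, eso, 10, cfg, seed = 7)
  expect_identical(s1, s2)
  g1 <- run_study_grid(list(cath), eso, cfg, seed = 3)
  g2 <- run_study_grid(list(cath), eso, cfg, seed = 3)
  expect_identical(g1, g2)
})

test_that("chamber sweep stops on the noise-free criterion or truncates with a flag", {
  cath <- toy_catheter()
  eso <- toy_eso(e_es = 8)   # series elastance 1.6: the stop is reachable
  cfg <- noise_free_cfg()
  # at p_box = +20 the sweep reaches 30 cmH2O and is not truncated
  sw <- simulate_chamber_sweep(cath, eso, 20, cfg)
  expect_false(attr(sw, "truncated"))
  n <- nrow(sw)
  expect_gte(sw$p_balloon_cmH2O[n], 30)
  expect_true(all(sw$p_balloon_cmH2O[-n] < 30))
  # TEP column is balloon minus chamber pressure at every step
  expect_equal(sw$tep_cmH2O, sw$p_balloon_cmH2O - sw$p_box_cmH2O)
  # at p_box = -20 the criterion is unreachable within 10 mL: flagged
  sw_neg <- simulate_chamber_sweep(cath, eso, -20, cfg)
  expect_true(attr(sw_neg, "truncated"))
  expect_equal(max(sw_neg$volume_mL), cfg$max_volume)
  # plateau covering v = 0 gives an initial TEP of exactly 0
  cath0 <- toy_catheter(v_u0 = 0, v_o0 = 1)
  sw0 <- simulate_chamber_sweep(cath0, eso, 0, cfg)
  expect_equal(sw0$tep_cmH2O[1], 0)
})

test_that("occlusion-test transmission follows the saturating volume law", {
  cath <- toy_catheter(v_dead = 0.1, tau = 0.2)
  eso <- toy_eso()
  cfg <- noise_free_cfg()
  # at the dead volume nothing is transmitted
  exc <- simulate_ppot(cath, eso, 0.1, cfg)
  expect_equal(exc$delta_p_box_cmH2O, c(2.5, 5, 7.5, 10))
  expect_equal(exc$delta_p_es_cmH2O, rep(0, 4))
  # solving 1 - exp(-x/tau) = 0.8 gives x = tau * ln 5
  v80 <- 0.1 + 0.2 * log(5)
  expect_equal(transmission_ratio(v80, cath), 0.8)
  exc80 <- simulate_ppot(cath, eso, v80, cfg)
  expect_equal(exc80$delta_p_es_cmH2O / exc80$delta_p_box_cmH2O, rep(0.8, 4))
  # r stays within [0, 1] (saturating below 1 up to float rounding) and is
  # strictly increasing above the dead volume before saturation
  v <- seq(0, 10, by = 0.05)
  r <- transmission_ratio(v, cath)
  expect_true(all(r >= 0 & r <= 1))
  v2 <- seq(0.15, 2, by = 0.05)
  expect_true(all(diff(transmission_ratio(v2, cath)) > 0))
  expect_lt(transmission_ratio(2, cath), 1)
})

test_that("study grid emits one sweep per catheter x pressure x replicate", {
  eso <- toy_eso()
  cfg <- bench_config(replicates = 2, p_box_levels = c(-5, 0, 5),
                      noise_sd = 0.05)
  caths <- list(toy_catheter(name = "A"), toy_catheter(name = "B"))
  grid <- run_study_grid(caths, eso, cfg, seed = 1)
  cells <- unique(grid[c("catheter", "p_box_cmH2O", "replicate")])
  expect_equal(nrow(cells), 2 * 3 * 2)
  expect_equal(sort(unique(grid$catheter)), c("A", "B"))
  # degenerate 1 x 1 x 1 grid
  one <- run_study_grid(list(toy_catheter()), eso,
                        bench_config(replicates = 1, p_box_levels = 0),
                        seed = 1)
  expect_equal(nrow(unique(one[c("catheter", "p_box_cmH2O", "replicate")])), 1)
  expect_error(bench_config(replicates = 0), "replicates")
})
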