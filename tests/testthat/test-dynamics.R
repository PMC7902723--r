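test_that("ph_at evaluates constant, sinusoid, and clamping", {
  expect_equal(ph_at(ph_sinusoid(6.3, 0.5, 1), 0.25), 6.8)
  expect_equal(ph_at(ph_sinusoid(6.3, 0.5, 1), 0), 6.3)
  expect_equal(ph_at(ph_sinusoid(6.3, 0, 1), c(0, 0.1, 3)), rep(6.3, 3))
  expect_equal(ph_at(ph_constant(6.0), c(0, 5)), c(6, 6))
  # clamped to the characterized range
  expect_equal(ph_at(ph_sinusoid(7.4, 0.5, 1), 0.25), 7.5)
  expect_equal(ph_at(ph_sinusoid(5.2, 0.5, 1), 0.75), 5.1)
  expect_error(ph_at(ph_constant(6.3), -1), ">= 0")
  expect_error(ph_sinusoid(6.3, -0.1, 1), ">= 0")
  expect_error(ph_sinusoid(6.3, 0.5, 0), "> 0")
})

test_that("telegraph driver switches between two levels, reproducibly", {
  drv <- ph_telegraph(6.3, 0.5, f_ph = 0.5, seed = 11)
  t <- seq(0, 200, by = 0.1)
  p <- ph_at(drv, t)
  expect_true(all(p %in% c(5.8, 6.8)))
  expect_identical(p, ph_at(ph_telegraph(6.3, 0.5, 0.5, seed = 11), t))
  expect_false(identical(p, ph_at(ph_telegraph(6.3, 0.5, 0.5, seed = 12), t)))
  # exponential holding times with mean 1/f
  sch <- phglv:::telegraph_schedule(ph_telegraph(6.3, 0.5, 2, seed = 3),
                                    5000)
  holds <- diff(sch$times)
  expect_equal(mean(holds), 1 / 2, tolerance = 0.05)
})

test_that("glv_rhs matches the analytic structure", {
  cfg <- sim_config()
  cfg$delta <- 0  # logistic equilibrium without dilution
  cm <- single_community(r = 0.5, K = 0.1)
  expect_equal(glv_rhs(0.1, 6.3, cm, cfg), 0)
  expect_equal(glv_rhs(0, 6.3, cm, cfg), 0)
  # complete niche overlap: total density follows a single logistic
  cm2 <- pair_community(-1, -1, r = c(0.5, 0.5), K = c(0.2, 0.2))
  for (s in list(c(0.01, 0.05), c(0.1, 0.02), c(0.2, 0.2))) {
    d <- glv_rhs(s, 6.3, cm2, sim_config(delta = 0.05))
    d1 <- glv_rhs(sum(s), 6.3, single_community(0.5, 0.2),
                  sim_config(delta = 0.05))
    expect_equal(sum(d), d1, tolerance = 1e-12)
  }
  expect_error(glv_rhs(c(NA, 1), 6.3, cm2), "finite")
  expect_error(glv_rhs(-0.1, 6.3, cm), ">= 0")
})

test_that("single-species steady state matches K(1 - delta/r)", {
  set.seed(1)
  for (i in 1:10) {
    r <- runif(1, 0.2, 1); K <- runif(1, 0.05, 1)
    delta <- runif(1, 0.03, min(0.3, 0.8 * r))
    cm <- single_community(r, K)
    tr <- simulate_community(cm, ph_constant(6.3), sim_config(delta = delta))
    expect_equal(unname(final_densities(tr)), K * (1 - delta / r),
                 tolerance = 1e-6)
  }
})

test_that("washout, empty start, positivity and extinction permanence", {
  cfg <- short_config()
  # r <= delta everywhere: washed out to exactly 0
  cm <- single_community(r = 0.05, K = 0.1)
  tr <- simulate_community(cm, ph_constant(6.3), cfg)
  expect_identical(unname(final_densities(tr)), 0)
  # all-zero start stays identically zero
  cm0 <- pair_community(-0.5, -0.5, s0 = c(0, 0))
  tr0 <- simulate_community(cm0, ph_constant(6.3), cfg)
  expect_true(all(tr0$densities == 0))
  # random community trajectories: non-negative, extinct stays extinct
  pan <- generate_base_panel(panel_spec(seed = 6))
  for (s in 1:3) {
    cm <- sample_assemblage(pan, 10, sim_config(), seed = s)
    tr <- simulate_community(cm, ph_sinusoid(6.3, 0.5, 0.2), cfg)
    expect_true(all(tr$densities >= 0))
    for (i in seq_len(nrow(tr$densities))) {
      z <- which(tr$densities[i, ] == 0)
      if (length(z) > 0)
        expect_true(all(tr$densities[i, z[1]:ncol(tr$densities)] == 0))
    }
  }
})

test_that("zero-amplitude sinusoid reproduces the constant driver exactly", {
  pan <- generate_base_panel(panel_spec(seed = 6))
  cm <- sample_assemblage(pan, 8, sim_config(), seed = 2)
  cfg <- short_config()
  t_out <- seq(0, 200, by = 10)
  tr_sin <- simulate_community(cm, ph_sinusoid(6.3, 0, 1), cfg,
                               t_end = 200, t_out = t_out)
  tr_con <- simulate_community(cm, ph_constant(6.3), cfg,
                               t_end = 200, t_out = t_out)
  expect_identical(tr_sin$densities, tr_con$densities)
})

test_that("halving solver tolerances leaves the benchmark composition fixed", {
  pan <- generate_base_panel(panel_spec(seed = 9))
  cm <- sample_assemblage(pan, 5, sim_config(), seed = 3)
  base <- sim_config()
  tight <- sim_config(rel_tol = base$rel_tol / 2, abs_tol = base$abs_tol / 2)
  f1 <- final_densities(simulate_community(cm, ph_constant(6.3), base))
  f2 <- final_densities(simulate_community(cm, ph_constant(6.3), tight))
  expect_lt(bray_curtis(rel_abundance(f1), rel_abundance(f2)), 1e-6)
})

test_that("runaway growth raises an error citing the instability condition", {
  cm <- pair_community(1.5, 1.5)  # product 2.25 > 1
  expect_error(simulate_community(cm, ph_constant(6.3), short_config(),
                                  t_end = 500),
               "mutual facilitation")
})

test_that("trajectories export as tidy data frames", {
  cm <- single_community()
  tr <- simulate_community(cm, ph_constant(6.3), short_config())
  df <- as.data.frame(tr)
  expect_named(df, c("time", "strain_id", "density", "ph"))
  expect_equal(nrow(df), length(tr$times))
  expect_true(all(df$ph == 6.3))
})
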