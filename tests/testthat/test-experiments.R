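test_that("bray_curtis matches the formula, alignment rules, and vegan", {
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  # union of named universes: absent strains count as zero
  expect_equal(bray_curtis(c(a = 1), c(b = 1)), 1)
  expect_equal(bray_curtis(c(a = 1, b = 1), c(b = 1, a = 1)), 0)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "universe")
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:25) {
    x <- runif(6); y <- runif(6)
    expect_equal(bray_curtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("fluctuation_response nulls: zero amplitude and single strain", {
  cfg <- short_config()
  sc1 <- enrich(single_community(0.5, 0.2), ph_constant(6.3), cfg)
  expect_equal(as.numeric(fluctuation_response(
    sc1, ph_sinusoid(6.3, 0.8, 0.2), cfg)), 0)  # degenerate composition
  pan <- generate_base_panel(panel_spec(seed = 2))
  sc <- enrich(sample_assemblage(pan, 10, sim_config(), seed = 1),
               ph_constant(6.3), cfg)
  expect_identical(as.numeric(fluctuation_response(
    sc, ph_sinusoid(6.3, 0, 0.2), cfg)), 0)
})

test_that("a slow driver that flips the competitive winner maximizes deviation", {
  cfg <- sim_config()
  sc <- as_stable(winner_flip_community(), p0 = 6.15)
  sc$densities <- final_densities(
    simulate_community(sc, ph_constant(6.15), cfg))
  expect_true(all(sc$densities > 0))  # coexistence at the reference pH
  # quasi-static oracle: support changes across the pH swing
  hi <- quasi_static_composition(sc, 7.0, cfg)
  at_ref <- quasi_static_composition(sc, 6.15, cfg)
  expect_identical(unname(hi[["a"]]), 0)      # a excluded at high pH
  expect_gt(at_ref[["a"]], at_ref[["b"]])     # a dominant at reference
  # the slow driver's upward excursion (half a period, longer than the
  # horizon) drives a extinct, so the final composition is near-disjoint
  # from the a-dominated reference
  d <- fluctuation_response(sc, ph_sinusoid(6.15, 0.9, 5e-4), cfg,
                            metric = "final")
  expect_gt(as.numeric(d), 0.6)
})

test_that("facilitation prevalence manipulation never creates mutual pairs", {
  pan <- generate_base_panel(panel_spec(n_positive = 0, seed = 12))
  expect_identical(set_facilitation_prevalence(pan$C, 0), pan$C)
  C5 <- set_facilitation_prevalence(pan$C, 0.5, seed = 3)
  off <- unclass(C5)[row(C5) != col(C5)]
  expect_equal(sum(off > 0), 15)  # half of 30
  expect_equal(nrow(screen_instability(C5)), 0)
  # no unordered pair positive in both directions
  M <- unclass(C5) > 0
  expect_true(all(!(M & t(M))))
  expect_identical(C5, set_facilitation_prevalence(pan$C, 0.5, seed = 3))
  expect_error(set_facilitation_prevalence(pan$C, 0.6), "0.5")
})

test_that("set_niche_overlap writes a uniform matrix with pinned diagonal", {
  pan <- generate_base_panel(panel_spec(seed = 13))
  C1 <- set_niche_overlap(pan$C, 1)
  expect_true(all(unclass(C1) == -1))
  C0 <- set_niche_overlap(pan$C, 0)
  expect_true(all(unclass(C0)[row(C0) != col(C0)] == 0))
  expect_true(all(diag(unclass(C0)) == -1))
  C.5 <- set_niche_overlap(pan$C, -0.5)  # sign ignored
  expect_equal(unclass(C.5), t(unclass(C.5)))
  expect_true(all(unclass(C.5)[row(C.5) != col(C.5)] == -0.5))
})

test_that("classify_facilitation counts positive off-diagonals", {
  pan <- generate_base_panel(panel_spec(n_positive = 3, seed = 14))
  expect_equal(classify_facilitation(pan$C), 0.1)  # 3 of 30
  expect_equal(classify_facilitation(set_niche_overlap(pan$C, 0.5)), 0)
  expect_equal(classify_facilitation(
    set_facilitation_prevalence(generate_base_panel(
      panel_spec(n_positive = 0, seed = 15))$C, 0.5, seed = 1)), 0.5)
})

test_that("compare_groups wraps the Mann-Whitney U test", {
  set.seed(8)
  a <- runif(100)
  same <- compare_groups(a, a)
  expect_gt(same$p_value, 0.9)
  expect_equal(unname(same$medians[1]), unname(same$medians[2]))
  shifted <- compare_groups(a, a + 0.5, labels = c("low", "high"))
  expect_lt(shifted$p_value, 1e-6)
  expect_error(compare_groups(numeric(0), a), "non-empty")
})

test_that("fluctuating assembly with zero amplitude changes no richness", {
  pan <- generate_base_panel(panel_spec(seed = 16))
  cfg <- short_config()
  res <- richness_under_fluctuating_assembly(pan, dph_values = c(0, 0.5),
                                             f_values = 0.2, config = cfg,
                                             n_assemblages = 5, seed = 2)
  zero_cells <- which(res$cells$dph == 0)
  expect_true(all(res$richness_delta[, zero_cells] == 0))
  res2 <- richness_under_fluctuating_assembly(pan, dph_values = c(0, 0.5),
                                              f_values = 0.2, config = cfg,
                                              n_assemblages = 5, seed = 2)
  expect_identical(res$richness_delta, res2$richness_delta)
  expect_identical(res$gained, res2$gained)
})
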