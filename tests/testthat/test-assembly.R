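test_that("enrich recovers the closed-form single-strain community", {
  cm <- single_community(r = 0.5, K = 0.1)
  cfg <- sim_config(delta = 0.05)
  sc <- enrich(cm, ph_constant(6.3), cfg)
  expect_s3_class(sc, "stable_community")
  expect_true(attr(sc, "stable"))
  expect_length(sc$strains, 1)
  expect_equal(unname(sc$densities), 0.1 * (1 - 0.05 / 0.5),
               tolerance = 1e-6)
})

test_that("washout strains are pruned during enrichment", {
  g <- ph_grid()
  viable <- strain("ok", "spA", flat_response(0.5, 0.2))
  doomed <- strain("dead", "spB", flat_response(0.04, 0.2))  # r < delta
  C <- interaction_matrix(matrix(c(-1, -0.3, -0.3, -1), 2, 2))
  cm <- glv_community(list(viable, doomed), C, 1e-4)
  sc <- enrich(cm, ph_constant(6.3), sim_config())
  expect_equal(names(sc$densities), "ok")
  expect_equal(attr(sc, "gained_lost")$lost, "spB")
})

test_that("enrichment is deterministic and idempotent", {
  pan <- generate_base_panel(panel_spec(seed = 5))
  cfg <- sim_config()
  asm1 <- sample_assemblage(pan, 20, cfg, seed = 13)
  asm2 <- sample_assemblage(pan, 20, cfg, seed = 13)
  sc1 <- enrich(asm1, ph_constant(6.3), cfg)
  sc2 <- enrich(asm2, ph_constant(6.3), cfg)
  expect_identical(names(sc1$densities), names(sc2$densities))
  expect_identical(sc1$densities, sc2$densities)
  # idempotence: enriching the stable community changes nothing material
  sc3 <- enrich(sc1, ph_constant(6.3), cfg)
  expect_identical(names(sc3$densities), names(sc1$densities))
  expect_lt(bray_curtis(rel_abundance(sc1$densities),
                        rel_abundance(sc3$densities)), 1e-3)
  # richness never exceeds the assemblage size
  expect_lte(length(sc1$strains), 20)
})

test_that("is_stable separates stationary from oscillating compositions", {
  cm <- single_community(r = 0.5, K = 0.1)
  cfg <- sim_config()
  tr <- simulate_community(cm, ph_constant(6.3), cfg)
  expect_true(is_stable(tr))
  # synthetic oscillating trajectory: BC amplitude ~0.1 between windows
  gen <- generation_time(cfg)
  times <- seq(0, 100 * gen, by = gen)
  dens <- matrix(0.5, 2, length(times),
                 dimnames = list(c("a", "b"), NULL))
  dens[1, ] <- 0.5 + 0.1 * (seq_along(times) %% 2)
  fake <- structure(list(times = times, densities = dens,
                         final = dens[, ncol(dens)], config = cfg,
                         t_end = max(times)),
                    class = "glv_trajectory")
  # windows 10 generations apart land on opposite phases
  fake$densities[1, ncol(dens) - 10] <- 0.6
  fake$densities[1, ncol(dens)] <- 0.5
  fake$final <- fake$densities[, ncol(dens)]
  expect_false(is_stable(fake))
  expect_error(is_stable(tr, window = 1000), "fewer")
})

test_that("dilution robustness filter keeps insensitive communities", {
  cfg <- sim_config()
  # a single-strain community always passes (degenerate composition)
  sc1 <- enrich(single_community(0.5, 0.1), ph_constant(6.3), cfg)
  expect_true(dilution_robustness_filter(sc1, cfg))
  # neutral pair: identical parameters, complete overlap; split unchanged
  scn <- enrich(pair_community(-1, -1, s0 = c(2e-4, 1e-4)),
                ph_constant(6.3), cfg)
  expect_true(dilution_robustness_filter(scn, cfg))
  # a community losing a member at 1.5 delta fails:
  # r = 0.12 survives delta = 0.1 but not 0.15
  frail <- glv_community(
    list(strain("a", "spA", flat_response(0.5, 0.1)),
         strain("b", "spB", flat_response(0.12, 0.4))),
    interaction_matrix(matrix(c(-1, -0.1, -0.1, -1), 2, 2)), 1e-4)
  scf <- enrich(frail, ph_constant(6.3), cfg)
  expect_equal(length(scf$strains), 2)
  res <- dilution_robustness_filter(scf, cfg)
  expect_false(res)
  expect_gt(attr(res, "deviation"), 0.2)
})

test_that("the assembly pipeline reports the facilitation-enrichment statistic", {
  pan <- generate_base_panel(panel_spec(seed = 21))
  ens <- assemble_ensemble(pan, 30, sim_config(), seed = 4)
  counts <- attr(ens, "counts")
  expect_true(counts["filtered"] <= counts["stable"])
  expect_true(counts["stable"] <= counts["assemblages"])
  fe <- attr(ens, "facilitation_enrichment")
  expect_true(is.na(fe) || (fe >= 0 && fe <= 1))
  # every kept community carries a realized facilitation fraction
  fr <- vapply(ens, function(s) attr(s, "facilitation_fraction"), numeric(1))
  expect_true(all(is.nan(fr) | (fr >= 0 & fr <= 0.5)))
})
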