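test_that("strain panel CSVs round-trip through the documented format", {
  pan <- generate_base_panel(panel_spec(seed = 31))
  f <- withr::local_tempfile(fileext = ".csv")
  write_strain_panel(pan, f)
  header <- names(read.csv(f, check.names = FALSE, nrows = 1))
  expect_true(all(c("strain_id", "species", "r@5.1", "r@7.5", "K@5.1",
                    "K@7.5") %in% header))
  back <- read_strain_panel(f)
  expect_equal(names(back), names(pan$species))
  for (sp in names(back)) {
    expect_equal(back[[sp]]$response$r, pan$species[[sp]]$r)
    expect_equal(back[[sp]]$response$K, pan$species[[sp]]$K)
  }
})

test_that("interaction matrices and slopes round-trip as CSV", {
  pan <- generate_base_panel(panel_spec(seed = 32))
  C <- interaction_matrix(unclass(pan$C),
                          slopes = matrix(0.05, 6, 6), p0 = 7.2)
  f <- withr::local_tempfile(fileext = ".csv")
  fs <- withr::local_tempfile(fileext = ".csv")
  write_interaction_matrix(C, f, slopes_path = fs)
  back <- read_interaction_matrix(f, slopes_path = fs)
  expect_equal(unclass(back), unclass(C), ignore_attr = TRUE)
  sl <- attr(back, "slopes")
  expect_equal(unname(sl[1, 2]), 0.05)
  expect_equal(unname(diag(sl)), rep(0, 6))  # diagonal slopes pinned to 0
})

test_that("load_panel pairs the files into an assembly-ready panel", {
  pan <- generate_base_panel(panel_spec(seed = 33))
  d <- withr::local_tempdir()
  write_strain_panel(pan, file.path(d, "panel.csv"))
  write_interaction_matrix(pan$C, file.path(d, "matrix.csv"))
  write_panel_sidecar(pan, file.path(d, "panel.json"))
  pan2 <- load_panel(file.path(d, "panel.csv"), file.path(d, "matrix.csv"))
  expect_equal(unclass(pan2$C), unclass(pan$C), ignore_attr = TRUE)
  cm <- sample_assemblage(pan2, 5, sim_config(), seed = 1)
  expect_length(cm$strains, 5)
  meta <- jsonlite::read_json(file.path(d, "panel.json"))
  expect_equal(meta$seed, 33)
  expect_equal(meta$n_species, 6)
})

test_that("config files validate, default, and round-trip", {
  d <- withr::local_tempdir()
  empty <- file.path(d, "empty.json")
  writeLines("{}", empty)
  cfg <- load_config(empty)
  expect_equal(cfg$n_c, 20)
  expect_equal(cfg$n_s, 10000)
  expect_equal(cfg$n_gen, 100)
  expect_equal(cfg$ph_range, c(5.1, 7.5))
  expect_equal(cfg$n_ext, 1e-6)
  expect_equal(cfg$f_p, 0.2)
  expect_equal(cfg$s0, 1e-4)
  bad <- file.path(d, "bad.json")
  writeLines('{"delta": -1}', bad)
  expect_error(load_config(bad), "> 0")
  unk <- file.path(d, "unk.json")
  writeLines('{"frobnicate": 2}', unk)
  expect_error(load_config(unk), "frobnicate")
  full <- file.path(d, "full.json")
  cfg1 <- sim_config(delta = 0.07, n_gen = 50, seed = 4)
  save_config(cfg1, full)
  expect_equal(load_config(full), cfg1)
})

test_that("run_reproduction produces a regenerable manifest bundle", {
  cfg <- short_config(n_s = 400)
  d <- withr::local_tempdir()
  expect_error(run_reproduction(scale = 0, config = cfg), "> 0")
  res <- run_reproduction(scale = 0.02, config = cfg, out_dir = d,
                          seed = 5, dph_values = c(0, 0.5),
                          f_values = c(0.02, 0.2))
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_true(file.exists(file.path(d, "panel.csv")))
  expect_true(file.exists(file.path(d, "amplitude_sweep.csv")))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$seed, 5)
  expect_equal(man$n_assemblages, 8)
  # identical manifest inputs -> identical outputs
  res2 <- run_reproduction(scale = 0.02, config = cfg, seed = 5,
                           dph_values = c(0, 0.5),
                           f_values = c(0.02, 0.2))
  expect_identical(res$amplitude$values, res2$amplitude$values)
  expect_identical(res$frequency$values, res2$frequency$values)
  # the zero-amplitude column is identically zero
  expect_true(all(res$amplitude$values[, 1] == 0))
})

test_that("the CLI runs a small assemble and rejects unknown commands", {
  d <- withr::local_tempdir()
  res <- cli_main(c("assemble", "--seed=2", "--n=4",
                    sprintf("--out=%s", d)))
  expect_true(file.exists(file.path(d, "communities.csv")))
  expect_true(file.exists(file.path(d, "assemble.json")))
  meta <- jsonlite::read_json(file.path(d, "assemble.json"))
  expect_equal(meta$seed, 2)
  expect_equal(meta$config$n_c, 20)
  expect_error(cli_main("no-such-command"), "unknown subcommand")
  expect_error(cli_main(c("assemble", "oops")), "unexpected")
})
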