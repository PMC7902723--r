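config_key_map <- c(N_c = "n_c", N_s = "n_s", N_gen = "n_gen",
                    pH_rng = "ph_range", delta = "delta", N_ext = "n_ext",
                    f_p = "f_p", S_0 = "s0", f_pH = "f_ph", dpH = "dph",
                    rel_tol = "rel_tol", abs_tol = "abs_tol", seed = "seed")

#' Load a simulation configuration file
#'
#' Reads a JSON configuration whose keys mirror the standard parameter
#' names (`N_c`, `N_s`, `N_gen`, `pH_rng`, `delta`, `N_ext`, `f_p`,
#' `S_0`, `f_pH`, `dpH`, plus `rel_tol`, `abs_tol`, `seed`).  Missing
#' keys fall back to the defaults of [sim_config()]; an empty file yields
#' the full default set.  Unknown keys or out-of-range values raise an
#' error naming the offenders.
#'
#' @param path JSON file path.
#' @return A [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) return(sim_config())
  unknown <- setdiff(names(raw), names(config_key_map))
  if (length(unknown) > 0)
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  args <- setNames(raw, config_key_map[names(raw)])
  do.call(sim_config, args)
}

#' Save a simulation configuration file
#'
#' Inverse of [load_config()]; the written JSON round-trips exactly.
#'
#' @param config a [sim_config()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  inv <- setNames(names(config_key_map), config_key_map)
  out <- list()
  for (k in names(config)) {
    if (is.null(config[[k]])) next
    out[[inv[[k]]]] <- config[[k]]
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Assemble an ensemble of filtered stable communities
#'
#' Pipeline stage shared by the experiments: sample `n` assemblages from
#' `panel`, enrich each at constant pH, and keep those that are
#' stationary and pass the dilution-robustness filter.
#'
#' @param panel a `"base_panel"`.
#' @param n number of assemblage instances.
#' @param config a [sim_config()].
#' @param p0 assembly pH.
#' @param seed master seed (fans out per assemblage).
#' @param filter apply [dilution_robustness_filter()] (default `TRUE`).
#' @return list of `"stable_community"` objects; attribute `counts` holds
#'   `c(assemblages, stable, filtered)` and attribute
#'   `facilitation_enrichment` the fraction of stable assemblies - among
#'   those whose initial assemblage had at least one facilitation
#'   interaction - in which the realized facilitation fraction increased
#'   from assemblage to final community.
#' @export
assemble_ensemble <- function(panel, n, config = sim_config(), p0 = 6.3,
                              seed = 1, filter = TRUE) {
  out <- list()
  n_stable <- 0L
  had_fac <- 0L
  fac_up <- 0L
  for (i in seq_len(n)) {
    asm <- sample_assemblage(panel, config = config,
                             seed = child_seed(seed, 1L, i))
    sc <- enrich(asm, ph_constant(p0), config)
    if (!isTRUE(attr(sc, "stable"))) next
    n_stable <- n_stable + 1L
    f0 <- classify_facilitation(asm)
    if (is.finite(f0) && f0 > 0) {
      had_fac <- had_fac + 1L
      f1 <- attr(sc, "facilitation_fraction")
      if (is.finite(f1) && f1 > f0) fac_up <- fac_up + 1L
    }
    if (filter && !isTRUE(dilution_robustness_filter(sc, config))) next
    out[[length(out) + 1]] <- sc
  }
  attr(out, "counts") <- c(assemblages = n, stable = n_stable,
                           filtered = length(out))
  attr(out, "facilitation_enrichment") <-
    if (had_fac > 0) fac_up / had_fac else NA_real_
  out
}

#' End-to-end reproduction driver
#'
#' Runs the whole pipeline at a reduced scale: synthetic panel ->
#' assemblage sampling -> enrichment -> stability and dilution-robustness
#' filters -> amplitude and frequency sweeps -> ensemble summaries.  All
#' randomness derives from `seed` through [child_seed()], so the same
#' manifest reproduces the same outputs bit for bit.  Results (panel
#' CSVs, tidy summary CSVs, JSON manifest) are written under `out_dir`.
#'
#' @param scale fraction of the full `n_s` ensemble to run (e.g. 0.01 for
#'   100 instances); must be > 0.
#' @param config a [sim_config()].
#' @param panel optional panel; generated from `seed` when `NULL`.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param seed master seed.
#' @param dph_values,f_values sweep grids.
#' @param f_ph_amp fixed frequency of the amplitude sweep (1/h).
#' @param dph_freq fixed amplitude of the frequency sweep (pH units).
#' @param p0 assembly / fluctuation center pH.
#' @return list with `ensemble`, `amplitude` and `frequency`
#'   (`"experiment_summary"`), `counts`, and `manifest`.
#' @export
run_reproduction <- function(scale = 0.01, config = sim_config(),
                             panel = NULL, out_dir = NULL, seed = 1,
                             dph_values = c(0, 0.25, 0.5, 1),
                             f_values = 10^seq(-2.5, 1, by = 0.5),
                             f_ph_amp = 0.2, dph_freq = 0.5, p0 = 6.3) {
  if (!is_number(scale) || scale <= 0)
    stopf("scale must be > 0 (an empty ensemble reproduces nothing)")
  n <- max(1L, as.integer(round(config$n_s * scale)))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(panel))
    panel <- generate_base_panel(panel_spec(seed = child_seed(seed, 100L)))
  ens <- assemble_ensemble(panel, n, config, p0 = p0, seed = seed)
  counts <- attr(ens, "counts")
  if (length(ens) == 0) stopf("no community passed the filters; enlarge n")
  amp <- amplitude_sweep(ens, dph_values, f_ph = f_ph_amp, config = config,
                         seed = child_seed(seed, 2L))
  freq <- frequency_sweep(ens, f_values, dph = dph_freq, config = config,
                          seed = child_seed(seed, 3L))
  elapsed <- proc.time()[["elapsed"]] - t0
  manifest <- list(
    package = "phglv",
    version = as.character(utils::packageVersion("phglv")),
    seed = seed, scale = scale, n_assemblages = n,
    counts = as.list(counts),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    panel_source = if (!is.null(panel$spec)) "generate_base_panel"
                   else "external",
    panel_seed = panel$spec$seed %||% NA,
    sweeps = list(dph_values = dph_values, f_values = f_values,
                  f_ph_amp = f_ph_amp, dph_freq = dph_freq, p0 = p0),
    elapsed_s = elapsed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_strain_panel(panel, file.path(out_dir, "panel.csv"))
    write_interaction_matrix(panel$C, file.path(out_dir, "interactions.csv"))
    if (!is.null(panel$spec))
      write_panel_sidecar(panel, file.path(out_dir, "panel_provenance.json"))
    write.csv(amp$stats, file.path(out_dir, "amplitude_sweep.csv"),
              row.names = FALSE)
    write.csv(freq$stats, file.path(out_dir, "frequency_sweep.csv"),
              row.names = FALSE)
    manifest$outputs <- c("panel.csv", "interactions.csv",
                          "amplitude_sweep.csv", "frequency_sweep.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(ensemble = ens, amplitude = amp, frequency = freq, counts = counts,
       manifest = manifest)
}
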