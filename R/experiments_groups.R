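enrich_from_panel <- function(panel, config, p0, seed) {
  asm <- sample_assemblage(panel, config = config, seed = seed)
  enrich(asm, ph_constant(p0), config)
}

#' Competitive vs cooperative group comparison
#'
#' Builds matched community pairs: for each draw a fully competitive
#' species panel (no facilitation) is generated, and a cooperative twin is
#' derived from the same pH responses by raising the facilitation
#' prevalence to 50% (every unordered pair positive in exactly one
#' direction, the maximum without mutual facilitation).  Both twins are
#' assembled from the same assemblage seed, enriched at constant pH, and
#' exposed to the same sinusoidal fluctuation; the two dissimilarity
#' samples are compared with [compare_groups()] (Mann-Whitney U).
#'
#' Only communities with at least `min_richness` surviving strains enter a
#' group: the facilitation fraction "among members" is undefined for a
#' single-member community, which would otherwise flood the competitive
#' group with trivially unresponsive singletons.
#'
#' @param n_per_group communities per group.
#' @param min_richness minimum surviving richness for group membership
#'   (default 2).
#' @param config a [sim_config()].
#' @param f_ph,dph fluctuation frequency (1/h) and amplitude.
#' @param p0 assembly / fluctuation center pH.
#' @param seed master seed.
#' @return The [compare_groups()] list (labels `competitive`,
#'   `cooperative`), plus elements `dissimilarities` (both samples) and
#'   `richness` (mean per group).
#' @export
facilitation_group_comparison <- function(n_per_group = 200,
                                          min_richness = 2,
                                          config = sim_config(),
                                          f_ph = 0.2, dph = 0.5, p0 = 6.3,
                                          seed = 1) {
  d_comp <- numeric(0)
  d_coop <- numeric(0)
  r_comp <- integer(0)
  r_coop <- integer(0)
  i <- 0L
  while (length(d_comp) < n_per_group || length(d_coop) < n_per_group) {
    i <- i + 1L
    if (i > 20 * n_per_group)
      stopf("could not collect %d stable communities per group", n_per_group)
    pan <- generate_base_panel(panel_spec(n_positive = 0,
                                          seed = child_seed(seed, 31L, i)))
    pan_coop <- pan
    pan_coop$C <- set_facilitation_prevalence(pan$C, 0.5,
                                              seed = child_seed(seed, 32L, i))
    asm_seed <- child_seed(seed, 33L, i)
    drv <- ph_sinusoid(p0, dph, f_ph)
    if (length(d_comp) < n_per_group) {
      sc <- enrich_from_panel(pan, config, p0, asm_seed)
      if (isTRUE(attr(sc, "stable")) && length(sc$strains) >= min_richness) {
        d_comp <- c(d_comp, as.numeric(fluctuation_response(sc, drv, config)))
        r_comp <- c(r_comp, length(sc$strains))
      }
    }
    if (length(d_coop) < n_per_group) {
      sc <- enrich_from_panel(pan_coop, config, p0, asm_seed)
      if (isTRUE(attr(sc, "stable")) && length(sc$strains) >= min_richness) {
        d_coop <- c(d_coop, as.numeric(fluctuation_response(sc, drv, config)))
        r_coop <- c(r_coop, length(sc$strains))
      }
    }
  }
  out <- compare_groups(d_comp, d_coop, labels = c("competitive",
                                                   "cooperative"))
  out$dissimilarities <- list(competitive = d_comp, cooperative = d_coop)
  out$richness <- c(competitive = mean(r_comp), cooperative = mean(r_coop))
  out
}

#' Niche-overlap sweep
#'
#' For each community draw, replaces all off-diagonal coefficients of a
#' generated panel with a fixed negative number of increasing magnitude
#' ([set_niche_overlap()]), re-assembles, and measures richness and the
#' fluctuation response.  Dissimilarity is expected to rise with overlap
#' until diversity collapses (mean richness toward 1), where it falls
#' again.
#'
#' @param overlaps overlap magnitudes to test.
#' @param n_communities community draws per overlap level.
#' @param config a [sim_config()].
#' @param f_ph,dph fluctuation frequency and amplitude.
#' @param p0 assembly pH.
#' @param seed master seed.
#' @return data.frame with columns `overlap`, `mean_dissimilarity`,
#'   `median_dissimilarity`, `mean_richness`, `n`.
#' @export
niche_overlap_sweep <- function(overlaps = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.2),
                                n_communities = 50, config = sim_config(),
                                f_ph = 0.2, dph = 0.5, p0 = 6.3, seed = 1) {
  rows <- lapply(seq_along(overlaps), function(vi) {
    v <- overlaps[vi]
    diss <- numeric(0)
    rich <- integer(0)
    for (i in seq_len(n_communities)) {
      pan <- generate_base_panel(panel_spec(seed = child_seed(seed, 41L, i)))
      pan$C <- set_niche_overlap(pan$C, v)
      sc <- enrich_from_panel(pan, config, p0, child_seed(seed, 42L, i))
      if (isTRUE(attr(sc, "washout"))) next
      rich <- c(rich, length(sc$strains))
      if (!isTRUE(attr(sc, "stable"))) next
      diss <- c(diss, as.numeric(
        fluctuation_response(sc, ph_sinusoid(p0, dph, f_ph), config)))
    }
    data.frame(overlap = v,
               mean_dissimilarity = mean(diss),
               median_dissimilarity = median(diss),
               mean_richness = mean(rich), n = length(diss))
  })
  do.call(rbind, rows)
}

#' Facilitation-prevalence sweep
#'
#' As [niche_overlap_sweep()], but raising the fraction of positive
#' off-diagonal interactions from 0 to 0.5 on an all-competitive base
#' panel.  Higher prevalence is expected to increase richness and
#' decrease the fluctuation response.
#'
#' @param fractions facilitation prevalences in `[0, 0.5]`.
#' @inheritParams niche_overlap_sweep
#' @return data.frame with columns `fraction`, `mean_dissimilarity`,
#'   `median_dissimilarity`, `mean_richness`, `n`.
#' @export
facilitation_prevalence_sweep <- function(fractions = c(0, 0.25, 0.5),
                                          n_communities = 50,
                                          config = sim_config(), f_ph = 0.2,
                                          dph = 0.5, p0 = 6.3, seed = 1) {
  rows <- lapply(fractions, function(fr) {
    diss <- numeric(0)
    rich <- integer(0)
    for (i in seq_len(n_communities)) {
      pan <- generate_base_panel(panel_spec(n_positive = 0,
                                            seed = child_seed(seed, 51L, i)))
      if (fr > 0)
        pan$C <- set_facilitation_prevalence(pan$C, fr,
                                             seed = child_seed(seed, 52L, i))
      sc <- enrich_from_panel(pan, config, p0, child_seed(seed, 53L, i))
      if (isTRUE(attr(sc, "washout"))) next
      rich <- c(rich, length(sc$strains))
      if (!isTRUE(attr(sc, "stable"))) next
      diss <- c(diss, as.numeric(
        fluctuation_response(sc, ph_sinusoid(p0, dph, f_ph), config)))
    }
    data.frame(fraction = fr, mean_dissimilarity = mean(diss),
               median_dissimilarity = median(diss),
               mean_richness = mean(rich), n = length(diss))
  })
  do.call(rbind, rows)
}
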