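#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`: 0 for identical
#' compositions, 1 for disjoint support.  Named vectors are aligned on the
#' union of their names (absent strains count as zero); unnamed vectors
#' must have equal length.
#'
#' @param x,y non-negative composition vectors (densities or relative
#'   abundances).
#' @return Dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(2, 1), c(1, 1))  # 0.2
bray_curtis <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    u <- union(names(x), names(y))
    xx <- setNames(numeric(length(u)), u)
    yy <- xx
    xx[names(x)] <- x
    yy[names(y)] <- y
    x <- xx; y <- yy
  }
  if (length(x) != length(y))
    stopf("compositions must share a strain universe (name them)")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0))
    stopf("compositions must be finite and >= 0")
  tot <- sum(x) + sum(y)
  if (tot <= 0) stopf("both compositions are all-zero")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Composition deviation of one community under a fluctuating pH
#'
#' Simulates the stable community under `driver` and, in parallel, under a
#' constant driver at the same center pH for the same duration, then
#' returns the Bray-Curtis dissimilarity between the two compositions.
#' By default each composition is the cycle-averaged relative abundance
#' over the final fluctuation period (metric `"cycle_mean"`); metric
#' `"final"` compares the final-instant compositions instead.  The horizon
#' is always `n_gen` generations, matching the assembly horizon: this is
#' what suppresses very slow fluctuations, whose pH barely moves within
#' the observation window.  When the period exceeds the horizon, the
#' averaging window is the whole trajectory.
#'
#' @param sc a `"stable_community"` (should have passed
#'   [dilution_robustness_filter()]).
#' @param driver a non-constant [ph_driver].
#' @param config a [sim_config()].
#' @param metric `"cycle_mean"` (default) or `"final"`.
#' @param n_cycle_samples samples per period for cycle averaging.
#' @return Dissimilarity in `[0, 1]`.  If the fluctuating run loses all
#'   members the value is 1 with attribute `washout = TRUE`.
#' @export
fluctuation_response <- function(sc, driver, config = sim_config(),
                                 metric = c("cycle_mean", "final"),
                                 n_cycle_samples = 33) {
  metric <- match.arg(metric)
  stopifnot(inherits(sc, "glv_community"), inherits(driver, "ph_driver"))
  gen <- generation_time(config)
  t_end <- config$n_gen * gen
  period <- if (driver$kind == "constant" || !is.finite(driver$f_ph)) gen
            else 1 / driver$f_ph
  period <- min(period, t_end)
  t_win <- seq(t_end - period, t_end, length.out = n_cycle_samples)
  ref_driver <- ph_constant(driver$p0, range = driver$range)
  tr_f <- simulate_community(sc, driver, config, t_end = t_end, t_out = t_win)
  tr_r <- simulate_community(sc, ref_driver, config, t_end = t_end,
                             t_out = t_win)
  comp <- function(tr) {
    if (metric == "final") {
      fin <- tr$final
      if (sum(fin) <= 0) return(NULL)
      return(rel_abundance(fin))
    }
    dens <- tr$densities
    tots <- colSums(dens)
    keep <- tots > 0
    if (!any(keep)) return(NULL)
    rel <- sweep(dens[, keep, drop = FALSE], 2, tots[keep], "/")
    rowMeans(rel)
  }
  cf <- comp(tr_f)
  cr <- comp(tr_r)
  if (is.null(cf)) {
    out <- 1
    attr(out, "washout") <- TRUE
    return(out)
  }
  if (is.null(cr)) stopf("reference (constant pH) run washed out")
  bray_curtis(cf, cr)
}

summarize_dissimilarities <- function(values, levels, level_name,
                                      cutoff = 0.2) {
  stats <- data.frame(
    level = levels,
    median = apply(values, 2, median, na.rm = TRUE),
    mean = colMeans(values, na.rm = TRUE),
    frac_below = colMeans(values < cutoff, na.rm = TRUE),
    n = colSums(!is.na(values)))
  names(stats)[1] <- level_name
  structure(list(values = values, stats = stats, cutoff = cutoff,
                 level_name = level_name),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("<experiment_summary> over", nrow(x$values), "communities\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Amplitude sweep of the fluctuation response
#'
#' Runs [fluctuation_response()] for every community in `ensemble` at
#' every amplitude in `dph_values`, at fixed frequency (default 0.2/h, the
#' sweep frequency of the headline experiments).
#'
#' @param ensemble list of `"stable_community"` objects.
#' @param dph_values fluctuation amplitudes to test (pH units).
#' @param f_ph fixed fluctuation frequency (1/h).
#' @param config a [sim_config()].
#' @param waveform `"sinusoid"` or `"telegraph"`.
#' @param cutoff dissimilarity cutoff for the `frac_below` summary
#'   (default 0.2).
#' @param seed base seed for telegraph schedules.
#' @return An `"experiment_summary"`; `$values` is a communities x
#'   amplitudes matrix.
#' @export
amplitude_sweep <- function(ensemble, dph_values = c(0, 0.25, 0.5, 1),
                            f_ph = 0.2, config = sim_config(),
                            waveform = c("sinusoid", "telegraph"),
                            cutoff = 0.2, seed = 1) {
  waveform <- match.arg(waveform)
  vals <- matrix(NA_real_, length(ensemble), length(dph_values))
  for (ci in seq_along(ensemble)) {
    sc <- ensemble[[ci]]
    p0 <- (attr(sc, "driver") %||% ph_constant())$p0
    for (ai in seq_along(dph_values)) {
      drv <- if (waveform == "sinusoid")
        ph_sinusoid(p0, dph_values[ai], f_ph)
      else ph_telegraph(p0, dph_values[ai], f_ph,
                        seed = child_seed(seed, 11L, ci))
      vals[ci, ai] <- fluctuation_response(sc, drv, config)
    }
  }
  summarize_dissimilarities(vals, dph_values, "dph", cutoff)
}

#' Frequency sweep of the fluctuation response
#'
#' As [amplitude_sweep()], but over fluctuation frequencies at fixed
#' amplitude (default 0.5 pH units).  The composition deviation is
#' expected to vanish in both the very-slow (quasi-static) and very-fast
#' (averaged-pH) limits and to peak at intermediate frequencies.
#'
#' @param ensemble list of `"stable_community"` objects.
#' @param f_values fluctuation frequencies (1/h), typically log-spaced.
#' @param dph fixed amplitude (pH units).
#' @inheritParams amplitude_sweep
#' @return An `"experiment_summary"`; `$values` is a communities x
#'   frequencies matrix.
#' @export
frequency_sweep <- function(ensemble, f_values = 10^seq(-4, 0, by = 0.5),
                            dph = 0.5, config = sim_config(),
                            waveform = c("sinusoid", "telegraph"),
                            cutoff = 0.2, seed = 1) {
  waveform <- match.arg(waveform)
  vals <- matrix(NA_real_, length(ensemble), length(f_values))
  for (ci in seq_along(ensemble)) {
    sc <- ensemble[[ci]]
    p0 <- (attr(sc, "driver") %||% ph_constant())$p0
    for (fi in seq_along(f_values)) {
      drv <- if (waveform == "sinusoid") ph_sinusoid(p0, dph, f_values[fi])
      else ph_telegraph(p0, dph, f_values[fi],
                        seed = child_seed(seed, 12L, ci))
      vals[ci, fi] <- fluctuation_response(sc, drv, config)
    }
  }
  summarize_dissimilarities(vals, f_values, "f_ph", cutoff)
}

#' Set the prevalence of facilitation in an interaction matrix
#'
#' Selects `floor(fraction * n_offdiagonal)` off-diagonal entries - never
#' two in the same unordered pair, and never in a pair that already has a
#' positive direction, so mutual facilitation is never created - and sets
#' them to positive values drawn from `magnitude_range`.  All other
#' entries are untouched.  Since no pair may be positive in both
#' directions, `fraction = 0.5` (every pair one-way positive) is the
#' maximum reachable prevalence.
#'
#' @param C an [interaction_matrix()].
#' @param fraction target fraction of positive off-diagonals, in
#'   `[0, 0.5]`.
#' @param magnitude_range range of positive magnitudes.
#' @param seed integer seed.
#' @return A new [interaction_matrix()].
#' @export
set_facilitation_prevalence <- function(C, fraction,
                                        magnitude_range = c(0.02, 0.3),
                                        seed = NULL) {
  stopifnot(inherits(C, "interaction_matrix"))
  if (!is_number(fraction) || fraction < 0 || fraction > 0.5)
    stopf("fraction must be in [0, 0.5]: mutual facilitation is never created")
  n <- nrow(C)
  n_off <- n * (n - 1)
  k <- floor(fraction * n_off)
  if (k == 0) return(C)
  with_seed(seed, {
    base <- unclass(C)
    pairs <- which(upper.tri(base), arr.ind = TRUE)
    eligible <- pairs[base[pairs] <= 0 & base[pairs[, c(2, 1), drop = FALSE]] <= 0,
                      , drop = FALSE]
    if (nrow(eligible) < k)
      stopf("cannot place %d facilitation entries: only %d pairs without %s",
            k, nrow(eligible), "an existing positive direction")
    sel <- eligible[sample.int(nrow(eligible), k), , drop = FALSE]
    flip <- runif(k) < 0.5
    rows <- ifelse(flip, sel[, 1], sel[, 2])
    cols <- ifelse(flip, sel[, 2], sel[, 1])
    base[cbind(rows, cols)] <- runif(k, magnitude_range[1],
                                     magnitude_range[2])
    diag(base) <- -1
    interaction_matrix(base, slopes = attr(C, "slopes"),
                       p0 = attr(C, "p0"))
  })
}

#' Set a uniform niche overlap
#'
#' Replaces every off-diagonal coefficient with the fixed negative number
#' `-|value|`; the diagonal stays -1.  Increasing `|value|` mimics
#' increasing inter-species niche overlap (`|value| -> 1` is complete
#' overlap; beyond that, inhibition stronger than resource competition).
#'
#' @param C an [interaction_matrix()].
#' @param value overlap magnitude; sign is ignored.
#' @return A new [interaction_matrix()].
#' @export
set_niche_overlap <- function(C, value) {
  stopifnot(inherits(C, "interaction_matrix"), is_number(value))
  base <- unclass(C)
  base[] <- -abs(value)
  diag(base) <- -1
  interaction_matrix(base, slopes = attr(C, "slopes"), p0 = attr(C, "p0"))
}

#' Realized facilitation fraction of a community
#'
#' The fraction of off-diagonal interaction coefficients among members
#' that are positive.  0 marks a fully competitive community; 0.5 (every
#' unordered pair positive in exactly one direction) is the maximum a
#' community without mutual facilitation can reach ("cooperative").
#'
#' @param x a [glv_community()] / `"stable_community"`, or an
#'   [interaction_matrix()].
#' @return Fraction in `[0, 0.5]`; `NaN` for a single-member community.
#' @export
classify_facilitation <- function(x) {
  C <- if (inherits(x, "glv_community")) x$C else x
  C <- unclass(C)
  off <- C[row(C) != col(C)]
  if (length(off) == 0) return(NaN)
  mean(off > 0)
}

#' Compare two groups of dissimilarities
#'
#' Medians, means, and a two-sided Mann-Whitney U (Wilcoxon rank-sum)
#' test, the standard comparison between e.g. competitive and cooperative
#' community groups.
#'
#' @param a,b numeric samples (non-empty).
#' @param labels optional group labels (length 2).
#' @return list with `medians`, `means`, `p_value`, `n`, `labels`.
#' @export
compare_groups <- function(a, b, labels = c("A", "B")) {
  if (length(a) == 0 || length(b) == 0)
    stopf("both groups must be non-empty")
  ht <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = FALSE))
  list(medians = setNames(c(median(a), median(b)), labels),
       means = setNames(c(mean(a), mean(b)), labels),
       p_value = ht$p.value, n = setNames(c(length(a), length(b)), labels),
       labels = labels)
}

#' Community assembly under a fluctuating environment
#'
#' Re-runs the enrichment assembly of matched assemblages (same seeds,
#' hence identical initial strain draws) under a constant pH and under
#' sinusoidal fluctuations on a grid of amplitudes and frequencies, and
#' reports how species richness changes and which species are most often
#' gained or lost relative to the constant-pH assembly.
#'
#' @param panel a `"base_panel"`.
#' @param dph_values amplitudes of the fluctuation grid (pH units).
#' @param f_values frequencies of the fluctuation grid (1/h).
#' @param config a [sim_config()].
#' @param n_assemblages number of matched assemblages.
#' @param p0 assembly pH (center of the fluctuations).
#' @param seed master seed.
#' @return list with `richness_delta` (assemblages x cells matrix),
#'   `cells` (data.frame of dph/f per cell), `gained` and `lost` (named
#'   species tallies across all cells), and `richness_constant`.
#' @export
richness_under_fluctuating_assembly <- function(panel,
                                                dph_values = c(0.5, 1),
                                                f_values = c(0.02, 0.2),
                                                config = sim_config(),
                                                n_assemblages = 50,
                                                p0 = 6.3, seed = 1) {
  cells <- expand.grid(dph = dph_values, f_ph = f_values)
  deltas <- matrix(NA_integer_, n_assemblages, nrow(cells))
  rich0 <- integer(n_assemblages)
  gained <- character(0)
  lost <- character(0)
  for (ai in seq_len(n_assemblages)) {
    asm <- sample_assemblage(panel, config = config,
                             seed = child_seed(seed, 21L, ai))
    sc0 <- enrich(asm, ph_constant(p0), config)
    sp0 <- if (isTRUE(attr(sc0, "washout"))) character(0)
           else unique(community_species(sc0))
    rich0[ai] <- length(sp0)
    for (ci in seq_len(nrow(cells))) {
      drv <- ph_sinusoid(p0, cells$dph[ci], cells$f_ph[ci])
      scf <- enrich(asm, drv, config)
      spf <- if (isTRUE(attr(scf, "washout"))) character(0)
             else unique(community_species(scf))
      deltas[ai, ci] <- length(spf) - length(sp0)
      gained <- c(gained, setdiff(spf, sp0))
      lost <- c(lost, setdiff(sp0, spf))
    }
  }
  list(richness_delta = deltas, cells = cells,
       gained = sort(table(gained), decreasing = TRUE),
       lost = sort(table(lost), decreasing = TRUE),
       richness_constant = rich0)
}
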