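#' Stationarity check for a trajectory
#'
#' A community counts as stably coexisting when its composition has
#' stopped moving: the Bray-Curtis dissimilarity between the relative
#' compositions `window` generations before the end and at the end must be
#' below `tol` (default 1e-3 over a 10-generation window).
#'
#' @param traj a `"glv_trajectory"` recorded at generation boundaries.
#' @param window number of generations between the two compositions.
#' @param tol Bray-Curtis tolerance.
#' @return `TRUE`/`FALSE`; `FALSE` as well when everything washed out.
#' @export
is_stable <- function(traj, window = 10, tol = 1e-3) {
  stopifnot(inherits(traj, "glv_trajectory"))
  gen <- generation_time(traj$config)
  t_ref <- traj$t_end - window * gen
  if (t_ref < 0) stopf("trajectory spans fewer than %d generations", window)
  i_ref <- which.min(abs(traj$times - t_ref))
  a <- traj$densities[, i_ref]
  b <- traj$final
  if (sum(a) <= 0 || sum(b) <= 0) return(FALSE)
  bray_curtis(rel_abundance(a), rel_abundance(b)) < tol
}

#' Enrichment-style assembly of a stable community
#'
#' Simulates an initial assemblage for `n_gen` generations at the given pH
#' driver (constant pH by default), prunes extinct strains, and verifies
#' stationarity with [is_stable()].  Mirrors an enrichment experiment: the
#' surviving, stably coexisting set is the assembled community.
#'
#' @param assemblage a [glv_community()] (e.g. from
#'   [sample_assemblage()]).
#' @param driver a [ph_driver]; default constant pH 6.3.
#' @param config a [sim_config()].
#' @param window,tol stationarity criterion, see [is_stable()].
#' @return An object of class `"stable_community"`: a [glv_community()] of
#'   the survivors at their steady densities, with attributes `stable`
#'   (logical), `driver`, `config`, `gained_lost` (species tally), and
#'   `facilitation_fraction` (realized fraction of positive off-diagonals
#'   among members, see [classify_facilitation()]).
#' @export
enrich <- function(assemblage, driver = ph_constant(), config = sim_config(),
                   window = 10, tol = 1e-3) {
  traj <- simulate_community(assemblage, driver, config)
  alive <- traj$final > 0
  stable <- sum(alive) > 0 && is_stable(traj, window = window, tol = tol)
  if (!any(alive)) {
    sc <- assemblage
    sc$densities[] <- 0
    out <- structure(sc, class = c("stable_community", class(sc)))
    attr(out, "stable") <- FALSE
    attr(out, "washout") <- TRUE
    attr(out, "driver") <- driver
    attr(out, "config") <- config
    return(out)
  }
  sc <- subset_community(assemblage, alive)
  sc$densities <- traj$final[alive]
  before <- sort(unique(community_species(assemblage)))
  after <- sort(unique(community_species(sc)))
  out <- structure(sc, class = c("stable_community", class(sc)))
  attr(out, "stable") <- stable
  attr(out, "washout") <- FALSE
  attr(out, "driver") <- driver
  attr(out, "config") <- config
  attr(out, "gained_lost") <- list(lost = setdiff(before, after),
                                   species = after)
  attr(out, "facilitation_fraction") <- classify_facilitation(sc)
  out
}

#' @export
print.stable_community <- function(x, ...) {
  cat("<stable_community>", length(x$strains), "survivors",
      if (isTRUE(attr(x, "stable"))) "(stationary)" else "(NOT stationary)",
      "\n")
  invisible(x)
}

#' Dilution-robustness filter
#'
#' Downstream fluctuation experiments only use communities whose
#' composition is insensitive to the exact dilution rate: the community is
#' re-simulated at `(1 - factor) * delta` and `(1 + factor) * delta`
#' (default +/-50%) from its steady state, and kept only if the largest
#' Bray-Curtis deviation of the resulting relative composition from the
#' nominal one stays below `threshold` (default 0.2).  Washout at the
#' raised dilution rate fails the filter.
#'
#' @param sc a `"stable_community"` from [enrich()].
#' @param config the nominal [sim_config()].
#' @param factor relative change of the dilution rate.
#' @param threshold Bray-Curtis acceptance threshold.
#' @return `TRUE` if the community passes, else `FALSE`; the maximal
#'   deviation is attached as attribute `deviation`.
#' @export
dilution_robustness_filter <- function(sc, config = attr(sc, "config"),
                                       factor = 0.5, threshold = 0.2) {
  stopifnot(inherits(sc, "stable_community"))
  if (is.null(config)) config <- sim_config()
  driver <- attr(sc, "driver") %||% ph_constant()
  ref <- rel_abundance(sc$densities)
  dev <- 0
  for (mult in c(1 - factor, 1 + factor)) {
    cfg <- config
    cfg$delta <- config$delta * mult
    traj <- simulate_community(sc, driver, cfg)
    fin <- final_densities(traj)
    if (sum(fin) <= 0) {
      out <- FALSE
      attr(out, "deviation") <- 1
      return(out)
    }
    dev <- max(dev, bray_curtis(ref, rel_abundance(fin)))
  }
  out <- dev < threshold
  attr(out, "deviation") <- dev
  out
}
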