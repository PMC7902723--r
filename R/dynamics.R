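#' gLV right-hand side
#'
#' Pure-R reference implementation of the pH-dependent generalized
#' Lotka-Volterra derivative with continuous dilution,
#' `dS_i/dt = r_i(p) [1 - (S_i - gamma_i)/K_i(p)] S_i - delta S_i`, with
#' `gamma_i = sum_{j != i} c_ij S_j`.  Negative `c_ij` (niche overlap /
#' inhibition) depresses growth; positive `c_ij` (facilitation) boosts it.
#' A strain at exactly zero density has zero derivative, so extinction is
#' permanent.  The compiled integrator used by [simulate_community()]
#' implements the same expression; this function is the slow, transparent
#' oracle used in tests.
#'
#' @param state non-negative density vector (OD).
#' @param p pH at which to evaluate the responses.
#' @param community a [glv_community()].
#' @param config a [sim_config()] (only `delta` is used).
#' @return Vector of derivatives (OD/h).
#' @export
glv_rhs <- function(state, p, community, config = sim_config()) {
  if (any(!is.finite(state))) stopf("state must be finite")
  if (any(state < 0)) stopf("state must be >= 0")
  n <- length(community$strains)
  stopifnot(length(state) == n)
  ceff <- interaction_at_ph(community$C, p)
  d <- numeric(n)
  for (i in seq_len(n)) {
    if (state[i] <= 0) next
    rk <- interp_response(community$strains[[i]]$response, p)
    gamma <- sum(ceff[i, -i] * state[-i])
    d[i] <- rk$rate * (1 - (state[i] - gamma) / rk$capacity) * state[i] -
      config$delta * state[i]
  }
  d
}

driver_code <- function(kind) match(kind, c("constant", "sinusoid",
                                            "telegraph")) - 1L

#' Simulate community dynamics under a pH driver
#'
#' Adaptive Dormand-Prince 5(4) integration of the gLV system.  Densities
#' are non-negative throughout; the extinction rule (any strain below
#' `n_ext` is set to zero, permanently) is applied at generation
#' boundaries, i.e. every `ln(2)/delta` hours, keeping the ODE smooth
#' between checkpoints.  Integration aborts with an informative error if
#' total density exceeds `10^3 * max(K)` (runaway growth, the signature of
#' strong mutual facilitation `c_ij * c_ji > 1`).
#'
#' @param community a [glv_community()]; its `densities` are the initial
#'   state.
#' @param driver a [ph_driver].
#' @param config a [sim_config()].
#' @param t_end simulation horizon in hours; default `n_gen` generations.
#' @param t_out times at which to record the state; default the generation
#'   boundaries (plus 0).
#' @return An object of class `"glv_trajectory"`: list with `times`,
#'   `densities` (strains x timepoints), `ph` (pH at each timepoint),
#'   `final` (named final densities), `nsteps`, and the inputs.
#' @export
simulate_community <- function(community, driver, config = sim_config(),
                               t_end = NULL, t_out = NULL) {
  stopifnot(inherits(community, "glv_community"),
            inherits(driver, "ph_driver"),
            inherits(config, "sim_config"))
  gen <- generation_time(config)
  if (is.null(t_end)) t_end <- config$n_gen * gen
  if (!is_number(t_end) || t_end <= 0) stopf("t_end must be > 0")
  checkpoints <- seq(gen, t_end, by = gen)
  if (is.null(t_out)) t_out <- c(0, checkpoints, t_end)
  t_out <- sort(unique(t_out))
  if (any(t_out < 0) || any(t_out > t_end))
    stopf("t_out must lie within [0, t_end]")
  tabs <- community_tables(community)
  sl <- attr(community$C, "slopes")
  if (driver$kind == "telegraph") {
    sch <- telegraph_schedule(driver, t_end)
    tele_t <- sch$times; tele_l <- sch$levels
  } else {
    tele_t <- 0; tele_l <- driver$p0
  }
  res <- .glv_integrate(
    S0 = as.numeric(community$densities), grid = tabs$grid,
    rtab = tabs$rtab, Ktab = tabs$Ktab, C = unclass(community$C),
    slopes = sl, pref = attr(community$C, "p0") %||% 7.2,
    delta = config$delta, driver_kind = driver_code(driver$kind),
    p0 = driver$p0, dph = driver$dph,
    fph = if (is.na(driver$f_ph %||% NA_real_)) 0 else driver$f_ph,
    tele_times = tele_t, tele_levels = tele_l, t_end = t_end,
    t_out = t_out, checkpoints = checkpoints, n_ext = config$n_ext,
    rtol = config$rel_tol, atol = config$abs_tol,
    max_total = 1e3 * max(tabs$Ktab))
  ids <- community_ids(community)
  dens <- res$states
  dimnames(dens) <- list(ids, NULL)
  final <- as.numeric(res$final)
  names(final) <- ids
  structure(list(times = t_out, densities = dens, ph = as.numeric(res$ph),
                 final = final, nsteps = res$nsteps,
                 community = community, driver = driver, config = config,
                 t_end = t_end),
            class = "glv_trajectory")
}

#' @export
print.glv_trajectory <- function(x, ...) {
  cat("<glv_trajectory>", nrow(x$densities), "strains,",
      length(x$times), "timepoints over", round(x$t_end, 2), "h;",
      sum(x$final > 0), "alive at end\n")
  invisible(x)
}

#' Final densities of a trajectory
#' @param traj a `"glv_trajectory"`.
#' @return Named numeric vector of final densities (OD).
#' @export
final_densities <- function(traj) traj$final

#' Export a trajectory as a tidy data.frame
#'
#' @param x a `"glv_trajectory"`.
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return data.frame with columns `time`, `strain_id`, `density`, `ph`.
#' @export
as.data.frame.glv_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  ids <- rownames(x$densities)
  data.frame(time = rep(x$times, each = length(ids)),
             strain_id = rep(ids, times = length(x$times)),
             density = as.numeric(x$densities),
             ph = rep(x$ph, each = length(ids)))
}
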