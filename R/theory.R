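#' Fast-fluctuation (WKB) oscillation envelope
#'
#' For growth forced at a rapidly oscillating rate
#' `r(t) = r0 + r_d * sin(2 pi f t)`, the first-order WKB envelope of the
#' population is `E(t) = exp(-(r_d / (2 pi f)) * cos(2 pi f t))` (up to a
#' constant factor).  Its peak log-amplitude `r_d / (2 pi f)` drops
#' inversely with the forcing frequency: fast fluctuations average out
#' and the population effectively sees the mean environment.
#'
#' @param r_d growth-rate oscillation amplitude (1/h), >= 0.
#' @param f forcing frequency (1/h), > 0.
#' @param t time(s) in hours.
#' @return Envelope factor(s), dimensionless.
#' @export
wkb_envelope <- function(r_d, f, t) {
  if (!is_number(r_d) || r_d < 0) stopf("r_d must be >= 0")
  if (!is_number(f) || f <= 0) stopf("f must be > 0")
  exp(-(r_d / (2 * pi * f)) * cos(2 * pi * f * t))
}

#' Peak log-amplitude of the WKB envelope
#'
#' @inheritParams wkb_envelope
#' @return `r_d / (2 pi f)`.
#' @export
wkb_peak_log_amplitude <- function(r_d, f) {
  if (!is_number(r_d) || r_d < 0) stopf("r_d must be >= 0")
  if (!is_number(f) || f <= 0) stopf("f must be > 0")
  r_d / (2 * pi * f)
}

# b_i = (delta - r_i(p)) * K_i(p) / r_i(p) at the given pH
qs_b_vector <- function(community, p, config) {
  n <- length(community$strains)
  b <- numeric(n)
  for (i in seq_len(n)) {
    rk <- interp_response(community$strains[[i]]$response, p)
    if (rk$rate <= 0)
      stopf("quasi-static solve needs r_i(p) > 0 (strain %d at pH %g)", i, p)
    b[i] <- (config$delta - rk$rate) * rk$capacity / rk$rate
  }
  b
}

#' Quasi-static community composition
#'
#' In the slow-fluctuation limit the community equilibrates to each
#' instantaneous pH; the steady state solves the linear system
#' `C S = b` with `b_i = (delta - r_i(p)) K_i(p) / r_i(p)`.  The raw
#' linear solve ignores positivity.  By default a negative component is
#' interpreted as "this strain leaves the community at this pH": the most
#' negative strain is removed and the reduced system re-solved until the
#' solution on the remaining support is non-negative (`reduce = FALSE`
#' returns the raw solve instead).
#'
#' @param community a [glv_community()] (e.g. a `"stable_community"`).
#' @param p pH at which to evaluate.
#' @param config a [sim_config()] (uses `delta`).
#' @param reduce iteratively drop strains until the equilibrium is
#'   feasible (non-negative) and locally stable (default `TRUE`).
#' @return Named vector of steady densities (zeros for dropped strains),
#'   with attributes `condition` (reciprocal condition estimate of the
#'   full matrix) and `reduced` (logical).
#' @export
quasi_static_composition <- function(community, p,
                                     config = sim_config(), reduce = TRUE) {
  stopifnot(inherits(community, "glv_community"))
  C <- interaction_at_ph(community$C, p)
  rc <- rcond(C)
  if (rc < 1e-12)
    stopf("interaction matrix is numerically singular at pH %g %s", p,
          sprintf("(reciprocal condition %.3g)", rc))
  ids <- community_ids(community)
  b <- qs_b_vector(community, p, config)
  rk <- lapply(community$strains,
               function(s) interp_response(s$response, p))
  active <- seq_along(ids)
  repeat {
    S_act <- solve(C[active, active, drop = FALSE], b[active])
    if (!reduce || length(active) == 1) break
    if (any(S_act < 0)) {  # infeasible: species leaves at this pH
      active <- active[-which.min(S_act)]
      next
    }
    # local stability: Jacobian at the interior point is
    # diag(S_i r_i / K_i) %*% C; a saddle (e.g. near-degenerate strain
    # twins) is not reachable by the dynamics, so drop the weakest strain
    scale <- vapply(active, function(i)
      rk[[i]]$rate / rk[[i]]$capacity, numeric(1)) * S_act
    J <- scale * C[active, active, drop = FALSE]
    if (max(Re(eigen(J, only.values = TRUE)$values)) < 0) break
    active <- active[-which.min(S_act)]
  }
  S <- setNames(numeric(length(ids)), ids)
  S[active] <- S_act
  if (length(active) == 1 && S[active] < 0) S[active] <- 0  # full washout
  attr(S, "condition") <- rc
  attr(S, "reduced") <- length(active) < length(ids)
  S
}

#' Slowest relaxation rate of a community at its equilibrium
#'
#' Magnitude of the least-negative real part among the eigenvalues of the
#' gLV Jacobian `diag(S_i r_i / K_i) %*% C` evaluated at the quasi-static
#' equilibrium for pH `p`.  This is the rate at which the community heals
#' perturbations; the quasi-static approximation is valid only when it is
#' much larger than the angular rate `2 pi f` of the pH driver.
#' Near-degenerate same-species strain twins make this rate arbitrarily
#' small, taking a community outside the approximation's domain at any
#' fixed driver frequency.
#'
#' @param community a [glv_community()].
#' @param p pH at which to evaluate (default 6.3).
#' @param config a [sim_config()].
#' @return Relaxation rate (1/h); `Inf` when nothing survives.
#' @export
relaxation_rate <- function(community, p = 6.3, config = sim_config()) {
  S <- quasi_static_composition(community, p, config)
  active <- which(S > 0)
  if (length(active) == 0) return(Inf)
  C <- interaction_at_ph(community$C, p)
  scale <- vapply(active, function(i) {
    rk <- interp_response(community$strains[[i]]$response, p)
    rk$rate / rk$capacity
  }, numeric(1)) * S[active]
  J <- scale * C[active, active, drop = FALSE]
  -max(Re(eigen(J, only.values = TRUE)$values))
}

#' Quasi-static composition change between two pH values
#'
#' Linearity of the quasi-static balance gives
#' `Delta S = C^{-1} (b(p) - b(p_ref))`: the composition shift tracks the
#' pH-induced change in the `b` vector (dominated by the growth-rate
#' change when `r` and `K` shift similarly with pH).  Computed from the
#' raw (non-reduced) solves.
#'
#' @param community a [glv_community()].
#' @param p,p_ref the two pH values.
#' @param config a [sim_config()].
#' @return Named vector `Delta S` (OD).
#' @export
quasi_static_delta <- function(community, p, p_ref, config = sim_config()) {
  C <- interaction_at_ph(community$C, p)
  C_ref <- interaction_at_ph(community$C, p_ref)
  if (!isTRUE(all.equal(C, C_ref)))
    stopf("quasi_static_delta assumes a pH-independent interaction matrix")
  db <- qs_b_vector(community, p, config) -
    qs_b_vector(community, p_ref, config)
  setNames(solve(C, db), community_ids(community))
}

#' Verify the analytic fast/slow-fluctuation limits against the simulator
#'
#' Two checks on a stable community:
#' \describe{
#'   \item{slow (quasi-static)}{at a very low driver frequency the
#'     instantaneous simulated composition must track
#'     [quasi_static_composition()] at the instantaneous pH, within a
#'     Bray-Curtis tolerance.}
#'   \item{fast (WKB)}{for a single-species reduction, the log-density
#'     oscillation amplitude across a high-frequency sweep must fall as
#'     `1/f` (log-log slope -1).}
#' }
#'
#' @param sc a `"stable_community"`.
#' @param config a [sim_config()].
#' @param f_slow slow driver frequency (1/h).
#' @param f_fast_range fast sweep range (1/h), spanning >= 2 decades.
#' @param dph fluctuation amplitude.
#' @param bc_tol tracking tolerance for the slow check.
#' @param slope_tol allowed deviation of the log-log slope from -1.
#' @return list with elements `slow` (list: `bc`, `pass`) and `fast`
#'   (list: `slope`, `pass`), plus `pass` overall.
#' @export
verify_limits <- function(sc, config = sim_config(), f_slow = 1e-4,
                          f_fast_range = c(1, 100), dph = 0.5,
                          bc_tol = 0.01, slope_tol = 0.1) {
  stopifnot(inherits(sc, "glv_community"))
  p0 <- (attr(sc, "driver") %||% ph_constant())$p0
  slow <- list(bc = 0, pass = TRUE)
  if (dph > 0) {
    drv <- ph_sinusoid(p0, dph, f_slow)
    t_probe <- seq(0.05, 0.25, by = 0.05) / f_slow  # within first quarter
    tr <- simulate_community(sc, drv, config, t_end = max(t_probe),
                             t_out = t_probe)
    bcs <- vapply(seq_along(t_probe), function(k) {
      sim <- tr$densities[, k]
      pred <- quasi_static_composition(sc, tr$ph[k], config)
      if (sum(sim) <= 0 || sum(pred) <= 0) return(1)
      bray_curtis(rel_abundance(sim), rel_abundance(pred))
    }, numeric(1))
    slow <- list(bc = max(bcs), pass = max(bcs) < bc_tol)
  }
  fast <- wkb_slope_check(sc, config, p0, dph, f_fast_range)
  fast$pass <- abs(fast$slope + 1) <= slope_tol || dph == 0
  list(slow = slow, fast = fast,
       pass = isTRUE(slow$pass) && isTRUE(fast$pass))
}

# Log-density oscillation amplitude of the dominant strain across a fast
# frequency sweep; returns the log-log regression slope.
wkb_slope_check <- function(sc, config, p0, dph, f_range, n_f = 7) {
  if (dph == 0) return(list(slope = -1, amplitudes = numeric(0),
                            f = numeric(0)))
  fs <- 10^seq(log10(f_range[1]), log10(f_range[2]), length.out = n_f)
  dom <- which.max(sc$densities)
  amps <- vapply(fs, function(f) {
    drv <- ph_sinusoid(p0, dph, f)
    t_settle <- 40 / config$delta  # many relaxation times
    t_win <- seq(t_settle, t_settle + 3 / f, length.out = 241)
    cfg <- config
    cfg$rel_tol <- min(config$rel_tol, 1e-9)
    cfg$abs_tol <- min(config$abs_tol, 1e-12)
    tr <- simulate_community(sc, drv, cfg, t_end = max(t_win), t_out = t_win)
    x <- log(tr$densities[dom, ])
    (max(x) - min(x)) / 2
  }, numeric(1))
  fit <- stats::lm(log(amps) ~ log(fs))
  list(slope = unname(stats::coef(fit)[2]), amplitudes = amps, f = fs)
}
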