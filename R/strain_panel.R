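#' pH grid
#'
#' Ordered pH points on which growth rate and carrying capacity are
#' tabulated.  The default grid covers the biologically relevant nasal
#' range, pH 5.1 to 7.5 at 0.3 intervals (9 points).
#'
#' @param values strictly increasing numeric pH values in `[0, 14]`,
#'   length >= 2.
#' @return A numeric vector of class `"ph_grid"`.
#' @export
#' @examples
#' ph_grid()
ph_grid <- function(values = seq(5.1, 7.5, by = 0.3)) {
  if (!is.numeric(values) || length(values) < 2)
    stopf("a pH grid needs at least 2 numeric points")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 14))
    stopf("pH grid values must be finite and within [0, 14]")
  if (any(diff(values) <= 0))
    stopf("pH grid must be strictly increasing")
  structure(as.numeric(values), class = "ph_grid")
}

#' Per-strain pH response
#'
#' Tabulated growth rate `r` (1/h) and carrying capacity `K` (OD units) on
#' a [ph_grid()]; values between grid nodes are obtained by linear
#' interpolation ([interp_response()]).
#'
#' @param grid a [ph_grid()].
#' @param r non-negative growth rates (1/h), one per grid point.
#' @param K strictly positive carrying capacities (OD), one per grid point.
#' @return An object of class `"ph_response"`.
#' @export
ph_response <- function(grid, r, K) {
  if (!inherits(grid, "ph_grid")) grid <- ph_grid(grid)
  if (length(r) != length(grid) || length(K) != length(grid))
    stopf("r and K must have one value per pH grid point")
  if (any(!is.finite(r)) || any(r < 0))
    stopf("growth rates must be finite and >= 0")
  if (any(!is.finite(K)) || any(K <= 0))
    stopf("carrying capacities must be finite and > 0")
  structure(list(grid = grid, r = as.numeric(r), K = as.numeric(K)),
            class = "ph_response")
}

#' @export
print.ph_response <- function(x, ...) {
  cat("<ph_response> on", length(x$grid), "pH points",
      sprintf("[%.1f, %.1f]", min(x$grid), max(x$grid)), "\n")
  cat("  r: ", paste(signif(x$r, 3), collapse = " "), "\n")
  cat("  K: ", paste(signif(x$K, 3), collapse = " "), "\n")
  invisible(x)
}

#' In silico strain
#'
#' A strain is a labelled instance of a base species: it carries its own
#' (possibly modulated) pH response.
#'
#' @param id unique strain label.
#' @param species base-species label.
#' @param response a [ph_response()].
#' @return An object of class `"strain"`.
#' @export
strain <- function(id, species, response) {
  stopifnot(is.character(id), length(id) == 1,
            is.character(species), length(species) == 1,
            inherits(response, "ph_response"))
  structure(list(id = id, species = species, response = response),
            class = "strain")
}

#' Interaction-coefficient matrix
#'
#' Square matrix of dimensionless gLV interaction coefficients `c_ij`
#' (effect of column species `j` on row species `i`).  The diagonal is
#' pinned at exactly -1 (complete niche overlap).  Optionally carries a
#' slope matrix for linear pH dependence,
#' `c_ij(p) = c_ij(p0) + m_ij * (p - p0)`; diagonal slopes are forced to 0
#' so the self-term stays at -1 at every pH.
#'
#' @param c square numeric matrix with diagonal exactly -1.
#' @param slopes optional slope matrix (per unit pH), same shape as `c`.
#' @param p0 reference pH at which `c` was characterized (default 7.2, the
#'   characterization pH of the nasal panel).
#' @return An object of class `"interaction_matrix"` (a matrix with
#'   attributes `slopes` and `p0`).
#' @export
interaction_matrix <- function(c, slopes = NULL, p0 = 7.2) {
  c <- as.matrix(c)
  if (nrow(c) != ncol(c)) stopf("interaction matrix must be square")
  if (any(!is.finite(c))) stopf("interaction coefficients must be finite")
  if (any(diag(c) != -1))
    stopf("interaction matrix diagonal must be exactly -1")
  if (!is.null(slopes)) {
    slopes <- as.matrix(slopes)
    if (!all(dim(slopes) == dim(c)))
      stopf("slope matrix must have the same shape as c")
    diag(slopes) <- 0  # self-term stays -1 at every pH
  }
  structure(c, slopes = slopes, p0 = p0, class = c("interaction_matrix",
                                                   "matrix", "array"))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("<interaction_matrix>", nrow(x), "x", ncol(x),
      if (!is.null(attr(x, "slopes"))) "(pH-dependent)" else "", "\n")
  print(round(unclass(x)[, , drop = FALSE], 3))
  invisible(x)
}

#' Interpolate a pH response
#'
#' Piecewise-linear interpolation of growth rate and carrying capacity at
#' arbitrary pH.  Exact at grid nodes; outside the measured grid the
#' response is clamped to the nearest end value (nothing was measured
#' beyond the grid, and pH drivers are clamped to the grid range anyway).
#'
#' @param response a [ph_response()].
#' @param p numeric pH value(s); must be finite.
#' @return A list with numeric components `rate` (1/h) and `capacity` (OD),
#'   each the length of `p`.
#' @export
#' @examples
#' resp <- ph_response(ph_grid(c(5.1, 5.4)), r = c(0.2, 0.4), K = c(0.1, 0.2))
#' interp_response(resp, 5.25)$rate  # 0.3
interp_response <- function(response, p) {
  stopifnot(inherits(response, "ph_response"))
  if (!is.numeric(p) || any(!is.finite(p)))
    stopf("pH must be finite and numeric")
  g <- as.numeric(response$grid)
  list(rate = approx(g, response$r, xout = p, rule = 2)$y,
       capacity = approx(g, response$K, xout = p, rule = 2)$y)
}

#' Infer an interaction coefficient from a supernatant assay
#'
#' The effect of species `j` on species `i` is estimated from the carrying
#' capacity `K_ij` that `i` reaches in cell-free spent medium of `j`:
#' `c_ij = (K_ij - K_i) / K_j`.  The self-case `K_ii = 0` yields
#' `c_ii = -1`.  When empirical standard deviations of the measured
#' capacities are supplied, the uncertainty of `c_ij` is propagated to
#' first order (delta method).
#'
#' @param K_ij carrying capacity of `i` in supernatant of `j` (OD), >= 0.
#' @param K_i monoculture carrying capacity of `i` (OD), > 0.
#' @param K_j monoculture carrying capacity of `j` (OD), > 0.
#' @param sd_K_ij,sd_K_i,sd_K_j optional standard deviations of the three
#'   capacities; if any is given the return value carries an `sd` attribute.
#' @return The coefficient `c_ij` (dimensionless), possibly with an `sd`
#'   attribute.
#' @export
#' @examples
#' infer_interaction(0, 0.2, 0.2)    # self-effect: -1
#' infer_interaction(0.3, 0.2, 0.1)  # facilitation: 1
infer_interaction <- function(K_ij, K_i, K_j,
                              sd_K_ij = NULL, sd_K_i = NULL, sd_K_j = NULL) {
  if (!is_number(K_ij) || K_ij < 0) stopf("K_ij must be a finite number >= 0")
  if (!is_number(K_i) || K_i <= 0) stopf("K_i must be a finite number > 0")
  if (!is_number(K_j) || K_j <= 0)
    stopf("K_j must be > 0: the supernatant donor must grow")
  cij <- (K_ij - K_i) / K_j
  if (!is.null(sd_K_ij) || !is.null(sd_K_i) || !is.null(sd_K_j)) {
    s_ij <- if (is.null(sd_K_ij)) 0 else sd_K_ij
    s_i <- if (is.null(sd_K_i)) 0 else sd_K_i
    s_j <- if (is.null(sd_K_j)) 0 else sd_K_j
    v <- (s_ij^2 + s_i^2) / K_j^2 + ((K_ij - K_i)^2 / K_j^4) * s_j^2
    attr(cij, "sd") <- sqrt(v)
  }
  cij
}

#' Predict the supernatant carrying capacity from a coefficient
#'
#' Forward model of the supernatant assay: `K_ij = K_i + c_ij * K_j`.
#' Round-trips exactly with [infer_interaction()].
#'
#' @param K_i,K_j monoculture carrying capacities (OD), > 0.
#' @param c_ij interaction coefficient.
#' @return Predicted supernatant capacity `K_ij` (OD).
#' @export
predict_supernatant_capacity <- function(K_i, c_ij, K_j) {
  if (!is_number(K_i) || K_i <= 0 || !is_number(K_j) || K_j <= 0)
    stopf("K_i and K_j must be finite numbers > 0")
  if (!is_number(c_ij)) stopf("c_ij must be a finite number")
  K_i + c_ij * K_j
}

#' Screen for runaway-growth instability
#'
#' A pair of mutually facilitating species destabilizes the gLV model when
#' the carrying-capacity terms stop acting as negative feedback; this
#' requires `c_ij > 0`, `c_ji > 0` and `c_ij * c_ji > 1` (strong mutual
#' facilitation).  Returns all such pairs.
#'
#' @param C an [interaction_matrix()] (or plain square matrix with -1
#'   diagonal).
#' @return A data.frame with columns `i`, `j` (`i < j`), `c_ij`, `c_ji`,
#'   `product`; zero rows when no pair is unstable.
#' @export
screen_instability <- function(C) {
  C <- interaction_matrix(C, slopes = attr(C, "slopes"),
                          p0 = attr(C, "p0") %||% 7.2)
  n <- nrow(C)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        cij <- C[i, j]; cji <- C[j, i]
        if (cij > 0 && cji > 0 && cij * cji > 1)
          out[[length(out) + 1]] <- data.frame(i = i, j = j, c_ij = cij,
                                               c_ji = cji,
                                               product = cij * cji)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer(), c_ij = numeric(),
                      c_ji = numeric(), product = numeric()))
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effective interaction matrix at a given pH
#'
#' Applies the linear pH dependence `c_ij(p) = c_ij(p0) + m_ij (p - p0)`
#' element-wise.  The diagonal remains exactly -1 (slopes on the diagonal
#' are forced to zero at construction).  A matrix without slopes is
#' returned unchanged.
#'
#' @param C an [interaction_matrix()].
#' @param p pH at which to evaluate.
#' @return A plain numeric matrix of effective coefficients.
#' @export
interaction_at_ph <- function(C, p) {
  stopifnot(inherits(C, "interaction_matrix"))
  if (!is_number(p)) stopf("pH must be a finite number")
  m <- attr(C, "slopes")
  base <- unclass(C)
  attributes(base) <- list(dim = dim(C), dimnames = dimnames(C))
  if (is.null(m)) return(base)
  eff <- base + m * (p - attr(C, "p0"))
  diag(eff) <- -1
  eff
}
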