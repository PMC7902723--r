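#' Specification for a synthetic base-species panel
#'
#' Describes the statistical structure of a generated panel: the measured
#' nasal panel it stands in for had 6 species, 3 positive values among the
#' 30 pairwise interaction coefficients (facilitation terms all small), a
#' handful of strongly inhibitory entries below -1.2, and no mutual or
#' cyclic facilitation.
#'
#' @param n_species number of base species (default 6).
#' @param n_positive number of positive off-diagonal coefficients (default
#'   3 of the 30).
#' @param strong_inhibition_fraction proportion of the negative
#'   off-diagonals drawn below -1.2 (default 0.2).
#' @param r_range attainable growth-rate range (1/h), default 0-1.
#' @param K_range attainable carrying-capacity range (OD), default
#'   0.05-1.
#' @param positive_cap upper bound on facilitation magnitudes (default
#'   0.3: facilitation terms are small).
#' @param grid the [ph_grid()] on which responses are tabulated.
#' @param seed integer seed; the panel is a deterministic function of it.
#' @return An object of class `"panel_spec"`.
#' @export
panel_spec <- function(n_species = 6, n_positive = 3,
                       strong_inhibition_fraction = 0.2,
                       r_range = c(0, 1), K_range = c(0.05, 1),
                       positive_cap = 0.3, grid = ph_grid(), seed = 1) {
  if (!is_count(n_species) || n_species < 1)
    stopf("n_species must be a positive count")
  n_off <- n_species * (n_species - 1)
  if (!is_count(n_positive) || n_positive > n_off)
    stopf("n_positive must be a count <= %d", n_off)
  if (n_positive > n_off / 2)
    stopf("n_positive > half the off-diagonals forces mutual facilitation")
  if (!is_number(strong_inhibition_fraction) ||
      strong_inhibition_fraction < 0 || strong_inhibition_fraction > 1)
    stopf("strong_inhibition_fraction must be in [0, 1]")
  stopifnot(length(r_range) == 2, r_range[1] >= 0, r_range[2] > r_range[1],
            length(K_range) == 2, K_range[1] > 0, K_range[2] > K_range[1],
            is_number(positive_cap), positive_cap > 0)
  if (!inherits(grid, "ph_grid")) grid <- ph_grid(grid)
  structure(list(n_species = n_species, n_positive = n_positive,
                 strong_inhibition_fraction = strong_inhibition_fraction,
                 r_range = r_range, K_range = K_range,
                 positive_cap = positive_cap, grid = grid,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

# TRUE if the directed graph with edge list (from, to) has a cycle
has_directed_cycle <- function(n, from, to) {
  adj <- vector("list", n)
  for (k in seq_along(from)) adj[[from[k]]] <- c(adj[[from[k]]], to[k])
  color <- integer(n)  # 0 white, 1 grey, 2 black
  found <- FALSE
  visit <- function(v) {
    color[v] <<- 1L
    for (w in adj[[v]]) {
      if (color[w] == 1L) { found <<- TRUE; return() }
      if (color[w] == 0L) visit(w)
      if (found) return()
    }
    color[v] <<- 2L
  }
  for (v in seq_len(n)) {
    if (color[v] == 0L) visit(v)
    if (found) break
  }
  found
}

#' Generate a synthetic base-species panel
#'
#' Draws smooth, unimodal pH-response curves (Gaussian bumps in pH,
#' clipped to the stated ranges) for each base species, and an interaction
#' matrix with diagonal -1, exactly `n_positive` small positive
#' off-diagonals, and the remaining entries negative down to -1.5.
#' Positive-edge placement is rejection-resampled until the facilitation
#' graph has no mutual pair and no directed cycle, so
#' [screen_instability()] is empty by construction and runaway growth
#' cannot occur.  The panel is a deterministic function of `spec$seed`.
#'
#' @param spec a [panel_spec()].
#' @param max_tries placement resampling budget.
#' @return An object of class `"base_panel"`: list with `species` (named
#'   list of [ph_response()]), `C` (species-level [interaction_matrix()])
#'   and `spec`.
#' @export
generate_base_panel <- function(spec = panel_spec(), max_tries = 1000) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    n <- spec$n_species
    g <- as.numeric(spec$grid)
    labels <- sprintf("sp%d", seq_len(n))
    species <- lapply(seq_len(n), function(i) {
      # growth-rate bump: optimum inside the grid, width comparable to it
      r_max <- runif(1, 0.4 * spec$r_range[2], spec$r_range[2])
      p_opt <- runif(1, g[1] + 0.3, g[length(g)] - 0.3)
      w <- runif(1, 0.6, 2.0)
      r <- r_max * exp(-(g - p_opt)^2 / (2 * w^2))
      r <- pmin(pmax(r, spec$r_range[1]), spec$r_range[2])
      K_max <- runif(1, 0.3 * spec$K_range[2], spec$K_range[2])
      p_opt_K <- p_opt + runif(1, -0.5, 0.5)
      w_K <- runif(1, 0.8, 2.5)
      K <- spec$K_range[1] +
        (K_max - spec$K_range[1]) * exp(-(g - p_opt_K)^2 / (2 * w_K^2))
      K <- pmin(pmax(K, spec$K_range[1]), spec$K_range[2])
      ph_response(spec$grid, r, K)
    })
    names(species) <- labels

    off <- which(diag(n) == 0)
    C <- matrix(0, n, n)
    if (spec$n_positive > 0) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        pos <- sample(off, spec$n_positive)
        fr <- (pos - 1) %% n + 1
        to <- (pos - 1) %/% n + 1  # column index: effector species
        mutual <- any(duplicated(rbind(cbind(pmin(fr, to), pmax(fr, to)))))
        if (!mutual && !has_directed_cycle(n, fr, to)) { ok <- TRUE; break }
      }
      if (!ok)
        stopf("could not place %d facilitation edges without mutual or %s",
              spec$n_positive, "cyclic facilitation; relax the panel spec")
      C[pos] <- runif(spec$n_positive, 0.02, spec$positive_cap)
    } else {
      pos <- integer(0)
    }
    neg <- setdiff(off, pos)
    n_strong <- round(spec$strong_inhibition_fraction * length(neg))
    strong <- if (n_strong > 0) sample(neg, n_strong) else integer(0)
    weak <- setdiff(neg, strong)
    C[strong] <- runif(length(strong), -1.5, -1.2)
    C[weak] <- runif(length(weak), -1.2, -0.05)
    diag(C) <- -1
    dimnames(C) <- list(labels, labels)
    structure(list(species = species,
                   C = interaction_matrix(C, p0 = 7.2), spec = spec),
              class = "base_panel")
  })
}

#' @export
print.base_panel <- function(x, ...) {
  cat("<base_panel>", length(x$species), "species;",
      sum(unclass(x$C)[row(x$C) != col(x$C)] > 0),
      "facilitation coefficients\n")
  invisible(x)
}

#' Modulate a species into an in silico strain
#'
#' Strain-level variation: one multiplier `u_r ~ Uniform(1 - f_p, 1 + f_p)`
#' scales the whole growth-rate curve and an independent `u_K` scales the
#' whole capacity curve (shape-preserving), so "up to 20%" variation is a
#' hard bound.  If interaction rows/columns are supplied, each entry gets
#' its own independent multiplier.  Draws come from the current RNG
#' stream; wrap in [with_seed()] (or pass `seed`) for reproducibility.
#'
#' @param response the base species' [ph_response()].
#' @param id,species labels for the new strain.
#' @param f_p variation proportion (default 0.2).
#' @param c_row,c_col optional numeric vectors of interaction coefficients
#'   (effects on / of this strain) to modulate entry-wise.
#' @param per_point if `TRUE`, draw an independent multiplier per pH grid
#'   point instead of per curve (non-default alternative).
#' @param seed optional seed.
#' @param eps positive floor applied to modulated `K` (and to `r` via
#'   `max(r, 0)`).
#' @return list with `strain` ([strain()]) and, when given, modulated
#'   `c_row` / `c_col`.
#' @export
modulate_strain <- function(response, id, species, f_p = 0.2,
                            c_row = NULL, c_col = NULL, per_point = FALSE,
                            seed = NULL, eps = 1e-8) {
  stopifnot(inherits(response, "ph_response"), is_number(f_p),
            f_p >= 0, f_p < 1)
  with_seed(seed, {
    npts <- length(response$grid)
    u_r <- if (per_point) runif(npts, 1 - f_p, 1 + f_p)
           else runif(1, 1 - f_p, 1 + f_p)
    u_K <- if (per_point) runif(npts, 1 - f_p, 1 + f_p)
           else runif(1, 1 - f_p, 1 + f_p)
    r <- pmax(response$r * u_r, 0)
    K <- pmax(response$K * u_K, eps)
    out <- list(strain = strain(id, species,
                                ph_response(response$grid, r, K)))
    if (!is.null(c_row))
      out$c_row <- c_row * runif(length(c_row), 1 - f_p, 1 + f_p)
    if (!is.null(c_col))
      out$c_col <- c_col * runif(length(c_col), 1 - f_p, 1 + f_p)
    out
  })
}

#' Sample a random strain assemblage from a panel
#'
#' Draws `n_c` strains with species chosen uniformly with replacement,
#' modulates each independently (up to `f_p` variation), and assembles the
#' strain-level interaction matrix from the species-level one, with an
#' independent multiplier per ordered strain pair.  Strain pairs of the
#' same species start from the complete-niche-overlap coefficient -1
#' before modulation.  Initial densities are `s0` per strain.
#'
#' @param panel a `"base_panel"` (or any list with `species` and `C`).
#' @param n_c number of strains (default from `config`).
#' @param config a [sim_config()] (`f_p`, `s0`).
#' @param seed integer seed; the assemblage is deterministic given it.
#' @return A [glv_community()].
#' @export
sample_assemblage <- function(panel, n_c = NULL, config = sim_config(),
                              seed = NULL) {
  stopifnot(!is.null(panel$species), !is.null(panel$C))
  if (is.null(n_c)) n_c <- config$n_c
  if (!is_count(n_c) || n_c < 1) stopf("n_c must be a positive count")
  with_seed(seed, {
    n_sp <- length(panel$species)
    sp_idx <- sample.int(n_sp, n_c, replace = TRUE)
    sp_names <- names(panel$species)[sp_idx]
    strains <- vector("list", n_c)
    for (k in seq_len(n_c)) {
      id <- sprintf("%s.s%02d", sp_names[k], k)
      strains[[k]] <- modulate_strain(panel$species[[sp_idx[k]]], id,
                                      sp_names[k], f_p = config$f_p)$strain
    }
    Csp <- unclass(panel$C)
    C <- matrix(-1, n_c, n_c)
    for (a in seq_len(n_c)) {
      for (b in seq_len(n_c)) {
        if (a == b) next
        base <- if (sp_idx[a] == sp_idx[b]) -1 else Csp[sp_idx[a], sp_idx[b]]
        C[a, b] <- base * runif(1, 1 - config$f_p, 1 + config$f_p)
      }
    }
    diag(C) <- -1
    glv_community(strains, interaction_matrix(C, p0 = attr(panel$C, "p0")),
                  densities = config$s0)
  })
}
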