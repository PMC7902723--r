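# Fixtures are built in code: flat (pH-independent) responses make the
# gLV system analytically tractable, and a short config keeps runtimes
# down where the full 100-generation horizon is not the point.

flat_response <- function(r, K, grid = ph_grid()) {
  ph_response(grid, r = rep(r, length(grid)), K = rep(K, length(grid)))
}

single_community <- function(r = 0.5, K = 0.1, s0 = 1e-4) {
  glv_community(list(strain("s1", "spA", flat_response(r, K))),
                interaction_matrix(matrix(-1, 1, 1)), s0)
}

pair_community <- function(c12, c21, r = c(0.5, 0.5), K = c(0.2, 0.2),
                           s0 = c(0.1, 0.1)) {
  C <- matrix(c(-1, c21, c12, -1), 2, 2)
  glv_community(list(strain("s1", "spA", flat_response(r[1], K[1])),
                     strain("s2", "spB", flat_response(r[2], K[2]))),
                interaction_matrix(C), s0)
}

short_config <- function(...) sim_config(n_gen = 40, ...)

# winner-flip pair: spA wins at low pH, spB at high pH; strong niche
# overlap makes the competitive outcome flip across the pH range
winner_flip_community <- function(s0 = 0.05) {
  g <- ph_grid()
  p <- as.numeric(g)
  rA <- 0.6 - 0.3 * (p - 6.3)   # favored at low pH
  rB <- 0.6 + 0.3 * (p - 6.3)   # favored at high pH
  respA <- ph_response(g, rA, rep(0.3, length(p)))
  respB <- ph_response(g, rB, rep(0.3, length(p)))
  C <- matrix(c(-1, -0.95, -0.95, -1), 2, 2)
  glv_community(list(strain("a", "spA", respA), strain("b", "spB", respB)),
                interaction_matrix(C), c(s0, s0))
}

as_stable <- function(cm, p0 = 6.3) {
  # tag a community as an assembled stable community at pH p0
  out <- structure(cm, class = unique(c("stable_community", class(cm))))
  attr(out, "stable") <- TRUE
  attr(out, "driver") <- ph_constant(p0)
  out
}
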