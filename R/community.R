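#' Multi-strain community
#'
#' Bundles a set of strains, their current densities (OD), and the
#' strain-level interaction matrix.  All strains must share one pH grid.
#'
#' @param strains list of [strain()] objects with unique ids.
#' @param C strain-level [interaction_matrix()], one row/column per strain.
#' @param densities named (or unnamed, in strain order) non-negative
#'   densities; a scalar is recycled.
#' @return An object of class `"glv_community"`.
#' @export
glv_community <- function(strains, C, densities = 1e-4) {
  stopifnot(is.list(strains), length(strains) >= 1)
  ok <- vapply(strains, inherits, logical(1), what = "strain")
  if (!all(ok)) stopf("strains must be a list of strain() objects")
  ids <- vapply(strains, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stopf("strain ids must be unique")
  n <- length(strains)
  C <- interaction_matrix(C, slopes = attr(C, "slopes"),
                          p0 = attr(C, "p0") %||% 7.2)
  if (nrow(C) != n) stopf("interaction matrix must be %d x %d", n, n)
  g0 <- strains[[1]]$response$grid
  same <- vapply(strains, function(s)
    isTRUE(all.equal(as.numeric(s$response$grid), as.numeric(g0))),
    logical(1))
  if (!all(same)) stopf("all strains must share the same pH grid")
  if (length(densities) == 1) densities <- rep(densities, n)
  if (length(densities) != n) stopf("need one density per strain")
  if (any(!is.finite(densities)) || any(densities < 0))
    stopf("densities must be finite and >= 0")
  densities <- as.numeric(densities)
  names(densities) <- ids
  dimnames(C) <- list(ids, ids)
  structure(list(strains = strains, C = C, densities = densities),
            class = "glv_community")
}

#' @export
print.glv_community <- function(x, ...) {
  cat("<glv_community>", length(x$strains), "strains:",
      paste(utils::head(names(x$densities), 8), collapse = ", "),
      if (length(x$strains) > 8) "..." else "", "\n")
  invisible(x)
}

community_ids <- function(community)
  vapply(community$strains, `[[`, character(1), "id")

community_species <- function(community)
  vapply(community$strains, `[[`, character(1), "species")

# n x ng tables of tabulated r and K plus the shared grid
community_tables <- function(community) {
  grid <- as.numeric(community$strains[[1]]$response$grid)
  rtab <- t(vapply(community$strains, function(s) s$response$r,
                   numeric(length(grid))))
  Ktab <- t(vapply(community$strains, function(s) s$response$K,
                   numeric(length(grid))))
  list(grid = grid, rtab = rtab, Ktab = Ktab)
}

#' Keep a subset of strains
#'
#' Subsets strains, densities and the interaction matrix consistently.
#'
#' @param community a [glv_community()].
#' @param keep logical/integer/character index of strains to keep.
#' @return A [glv_community()].
#' @export
subset_community <- function(community, keep) {
  ids <- community_ids(community)
  if (is.character(keep)) keep <- match(keep, ids)
  if (is.logical(keep)) keep <- which(keep)
  if (length(keep) == 0) stopf("cannot keep an empty community")
  C <- unclass(community$C)[keep, keep, drop = FALSE]
  sl <- attr(community$C, "slopes")
  if (!is.null(sl)) sl <- sl[keep, keep, drop = FALSE]
  glv_community(community$strains[keep],
                interaction_matrix(C, slopes = sl,
                                   p0 = attr(community$C, "p0")),
                community$densities[keep])
}

#' Relative abundances of a density vector
#'
#' @param x non-negative densities.
#' @return `x / sum(x)`; an error if all entries are zero.
#' @export
rel_abundance <- function(x) {
  if (any(x < 0)) stopf("densities must be >= 0")
  s <- sum(x)
  if (s <= 0) stopf("cannot normalize an all-zero composition")
  x / s
}
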