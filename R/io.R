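#' Read and write strain panel files
#'
#' The panel file is a plain CSV with one row per strain and columns
#' `strain_id`, `species`, then `r@<pH>` and `K@<pH>` for every grid
#' point; the header encodes the pH grid.  [write_strain_panel()] accepts
#' a `"base_panel"` (species as rows) or a [glv_community()] (strains as
#' rows); [read_strain_panel()] returns a named list of [strain()]
#' objects.
#'
#' @param x a `"base_panel"` or [glv_community()].
#' @param path CSV file path.
#' @return `read_strain_panel()`: named list of [strain()]s.
#'   `write_strain_panel()`: `path`, invisibly.
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
write_strain_panel <- function(x, path) {
  if (inherits(x, "base_panel")) {
    ids <- names(x$species)
    species <- ids
    responses <- x$species
  } else if (inherits(x, "glv_community")) {
    ids <- community_ids(x)
    species <- community_species(x)
    responses <- lapply(x$strains, `[[`, "response")
  } else stopf("cannot write a %s as a strain panel", class(x)[1])
  grid <- as.numeric(responses[[1]]$grid)
  df <- data.frame(strain_id = ids, species = species,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(grid))
    df[[sprintf("r@%g", grid[k])]] <-
      vapply(responses, function(r) r$r[k], numeric(1))
  for (k in seq_along(grid))
    df[[sprintf("K@%g", grid[k])]] <-
      vapply(responses, function(r) r$K[k], numeric(1))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_strain_panel <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("strain_id", "species")
  if (!all(need %in% names(df)))
    stopf("panel file must have strain_id and species columns")
  rcols <- grep("^r@", names(df), value = TRUE)
  kcols <- grep("^K@", names(df), value = TRUE)
  grid_r <- as.numeric(sub("^r@", "", rcols))
  grid_k <- as.numeric(sub("^K@", "", kcols))
  if (length(grid_r) < 2 || !isTRUE(all.equal(sort(grid_r), sort(grid_k))))
    stopf("panel header must encode matching r@ and K@ pH grids")
  o <- order(grid_r)
  grid <- ph_grid(grid_r[o])
  strains <- lapply(seq_len(nrow(df)), function(i) {
    strain(df$strain_id[i], df$species[i],
           ph_response(grid, as.numeric(df[i, rcols[o]]),
                       as.numeric(df[i, kcols[o]])))
  })
  names(strains) <- df$strain_id
  strains
}

#' Read and write interaction-matrix files
#'
#' A square CSV with strain/species ids as row and column headers; an
#' optional companion CSV of pH slopes has the same layout.
#'
#' @param C an [interaction_matrix()].
#' @param path CSV path for the coefficients.
#' @param slopes_path optional CSV path for the slope matrix.
#' @param p0 reference pH recorded with the matrix (read side).
#' @return `read_interaction_matrix()`: an [interaction_matrix()].
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_interaction_matrix <- function(C, path, slopes_path = NULL) {
  stopifnot(inherits(C, "interaction_matrix"))
  m <- unclass(C)
  attributes(m) <- list(dim = dim(C), dimnames = dimnames(C))
  write.csv(as.data.frame(m), path, row.names = TRUE)
  sl <- attr(C, "slopes")
  if (!is.null(slopes_path) && !is.null(sl)) {
    dimnames(sl) <- dimnames(C)
    write.csv(as.data.frame(sl), slopes_path, row.names = TRUE)
  }
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_interaction_matrix <- function(path, slopes_path = NULL, p0 = 7.2) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  sl <- NULL
  if (!is.null(slopes_path) && file.exists(slopes_path))
    sl <- as.matrix(read.csv(slopes_path, row.names = 1,
                             check.names = FALSE))
  interaction_matrix(m, slopes = sl, p0 = p0)
}

#' Load a strain panel and matrix as an assembly-ready panel
#'
#' Convenience wrapper pairing [read_strain_panel()] and
#' [read_interaction_matrix()] into the list structure expected by
#' [sample_assemblage()].  Row order of the matrix must match the panel.
#'
#' @param panel_path strain panel CSV.
#' @param matrix_path interaction matrix CSV.
#' @param slopes_path optional slope CSV.
#' @param p0 reference pH of the matrix.
#' @return list with `species` (named [ph_response()] list) and `C`.
#' @export
load_panel <- function(panel_path, matrix_path, slopes_path = NULL,
                       p0 = 7.2) {
  strains <- read_strain_panel(panel_path)
  C <- read_interaction_matrix(matrix_path, slopes_path, p0)
  ids <- names(strains)
  if (!is.null(rownames(C)) && !all(rownames(C) == ids)) {
    if (!all(ids %in% rownames(C)))
      stopf("matrix row names do not match the panel strain ids")
    C <- interaction_matrix(unclass(C)[ids, ids],
                            slopes = attr(C, "slopes")[ids, ids],
                            p0 = attr(C, "p0"))
  }
  structure(list(species = setNames(lapply(strains, `[[`, "response"), ids),
                 C = C),
            class = "base_panel")
}

#' Write a generation-provenance sidecar
#'
#' Records the generator parameters and seed of a synthetic panel as JSON
#' next to the CSV outputs, so any panel file can be regenerated.
#'
#' @param panel a `"base_panel"` from [generate_base_panel()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_panel_sidecar <- function(panel, path) {
  spec <- panel$spec
  if (is.null(spec)) stopf("panel has no generator spec to record")
  meta <- list(generator = "generate_base_panel",
               package = "phglv",
               version = as.character(utils::packageVersion("phglv")),
               n_species = spec$n_species, n_positive = spec$n_positive,
               strong_inhibition_fraction = spec$strong_inhibition_fraction,
               r_range = spec$r_range, K_range = spec$K_range,
               positive_cap = spec$positive_cap,
               grid = as.numeric(spec$grid), seed = spec$seed)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
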