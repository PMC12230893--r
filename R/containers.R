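#' Species-by-trait table
#'
#' A `trait_table` is a data frame with one row per species, a `species` id
#' column, a logical `nonnative` flag, and one column per trait. Trait
#' metadata (functional group, ecosystem-service set, continuous/binary type)
#' lives in the `"trait_meta"` attribute, a data frame with columns `trait`,
#' `group`, `service` (`"cultural"` or `"regulating"`) and `type`
#' (`"continuous"` or `"binary"`). The nine functional trait groups are: the
#' five single-trait cultural groups (relative tail length, colour diversity,
#' colour elaboration, crest length, inverse body mass) and the four binary
#' regulating groups (social degree, nesting strategy, diet, foraging
#' technique) plus body mass.
#'
#' @param df data frame with `species`, `nonnative` and trait columns.
#' @param meta trait metadata data frame (`trait`, `group`, `service`, `type`).
#' @return A `trait_table` object.
#' @export
trait_table <- function(df, meta) {
  stopifnot(is.data.frame(df), is.data.frame(meta))
  need <- c("trait", "group", "service", "type")
  if (!all(need %in% names(meta))) stopf("trait meta must have columns %s", paste(need, collapse = ", "))
  if (!all(c("species", "nonnative") %in% names(df))) {
    stopf("trait table must have 'species' and 'nonnative' columns")
  }
  missing_cols <- setdiff(meta$trait, names(df))
  if (length(missing_cols)) stopf("trait columns absent from table: %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$species)) stopf("duplicated species ids")
  bad <- setdiff(meta$service, c("cultural", "regulating"))
  if (length(bad)) stopf("unknown service tag: %s", paste(bad, collapse = ", "))
  out <- df
  attr(out, "trait_meta") <- meta
  class(out) <- c("trait_table", "data.frame")
  out
}

#' @export
#' @rdname trait_table
#' @param x object to query.
trait_meta <- function(x) attr(x, "trait_meta")

# columns belonging to one service set, in metadata order
service_traits <- function(table, service) {
  meta <- trait_meta(table)
  meta$trait[meta$service == service]
}

#' Presence/absence community matrix
#'
#' A `community_matrix` couples a cells-by-species 0/1 occurrence matrix with
#' per-cell metadata (functional urban area and country ids) and per-species
#' metadata (native/non-native flag). Each grid cell is treated as one
#' community.
#'
#' @param pa integer/numeric matrix, cells in rows, species in columns, values
#'   in `{0, 1}`; dimnames give cell and species ids.
#' @param cells data frame with columns `cell`, `fua`, `country` (one row per
#'   matrix row).
#' @param species data frame with columns `species`, `nonnative` (one row per
#'   matrix column).
#' @return A `community_matrix` object (list with elements `pa`, `cells`,
#'   `species`).
#' @export
community_matrix <- function(pa, cells, species) {
  pa <- as.matrix(pa)
  if (!all(pa %in% c(0, 1))) stopf("presence/absence matrix must be 0/1")
  if (is.null(rownames(pa)) || is.null(colnames(pa))) stopf("pa matrix needs dimnames")
  stopifnot(nrow(pa) == nrow(cells), ncol(pa) == nrow(species))
  if (!all(c("cell", "fua", "country") %in% names(cells))) {
    stopf("cells metadata needs cell, fua, country")
  }
  if (!all(c("species", "nonnative") %in% names(species))) {
    stopf("species metadata needs species, nonnative")
  }
  if (!identical(rownames(pa), as.character(cells$cell))) stopf("row names must match cell ids")
  if (!identical(colnames(pa), as.character(species$species))) stopf("column names must match species ids")
  structure(
    list(pa = pa, cells = cells, species = species),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf(
    "community_matrix: %d cells x %d species (%d non-native); %d FUAs, %d countries\n",
    nrow(x$pa), ncol(x$pa), sum(x$species$nonnative),
    length(unique(x$cells$fua)), length(unique(x$cells$country))
  ))
  invisible(x)
}

#' Species richness per community
#' @param m a [community_matrix()].
#' @return Named integer vector of per-cell species counts.
#' @export
richness <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  r <- rowSums(m$pa)
  names(r) <- rownames(m$pa)
  r
}

# subset helper keeping metadata in sync
cm_subset <- function(m, cells = NULL, species = NULL) {
  i <- if (is.null(cells)) seq_len(nrow(m$pa)) else match(cells, rownames(m$pa))
  j <- if (is.null(species)) seq_len(ncol(m$pa)) else match(species, colnames(m$pa))
  if (anyNA(i)) stopf("unknown cell id")
  if (anyNA(j)) stopf("unknown species id")
  community_matrix(
    m$pa[i, j, drop = FALSE],
    m$cells[i, , drop = FALSE],
    m$species[j, , drop = FALSE]
  )
}
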