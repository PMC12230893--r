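#' Classify communities by invasion status
#'
#' A community is *invaded* when at least one non-native species is present,
#' *non-invaded* otherwise. Empty cells classify as non-invaded and are
#' flagged in the `"empty_cells"` attribute (the minimum-richness filter will
#' drop them before dispersion is computed).
#'
#' @param m a [community_matrix()].
#' @return Named factor (`invaded`/`non-invaded`) per cell.
#' @export
classify_communities <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  alien <- m$species$nonnative
  n_alien <- as.vector(m$pa %*% as.numeric(alien))
  lab <- factor(ifelse(n_alien >= 1, "invaded", "non-invaded"),
                levels = c("non-invaded", "invaded"))
  names(lab) <- rownames(m$pa)
  attr(lab, "empty_cells") <- rownames(m$pa)[rowSums(m$pa) == 0]
  lab
}

#' Native component of invaded communities
#'
#' Copies the invaded cells and zeroes their non-native presences
#' (*invaded no alien*), keeping cell ids so each derived community stays
#' paired with its original. Errors if any requested cell is not invaded.
#'
#' @param m a [community_matrix()].
#' @param cells optional cell ids (default: all invaded cells).
#' @return A [community_matrix()] of the no-alien communities.
#' @export
derive_no_alien <- function(m, cells = NULL) {
  stopifnot(inherits(m, "community_matrix"))
  lab <- classify_communities(m)
  cells <- cells %||% names(lab)[lab == "invaded"]
  if (any(lab[cells] != "invaded")) {
    stopf("derive_no_alien applies only to invaded cells")
  }
  out <- cm_subset(m, cells = cells)
  out$pa[, out$species$nonnative] <- 0L
  out
}

#' Occurrence threshold for the rare-species filter
#'
#' Number of occupied cells a species needs to pass the fractional occurrence
#' rule, computed as round-half-away-from-zero of `fraction * n_cells`. At
#' the 1% default this gives 7 for a 709-cell country and 1 for a 111-cell
#' country.
#'
#' @param n_cells number of atlas cells in the country.
#' @param fraction occurrence fraction in (0, 1); default 0.01.
#' @return Integer threshold.
#' @export
occurrence_threshold <- function(n_cells, fraction = 0.01) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  as.integer(round_half_up(fraction * n_cells))
}

#' Rare-species occurrence filter
#'
#' Per country, removes (zeroes) the presences of species observed in fewer
#' than `occurrence_threshold(n_cells_country, fraction)` of that country's
#' cells; species present in exactly the threshold count are retained ("at
#' least"). Species left with no presences anywhere are dropped from the
#' matrix. This is a sensitivity variant, not the default pipeline step: the
#' all-species analysis is the primary one.
#'
#' @param m a [community_matrix()].
#' @param fraction occurrence fraction in (0, 1); default 0.01.
#' @return Filtered [community_matrix()]; attributes `"thresholds"` (named
#'   per country) and `"dropped_species"` record the decisions.
#' @export
occurrence_filter <- function(m, fraction = 0.01) {
  stopifnot(inherits(m, "community_matrix"))
  pa <- m$pa
  thresholds <- integer()
  for (ctry in unique(m$cells$country)) {
    rows <- m$cells$country == ctry
    thr <- occurrence_threshold(sum(rows), fraction)
    thresholds[ctry] <- thr
    occ <- colSums(pa[rows, , drop = FALSE])
    pa[rows, occ < thr] <- 0L
  }
  keep <- colSums(pa) > 0
  out <- community_matrix(
    pa[, keep, drop = FALSE], m$cells, m$species[keep, , drop = FALSE]
  )
  attr(out, "thresholds") <- thresholds
  attr(out, "dropped_species") <- colnames(m$pa)[!keep]
  out
}

#' Minimum-richness filter
#'
#' Removes cells holding fewer than `k` species (default 3) before any
#' dispersion computation, since dispersion over fewer than three species is
#' biased and the pairwise mean is undefined below two.
#'
#' @param m a [community_matrix()].
#' @param k minimum species count (default 3).
#' @return Filtered [community_matrix()]; `"dropped_cells"` attribute lists
#'   removals.
#' @export
min_richness_filter <- function(m, k = 3) {
  stopifnot(inherits(m, "community_matrix"))
  r <- rowSums(m$pa)
  keep <- r >= k
  out <- cm_subset(m, cells = rownames(m$pa)[keep])
  attr(out, "dropped_cells") <- rownames(m$pa)[!keep]
  out
}

#' Filter grid cells by functional-urban-area overlap
#'
#' Keeps cells whose intersection area with the union of the FUA polygons is
#' at least `min_frac` of the cell area (50% by default; exactly 50% is
#' kept). Cells straddling several FUAs are assigned to the FUA with the
#' largest overlap.
#'
#' @param cells rectangle data frame with a `cell` id column.
#' @param fuas rectangle data frame with a `fua` id column.
#' @param min_frac minimum overlap fraction (default 0.5).
#' @return Data frame of kept cells: `cell`, `fua` (largest overlap),
#'   `overlap_frac`.
#' @export
fua_overlap_filter <- function(cells, fuas, min_frac = 0.5) {
  if (any(cells$xmax <= cells$xmin) || any(cells$ymax <= cells$ymin)) {
    stopf("invalid cell geometry")
  }
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cellrect <- cells[i, ]
    pieces <- rect_clip(fuas, cellrect)
    if (nrow(pieces) == 0) {
      return(data.frame(cell = cellrect$cell, fua = NA_character_,
                        overlap_frac = 0, stringsAsFactors = FALSE))
    }
    ov <- rect_union_area(pieces) / rect_area(cellrect)
    per_fua <- rect_intersection_area(fuas, cellrect)
    best <- fuas$fua[which.max(per_fua)]
    data.frame(cell = cellrect$cell, fua = best, overlap_frac = ov,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res[res$overlap_frac >= min_frac - 1e-12, , drop = FALSE]
}

#' Area-weighted cell income
#'
#' Median income of a grid cell as the overlap-area-weighted average of the
#' neighbourhood polygons intersecting it:
#' `income_cell = sum(area_k * income_k) / sum(area_k)`. A neighbourhood
#' therefore contributes to each cell only through the area it shares with
#' it, so neighbourhoods spanning several cells are never over-represented.
#' Cells intersecting no income polygon get `NA` (missing, not zero) and are
#' later dropped listwise from models.
#'
#' @param cells rectangle data frame with `cell` (and optionally `fua`,
#'   `country`) columns.
#' @param neighbourhoods rectangle data frame with an `income` column
#'   (incomes must be positive).
#' @return Data frame `cell`, (`fua`, `country` if present,) `income`.
#' @export
cell_income <- function(cells, neighbourhoods) {
  if (any(neighbourhoods$income <= 0)) stopf("incomes must be positive")
  inc <- vapply(seq_len(nrow(cells)), function(i) {
    a <- rect_intersection_area(neighbourhoods, cells[i, ])
    if (sum(a) == 0) return(NA_real_)
    sum(a * neighbourhoods$income) / sum(a)
  }, numeric(1))
  keep <- intersect(c("cell", "fua", "country"), names(cells))
  out <- cells[, keep, drop = FALSE]
  out$income <- inc
  rownames(out) <- NULL
  out
}

#' Standardize income within countries
#'
#' Adds `z_income = (income - mean_country) / sd_country` (sample sd) over
#' each country's cells with non-missing income, making income gradients
#' comparable across countries with different costs of living. Affine
#' changes of currency unit leave z unchanged.
#'
#' @param g data frame with `cell`, `country`, `income`.
#' @return The data frame with a `z_income` column.
#' @export
standardize_income <- function(g) {
  if (!all(c("cell", "country", "income") %in% names(g))) {
    stopf("income grid needs cell, country, income")
  }
  g$z_income <- NA_real_
  for (ctry in unique(g$country)) {
    i <- g$country == ctry & !is.na(g$income)
    if (sum(i) < 2) stopf("country '%s' has fewer than 2 cells with income", ctry)
    s <- stats::sd(g$income[i])
    if (s == 0) stopf("country '%s' has constant income", ctry)
    g$z_income[i] <- (g$income[i] - mean(g$income[i])) / s
  }
  g
}

#' Assemble the analysis table
#'
#' Runs the fixed pipeline order on a community matrix and landscape:
#' FUA-overlap filter, optional rare-species occurrence filter, invasion
#' classification, minimum-richness filter, income join (cells with missing
#' income dropped listwise). Counts at each stage are logged in the
#' `"filter_log"` attribute.
#'
#' @param m a [community_matrix()].
#' @param landscape a landscape list as from [generate_landscape()] (elements
#'   `cells`, `fuas`, `income`).
#' @param occurrence_fraction if non-`NULL`, apply [occurrence_filter()] with
#'   this fraction (default `NULL`: all species retained, the primary
#'   analysis).
#' @param min_overlap FUA overlap fraction (default 0.5).
#' @param min_rich minimum richness (default 3).
#' @return List: `communities` (the filtered [community_matrix()]) and
#'   `table` (`cell`, `fua`, `country`, `richness`, `type`, `z_income`).
#' @export
assemble_analysis <- function(m, landscape, occurrence_fraction = NULL,
                              min_overlap = 0.5, min_rich = 3) {
  stopifnot(inherits(m, "community_matrix"))
  log <- c(start = nrow(m$pa))
  kept <- fua_overlap_filter(landscape$cells, landscape$fuas, min_overlap)
  m <- cm_subset(m, cells = intersect(rownames(m$pa), kept$cell))
  log["after_overlap_filter"] <- nrow(m$pa)
  if (!is.null(occurrence_fraction)) {
    m <- occurrence_filter(m, occurrence_fraction)
  }
  log["after_occurrence_filter"] <- nrow(m$pa)
  type <- classify_communities(m)
  m <- min_richness_filter(m, min_rich)
  log["after_min_richness"] <- nrow(m$pa)
  inc <- landscape$income
  tab <- data.frame(
    cell = rownames(m$pa), fua = m$cells$fua, country = m$cells$country,
    richness = as.integer(rowSums(m$pa)),
    type = type[rownames(m$pa)],
    z_income = inc$z_income[match(rownames(m$pa), inc$cell)],
    stringsAsFactors = FALSE
  )
  has_income <- !is.na(tab$z_income)
  tab <- tab[has_income, , drop = FALSE]
  m <- cm_subset(m, cells = tab$cell)
  log["after_income_join"] <- nrow(tab)
  log["invaded"] <- sum(tab$type == "invaded")
  log["non_invaded"] <- sum(tab$type == "non-invaded")
  attr(tab, "filter_log") <- log
  list(communities = m, table = tab)
}
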