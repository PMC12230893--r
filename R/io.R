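#' Write rectangles as a GeoJSON FeatureCollection
#'
#' Each row becomes a Polygon feature (closed ring, counterclockwise) with
#' all non-coordinate columns as properties.
#'
#' @param rects rectangle data frame (`xmin`, `xmax`, `ymin`, `ymax` plus
#'   attribute columns).
#' @param path output file.
#' @export
write_geojson <- function(rects, path) {
  props <- setdiff(names(rects), c("xmin", "xmax", "ymin", "ymax"))
  features <- lapply(seq_len(nrow(rects)), function(i) {
    r <- rects[i, ]
    ring <- list(
      c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
      c(r$xmin, r$ymax), c(r$xmin, r$ymin)
    )
    list(
      type = "Feature",
      properties = as.list(r[props]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read rectangle polygons from GeoJSON
#'
#' Inverse of [write_geojson()] for axis-aligned rectangles: bounding boxes
#' of the polygon rings are taken as the rectangles.
#'
#' @param path GeoJSON file.
#' @return Rectangle data frame with property columns restored.
#' @export
read_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  rows <- lapply(g$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    cbind(
      as.data.frame(f$properties, stringsAsFactors = FALSE),
      data.frame(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
    )
  })
  do.call(rbind, rows)
}

#' Write a synthetic study to plain-text files
#'
#' Serializes every component in the formats downstream tools read:
#' `traits.csv` + `trait_meta.csv`, `communities.csv` (cell, fua, country,
#' then one 0/1 column per species), `species_meta.csv`, `phylogeny.nwk`
#' (Newick), `cells.geojson`, `neighbourhoods.geojson`, `income.csv` and
#' `truth.json`.
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(study$traits), file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(trait_meta(study$traits), file.path(dir, "trait_meta.csv"), row.names = FALSE)
  comm <- cbind(study$communities$cells, as.data.frame(study$communities$pa))
  utils::write.csv(comm, file.path(dir, "communities.csv"), row.names = FALSE)
  utils::write.csv(study$communities$species, file.path(dir, "species_meta.csv"), row.names = FALSE)
  ape::write.tree(study$phylogeny, file.path(dir, "phylogeny.nwk"))
  write_geojson(study$landscape$cells, file.path(dir, "cells.geojson"))
  write_geojson(study$landscape$neighbourhoods, file.path(dir, "neighbourhoods.geojson"))
  utils::write.csv(study$income, file.path(dir, "income.csv"), row.names = FALSE)
  jsonlite::write_json(
    study$truth[c("richness_income_slope", "invasion_income_slope", "service_income_slope")],
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a synthetic study back from [write_study()] output
#'
#' @param dir directory written by [write_study()].
#' @return A `synthetic_study`-shaped list (`truth` holds only the slopes).
#' @export
read_study <- function(dir) {
  traits <- trait_table(
    utils::read.csv(file.path(dir, "traits.csv"), stringsAsFactors = FALSE),
    utils::read.csv(file.path(dir, "trait_meta.csv"), stringsAsFactors = FALSE)
  )
  comm_df <- utils::read.csv(file.path(dir, "communities.csv"), stringsAsFactors = FALSE, check.names = FALSE)
  spmeta <- utils::read.csv(file.path(dir, "species_meta.csv"), stringsAsFactors = FALSE)
  pa <- as.matrix(comm_df[, spmeta$species, drop = FALSE])
  rownames(pa) <- comm_df$cell
  communities <- community_matrix(pa, comm_df[c("cell", "fua", "country")], spmeta)
  income <- utils::read.csv(file.path(dir, "income.csv"), stringsAsFactors = FALSE)
  cells <- read_geojson(file.path(dir, "cells.geojson"))
  nbs <- read_geojson(file.path(dir, "neighbourhoods.geojson"))
  fuas <- do.call(rbind, lapply(split(cells, cells$fua), function(r) {
    data.frame(fua = r$fua[1], country = r$country[1], xmin = min(r$xmin),
               xmax = max(r$xmax), ymin = min(r$ymin), ymax = max(r$ymax),
               stringsAsFactors = FALSE)
  }))
  rownames(fuas) <- NULL
  structure(
    list(
      traits = traits,
      phylogeny = ape::read.tree(file.path(dir, "phylogeny.nwk")),
      landscape = structure(
        list(cells = cells, fuas = fuas, neighbourhoods = nbs, income = income),
        class = "landscape"
      ),
      income = income, communities = communities,
      truth = jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
    ),
    class = "synthetic_study"
  )
}

#' Write CFD results as TSV
#'
#' @param x a [cfd()] object.
#' @param path output file.
#' @export
write_cfd <- function(x, path) {
  stopifnot(inherits(x, "cfd"))
  tab <- x$table
  tab$service <- x$service %||% NA_character_
  tab$n_iter <- x$n_iter
  tab$seed <- x$seed
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
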