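#' Derive relative tail length
#'
#' Regresses log tail length on log body mass (ordinary least squares) and
#' stores the residuals as `rel_tail_length`: the component of tail length not
#' explained by size, an ornament proxy. The raw `tail_length` column is
#' retired from the cultural set (its metadata row is replaced by the derived
#' trait). Residuals have mean zero by construction.
#'
#' @param table a [trait_table()] with positive `tail_length` and `body_mass`.
#' @return The table with a `rel_tail_length` column.
#' @export
derive_relative_tail_length <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  if (!all(c("tail_length", "body_mass") %in% names(table))) {
    stopf("tail_length and body_mass required")
  }
  if (any(table$tail_length <= 0) || any(table$body_mass <= 0)) {
    stopf("tail length and body mass must be positive")
  }
  fit <- stats::lm(log(table$tail_length) ~ log(table$body_mass))
  meta <- trait_meta(table)
  i <- match("tail_length", meta$trait)
  meta$trait[i] <- "rel_tail_length"
  out <- table
  out$rel_tail_length <- as.numeric(stats::residuals(fit))
  out$tail_length <- NULL
  trait_table(as.data.frame(out), meta)
}

#' Derive inverse body mass
#'
#' Adds `inv_body_mass = 1 / body_mass` as the cultural size trait (small
#' birds are preferred aesthetically, and the inversion avoids collinearity
#' with relative tail length). The regulating set keeps raw `body_mass`.
#'
#' @param table a [trait_table()] with positive `body_mass`.
#' @return The table with an `inv_body_mass` column tagged cultural.
#' @export
derive_inverse_body_mass <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  if (!"body_mass" %in% names(table)) stopf("body_mass required")
  if (any(table$body_mass <= 0)) stopf("body mass must be positive")
  meta <- trait_meta(table)
  if (!"inv_body_mass" %in% meta$trait) {
    meta <- rbind(meta, data.frame(
      trait = "inv_body_mass", group = "inv_body_mass",
      service = "cultural", type = "continuous", stringsAsFactors = FALSE
    ))
  }
  out <- table
  out$inv_body_mass <- 1 / table$body_mass
  trait_table(as.data.frame(out), meta)
}

#' Min-max scale continuous traits to [0, 1]
#'
#' Scales every continuous trait column to `(x - min) / (max - min)`. Body
#' mass is log-transformed first to avoid extreme values dominating the
#' range (tail length enters as log-log residuals, already tamed). Constant
#' columns map to 0 rather than NaN: they carry no dissimilarity information
#' either way. Idempotent.
#'
#' @param table a [trait_table()].
#' @return The table with continuous traits in `[0, 1]`.
#' @export
scale_continuous <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  meta <- trait_meta(table)
  out <- table
  for (tr in meta$trait[meta$type == "continuous"]) {
    x <- out[[tr]]
    if (tr == "body_mass" && any(x > 1)) x <- log(x)
    rng <- range(x)
    out[[tr]] <- if (diff(rng) == 0) rep(0, length(x)) else (x - rng[1]) / diff(rng)
  }
  trait_table(as.data.frame(out), meta)
}

#' Screen trait collinearity within each service set
#'
#' Computes pairwise Pearson correlations among the analysis-ready trait
#' columns of each service set and iteratively removes one member of any pair
#' with `|r|` strictly above `threshold` (`|r| <= threshold` is the acceptable
#' region). At each step the offending pair with the largest `|r|` is
#' considered and the member with the larger mean absolute correlation with
#' all remaining columns is dropped; ties fall back to column order, so the
#' result is deterministic. Screening is per service set, since each set
#' enters its own Gower matrix.
#'
#' @param table a prepared [trait_table()].
#' @param threshold correlation magnitude above which a pair is collinear
#'   (default 0.70); must be in (0, 1].
#' @return The table without the dropped columns; the `"collinearity_report"`
#'   attribute records each dropped trait, its partner and their r.
#' @export
screen_collinearity <- function(table, threshold = 0.70) {
  stopifnot(inherits(table, "trait_table"))
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  meta <- trait_meta(table)
  report <- data.frame(
    service = character(), dropped = character(), partner = character(),
    r = numeric(), stringsAsFactors = FALSE
  )
  dropped_all <- character()
  for (svc in c("cultural", "regulating")) {
    keep <- service_traits(table, svc)
    repeat {
      if (length(keep) < 2) break
      cm <- suppressWarnings(stats::cor(as.matrix(as.data.frame(table)[keep])))
      cm[is.na(cm)] <- 0
      diag(cm) <- 0
      worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
      if (abs(cm[worst[1], worst[2]]) <= threshold) break
      pair <- keep[c(worst[1], worst[2])]
      mac <- rowMeans(abs(cm[pair, , drop = FALSE]))
      drop <- pair[which.max(mac)]
      partner <- setdiff(pair, drop)
      report <- rbind(report, data.frame(
        service = svc, dropped = drop, partner = partner,
        r = cm[worst[1], worst[2]], stringsAsFactors = FALSE
      ))
      keep <- setdiff(keep, drop)
      dropped_all <- c(dropped_all, drop)
    }
  }
  meta <- meta[!meta$trait %in% dropped_all, , drop = FALSE]
  df <- as.data.frame(table)
  df <- df[, !names(df) %in% dropped_all, drop = FALSE]
  out <- trait_table(df, meta)
  attr(out, "collinearity_report") <- report
  attr(out, "collinearity_scope") <- "per service set"
  out
}

#' Prepare a raw trait table for analysis
#'
#' Full preparation chain: derive relative tail length and inverse body mass,
#' min-max scale continuous traits (log mass first), and screen collinearity.
#' After preparation every continuous trait lies in `[0, 1]`, binaries stay
#' `{0, 1}`, and no retained within-set pair exceeds the correlation
#' threshold.
#'
#' @inheritParams screen_collinearity
#' @return An analysis-ready [trait_table()].
#' @export
prepare_traits <- function(table, threshold = 0.70) {
  table <- derive_relative_tail_length(table)
  table <- derive_inverse_body_mass(table)
  table <- scale_continuous(table)
  screen_collinearity(table, threshold = threshold)
}
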