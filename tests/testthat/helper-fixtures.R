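# Shared fixtures, built in code.

# The 4-taxon additive reference tree ((A:1,B:2):1,(C:3,D:4));
# pairwise path lengths: AB=3, AC=5, AD=6, BC=6, BD=7, CD=7.
quad_tree <- function() {
  ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
}

quad_matrix <- function() {
  lab <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(lab, lab))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  d
}

# a small trait table with explicit groups, for Gower tests
toy_traits <- function(df, groups, services, types) {
  meta <- data.frame(
    trait = setdiff(names(df), c("species", "nonnative")),
    group = groups, service = services, type = types,
    stringsAsFactors = FALSE
  )
  trait_table(df, meta)
}

# independent brute-force group-weighted Gower (double loop, scalar code)
gower_brute <- function(table, service) {
  meta <- trait_meta(table)
  meta <- meta[meta$service == service, ]
  x <- as.data.frame(table)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(x$species, x$species))
  groups <- unique(meta$group)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (g in groups) {
        cols <- meta$trait[meta$group == g]
        s <- 0
        for (cl in cols) {
          rng <- max(x[[cl]]) - min(x[[cl]])
          s <- s + if (rng > 0) abs(x[[cl]][i] - x[[cl]][j]) / rng else 0
        }
        acc <- acc + s / length(cols)
      }
      d[i, j] <- acc / length(groups)
    }
  }
  d
}

# a tiny community matrix built from explicit presences
make_cm <- function(pa, fua = NULL, country = NULL, nonnative = NULL) {
  cells <- data.frame(
    cell = rownames(pa),
    fua = fua %||% rep("f1", nrow(pa)),
    country = country %||% rep("A", nrow(pa)),
    stringsAsFactors = FALSE
  )
  species <- data.frame(
    species = colnames(pa),
    nonnative = nonnative %||% rep(FALSE, ncol(pa)),
    stringsAsFactors = FALSE
  )
  community_matrix(pa, cells, species)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
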