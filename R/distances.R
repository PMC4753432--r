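# Kimura 2-parameter distances with pairwise deletion, and the
# rank-level summaries used in barcode-gap audits.

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or a non-ACGT symbol are
#' excluded (pairwise deletion). With P the transition and Q the
#' transversion fraction over the usable sites,
#' \deqn{d = -\tfrac{1}{2}\ln\big((1-2P-Q)\sqrt{1-2Q}\big).}
#' The distance is undefined (`NA`) when no usable sites remain or the
#' logarithm's argument is non-positive (saturation).
#'
#' @param seq_a,seq_b aligned DNA strings of equal length.
#' @return numeric distance in substitutions/site (`NA` if undefined),
#'   with attribute `"sites"` giving the usable-site count.
#' @export
k2p <- function(seq_a, seq_b) {
  a <- toupper(seq_a)
  b <- toupper(seq_b)
  if (nchar(a) != nchar(b))
    stop("sequences must be aligned to equal length (",
         nchar(a), " vs ", nchar(b), ")")
  x <- match(strsplit(a, "")[[1]], c("A", "C", "G", "T"))
  y <- match(strsplit(b, "")[[1]], c("A", "C", "G", "T"))
  x[is.na(x)] <- 0L
  y[is.na(y)] <- 0L
  use <- x > 0L & y > 0L
  n <- sum(use)
  if (n == 0L) return(structure(NA_real_, sites = 0L))
  xd <- x[use]
  yd <- y[use]
  diff <- xd != yd
  s <- xd + yd
  ts <- sum(diff & (s == 4L | s == 6L))   # A<->G (1+3), C<->T (2+4)
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  d <- if (a1 <= 0 || a2 <= 0) NA_real_ else -0.5 * log(a1 * sqrt(a2))
  structure(d, sites = as.integer(n))
}

#' All-pairs K2P distance matrix
#'
#' Computes every unordered pair by the same pairwise-deletion rule as
#' [k2p()], using indicator-matrix products so large libraries stay fast.
#' Undefined (saturated or zero-overlap) pairs are `NA`, never silently
#' zeroed.
#'
#' @param x an aligned [barcode_library()], a character matrix, or a named
#'   character vector of equal-length aligned sequences.
#' @return object of class `k2p_dist`: list with `ids`, symmetric `d`
#'   (substitutions/site) and `sites` (usable-site counts per pair).
#' @export
distance_matrix <- function(x) {
  aln <- .alignment_of(x)
  ids <- rownames(aln) %||% as.character(seq_len(nrow(aln)))
  M <- .code_alignment(aln)
  ok <- (M > 0L) * 1
  usable <- ok %*% t(ok)
  Ib <- lapply(1:4, function(b) (M == b) * 1)
  same <- Reduce(`+`, lapply(Ib, function(I) I %*% t(I)))
  ts <- Ib[[1]] %*% t(Ib[[3]]) + Ib[[3]] %*% t(Ib[[1]]) +
    Ib[[2]] %*% t(Ib[[4]]) + Ib[[4]] %*% t(Ib[[2]])
  P <- ifelse(usable > 0, ts / usable, NA_real_)
  Q <- ifelse(usable > 0, (usable - same - ts) / usable, NA_real_)
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  d <- ifelse(!is.na(a1) & a1 > 0 & a2 > 0,
              -0.5 * log(a1 * sqrt(a2)), NA_real_)
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  dimnames(usable) <- list(ids, ids)
  structure(list(ids = ids, d = d,
                 sites = matrix(as.integer(usable), nrow(usable),
                                dimnames = dimnames(usable))),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  nn <- length(x$ids)
  off <- x$d[upper.tri(x$d)]
  cat("k2p_dist:", nn, "sequences,", length(off), "pairs (",
      sum(is.na(off)), "undefined )\n")
  invisible(x)
}

#' Drop ambiguous and invalid-name records before distance summaries
#'
#' Removes records that cannot contribute to rank-level distance
#' statistics: genus-level or uncertain identifications (qualifier
#' `sp`/`cf`/`aff`), records with no morpho-species name, and species whose
#' names are flagged invalid.
#'
#' @param library a [barcode_library()].
#' @param invalid_names character vector of morpho-species names to drop.
#' @return the filtered [barcode_library()]; removed ids in attribute
#'   `"excluded"`.
#' @export
exclusion_filter <- function(library, invalid_names = character()) {
  stopifnot(inherits(library, "barcode_library"))
  m <- library$meta
  drop <- m$qualifier %in% c("sp", "cf", "aff") |
    m$morpho_species == "" |
    m$morpho_species %in% invalid_names
  out <- subset_library(library, m$specimen_id[!drop])
  attr(out, "excluded") <- m$specimen_id[drop]
  out
}

# Logical pair mask (n x n, upper triangle meaningful) for a rank.
.rank_pair_mask <- function(meta, rank) {
  sp <- meta$morpho_species
  gn <- meta$genus
  fa <- meta$family
  named <- sp != ""
  switch(rank,
    species = outer(sp, sp, "==") & named,
    genus   = outer(gn, gn, "==") & outer(sp, sp, "!=") & gn != "" & named,
    family  = outer(fa, fa, "==") & outer(gn, gn, "!=") & fa != "" & named,
    stop("rank must be species, genus or family"))
}

#' Rank-level K2P distance summary
#'
#' Aggregates pairwise distances the way reference-library distance tables
#' do: at species rank, pairs within the same morpho-species; at genus
#' rank, pairs between different species of the same genus; at family
#' rank, pairs between different genera of the same family. The mean is
#' the simple mean over qualifying pairs and SE its standard error;
#' statistics are reported in percent.
#'
#' @param dm a `k2p_dist` from [distance_matrix()].
#' @param meta the library metadata (or a [barcode_library()]).
#' @param rank one of `"species"`, `"genus"`, `"family"`.
#' @return one-row data.frame: `rank`, `n_groups`, `n_comparisons`
#'   (all qualifying pairs), `n_usable` (pairs with a defined distance),
#'   `min`, `mean`, `max`, `se` (percent).
#' @export
summarize_distances <- function(dm, meta, rank = c("species", "genus",
                                                   "family")) {
  rank <- match.arg(rank)
  stopifnot(inherits(dm, "k2p_dist"))
  if (inherits(meta, "barcode_library")) meta <- meta$meta
  meta <- meta[match(dm$ids, meta$specimen_id), , drop = FALSE]
  mask <- .rank_pair_mask(meta, rank) & upper.tri(dm$d)
  vals <- dm$d[mask]
  n_und <- sum(is.na(vals))
  if (n_und > 0)
    warning(n_und, " undefined pair(s) excluded from ", rank,
            "-rank summary")
  group_col <- switch(rank, species = meta$morpho_species,
                      genus = meta$genus, family = meta$family)
  pair_idx <- which(mask, arr.ind = TRUE)
  n_groups <- length(unique(group_col[pair_idx[, 1]]))
  vals_ok <- vals[!is.na(vals)] * 100
  if (!length(vals_ok))
    return(data.frame(rank = rank, n_groups = n_groups,
                      n_comparisons = length(vals), n_usable = 0L,
                      min = NA_real_, mean = NA_real_, max = NA_real_,
                      se = NA_real_, stringsAsFactors = FALSE))
  data.frame(rank = rank, n_groups = n_groups,
             n_comparisons = length(vals), n_usable = length(vals_ok),
             min = min(vals_ok), mean = mean(vals_ok), max = max(vals_ok),
             se = stats::sd(vals_ok) / sqrt(length(vals_ok)),
             stringsAsFactors = FALSE)
}

#' Nearest-neighbour distance per species
#'
#' For each species, the minimum K2P distance from any of its members to
#' any member of a different species, with the species attaining it (all
#' of them, when tied).
#'
#' @param dm a `k2p_dist`.
#' @param species character vector of species labels aligned with
#'   `dm$ids` (or a [barcode_library()], whose named morpho-species are
#'   used).
#' @return data.frame `species`, `nn_species` (`;`-joined on ties),
#'   `nn_distance` (percent).
#' @export
nearest_neighbor <- function(dm, species) {
  stopifnot(inherits(dm, "k2p_dist"))
  if (inherits(species, "barcode_library")) {
    meta <- species$meta[match(dm$ids, species$meta$specimen_id), ]
    species <- meta$morpho_species
  }
  stopifnot(length(species) == length(dm$ids))
  keep <- species != "" & !is.na(species)
  sp <- species[keep]
  d <- dm$d[keep, keep, drop = FALSE]
  u <- unique(sp)
  if (length(u) < 2)
    stop("nearest-neighbour distances need at least 2 species")
  rows <- lapply(u, function(s) {
    inside <- sp == s
    sub <- d[inside, !inside, drop = FALSE]
    other_sp <- sp[!inside]
    if (all(is.na(sub)))
      return(data.frame(species = s, nn_species = NA_character_,
                        nn_distance = NA_real_, stringsAsFactors = FALSE))
    mn <- min(sub, na.rm = TRUE)
    hits <- unique(other_sp[which(sub == mn, arr.ind = TRUE)[, 2]])
    data.frame(species = s, nn_species = paste(sort(hits), collapse = ";"),
               nn_distance = mn * 100, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a distance matrix
#'
#' @param dm a `k2p_dist`.
#' @param path output file.
#' @param format `"tsv"` (square, with header) or `"phylip"`
#'   (lower-triangle).
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  stopifnot(inherits(dm, "k2p_dist"))
  if (format == "tsv") {
    df <- data.frame(specimen_id = dm$ids, dm$d, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(length(dm$ids)), con)
    for (i in seq_along(dm$ids)) {
      vals <- if (i > 1)
        paste(sprintf("%.6f", dm$d[i, seq_len(i - 1)]), collapse = " ")
      else ""
      writeLines(trimws(paste(sprintf("%-10s", dm$ids[i]), vals)), con)
    }
  }
  invisible(path)
}
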