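# Fixture builders shared across the test files. Everything is generated
# in code under fixed seeds; no data files.

rand_dna <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# random sequence with no frame-1 stop codons (invertebrate mito code)
rand_coding <- function(L = 658, seed = 1) {
  set.seed(seed)
  code <- invertebrate_mito_code()
  cods <- names(code)[code != "*"]
  substr(paste(sample(cods, ceiling(L / 3), replace = TRUE),
               collapse = ""), 1, L)
}

# substitute exactly n positions (chosen under seed) by a different base
mutate_seq <- function(seq, n, seed) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

make_meta_row <- function(id, species, genus = NULL, family = "Fam",
                          qualifier = "none", source = "own",
                          published = FALSE) {
  genus <- genus %||% strsplit(species, " ")[[1]][1]
  data.frame(specimen_id = id, morpho_species = species, genus = genus,
             family = family, qualifier = qualifier, locality = "here",
             source = source, published = published,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Library engineered so each grade A-E fires exactly once:
#   Alpha una   3 own + 2 external, one cluster          -> A
#   Beta dua    3 own, one cluster, no externals         -> B
#   Gamma tria  3 own split over two clusters            -> C
#   Delta quat  1 own, no externals                      -> D
#   Epsil quin  2 own sharing a cluster with Zeta sexta  -> E
graded_fixture <- function() {
  base <- rand_coding(658, seed = 42)
  centers <- lapply(1:6, function(k) mutate_seq(base, 35, seed = 100 + k))
  near <- function(center, k, seed) if (k == 0) center
    else mutate_seq(center, k, seed)
  rows <- rbind(
    make_meta_row("A1", "Alpha una"), make_meta_row("A2", "Alpha una"),
    make_meta_row("A3", "Alpha una"),
    make_meta_row("A4", "Alpha una", source = "external",
                  published = TRUE),
    make_meta_row("A5", "Alpha una", source = "external",
                  published = TRUE),
    make_meta_row("B1", "Beta dua"), make_meta_row("B2", "Beta dua"),
    make_meta_row("B3", "Beta dua"),
    make_meta_row("C1", "Gamma tria"), make_meta_row("C2", "Gamma tria"),
    make_meta_row("C3", "Gamma tria"),
    make_meta_row("D1", "Delta quat"),
    make_meta_row("E1", "Epsil quin"), make_meta_row("E2", "Epsil quin"),
    make_meta_row("F1", "Zeta sexta", source = "external",
                  published = TRUE),
    make_meta_row("F2", "Zeta sexta", source = "external",
                  published = TRUE))
  gamma_far <- mutate_seq(centers[[3]], 35, seed = 321)
  seqs <- c(
    A1 = near(centers[[1]], 0, 0), A2 = near(centers[[1]], 1, 201),
    A3 = near(centers[[1]], 2, 202), A4 = near(centers[[1]], 1, 203),
    A5 = near(centers[[1]], 2, 204),
    B1 = near(centers[[2]], 0, 0), B2 = near(centers[[2]], 1, 205),
    B3 = near(centers[[2]], 2, 206),
    C1 = near(centers[[3]], 0, 0), C2 = near(centers[[3]], 1, 207),
    C3 = gamma_far,
    D1 = near(centers[[4]], 0, 0),
    E1 = near(centers[[5]], 0, 0), E2 = near(centers[[5]], 1, 208),
    F1 = near(centers[[5]], 1, 209), F2 = near(centers[[5]], 2, 210))
  barcode_library(rows, seqs, alignment = seqs)
}

# wrap a plain distance matrix as a k2p_dist (for clustering / NJ tests
# that start from distances rather than sequences)
as_k2p_dist <- function(d, ids = NULL) {
  ids <- ids %||% (rownames(d) %||% as.character(seq_len(nrow(d))))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d,
                 sites = matrix(1L, nrow(d), ncol(d),
                                dimnames = dimnames(d))),
            class = "k2p_dist")
}

expect_motu_sets <- function(assignment, expected_sets) {
  got <- split(assignment$specimen_id, assignment$motu_id)
  got <- lapply(got, sort)
  expected_sets <- lapply(expected_sets, sort)
  expect_true(setequal(lapply(got, paste, collapse = ","),
                       lapply(expected_sets, paste, collapse = ",")))
}
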