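test_that("k2p matches closed-form hand evaluations", {
  s <- rand_coding(658, seed = 1)
  expect_equal(as.numeric(k2p(s, s)), 0)
  # one transition in four sites: P=0.25, Q=0
  d <- k2p("AAAA", "AAAG")
  expect_equal(as.numeric(d), -0.5 * log(0.5), tolerance = 1e-12)
  expect_equal(attr(d, "sites"), 4L)
  # ambiguity sites drop out pairwise
  d <- k2p("AAAA", "AAAN")
  expect_equal(as.numeric(d), 0)
  expect_equal(attr(d, "sites"), 3L)
  # one transversion in four: P=0, Q=0.25
  expect_equal(as.numeric(k2p("AAAA", "AAAC")),
               -0.5 * log(0.75 * sqrt(0.5)), tolerance = 1e-12)
  expect_error(k2p("AAA", "AAAA"), "equal length")
})

test_that("saturated and zero-overlap pairs are undefined, not zeroed", {
  expect_true(is.na(k2p("AGAG", "GAGA")))       # P=1 saturates
  d <- k2p("NNNN", "ACGT")
  expect_true(is.na(d))
  expect_equal(attr(d, "sites"), 0L)
})

test_that("k2p approaches the p-distance for small P with Q=0", {
  # 1 transition over 1000 sites: d ~ P to first order
  a <- strrep("A", 1000)
  b <- paste0(strrep("A", 999), "G")
  expect_lt(abs(as.numeric(k2p(a, b)) - 0.001), 1e-5)
})

test_that("distance matrix equals per-pair recomputation and ape's K80", {
  set.seed(33)
  n <- 12
  seqs <- vapply(1:n, function(i) {
    s <- mutate_seq(rand_coding(300, seed = 50), sample(0:30, 1),
                    seed = 60 + i)
    # sprinkle gaps and Ns to exercise pairwise deletion
    ch <- strsplit(s, "")[[1]]
    ch[sample(300, 5)] <- "N"
    ch[sample(300, 3)] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:n)
  dm <- distance_matrix(seqs)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    expect_equal(dm$d[i, j], as.numeric(k2p(seqs[i], seqs[j])),
                 tolerance = 1e-12)
    expect_equal(dm$sites[i, j], attr(k2p(seqs[i], seqs[j]), "sites"))
  }
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, n))

  # independent oracle: ape dist.dna K80 with pairwise deletion
  clean <- vapply(1:n, function(i)
    mutate_seq(rand_coding(300, seed = 51), sample(0:30, 1),
               seed = 70 + i), character(1))
  names(clean) <- paste0("c", 1:n)
  dm2 <- distance_matrix(clean)
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(clean), ""), identity))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dm2$d), unname(ref[names(clean), names(clean)]),
               tolerance = 1e-9)
})

test_that("distances are invariant to record order", {
  lib <- graded_fixture()
  dm <- distance_matrix(lib)
  set.seed(9)
  perm <- sample(lib$meta$specimen_id)
  dmp <- distance_matrix(subset_library(lib, lib$meta$specimen_id)
                         $alignment[perm, ])
  expect_equal(dmp$d[lib$meta$specimen_id, lib$meta$specimen_id], dm$d)
})

test_that("exclusion filter drops ambiguous and invalid records", {
  meta <- rbind(
    make_meta_row("X1", "Gibbula sp.", qualifier = "sp"),
    make_meta_row("X2", "Ocinebrina edwardsii", qualifier = "cf"),
    make_meta_row("X3", "Osilinus lineatus"),
    make_meta_row("X4", "Patella aspera"))
  lib <- barcode_library(meta, setNames(rep("ACGTACGT", 4),
                                        paste0("X", 1:4)))
  out <- exclusion_filter(lib, invalid_names = "Osilinus lineatus")
  expect_equal(out$meta$specimen_id, "X4")
  expect_setequal(attr(out, "excluded"), c("X1", "X2", "X3"))
})

test_that("rank summaries equal brute-force pair aggregation", {
  lib <- graded_fixture()
  dm <- distance_matrix(lib)
  meta <- lib$meta
  # brute force: stream over unordered pairs
  agg <- function(rank) {
    vals <- c()
    n <- nrow(meta)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      qualify <- switch(rank,
        species = meta$morpho_species[i] == meta$morpho_species[j],
        genus = meta$genus[i] == meta$genus[j] &&
          meta$morpho_species[i] != meta$morpho_species[j],
        family = meta$family[i] == meta$family[j] &&
          meta$genus[i] != meta$genus[j])
      if (qualify) vals <- c(vals, dm$d[i, j])
    }
    vals * 100
  }
  for (rank in c("species", "genus", "family")) {
    s <- summarize_distances(dm, meta, rank)
    v <- agg(rank)
    expect_equal(s$n_comparisons, length(v))
    if (length(v)) {
      expect_equal(s$mean, mean(v), tolerance = 1e-12)
      expect_equal(s$min, min(v))
      expect_equal(s$max, max(v))
      expect_equal(s$se, sd(v) / sqrt(length(v)), tolerance = 1e-12)
      expect_lte(s$min, s$mean)
      expect_lte(s$mean, s$max)
    }
  }
})

test_that("one species with two identical specimens summarizes to zero", {
  meta <- rbind(make_meta_row("Z1", "Aa bb"), make_meta_row("Z2", "Aa bb"))
  s <- rand_coding(100, seed = 2)
  lib <- barcode_library(meta, c(Z1 = s, Z2 = s), alignment = c(Z1 = s,
                                                                Z2 = s))
  out <- summarize_distances(distance_matrix(lib), lib, "species")
  expect_equal(out$n_comparisons, 1)
  expect_equal(c(out$min, out$mean, out$max), c(0, 0, 0))
  # no congeneric pairs exist at genus rank
  g <- summarize_distances(distance_matrix(lib), lib, "genus")
  expect_equal(g$n_comparisons, 0)
  expect_true(is.na(g$mean))
})

test_that("nearest neighbours match exhaustive search and report ties", {
  lib <- graded_fixture()
  dm <- distance_matrix(lib)
  nn <- nearest_neighbor(dm, lib)
  meta <- lib$meta
  for (r in seq_len(nrow(nn))) {
    s <- nn$species[r]
    inside <- which(meta$morpho_species == s)
    outside <- which(meta$morpho_species != s & meta$morpho_species != "")
    best <- min(dm$d[inside, outside])
    expect_equal(nn$nn_distance[r], best * 100, tolerance = 1e-12)
  }
  # symmetric two-species case
  m2 <- rbind(make_meta_row("P1", "Aa bb"), make_meta_row("P2", "Cc dd"))
  s1 <- rand_coding(200, seed = 4)
  s2 <- mutate_seq(s1, 20, seed = 5)
  lib2 <- barcode_library(m2, c(P1 = s1, P2 = s2),
                          alignment = c(P1 = s1, P2 = s2))
  nn2 <- nearest_neighbor(distance_matrix(lib2), lib2)
  expect_equal(nn2$nn_distance[1], nn2$nn_distance[2])
  expect_error(nearest_neighbor(distance_matrix(lib2),
                                rep("Aa bb", 2)), "at least 2")
})

test_that("distance matrices export to TSV and PHYLIP", {
  lib <- graded_fixture()
  dm <- distance_matrix(subset_library(lib, c("A1", "A2", "B1")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  phy <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(dm, tsv, "tsv")
  back <- read.delim(tsv)
  expect_equal(back$specimen_id, dm$ids)
  write_distance_matrix(dm, phy, "phylip")
  expect_equal(readLines(phy)[1], "3")
})
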