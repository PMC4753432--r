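# shared fixture: clusters with known composition
conc_fixture <- function() {
  base <- rand_coding(400, seed = 10)
  c1 <- base
  c2 <- mutate_seq(base, 30, seed = 11)
  c3 <- mutate_seq(base, 60, seed = 12)
  c4 <- mutate_seq(base, 90, seed = 13)
  meta <- rbind(
    make_meta_row("M1", "Phorcus lineatus"),
    make_meta_row("M2", "Osilinus lineatus", source = "external",
                  published = TRUE),
    make_meta_row("M3", "Phorcus lineatus"),
    make_meta_row("L1", "Littorina saxatilis"),
    make_meta_row("L2", "Littorina compressa", source = "external",
                  published = TRUE),
    make_meta_row("L3", "Littorina arcana", source = "external",
                  published = TRUE),
    make_meta_row("N1", "Nassarius incrassatus"),
    make_meta_row("N2", "Nassarius incrassatus"),
    make_meta_row("N3", "", genus = "Nassarius", qualifier = "sp"),
    make_meta_row("S1", "Siphonaria pectinata"))
  seqs <- c(M1 = c1, M2 = mutate_seq(c1, 1, seed = 21),
            M3 = mutate_seq(c1, 2, seed = 22),
            L1 = c2, L2 = mutate_seq(c2, 1, seed = 23),
            L3 = mutate_seq(c2, 2, seed = 24),
            N1 = c3, N2 = mutate_seq(c3, 1, seed = 25),
            N3 = mutate_seq(c3, 2, seed = 26),
            S1 = c4)
  lib <- barcode_library(meta, seqs, alignment = seqs)
  dm <- distance_matrix(lib)
  a <- motu_cluster(dm)
  list(lib = lib, dm = dm, a = a)
}

test_that("MOTUs classify as concordant, discordant or singleton", {
  fx <- conc_fixture()
  cl <- classify_motus(fx$a, fx$lib)
  expect_equal(attr(fx$a, "n_motus"), 4)
  status <- setNames(cl$status, cl$member_species)
  # Phorcus + Osilinus: two distinct names -> discordant (species rank;
  # same genus field differs) -- genus column differs so rank=genus
  disc <- cl[cl$status == "discordant", ]
  expect_equal(nrow(disc), 2)
  expect_equal(sum(cl$status == "singleton"), 1)
  expect_equal(sum(cl$status == "concordant"), 1)
  # genus-level member never makes its MOTU discordant
  nas <- cl[grepl("Nassarius", cl$member_species), ]
  expect_equal(nas$status, "concordant")
  expect_true(grepl("Nassarius sp\\.", nas$member_species))
  # partition invariant
  expect_equal(sum(cl$status %in% c("concordant", "discordant",
                                    "singleton")), nrow(cl))
  expect_equal(nrow(cl), attr(fx$a, "n_motus"))
})

test_that("discordance rank separates genus- from species-level conflicts", {
  fx <- conc_fixture()
  cl <- classify_motus(fx$a, fx$lib)
  m_rank <- setNames(cl$discordance_rank, cl$member_species)
  gen <- cl$discordance_rank[grepl("Osilinus", cl$member_species)]
  expect_equal(gen, "genus")
  sax <- cl$discordance_rank[grepl("saxatilis", cl$member_species)]
  expect_equal(sax, "species")
})

test_that("review reclassifies synonyms and confirms real conflicts", {
  fx <- conc_fixture()
  cl <- classify_motus(fx$a, fx$lib)
  syn <- data.frame(name = "Osilinus lineatus",
                    accepted_name = "Phorcus lineatus",
                    note = "accepted genus is Phorcus",
                    stringsAsFactors = FALSE)
  rv <- review_motus(cl, fx$a, fx$lib, syn)
  osi <- rv[grepl("Osilinus", rv$member_species), ]
  expect_equal(osi$review_status, "reclassified_concordant")
  expect_true(grepl("Osilinus lineatus -> Phorcus lineatus",
                    osi$review_reason))
  sax <- rv[grepl("saxatilis", rv$member_species), ]
  expect_equal(sax$review_status, "confirmed_discordant")
  # concordant and singleton MOTUs are untouched by review
  expect_true(all(rv$review_status[rv$status != "discordant"] ==
                    "as_reported"))
  # with no synonyms, nothing is reclassified
  rv0 <- review_motus(cl, fx$a, fx$lib, NULL)
  expect_true(all(rv0$review_status[rv0$status == "discordant"] ==
                    "confirmed_discordant"))

  s <- concordance_summary(rv)
  expect_equal(s$n_motus, 4)
  expect_equal(s$n_reclassified, 1)
  expect_equal(s$n_concordant_after_review, 3)  # 1 conc + 1 recl + 1 single
  expect_equal(s$pct_concordant, 75)
})

test_that("reference matching ranks hits by identity over the overlap", {
  fx <- conc_fixture()
  hits <- match_reference("M1", fx$lib, min_overlap = 100)
  expect_equal(hits$hit_id[1], "M2")
  expect_equal(hits$identity[1], 100 * (1 - 1 / 400))
  expect_true(all(diff(hits$identity) <= 0))
  expect_false("M1" %in% hits$hit_id)
  # worked example: 3 mismatches over 650 usable sites
  ref <- rand_coding(650, seed = 31)
  qry <- mutate_seq(ref, 3, seed = 32)
  lib2 <- barcode_library(rbind(make_meta_row("R1", "Aa bb")),
                          c(R1 = ref), alignment = c(R1 = ref))
  out <- match_reference(qry, lib2, min_overlap = 400)
  expect_equal(out$identity, 100 * (1 - 3 / 650), tolerance = 1e-9)
  # insufficient overlap yields an empty result, not an error
  short <- paste0(substr(ref, 1, 300), strrep("N", 350))
  expect_equal(nrow(match_reference(short, lib2, min_overlap = 400)), 0)
})

test_that("barcode-based identification propagates unambiguous names", {
  fx <- conc_fixture()
  cl <- review_motus(classify_motus(fx$a, fx$lib), fx$a, fx$lib, NULL)
  # Nassarius sp. sits in an otherwise pure N. incrassatus MOTU
  expect_equal(propagate_id("N3", fx$a, cl, fx$lib),
               "Nassarius incrassatus")
  # members of confirmed-discordant MOTUs get nothing
  meta2 <- rbind(fx$lib$meta,
                 make_meta_row("L4", "", genus = "Littorina",
                               qualifier = "sp"))
  seqs2 <- c(apply(fx$lib$alignment, 1, paste, collapse = ""),
             L4 = mutate_seq(fx$lib$seqs[["L1"]], 1, seed = 41))
  lib2 <- barcode_library(meta2, seqs2, alignment = seqs2)
  dm2 <- distance_matrix(lib2)
  a2 <- motu_cluster(dm2)
  cl2 <- review_motus(classify_motus(a2, lib2), a2, lib2, NULL)
  expect_true(is.na(propagate_id("L4", a2, cl2, lib2)))
  # a genus-inconsistent proposal is withheld
  meta3 <- rbind(fx$lib$meta[fx$lib$meta$specimen_id %in%
                               c("N1", "N2"), ],
                 make_meta_row("G9", "", genus = "Gibbula",
                               qualifier = "sp"))
  seqs3 <- c(N1 = fx$lib$seqs[["N1"]], N2 = fx$lib$seqs[["N2"]],
             G9 = mutate_seq(fx$lib$seqs[["N1"]], 1, seed = 42))
  lib3 <- barcode_library(meta3, seqs3, alignment = seqs3)
  a3 <- motu_cluster(distance_matrix(lib3))
  cl3 <- review_motus(classify_motus(a3, lib3), a3, lib3, NULL)
  expect_true(is.na(propagate_id("G9", a3, cl3, lib3)))
  # singletons propose nothing
  s1 <- fx$a$specimen_id[fx$a$motu_id ==
                           fx$a$motu_id[fx$a$specimen_id == "S1"]]
  expect_equal(s1, "S1")
  expect_true(is.na(propagate_id("S1", fx$a, cl, fx$lib)))
})

test_that("review arithmetic reproduces count bookkeeping", {
  s <- bin_report_summary(3, 2, 1, n_reclassified = 1)
  expect_equal(s$n_motus, 6)
  expect_equal(s$n_concordant_after_review, 5)
  expect_equal(s$pct_concordant, 100 * 5 / 6)
  s2 <- bin_report_summary(3, 2, 1, n_reclassified = 1,
                           singletons_as_concordant = FALSE)
  expect_equal(s2$n_concordant_after_review, 4)
  expect_error(bin_report_summary(3, 2, 1, n_reclassified = 3))
})
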