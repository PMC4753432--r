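test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_species = 5, specimens_per_species = c(4, 4),
                    intra_divergence = 0.5, inter_divergence = 8,
                    min_inter_frac = 0.6, seed = 1)
  s1 <- simulate_library(cfg)
  s2 <- simulate_library(cfg)
  expect_identical(s1$library$seqs, s2$library$seqs)
  expect_identical(s1$library$meta, s2$library$meta)
  expect_identical(s1$truth, s2$truth)
  # and different under another seed
  s3 <- simulate_library(sim_config(n_species = 5,
                                    specimens_per_species = c(4, 4),
                                    intra_divergence = 0.5,
                                    inter_divergence = 8,
                                    min_inter_frac = 0.6, seed = 2))
  expect_false(identical(s1$library$seqs, s3$library$seqs))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_species = 5, seed = 1,
                          intra_divergence = 9, inter_divergence = 8),
               "contradictory")
  expect_error(sim_config(n_species = 5, mislabel_rate = 2, seed = 1),
               "rates")
  expect_error(sim_config(n_species = 5), "seed")
})

test_that("simulated sequences honour the coding constraint", {
  sim <- simulate_library(sim_config(n_species = 6,
                                     specimens_per_species = c(3, 4),
                                     seed = 8))
  stops <- vapply(sim$library$seqs, function(s)
    translate_screen(s, frame = 1)$n_stops, numeric(1))
  expect_true(all(stops == 0))
  qc <- qc_library(sim$library)
  expect_true(all(qc$passed))
})

test_that("realized divergences are calibrated to the targets", {
  intra <- c()
  cong <- c()
  for (s in 1:12) {
    sim <- simulate_library(sim_config(n_species = 8,
                                       specimens_per_species = c(3, 3),
                                       intra_divergence = 1,
                                       inter_divergence = 13.32,
                                       seed = 400 + s))
    rs <- realized_stats(sim$library, sim$truth)
    intra <- c(intra, rs$intra_species_mean_pct)
    cong <- c(cong, rs$congeneric_mean_pct)
  }
  expect_lt(abs(mean(intra) - 1), 0.3)
  expect_lt(abs(mean(cong) - 13.32), 2)
})

test_that("zero intraspecific divergence gives zero realized intra", {
  sim <- simulate_library(sim_config(n_species = 4,
                                     specimens_per_species = c(3, 3),
                                     intra_divergence = 1e-9,
                                     inter_divergence = 8,
                                     min_inter_frac = 0.6, seed = 15))
  rs <- realized_stats(sim$library, sim$truth)
  expect_equal(rs$intra_species_mean_pct, 0, tolerance = 1e-6)
})

test_that("a wide barcode gap makes MOTUs coincide with true species", {
  skip_if_not_installed("mclust")
  for (s in 1:5) {
    sim <- simulate_library(sim_config(n_species = 6,
                                       specimens_per_species = c(3, 4),
                                       intra_divergence = 0.5,
                                       inter_divergence = 8,
                                       min_inter_frac = 0.6,
                                       seed = 500 + s))
    a <- motu_cluster(distance_matrix(sim$library))
    tt <- sim$truth[match(a$specimen_id, sim$truth$specimen_id), ]
    expect_equal(mclust::adjustedRandIndex(a$motu_id, tt$true_species), 1)
  }
})

test_that("cryptic splits create two lineages about 3x the threshold apart", {
  sim <- simulate_library(sim_config(n_species = 4,
                                     specimens_per_species = c(4, 4),
                                     intra_divergence = 0.3,
                                     inter_divergence = 12,
                                     min_inter_frac = 0.6,
                                     cryptic_split_rate = 1, seed = 16))
  expect_true(any(grepl("/L2", sim$truth$true_lineage)))
  dm <- distance_matrix(sim$library)
  tt <- sim$truth[match(dm$ids, sim$truth$specimen_id), ]
  for (sp in unique(tt$true_species)) {
    l1 <- which(tt$true_species == sp & grepl("/L1", tt$true_lineage))
    l2 <- which(tt$true_species == sp & grepl("/L2", tt$true_lineage))
    if (length(l1) && length(l2)) {
      between <- mean(dm$d[l1, l2])
      expect_gt(between, 0.022)            # splits exceed the threshold
      expect_lt(between, 0.15)
    }
  }
})

test_that("mislabelled records are flagged in the truth table", {
  sim <- simulate_library(sim_config(n_species = 6,
                                     specimens_per_species = c(3, 3),
                                     intra_divergence = 0.5,
                                     inter_divergence = 8,
                                     min_inter_frac = 0.6,
                                     mislabel_rate = 0.1, seed = 17))
  swapped <- sim$truth$specimen_id[sim$truth$mislabeled]
  expect_gte(length(swapped), 2)
  m <- sim$library$meta
  tt <- sim$truth
  for (id in swapped) {
    i <- match(id, m$specimen_id)
    expect_false(m$morpho_species[i] == tt$true_species[match(id,
                                                              tt$specimen_id)])
  }
})

test_that("injected indels change sequence lengths and are recorded", {
  sim <- simulate_library(sim_config(n_species = 4,
                                     specimens_per_species = c(3, 3),
                                     intra_divergence = 0.5,
                                     inter_divergence = 8,
                                     min_inter_frac = 0.6,
                                     indel_rate = 1, seed = 18))
  expect_null(sim$library$alignment)        # indels break the common frame
  expect_false(is.null(sim$library$anchor))
  tt <- sim$truth
  with_ev <- !is.na(tt$indel_kind)
  expect_true(any(with_ev))
  lens <- nchar(sim$library$seqs)[tt$specimen_id[with_ev]]
  kinds <- tt$indel_kind[with_ev]
  expect_true(all(lens[kinds == "insertion"] == 661))
  expect_true(all(lens[kinds == "deletion"] == 655))
  expect_true(all(tt$indel_end[with_ev] - tt$indel_start[with_ev] == 2))
})
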