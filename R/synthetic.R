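# Synthetic COI-5P barcode libraries with controlled divergence structure:
# a pure-birth species tree, K2P sequence evolution with a coding
# constraint (no in-frame stops), within-species star genealogies, and
# optional cryptic splits, mislabelled vouchers and 3-bp frame-preserving
# indels -- everything the audit stages need to be exercised end to end
# with known truth.

#' Configuration for a synthetic barcode library
#'
#' Defaults emulate a regional reference library: a few hundred records
#' over tens of morpho-species, mean intraspecific divergence below 1%,
#' congeneric divergence around 13% with the smallest species pairs near
#' 20% of that mean, roughly half the records contributed by external
#' (published) sources.
#'
#' @param n_species number of species (>= 2).
#' @param specimens_per_species inclusive range (length-2 integer) for the
#'   per-species specimen count.
#' @param seq_length barcode length in bp (default 658, the Folmer
#'   amplicon; >= 60).
#' @param kappa transition/transversion rate ratio of the K2P process
#'   (default 2).
#' @param intra_divergence target mean intraspecific K2P distance, in
#'   percent (default 0.8).
#' @param inter_divergence target mean congeneric (between species within
#'   a genus) K2P distance, in percent (default 13.32).
#' @param min_inter_frac floor on the smallest between-species divergence,
#'   as a fraction of `inter_divergence` (default 0.2). Raising it widens
#'   the barcode gap; the default reproduces a realistic regime in which
#'   the closest species pairs sit near the clustering threshold.
#' @param cryptic_split_rate probability a species is split into two deep
#'   lineages at ~3x the 2.2% clustering threshold (default 0).
#' @param mislabel_rate fraction of records whose species labels are
#'   swapped with a record of another species (default 0).
#' @param indel_rate probability a record receives one 3-bp
#'   frame-preserving indel (default 0).
#' @param external_fraction probability a record is marked
#'   `source=external`, `published=TRUE` (default 0.5).
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 34, specimens_per_species = c(2, 6),
                       seq_length = 658, kappa = 2,
                       intra_divergence = 0.8, inter_divergence = 13.32,
                       min_inter_frac = 0.2, cryptic_split_rate = 0,
                       mislabel_rate = 0, indel_rate = 0,
                       external_fraction = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_species >= 2, seq_length >= 60,
            length(specimens_per_species) == 2,
            specimens_per_species[1] >= 1,
            specimens_per_species[1] <= specimens_per_species[2],
            kappa > 0, min_inter_frac >= 0, min_inter_frac <= 1)
  rates <- c(cryptic_split_rate, mislabel_rate, indel_rate,
             external_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (intra_divergence >= inter_divergence)
    stop("contradictory targets: intraspecific divergence must be ",
         "below interspecific divergence")
  structure(list(n_species = as.integer(n_species),
                 specimens_per_species = as.integer(specimens_per_species),
                 seq_length = as.integer(seq_length), kappa = kappa,
                 intra_divergence = intra_divergence,
                 inter_divergence = inter_divergence,
                 min_inter_frac = min_inter_frac,
                 cryptic_split_rate = cryptic_split_rate,
                 mislabel_rate = mislabel_rate, indel_rate = indel_rate,
                 external_fraction = external_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# sample one element of x (safe for length-1 vectors)
.sample1 <- function(x) x[sample.int(length(x), 1L)]
# transition partner and the two transversion partners per base (A C G T)
TS_PARTNER <- c(3L, 4L, 1L, 2L)
TV1 <- c(2L, 1L, 2L, 1L)
TV2 <- c(4L, 3L, 4L, 3L)

# Evolve integer-coded sequence for distance t (substitutions/site) under
# K2P with the given kappa, using the exact transition probabilities.
.evolve_k2p_codes <- function(codes, t, kappa) {
  if (t <= 0) return(codes)
  bt <- t / (kappa + 2)
  at <- kappa * bt
  e4 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e4 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e4       # each of the two transversions
  r <- stats::runif(length(codes))
  out <- codes
  out[r < p_ts] <- TS_PARTNER[codes[r < p_ts]]
  sel <- r >= p_ts & r < p_ts + p_tv
  out[sel] <- TV1[codes[sel]]
  sel <- r >= p_ts + p_tv & r < p_ts + 2 * p_tv
  out[sel] <- TV2[codes[sel]]
  out
}

.codon_is_stop <- function(codes, starts) {
  s <- vapply(starts, function(p)
    paste(BASES[codes[p:(p + 2L)]], collapse = ""), character(1))
  s %in% c("TAA", "TAG")
}

# Evolve with the coding constraint: any frame-1 codon that becomes a stop
# (TAA/TAG under the invertebrate mitochondrial code) is re-evolved from
# the parent codon; after 20 failed draws it reverts to the parent codon.
.evolve_coding <- function(codes, t, kappa) {
  child <- .evolve_k2p_codes(codes, t, kappa)
  n_cod <- length(codes) %/% 3L
  if (n_cod == 0L) return(child)
  starts <- seq.int(1L, by = 3L, length.out = n_cod)
  bad <- starts[.codon_is_stop(child, starts)]
  for (p in bad) {
    idx <- p:(p + 2L)
    ok <- FALSE
    for (try in 1:20) {
      cand <- .evolve_k2p_codes(codes[idx], t, kappa)
      if (!.codon_is_stop(cand, 1L)[1]) {
        child[idx] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) child[idx] <- codes[idx]
  }
  child
}

.random_coding_root <- function(L) {
  code <- invertebrate_mito_code()
  cods <- names(code)[code != "*"]
  s <- paste(sample(cods, ceiling(L / 3), replace = TRUE), collapse = "")
  codes <- match(strsplit(substr(s, 1, L), "")[[1]], BASES)
  as.integer(codes)
}

# Species tree: pure-birth topology, branch lengths rescaled so the mean
# within-genus between-species path length equals the congeneric target
# minus the intraspecific contribution (specimen pairs add one terminal
# intraspecific branch on each side), then terminal branches lengthened
# until no species pair is closer than the floor.
.species_tree <- function(n_species, inter_d, min_inter_frac,
                          intra_d = 0) {
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  coph <- ape::cophenetic.phylo(tr)
  hc <- stats::hclust(stats::as.dist(coph), method = "average")
  k_gen <- max(1L, ceiling(n_species / 3))
  k_fam <- max(1L, ceiling(k_gen / 2))
  genus <- stats::cutree(hc, k = k_gen)[tr$tip.label]
  family <- stats::cutree(hc, k = k_fam)[tr$tip.label]
  same_gen <- outer(genus[rownames(coph)], genus[colnames(coph)], "==") &
    upper.tri(coph)
  base <- if (any(same_gen)) mean(coph[same_gen]) else
    mean(coph[upper.tri(coph)])
  f <- (max(inter_d - intra_d, inter_d / 2) / 100) / base
  tr$edge.length <- tr$edge.length * f
  floor_d <- min_inter_frac * inter_d / 100
  term_edge <- match(seq_len(n_species), tr$edge[, 2])
  for (iter in 1:100) {
    coph <- ape::cophenetic.phylo(tr)
    off <- which(coph < floor_d - 1e-12 & upper.tri(coph), arr.ind = TRUE)
    if (!nrow(off)) break
    i <- match(rownames(coph)[off[1, 1]], tr$tip.label)
    j <- match(colnames(coph)[off[1, 2]], tr$tip.label)
    add <- (floor_d - coph[off[1, 1], off[1, 2]]) / 2
    tr$edge.length[term_edge[i]] <- tr$edge.length[term_edge[i]] + add
    tr$edge.length[term_edge[j]] <- tr$edge.length[term_edge[j]] + add
  }
  list(tree = tr, genus = genus, family = family)
}

# Preorder traversal evolving one coding sequence per node.
.evolve_tree <- function(tr, root_codes, kappa) {
  tr <- ape::reorder.phylo(tr, "cladewise")
  n_tip <- length(tr$tip.label)
  seqs <- vector("list", n_tip + tr$Nnode)
  seqs[[n_tip + 1L]] <- root_codes
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    chd <- tr$edge[e, 2]
    seqs[[chd]] <- .evolve_coding(seqs[[par]], tr$edge.length[e], kappa)
  }
  stats::setNames(seqs[seq_len(n_tip)], tr$tip.label)
}

# Inject one codon-aligned 3-bp indel and report its coordinates in the
# canonical (leftmost best-matching placement) convention shared with
# detect_indels -- relative to a diverged reference an indel's position is
# only defined up to alignment, so the truth is recorded in the same
# normalized coordinate frame the detector reports.
.inject_indel <- function(seq_chars, root_chars) {
  L <- length(seq_chars)
  n_cod <- L %/% 3L
  kind <- if (stats::runif(1) < 0.5) "insertion" else "deletion"
  c_idx <- .sample1(10:(n_cod - 10))        # keep events off the ends
  if (kind == "insertion") {
    p <- 3L * c_idx                          # insert after position p
    motif <- strsplit(sample(c("TTG", "GGG", "GGA"), 1), "")[[1]]
    new <- c(seq_chars[1:p], motif, seq_chars[(p + 1L):L])
    qa <- new
    ra <- append(root_chars, rep("-", 3L), after = p)
    opt <- .reoptimize_gap_run(qa, ra, p + 1L, p + 3L, "insertion")
    list(seq = new, kind = "insertion", start = opt$start, end = opt$end,
         motif = opt$motif)
  } else {
    s <- 3L * c_idx + 1L                     # delete one full codon
    new <- seq_chars[-(s:(s + 2L))]
    qa <- seq_chars
    qa[s:(s + 2L)] <- "-"
    opt <- .reoptimize_gap_run(qa, root_chars, s, s + 2L, "deletion")
    list(seq = new, kind = "deletion", start = opt$start, end = opt$end,
         motif = "")
  }
}

#' Simulate a barcode library with known truth
#'
#' See [sim_config()] for the model: pure-birth species tree, K2P
#' substitution process with exact per-branch transition probabilities and
#' a no-stop coding constraint, star genealogies within species, optional
#' cryptic splits (two lineages at ~3x the 2.2% threshold), label swaps
#' and codon-aligned 3-bp indels. Fully deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list with `library` (a [barcode_library()]; aligned when no
#'   indels were injected, otherwise carrying the reference anchor for
#'   [align_to_anchor()]) and `truth` (data.frame `specimen_id`,
#'   `true_species`, `true_genus`, `true_family`, `true_lineage`,
#'   `mislabeled`, `indel_kind`, `indel_start`, `indel_end`,
#'   `indel_motif`).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$seq_length
  st <- .species_tree(config$n_species, config$inter_divergence,
                      config$min_inter_frac, config$intra_divergence)
  tr <- st$tree
  root_codes <- .random_coding_root(L)
  root_chars <- BASES[root_codes]
  tip_seqs <- .evolve_tree(tr, root_codes, config$kappa)

  genus_names <- sprintf("Genus%02d", st$genus)
  family_names <- sprintf("Familia%02d", st$family)
  sp_names <- paste0(genus_names, " species", sprintf("%02d",
                                                      seq_len(config$n_species)))

  meta <- list()
  seqs <- list()
  truth <- list()
  rec <- 0L
  split_threshold_branch <- 1.5 * 0.022   # lineage pair diverges ~3x 2.2%
  for (s in seq_len(config$n_species)) {
    base_codes <- tip_seqs[[tr$tip.label[s]]]
    lineages <- list(L1 = base_codes)
    if (stats::runif(1) < config$cryptic_split_rate) {
      lineages <- list(
        L1 = .evolve_coding(base_codes, split_threshold_branch,
                            config$kappa),
        L2 = .evolve_coding(base_codes, split_threshold_branch,
                            config$kappa))
    }
    n_i <- .sample1(config$specimens_per_species[1]:
                      config$specimens_per_species[2])
    lin_of <- if (length(lineages) == 2)
      c("L1", "L2", sample(names(lineages), max(0L, n_i - 2L),
                           replace = TRUE))[seq_len(n_i)]
    else rep("L1", n_i)
    for (k in seq_len(n_i)) {
      rec <- rec + 1L
      branch <- (config$intra_divergence / 100 / 2) *
        stats::runif(1, 0.5, 1.5)
      codes <- .evolve_coding(lineages[[lin_of[k]]], branch, config$kappa)
      id <- sprintf("SP%04d", rec)
      is_ext <- stats::runif(1) < config$external_fraction
      meta[[rec]] <- data.frame(
        specimen_id = id, morpho_species = sp_names[s],
        genus = genus_names[s], family = family_names[s],
        qualifier = "none",
        locality = sample(c("North shore", "Central shore", "South shore",
                            "Island A", "Island B"), 1),
        source = if (is_ext) "external" else "own",
        published = is_ext, stringsAsFactors = FALSE)
      seqs[[rec]] <- BASES[codes]
      truth[[rec]] <- data.frame(
        specimen_id = id, true_species = sp_names[s],
        true_genus = genus_names[s], true_family = family_names[s],
        true_lineage = paste0(sp_names[s], "/", lin_of[k]),
        mislabeled = FALSE, indel_kind = NA_character_,
        indel_start = NA_integer_, indel_end = NA_integer_,
        indel_motif = NA_character_, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  truth <- do.call(rbind, truth)

  # label swaps between records of different species
  if (config$mislabel_rate > 0) {
    n_pairs <- max(1L, round(config$mislabel_rate * rec / 2))
    for (p in seq_len(n_pairs)) {
      i <- .sample1(seq_len(rec))
      cand <- which(truth$true_species != truth$true_species[i])
      if (!length(cand)) break
      j <- .sample1(cand)
      cols <- c("morpho_species", "genus", "family")
      tmp <- meta[i, cols]
      meta[i, cols] <- meta[j, cols]
      meta[j, cols] <- tmp
      truth$mislabeled[c(i, j)] <- TRUE
    }
  }

  # codon-aligned 3-bp indels (frame-preserving, as in Lottiidae COI)
  has_indel <- stats::runif(rec) < config$indel_rate
  for (i in which(has_indel)) {
    ev <- .inject_indel(seqs[[i]], root_chars)
    seqs[[i]] <- ev$seq
    truth$indel_kind[i] <- ev$kind
    truth$indel_start[i] <- ev$start
    truth$indel_end[i] <- ev$end
    truth$indel_motif[i] <- ev$motif
  }

  seq_strings <- stats::setNames(
    vapply(seqs, paste, character(1), collapse = ""), meta$specimen_id)
  aligned <- !any(has_indel)
  lib <- barcode_library(meta, seq_strings,
                         alignment = if (aligned) seq_strings,
                         anchor = paste(root_chars, collapse = ""))
  list(library = lib, truth = truth)
}

#' Realized divergence statistics of a simulated library
#'
#' Reports the realized K2P structure against the generator's targets:
#' mean within-lineage and within-species distance, mean congeneric
#' (between species within a genus) distance, and the minimum
#' between-species distance. All in percent, using the truth labels (so
#' mislabels do not distort calibration).
#'
#' @param library the simulated [barcode_library()].
#' @param truth the matching truth table.
#' @return list `intra_lineage_mean_pct`, `intra_species_mean_pct`,
#'   `congeneric_mean_pct`, `min_interspecific_pct`.
#' @export
realized_stats <- function(library, truth) {
  if (is.null(library$alignment)) library <- align_to_anchor(library)
  dm <- distance_matrix(library)
  tt <- truth[match(dm$ids, truth$specimen_id), ]
  ut <- upper.tri(dm$d)
  same_lin <- outer(tt$true_lineage, tt$true_lineage, "==") & ut
  same_sp <- outer(tt$true_species, tt$true_species, "==") & ut
  cong <- outer(tt$true_genus, tt$true_genus, "==") & !same_sp & ut
  inter <- !same_sp & ut
  mean_pct <- function(m) if (any(m)) 100 * mean(dm$d[m], na.rm = TRUE)
    else NA_real_
  list(intra_lineage_mean_pct = mean_pct(same_lin),
       intra_species_mean_pct = mean_pct(same_sp),
       congeneric_mean_pct = mean_pct(cong),
       min_interspecific_pct = if (any(inter))
         100 * min(dm$d[inter], na.rm = TRUE) else NA_real_)
}
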