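# Sequence vetting: translation screen against the invertebrate
# mitochondrial code, BOLD-style compliance flags, and indel detection in
# Folmer (reference) coordinates.

#' Invertebrate mitochondrial genetic code
#'
#' NCBI translation table 5, in which TAA/TAG are the only stop codons and
#' AGA/AGG encode serine (they are stops in the standard code) -- the
#' relevant code for metazoan COI barcodes.
#'
#' @return named character vector mapping codons to amino acids.
#' @export
invertebrate_mito_code <- function() {
  Biostrings::getGeneticCode("5")
}

#' Translate a barcode sequence and report in-frame stop codons
#'
#' The screen used to flag putative pseudogenes (NUMTs) and sequencing
#' artefacts: a genuine protein-coding mitochondrial barcode translates
#' without stops. Codons containing ambiguity codes or gaps translate to
#' `X` and are never counted as stops.
#'
#' @param sequence DNA string (gaps are removed before translation).
#' @param frame reading frame 1, 2 or 3, or `NULL` to pick the frame with
#'   the fewest stops (ties broken by the lowest frame number).
#' @param code genetic code table; defaults to [invertebrate_mito_code()].
#' @return list with `frame`, `n_stops`, `stop_positions` (1-based
#'   nucleotide position of each stop codon's first base), and `protein`.
#' @export
translate_screen <- function(sequence, frame = NULL,
                             code = invertebrate_mito_code()) {
  seq <- gsub("-", "", toupper(sequence), fixed = TRUE)
  if (nchar(seq) < 3)
    return(list(frame = 1L, n_stops = 0L, stop_positions = integer(),
                protein = "", translatable = FALSE))
  one <- function(f) {
    s <- substring(seq, f)
    n_cod <- nchar(s) %/% 3
    if (n_cod == 0)
      return(list(frame = f, n_stops = 0L, stop_positions = integer(),
                  protein = "", translatable = FALSE))
    starts <- seq.int(1L, by = 3L, length.out = n_cod)
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    stops <- which(aa == "*")
    list(frame = f, n_stops = length(stops),
         stop_positions = as.integer(starts[stops] + f - 1L),
         protein = paste(aa, collapse = ""), translatable = TRUE)
  }
  if (!is.null(frame)) {
    stopifnot(frame %in% 1:3)
    return(one(as.integer(frame)))
  }
  cands <- lapply(1:3, one)
  cands[[which.min(vapply(cands, `[[`, integer(1), "n_stops"))]]
}

#' Check a single sequence for barcode compliance
#'
#' Mirrors the minimum standards a sequence must meet to count as a full
#' barcode record: long enough, few ambiguities, and a clean translation.
#'
#' @param sequence DNA string (may contain gaps, which are ignored).
#' @param min_len minimum ungapped length in bp (default 500).
#' @param max_ambig_frac maximum tolerated fraction of `N` sites
#'   (default 0.01; the flag fires at or above this fraction).
#' @param code genetic code for the translation screen.
#' @return list with `passed`, `flags` (character vector drawn from
#'   `too_short`, `excess_ambiguity`, `stop_codon`, `not_translatable`),
#'   and `details` (named list of 1-based positions per flag).
#' @export
compliance_check <- function(sequence, min_len = 500,
                             max_ambig_frac = 0.01,
                             code = invertebrate_mito_code()) {
  seq <- gsub("-", "", toupper(sequence), fixed = TRUE)
  flags <- character()
  details <- list()
  len <- nchar(seq)
  if (len < min_len) flags <- c(flags, "too_short")
  n_amb <- lengths(regmatches(seq, gregexpr("N", seq, fixed = TRUE)))
  if (len > 0 && n_amb / len >= max_ambig_frac) {
    flags <- c(flags, "excess_ambiguity")
    details$excess_ambiguity <- gregexpr("N", seq, fixed = TRUE)[[1]]
  }
  tr <- translate_screen(seq, code = code)
  if (!isTRUE(tr$translatable)) {
    flags <- c(flags, "not_translatable")
  } else if (tr$n_stops > 0) {
    flags <- c(flags, "stop_codon")
    details$stop_codon <- tr$stop_positions
  }
  list(passed = length(flags) == 0, flags = flags, details = details,
       frame = tr$frame)
}

#' QC an entire library
#'
#' Runs [compliance_check()] on every record; when the library carries a
#' Folmer reference anchor (or one is supplied) each record is also
#' anchor-aligned and frame-disrupting indels add a `frameshift` flag.
#'
#' @param library a [barcode_library()].
#' @param min_len,max_ambig_frac see [compliance_check()].
#' @param reference optional gap-free Folmer reference; defaults to the
#'   library anchor if present.
#' @return data.frame (`specimen_id`, `passed`, `flags`, `n_stops`,
#'   `frame`) with the per-record indel events, if screened, in attribute
#'   `"indels"`.
#' @export
qc_library <- function(library, min_len = 500, max_ambig_frac = 0.01,
                       reference = NULL) {
  stopifnot(inherits(library, "barcode_library"))
  reference <- reference %||% library$anchor
  ids <- library$meta$specimen_id
  rows <- vector("list", length(ids))
  indels <- list()
  for (i in seq_along(ids)) {
    cc <- compliance_check(library$seqs[[i]], min_len, max_ambig_frac)
    flags <- cc$flags
    if (!is.null(reference)) {
      aln <- try(anchor_align(library$seqs[[i]], reference), silent = TRUE)
      if (inherits(aln, "try-error")) {
        flags <- c(flags, "not_alignable")
      } else {
        ev <- detect_indels(aln, specimen_id = ids[i])
        if (nrow(ev)) indels[[ids[i]]] <- ev
        if (nrow(ev) && any(!ev$frame_preserving))
          flags <- c(flags, "frameshift")
      }
    }
    rows[[i]] <- data.frame(specimen_id = ids[i],
                            passed = length(flags) == 0,
                            flags = paste(flags, collapse = ";"),
                            n_stops = if ("stop_codon" %in% flags)
                              length(cc$details$stop_codon) else 0L,
                            frame = cc$frame,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "indels") <- if (length(indels))
    do.call(rbind, c(indels, make.row.names = FALSE)) else NULL
  out
}

#' Globally align a query to the Folmer reference anchor
#'
#' Needleman-Wunsch global alignment (via Biostrings) of one barcode
#' against a gap-free reference, giving the coordinate frame in which
#' indels are reported (1-based reference positions 1..658 for a full
#' Folmer amplicon).
#'
#' @param query DNA string.
#' @param reference gap-free reference DNA string.
#' @param match,mismatch,gap_open,gap_extend alignment scores
#'   (defaults 1, -1, -5, -2).
#' @return list of class `anchor_alignment` with aligned `query` and
#'   `reference` rows, percent `identity` over mutually ungapped columns,
#'   and `map`, an integer vector giving for each ungapped query position
#'   its reference coordinate (`NA` inside insertions).
#' @export
anchor_align <- function(query, reference, match = 1, mismatch = -1,
                         gap_open = -5, gap_extend = -2) {
  query <- gsub("-", "", toupper(query), fixed = TRUE)
  reference <- toupper(reference)
  lets <- setdiff(IUPAC_DNA, "-")
  sm <- matrix(mismatch, length(lets), length(lets),
               dimnames = list(lets, lets))
  diag(sm) <- match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = sm,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- qa != "-" & ra != "-"
  identity <- if (any(both)) 100 * mean(qa[both] == ra[both]) else 0
  if (identity < 50)
    stop("not homologous to anchor (identity ",
         sprintf("%.1f", identity), "%)")
  refpos <- cumsum(ra != "-")
  map <- ifelse(ra[qa != "-"] == "-", NA_integer_,
                refpos[qa != "-"])
  structure(list(query = paste(qa, collapse = ""),
                 reference = paste(ra, collapse = ""),
                 identity = identity, map = as.integer(map)),
            class = "anchor_alignment")
}

# Left-normalize an indel so that equivalent gap placements get canonical
# coordinates (an insertion is shifted left while the reference base before
# it equals the last base of the inserted motif; a deletion likewise).
.left_normalize_indel <- function(kind, start, motif, ref_chars) {
  L <- nchar(motif)
  m <- strsplit(motif, "")[[1]]
  if (kind == "insertion") {
    p <- start - 1L                       # insertion sits after ref pos p
    while (p >= 1L && ref_chars[p] == m[L]) {
      m <- c(m[L], m[-L])
      p <- p - 1L
    }
    list(start = p + 1L, end = p + L, motif = paste(m, collapse = ""))
  } else {
    s <- start
    e <- start + L - 1L
    while (s > 1L && ref_chars[s - 1L] == ref_chars[e]) {
      s <- s - 1L
      e <- e - 1L
    }
    list(start = s, end = e, motif = "")
  }
}

# Re-optimize one gap run's placement inside a local window: among all
# placements of the run within the window, keep the one maximizing the
# number of matching flanking sites, breaking ties by the leftmost
# position. Global alignment fixes the run's existence and length but can
# park score-equivalent gaps anywhere inside an ambiguity region; this
# makes the reported coordinate canonical (and rotation-equivalent
# insertions resolve to their left-normalized form).
.reoptimize_gap_run <- function(qa, ra, run_start, run_end, kind,
                                window = 10L) {
  n_col <- length(qa)
  L <- run_end - run_start + 1L
  gap_row <- if (kind == "insertion") ra else qa
  other_gaps <- which(gap_row == "-" | (qa == "-" & ra == "-") |
                        (if (kind == "insertion") qa else ra) == "-")
  other_gaps <- setdiff(other_gaps, run_start:run_end)
  lo <- max(c(1L, other_gaps[other_gaps < run_start] + 1L))
  hi <- min(c(n_col, other_gaps[other_gaps > run_end] - 1L))
  wstart <- max(lo, run_start - window)
  wend <- min(hi, run_end + window)
  cols <- wstart:wend
  qseg <- qa[cols][qa[cols] != "-"]
  rseg <- ra[cols][ra[cols] != "-"]
  ref_before <- sum(ra[seq_len(wstart - 1L)] != "-")
  if (kind == "insertion") {
    R <- length(rseg)                     # qseg has R + L chars
    m0 <- if (R) cumsum(qseg[seq_len(R)] == rseg) else integer()
    mL <- if (R) cumsum(qseg[L + seq_len(R)] == rseg) else integer()
    score <- vapply(0:R, function(k) {
      pre <- if (k > 0) m0[k] else 0L
      post <- if (k < R) mL[R] - (if (k > 0) mL[k] else 0L) else 0L
      pre + post
    }, numeric(1))
    k <- which.max(score) - 1L            # leftmost maximum
    list(start = ref_before + k + 1L, end = ref_before + k + L,
         motif = paste(qseg[k + seq_len(L)], collapse = ""))
  } else {
    Qn <- length(qseg)                    # rseg has Qn + L chars
    m0 <- if (Qn) cumsum(qseg == rseg[seq_len(Qn)]) else integer()
    mL <- if (Qn) cumsum(qseg == rseg[L + seq_len(Qn)]) else integer()
    score <- vapply(0:Qn, function(k) {
      pre <- if (k > 0) m0[k] else 0L
      post <- if (k < Qn) mL[Qn] - (if (k > 0) mL[k] else 0L) else 0L
      pre + post
    }, numeric(1))
    k <- which.max(score) - 1L
    list(start = ref_before + k + 1L, end = ref_before + k + L,
         motif = "")
  }
}

#' Detect indels from an anchored alignment
#'
#' Converts maximal gap runs in an [anchor_align()] result into indel
#' events with 1-based inclusive reference (Folmer) coordinates. An
#' insertion of length L after reference position p is reported as
#' occupying p+1..p+L. Each run's placement is locally re-optimized
#' (most matching flanks, leftmost on ties) so score-equivalent gap
#' placements yield identical, left-normalized coordinates. Events whose
#' length is a multiple of 3 preserve the reading frame.
#'
#' @param alignment an `anchor_alignment`.
#' @param specimen_id id recorded on each event.
#' @return data.frame with columns `specimen_id`, `kind`
#'   (`insertion`/`deletion`), `start`, `end`, `length`,
#'   `inserted_motif`, `frame_preserving`.
#' @export
detect_indels <- function(alignment, specimen_id = NA_character_) {
  stopifnot(inherits(alignment, "anchor_alignment"))
  qa <- strsplit(alignment$query, "")[[1]]
  ra <- strsplit(alignment$reference, "")[[1]]
  events <- list()
  add_runs <- function(is_gap, kind) {
    r <- rle(is_gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      L <- r$lengths[k]
      opt <- .reoptimize_gap_run(qa, ra, starts[k], ends[k], kind)
      events[[length(events) + 1L]] <- data.frame(
        specimen_id = specimen_id, kind = kind,
        start = opt$start, end = opt$end, length = L,
        inserted_motif = opt$motif,
        frame_preserving = L %% 3L == 0L, stringsAsFactors = FALSE)
    }
    events
  }
  events <- add_runs(ra == "-", "insertion")
  events <- add_runs(qa == "-", "deletion")
  if (!length(events))
    return(data.frame(specimen_id = character(), kind = character(),
                      start = integer(), end = integer(), length = integer(),
                      inserted_motif = character(),
                      frame_preserving = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, events)
  out[order(out$start), , drop = FALSE]
}

#' Project a library onto its Folmer reference anchor
#'
#' Anchor-aligns every record and rebuilds the library alignment in
#' reference coordinates: each row holds the query base at reference
#' positions 1..L (gaps where the record is deleted or missing); inserted
#' bases fall outside the reference frame and are recorded as indel events
#' in attribute `"indels"` of the returned library.
#'
#' @param library a [barcode_library()] with an anchor (or pass
#'   `reference`).
#' @param reference optional gap-free reference overriding the anchor.
#' @return the library with `$alignment` set (n x nchar(reference)).
#' @export
align_to_anchor <- function(library, reference = NULL) {
  stopifnot(inherits(library, "barcode_library"))
  reference <- reference %||% library$anchor
  if (is.null(reference))
    stop("no reference anchor available")
  L <- nchar(reference)
  ids <- library$meta$specimen_id
  aln <- matrix("-", nrow = length(ids), ncol = L,
                dimnames = list(ids, NULL))
  indels <- list()
  for (i in seq_along(ids)) {
    pa <- anchor_align(library$seqs[[i]], reference)
    qa <- strsplit(pa$query, "")[[1]]
    ra <- strsplit(pa$reference, "")[[1]]
    refpos <- cumsum(ra != "-")
    keep <- ra != "-"
    aln[i, refpos[keep]] <- qa[keep]
    ev <- detect_indels(pa, specimen_id = ids[i])
    if (nrow(ev)) indels[[ids[i]]] <- ev
  }
  library$alignment <- aln
  library$anchor <- toupper(reference)
  attr(library, "indels") <- if (length(indels))
    do.call(rbind, c(indels, make.row.names = FALSE)) else NULL
  library
}

#' Mean amino-acid divergence from the library consensus
#'
#' Reported metric (no pass/fail threshold) for spotting unusually
#' divergent amino-acid profiles: each record's best-frame translation is
#' compared to the positional consensus by p-distance.
#'
#' @param library an aligned [barcode_library()].
#' @return data.frame `specimen_id`, `aa_pdist_to_consensus`.
#' @export
aa_profile_divergence <- function(library) {
  stopifnot(inherits(library, "barcode_library"),
            !is.null(library$alignment))
  seqs <- apply(library$alignment, 1, paste, collapse = "")
  prot <- vapply(seqs, function(s) translate_screen(s)$protein,
                 character(1))
  n <- max(nchar(prot))
  pm <- do.call(rbind, lapply(prot, function(p) {
    ch <- strsplit(p, "")[[1]]
    length(ch) <- n
    ch
  }))
  cons <- apply(pm, 2, function(col) {
    col <- col[!is.na(col) & col != "X"]
    if (!length(col)) NA_character_ else names(sort(table(col),
                                                    decreasing = TRUE))[1]
  })
  d <- apply(pm, 1, function(row) {
    ok <- !is.na(row) & !is.na(cons) & row != "X"
    if (!any(ok)) NA_real_ else mean(row[ok] != cons[ok])
  })
  data.frame(specimen_id = library$meta$specimen_id,
             aa_pdist_to_consensus = unname(d),
             stringsAsFactors = FALSE)
}
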