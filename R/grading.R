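# Per-species A-E reliability grading of barcode records.
#
# A: external concordance -- own records share one MOTU with same-named
#    records from other sources, and every record of that name is there.
# B: internal concordance -- a single MOTU, >= 3 own specimens, no
#    external records of the name to compare against.
# C: sub-optimal concordance -- >= 3 own specimens split over > 1 MOTU
#    (possible genetic structure).
# D: insufficient data -- 1-2 own specimens and no external match.
# E: discordant -- own records co-cluster with records of a different
#    accepted name, or fail to co-cluster with same-named external
#    records present elsewhere.
#
# Decision order E > C > A > B > D; D is the documented fallback for
# combinations the rules leave open.

#' Grade one morpho-species
#'
#' @param species accepted morpho-species name.
#' @param assignment a `motu_assignment` covering the library.
#' @param library the [barcode_library()] (names assumed already resolved
#'   to accepted names; see [apply_synonyms()]).
#' @return one-row data.frame: `species`, `grade`, `n_specimens_own`,
#'   `n_motus_occupied`, `has_external_match`, `rationale`.
#' @export
grade_species <- function(species, assignment, library) {
  stopifnot(inherits(assignment, "motu_assignment"),
            inherits(library, "barcode_library"))
  meta <- library$meta
  motu_of <- stats::setNames(assignment$motu_id, assignment$specimen_id)
  own <- meta$specimen_id[meta$source == "own" &
                            meta$morpho_species == species]
  if (!length(own))
    stop("species '", species, "' has no own records to grade")
  own_motus <- unique(unname(motu_of[own]))
  n_own <- length(own)
  ext_same <- meta$specimen_id[meta$source == "external" &
                                 meta$morpho_species == species]
  ext_motus <- unique(unname(motu_of[ext_same]))
  shares_ext <- length(intersect(own_motus, ext_motus)) > 0

  # counted members of the own MOTUs that carry a different species name
  conflict <- FALSE
  for (m in own_motus) {
    ids <- assignment$specimen_id[assignment$motu_id == m]
    mm <- meta[match(ids, meta$specimen_id), , drop = FALSE]
    counted <- mm$qualifier == "none" & mm$morpho_species != ""
    if (any(counted & mm$morpho_species != species)) conflict <- TRUE
  }
  misses_ext <- length(ext_same) > 0 && !shares_ext

  grade <- NULL
  rationale <- NULL
  if (conflict || misses_ext) {
    grade <- "E"
    rationale <- if (conflict)
      "own records co-cluster with records of a different accepted name"
    else
      "same-named external records occupy only non-shared MOTUs"
  } else if (n_own >= 3 && length(own_motus) > 1) {
    grade <- "C"
    rationale <- paste0(">= 3 own specimens split over ",
                        length(own_motus), " MOTUs")
  } else if (length(ext_same) > 0 && shares_ext &&
             length(unique(unname(motu_of[c(own, ext_same)]))) == 1) {
    grade <- "A"
    rationale <- "all own and external records of the name share one MOTU"
  } else if (length(own_motus) == 1 && n_own >= 3 &&
             length(ext_same) == 0) {
    grade <- "B"
    rationale <- ">= 3 own specimens in a single MOTU, no external records"
  } else {
    grade <- "D"
    rationale <- if (n_own <= 2 && length(ext_same) == 0)
      "1-2 own specimens and no matching external sequence"
    else
      "insufficient or ambiguous data (fallback)"
  }
  data.frame(species = species, grade = grade,
             n_specimens_own = n_own,
             n_motus_occupied = length(own_motus),
             has_external_match = shares_ext,
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Grade every morpho-species with own records
#'
#' @param library a [barcode_library()] (accepted names).
#' @param assignment a `motu_assignment`.
#' @return object of class `grade_table`: per-species data.frame as in
#'   [grade_species()], with attribute `"summary"` holding grade counts
#'   and the A+B percentage (see [grade_summary()]).
#' @export
grade_table <- function(library, assignment) {
  meta <- library$meta
  species <- sort(unique(meta$morpho_species[meta$source == "own" &
                                               meta$qualifier == "none" &
                                               meta$morpho_species != ""]))
  if (!length(species)) stop("no gradable species (no named own records)")
  out <- do.call(rbind, lapply(species, grade_species,
                               assignment = assignment, library = library))
  counts <- table(factor(out$grade, levels = c("A", "B", "C", "D", "E")))
  structure(out, class = c("grade_table", "data.frame"),
            summary = grade_summary(counts))
}

#' Summary arithmetic over grade counts
#'
#' @param counts named integer vector (or table) of grade counts with
#'   names among A-E.
#' @return list with `counts`, `n_species`, `pct_ab` (percentage of graded
#'   species scoring A or B, full precision) and `pct_d`.
#' @export
grade_summary <- function(counts) {
  counts <- stats::setNames(as.integer(counts), names(counts))
  full <- stats::setNames(integer(5), c("A", "B", "C", "D", "E"))
  full[names(counts)] <- counts
  n <- sum(full)
  list(counts = full, n_species = n,
       pct_ab = 100 * (full[["A"]] + full[["B"]]) / n,
       pct_d = 100 * full[["D"]] / n)
}

#' @export
print.grade_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat("grade_table:", s$n_species, "species; counts",
      paste(names(s$counts), s$counts, sep = "=", collapse = " "),
      sprintf("; A+B = %.1f%%\n", s$pct_ab))
  invisible(x)
}
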