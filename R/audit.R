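# One-call end-to-end audit: QC -> anchor alignment -> distances ->
# MOTU delimitation -> concordance review -> grading -> optional tree.

#' Run the full barcode-library audit
#'
#' Stages run in order: QC/compliance, anchor alignment (when the library
#' is unaligned and carries a reference anchor), synonym resolution, K2P
#' distance matrix and rank summaries (with the ambiguity exclusions
#' applied for the summary table), MOTU delimitation, concordance
#' classification and review, splitter listing, barcode-based
#' identification proposals for genus-level specimens, A-E grading, and
#' optionally an NJ phenogram with bootstrap support. Any stage failure
#' aborts with a stage-named error.
#'
#' @param library a [barcode_library()].
#' @param threshold MOTU clustering threshold (proportion; default 0.022).
#' @param synonyms optional synonym table (see [read_synonyms()]).
#' @param invalid_names species names excluded from distance summaries.
#' @param min_len,max_ambig_frac QC thresholds (see [compliance_check()]).
#' @param drop_noncompliant drop records failing QC before analysis
#'   (default `FALSE`: they are reported but retained).
#' @param tree build an NJ phenogram (default `FALSE`).
#' @param bootstrap bootstrap replicates for the tree (0 = none).
#' @param seed RNG seed used by the bootstrap.
#' @param singletons_as_concordant see [concordance_summary()].
#' @return object of class `audit_report`: list with elements `qc`,
#'   `distance_summary` (rank x statistics, exclusions applied),
#'   `nearest_neighbor`, `assignment`, `classes`, `concordance`,
#'   `splitters`, `propagated_ids`, `grades`, `grade_summary`, `tree`
#'   (or `NULL`) and `provenance`.
#' @export
run_audit <- function(library, threshold = 0.022, synonyms = NULL,
                      invalid_names = character(), min_len = 500,
                      max_ambig_frac = 0.01, drop_noncompliant = FALSE,
                      tree = FALSE, bootstrap = 0, seed = 1,
                      singletons_as_concordant = TRUE) {
  stopifnot(inherits(library, "barcode_library"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("audit stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  qc <- stage("qc", qc_library(library, min_len = min_len,
                               max_ambig_frac = max_ambig_frac))
  if (drop_noncompliant && any(!qc$passed))
    library <- stage("qc", subset_library(
      library, qc$specimen_id[qc$passed]))
  if (is.null(library$alignment))
    library <- stage("align", align_to_anchor(library))
  library <- stage("synonyms", apply_synonyms(library, synonyms))
  dm <- stage("distances", distance_matrix(library))
  excl <- stage("distances", exclusion_filter(library, invalid_names))
  dm_excl <- stage("distances", distance_matrix(excl))
  dist_summary <- stage("distances", do.call(rbind, lapply(
    c("species", "genus", "family"), function(r)
      suppressWarnings(summarize_distances(dm_excl, excl, r)))))
  nn <- stage("distances", {
    sp <- excl$meta$morpho_species
    if (length(unique(sp[sp != ""])) >= 2)
      nearest_neighbor(dm_excl, excl) else NULL
  })
  assignment <- stage("motu",
                      suppressWarnings(motu_cluster(dm, threshold)))
  classes <- stage("concordance", classify_motus(assignment, library))
  classes <- stage("concordance",
                   review_motus(classes, assignment, library, synonyms))
  conc <- stage("concordance",
                concordance_summary(classes, singletons_as_concordant))
  splitters <- stage("concordance",
                     splitter_report(assignment, library, dm))
  amb_ids <- library$meta$specimen_id[
    library$meta$qualifier %in% c("sp", "cf", "aff")]
  prop <- stage("concordance", if (length(amb_ids))
    data.frame(specimen_id = amb_ids,
               proposed_species = vapply(amb_ids, propagate_id,
                                         character(1),
                                         assignment = assignment,
                                         classes = classes,
                                         library = library,
                                         synonyms = synonyms),
               stringsAsFactors = FALSE)
    else NULL)
  grades <- stage("grading", grade_table(library, assignment))
  phen <- NULL
  if (tree) {
    phen <- stage("trees", if (bootstrap > 0)
      bootstrap_support(library, n_reps = bootstrap, seed = seed)
      else nj_phenogram(dm))
  }
  structure(list(
    qc = qc,
    distance_summary = dist_summary,
    nearest_neighbor = nn,
    assignment = assignment,
    classes = classes,
    concordance = conc,
    splitters = splitters,
    propagated_ids = prop,
    grades = grades,
    grade_summary = attr(grades, "summary"),
    tree = phen,
    provenance = list(
      n_records = nrow(library$meta),
      threshold = threshold, min_len = min_len,
      max_ambig_frac = max_ambig_frac, seed = seed,
      singletons_as_concordant = singletons_as_concordant,
      package_version = as.character(utils::packageVersion("barcodeAudit")))),
    class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Barcode library audit\n")
  cat("  records:            ", x$provenance$n_records, "\n")
  cat("  QC failures:        ", sum(!x$qc$passed), "\n")
  cat("  MOTUs (threshold ", x$provenance$threshold, "): ",
      x$concordance$n_motus, "\n", sep = "")
  cat(sprintf("  concordant after review: %d (%.1f%%)\n",
              x$concordance$n_concordant_after_review,
              x$concordance$pct_concordant))
  s <- x$grade_summary
  cat("  grades:             ",
      paste(names(s$counts), s$counts, sep = "=", collapse = " "),
      sprintf(" (A+B = %.1f%%)\n", s$pct_ab))
  invisible(x)
}

#' Write an audit report's tables to a directory
#'
#' Emits the standard artefacts: QC TSV, distance summary TSV, MOTU
#' assignment TSV, MOTU class report TSV, grade table TSV, a JSON summary
#' with full-precision percentages, and the newick tree when present.
#'
#' @param report an `audit_report`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_audit_report <- function(report, dir) {
  stopifnot(inherits(report, "audit_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) if (!is.null(df))
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(report$qc, "qc.tsv")
  tsv(report$distance_summary, "distance_summary.tsv")
  tsv(report$nearest_neighbor, "nearest_neighbor.tsv")
  tsv(as.data.frame(report$assignment), "motu_assignment.tsv")
  tsv(as.data.frame(report$classes), "motu_classes.tsv")
  tsv(report$splitters, "splitters.tsv")
  tsv(report$propagated_ids, "propagated_ids.tsv")
  tsv(as.data.frame(report$grades), "grades.tsv")
  summary_json <- list(
    concordance = report$concordance,
    grade_summary = list(
      counts = as.list(report$grade_summary$counts),
      n_species = report$grade_summary$n_species,
      pct_ab = report$grade_summary$pct_ab,
      pct_ab_rounded = round(report$grade_summary$pct_ab, 1)),
    provenance = report$provenance)
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$tree))
    write_phenogram(report$tree, file.path(dir, "phenogram.nwk"))
  invisible(dir)
}
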