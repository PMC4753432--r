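# MOTU-report semantics: concordant / discordant / singleton clusters,
# synonym-aware expert review, local reference matching, and barcode-based
# identification of genus-level specimens.

#' Classify each MOTU as concordant, discordant or singleton
#'
#' A singleton holds exactly one record; a discordant MOTU holds two or
#' more records carrying more than one distinct morpho-species name; all
#' other MOTUs are concordant. Records identified only to genus level
#' (qualifier `sp`/`cf`/`aff`) remain members but never enter the
#' distinct-name count, so they cannot make a MOTU discordant by
#' themselves. Discordance is ranked `genus` when the counted members span
#' more than one genus, else `species`.
#'
#' @param assignment a `motu_assignment` from [motu_cluster()].
#' @param library the [barcode_library()] the assignment covers.
#' @return object of class `motu_classes`: data.frame with `motu_id`,
#'   `n_members`, `status`, `discordance_rank`, `member_species`
#'   (`;`-joined multiset), `review_status`, `review_reason`.
#' @export
classify_motus <- function(assignment, library) {
  stopifnot(inherits(assignment, "motu_assignment"),
            inherits(library, "barcode_library"))
  meta <- library$meta[match(assignment$specimen_id,
                             library$meta$specimen_id), , drop = FALSE]
  if (anyNA(meta$specimen_id))
    stop("assignment contains ids not in the library")
  rows <- lapply(sort(unique(assignment$motu_id)), function(m) {
    in_m <- assignment$motu_id == m
    mm <- meta[in_m, , drop = FALSE]
    counted <- mm$qualifier == "none" & mm$morpho_species != ""
    names_counted <- unique(mm$morpho_species[counted])
    n <- nrow(mm)
    status <- if (n == 1) "singleton"
      else if (length(names_counted) > 1) "discordant"
      else "concordant"
    rank <- "none"
    if (status == "discordant") {
      genera <- unique(mm$genus[counted])
      rank <- if (length(genera) > 1) "genus" else "species"
    }
    member <- ifelse(mm$morpho_species != "", mm$morpho_species,
                     paste0(mm$genus, " ",
                            ifelse(mm$qualifier == "none", "sp",
                                   mm$qualifier), "."))
    data.frame(motu_id = m, n_members = n, status = status,
               discordance_rank = rank,
               member_species = paste(sort(member), collapse = ";"),
               review_status = "as_reported", review_reason = "",
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("motu_classes", "data.frame"))
}

#' Expert review of discordant MOTUs with a synonym table
#'
#' Re-evaluates every discordant MOTU after resolving names to their
#' accepted forms: a MOTU whose counted members collapse to a single
#' accepted name becomes `reclassified_concordant` (the triggering synonym
#' is recorded in `review_reason`); the rest are `confirmed_discordant`.
#' Concordant and singleton MOTUs are never changed.
#'
#' @param classes a `motu_classes` from [classify_motus()].
#' @param assignment the `motu_assignment` the classes came from.
#' @param library the [barcode_library()].
#' @param synonyms synonym table (see [read_synonyms()]); may be `NULL`.
#' @return the `motu_classes` with `review_status`/`review_reason` filled.
#' @export
review_motus <- function(classes, assignment, library, synonyms = NULL) {
  stopifnot(inherits(classes, "motu_classes"),
            inherits(assignment, "motu_assignment"))
  meta <- library$meta[match(assignment$specimen_id,
                             library$meta$specimen_id), , drop = FALSE]
  for (i in which(classes$status == "discordant")) {
    m <- classes$motu_id[i]
    mm <- meta[assignment$motu_id == m, , drop = FALSE]
    counted <- mm$qualifier == "none" & mm$morpho_species != ""
    raw <- unique(mm$morpho_species[counted])
    accepted <- unique(.map_names(raw, synonyms))
    if (length(accepted) <= 1) {
      renamed <- raw[raw != .map_names(raw, synonyms)]
      classes$review_status[i] <- "reclassified_concordant"
      classes$review_reason[i] <- paste0(
        "synonyms: ",
        paste(paste0(renamed, " -> ", .map_names(renamed, synonyms)),
              collapse = "; "))
    } else {
      classes$review_status[i] <- "confirmed_discordant"
      classes$review_reason[i] <- paste0(
        "distinct accepted names remain: ",
        paste(sort(accepted), collapse = "; "))
    }
  }
  classes
}

#' Concordance summary of a classified (and reviewed) MOTU set
#'
#' @param classes a `motu_classes`.
#' @param singletons_as_concordant count singleton MOTUs as concordant in
#'   the percentage (default `TRUE`, the convention under which a
#'   23 + 8 + 1 review arithmetic yields 32 concordant of 35).
#' @return list with `n_motus`, `n_concordant`, `n_discordant`,
#'   `n_singleton`, `n_reclassified`, `n_confirmed_discordant`,
#'   `n_concordant_after_review`, `pct_concordant` (full precision).
#' @export
concordance_summary <- function(classes, singletons_as_concordant = TRUE) {
  stopifnot(inherits(classes, "motu_classes"))
  n_con <- sum(classes$status == "concordant")
  n_dis <- sum(classes$status == "discordant")
  n_sin <- sum(classes$status == "singleton")
  n_rec <- sum(classes$review_status == "reclassified_concordant")
  bin_report_summary(n_con, n_dis, n_sin, n_reclassified = n_rec,
                     singletons_as_concordant = singletons_as_concordant)
}

#' Concordance arithmetic from MOTU-report counts
#'
#' The bookkeeping applied to a cluster report after expert review:
#' reclassified clusters move from discordant to concordant, singletons
#' optionally count as concordant, and the concordant percentage is taken
#' over all clusters.
#'
#' @param n_concordant,n_discordant,n_singleton counts before review.
#' @param n_reclassified discordant clusters reclassified concordant on
#'   review.
#' @param singletons_as_concordant see [concordance_summary()].
#' @return list as in [concordance_summary()].
#' @export
bin_report_summary <- function(n_concordant, n_discordant, n_singleton,
                               n_reclassified = 0,
                               singletons_as_concordant = TRUE) {
  stopifnot(n_reclassified <= n_discordant)
  n_motus <- n_concordant + n_discordant + n_singleton
  after <- n_concordant + n_reclassified +
    if (singletons_as_concordant) n_singleton else 0L
  list(n_motus = n_motus,
       n_concordant = n_concordant,
       n_discordant = n_discordant,
       n_singleton = n_singleton,
       n_reclassified = n_reclassified,
       n_confirmed_discordant = n_discordant - n_reclassified,
       n_concordant_after_review = after,
       pct_concordant = 100 * after / n_motus)
}

#' Match a query barcode against a reference library
#'
#' Local stand-in for an online identification query: percent identity is
#' computed as 100 x (1 - p-distance) over the mutually usable (ACGT)
#' overlapping sites of the common alignment; hits with too little overlap
#' are dropped, and the rest ranked by identity (ties by hit id).
#'
#' @param query a specimen id present in `library`, or an aligned DNA
#'   string of the same length as the library alignment.
#' @param library an aligned [barcode_library()] of reference records.
#' @param min_overlap minimum usable overlapping sites (default 400).
#' @return data.frame `hit_id`, `hit_species`, `identity` (percent),
#'   `overlap`, sorted best-first; zero rows when nothing overlaps enough.
#' @export
match_reference <- function(query, library, min_overlap = 400) {
  stopifnot(inherits(library, "barcode_library"),
            !is.null(library$alignment))
  aln <- library$alignment
  self_id <- NULL
  if (nchar(query[1]) != ncol(aln) && query[1] %in% rownames(aln)) {
    self_id <- query
    q <- aln[query, ]
  } else {
    if (nchar(query[1]) != ncol(aln))
      stop("query must be a library id or an aligned sequence of width ",
           ncol(aln))
    q <- strsplit(toupper(query), "")[[1]]
  }
  qc <- match(q, c("A", "C", "G", "T"))
  hits <- setdiff(rownames(aln), self_id)
  rows <- lapply(hits, function(h) {
    hcv <- match(aln[h, ], c("A", "C", "G", "T"))
    use <- !is.na(qc) & !is.na(hcv)
    n <- sum(use)
    if (n < min_overlap) return(NULL)
    ident <- 100 * mean(qc[use] == hcv[use])
    data.frame(hit_id = h,
               hit_species = library$meta$morpho_species[
                 match(h, library$meta$specimen_id)],
               identity = ident, overlap = n, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(hit_id = character(), hit_species = character(),
                      identity = numeric(), overlap = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-out$identity, out$hit_id), , drop = FALSE]
}

#' Propose a species name for a genus-level specimen from its MOTU
#'
#' A specimen identified only to genus (qualifier `sp`/`cf`/`aff`) can be
#' identified from its barcode when its MOTU's other members all carry one
#' accepted species name whose genus does not contradict the specimen's
#' own. Confirmed-discordant MOTUs and singletons never propagate a name.
#'
#' @param specimen_id the query specimen.
#' @param assignment a `motu_assignment`.
#' @param classes a (reviewed) `motu_classes`.
#' @param library the [barcode_library()].
#' @param synonyms optional synonym table used to read member names as
#'   accepted names.
#' @return proposed species name, or `NA_character_`.
#' @export
propagate_id <- function(specimen_id, assignment, classes, library,
                         synonyms = NULL) {
  stopifnot(inherits(assignment, "motu_assignment"),
            inherits(classes, "motu_classes"))
  i <- match(specimen_id, assignment$specimen_id)
  if (is.na(i)) stop("specimen '", specimen_id, "' not in assignment")
  m <- assignment$motu_id[i]
  cl <- classes[classes$motu_id == m, ]
  if (nrow(cl) && cl$review_status == "confirmed_discordant")
    return(NA_character_)
  members <- assignment$specimen_id[assignment$motu_id == m]
  others <- setdiff(members, specimen_id)
  if (!length(others)) return(NA_character_)
  meta <- library$meta[match(others, library$meta$specimen_id), ,
                       drop = FALSE]
  counted <- meta$qualifier == "none" & meta$morpho_species != ""
  accepted <- unique(.map_names(unique(meta$morpho_species[counted]),
                                synonyms))
  if (length(accepted) != 1) return(NA_character_)
  own_genus <- library$meta$genus[match(specimen_id,
                                        library$meta$specimen_id)]
  prop_genus <- strsplit(accepted, "\\s+")[[1]][1]
  if (!is.na(own_genus) && own_genus != "" && own_genus != prop_genus)
    return(NA_character_)
  accepted
}
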