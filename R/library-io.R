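#' @importFrom utils read.delim write.table
NULL

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

REQUIRED_META <- c("specimen_id", "morpho_species", "genus", "family",
                   "qualifier", "locality", "source", "published")

QUALIFIERS <- c("none", "sp", "cf", "aff")

#' Construct a barcode library
#'
#' A barcode library bundles specimen sequences with their metadata and,
#' optionally, a common alignment and a 658-site Folmer reference anchor.
#' This is the container every downstream stage (QC, distances, MOTU
#' delimitation, grading) operates on.
#'
#' @param meta data.frame with at least the columns
#'   `specimen_id`, `morpho_species`, `genus`, `family`, `qualifier`
#'   (`none`/`sp`/`cf`/`aff`), `locality`, `source` (`own`/`external`),
#'   `published` (logical). Extra columns are retained untouched.
#' @param seqs named character vector of IUPAC DNA sequences; names must
#'   match `meta$specimen_id`.
#' @param alignment optional character matrix (rows named by specimen id,
#'   one column per site) with every record present.
#' @param anchor optional gap-free reference sequence for the barcode
#'   region (Folmer coordinates 1..nchar(anchor)).
#' @return An object of class `barcode_library`.
#' @export
barcode_library <- function(meta, seqs, alignment = NULL, anchor = NULL) {
  stopifnot(is.data.frame(meta), is.character(seqs))
  missing_cols <- setdiff(REQUIRED_META, names(meta))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  meta$specimen_id <- as.character(meta$specimen_id)
  if (anyDuplicated(meta$specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
               collapse = ", "))
  if (is.null(names(seqs)))
    stop("sequences must be named by specimen_id")
  only_fa <- setdiff(names(seqs), meta$specimen_id)
  only_meta <- setdiff(meta$specimen_id, names(seqs))
  if (length(only_fa) || length(only_meta))
    stop("sequence/metadata mismatch; sequence-only: [",
         paste(only_fa, collapse = ", "), "]; metadata-only: [",
         paste(only_meta, collapse = ", "), "]")
  seqs <- toupper(seqs[meta$specimen_id])
  .check_iupac(seqs)
  if (any(!nzchar(seqs)))
    stop("empty sequence for: ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  meta$qualifier <- .norm_qualifier(meta$qualifier)
  meta$published <- .norm_logical(meta$published)
  meta$source <- tolower(trimws(as.character(meta$source)))
  bad_src <- setdiff(unique(meta$source), c("own", "external"))
  if (length(bad_src))
    stop("source must be 'own' or 'external'; got: ",
         paste(bad_src, collapse = ", "))
  meta <- .normalize_genus_level(meta)
  if (!is.null(alignment)) {
    alignment <- .as_char_matrix(alignment)
    if (!setequal(rownames(alignment), meta$specimen_id))
      stop("alignment rows must match specimen ids exactly")
    alignment <- alignment[meta$specimen_id, , drop = FALSE]
  }
  if (!is.null(anchor)) {
    anchor <- toupper(anchor)
    if (grepl("-", anchor, fixed = TRUE))
      stop("reference anchor must be gap-free")
  }
  structure(list(meta = meta, seqs = seqs, alignment = alignment,
                 anchor = anchor),
            class = "barcode_library")
}

.check_iupac <- function(seqs) {
  for (id in names(seqs)) {
    ch <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% IUPAC_DNA))
    if (length(bad))
      stop("non-IUPAC character '", ch[bad[1]], "' in sequence '", id,
           "' at position ", bad[1])
  }
  invisible(TRUE)
}

.norm_qualifier <- function(q) {
  q <- tolower(trimws(as.character(q)))
  q <- sub("\\.$", "", q)
  q[is.na(q) | q == ""] <- "none"
  bad <- setdiff(unique(q), QUALIFIERS)
  if (length(bad))
    stop("unknown qualifier value(s): ", paste(bad, collapse = ", "))
  q
}

.norm_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes", "y")
  bad <- !(x %in% c("true", "t", "1", "yes", "y",
                    "false", "f", "0", "no", "n"))
  if (any(bad)) stop("published column must be logical-like")
  out
}

# A genus-level identification written as "Gibbula sp." in morpho_species
# is stored as qualifier=sp, genus filled, morpho_species empty.
.normalize_genus_level <- function(meta) {
  ms <- trimws(as.character(meta$morpho_species))
  ms[is.na(ms)] <- ""
  gn <- trimws(as.character(meta$genus))
  gn[is.na(gn)] <- ""
  is_sp <- grepl("\\ssp\\.?$", ms)
  if (any(is_sp)) {
    stem <- trimws(sub("\\ssp\\.?$", "", ms))
    meta$qualifier[is_sp] <- "sp"
    gn[is_sp & gn == ""] <- stem[is_sp & gn == ""]
    ms[is_sp] <- ""
  }
  gn[gn == "" & ms != ""] <- vapply(strsplit(ms[gn == "" & ms != ""], "\\s+"),
                                    `[`, character(1), 1)
  meta$morpho_species <- ms
  meta$genus <- gn
  meta
}

.as_char_matrix <- function(x) {
  if (is.matrix(x) && is.character(x)) return(x)
  if (is.character(x)) {
    L <- unique(nchar(x))
    if (length(L) != 1) stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
    return(m)
  }
  stop("cannot coerce to character alignment matrix")
}

#' Read a barcode library from FASTA plus metadata TSV
#'
#' The metadata file is tab-separated with a header containing at least the
#' required columns (see [barcode_library()]); unknown columns are retained
#' untouched. FASTA ids must correspond one-to-one with the
#' `specimen_id` column. If every sequence has the same length the set is
#' treated as pre-aligned and stored as the library alignment.
#'
#' @param fasta_path path to a FASTA file (wrapped or single-line).
#' @param metadata_path path to the metadata TSV.
#' @param aligned force (`TRUE`/`FALSE`) whether sequences are treated as an
#'   alignment; default guesses from equal lengths and presence of gaps.
#' @return A [barcode_library()].
#' @export
read_library <- function(fasta_path, metadata_path, aligned = NULL) {
  ss <- Biostrings::readBStringSet(fasta_path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA id: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  meta <- read.delim(metadata_path, sep = "\t", header = TRUE,
                     colClasses = "character", check.names = FALSE)
  if (is.null(aligned))
    aligned <- length(unique(nchar(seqs))) == 1 &&
      (length(seqs) > 1 || grepl("-", seqs[1], fixed = TRUE))
  aln <- if (isTRUE(aligned)) seqs else NULL
  lib <- barcode_library(meta, gsub("-", "", seqs, fixed = TRUE),
                         alignment = aln)
  lib
}

#' Write a barcode library to FASTA plus metadata TSV
#'
#' Inverse of [read_library()]: a round trip preserves every field.
#'
#' @param library a [barcode_library()].
#' @param fasta_path,metadata_path output paths.
#' @export
write_library <- function(library, fasta_path, metadata_path) {
  stopifnot(inherits(library, "barcode_library"))
  seqs <- if (!is.null(library$alignment))
    apply(library$alignment, 1, paste, collapse = "") else library$seqs
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fasta_path)
  meta <- library$meta
  meta$published <- tolower(as.character(meta$published))
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(library)
}

#' Subset a barcode library by specimen id
#'
#' @param library a [barcode_library()].
#' @param ids specimen ids to keep (original record order preserved).
#' @return the subset [barcode_library()].
#' @export
subset_library <- function(library, ids) {
  stopifnot(inherits(library, "barcode_library"))
  keep <- library$meta$specimen_id %in% ids
  barcode_library(library$meta[keep, , drop = FALSE],
                  library$seqs[keep],
                  alignment = if (!is.null(library$alignment))
                    library$alignment[keep, , drop = FALSE],
                  anchor = library$anchor)
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("barcode_library:", nrow(x$meta), "records,",
      length(unique(x$meta$morpho_species[x$meta$morpho_species != ""])),
      "named morpho-species\n")
  cat("  aligned:", !is.null(x$alignment),
      " anchor:", !is.null(x$anchor), "\n")
  invisible(x)
}

#' Read a synonym table
#'
#' TSV with header `name`, `accepted_name`, `note`. Used to resolve outdated
#' taxonomy (e.g. genus transfers) during concordance review.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `name`, `accepted_name`, `note`.
#' @export
read_synonyms <- function(path) {
  syn <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  stopifnot(all(c("name", "accepted_name") %in% names(syn)))
  if (is.null(syn$note)) syn$note <- ""
  syn
}

# Resolve each name to its final accepted name, failing on cycles.
.resolve_synonyms <- function(synonyms) {
  map <- stats::setNames(synonyms$accepted_name, synonyms$name)
  out <- map
  for (nm in names(map)) {
    seen <- nm
    cur <- map[[nm]]
    while (cur %in% names(map) && map[[cur]] != cur) {
      if (cur %in% seen)
        stop("cyclic synonym mapping involving '", nm, "'")
      seen <- c(seen, cur)
      cur <- map[[cur]]
    }
    out[[nm]] <- cur
  }
  out
}

#' Apply a synonym table to a library
#'
#' Replaces every morpho-species (and genus) name by its accepted name.
#' Idempotent: applying the result again changes nothing. An audit trail of
#' replacements is attached as attribute `"synonym_audit"`.
#'
#' @param library a [barcode_library()].
#' @param synonyms a synonym table as returned by [read_synonyms()], or
#'   `NULL`/empty for a no-op.
#' @return the renamed [barcode_library()].
#' @export
apply_synonyms <- function(library, synonyms) {
  stopifnot(inherits(library, "barcode_library"))
  if (is.null(synonyms) || nrow(synonyms) == 0) {
    attr(library, "synonym_audit") <-
      data.frame(specimen_id = character(), field = character(),
                 from = character(), to = character(),
                 note = character(), stringsAsFactors = FALSE)
    return(library)
  }
  map <- .resolve_synonyms(synonyms)
  note <- stats::setNames(synonyms$note, synonyms$name)
  meta <- library$meta
  audit <- list()
  hit <- meta$morpho_species %in% names(map) &
    meta$morpho_species != map[meta$morpho_species]
  if (any(hit)) {
    from <- meta$morpho_species[hit]
    to <- unname(map[from])
    audit[[1]] <- data.frame(specimen_id = meta$specimen_id[hit],
                             field = "morpho_species", from = from, to = to,
                             note = unname(note[from]),
                             stringsAsFactors = FALSE)
    meta$morpho_species[hit] <- to
    meta$genus[hit] <- vapply(strsplit(to, "\\s+"), `[`, character(1), 1)
  }
  ghit <- meta$morpho_species == "" & meta$genus %in% names(map) &
    meta$genus != map[meta$genus]
  if (any(ghit)) {
    from <- meta$genus[ghit]
    to <- unname(map[from])
    audit[[2]] <- data.frame(specimen_id = meta$specimen_id[ghit],
                             field = "genus", from = from, to = to,
                             note = unname(note[from]),
                             stringsAsFactors = FALSE)
    meta$genus[ghit] <- to
  }
  library$meta <- meta
  attr(library, "synonym_audit") <-
    if (length(audit)) do.call(rbind, audit) else
      data.frame(specimen_id = character(), field = character(),
                 from = character(), to = character(), note = character(),
                 stringsAsFactors = FALSE)
  library
}

# Map a vector of names through a synonym table (names absent are kept).
.map_names <- function(x, synonyms) {
  if (is.null(synonyms) || nrow(synonyms) == 0) return(x)
  map <- .resolve_synonyms(synonyms)
  hit <- x %in% names(map)
  x[hit] <- unname(map[x[hit]])
  x
}
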