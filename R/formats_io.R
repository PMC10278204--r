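# External representations: DisProt-style JSON, FASTA, aligned FASTA /
# Clustal MSAs, the TSV transfer table and the JSON quality report.
#
# Coordinates in every external file are 1-based inclusive (DisProt
# convention). They are kept 1-based inclusive in all public data
# structures; the only coordinate arithmetic happens inside the
# coordinate-map helpers of the alignment engine.

#' Construct a protein-record table
#'
#' The package represents a collection of protein sequences as a plain
#' `data.frame` with columns `accession`, `sequence`, `source` and
#' `description`. Sequences are upper-cased and validated against the 20
#' standard residues; an `X` (undefined residue) is tolerated but flagged
#' in the `has_x` column so downstream filters can reject it.
#'
#' @param accession character vector of unique identifiers.
#' @param sequence character vector of amino-acid strings (any case).
#' @param source `"reference"` or `"ortholog"` (recycled).
#' @param description free text (recycled, default `""`).
#' @return `data.frame` with columns `accession`, `sequence`, `source`,
#'   `description`, `has_x`.
#' @export
protein_records <- function(accession, sequence, source = "ortholog",
                            description = "") {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (length(accession) != length(sequence))
    stop("accession and sequence must have the same length")
  if (anyDuplicated(accession))
    stop("duplicate accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for: ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X]"), sequence)
  if (any(bad))
    stop("non-standard residues in: ", paste(accession[bad], collapse = ", "))
  source <- rep_len(match.arg(source, c("ortholog", "reference"),
                              several.ok = FALSE), length(accession))
  data.frame(accession = accession, sequence = sequence, source = source,
             description = rep_len(as.character(description), length(accession)),
             has_x = grepl("X", sequence, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Construct an annotated-region table
#'
#' Regions carry a 1-based inclusive span on their protein plus an ontology
#' term. The ontology is derived from the term prefix (`GO:` or `IDPO:`)
#' and must be consistent with it.
#'
#' @param region_id,protein_accession,term_id,term_name character vectors.
#' @param start,end 1-based inclusive residue indices.
#' @return `data.frame` with an added `ontology` column.
#' @export
annotated_regions <- function(region_id, protein_accession, start, end,
                              term_id, term_name = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 1L) ||
      any(start > end))
    stop("invalid region span(s): need 1 <= start <= end")
  ontology <- ifelse(startsWith(term_id, "GO:"), "GO",
                     ifelse(startsWith(term_id, "IDPO:"), "IDPO", NA))
  if (anyNA(ontology))
    stop("term_id must start with 'GO:' or 'IDPO:': ",
         paste(term_id[is.na(ontology)], collapse = ", "))
  data.frame(region_id = as.character(region_id),
             protein_accession = as.character(protein_accession),
             start = start, end = end,
             term_id = as.character(term_id),
             term_name = rep_len(as.character(term_name), length(region_id)),
             ontology = ontology, stringsAsFactors = FALSE)
}

#' Construct an annotated entry
#'
#' One reference protein together with its annotated regions. Regions with
#' identical spans but different terms are distinct records, and regions
#' may overlap each other.
#'
#' @param protein single-row protein-record `data.frame`
#'   (see [protein_records()]).
#' @param regions region table (see [annotated_regions()]); all rows must
#'   reference the protein's accession.
#' @param disprot_id database identifier of the entry.
#' @param valid logical; entries that fail structural validation are kept,
#'   flagged invalid with a reason, never silently dropped.
#' @param invalid_reason character reason when `valid` is `FALSE`.
#' @return object of class `"annotated_entry"`.
#' @export
annotated_entry <- function(protein, regions, disprot_id,
                            valid = TRUE, invalid_reason = NA_character_) {
  stopifnot(is.data.frame(protein), nrow(protein) == 1L)
  if (nrow(regions) > 0 &&
      !all(regions$protein_accession == protein$accession))
    stop("all regions must reference the entry's accession")
  structure(list(protein = protein, regions = regions,
                 disprot_id = as.character(disprot_id),
                 valid = isTRUE(valid),
                 invalid_reason = invalid_reason),
            class = "annotated_entry")
}

#' @export
print.annotated_entry <- function(x, ...) {
  cat(sprintf("<annotated_entry %s (%s), %d aa, %d region(s)%s>\n",
              x$disprot_id, x$protein$accession, nchar(x$protein$sequence),
              nrow(x$regions),
              if (x$valid) "" else paste0(", INVALID: ", x$invalid_reason)))
  invisible(x)
}

#' Read a DisProt-style JSON release
#'
#' Parses the release layout where entries sit under a top-level `data`
#' array (a bare top-level array is also accepted), each with `disprot_id`,
#' `acc`, `sequence` and a `regions` array. Region terms are read from a
#' nested `term` object (`id`, `name`) or from flat `term_id`/`term_name`
#' fields; missing optional fields default to empty. Entries whose regions
#' fall outside the sequence are flagged invalid with a reason rather than
#' dropped.
#'
#' @param path JSON file.
#' @return list of [annotated_entry()] objects.
#' @export
read_disprot_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc$data)) doc <- doc$data
  if (!is.list(doc)) stop("malformed DisProt JSON: expected an entry array")
  lapply(doc, parse_disprot_entry)
}

parse_disprot_entry <- function(e) {
  acc <- as.character(e[["acc"]] %||% e[["accession"]] %||% "")
  did <- as.character(e[["disprot_id"]] %||% acc)
  seq <- toupper(as.character(e[["sequence"]] %||% ""))
  regs <- e[["regions"]] %||% list()
  prot <- tryCatch(
    protein_records(acc, seq, source = "reference",
                    description = as.character(e[["name"]] %||% "")),
    error = function(err) conditionMessage(err))
  if (is.character(prot)) {
    dummy <- data.frame(accession = acc, sequence = seq, source = "reference",
                        description = "", has_x = NA, stringsAsFactors = FALSE)
    return(annotated_entry(dummy, empty_region_table(), did,
                           valid = FALSE, invalid_reason = prot))
  }
  rows <- lapply(seq_along(regs), function(i) {
    r <- regs[[i]]
    term_id <- as.character(r[["term_id"]] %||% r[["term"]][["id"]] %||% "")
    term_name <- as.character(r[["term_name"]] %||%
                                r[["term"]][["name"]] %||% "")
    data.frame(region_id = as.character(r[["region_id"]] %||%
                                          sprintf("%sr%03d", did, i)),
               protein_accession = acc,
               start = as.integer(r[["start"]] %||% NA),
               end = as.integer(r[["end"]] %||% NA),
               term_id = term_id, term_name = term_name,
               stringsAsFactors = FALSE)
  })
  rt <- if (length(rows)) do.call(rbind, rows) else empty_region_table()
  bad <- which(is.na(rt$start) | is.na(rt$end) | rt$start < 1L |
                 rt$start > rt$end | rt$end > nchar(seq) |
                 !grepl("^(GO|IDPO):", rt$term_id))
  if (length(bad) > 0)
    return(annotated_entry(prot, empty_region_table(), did, valid = FALSE,
                           invalid_reason = paste0("invalid region(s): ",
                                                   paste(rt$region_id[bad],
                                                         collapse = ", "))))
  regions <- if (nrow(rt)) annotated_regions(rt$region_id,
                                             rt$protein_accession, rt$start,
                                             rt$end, rt$term_id, rt$term_name)
             else empty_region_table()
  annotated_entry(prot, regions, did)
}

empty_region_table <- function() {
  data.frame(region_id = character(), protein_accession = character(),
             start = integer(), end = integer(), term_id = character(),
             term_name = character(), ontology = character(),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read/write FASTA protein records
#'
#' Thin wrappers over Biostrings that return/accept the package's
#' protein-record `data.frame`. Reading upper-cases sequences; writing wraps
#' at 60 columns. `read(write(x))` reproduces `x` up to line wrapping.
#'
#' @param path FASTA file.
#' @param source `source` value assigned to every record read.
#' @return `read_fasta`: protein-record `data.frame`.
#' @export
read_fasta <- function(path, source = "ortholog") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    warning("empty FASTA file: ", path)
    return(protein_records(character(), character()))
  }
  set <- Biostrings::readBStringSet(path)
  acc <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  desc <- sub("^\\S+\\s*", "", names(set))
  protein_records(acc, as.character(set), source = source,
                  description = desc)
}

#' @param records protein-record `data.frame`.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(stats::setNames(records$sequence,
                                                records$accession))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Multiple sequence alignment container
#'
#' A lightweight rectangular alignment: a named character vector of
#' equal-length gapped rows plus the identifier of the reference row.
#' Gap characters `"."` and `"-"` are both accepted and normalized to
#' `"-"`.
#'
#' @param seqs named character vector of gapped rows.
#' @param reference accession of the reference row (default: first row).
#' @return object of class `"msa"`.
#' @export
msa <- function(seqs, reference = names(seqs)[1]) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment rows must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate row identifiers")
  seqs <- toupper(chartr(".", "-", seqs))
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("ragged alignment: row '",
         names(seqs)[which(nchar(seqs) != nchar(seqs)[1])[1]],
         "' has a different length")
  if (!reference %in% names(seqs))
    stop("reference row '", reference, "' not present")
  structure(list(seqs = seqs, reference = reference), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa: %d rows x %d columns, reference %s>\n",
              length(x$seqs), msa_width(x), x$reference))
  invisible(x)
}

#' @rdname msa
#' @param x an `msa` object.
#' @export
msa_width <- function(x) if (length(x$seqs)) nchar(x$seqs[[1]]) else 0L

#' @rdname msa
#' @export
msa_ids <- function(x) names(x$seqs)

#' Remove gaps from alignment rows
#'
#' @param x an `msa` object.
#' @param ids rows to ungap (default all).
#' @return named character vector of ungapped sequences.
#' @export
ungap_rows <- function(x, ids = msa_ids(x)) {
  gsub("-", "", x$seqs[ids], fixed = TRUE)
}

#' Read/write a multiple sequence alignment
#'
#' Aligned FASTA (`"afa"`) and Clustal (`"clustal"`) are supported; row
#' order is preserved and both `"."` and `"-"` gaps are normalized to
#' `"-"` on read. Ragged inputs are a fatal error naming the offending row.
#'
#' @param path alignment file.
#' @param format `"afa"` or `"clustal"`.
#' @param reference reference row identifier (default: first row).
#' @return an [msa()] object.
#' @export
read_msa <- function(path, format = c("afa", "clustal"), reference = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "afa") {
    set <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(as.character(set),
                            vapply(strsplit(names(set), "\\s+"), `[`, "", 1L))
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(aln)
    if (is.null(names(seqs))) names(seqs) <- rownames(aln)
  }
  msa(seqs, reference = reference %||% names(seqs)[1])
}

#' @param x an `msa` object.
#' @rdname read_msa
#' @export
write_msa <- function(x, path, format = c("afa", "clustal")) {
  format <- match.arg(format)
  if (format == "afa") {
    set <- Biostrings::BStringSet(x$seqs)
    Biostrings::writeXStringSet(set, path, width = 60L)
  } else {
    write_clustal(x, path)
  }
  invisible(path)
}

# minimal Clustal writer (Biostrings reads but does not write this format)
write_clustal <- function(x, path) {
  ids <- msa_ids(x)
  pad <- max(nchar(ids)) + 3L
  w <- msa_width(x)
  lines <- c("CLUSTAL W multiple sequence alignment", "", "")
  for (from in seq(1L, w, by = 60L)) {
    to <- min(from + 59L, w)
    lines <- c(lines,
               sprintf("%-*s%s", pad, ids, substr(x$seqs, from, to)), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the transfer table as TSV
#'
#' One line per (ortholog, term, region), deterministically sorted by
#' region start, term identifier, then ortholog accession. An empty record
#' set yields a header-only file.
#'
#' @param records transfer-record `data.frame` (see [transfer_region()]).
#' @param path output file.
#' @export
write_transfer_table <- function(records, path) {
  cols <- transfer_record_columns()
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols))
  } else {
    stopifnot(all(cols %in% names(records)))
    records <- records[order(records$ref_start, records$term_id,
                             records$ortholog_accession), cols]
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

transfer_record_columns <- function() {
  c("reference_accession", "region_id", "term_id", "term_name",
    "ref_start", "ref_end", "ortholog_accession", "ortho_start",
    "ortho_end", "region_normd", "region_identity",
    "n_orthologs_in_region", "tricky")
}

#' Read a transfer table written by [write_transfer_table()]
#' @param path TSV file.
#' @return transfer-record `data.frame`.
#' @export
read_transfer_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a quality report as JSON
#' @param report a `quality_report` (see [quality_report()]), or a list of
#'   them.
#' @param path output file.
#' @export
write_quality_json <- function(report, path) {
  jsonlite::write_json(unclass_reports(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_reports <- function(x) {
  if (inherits(x, "quality_report")) return(unclass(x))
  lapply(x, unclass_reports)
}
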