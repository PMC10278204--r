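# Family MSA construction (builtin progressive aligner + external aligner
# adapters), identity-to-reference computation and filtering, and the
# residue <-> alignment-column coordinate maps every downstream stage
# relies on.

#' Aligner specification
#'
#' @param method `"builtin"`, `"mafft"` or `"clustal-omega"`. External
#'   methods shell out to the corresponding binary with its defaults; the
#'   builtin method is a deterministic progressive aligner (see
#'   [builtin_progressive_align()]).
#' @param options named character vector of extra command-line options for
#'   external methods (ignored by `builtin`).
#' @return object of class `"aligner_spec"`.
#' @export
aligner_spec <- function(method = c("builtin", "mafft", "clustal-omega"),
                         options = character()) {
  structure(list(method = match.arg(method), options = options),
            class = "aligner_spec")
}

#' Align an ortholog family
#'
#' Produces a multiple sequence alignment of the reference plus its
#' orthologs. Row order of the input is preserved and ungapping any row of
#' the result reproduces the corresponding input sequence exactly (checked).
#'
#' @param records protein-record `data.frame` (>= 2 rows).
#' @param reference_id accession of the reference record.
#' @param spec an [aligner_spec()].
#' @return an [msa()] with `reference` set, and attribute `"method"`.
#' @export
align_family <- function(records, reference_id, spec = aligner_spec()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L)
    stop("alignment needs at least 2 sequences")
  if (!reference_id %in% records$accession)
    stop("reference '", reference_id, "' not among the records")
  out <- switch(spec$method,
    builtin = builtin_progressive_align(records, reference_id),
    mafft = external_align(records, reference_id, "mafft", spec$options),
    `clustal-omega` = external_align(records, reference_id, "clustalo",
                                     spec$options))
  assert_ungap_identity(out, records)
  attr(out, "method") <- spec$method
  out
}

assert_ungap_identity <- function(aln, records) {
  ung <- ungap_rows(aln)
  input <- stats::setNames(records$sequence, records$accession)
  bad <- names(ung)[ung != input[names(ung)]]
  if (length(bad))
    stop("aligner mutated sequence(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

external_align <- function(records, reference_id, binary, options) {
  path <- Sys.which(binary)
  if (!nzchar(path))
    stop("external aligner '", binary, "' not found on PATH; ",
         "use aligner_spec(\"builtin\") instead")
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)))
  write_fasta(records, fin)
  if (binary == "mafft") {
    status <- system2(path, c("--quiet", "--auto", options, shQuote(fin)),
                      stdout = fout, stderr = FALSE)
  } else {
    status <- system2(path, c("-i", shQuote(fin), "-o", shQuote(fout),
                              "--outfmt=fa", "--force", options),
                      stdout = FALSE, stderr = FALSE)
  }
  if (status != 0L || !file.exists(fout) || file.size(fout) == 0L)
    stop(binary, " failed with status ", status)
  aln <- read_msa(fout, "afa", reference = reference_id)
  # restore input row order (mafft keeps it; clustalo may not)
  msa(aln$seqs[records$accession], reference = reference_id)
}

#' Deterministic builtin progressive aligner
#'
#' A classic progressive scheme: pairwise distances from 3-mer composition
#' (cosine distance), a UPGMA guide tree, and profile-profile merging by
#' global dynamic programming with affine gap costs and BLOSUM62 scores.
#' Entirely deterministic: ties in the guide tree and in the traceback are
#' broken by fixed rules. Intended for desk-scale families; external
#' aligners remain the production path.
#'
#' @param records protein-record `data.frame` (>= 2 rows).
#' @param reference_id accession of the reference record.
#' @param sub_matrix 20x20 substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @return an [msa()].
#' @export
builtin_progressive_align <- function(records, reference_id,
                                      sub_matrix = blosum62_20(),
                                      gap_open = 10, gap_extend = 0.5) {
  stopifnot(nrow(records) >= 2L)
  seqs <- stats::setNames(records$sequence, records$accession)
  n <- length(seqs)
  if (n == 2L) {
    merged <- merge_profiles(seqs[1], seqs[2], sub_matrix, gap_open,
                             gap_extend)
  } else {
    d <- kmer_cosine_dist(seqs, k = 3L)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    # walk the merge table; negative entries are leaves
    groups <- vector("list", nrow(hc$merge))
    leaf <- function(i) stats::setNames(seqs[hc$labels[i]], hc$labels[i])
    for (i in seq_len(nrow(hc$merge))) {
      a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
      ga <- if (a < 0) leaf(-a) else groups[[a]]
      gb <- if (b < 0) leaf(-b) else groups[[b]]
      groups[[i]] <- merge_profiles(ga, gb, sub_matrix, gap_open, gap_extend)
    }
    merged <- groups[[nrow(hc$merge)]]
  }
  msa(merged[names(seqs)], reference = reference_id)
}

# gapped row set A x gapped row set B -> merged row set, via profile DP
merge_profiles <- function(a, b, sub_matrix, gap_open, gap_extend) {
  pa <- profile_matrix(a); pb <- profile_matrix(b)
  sim <- crossprod(pa, sub_matrix %*% pb)  # ncol(a) x ncol(b)
  path <- .gotoh_profile_path(sim, gap_open, gap_extend)
  expand <- function(rows, consume) {
    mat <- do.call(rbind, strsplit(unname(rows), ""))
    out <- matrix("-", nrow = nrow(mat), ncol = length(path))
    out[, consume] <- mat
    stats::setNames(apply(out, 1L, paste, collapse = ""), names(rows))
  }
  c(expand(a, path != 3L), expand(b, path != 2L))
}

# residue-frequency profile: 20 x width, gap columns weigh less
profile_matrix <- function(rows) {
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  apply(mat, 2L, function(col) {
    tab <- table(factor(col[col %in% AA20], levels = AA20))
    as.numeric(tab) / length(col)
  })
}

# cosine distance between k-mer count vectors
kmer_cosine_dist <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(stats::setNames(1, substr(s, 1L, n)))
    kmers <- substring(s, 1:(n - k + 1L), k:n)
    table(kmers)
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- intersect(names(ci), names(cj))
    num <- sum(as.numeric(ci[shared]) * as.numeric(cj[shared]))
    den <- sqrt(sum(as.numeric(ci)^2)) * sqrt(sum(as.numeric(cj)^2))
    d[i, j] <- d[j, i] <- 1 - if (den > 0) num / den else 0
  }
  d
}

#' BLOSUM62 restricted to the 20 standard residues
#' @return 20x20 numeric matrix.
#' @export
blosum62_20 <- function() {
  m <- get_blosum62()
  m[AA20, AA20]
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' Percent identity of a row to the reference row
#'
#' Identity is computed against the reference's residues: the denominator
#' is the number of columns (within `columns`, if given) where the
#' reference is not a gap, and a gap in the other row opposite a reference
#' residue counts as a mismatch. This makes deletions in the ortholog lower
#' its score, which is the property that matters when judging fidelity to
#' annotated reference positions.
#'
#' @param x an [msa()].
#' @param row_id row to score.
#' @param columns optional integer range of alignment columns.
#' @return percent in `[0, 100]`.
#' @export
identity_to_reference <- function(x, row_id, columns = NULL) {
  stopifnot(inherits(x, "msa"), row_id %in% msa_ids(x))
  ref <- strsplit(x$seqs[[x$reference]], "")[[1]]
  oth <- strsplit(x$seqs[[row_id]], "")[[1]]
  if (!is.null(columns)) {
    if (min(columns) < 1L || max(columns) > msa_width(x))
      stop("column range outside alignment width")
    ref <- ref[columns]; oth <- oth[columns]
  }
  keep <- ref != "-"
  if (!any(keep))
    stop("reference is all-gap in the requested range")
  100 * sum(ref[keep] == oth[keep]) / sum(keep)
}

#' Drop alignment rows below an identity threshold
#'
#' The reference row is always retained. After filtering, columns that
#' became gap-only are removed. Idempotent, and monotone in the threshold:
#' a higher threshold keeps a subset of the rows kept by a lower one.
#'
#' @param x an [msa()].
#' @param threshold percent identity in `(0, 100]`.
#' @param columns optional column range over which identity is measured.
#' @return filtered [msa()]; may contain only the reference.
#' @export
drop_low_identity_rows <- function(x, threshold, columns = NULL) {
  stopifnot(threshold > 0, threshold <= 100)
  keep <- vapply(msa_ids(x), function(id) {
    id == x$reference ||
      identity_to_reference(x, id, columns) >= threshold
  }, logical(1))
  remove_gap_only_columns(msa(x$seqs[keep], reference = x$reference))
}

#' Remove columns that contain only gaps
#' @param x an [msa()].
#' @return [msa()] without gap-only columns.
#' @export
remove_gap_only_columns <- function(x) {
  mat <- do.call(rbind, strsplit(unname(x$seqs), ""))
  keep <- colSums(mat != "-") > 0L
  if (all(keep)) return(x)
  seqs <- stats::setNames(apply(mat[, keep, drop = FALSE], 1L, paste,
                                collapse = ""), msa_ids(x))
  msa(seqs, reference = x$reference)
}

#' Residue/column coordinate maps for an alignment
#'
#' For every row, a bidirectional map between 1-based residue positions
#' and 1-based alignment columns. `seq_to_column` is strictly increasing;
#' `column_to_seq` returns `NA` at gap columns and is the exact inverse of
#' `seq_to_column` on non-gap positions.
#'
#' @param x an [msa()].
#' @return object of class `"coordinate_map"`: per row, `col_of_pos`
#'   (residue -> column) and `pos_of_col` (column -> residue or `NA`).
#' @export
coordinate_map <- function(x) {
  maps <- lapply(x$seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    nongap <- chars != "-"
    pos_of_col <- ifelse(nongap, cumsum(nongap), NA_integer_)
    list(col_of_pos = which(nongap), pos_of_col = as.integer(pos_of_col))
  })
  structure(maps, class = "coordinate_map", width = msa_width(x))
}

#' @rdname coordinate_map
#' @param map a `coordinate_map`.
#' @param row_id row identifier.
#' @param pos 1-based residue position(s).
#' @export
seq_to_column <- function(map, row_id, pos) {
  m <- map[[row_id]]
  if (is.null(m)) stop("no such row: ", row_id)
  if (any(pos < 1L) || any(pos > length(m$col_of_pos)))
    stop("residue position out of range for row ", row_id)
  m$col_of_pos[pos]
}

#' @rdname coordinate_map
#' @param column 1-based alignment column(s).
#' @return `column_to_seq`: residue position, or `NA` where the row has a
#'   gap.
#' @export
column_to_seq <- function(map, row_id, column) {
  m <- map[[row_id]]
  if (is.null(m)) stop("no such row: ", row_id)
  if (any(column < 1L) || any(column > attr(map, "width")))
    stop("column out of range")
  m$pos_of_col[column]
}
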