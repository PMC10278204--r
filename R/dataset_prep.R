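# Entry-level filters, greedy identity clustering of reference proteins,
# ortholog-set merging across providers, and the ortholog length filter.

#' Filter annotated entries by curation rules
#'
#' Applies, in order: (i) the accession is present in the supplied
#' canonical-sequence map, (ii) the entry parsed as structurally valid
#' (full-length regions within bounds), (iii) the sequence has no
#' undefined residues (`X`), (iv) the sequence is identical to the
#' canonical one. Rules (i) and (iv) need a caller-supplied map of
#' canonical sequences; when it is absent they are skipped with a warning
#' (no network access is ever attempted). Rejection is data, not an
#' error: each rejected entry carries the first failing rule.
#'
#' @param entries list of [annotated_entry()] objects.
#' @param canonical optional named character vector, accession ->
#'   canonical sequence.
#' @return list with `kept` (entries) and `rejected` (`data.frame` with
#'   `accession`, `disprot_id`, `reason`).
#' @export
filter_entries <- function(entries, canonical = NULL) {
  if (is.null(canonical))
    warning("no canonical sequences supplied; rules (i)/(iv) skipped")
  reasons <- vapply(entries, function(e) {
    acc <- e$protein$accession
    if (!is.null(canonical) && !acc %in% names(canonical))
      return("rule (i): not a known canonical protein")
    if (!e$valid)
      return(paste0("rule (ii): ", e$invalid_reason))
    if (isTRUE(e$protein$has_x))
      return("rule (iii): undefined residue 'X' in sequence")
    if (!is.null(canonical) && e$protein$sequence != canonical[[acc]])
      return("rule (iv): sequence differs from canonical")
    NA_character_
  }, character(1))
  keep <- is.na(reasons)
  rejected <- data.frame(
    accession = vapply(entries[!keep], function(e) e$protein$accession, ""),
    disprot_id = vapply(entries[!keep], function(e) e$disprot_id, ""),
    reason = reasons[!keep], stringsAsFactors = FALSE)
  list(kept = entries[keep], rejected = rejected)
}

#' Count region terms across entries
#' @param entries list of [annotated_entry()] objects.
#' @return named integer vector with elements `GO` and `IDPO`.
#' @export
count_region_terms <- function(entries) {
  ont <- unlist(lapply(entries, function(e) e$regions$ontology))
  c(GO = sum(ont == "GO"), IDPO = sum(ont == "IDPO"))
}

#' Global pairwise percent identity between two sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps 10/0.5) via
#' Biostrings; identity is the number of identical aligned pairs over the
#' full alignment length, gap columns included. This alignment-based value
#' is the clustering contract; word-based tools are accelerators of it.
#'
#' @param a,b amino-acid strings.
#' @return percent in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  100 * sum(p == s & p != "-") / length(p)
}

#' Greedy incremental clustering by percent identity
#'
#' CD-HIT-style scheme: sequences are sorted by length descending (ties
#' broken by accession) and each one joins the first existing cluster
#' whose representative it matches at `>= threshold` percent identity
#' ([pairwise_identity()]), otherwise it founds a new cluster. The
#' representative is always the founding (longest) member. The result is a
#' partition of the input accessions.
#'
#' @param records protein-record `data.frame`.
#' @param threshold percent identity in `(0, 100]`.
#' @return list of cluster groups, each
#'   `list(representative, members, identity_threshold)`.
#' @export
cluster_by_identity <- function(records, threshold = 80) {
  stopifnot(threshold > 0, threshold <= 100)
  if (nrow(records) == 0L) return(list())
  ord <- order(-nchar(records$sequence), records$accession)
  records <- records[ord, ]
  reps <- character(0)
  members <- list()
  for (i in seq_len(nrow(records))) {
    acc <- records$accession[i]
    seqi <- records$sequence[i]
    placed <- FALSE
    for (k in seq_along(reps)) {
      repseq <- records$sequence[records$accession == reps[k]]
      if (pairwise_identity(seqi, repseq) >= threshold) {
        members[[k]] <- c(members[[k]], acc)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, acc)
      members[[length(reps)]] <- acc
    }
  }
  mapply(function(r, m) list(representative = r, members = m,
                             identity_threshold = threshold),
         reps, members, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Ortholog set for one reference protein
#'
#' @param reference accession of the reference.
#' @param orthologs protein-record `data.frame` (must not include the
#'   reference).
#' @param provider name of the source database; recorded per accession in
#'   the provenance map.
#' @return object of class `"ortholog_set"`.
#' @export
ortholog_set <- function(reference, orthologs, provider = "unknown") {
  if (reference %in% orthologs$accession)
    stop("reference must not be listed among the orthologs")
  structure(list(reference = reference, orthologs = orthologs,
                 provenance = stats::setNames(
                   rep(list(provider), nrow(orthologs)),
                   orthologs$accession)),
            class = "ortholog_set")
}

#' Merge ortholog sets from multiple providers
#'
#' Accession-level union; provenance records every contributing provider.
#' When two providers disagree on the sequence behind an accession the
#' first one wins, with a warning.
#'
#' @param sets list of [ortholog_set()] objects sharing one reference.
#' @return a merged [ortholog_set()].
#' @export
merge_ortholog_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  refs <- unique(vapply(sets, `[[`, "", "reference"))
  if (length(refs) != 1L)
    stop("all sets must share the same reference")
  merged <- sets[[1]]$orthologs
  prov <- sets[[1]]$provenance
  for (s in sets[-1]) {
    for (i in seq_len(nrow(s$orthologs))) {
      acc <- s$orthologs$accession[i]
      if (acc %in% merged$accession) {
        if (merged$sequence[merged$accession == acc] !=
              s$orthologs$sequence[i])
          warning("conflicting sequences for ", acc, "; keeping first")
        prov[[acc]] <- union(prov[[acc]], s$provenance[[acc]])
      } else {
        merged <- rbind(merged, s$orthologs[i, ])
        prov[acc] <- s$provenance[acc]
      }
    }
  }
  out <- ortholog_set(refs, merged)
  out$provenance <- prov
  out
}

#' Length-filter an ortholog set against its reference
#'
#' Literal mode keeps orthologs whose length lies in
#' `[0.30, 1.30] * ref_length` (bounds inclusive); strict mode uses
#' `[0.70, 1.30]`. Idempotent.
#'
#' @param orthologs an [ortholog_set()].
#' @param ref_length reference length in residues (> 0).
#' @param mode `"literal"` or `"strict"`.
#' @return list with `kept` ([ortholog_set()]) and `rejected`
#'   (`data.frame` with `accession`, `length`, `reason`).
#' @export
filter_ortholog_lengths <- function(orthologs, ref_length,
                                    mode = c("literal", "strict")) {
  mode <- match.arg(mode)
  stopifnot(ref_length > 0)
  lo <- if (mode == "literal") 0.30 else 0.70
  len <- nchar(orthologs$orthologs$sequence)
  ok <- len >= lo * ref_length & len <= 1.30 * ref_length
  rejected <- data.frame(
    accession = orthologs$orthologs$accession[!ok],
    length = len[!ok],
    reason = ifelse(len[!ok] < lo * ref_length,
                    sprintf("coverage below %d%% of reference", 100 * lo),
                    "length above 130% of reference"),
    stringsAsFactors = FALSE)
  kept <- orthologs
  kept$orthologs <- orthologs$orthologs[ok, , drop = FALSE]
  kept$provenance <- orthologs$provenance[kept$orthologs$accession]
  list(kept = kept, rejected = rejected)
}

#' Drop clusters whose alignment would hold only the reference
#'
#' @param groups list of cluster groups, each carrying an `orthologs`
#'   element ([ortholog_set()] or `NULL`).
#' @return the groups with at least one ortholog.
#' @export
drop_singleton_clusters <- function(groups) {
  Filter(function(g) {
    !is.null(g$orthologs) && nrow(g$orthologs$orthologs) > 0L
  }, groups)
}
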