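# Internal validation: overlap between transferred and independently
# annotated regions on alignments that contain more than one annotated
# protein, and the plDDT-based disorder call used to check transfers
# against predicted structure confidence.

#' Annotation overlap between a reference region and another row
#'
#' The reference region is mapped to its alignment-column window; each of
#' the other protein's regions (restricted to the same ontology namespace)
#' is mapped likewise, and the overlap is the percentage of the reference
#' window's columns annotated in both. The statistic is deliberately
#' reference-normalized: swapping the two proteins changes the denominator
#' unless their windows have equal width. When the other protein carries
#' no annotation over the window the overlap is zero.
#'
#' @param x [msa()] containing both proteins as rows.
#' @param ref_region single-row annotated-region `data.frame` for the
#'   reference row.
#' @param other_regions annotated-region `data.frame` for the other row
#'   (may be empty).
#' @param other_accession row identifier of the other protein.
#' @param pooled pool the other protein's regions before counting
#'   (default); `FALSE` reports the best single region.
#' @return list of class `"overlap_result"`: `reference_region_id`,
#'   `other_accession`, `other_region_id` (best single region or `NA`),
#'   `overlap_percent`, `bin` (decile label).
#' @export
annotation_overlap <- function(x, ref_region, other_regions,
                               other_accession, pooled = TRUE) {
  stopifnot(inherits(x, "msa"), nrow(ref_region) == 1L)
  ref_acc <- ref_region$protein_accession
  if (!ref_acc %in% msa_ids(x))
    stop("reference region's protein is not a row of the alignment")
  if (!other_accession %in% msa_ids(x))
    stop("'", other_accession, "' is not a row of the alignment")
  cmap <- coordinate_map(x)
  win <- seq_to_column(cmap, ref_acc, ref_region$start:ref_region$end)

  same_ns <- other_regions[other_regions$ontology == ref_region$ontology, ,
                           drop = FALSE]
  cover <- rep(FALSE, length(win))
  best_id <- NA_character_
  best_pct <- 0
  if (nrow(same_ns) > 0) {
    for (i in seq_len(nrow(same_ns))) {
      oc <- seq_to_column(cmap, other_accession,
                          same_ns$start[i]:same_ns$end[i])
      hit <- win %in% oc
      pct_i <- 100 * sum(hit) / length(win)
      if (pct_i > best_pct) {
        best_pct <- pct_i
        best_id <- same_ns$region_id[i]
      }
      cover <- cover | hit
    }
  }
  pct <- if (pooled) 100 * sum(cover) / length(win) else best_pct
  structure(list(reference_region_id = ref_region$region_id,
                 other_accession = other_accession,
                 other_region_id = best_id,
                 overlap_percent = pct,
                 bin = overlap_bin(pct)),
            class = "overlap_result")
}

overlap_bin <- function(pct) {
  idx <- pmin(floor(pct / 10), 9)
  sprintf("%d-%d", 10 * idx, 10 * idx + 10)
}

#' Decile histogram of overlap results
#'
#' Bins are left-closed deciles `[0,10) ... [80,90) [90,100]`; counts sum
#' to the number of results.
#'
#' @param results list of `overlap_result` objects, or a numeric vector
#'   of overlap percentages.
#' @return named integer vector of 10 bin counts.
#' @export
overlap_distribution <- function(results) {
  pct <- if (is.numeric(results)) results
         else vapply(results, `[[`, numeric(1), "overlap_percent")
  if (length(pct) == 0L) stop("no overlap results")
  idx <- pmin(floor(pct / 10), 9) + 1
  counts <- tabulate(idx, nbins = 10)
  names(counts) <- sprintf("%d-%d", seq(0, 90, 10), seq(10, 100, 10))
  counts
}

#' Classify residues as disordered from plDDT confidence
#'
#' A residue is called disordered when its plDDT falls below the cutoff
#' (default 0.7 on the 0-1 scale). Vectors on the 0-100 scale (any value
#' above 1.5) are rescaled by 1/100 before thresholding.
#'
#' @param values numeric per-residue plDDT vector.
#' @param cutoff disorder cutoff on the 0-1 scale.
#' @return character vector of `"disordered"` / `"ordered"`.
#' @export
classify_disorder_plddt <- function(values, cutoff = 0.7) {
  if (length(values) == 0L) stop("empty plDDT vector")
  if (any(!is.finite(values))) stop("plDDT values must be finite")
  if (any(values > 1.5)) values <- values / 100
  ifelse(values < cutoff, "disordered", "ordered")
}

#' Read a two-column plDDT table
#'
#' @param path TSV with columns position and plDDT value (header
#'   optional).
#' @return numeric vector ordered by position.
#' @export
read_plddt_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- !grepl("^\\s*\\d", first)
  tab <- utils::read.delim(path, header = header,
                           col.names = c("position", "plddt"))
  tab$plddt[order(tab$position)]
}
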