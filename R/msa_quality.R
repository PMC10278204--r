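# NorMD-style alignment quality scoring.
#
# The objective follows the normalized mean-distance construction: each
# residue is a point in a continuous similarity space (its vector of
# substitution scores against the 20 residue types), a column is scored by
# how tightly its residues cluster around the column consensus, the raw
# score is corrected by the expected score of unrelated sequences with the
# same residue composition and lengths, and normalized by the maximal
# (self-alignment) score. Scores above 1 are legal for gap-rich but
# internally consistent alignments; > 0.6 is the conventional reliability
# threshold.

#' NorMD scoring parameters
#'
#' @param sub_matrix 20x20 substitution matrix defining the residue
#'   similarity space (default BLOSUM62).
#' @param dist_scale divisor applied to consensus distances before
#'   exponentiation; `NULL` uses the mean pairwise distance between
#'   distinct residue vectors under the matrix, which puts a random
#'   mismatch at roughly `exp(-1)` column credit.
#' @param gap_open,gap_extend per-event gap costs subtracted from the raw
#'   column-score sum (per row, averaged over rows). Kept small: gaps
#'   already earn no column credit.
#' @return list of class `"normd_params"`.
#' @export
normd_params <- function(sub_matrix = blosum62_20(), dist_scale = NULL,
                         gap_open = 0.5, gap_extend = 0.05) {
  v <- sub_matrix  # rows are the residue points in similarity space
  pd <- as.matrix(stats::dist(v))
  if (is.null(dist_scale)) dist_scale <- mean(pd[upper.tri(pd)])
  structure(list(sub_matrix = sub_matrix, dist_scale = dist_scale,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "normd_params")
}

#' NorMD score of a multiple sequence alignment
#'
#' Deterministic, invariant to row order. Errors on a single-row
#' alignment (the score is undefined); returns `NA` with a warning for the
#' degenerate case where the alignment is so gap-rich that the
#' composition-expected score reaches the self-alignment maximum.
#'
#' @param x an [msa()].
#' @param params a [normd_params()] object.
#' @return a single numeric score (typically in `[0, ~1.3]`).
#' @export
normd_score <- function(x, params = normd_params()) {
  stopifnot(inherits(x, "msa"))
  n <- length(x$seqs)
  if (n < 2L) stop("NorMD is undefined for fewer than 2 rows")
  if (msa_width(x) < 1L) stop("empty alignment")

  V <- params$sub_matrix          # 20 x 20, row per residue point
  sigma <- params$dist_scale
  mat <- do.call(rbind, strsplit(unname(x$seqs), ""))
  mat[!(mat %in% AA20)] <- "-"    # unknown residues scored as gaps

  # residue counts per column: 20 x C
  counts <- apply(mat, 2L, function(col)
    tabulate(match(col, AA20), nbins = 20L))
  ncol_aln <- ncol(counts)
  nres <- colSums(counts)         # non-gap residues per column

  scored <- nres > 0L
  # column consensus points X = V^T counts / nres : 20 x C
  X <- (t(V) %*% counts[, scored, drop = FALSE]) %*%
    diag(1 / nres[scored], nrow = sum(scored))
  # distances of each residue point to each column consensus: 20 x C
  self_sq <- rowSums(V^2)
  cons_sq <- colSums(X^2)
  D <- sqrt(pmax(outer(self_sq, cons_sq, "+") - 2 * (V %*% X), 0))
  credit <- exp(-D / sigma)       # 20 x C
  col_scores <- colSums(counts[, scored, drop = FALSE] * credit) /
    nres[scored]

  # gap cost: affine, counted per row, averaged over rows
  gaprun <- function(row) {
    r <- rle(row == "-")
    opens <- sum(r$values)
    exts <- sum(r$lengths[r$values]) - opens
    c(opens, exts)
  }
  gp <- rowSums(apply(mat, 1L, gaprun))
  raw <- sum(col_scores) -
    (params$gap_open * gp[1] + params$gap_extend * gp[2]) / n

  # composition-expected score of unrelated sequences, same composition
  # and alignment length
  p <- rowSums(counts) / sum(counts)
  xbar <- as.numeric(t(V) %*% p)
  d0 <- sqrt(pmax(self_sq - 2 * (V %*% xbar) + sum(xbar^2), 0))
  e_col <- sum(p * exp(-d0 / sigma))
  expected <- ncol_aln * e_col

  # maximal (self-alignment) score: each sequence against itself scores 1
  # per residue, so the mean ungapped length
  max_self <- mean(nchar(gsub("-", "", x$seqs, fixed = TRUE)))

  denom <- max_self - expected
  if (denom <= 0) {
    warning("alignment too gap-rich for NorMD normalization; returning NA")
    return(NA_real_)
  }
  (raw - expected) / denom
}

#' Reliability call for a NorMD score
#'
#' Strict inequality: a score of exactly `threshold` is not reliable.
#'
#' @param score numeric NorMD score(s).
#' @param threshold reliability cutoff (default 0.6).
#' @return logical.
#' @export
is_reliable <- function(score, threshold = 0.6) {
  !is.na(score) & score > threshold
}

#' Quality report for an alignment
#'
#' @param x an [msa()].
#' @param scope `"global"` or `"region"`.
#' @param threshold reliability cutoff passed to [is_reliable()].
#' @param params [normd_params()].
#' @return list of class `"quality_report"` with fields `normd`, `n_rows`,
#'   `n_columns`, `scope`, `reliable`, and `identity_to_reference` (named
#'   numeric, percent per non-reference row).
#' @export
quality_report <- function(x, scope = c("global", "region"),
                           threshold = 0.6, params = normd_params()) {
  scope <- match.arg(scope)
  score <- normd_score(x, params)
  others <- setdiff(msa_ids(x), x$reference)
  ids <- vapply(others, function(id) identity_to_reference(x, id),
                numeric(1))
  structure(list(normd = score, n_rows = length(x$seqs),
                 n_columns = msa_width(x), scope = scope,
                 reliable = is_reliable(score, threshold),
                 identity_to_reference = as.list(ids)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report %s: NorMD %.3f (%s), %d rows x %d cols>\n",
              x$scope, x$normd, if (x$reliable) "reliable" else "unreliable",
              x$n_rows, x$n_columns))
  invisible(x)
}
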