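test_that("two identical sequences align gap-free", {
  recs <- protein_records(c("A", "B"), c("ACDEFGHIKL", "ACDEFGHIKL"))
  aln <- align_family(recs, "A")
  expect_equal(unname(aln$seqs), c("ACDEFGHIKL", "ACDEFGHIKL"))
})

test_that("a deletion yields one gap column in the shorter row", {
  # exhaustive check over the 3 possible single-gap placements in "ACE":
  # A-CE, AC-E, ACE-; BLOSUM62 favors AC-E (keeps A, C and E matched)
  recs <- protein_records(c("A", "B"), c("ACDE", "ACE"))
  aln <- align_family(recs, "A")
  expect_equal(unname(aln$seqs[["A"]]), "ACDE")
  expect_equal(unname(aln$seqs[["B"]]), "AC-E")
})

test_that("pairwise builtin alignment matches the Needleman-Wunsch oracle", {
  set.seed(14)
  for (rep in 1:5) {
    a <- rand_seq(60)
    ch <- strsplit(a, "")[[1]]
    drop <- sort(sample(60, 4))
    b <- paste(ch[-drop], collapse = "")
    aln <- builtin_progressive_align(protein_records(c("A", "B"), c(a, b)),
                                     "A")
    or <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    score_of <- function(x, y) {
      xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
      M <- blosum62_20()
      s <- 0
      for (row in list(xs, ys)) {
        r <- rle(row == "-")
        s <- s - 10 * sum(r$values) - 0.5 * (sum(r$lengths[r$values]) -
                                               sum(r$values))
      }
      both <- xs != "-" & ys != "-"
      s + sum(M[cbind(xs[both], ys[both])])
    }
    # the builtin path is optimal under its own objective, so it must
    # score at least as well as the independent aligner's path does
    # (gap-cost conventions differ slightly between the two)
    expect_gte(score_of(aln$seqs[["A"]], aln$seqs[["B"]]),
               score_of(as.character(Biostrings::alignedPattern(or)),
                        as.character(Biostrings::alignedSubject(or))) -
                 1e-8)
  }
})

test_that("progressive alignment never mutates residues", {
  fam <- basic_family(seed = 3)
  recs <- protein_records(
    c(fam$reference$accession, fam$orthologs$accession),
    c(fam$reference$sequence, fam$orthologs$sequence))
  for (method in c("builtin", "mafft")) {
    if (method == "mafft" && !nzchar(Sys.which("mafft"))) next
    aln <- align_family(recs, fam$accession, aligner_spec(method))
    expect_equal(unname(ungap_rows(aln)), recs$sequence)
    expect_equal(msa_ids(aln), recs$accession)
  }
})

test_that("aligned identity tracks the exhaustive pairwise oracle", {
  fam <- basic_family(seed = 5, indel_rate = 0)
  recs <- protein_records(
    c(fam$reference$accession, fam$orthologs$accession),
    c(fam$reference$sequence, fam$orthologs$sequence))
  aln <- align_family(recs, fam$accession)
  for (id in fam$orthologs$accession) {
    pw <- pairwise_identity(fam$reference$sequence,
                            recs$sequence[recs$accession == id])
    expect_gte(identity_to_reference(aln, id), pw - 2)
  }
})

test_that("three identical sequences align gap-free", {
  s <- rand_seq(40)
  aln <- builtin_progressive_align(
    protein_records(c("A", "B", "C"), c(s, s, s)), "A")
  expect_false(any(grepl("-", aln$seqs, fixed = TRUE)))
})

test_that("identity to reference counts reference columns only", {
  x <- msa(c(R = "ACDE", O = "A-DE"), reference = "R")
  expect_equal(identity_to_reference(x, "O"), 75)
  expect_equal(identity_to_reference(x, "R"), 100)

  # brute-force column-scan oracle on random gapped pairs
  set.seed(6)
  for (rep in 1:10) {
    n <- 30L
    mk_row <- function() paste(sample(c(AA20_test(), "-"), n, replace = TRUE,
                                      prob = c(rep(1, 20), 5)),
                               collapse = "")
    r <- mk_row(); o <- mk_row()
    if (!grepl("[A-Z]", r)) next
    x2 <- msa(c(R = r, O = o), reference = "R")
    rs <- strsplit(r, "")[[1]]; os <- strsplit(o, "")[[1]]
    oracle <- 100 * sum(rs != "-" & rs == os) / sum(rs != "-")
    expect_equal(identity_to_reference(x2, "O"), oracle)
  }
})

test_that("identity is invariant to row order and gap-only columns", {
  x <- msa(c(R = "ACDEFG", O = "ACKEFG", P = "AC--FG"), reference = "R")
  base <- identity_to_reference(x, "O")
  sh <- msa(x$seqs[c("P", "O", "R")], reference = "R")
  expect_equal(identity_to_reference(sh, "O"), base)
  padded <- msa(vapply(x$seqs, function(s)
    paste0(substr(s, 1, 3), "-", substr(s, 4, 6)), ""), reference = "R")
  expect_equal(identity_to_reference(padded, "O"), base)
})

test_that("identity errors when the reference is all-gap in range", {
  x <- msa(c(R = "--AC", O = "GGAC"), reference = "R")
  expect_error(identity_to_reference(x, "O", columns = 1:2), "all-gap")
})

test_that("row filtering keeps the reference, is idempotent and monotone", {
  x <- msa(c(R = "ACDEFGHIKL", O1 = "ACDEFGHIKL", O2 = "ACDEFGAAAA",
             O3 = "AAAAAAAAAA"), reference = "R")
  same <- drop_low_identity_rows(x, 80)
  expect_setequal(msa_ids(same), c("R", "O1"))
  # a 60%-identity decoy is removed at threshold 80 but kept at 60
  expect_true("O2" %in% msa_ids(drop_low_identity_rows(x, 60)))
  # idempotent
  expect_equal(drop_low_identity_rows(same, 80), same)
  # monotone: higher threshold keeps a subset
  for (thr in c(20, 40, 60, 80, 100)) {
    lo <- msa_ids(drop_low_identity_rows(x, max(thr - 20, 1)))
    hi <- msa_ids(drop_low_identity_rows(x, thr))
    expect_true(all(hi %in% lo))
  }
  # reference always survives, even alone
  only_ref <- drop_low_identity_rows(
    msa(c(R = "ACDE", O = "GGGG"), reference = "R"), 90)
  expect_equal(msa_ids(only_ref), "R")
})

test_that("gap-only columns are removed after filtering", {
  # O2 diverges on reference columns; once it is dropped, column 3
  # holds only gaps and must disappear
  x <- msa(c(R = "AC-DE", O1 = "AC-DE", O2 = "ACK-E"), reference = "R")
  expect_equal(identity_to_reference(x, "O2"), 75)
  f <- drop_low_identity_rows(x, 90)
  expect_setequal(msa_ids(f), c("R", "O1"))
  expect_equal(msa_width(f), 4L)
})

test_that("coordinate maps invert exactly through gaps", {
  x <- msa(c(A = "A-CD", B = "ABCD"))
  cm <- coordinate_map(x)
  expect_equal(seq_to_column(cm, "A", 2), 3L)
  expect_true(is.na(column_to_seq(cm, "A", 2)))
  expect_equal(column_to_seq(cm, "A", 3), 2L)
  expect_error(seq_to_column(cm, "A", 4), "out of range")
  expect_error(column_to_seq(cm, "A", 5), "out of range")

  # round-trip property over 1,000 random gapped rows
  set.seed(60)
  rows <- replicate(1000, paste(
    sample(c(AA20_test(), "-"), 40, replace = TRUE,
           prob = c(rep(1, 20), 8)), collapse = ""))
  rows <- vapply(rows, function(r)
    if (grepl("[A-Z]", r)) r else sub("-", "A", r), "")
  names(rows) <- sprintf("r%04d", seq_along(rows))
  big <- msa(rows)
  cm2 <- coordinate_map(big)
  for (id in sample(names(rows), 60)) {
    npos <- sum(strsplit(rows[[id]], "")[[1]] != "-")
    pos <- seq_len(npos)
    expect_equal(column_to_seq(cm2, id, seq_to_column(cm2, id, pos)), pos)
  }
})

test_that("external aligner adapters honor the error contract", {
  recs <- protein_records(c("A", "B"), c("ACDE", "ACDE"))
  expect_error(align_family(recs, "A", aligner_spec("clustal-omega")),
               "builtin")
  expect_error(align_family(recs[1, ], "A"), "at least 2")
})
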