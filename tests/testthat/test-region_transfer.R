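region_row <- function(acc, start, end, term = "IDPO:00076",
                       name = "disorder", id = "R1") {
  annotated_regions(id, acc, start, end, term, name)
}

test_that("chopping maps reference residues through gaps", {
  x <- msa(c(R = "ACDEF", O = "ACKEF"), reference = "R")
  ch <- chop_region(x, region_row("R", 2, 4))
  expect_equal(ch$columns, 2:4)
  expect_equal(ch$rows$subseq[ch$rows$accession == "R"], "CDE")

  x2 <- msa(c(R = "A-CD", O = "ABCD"), reference = "R")
  ch2 <- chop_region(x2, region_row("R", 2, 3))
  expect_equal(ch2$columns, 3:4)  # residues C,D sit in columns 3-4
  expect_equal(ch2$rows$span_start, c(2L, 3L))
  expect_equal(ch2$rows$span_end, c(3L, 4L))
})

test_that("chopped subsequences equal direct extraction via the truth map", {
  fam <- basic_family(seed = 23, indel_rate = 0.05)
  region <- fam$regions[1, ]
  for (k in seq_along(fam$alignments)) {
    pair <- msa(stats::setNames(
      c(fam$alignments[[k]][["reference"]],
        fam$alignments[[k]][["ortholog"]]),
      c(fam$accession, fam$orthologs$accession[k])),
      reference = fam$accession)
    ch <- chop_region(pair, region)
    orow <- ch$rows[ch$rows$accession == fam$orthologs$accession[k], ]
    oracle <- substr(fam$orthologs$sequence[k], orow$span_start,
                     orow$span_end)
    expect_equal(orow$subseq, oracle)
  }
})

test_that("regions outside reference coverage are an error", {
  x <- msa(c(R = "ACDE", O = "ACDE"), reference = "R")
  expect_error(chop_region(x, region_row("R", 3, 9)), "coverage")
  expect_error(chop_region(x, region_row("O", 1, 2)), "reference")
})

test_that("region pipeline keeps identical orthologs and drops decoys", {
  fam <- decoy_family()
  recs <- protein_records(
    c(fam$reference$accession, fam$orthologs$accession),
    c(fam$reference$sequence, fam$orthologs$sequence))
  config <- pipeline_config()
  global <- drop_low_identity_rows(align_family(recs, fam$accession),
                                   config$global_identity)
  expect_true(decoy_accession(fam) %in% msa_ids(global))  # kept globally
  rp <- region_pipeline(global, fam$regions[1, ], config)
  expect_false(rp$untransferable)
  expect_true(rp$report$reliable)
  expect_false(decoy_accession(fam) %in% msa_ids(rp$region_msa))
})

test_that("transfers need both global and region gates to pass", {
  fam <- basic_family(seed = 29)
  recs <- protein_records(
    c(fam$reference$accession, fam$orthologs$accession),
    c(fam$reference$sequence, fam$orthologs$sequence))
  config <- pipeline_config()
  global <- drop_low_identity_rows(align_family(recs, fam$accession),
                                   config$global_identity)
  greport <- quality_report(global, "global")
  rp <- region_pipeline(global, fam$regions[1, ], config)
  records <- transfer_region(rp, fam$regions[1, ], greport, config)
  expect_gt(nrow(records), 0)

  # an unreliable global report suppresses all records
  bad <- greport; bad$reliable <- FALSE
  expect_equal(nrow(transfer_region(rp, fam$regions[1, ], bad, config)), 0)
  # an unreliable region report likewise
  rp_bad <- rp; rp_bad$report$reliable <- FALSE
  expect_equal(nrow(transfer_region(rp_bad, fam$regions[1, ], greport,
                                    config)), 0)
})

test_that("projected spans are exact when no indels are planted", {
  fam <- simulate_family(family_sim_config(
    n_orthologs = 10, target_identities = 90, indel_rate = 0,
    planted_regions = data.frame(start = 40L, end = 90L,
                                 term_id = "IDPO:00076"),
    seed = 37), "EXACT001", 1L)
  fx <- fixture_dir(list(fam))
  res <- run_pipeline(read_disprot_json(fx$json), fx$dir)
  expect_equal(nrow(res$transfers), 10L)
  expect_true(all(res$transfers$ortho_start == 40L))
  expect_true(all(res$transfers$ortho_end == 90L))
})

test_that("tricky terms are exactly the eleven modification-site ids", {
  expect_true(flag_tricky_terms("IDPO:00024"))
  expect_true(flag_tricky_terms("IDPO:00034"))
  expect_false(flag_tricky_terms("IDPO:00023"))
  expect_false(flag_tricky_terms("IDPO:00035"))
  expect_false(flag_tricky_terms("IDPO:00076"))
  expect_false(flag_tricky_terms("GO:0005515"))
  all_ids <- sprintf("IDPO:%05d", 1:100)
  expect_equal(sum(flag_tricky_terms(all_ids)), 11L)
  # flagged records are emitted, never suppressed
  fam <- grid_families()[[3]]
  fx <- fixture_dir(list(fam))
  res <- run_pipeline(read_disprot_json(fx$json), fx$dir)
  tricky <- res$transfers[res$transfers$term_id == "IDPO:00024", ]
  expect_gt(nrow(tricky), 0)
  expect_true(all(tricky$tricky))
  expect_false(any(res$transfers$tricky[res$transfers$term_id ==
                                          "IDPO:00076"]))
})

test_that("an empty ortholog directory yields zero transfers", {
  fam <- basic_family(seed = 41)
  fx <- fixture_dir(list(fam))
  empty <- tempfile("empty"); dir.create(empty)
  res <- run_pipeline(read_disprot_json(fx$json), empty)
  expect_equal(nrow(res$transfers), 0L)
  expect_equal(res$summary$clusters, 1L)
  expect_equal(res$summary$clusters_with_orthologs, 0L)
  expect_equal(res$summary$terms_transferred, 0L)
  expect_equal(res$summary$proteins_reached, 0L)
})

test_that("pipeline output equals the generator's expected table", {
  fam <- basic_family(seed = 11)
  fx <- fixture_dir(list(fam))
  res <- run_pipeline(read_disprot_json(fx$json), fx$dir)
  key <- c("region_id", "term_id", "ref_start", "ref_end",
           "ortholog_accession", "ortho_start", "ortho_end")
  got <- res$transfers[, key]
  want <- fx$expected[, key]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("no emitted record violates the quality gates", {
  families <- grid_families()
  fx <- fixture_dir(families)
  config <- pipeline_config()
  res <- run_pipeline(read_disprot_json(fx$json), fx$dir, config)
  expect_gt(nrow(res$transfers), 0)
  expect_true(all(res$transfers$region_normd > config$normd_min))
  expect_true(all(res$transfers$region_identity >=
                    config$region_identity))
})

test_that("disabling the region gate yields a strict superset", {
  fam <- decoy_family()
  fx <- fixture_dir(list(fam))
  entries <- read_disprot_json(fx$json)
  gated <- run_pipeline(entries, fx$dir)
  ungated <- run_pipeline(entries, fx$dir,
                          pipeline_config(region_gate = FALSE))
  expect_false(decoy_accession(fam) %in%
                 gated$transfers$ortholog_accession)
  expect_true(decoy_accession(fam) %in%
                ungated$transfers$ortholog_accession)
  expect_true(all(transfer_key(gated$transfers) %in%
                    transfer_key(ungated$transfers)))
  expect_gt(nrow(ungated$transfers), nrow(gated$transfers))
})

test_that("per-family failures are isolated and logged", {
  fam <- basic_family(seed = 47)
  fx <- fixture_dir(list(fam))
  # corrupt one provider file so that family fails while parsing
  bad_dir <- tempfile("bad"); dir.create(bad_dir)
  file.copy(fx$fasta[[1]], file.path(bad_dir,
                                     basename(fx$fasta[[1]])))
  writeLines(c(">X1", "ACDE", ">X1", "ACDF"),
             file.path(bad_dir, "OTHER001.sim.fasta"))
  other <- annotated_entry(
    protein_records("OTHER001", rand_seq(50), source = "reference"),
    orthotransfer:::empty_region_table(), "DPX")
  entries <- c(read_disprot_json(fx$json), list(other))
  res <- suppressWarnings(run_pipeline(entries, bad_dir))
  expect_gt(nrow(res$transfers), 0)          # good family still ran
  expect_true("OTHER001" %in% names(res$failures))
})
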