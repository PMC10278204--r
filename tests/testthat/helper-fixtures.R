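# Shared fixture builders. Everything is generated in code at test time;
# no data files are read from disk except those the tests write first.

rand_seq <- function(n) paste(sample(AA20_test(), n, replace = TRUE),
                              collapse = "")

AA20_test <- function() c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# a family with one planted disorder region, defaults of the generator
basic_family <- function(seed = 11, accession = "SIM0001", ...) {
  simulate_family(
    family_sim_config(
      planted_regions = data.frame(start = 40L, end = 90L,
                                   term_id = "IDPO:00076",
                                   term_name = "disorder"),
      seed = seed, ...),
    accession = accession, family_index = 1L)
}

# family with one ortholog diverged only inside the annotated region
# (kept by the global gate, rejected by the region gate)
decoy_family <- function(seed = 7, accession = "SIM0002") {
  simulate_family(
    family_sim_config(
      n_orthologs = 8L,
      target_identities = c(95, 92, 90, 88, 86, 84, 82, 85),
      planted_regions = data.frame(
        start = 60L, end = 110L, term_id = "GO:0005515",
        term_name = "Protein binding",
        region_identity = I(list(c(NA, NA, NA, NA, NA, NA, NA, 30)))),
      indel_rate = 0, seed = seed),
    accession = accession, family_index = 1L)
}

decoy_accession <- function(fam) paste0(fam$accession, "_o08")

# three unrelated families spanning both identity bands, for grid runs
grid_families <- function(seed = 42) {
  famA <- simulate_family(family_sim_config(
    reference_length = 180L,
    planted_regions = data.frame(start = 30L, end = 80L,
                                 term_id = "IDPO:00076",
                                 term_name = "disorder"),
    seed = seed), "GRIDA001", 1L)
  famB <- simulate_family(family_sim_config(
    reference_length = 160L, n_orthologs = 8L,
    target_identities = c(96, 94, 92, 90, 88, 87, 86, 85),
    planted_regions = data.frame(
      start = 50L, end = 100L, term_id = "GO:0005515",
      term_name = "Protein binding",
      region_identity = I(list(c(90, 88, 85, 82, 75, 72, 65, 62)))),
    seed = seed), "GRIDB001", 2L)
  famC <- simulate_family(family_sim_config(
    reference_length = 150L, n_orthologs = 6L,
    target_identities = c(92, 88, 84, 78, 72, 68),
    planted_regions = data.frame(
      start = c(20L, 90L), end = c(60L, 130L),
      term_id = c("IDPO:00076", "IDPO:00024"),
      term_name = c("disorder", "molecular recognition display site")),
    seed = seed), "GRIDC001", 3L)
  list(famA, famB, famC)
}

# write a families fixture to a temp dir; returns make_disprot_fixture()
# output plus the dir
fixture_dir <- function(families, config = pipeline_config()) {
  dir <- tempfile("fixture")
  fx <- make_disprot_fixture(families, dir, config)
  fx$dir <- dir
  fx
}

# key columns identifying a transfer
transfer_key <- function(tab) {
  paste(tab$region_id, tab$term_id, tab$ortholog_accession)
}

# mutate a fraction p of alignment cells to random residues (degradation)
degrade_msa <- function(x, p) {
  mat <- do.call(rbind, strsplit(unname(x$seqs), ""))
  res <- which(mat != "-")
  n <- round(p * length(res))
  if (n > 0) {
    pick <- res[sample.int(length(res), n)]
    mat[pick] <- sample(AA20_test(), n, replace = TRUE)
  }
  msa(stats::setNames(apply(mat, 1L, paste, collapse = ""), msa_ids(x)),
      reference = x$reference)
}
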