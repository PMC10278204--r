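# The core of the package: chop the gated global alignment at each
# annotated region, filter and realign per region, score the region MSA
# with NorMD, and emit transfer records only when both the global and the
# region alignment pass the quality gate.

#' Pipeline configuration
#'
#' The four identity thresholds form the standard 2x2x2x2 parameter grid
#' (clustering 60/80, global 60/80, region 60/80, two aligners); the
#' defaults are 80% reference clustering and 60% global and region
#' identity, with the reliability cutoff at a NorMD of 0.6.
#'
#' @param disprot_cluster_identity percent identity for reference
#'   clustering (60 or 80 in the standard grid).
#' @param aligner an [aligner_spec()]. The deterministic builtin aligner
#'   is the default; `"clustal-omega"` and `"mafft"` adapters are the
#'   production path when the binaries are installed.
#' @param global_identity,region_identity row-filter thresholds (percent).
#' @param normd_min reliability cutoff (strict `>`).
#' @param length_filter_mode `"literal"` (`[0.30, 1.30]` of the reference
#'   length) or `"strict"` (`[0.70, 1.30]`).
#' @param realign_regions realign chopped region subsequences before and
#'   after the region identity filter (default); `FALSE` slices the
#'   global alignment only.
#' @param region_gate apply the region-level quality gate (default). With
#'   `FALSE` every ortholog surviving the global gate receives every
#'   region annotation — the permissive behavior the region gate exists
#'   to correct; useful for quantifying how much it rejects.
#' @param seed integer seed recorded in manifests.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(disprot_cluster_identity = 80,
                            aligner = aligner_spec("builtin"),
                            global_identity = 60,
                            region_identity = 60,
                            normd_min = 0.6,
                            length_filter_mode = c("literal", "strict"),
                            realign_regions = TRUE,
                            region_gate = TRUE,
                            seed = 1L) {
  stopifnot(disprot_cluster_identity > 0, disprot_cluster_identity <= 100,
            global_identity > 0, global_identity <= 100,
            region_identity > 0, region_identity <= 100)
  structure(list(disprot_cluster_identity = disprot_cluster_identity,
                 aligner = aligner,
                 global_identity = global_identity,
                 region_identity = region_identity,
                 normd_min = normd_min,
                 length_filter_mode = match.arg(length_filter_mode),
                 realign_regions = isTRUE(realign_regions),
                 region_gate = isTRUE(region_gate),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Chop a global alignment at an annotated region
#'
#' The column window spans the reference residues `start..end` mapped
#' through the reference row's gaps. For every row the window's ungapped
#' subsequence and its span in the row's own 1-based numbering are
#' returned; rows with no residues in the window are marked absent.
#'
#' @param x global [msa()] (the region's protein must be its reference
#'   row).
#' @param region single-row annotated-region `data.frame`.
#' @return list with `columns` (integer range), `slice` (the column-slice
#'   [msa()]), and `rows` (`data.frame`: `accession`, `subseq`,
#'   `span_start`, `span_end`, `absent`).
#' @export
chop_region <- function(x, region) {
  stopifnot(inherits(x, "msa"), nrow(region) == 1L)
  if (region$protein_accession != x$reference)
    stop("region does not belong to the alignment's reference row")
  cmap <- coordinate_map(x)
  ref_len <- length(cmap[[x$reference]]$col_of_pos)
  if (region$end > ref_len)
    stop("region outside reference coverage")
  cols <- seq_to_column(cmap, x$reference, region$start):
    seq_to_column(cmap, x$reference, region$end)
  sub <- substr(x$seqs, cols[1], cols[length(cols)])
  rows <- lapply(msa_ids(x), function(id) {
    pos <- column_to_seq(cmap, id, cols)
    nong <- pos[!is.na(pos)]
    data.frame(accession = id,
               subseq = gsub("-", "", sub[[id]], fixed = TRUE),
               span_start = if (length(nong)) nong[1] else NA_integer_,
               span_end = if (length(nong)) nong[length(nong)]
                          else NA_integer_,
               absent = length(nong) == 0L,
               stringsAsFactors = FALSE)
  })
  slice <- msa(stats::setNames(sub, msa_ids(x)), reference = x$reference)
  list(columns = cols, slice = slice, rows = do.call(rbind, rows))
}

#' Per-region alignment pipeline
#'
#' Order of operations: chop the global alignment, realign the ungapped
#' window subsequences with the configured aligner, measure each row's
#' identity to the reference over the region, drop rows below
#' `config$region_identity`, realign the survivors, and score the result
#' with NorMD. Rows absent from the window never reappear. With
#' `config$realign_regions = FALSE` the global-alignment slice is
#' filtered directly without realignment.
#'
#' @param x global [msa()], already row-filtered at the global identity
#'   threshold.
#' @param region single-row annotated-region `data.frame`.
#' @param config a [pipeline_config()].
#' @return list with `region_msa` ([msa()] or `NULL`), `report`
#'   ([quality_report()] or `NULL`), `rows` (the chop table), and
#'   `untransferable` (logical: fewer than 2 survivors).
#' @export
region_pipeline <- function(x, region, config = pipeline_config()) {
  chop <- chop_region(x, region)
  present <- chop$rows[!chop$rows$absent, ]
  if (!x$reference %in% present$accession)
    stop("reference absent from its own region window")
  if (nrow(present) < 2L)
    return(list(region_msa = NULL, report = NULL, rows = chop$rows,
                untransferable = TRUE))

  realign <- function(tab) {
    if (nrow(tab) < 2L) return(NULL)
    recs <- protein_records(tab$accession, tab$subseq)
    align_family(recs, x$reference, config$aligner)
  }
  first <- if (config$realign_regions) realign(present) else
    remove_gap_only_columns(
      msa(chop$slice$seqs[present$accession], reference = x$reference))
  filtered <- drop_low_identity_rows(first, config$region_identity)
  survivors <- present[present$accession %in% msa_ids(filtered), ]
  if (nrow(survivors) < 2L)
    return(list(region_msa = NULL, report = NULL, rows = chop$rows,
                untransferable = TRUE))
  final <- if (config$realign_regions && nrow(survivors) < nrow(present))
    realign(survivors) else filtered
  report <- quality_report(final, scope = "region",
                           threshold = config$normd_min)
  list(region_msa = final, report = report, rows = chop$rows,
       untransferable = FALSE)
}

#' Emit transfer records for one region
#'
#' Records are emitted only when both the global and the region NorMD
#' exceed the reliability cutoff; one record per surviving ortholog with
#' at least one residue in the region window. The projected span is the
#' first/last aligned residue of that ortholog within the window, in the
#' ortholog's own 1-based numbering. Terms whose transfer requires
#' conservation of specific modifiable residues are flagged tricky, never
#' suppressed.
#'
#' @param pipeline result of [region_pipeline()].
#' @param region single-row annotated-region `data.frame`.
#' @param global_report the global [quality_report()].
#' @param config a [pipeline_config()].
#' @return transfer-record `data.frame` (possibly empty).
#' @export
transfer_region <- function(pipeline, region, global_report,
                            config = pipeline_config()) {
  empty <- expected_transfers(list(), config)
  if (!isTRUE(global_report$reliable)) return(empty)
  if (pipeline$untransferable || is.null(pipeline$report)) return(empty)
  if (!isTRUE(pipeline$report$reliable)) return(empty)
  ids <- setdiff(msa_ids(pipeline$region_msa),
                 region$protein_accession)
  rows <- pipeline$rows[match(ids, pipeline$rows$accession), ]
  rows <- rows[!rows$absent, , drop = FALSE]
  if (nrow(rows) == 0L) return(empty)
  ident <- vapply(rows$accession, function(id)
    identity_to_reference(pipeline$region_msa, id), numeric(1))
  data.frame(reference_accession = region$protein_accession,
             region_id = region$region_id,
             term_id = region$term_id,
             term_name = region$term_name,
             ref_start = region$start, ref_end = region$end,
             ortholog_accession = rows$accession,
             ortho_start = rows$span_start,
             ortho_end = rows$span_end,
             region_normd = pipeline$report$normd,
             region_identity = unname(ident),
             n_orthologs_in_region = nrow(rows),
             tricky = flag_tricky_terms(region$term_id),
             stringsAsFactors = FALSE)
}

#' Flag ontology terms whose homology transfer needs expert review
#'
#' Eleven disorder-ontology terms — mostly post-translational-modification
#' display sites (phosphorylation, acetylation, methylation, ...) — depend
#' on the conservation of specific modifiable residues, which sequence
#' identity alone does not guarantee. They span the identifier range
#' IDPO:00024 to IDPO:00034. GO terms are never flagged.
#'
#' @param term_id character vector of term identifiers.
#' @return logical vector.
#' @export
flag_tricky_terms <- function(term_id) {
  num <- suppressWarnings(as.integer(sub("^IDPO:", "", term_id)))
  startsWith(term_id, "IDPO:") & !is.na(num) & num >= 24L & num <= 34L
}

#' Run the full transfer pipeline
#'
#' Stages: entry filtering, reference clustering, per-cluster ortholog
#' merge and length filter, singleton removal, global alignment, global
#' identity filter, global NorMD gate, per-region pipeline, transfer.
#' Per-family failures are isolated and logged in the summary; the run
#' continues.
#'
#' @param entries list of [annotated_entry()] objects.
#' @param ortholog_files directory containing per-provider FASTA files
#'   named `<reference_accession>.<provider>.fasta`, or a named character
#'   vector of FASTA paths keyed by reference accession.
#' @param config a [pipeline_config()].
#' @param canonical optional accession -> canonical sequence map for the
#'   entry filters.
#' @return list of class `"pipeline_result"` with `transfers`
#'   (transfer-record `data.frame`), `reports` (per family: global and
#'   per-region quality reports), `summary` (stage counts), `rejected`
#'   (entry rejections), `failures` (per-family error messages).
#' @export
run_pipeline <- function(entries, ortholog_files,
                         config = pipeline_config(), canonical = NULL) {
  filt <- if (is.null(canonical)) suppressWarnings(filter_entries(entries))
          else filter_entries(entries, canonical)
  kept <- filt$kept
  summary <- list(entries_in = length(entries),
                  entries_kept = length(kept))
  if (length(kept) == 0L)
    return(pipeline_result(NULL, list(), summary, filt$rejected, list(),
                           config))

  prots <- do.call(rbind, lapply(kept, `[[`, "protein"))
  groups <- cluster_by_identity(prots, config$disprot_cluster_identity)
  summary$clusters <- length(groups)
  entry_of <- stats::setNames(kept, vapply(kept, function(e)
    e$protein$accession, ""))

  # attach merged, length-filtered ortholog sets; a family whose files
  # fail to parse is recorded and skipped, never fatal for the run
  failures <- list()
  for (k in seq_along(groups)) {
    rep_acc <- groups[[k]]$representative
    groups[[k]]$orthologs <- tryCatch({
      sets <- read_provider_sets(rep_acc, ortholog_files)
      if (length(sets) == 0L) NULL else {
        merged <- merge_ortholog_sets(sets)
        ref_len <- nchar(entry_of[[rep_acc]]$protein$sequence)
        filter_ortholog_lengths(merged, ref_len,
                                config$length_filter_mode)$kept
      }
    }, error = function(e) {
      failures[[rep_acc]] <<- conditionMessage(e)
      NULL
    })
  }
  groups <- drop_singleton_clusters(groups)
  summary$clusters_with_orthologs <- length(groups)

  transfers <- list()
  reports <- list()
  n_global_pass <- 0L
  n_region_total <- 0L
  n_region_pass <- 0L
  for (g in groups) {
    rep_acc <- g$representative
    res <- tryCatch({
      entry <- entry_of[[rep_acc]]
      fam <- rbind(entry$protein[, c("accession", "sequence")],
                   g$orthologs$orthologs[, c("accession", "sequence")])
      recs <- protein_records(fam$accession, fam$sequence)
      global <- align_family(recs, rep_acc, config$aligner)
      global <- drop_low_identity_rows(global, config$global_identity)
      greport <- quality_report(global, scope = "global",
                                threshold = config$normd_min)
      fam_reports <- list(global = greport, regions = list())
      fam_transfers <- list()
      if (greport$reliable && length(global$seqs) >= 2L) {
        n_global_pass <- n_global_pass + 1L
        for (i in seq_len(nrow(entry$regions))) {
          region <- entry$regions[i, ]
          n_region_total <- n_region_total + 1L
          rp <- region_pipeline(global, region, config)
          fam_reports$regions[[region$region_id]] <- rp$report
          if (config$region_gate) {
            rec <- transfer_region(rp, region, greport, config)
          } else {
            rec <- ungated_transfer(rp, region, config)
          }
          if (!is.null(rp$report) && isTRUE(rp$report$reliable))
            n_region_pass <- n_region_pass + 1L
          if (nrow(rec)) fam_transfers[[length(fam_transfers) + 1L]] <- rec
        }
      }
      list(reports = fam_reports,
           transfers = if (length(fam_transfers))
             do.call(rbind, fam_transfers) else NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[rep_acc]] <- conditionMessage(res)
    } else {
      reports[[rep_acc]] <- res$reports
      if (!is.null(res$transfers))
        transfers[[length(transfers) + 1L]] <- res$transfers
    }
  }
  summary$global_msas_passing <- n_global_pass
  summary$region_msas_total <- n_region_total
  summary$region_msas_passing <- n_region_pass
  tab <- if (length(transfers)) do.call(rbind, transfers) else NULL
  pipeline_result(tab, reports, summary, filt$rejected, failures, config)
}

# transfers with the region gate disabled: every ortholog surviving the
# global gate, with at least one residue in the window, gets the term
ungated_transfer <- function(pipeline, region, config) {
  rows <- pipeline$rows[!pipeline$rows$absent &
                          pipeline$rows$accession !=
                            region$protein_accession, , drop = FALSE]
  if (nrow(rows) == 0L) return(expected_transfers(list(), config))
  data.frame(reference_accession = region$protein_accession,
             region_id = region$region_id, term_id = region$term_id,
             term_name = region$term_name,
             ref_start = region$start, ref_end = region$end,
             ortholog_accession = rows$accession,
             ortho_start = rows$span_start, ortho_end = rows$span_end,
             region_normd = NA_real_, region_identity = NA_real_,
             n_orthologs_in_region = nrow(rows),
             tricky = flag_tricky_terms(region$term_id),
             stringsAsFactors = FALSE)
}

pipeline_result <- function(transfers, reports, summary, rejected,
                            failures, config) {
  if (is.null(transfers))
    transfers <- expected_transfers(list(), config)
  transfers <- transfers[order(transfers$ref_start, transfers$term_id,
                               transfers$ortholog_accession), ]
  rownames(transfers) <- NULL
  summary$terms_transferred <- nrow(transfers)
  summary$proteins_reached <-
    length(unique(transfers$ortholog_accession))
  structure(list(transfers = transfers, reports = reports,
                 summary = summary, rejected = rejected,
                 failures = failures, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-24s %s\n", nm, x$summary[[nm]]))
  if (length(x$failures))
    cat("  failures:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

# discover `<acc>.<provider>.fasta` files for one reference
read_provider_sets <- function(acc, ortholog_files) {
  paths <- if (length(ortholog_files) == 1L &&
                 dir.exists(ortholog_files)) {
    list.files(ortholog_files,
               pattern = paste0("^", acc, "\\.[^.]+\\.fasta$"),
               full.names = TRUE)
  } else {
    unname(ortholog_files[names(ortholog_files) == acc])
  }
  lapply(sort(paths), function(p) {
    provider <- sub("\\.fasta$", "", sub(paste0("^", acc, "\\."), "",
                                         basename(p)))
    recs <- read_fasta(p)
    ortholog_set(acc, recs, provider = provider)
  })
}
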