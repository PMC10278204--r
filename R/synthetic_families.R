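# Synthetic ortholog families with controlled identities and exact ground
# truth. The generator stands in for ortholog databases: it controls
# percent identity (globally and inside planted annotated regions), plants
# indels, and reports the generation-time alignment so every downstream
# stage can be checked against construction rather than estimation.

#' Configuration for one simulated ortholog family
#'
#' Defaults emulate a vertebrate-style one-to-one ortholog set of a
#' disordered reference protein: ten orthologs spanning 65-95% identity
#' (most of them high), conservative BLOSUM-weighted substitutions, and a
#' low indel rate with short geometric lengths. Identity control is exact:
#' without indels a target of t% on length L yields exactly
#' `round(L*(1-t/100))` substituted positions, and substitutions never hit
#' the same site twice nor re-draw the original residue.
#'
#' @param reference_length residues in the reference.
#' @param n_orthologs number of orthologs.
#' @param target_identities percent identity per ortholog (recycled to
#'   `n_orthologs`).
#' @param indel_rate expected indel events per residue (outside planted
#'   regions unless `allow_indels_in_regions`).
#' @param indel_length_mean mean indel length (geometric).
#' @param planted_regions `data.frame` with columns `start`, `end`,
#'   `term_id`, optional `term_name` and `region_identity` (per-ortholog
#'   identity override inside the window; `NA` = follow the global
#'   target). An override may also be a single percent applied to all
#'   orthologs, or a vector of length `n_orthologs`.
#' @param substitution_model `"blosum"` (replacement weighted by
#'   substitution-score odds, ortholog-like) or `"uniform"`.
#' @param allow_indels_in_regions if `FALSE` (default) indels never fall
#'   inside planted windows, so ground-truth projected spans stay
#'   well-defined.
#' @param seed integer; generation is deterministic given the seed.
#' @return list of class `"family_sim_config"`.
#' @export
family_sim_config <- function(reference_length = 240L,
                              n_orthologs = 10L,
                              target_identities = c(95, 93, 91, 89, 87,
                                                    84, 80, 74, 70, 66),
                              indel_rate = 0.01,
                              indel_length_mean = 2,
                              planted_regions = NULL,
                              substitution_model = c("blosum", "uniform"),
                              allow_indels_in_regions = FALSE,
                              seed = 1L) {
  substitution_model <- match.arg(substitution_model)
  target_identities <- rep_len(target_identities, n_orthologs)
  stopifnot(all(target_identities > 0), all(target_identities <= 100),
            reference_length >= 10L, indel_rate >= 0)
  if (!is.null(planted_regions)) {
    stopifnot(is.data.frame(planted_regions),
              all(c("start", "end", "term_id") %in% names(planted_regions)),
              all(planted_regions$start >= 1L),
              all(planted_regions$end <= reference_length),
              all(planted_regions$start <= planted_regions$end))
    if (is.null(planted_regions$term_name))
      planted_regions$term_name <- planted_regions$term_id
    if (is.null(planted_regions$region_identity))
      planted_regions$region_identity <- NA_real_
  }
  structure(list(reference_length = as.integer(reference_length),
                 n_orthologs = as.integer(n_orthologs),
                 target_identities = target_identities,
                 indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 planted_regions = planted_regions,
                 substitution_model = substitution_model,
                 allow_indels_in_regions = isTRUE(allow_indels_in_regions),
                 seed = as.integer(seed)),
            class = "family_sim_config")
}

# evaluate `code` under a private RNG state, restoring the caller's
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable per-family substream below 2^31
family_seed <- function(seed, family_index) {
  (as.integer(seed) + 7919L * as.integer(family_index)) %% 2000000011L
}

# sample() without the scalar-x surprise
sample_vec <- function(x, n) x[sample.int(length(x), n)]

#' Simulate one ortholog family with ground truth
#'
#' @param config a [family_sim_config()].
#' @param accession reference accession to use.
#' @param family_index index used to derive the per-family RNG substream
#'   from `config$seed`.
#' @return list of class `"sim_family"`: `reference` and `orthologs`
#'   (protein-record data frames), `regions` (planted annotated regions,
#'   or an empty table), `truth` (per-ortholog realized global identity
#'   and, per planted region, realized region identity and true projected
#'   span in the ortholog's own numbering), `alignments` (generation-time
#'   pairwise alignment of each ortholog to the reference), `config`.
#' @export
simulate_family <- function(config, accession = "REF0001",
                            family_index = 1L) {
  stopifnot(inherits(config, "family_sim_config"))
  with_seed(family_seed(config$seed, family_index), {
    L <- config$reference_length
    ref <- sample(AA20, L, replace = TRUE)
    regions <- config$planted_regions
    in_region <- rep(FALSE, L)
    if (!is.null(regions))
      for (i in seq_len(nrow(regions)))
        in_region[regions$start[i]:regions$end[i]] <- TRUE

    subst <- switch(config$substitution_model,
      uniform = function(a) sample(AA20[AA20 != a], 1L),
      blosum = local({
        M <- blosum62_20()
        W <- 2^(M / 2)
        diag(W) <- 0
        function(a) sample(AA20, 1L, prob = W[a, ])
      }))

    orth_rows <- vector("list", config$n_orthologs)
    truth_rows <- vector("list", config$n_orthologs)
    alns <- vector("list", config$n_orthologs)
    for (k in seq_len(config$n_orthologs)) {
      t_global <- config$target_identities[k]
      orth <- ref
      # per-region overrides first, then the global target on the rest
      override_mask <- rep(FALSE, L)
      if (!is.null(regions)) {
        for (i in seq_len(nrow(regions))) {
          ov <- region_override(regions$region_identity[[i]], k)
          if (is.na(ov)) next
          win <- regions$start[i]:regions$end[i]
          nsub <- round(length(win) * (1 - ov / 100))
          if (nsub > length(win))
            stop("region override incompatible with window size")
          sites <- if (nsub > 0) sample_vec(win, nsub) else integer(0)
          for (s in sites) orth[s] <- subst(ref[s])
          override_mask[win] <- TRUE
        }
      }
      free <- which(!override_mask)
      nsub <- round(length(free) * (1 - t_global / 100))
      sites <- if (nsub > 0) sample_vec(free, nsub) else integer(0)
      for (s in sites) orth[s] <- subst(ref[s])

      # indels on the substituted ortholog, as an alignment to the
      # reference: a deletion gaps the ortholog, an insertion gaps the
      # reference
      ref_aln <- ref
      orth_aln <- orth
      if (config$indel_rate > 0) {
        allowed <- if (config$allow_indels_in_regions) rep(TRUE, L)
                   else !in_region
        n_events <- stats::rbinom(1L, L, config$indel_rate)
        if (n_events > 0) {
          at <- sort(sample_vec(which(allowed),
                                min(n_events, sum(allowed))),
                     decreasing = TRUE)
          for (pos in at) {
            len <- stats::rgeom(1L, 1 / config$indel_length_mean) + 1L
            if (stats::runif(1) < 0.5) {        # deletion in the ortholog
              span <- pos:min(pos + len - 1L, length(ref_aln))
              span <- span[ref_aln[span] != "-" &
                             !region_col(ref_aln, span, in_region,
                                         config$allow_indels_in_regions)]
              orth_aln[span] <- "-"
            } else {                             # insertion in the ortholog
              ins <- sample(AA20, len, replace = TRUE)
              ref_aln <- append(ref_aln, rep("-", len), after = pos)
              orth_aln <- append(orth_aln, ins, after = pos)
            }
          }
        }
      }

      orth_seq <- paste(orth_aln[orth_aln != "-"], collapse = "")
      acc_k <- sprintf("%s_o%02d", accession, k)
      ref_pos <- ref_aln != "-"
      realized <- 100 * sum(ref_aln == orth_aln & ref_pos) / L
      reg_truth <- region_truths(ref_aln, orth_aln, regions)
      orth_rows[[k]] <- data.frame(accession = acc_k, sequence = orth_seq,
                                   stringsAsFactors = FALSE)
      truth_rows[[k]] <- cbind(
        data.frame(accession = acc_k, target_identity = t_global,
                   realized_identity = realized, stringsAsFactors = FALSE),
        reg_truth)
      alns[[k]] <- c(reference = paste(ref_aln, collapse = ""),
                     ortholog = paste(orth_aln, collapse = ""))
    }

    orth_df <- do.call(rbind, orth_rows)
    region_table <- if (is.null(regions)) empty_region_table() else
      annotated_regions(sprintf("%sr%03d", accession,
                                seq_len(nrow(regions))),
                        accession, regions$start, regions$end,
                        regions$term_id, regions$term_name)
    structure(list(
      reference = protein_records(accession, paste(ref, collapse = ""),
                                  source = "reference"),
      orthologs = protein_records(orth_df$accession, orth_df$sequence),
      regions = region_table,
      truth = do.call(rbind, truth_rows),
      alignments = alns,
      config = config,
      accession = accession), class = "sim_family")
  })
}

region_override <- function(ov, k) {
  if (is.null(ov)) return(NA_real_)
  if (length(ov) == 1L) return(as.numeric(ov))
  as.numeric(ov[[k]])
}

region_col <- function(ref_aln, span, in_region, allow) {
  if (allow) return(rep(FALSE, length(span)))
  # map alignment positions back to reference positions to test membership
  pos <- cumsum(ref_aln != "-")
  ifelse(ref_aln[span] == "-", FALSE, in_region[pos[span]])
}

# per planted region: realized identity and true projected span
region_truths <- function(ref_aln, orth_aln, regions) {
  if (is.null(regions) || nrow(regions) == 0L)
    return(data.frame(row.names = 1L)[, 0, drop = FALSE])
  ref_pos <- cumsum(ref_aln != "-")
  orth_pos <- cumsum(orth_aln != "-")
  out <- list()
  for (i in seq_len(nrow(regions))) {
    cols <- which(ref_aln != "-" & ref_pos >= regions$start[i] &
                    ref_pos <= regions$end[i])
    w <- regions$end[i] - regions$start[i] + 1L
    ident <- 100 * sum(ref_aln[cols] == orth_aln[cols]) / w
    nongap <- cols[orth_aln[cols] != "-"]
    span <- if (length(nongap)) c(orth_pos[nongap[1]],
                                  orth_pos[nongap[length(nongap)]])
            else c(NA_integer_, NA_integer_)
    out[[paste0("region", i, "_identity")]] <- ident
    out[[paste0("region", i, "_ortho_start")]] <- span[1]
    out[[paste0("region", i, "_ortho_end")]] <- span[2]
  }
  as.data.frame(out)
}

#' Write a DisProt-style fixture from simulated families
#'
#' Emits one DisProt-style JSON covering every family's reference and
#' planted regions, one ortholog FASTA per family (pattern
#' `<accession>.sim.fasta`, readable by [run_pipeline()]), and the
#' generator's expected transfer table for the given thresholds.
#'
#' @param families list of `sim_family` objects.
#' @param dir output directory (created if needed).
#' @param config [pipeline_config()] used to derive the expected table.
#' @return list with paths `json`, `fasta` (named by accession) and
#'   `expected` plus the expected-transfer `data.frame`.
#' @export
make_disprot_fixture <- function(families, dir, config = pipeline_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(families, function(f) {
    regs <- lapply(seq_len(nrow(f$regions)), function(i)
      list(region_id = f$regions$region_id[i], start = f$regions$start[i],
           end = f$regions$end[i], term_id = f$regions$term_id[i],
           term_name = f$regions$term_name[i]))
    list(disprot_id = paste0("DPSIM", f$accession), acc = f$accession,
         sequence = f$reference$sequence, regions = regs)
  })
  json <- file.path(dir, "disprot_fixture.json")
  jsonlite::write_json(list(data = entries, size = length(entries)), json,
                       auto_unbox = TRUE)
  fasta <- vapply(families, function(f) {
    p <- file.path(dir, paste0(f$accession, ".sim.fasta"))
    write_fasta(f$orthologs, p)
    p
  }, character(1))
  names(fasta) <- vapply(families, `[[`, "", "accession")
  expected <- expected_transfers(families, config)
  exp_path <- file.path(dir, "expected_transfers.tsv")
  write_transfer_table(expected, exp_path)
  list(json = json, fasta = fasta, expected_path = exp_path,
       expected = expected)
}

#' Ground-truth expected transfer table for simulated families
#'
#' A (region, ortholog) pair is expected iff the ortholog's realized
#' global identity passes `config$global_identity` and its realized
#' identity inside the region passes `config$region_identity`; the
#' projected span is taken from the generation-time alignment. Alignment
#' quality gates are assumed to pass under the generator's default
#' conditions (high-identity surviving rows), which is what the recovery
#' tests verify.
#'
#' @param families list of `sim_family` objects.
#' @param config a [pipeline_config()].
#' @return transfer-record `data.frame` (same columns as
#'   [write_transfer_table()]).
#' @export
expected_transfers <- function(families, config = pipeline_config()) {
  rows <- list()
  for (f in families) {
    if (nrow(f$regions) == 0L) next
    for (i in seq_len(nrow(f$regions))) {
      id_col <- paste0("region", i, "_identity")
      s_col <- paste0("region", i, "_ortho_start")
      e_col <- paste0("region", i, "_ortho_end")
      ok <- f$truth$realized_identity >= config$global_identity &
        f$truth[[id_col]] >= config$region_identity &
        !is.na(f$truth[[s_col]])
      n_ok <- sum(ok)
      if (n_ok == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        reference_accession = f$accession,
        region_id = f$regions$region_id[i],
        term_id = f$regions$term_id[i],
        term_name = f$regions$term_name[i],
        ref_start = f$regions$start[i], ref_end = f$regions$end[i],
        ortholog_accession = f$truth$accession[ok],
        ortho_start = f$truth[[s_col]][ok],
        ortho_end = f$truth[[e_col]][ok],
        region_normd = NA_real_,
        region_identity = f$truth[[id_col]][ok],
        n_orthologs_in_region = n_ok,
        tricky = flag_tricky_terms(f$regions$term_id[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- as.data.frame(stats::setNames(
      replicate(length(transfer_record_columns()), character(0),
                simplify = FALSE), transfer_record_columns()))
    return(out)
  }
  out <- do.call(rbind, rows)
  out[order(out$ref_start, out$term_id, out$ortholog_accession), ]
}
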