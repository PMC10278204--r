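# orthotransfer

Quality-gated homology transfer of curated disorder annotations (GO and
IDPO region terms) from a reference protein to its orthologs.

Disordered regions evolve fast and align poorly, so projecting a
region-level annotation across a family alignment on the strength of
global similarity alone transfers errors along with terms. This package
implements a transfer protocol for that problem, aimed at curators and
bioinformaticians enriching ortholog sets of annotated IDPs: a term is
projected only when the *family* alignment and the *region* alignment —
chopped out, re-filtered and re-aligned on its own — both pass an
identity filter and the NorMD alignment-quality gate.

The NorMD objective scores an MSA by column coherence in a continuous
residue-similarity space: each residue type is its vector of
substitution scores $v_a$, a column earns
$\frac{1}{k}\sum_i e^{-\lVert v_{r_i}-\bar{x}\rVert/\sigma}$ around its
consensus $\bar{x}$, and the gap-penalized total is corrected by the
expected score of unrelated sequences of the same composition and
normalized by the self-alignment maximum. Identical sequences score 1,
random ones near 0, values above 1 are legal for gap-rich but consistent
alignments, and scores strictly above 0.6 count as reliable.

The package provides:

- DisProt-style JSON, FASTA, aligned-FASTA/Clustal and TSV I/O
- entry filters, greedy identity clustering of references,
  provider-level ortholog merging with provenance, length filtering
- a deterministic builtin progressive aligner plus `mafft` /
  `clustal-omega` adapters, identity-to-reference filtering, and exact
  residue↔column coordinate maps
- NorMD scoring and the double quality gate, with per-region
  re-alignment and transfer-record emission (modification-site terms in
  the IDPO:00024–00034 range are flagged for expert review, never
  dropped)
- overlap-based internal validation and a plDDT disorder classifier
- a synthetic ortholog-family generator with exact identity control and
  ground truth, so the whole pipeline is testable offline
- a CLI (`inst/cli/orthotransfer`) with `simulate`, `prepare`, `align`,
  `quality`, `transfer`, `validate` and `run-all` subcommands, writing a
  run manifest alongside every output

## Worked example

Simulate a ten-ortholog family with a planted disordered region
(residues 40–90), write it as a DisProt-style fixture, and run the full
pipeline:

```r
library(orthotransfer)

cfg <- family_sim_config(
  planted_regions = data.frame(start = 40L, end = 90L,
                               term_id = "IDPO:00076",
                               term_name = "disorder"),
  seed = 11)
fam <- simulate_family(cfg, accession = "REFA0001")
dir <- tempfile("family")
fx  <- make_disprot_fixture(list(fam), dir)

res <- run_pipeline(read_disprot_json(fx$json), dir)
res
#> <pipeline_result>
#>   entries_in               1
#>   entries_kept             1
#>   clusters                 1
#>   clusters_with_orthologs  1
#>   global_msas_passing      1
#>   region_msas_total        1
#>   region_msas_passing      1
#>   terms_transferred        10
#>   proteins_reached         10

head(res$transfers[, c("region_id", "term_id", "ortholog_accession",
                       "ortho_start", "ortho_end", "region_normd",
                       "region_identity")], 4)
#>      region_id    term_id ortholog_accession ortho_start ortho_end region_normd
#> 1 REFA0001r001 IDPO:00076       REFA0001_o01          40        90    0.6866613
#> 2 REFA0001r001 IDPO:00076       REFA0001_o02          40        90    0.6866613
#> 3 REFA0001r001 IDPO:00076       REFA0001_o03          40        90    0.6866613
#> 4 REFA0001r001 IDPO:00076       REFA0001_o04          40        90    0.6866613
#>   region_identity
#> 1        88.23529
#> 2        94.11765
#> 3        92.15686
#> 4        94.11765

res$reports$REFA0001$global
#> <quality_report global: NorMD 0.720 (reliable), 11 rows x 258 cols>
```

All ten orthologs pass both gates: the global MSA scores NorMD 0.720
(reliable, > 0.6) after the 60% identity filter, the realigned region
MSA scores 0.687, and every surviving ortholog carries the disorder term
with its span mapped into its own residue numbering (40–90 here; shifted
where indels precede the region). `expected_transfers(list(fam))`
returns the generator's ground-truth table, which matches this output
exactly. The same run from the shell:

```sh
Rscript inst/cli/orthotransfer simulate --out fam/ --families 1 --seed 11
Rscript inst/cli/orthotransfer run-all --disprot fam/disprot_fixture.json \
        --orthologs fam/ --out out/
```

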