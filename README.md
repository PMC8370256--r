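# phosphoscreen

Differential phosphosite screening for amino-acid-signaling
phosphoproteomics in R.

## The problem

Amino acids act as intracellular signaling molecules: withdrawing them
inactivates mTORC1, induces autophagy, and remodels protein
phosphorylation within an hour. A standard screen for the phosphosites
carrying these signals profiles cells under five conditions — untreated
(`NT`), serum-starved (`SS`), amino-acid-starved (`AAS`), and
amino-acid-starved cells restimulated with leucine (`LeuS`) or with a
complete amino acid mixture (`AllS`) — as single pooled samples quantified
by LC-MS/MS at the phosphopeptide level.

`phosphoscreen` implements the complete downstream analysis of such a
screen, for proteomics analysts who have peptide-level quantification
tables (plus, optionally, a FASTA proteome, GMT annotation sets and a
protein-interaction edge list) and want a reproducible, tested pipeline
instead of a spreadsheet.

## The method

Peptide records are reliability-filtered, deduplicated, and collapsed to
residue-level phosphosites (abundances summed per site and condition).
For every site present in both conditions of a contrast, fold changes are
formed:

    fc_aas_ss   = AAS  / SS      (starvation effect)
    fc_leus_aas = LeuS / AAS     (leucine restimulation)
    fc_alls_aas = AllS / AAS     (full restimulation)

Sites are classified into four **frames** with strict thresholds
θ_up = 2, θ_down = 0.5 (|log₂ FC| > 1):

- **Frame 1** — fc_aas_ss > 2 and fc_leus_aas < 0.5 (phosphorylation
  negatively regulated by leucine)
- **Frame 2** — fc_aas_ss < 0.5 and fc_leus_aas > 2 (positively regulated
  by leucine)
- **Frame 3** — fc_aas_ss > 2 and fc_alls_aas < 0.5 (negatively regulated
  by amino acids)
- **Frame 4** — fc_aas_ss < 0.5 and fc_alls_aas > 2 (positively regulated
  by amino acids)

A stricter tier keeps sites whose defining fold changes pass
|log₁₀ FC| > 1. Downstream, the package summarises residue composition
and per-protein site multiplicity, discovers sequence motifs around the
screened sites with an iterative binomial (motif-x style) algorithm over
13-residue windows, runs hypergeometric over-representation analysis with
BH correction against user-supplied term sets, and ranks interaction-hub
proteins by degree. A ground-truth synthetic data generator
(`simulate_phospho()`) emulates the whole five-condition design so every
stage is benchmarked end to end.

## Worked example

Classify three sites from their fold changes, then run the screen on a
simulated data set:

```r
library(phosphoscreen)

ratios <- tibble::tibble(
  site_key   = c("chx:102190693:S722", "chx:100860851:S252", "chx:102173139:S25"),
  protein_id = c("chx:102190693", "chx:100860851", "chx:102173139"),
  residue    = "S",
  fc_aas_ss   = c(2.35, 0.01, 0.02),
  fc_leus_aas = c(0.06, 6.11, NA),
  fc_alls_aas = c(NA, 23.49, 113.30))
asg <- assign_frames(ratios)
asg[, c("site_key", "fc_aas_ss", "frame1", "frame2", "frame4")]
#>             site_key fc_aas_ss frame1 frame2 frame4
#> 1 chx:102190693:S722      2.35   TRUE  FALSE  FALSE
#> 2 chx:100860851:S252      0.01  FALSE   TRUE   TRUE
#> 3  chx:102173139:S25      0.02  FALSE  FALSE   TRUE
```

The first site goes up 2.35-fold under starvation and collapses under
leucine (frame 1); the second is restored by both leucine and the full
mixture, so it sits in frames 2 *and* 4; the third is restored only by
the full mixture. Two of the frame-4 fold-change pairs exceed ten-fold in
both directions, so `top_subset(asg, 4)` keeps 2 sites on 2 proteins.

End to end on synthetic data with recorded ground truth:

```r
sim <- simulate_phospho(sim_config(), seed = 1)
tab <- merge_to_sites(filter_reliable(sim$peptides, 0.75))
asg <- assign_frames(compute_frame_ratios(tab))
evaluate_frame_recovery(sim$truth, asg)
#> sensitivity specificity
#>   1.0000000   0.9990521

f4 <- parse_site_key(asg$site_key[asg$frame4])
fg <- extract_windows(f4, sim$proteome)
motifs <- discover_motifs(fg$window[fg$residue == "S"],
                          background_windows(sim$proteome, "S"))
motifs[, c("motif", "fixed", "n_matches", "proportion", "score")]
#>       motif fixed n_matches proportion    score
#> 1 xxx_S_Pxx   +1P        93      53.45 64.79155
#> 2 xxx_S_xDx   +2D        27      15.52 14.70958
#> 3 xxx_S_xxE   +3E        22      12.64 13.75365
```

All 200 planted amino-acid-responsive sites are recovered at 20%
measurement noise, and the three planted motif classes — proline-directed
plus the two acidic (CK2-type) contexts — come back as disjoint classes
with their proportions of the foreground windows.

`run_pipeline(sim, "out/")` chains every stage and writes one TSV per
stage plus a `manifest.json` with MD5 checksums for reproducibility. A
thin command-line wrapper lives at `inst/scripts/phospho-aa-screen.R`.

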