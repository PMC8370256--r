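---
title: "Screening phosphosites regulated by amino acid signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening phosphosites regulated by amino acid signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoscreen)
```

## The experimental design and the screening model

Amino acids are not only substrates for protein synthesis but signaling
molecules: their withdrawal inactivates mTORC1, induces autophagy, and
reshapes the phosphoproteome within an hour. A common screen for the
phosphosites carrying these signals profiles cells under five conditions —
untreated (`NT`), serum-starved (`SS`), amino-acid-starved after serum
starvation (`AAS`), leucine-restimulated (`LeuS`) and restimulated with a
complete amino acid mixture (`AllS`) — each as a single pooled sample
quantified by LC-MS/MS at the peptide level.

The screen itself is deliberately simple, because the pooled design has no
replicates and supports no variance estimate. For each phosphosite present
in both conditions of a contrast, a fold change is formed:

- `fc_aas_ss = AAS / SS` — the effect of amino acid starvation,
- `fc_leus_aas = LeuS / AAS` — the effect of leucine restimulation,
- `fc_alls_aas = AllS / AAS` — the effect of full restimulation.

Sites are then classified into four *frames* by thresholding at
`theta_up = 2` and `theta_down = 0.5` (i.e. `|log2 FC| > 1`), with strict
inequalities:

| Frame | starvation | restimulation | interpretation |
|---|---|---|---|
| 1 | `fc_aas_ss > 2` | `fc_leus_aas < 0.5` | negatively regulated by leucine |
| 2 | `fc_aas_ss < 0.5` | `fc_leus_aas > 2` | positively regulated by leucine |
| 3 | `fc_aas_ss > 2` | `fc_alls_aas < 0.5` | negatively regulated by amino acids |
| 4 | `fc_aas_ss < 0.5` | `fc_alls_aas > 2` | positively regulated by amino acids |

Frames are not mutually exclusive — a site restored by both leucine alone
and the full mixture belongs to frames 2 and 4 at once. A stricter tier
keeps the sites whose two defining fold changes pass `|log10 FC| > 1`
(below 0.1 and above 10); since 10 > 2 this tier always nests inside its
frame.

```{r frames}
ratios <- tibble::tibble(
  site_key = c("pA:S722", "pB:S252"), protein_id = c("pA", "pB"),
  residue = "S",
  fc_aas_ss = c(2.35, 0.01), fc_leus_aas = c(0.06, 6.11),
  fc_alls_aas = c(NA, 23.49))
assign_frames(ratios)[, c("site_key", "frame1", "frame2", "frame4")]
```

## From peptides to sites

Quantification arrives as peptide-level records (sequence, protein
accession, modified positions, abundance, optional reliability score).
Three choices in the peptide-to-site collapse deserve justification:

- **Redundancy.** Exact duplicate records (same condition, peptide,
  positions, abundance) are collapsed to one before aggregation; peptides
  that genuinely re-measure a site are *summed*, preserving total signal.
  The statistic is configurable to the mean.
- **Multi-phospho peptides.** A peptide carrying several sites contributes
  its full abundance to each of them. The screen counts sites, not
  fractional occupancies, so splitting would only add an arbitrary factor
  that cancels in every fold change.
- **Reliability.** Records scoring below 0.75 are dropped; records without
  a score are kept by default (both configurable). No criterion beyond a
  threshold is imposed because upstream search engines differ in what
  their score means.

Zero or missing cells are treated as *absent*: a site missing in either
condition of a contrast is excluded from that contrast entirely, never
imputed, and never yields an infinite fold change.

## Normalisation

`normalize_sites()` offers per-condition median scaling (default for real
data), total-sum scaling, or none. Median scaling removes arbitrary
between-run intensity scales and is robust to a few very abundant sites.
One caveat matters and is easy to miss: when a condition's observed sites
are dominated by *regulated* sites — as in the amino-acid-starved column of
this design, where most surviving sites are strongly down-regulated — the
column median is itself shifted by the biology, and dividing by it biases
every fold change in that contrast. The benchmark analyses in this package
therefore run with `normalize = "none"`: the simulator emits all five
conditions on one common intensity scale, so there is no between-run scale
to remove, and median scaling would only re-introduce composition bias.
For real exports with arbitrary per-run scales the median default stands,
with the caveat above as a known limitation of ratio thresholding under
heavy regulation.

## Descriptive summaries and rounding

`composition_summary()`, `multiplicity()` and `updown_counts()` reproduce
the screen's descriptive tables: Ser/Thr/Tyr composition per condition,
the per-protein site multiplicity histogram with its implied totals, and
per-contrast up/down counts. Percentages are rounded **half-up to two
decimals** (`round_half_up()`), the convention that reproduces published
tables of this kind; note that base R's `round()` rounds half to even and
would disagree on exact halves such as 0.125. One such published cell
(a serine share of 134/144) is 93.06 under this rule; reproductions that
print 93.05 follow some other convention, which this package does not
attempt to imitate.

## Motif discovery

`discover_motifs()` reimplements the classic iterative binomial
("motif-x") algorithm over 13-residue windows centered on phosphosites
(termini padded with `_`):

1. For every unfixed position and residue, count foreground occurrences
   `k` among the `n` windows not padded there, and compute the binomial
   upper tail `P[X >= k]` at the background frequency of that residue at
   that position. Padded windows are excluded from both counts at that
   offset, so terminal sites do not dilute the statistics.
2. Fix the most significant pair if it passes both `p <= 1e-6` and
   `k >= 20` (defaults, configurable), restrict both window sets to the
   matching windows, and repeat until no pair qualifies.
3. Report the fixed pattern as one motif, remove its matching foreground
   windows, and restart. Classes are therefore disjoint and their
   proportions (of the *original* foreground) sum to at most 100%.

Numerical choices: candidates whose background count is zero are skipped —
they have no finite enrichment estimate and would otherwise produce
degenerate infinitely-scored motifs; ties in the p-value are broken by
larger count, then leftmost position, then alphabetical residue, making
output deterministic. The reported `score` is `-log10` of the binomial p
of the last position fixed. S-, T- and Y-centered windows are analysed
separately against the same-center background, the background defaulting
to every same-residue window of the supplied proteome.

## Enrichment and network stages

Annotation databases age quickly and are organism-specific, so the
package performs a *generic* over-representation analysis against
user-supplied GMT term sets: hypergeometric upper-tail p-values with
Benjamini–Hochberg correction, universe defaulting to all quantified
proteins. Likewise the network stage takes a user-supplied edge list
(optionally score-thresholded at 0.4, the conventional medium-confidence
cut) and ranks hubs by degree within the queried protein set, ties broken
lexicographically.

## The synthetic data generator

`simulate_phospho()` generates the full five-condition design with
recorded ground truth, so that every stage is testable without any
proteomics deposit. What it emulates:

- **Planted regulation.** Default 30/30/30/200 sites in frames 1–4 plus
  310 unregulated sites. Effects are multiplicative 16-fold (e.g. a
  frame-4 site has `AAS = baseline/16`, `AllS = baseline`), chosen so both
  the 2-fold screen and the 10-fold strict tier are exercised.
- **Noise.** Log-normal multiplicative noise per (site, condition) cell
  with CV 0.2 by default (mean exactly 1; CV 0 gives byte-identical
  noiseless data).
- **Peptide structure.** Each observed cell is split over 1–3 redundant
  peptides whose abundances sum *exactly* to the cell value, so summing
  aggregation recovers the planted signal to floating-point precision.
- **Nuisance records.** A fraction of cells emit an extra junk record with
  reliability below 0.7 and abundance unrelated to the planted signal —
  they must be removed by `filter_reliable()` — and a fraction of records
  are re-emitted as exact duplicates that `merge_to_sites()` must
  collapse. Junk is additional on top of the truth-bearing records so the
  default 0.75 reliability filter restores the planted signal exactly.
- **Missingness.** Unregulated sites drop out per condition (heavily in
  the starved and leucine columns, mirroring the small observed site
  counts there); planted sites are always observed so every truth row is
  evaluable.
- **Sequence context.** A synthetic proteome carries each site's residue
  (S/T/Y at 90/9/1%), and frame-4 serine sites receive a planted motif
  class: proline at +1 (45%), glutamate at +3 (19%), aspartate at +2
  (16%), remainder none — the mixture shape expected for
  proline-directed-kinase plus CK2-type substrates. Sites on one protein
  are spaced at least 13 residues apart so planted contexts never
  overlap.
- **Annotation and network.** A GMT file with one term enriched in
  frame-4 proteins among random terms, and a random edge list among
  frame-4 proteins.

What it does **not** emulate: spectrum-level effects (charge, retention
time, co-isolation), phospho-localisation ambiguity, missingness that is
*correlated with abundance*, and replicate structure. Passing recovery
tests therefore demonstrates the correctness of the screening logic under
its own model assumptions, not the behaviour of the method on real
spectra.

```{r simulate}
sim <- simulate_phospho(sim_config(cv = 0), seed = 1)
recs <- filter_reliable(sim$peptides, 0.75)
tab <- merge_to_sites(recs)
asg <- assign_frames(compute_frame_ratios(tab))
evaluate_frame_recovery(sim$truth, asg)
```

## Problem sizes and determinism

The defaults (600 sites, ~440 proteins of length 400, ~5,500 records)
keep a full simulate–screen–motif cycle to a few seconds while leaving
every planted motif class above the 20-occurrence reporting floor; these
sizes are the package's chosen benchmark conditions. All randomness flows
from a single integer seed: the generator is deterministic given seed and
configuration, and `run_pipeline()` writes a manifest with MD5 checksums
of every output so reruns can be verified byte-for-byte.

## Known limitations

- Ratio thresholding without replicates cannot separate biological effect
  from measurement noise; the frame rule is a screen, not a test, and
  sites near a threshold flip under noise.
- The strict inequality at thresholds means a fold change of exactly 2.0
  (or 0.5) is excluded — relevant only for hand-constructed data.
- Median normalisation interacts badly with regulation-dominated columns
  (see above).
- Motif discovery reports nothing when the foreground is smaller than
  `min_occurrences`, and greedy fixing can absorb chance co-occurrences
  of a second class's residue into an earlier motif; proportions are
  exact for the discovered disjoint classes, not for the planted ones.
- An empty frame (as frame 3 often is under this biology) is a valid
  result and is handled without special-casing throughout.
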