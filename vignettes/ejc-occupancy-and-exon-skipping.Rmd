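---
title: "EJC occupancy, multi-exon skipping and paralog divergence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EJC occupancy, multi-exon skipping and paralog divergence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ejcsplice)
library(data.table)
```

## Scope and model

`ejcsplice` implements the computational core of an analysis of how exon
junction complex (EJC) occupancy relates to aberrant exon skipping when the
EJC core paralogs MAGOH and MAGOHB are knocked down. Four analyses are
covered, all anchored to a single reference transcript per gene:

1. **Junction classification and skipped-exon (SE) calling.** Splice-junction
   reads are interpreted against a strand-oriented exon chain; a junction
   joining the 3' boundary of exon $i$ to the 5' boundary of exon $j$ is
   canonical when $j = i + 1$ and a skip of $k = j - i - 1$ exons otherwise.
   Per-exon inclusion is quantified as a junction-count PSI and events pass
   when $|\Delta PSI| > 0.2$ and BH-adjusted FDR $< 0.01$.
2. **The EJC occupancy ratio statistic.** For a gene with exon-level
   crosslink counts $x_1..x_n$, the internal-exon mean is
   $\bar{x}_{int} = \mathrm{mean}(x_2..x_{n-1})$; the statistic for a skip
   event with upstream exon $u$ is $r = x_{u}/\bar{x}_{int}$ (offset 1), or
   $x_{u-1}/\bar{x}_{int}$ for the next exon 5'-ward (offset 2). The observed
   mean of $r$ over events is compared against $B$ bootstrap means of
   randomly selected pool exons; significance is a two-tailed,
   add-one-corrected empirical p-value.
3. **Consequence calling.** A skip event removes a contiguous coding span;
   its consequence is the mod-3 frame status, the first in-frame stop of the
   spliced-and-translated mutant (premature iff strictly before the position
   homologous to the annotated stop), and per-domain none/partial/total loss
   mapped onto the original protein.
4. **Paralog divergence.** Global affine-gap alignment identity at protein
   and CDS level, and dN/dS by Nei–Gojobori (1986) counting with
   Jukes–Cantor correction.

## Assumptions

* One reference (MANE-style) transcript per gene is an adequate coordinate
  frame; multi-isoform projection is out of scope.
* Only genes with three or more exons are evaluated — a skip needs an
  internal exon, and first/last exons are excluded from the occupancy
  denominator because their apparent skipping is usually driven by other
  events (alternative first/last exon usage).
* Junction boundary matching is exact (modern aligners are base-precise); a
  slop window is deliberately not applied.
* Crosslink counts are used raw. The statistic is a within-gene ratio, so
  per-gene scale factors cancel (tested as an invariance); exon-length and
  library-size normalisation are unnecessary for it. RNA-seq counts serve
  only the at-least-one-read expression filter.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_exons` | 3 | exons | eligibility gate; a skip requires an internal exon |
| `dpsi_min` | 0.2 | PSI | SE significance gate |
| `fdr_max` | 0.01 | — | BH-adjusted significance gate |
| `B` | 100,000 | resamplings | bootstrap null resolution; p floor $2/(B+1) = 2\times10^{-5}$ |
| `pool` | internal | — | resampling pool restricted to exons 2..n−1, matching the statistic's domain |
| `pseudocount` | 0.5 | CPM | stabilises kd/control skip-read ratios at zero counts |
| `offset` | 1 and 2 | exons | immediately-upstream vs further-upstream contrast |

Design decisions where the procedure was genuinely open:

* **Resampling pool composition.** The internal-exon mean excludes first and
  last exons, so the self-consistent null draws from internal exons only;
  `occupancy_pool()` also exposes `all_but_last` and `all`.
* **Events are deduplicated** on (gene, upstream exon) before the test so one
  junction cannot contribute twice when event lists from several analyses
  are pooled.
* **Per-replicate sample size m** equals the number of observed contributing
  events, making observed and null means exchangeable under the null.
* **Means, not medians,** of the ratios are compared, matching the
  description of the procedure this package re-implements.
* **The SE test is declared plumbing**: a Fisher exact test on pooled 2×2
  (inclusion, exclusion) × (control, kd) counts with BH correction, not an
  rMATS-style paired likelihood model. The gates, not the test, carry the
  scientific content. Inclusion enters the table as the rounded average of
  the two inclusion junctions so inclusion and exclusion sit on the same
  per-transcript scale, and PSI deliberately omits effective-length
  weighting — a junction-count-only estimator.
* **Skip-ratio normalisation** is counts-per-million of junction reads per
  sample, ratios computed per event before taking the per-k median (a
  per-k-class variant is config-exposed via `per_event = FALSE`).
* **No NMD heuristics** (e.g. the 50-nt rule): a PTC is purely "stop before
  the homologous annotated stop".
* **Partial vs total domain loss** is interval arithmetic: total when the
  domain is fully covered by lost intervals or lies entirely at/after the
  truncation point, partial when properly overlapped.
* **Truncation origin**: for frameshifts and in-frame junction PTCs, every
  original-protein position from the first affected codon onward is treated
  as lost. This is conservative for in-frame PTCs, where a few residues
  between the deletion and the new stop retain identity.
* **Alignment** is standard Needleman–Wunsch with affine gaps
  (BLOSUM62 for protein; +5/−4, gap 10/0.5 for nucleotide) rather than a
  shell-out to an external multiple aligner; for ~99%-identical paralogs the
  alignment is gap-free and method-insensitive. dN/dS uses NG86 counting
  (pathways through stop codons excluded; mutations to stops counted
  nonsynonymous when counting sites) with Jukes–Cantor correction — a
  transparent, exactly testable estimator rather than a codeml-style ML fit;
  the purifying-selection conclusion ($\omega \ll 1$) is method-robust, the
  third decimal of $\omega$ is not.

## Numerical choices

* Coordinates are 0-based half-open internally; GTF's 1-based inclusive
  convention is converted once at the parser boundary.
* The empirical p-value is add-one corrected:
  $p = \min(1,\, 2\min(\frac{1+\#\{null \ge obs\}}{B+1}, \frac{1+\#\{null \le obs\}}{B+1}))$,
  never exactly 0, floored at $2/(B+1)$.
* Bootstrap draws precompute each pool exon's within-gene ratio once and
  sample indices in chunks (identical in law to per-replicate recomputation,
  linear memory).
* Reference-transcript ties break deterministically: MANE tag, longest CDS,
  lexicographically smallest transcript id; two MANE tags on one gene are an
  error, not a silent choice.
* Degenerate inputs resolve to `NA`, not exceptions, wherever `NA` is the
  exclusion signal (ratio of a first exon, zero internal mean, PSI with no
  reads); Jukes–Cantor saturation ($p \ge 0.75$) and empty resampling pools
  are hard errors.
* Overlapping exons within one transcript are merged with a warning rather
  than rejected, to tolerate messy annotations.

## What the synthetic data emulates — and what it does not

The generator (`sim_config()` and the `simulate_*` functions) produces
annotation, junction tables, occupancy tables, CDS/domain fixtures and
ground truth so every stage is testable without downloads:

* **Junction reads** are Poisson; each gene's depth is shared over its
  canonical junctions, and affected genes carry one designated skip event of
  class $k$ at rate `base_skip_rate[k]`, multiplied by `kd_multiplier[k]` in
  the knockdown. The default multipliers rise with $k$ to 3× at $k = 5$,
  emulating the observation that multi-exon skips respond more strongly to
  knockdown (roughly 2× at $k = 2$ and 3× at $k = 5$).
* **Crosslink counts** are negative binomial (`occ_mean` 50,
  `occ_dispersion` 0.5 — strong CLIP-like overdispersion), with the exon
  immediately upstream of each designated skipped exon multiplied by
  `enrichment_gamma`.
* **Gene structure** defaults to 4–12 exons of 80–300 nt — compact but
  realistic multi-exon genes; CDSs cover all internal exons plus parts of
  the flanks.
* Simulation problem sizes used by the checked-in analyses and tests: 200
  simulated datasets of 210 genes at $B = 2{,}000$ for null calibration, 100
  for the enrichment contrast, depth $10^4$ junction reads/gene for ratio
  recovery. These sizes put Monte-Carlo error comfortably below the
  assertion tolerances.

What it does **not** emulate: read-level data (no FASTQ/BAM),
sequence-dependent splice-site strength, positional crosslink structure within
exons, correlated expression between genes, or isoform complexity. Passing
tests therefore demonstrate correctness of the statistics and plumbing under
the stated noise model, not robustness to every artefact of real RNA-seq or
CLIP libraries.

One property of the statistic deserves emphasis. Because the upstream exon
sits inside its own gene's internal-exon mean, a strong enrichment
$\gamma$ on it inflates that denominator by $\approx (n_{int}-1+\gamma)/n_{int}$,
which biases the ratios of *sibling* exons (including the offset-2 exon)
below 1 by roughly $2/(n_{int}+2)$ at $\gamma = 3$. At hundreds of events
this bias is detectable against the bootstrap null, so under strong
simulated enrichment the offset-2 test is *not* exactly null-distributed —
a denominator-contamination effect inherent to the ratio definition, visible
in the power analysis and worth remembering when interpreting the
further-upstream contrast on real data (where enrichment is far weaker).

The shipped paralog sequences (`inst/extdata/synthetic_magoh_paralogs_*`)
are **synthetic stand-ins**, generated by `simulate_paralog_pair()`: two
146-residue proteins identical except the first two residues (144/146 =
98.63% identity) and CDSs driven to 86% nucleotide identity by
single-nucleotide synonymous substitutions. They reproduce the published
divergence *structure* of the human MAGOH/MAGOHB pair for testing purposes;
they are not the database sequences, and identity measured on them is by
construction.

## Limitations

* The SE caller pools replicates before testing; replicate-level dispersion
  is not modelled.
* Only skipped-exon events are handled; intron retention, mutually exclusive
  exons and alternative splice sites are out of scope, as are GO enrichment,
  survival analyses and expression quantification.
* Junctions are reconciled to the reference chain by exact boundary
  matching; events whose coordinates disagree with the reference exon
  boundaries are reported as unannotated rather than rescued.
* Domain impact ignores residue conservation: a "partial" loss of one
  residue and of 90% of a domain are the same category.
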