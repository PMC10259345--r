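# ejcsplice

Analysis toolkit for a question in RNA processing: when the exon junction
complex (EJC) core paralogs **MAGOH and MAGOHB** are knocked down, which
exons get skipped — and does EJC occupancy on the exon *upstream* of a
skipped exon mark junctions that need EJC protection against aberrant
(multi-exon, potentially recursive) splicing? The package is aimed at
computational biologists working with splice-junction count tables and
exon-level CLIP quantifications.

## What it computes

Everything is anchored to one reference (MANE-style) transcript per gene,
restricted to genes with ≥ 3 exons.

* **Junction classification & SE calling.** A junction joining exon *i* to
  exon *j* in transcript orientation is canonical (*j = i+1*) or a skip of
  *k = j−i−1* exons. Per internal exon,
  PSI = ((inc_up + inc_down)/2) / ((inc_up + inc_down)/2 + exc); events are
  significant when |ΔPSI| > 0.2 and BH FDR < 0.01.
* **Skip-read ratio profile.** Per skip class *k*, the median
  knockdown/control ratio of CPM-normalised skip-junction reads.
* **EJC occupancy bootstrap test.** For each skip event with upstream exon
  *u* and gene crosslink counts *x₁..xₙ*:
  *r = x_u / mean(x₂..x₋₁)* (offset 1; offset 2 uses *x₍u−1₎*). The observed
  mean of *r* is compared to B = 100,000 bootstrap means of randomly drawn
  internal exons; p is two-tailed empirical with add-one correction.
* **Consequence calling.** Coding span removed by a skip → frame status
  (none / in-frame / frameshift), premature termination codon in the mutant
  frame, and per-domain none/partial/total loss on the annotated protein.
* **Paralog divergence.** Global alignment identity (protein and CDS) and
  Nei–Gojobori dN/dS with Jukes–Cantor correction (ω = dN/dS).

A synthetic-data generator (`sim_config()`, `simulate_dataset()`) emits GTF,
junction tables (STAR SJ-style and 4-column TSV), occupancy tables, CDS and
domain fixtures with known ground truth, so the whole pipeline runs and is
tested without any downloads.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, each a thin
script over the package API that writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic study dataset + ground truth
Rscript analysis/02_call_se_events.R  # PSI, dPSI, FDR, significance gates
Rscript analysis/03_skip_profile.R    # per-k kd/control skip-read ratios
Rscript analysis/04_ejc_test.R        # occupancy bootstrap test (B = 100,000)
Rscript analysis/05_consequences.R    # frame / PTC / domain-loss calls
Rscript analysis/06_divergence.R      # paralog identity and dN/dS
```

Output actually printed by stages 3, 4 and 6 on the default simulated
dataset (120 genes, half carrying designated skip events, knockdown
multipliers rising to 3× at k = 5):

```
median kd/control skip-read ratio by skip class:
        k n_events median_ratio
1:      1       13     1.530234
2:      2       16     1.996917
3:      3       17     2.293267
4:      4        8     2.616389
5:      5        6     2.725211
6:    ge2       47     2.378589

offset 1: m = 47 events, observed mean ratio 1.701 vs null 1.000 +/- 0.164, p = 0.00012
offset 2: m = 29 events, observed mean ratio 0.918 vs null 0.999 +/- 0.208, p = 0.73

protein identity: 98.63% (146 aa)
CDS identity:     85.94% (rounds to 86%)
dN = 0.0131, dS = 1.3173, omega = 0.0100 (NG86 counting + Jukes-Cantor correction)
```

Reading this: knockdown samples carry progressively more reads supporting
multi-exon skips (ratios ≈ 2× at k = 2 up to ≈ 3× at k = 5); exons
immediately upstream of skipped exons are strongly EJC-enriched relative to
the bootstrap null (p ≈ 1e-4) while the next exon 5'-ward is not (p ≈ 0.7);
and the MAGOH/MAGOHB-like paralog pair shows near-identical proteins over a
much more divergent CDS, i.e. ω ≪ 1, strong purifying selection. The
paralog sequences shipped in `inst/extdata/` are *synthetic stand-ins*
constructed to the published divergence structure (146 aa differing at the
first two residues; 86% CDS identity) — see the methods vignette.

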