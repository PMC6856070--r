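---
title: "Calling and testing alternative polyadenylation sites with apacall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and testing alternative polyadenylation sites with apacall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apacall)
```

## The measurement and its model

3′-terminus sequencing reads a transcript's polyadenylation site
directly. Oligo(dT)-primed first-strand synthesis leaves each read with a
leading poly-T tract (the complement of the poly(A) tail) followed by the
reverse complement of the mRNA 3′ end. Two consequences shape the whole
pipeline:

* after trimming the poly-T run, the read's **first nucleotide** is the
  genomic base adjacent to the poly(A) junction;
* the read is **antisense** to the mRNA, so a read from a + strand gene
  aligns to the − strand. `pas_from_alignments()` therefore reports the
  site on the strand opposite the alignment; the convention is exposed as
  `orientation = "antisense" | "sense"` for libraries with the other
  chemistry.

Reads from one site do not land on a single base in real data (imprecise
cleavage, templated Ts), so polyadenylation-adjacent positions within a
24-nt window are merged into one predicted APA site by single-linkage
chaining, and sites supported by fewer than 16 reads across all samples
are discarded as noise.

Differential usage between two conditions is modelled per site with
negative-binomial counts: a count with mean $\mu$ and dispersion $\alpha$
has variance $\mu + \alpha\mu^2$. Counts are normalized by
median-of-ratios size factors, $\alpha$ is estimated by method of
moments with trend shrinkage, and the per-site Wald statistic
$\log_2\!\frac{\mu_T + \tfrac12}{\mu_C + \tfrac12} \big/ \mathrm{SE}$
is referred to the standard normal, two-sided, followed by
Benjamini–Hochberg adjustment.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `qual_threshold`, `qual_fraction` | Phred 10, 0.5 | a read passes when ≥ 50 % of its bases reach Q10 (90 % base-call accuracy); the boundary passes. `N` bases always count as failing. |
| `min_length` | 16 nt | minimum post-trim read length; 16 is kept, 15 dropped. |
| `window` | 24 nt | maximal gap between adjacent member positions of one cluster; a gap of exactly 24 still chains. |
| `min_total_reads` | 16 | expression cutoff on the cluster total across all samples, inclusive. |
| `di_tolerance` | 24 nt | distance from the annotated 3′ terminus within which a site is *distal*. No published value exists for this tolerance; it is set equal to the clustering window so that "at the terminus" and "in the same cluster as the terminus" coincide. |
| `edi_max` | 2000 nt | maximum downstream distance for *extended distal*. |
| `eex_min_intronic` | 10 nt | minimum intronic extent of a cluster span for *extended exonic*. |
| `mapq_min` | 70 | minimum cluster mean MAPQ; strictly lower fails. The built-in exact-match mapper always reports MAPQ 60, so `apa_pipeline()` defaults to `mapq_min = 0` for simulated data; the 70 threshold is meant for real aligner output. |
| `alpha_raw`, `alpha_adj` | 0.01, 0.1 | the two significance surfaces reported side by side: raw p-values and BH-adjusted ones. Both appear in every summary because practice in this assay's literature uses both without reconciling them; the package does not pick a winner. |
| `pseudocount` | 0.5 | added inside fold-change ratios so they are defined when one condition has mean zero. |

## Classification rules and their priority

Sense candidates for a cluster are transcripts on the same strand whose
span, extended `edi_max` downstream of the terminus, contains the
representative. Each candidate is scored in this order:

1. **Di** — representative within `di_tolerance` of the 3′ terminus;
2. **Ex** — cluster span entirely inside one exon;
3. **Eex** — span overlaps an exon and reaches ≥ `eex_min_intronic` nt
   into an adjacent intron (evaluated on the span because a single
   position cannot "extend": singleton clusters are never Eex);
4. **In** — span entirely inside one intron;
5. **Edi** — representative 1..`edi_max` nt downstream of the terminus.

The highest-priority class achieved by any candidate wins, so a site that
qualifies as Di is never reported as Edi however many transcripts
overlap. Among candidates achieving the winning class the nearest
terminus wins, ties broken lexicographically by transcript id for
determinism. Only when every sense assignment fails is the site antisense
(**An**: representative inside an exon of an opposite-strand transcript),
and otherwise unassigned. Ex/Di/Edi are flagged *conventional*,
Eex/In/An *non-conventional*.

Internal coordinates are 0-based half-open everywhere; conversion happens
only at the GFF3/BED/SAM boundaries.

## What the simulator emulates — and what it does not

`sim_params()` fixes the study conditions used throughout the tests:
8 samples per condition, 60 sites spread evenly over the six classes,
NB counts with per-sample mean 60 and dispersion 0.05, 50-nt reads with a
uniform 5–15 nt poly-T prefix, error-free by default. Genes are placed
with ≥ 2.5 kb gaps so every 2-kb downstream flank is unambiguous, and
same-strand sites are kept ≥ 25 nt apart so distinct truth sites cannot
merge under the 24-nt window.

Choices worth knowing about:

* **Poly-T length** is uniform on [5, 15]; the protocol literature gives
  no distribution, so a broad flat one exercises the trimmer without
  dominating the read.
* **Templated T exclusion.** A site whose immediately adjacent genomic
  base would extend the poly-T run is re-placed during planting: for such
  sites the trimmer necessarily eats one genomic base and exact recovery
  is impossible in any pipeline. Real data has this ambiguity; synthetic
  truth must not, or "100 % recovery" would be unattainable by
  construction rather than by implementation error.
* **Extended-exonic truth sites are two-position clusters.** A single
  planted position can never satisfy the Eex definition, so each Eex
  truth record carries a satellite position 10–15 nt into the adjacent
  intron, ≤ 24 nt from the representative, receiving ~30 % of the reads.
  The representative therefore stays the modal position.
* **Substitution errors** (optional) hit the genomic payload only, never
  the poly-T prefix, isolating their effect to mapping: the exact-match
  mapper drops errored reads, costing depth but not positional accuracy.
* Not modelled: RNA secondary structure, internal priming artifacts,
  fragment-length effects, PCR duplicates, platform-specific flow-space
  errors, spliced reads. Passing tests therefore demonstrate correctness
  of the pipeline's logic under clean geometry and NB counts, not
  robustness to those artifacts.

## Numerical choices

* **Clustering** is implemented as sorted-gap splitting, which equals
  connected components of the ≤ window adjacency graph; the test suite
  checks this against a brute-force $O(n^2)$ oracle on hundreds of random
  instances. Clusters are never split however long the chain grows; spans
  over 200 nt trigger a warning.
* **Representative ties** go to the 3′-most position relative to the
  cluster strand (largest coordinate on +, smallest on −).
* **Size factors** follow the geometric-mean-referenced median-of-ratios
  formula, computed over sites with strictly positive counts in every
  sample; if no such site exists the function stops rather than invent a
  pseudo-reference. Note the estimator is invariant to globally rescaling
  all counts — the factors capture *relative* depth only — and scaling a
  single sample by $c$ scales the *ratio* of its factor to the others by
  $c$ (the factor itself by $c^{(n-1)/n}$).
* **Dispersion**: the raw moment estimate
  $\max(10^{-8}, (s^2 - m)/m^2)$ uses within-condition pooled variance so
  planted condition effects do not inflate it, then shrinks 50/50 toward
  a trend $a + b/m$ fitted by least squares across sites (median fallback
  when the mean range is degenerate). Constant count matrices collapse to
  the floor. The shrinkage stabilizes the Wald denominator enough that
  the test holds its nominal 5 % type-I error within [0.03, 0.07] at
  $n = 8 + 8$ — verified by Monte-Carlo in the acceptance tests.
* **Degenerate sites**: all-zero rows return $p = 1$ and zero fold
  change; equal means give signed fold change $+1$ (the positive branch
  is taken on ties for determinism).
* **Chi-square** uses the Pearson statistic with no continuity
  correction by default (a flag exposes Yates for 2×2); a zero margin is
  an error, expected cells below 5 a warning.

## Problem sizes used in the tests

The suite exercises the end-to-end chain at 60 planted sites
(~58 000 reads) per run, the clustering oracle on 500 random instances of
up to 200 positions, DE calibration on 20 × 2000-site null simulations
and one 2000-site power simulation with 100 planted 4-fold shifts, and
chi-square calibration on 2000 multinomial tables. These sizes give the
Monte-Carlo assertions comfortable margins while keeping a full test run
in the low minutes on one core.

## Known limitations

* The exact-match mapper is a desk-scale stand-in: no mismatches, indels
  or splicing; multi-mapping reads are dropped and tallied. Real data
  should be aligned externally and ingested via `read_sam()`.
* The Wald test uses a normal reference with moment-estimated, shrunk
  dispersions; at very small sample sizes (≤ 3 per condition) it will be
  anti-conservative, and it makes no outlier provision (no equivalent of
  Cook's-distance refitting).
* Biotype labels are taken verbatim from the annotation when present;
  the package infers none.
* With few sites and a large fraction of them shifted in one direction,
  median-of-ratios normalization absorbs part of the signal (as any
  global-scaling normalization must); differential summaries on such
  designs should be read with care.
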