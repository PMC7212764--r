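---
title: "Scanning promoters for CRZ1/CDRE-type sites: model, calibration and design notes"
author: "crzscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning promoters for CRZ1/CDRE-type sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crzscan)
```

## The model

`crzscan` treats a transcription-factor binding motif as an independent
per-position model: a frequency matrix giving, for each of the `w` motif
positions, a probability over {A, C, G, T}. Scanning converts this to an
additive log2-odds scoring matrix against a background model. For window
`x = x_1 ... x_w`,

$$S(x) = \sum_{j=1}^{w} \log_2 \frac{p'_j(x_j)}{q(x_j)},$$

where $q$ is the background (uniform by default) and $p'$ the
pseudocount-regularized probabilities

$$p'_j(b) = \frac{p_j(b) + \varepsilon\, q(b)}{1 + \varepsilon},
\qquad \varepsilon = 0.01 \text{ by default}.$$

Distributing the pseudocount proportionally to the background keeps each
regularized column an exact probability distribution and guarantees finite
log-odds for count-derived matrices. With $\varepsilon = 0$ a
zero-probability base gets $-\infty$: windows containing it simply can
never be called, which is the coherent limit of the model rather than an
error state (only an all-zero column, where no consensus base exists, is
rejected).

A signed log-odds score is the only reading under which the selection rule
"keep windows scoring above zero" is meaningful — a probability product is
always positive — so positive raw scores mark windows more likely under the
motif than under the background. Kept scores are normalized by the maximum
attainable score

$$S_{norm}(x) = S(x) / \text{MaxScore}, \qquad
\text{MaxScore} = \sum_j \max_b \log_2 \frac{p'_j(b)}{q(b)},$$

which is the score of the consensus word; $S_{norm} \in (0, 1]$ with
equality exactly at consensus windows. A site is called when $S_{norm}$
reaches the threshold (0.8 by default). Both strands are scanned; the
antisense strand is implemented as a reverse-complement-matrix scan of the
sense sequence, so every reported offset lives in promoter coordinates
(0-based window starts, 5'→3' in gene orientation). Overlapping and nested
hits are each kept — the output is the absolute occurrence frequency, with
no merging or greedy masking rule.

### Degenerate inputs

Windows containing `N` are unscorable and return `NA`, never a number:
averaging over ambiguity would invent evidence. Sequences shorter than the
matrix yield an empty scan. A uniform matrix against a uniform background
has `MaxScore = 0`; since calls require a *positive* raw score, such a
matrix can never call a site — the degenerate case degrades to "no
information, no calls" rather than to nonsense.

## Promoter extraction

The regulatory region is defined as the fixed window (1000 nt by default)
immediately upstream of the translation start — the annotated CDS start on
the gene's strand, ATG excluded — reverse-complemented for minus-strand
genes so that the output always reads 5'→3' relative to the gene. When a
gene has several mRNAs the 5'-most CDS start is used, the most inclusive
choice when isoform structure is unresolved. Interfaces use 1-based
inclusive coordinates (GFF3 convention); the BED export converts to 0-based
half-open. Windows running off a contig edge are truncated and flagged
rather than discarded or padded: the flag keeps the information while
letting downstream counts remain honest about shorter search space.
Overlap with an upstream neighbouring gene is deliberately not trimmed —
the window is a fixed-length convention, not a claim about gene boundaries.

## Threshold calibration against an empirical null

A fixed normalized-score cutoff of 0.8 is a sensible motif-scanning
convention, but its stringency depends on the matrix's information content.
`crzscan` therefore also calibrates the cutoff against randomized controls:

* **Null models.** The default is a mononucleotide shuffle of each real
  promoter (length- and composition-matched, 10 replicates) — the weakest
  null that controls base-composition artefacts. A dinucleotide-preserving
  shuffle (random Eulerian walk over the dinucleotide multigraph, i.e. the
  Altschul–Erickson construction, written here and verified against an
  independent dinucleotide-counting oracle) and i.i.d. draws from each
  promoter's own composition are available for stiffer or looser nulls.
* **Statistic.** Both real and control sequences are scanned identically;
  the normalized scores of positive-raw-score windows form the samples. The
  false-positive rate at a threshold `t` is the fraction of the null sample
  at or above `t` — a rate over *candidate* windows, the ones the selection
  rule admits.
* **Selection.** The calibrated threshold is the smallest point on a 0.005
  grid whose null FPR does not exceed the target (0.005 is far finer than
  the one-decimal convention the fixed cutoff reflects, and costs nothing).
  The default target FPR is 0.01 — one expected false candidate per hundred
  admitted windows, a conventional stringency for short-motif scans. The
  report always also states the empirical FPR and real-sequence hit rate at
  the fixed reference cutoff, so a user can see directly how conservative
  0.8 is for their matrix; passing an explicit threshold always overrides
  calibration. If even `t = 1` exceeds the target, a sentinel (`NA`
  threshold, diagnostic message) is returned instead of a fabricated
  cutoff, and a report flag marks the no-enrichment situation where the
  real hit rate does not exceed the null's.

Selection is monotone by construction: a smaller target FPR can never give
a smaller threshold. Because the threshold sits on a discrete grid its
achieved null FPR lies somewhere at or below the target; reproducibility on
a fresh control replicate is therefore judged against binomial sampling
error of the achieved rate, not as exact re-attainment of the target.

## The synthetic study generator

`generate_study_like_set()` emulates the survey design this package is
built around: 30 promoters of 1000 nt with between 0 and 7 motif instances
each, planted in sense or antisense orientation. Defaults follow that
design; where the design leaves a quantity open the generator fixes one
realistic choice: per-promoter totals are drawn uniformly on 0..7, each
site's strand is a fair coin, the background is uniform, and planted sites
are placed uniformly among non-overlapping arrangements (via the exact
spacing construction — sorted uniform draws on the length shrunk by the
total site footprint, shifted by cumulative widths — which samples the
non-overlap region directly instead of rejection-looping). Words are
either the consensus or drawn position-wise from the matrix; antisense
sites are written as the reverse complement of the drawn word.

The bundled test matrix (`crz1_like_freqs()`) is an eight-position,
high-information, non-reverse-palindromic matrix with consensus
`GAGGCTCA`, matching the width and information scale of a CDRE-class
motif. It is synthetic: tests against it validate the machinery, not any
biological motif.

One deliberate deviation from a purely i.i.d. background: by default the
generator scrubs chance occurrences of the consensus word (and its reverse
complement) from the background by point mutation outside planted
intervals. With a width-8 motif, 30 kb of random sequence is expected to
contain about one chance consensus word, which would make "the scan at
threshold 1.0 recovers exactly the truth table" a coin flip rather than a
contract. Cleaning makes the truth table exhaustive and every exact-recovery
test deterministic; `clean_background = FALSE` restores the raw background,
in which case `compare_to_truth()` classifies chance hits as false
positives. For `mode = "sample"` the exact expected recall at any threshold
is computable by enumeration (`planted_word_pass_rate()`); for the bundled
matrix at threshold 0.8 only the consensus word passes, so that pass rate
equals $0.85^8 \approx 0.27$ — sampled-word planting is intentionally a
harder recovery problem than consensus planting.

### What passing tests do and do not show

The generator's promoters are i.i.d. (or scrubbed-i.i.d.) sequence with
exact motif copies planted. Real promoters have repeat structure,
composition gradients, degenerate motif instances and co-occurring motifs,
none of which are emulated. Green tests therefore demonstrate that the
scanner, normalizer, calibrator and truth accounting are correct — not that
any particular genome scan has biological sensitivity or specificity.
Reproducing a real survey additionally requires the external genome build,
the original database matrix and the published gene list, inputs this
package deliberately treats as user-supplied.

## Relative expression (2^−ΔΔCt)

The expression module implements the Livak method exactly as named:
amplification efficiency fixed at 2, no efficiency correction. Within each
(strain, condition) group replicate Ct values are averaged per gene before
differencing (the classic formulation), ΔCt is taken against the reference
gene, and ΔΔCt against the same strain's calibrator condition, so each
strain is its own baseline. Per-replicate ΔCt values (target and reference
paired by replicate id) are kept alongside: their standard deviation is
reported per group and a per-replicate fold table is attached for error
bars. Useful identities — fold 1 when a group is its own calibrator,
invariance under group-wide Ct shifts, antisymmetry of log-fold under
swapping group and calibrator — are asserted in the test suite.

## Pipeline and reproducibility

`run_pipeline()` chains the stages (matrix, promoters, scan, null
comparison, optional expression) under a single validated configuration in
which exactly one of {fixed threshold, calibrate} is active. Every random
draw in a run derives from the single configured seed, and no output table
or JSON carries wall-clock state, so identical configurations reproduce
every TSV/JSON/BED/FASTA output byte for byte (the free-form `run.log` is
the one exempt file). A failing stage raises a condition naming the stage
and removes the run's partial outputs. Problem sizes used by the test
suite and acceptance script — 30 × 1 kb promoters, 2–10 null replicates
(≥ 10^5 control windows for calibration checks), ~100 oracle-comparison
sequences — are small enough to run anywhere in seconds while keeping
every statistical check adequately powered.

## Known limitations

* Independent-position PWM only: no dinucleotide dependencies, no motif
  discovery, no per-hit p-values (the thresholding is on normalized score,
  by design).
* ATG-anchored promoter definition; TSS/UTR structure is out of scope.
* Null models are composition-matched at order one or two; GC-stratified
  or region-matched nulls are not provided.
* Expression quantification assumes perfect doubling; use an
  efficiency-corrected method when standard-curve efficiencies deviate
  materially from 2.
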