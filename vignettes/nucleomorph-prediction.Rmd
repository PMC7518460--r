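---
title: "Predicting nucleomorph-encoded genes from a transcriptome assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting nucleomorph-encoded genes from a transcriptome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmfinder)
```

## The problem

Nucleomorphs are the relic nuclei of eukaryotic endosymbionts, retained in
a handful of algal lineages (cryptophytes, chlorarachniophytes, and two
recently described green dinoflagellates). Their genomes share a striking
signature: they are strongly AT-biased relative to the host nucleus and
their genes are highly expressed. When no nucleomorph genome sequence is
available, that signature is visible in the host's *transcriptome*: among
transcripts of green-algal affinity, the nucleomorph-encoded ones form a
low-G+C, high-expression population, well separated from their
nuclear-encoded counterparts.

`nmfinder` turns that observation into a reproducible classifier. Given a
transcriptome assembly, protein homology hit tables against a
taxonomically labelled database, an all-vs-all nucleotide self-search, and
a per-transcript abundance table, it produces a table of
nucleomorph-candidate ("Nm-candidate") calls with posterior
probabilities, plus the per-category annotation summary used to describe
putative nucleomorph gene content.

## The procedure

1. **Green-algal provenance.** Protein hits are filtered at
   `evalue <= 1e-10`, collapsed to one best hit per subject, and ranked
   within each query (ascending e-value, ties by descending bit-score,
   then subject id — a deterministic stand-in for BLAST's
   version-dependent native order, switchable with `rank_by`). A
   transcript is kept iff one of its top 5 hits is to Viridiplantae.
   Transcripts with *any* surviving hit to a plastid-genome-encoded
   protein are removed, at any rank: the removal targets
   plastid-genome-encoded genes, which would otherwise contaminate the
   low-G+C population (plastid genomes are AT-rich too).
2. **Splice-variant deduplication.** Nucleotide self-hits with bit-score
   strictly greater than 100 join two transcripts as putative splice
   variants of one locus. Bins are *connected components* of this graph
   (a–b and b–c merge even without an a–c hit): a "bin" partitions the
   candidate set, and transitive merging is the only reading that
   guarantees a partition. The representative is the member with the
   longest ORF, ties broken by smallest id.
3. **Features.** For each representative: G+C fraction at codon positions
   1 and 3 of the longest complete ORF, and the natural log of TPM.
   ORFs must be complete (ATG to stop, both strands scanned, ties
   resolved + strand first, then smaller start) — codon-position G+C
   needs an unambiguous frame, and assemblies do not guarantee sense
   orientation. The stop codon counts toward ORF length but is excluded
   from the G+C tallies by default (`count_stop_codon = FALSE`): stop
   codons are constrained to TAA/TAG/TGA and would bias composition.
   TPM is recomputed from expected counts and effective lengths
   (`tpm_i = 1e6 (c_i/l_i) / sum_j (c_j/l_j)`); zero-TPM transcripts have
   no defined log expression and are excluded from clustering, reported
   in `unexpressed.tsv` rather than pseudocounted.
4. **Classification.** The three features are standardized with the
   population (divide-by-n) standard deviation — a pure function of the
   data, chosen so results are bit-stable — and a two-component Gaussian
   mixture with one *tied* covariance matrix is fitted by EM.
   The component with the lower de-standardized mean GC3 (tie-break:
   GC1) is the nucleomorph component; GC3 is the least constrained codon
   position and the most diagnostic of compositional pressure. A
   transcript is an Nm-candidate iff its posterior for that component is
   strictly greater than 0.95.

## The model and its numerics

With observations $x_i \in \mathbb{R}^3$, weights $\pi_k$, means
$\mu_k$ and one shared covariance $\Sigma$:

$$ p(x_i) = \sum_{k=1}^{2} \pi_k \, \mathcal{N}(x_i \mid \mu_k, \Sigma). $$

The E-step computes responsibilities in log space with log-sum-exp; the
M-step sets $\pi_k$, $\mu_k$ from responsibility-weighted sums and the
tied covariance from the pooled responsibility-weighted outer products of
residuals divided by $n$, plus `reg = 1e-6` on the diagonal to guarantee
positive-definiteness. Convergence is declared when the mean per-point
log-likelihood improves by less than `tol = 1e-6`. Ten seeded random
restarts are run and the best final log-likelihood wins.

**Initialization** places the component means on two distinct randomly
chosen data points, with equal weights and the pooled data covariance.
We deliberately avoided the other classic scheme — random responsibility
draws — because it starts both means within $O(n^{-1/2})$ of the pooled
mean, which is the *symmetric unstable fixed point* of EM: the
log-likelihood then improves by less than `tol` per iteration while the
symmetry slowly breaks, and a tolerance-based stop misreads the plateau
as convergence, returning a degenerate one-cluster fit. Random-point
initialization starts far from that fixed point; with well-separated
populations, a handful of restarts virtually guarantees one split that
matches the true partition.

The EM log-likelihood is non-decreasing by construction, and the test
suite asserts it on every fuzzed run, along with row-normalization of
responsibilities and agreement of the posterior with an independently
coded density-ratio oracle. On unimodal data the fitted mixture conserves
sample moments exactly (mixture mean = sample mean; tied covariance plus
between-component scatter = sample covariance), which the suite also
checks — note that on such data the two fitted means legitimately split
apart; a mixture fit on one Gaussian is not required to collapse.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `evalue_cutoff` | 1e-10 | retain hits with e-value at or below this |
| `top_n` | 5 | ranks inspected for a Viridiplantae hit |
| `bitscore_min` | 100 | splice-variant edge threshold (strict `>`) |
| `threshold` | 0.95 | posterior call threshold (strict `>`) |
| `seed` | — | EM initialization seed, always logged |
| `n_init` | 10 | EM random restarts |
| `tol` | 1e-6 | EM convergence tolerance (mean log-lik / point) |
| `reg` | 1e-6 | diagonal covariance regularization |
| `count_stop_codon` | FALSE | include the stop codon in G+C counts |
| `use_input_tpm` | FALSE | trust an input TPM column instead of recomputing |

Boundary semantics are strict everywhere they matter: a bit-score of
exactly 100 creates no edge, a posterior of exactly 0.95 is not a
candidate, and a Viridiplantae hit at rank 6 does not qualify a
transcript.

## What the synthetic generator emulates

`simulate_dataset()` builds a complete truth-labelled input bundle: two
transcript populations differing in GC1/GC3 (defaults: GC3
0.25 ± 0.05 vs 0.55 ± 0.05; GC1 0.40 ± 0.05 vs 0.52 ± 0.05), log-normal
expression with the low-G+C population two log-units higher (7.5 vs 5.5,
sd 1, on the log relative-expression scale — TPM renormalization adds one
dataset-wide constant to both populations), valid complete ORFs of
100–400 codons, splice-variant duplicates (10% of each green population,
truncated re-emissions linked by a bit-score-200 self-hit), non-green
decoys whose only Viridiplantae hit sits at rank 8, and plastid-subject
hits on 5% of nuclear transcripts. The default sizes are 150 nucleomorph,
350 nuclear and 100 decoy transcripts at seed 7; all files are
byte-identical across runs with the same seed. These GC separations put
the standardized populations roughly five mean standard deviations apart
(per-ORF binomial sampling of codons widens the nominal 0.05 sds to
about 0.06), matching the clearly bimodal GC3 histograms this kind of
data shows.

What it does **not** emulate: real codon-usage structure, sequencing or
assembly error, partial ORFs at contig ends, multi-mapping ambiguity in
abundance estimation, homology-detection failure, or a realistic KO
category distribution (the generator's category frequencies are
plausible, not estimated from any organism). Passing the end-to-end
recovery test therefore demonstrates that the pipeline's logic and the
classifier are correct under the stated generative assumptions — not that
real transcriptomes meet those assumptions. Stop-codon avoidance during
simulation biases realized GC3 upward by about 0.01 at low GC targets;
tests account for this.

Mock e-values and bit-scores are deterministic functions of the truth
label and the seeded RNG, not of any alignment: the provenance module
only ever reads the table, so nothing is lost by not aligning.

## Problem sizes and determinism

The test suite fits EM on twenty 2,000-point datasets, checks the ORF
finder against an exhaustive six-frame oracle on 100 fuzzed sequences,
compares variant bins with a brute-force transitive closure on 200 random
graphs, verifies generator convergence on a 5,000-transcript bundle, and
runs the full pipeline on the 600-transcript default bundle — sizes
chosen to exercise every asymptotic property while keeping a full run in
the order of a minute. Every random draw is seeded; `calls.tsv` and
`model.json` digests are asserted identical across reruns.

## Known limitations

- The classifier assumes exactly two populations; transcriptomes with a
  third compositional class (e.g. a large plastid-transcript carryover
  that survives filtering) violate the model.
- Expression must be informative: if nucleomorph and nuclear expression
  distributions overlap entirely, separation rests on GC alone.
- Transcripts without a complete ORF or with zero TPM never reach the
  classifier; heavily truncated assemblies will lose candidates.
- The low-G+C rule is relative: in a genome whose nucleus is itself
  AT-rich the component identification could in principle invert.
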