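---
title: "Dating microprotein origins: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating microprotein origins: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microorigin)
```

## The problem

A microprotein exists only where two conditions hold simultaneously: an
open reading frame is present in the genome, and the locus is transcribed.
Dating the origin of a human microprotein therefore decomposes into two
independent dating problems on the same species phylogeny — when the ORF
formed, and when transcription was gained — which are then combined. This
vignette explains the models behind each stage, the parameters that matter,
the numerical choices, and what the synthetic benchmark does and does not
demonstrate.

Throughout, ages are **ordinal**: a node's age is its position on the
labelled ancestor path from the human leaf to the root (`N1` most recent).
Calendar ages are presentational and deliberately out of scope; every
inference in the pipeline is node-based.

## Dating ORF formation

### Alignment and branch lengths

Orthologous regions are aligned with a progressive sum-of-pairs profile
aligner (pairwise Gotoh steps over the guide tree, match +1, mismatch −1,
gap open −4, gap extension −1, a run of *g* gaps costing `open + (g−1)·ext`).
A built-in aligner keeps the pipeline self-contained and deterministic;
`read_external_msa()` accepts output of any external aligner that writes
FASTA, validated by the same row-width and round-trip checks. DP ties are
broken in a fixed order (substitution > gap-in-second > gap-in-first), so
alignments are reproducible.

Branch lengths are then fitted on the *fixed* species topology by maximum
likelihood (Felsenstein pruning; coordinate-wise Brent updates per branch
until the log-likelihood improves by < 1e−6 relative). Gaps and `N` are
missing data. Two models are available: Jukes–Cantor, and GTR with
4-category discrete-gamma rates. The two-sequence JC fit reproduces the
closed form −(3/4)·ln(1 − 4p/3) to ~1e−9, and on simulated 10 kb alignments
the total tree length is recovered within 20% relative error (median).

### Marginal ancestral reconstruction

Ancestral states are reconstructed marginally: an inside–outside pass gives
the exact per-column posterior over {A,C,G,T} at every internal node,
verified against brute-force enumeration of all ancestral state assignments
on small trees (agreement ≤ 1e−10). Reconstruction uses JC by default even
when branch lengths were fitted under GTR+Γ, mirroring the common
fit-rich / reconstruct-simple split; both stages accept a model override.
Calls are the argmax state, with ties broken alphabetically (A<C<G<T) for
determinism; posteriors are exposed but calls are made regardless of
confidence, a known simplification.

Indels are reconstructed from the gap pattern with a two-state
(present/absent) continuous-time chain whose gain/loss rates are estimated
by ML on the alignment, the same inside–outside machinery giving a
per-column posterior of "present". For alignments narrower than 10 columns
there is too little signal to estimate two rates, and the code falls back
to Fitch parsimony with ambiguity resolved toward "present" (keeping
sequence is the conservative choice for a length-ratio test). An ancestor's
sequence is the concatenation of its present-state columns.

### The intactness rule

`call_intactness()` reads the reconstructed ancestor in frame +1 from
position 1 — the frame of the human microprotein; other frames are a
documented non-goal — and computes

```
ratio = (nt before the first in-frame stop) / denominator
```

where the denominator is the ancestral length, replaced by the human ORF
length when the ancestor is longer. "Length of the ancestral ORF" is
interpreted as the span before the *first* stop; this is the reading under
which the ratio formulation and its "stops disrupt no more than 30%" gloss
coincide. The ancestor is **intact** when `ratio ≥ intact_ratio_cutoff`
(default 0.70; 0.50/0.80 are reported as sensitivity columns by
`render_report()`). No ATG is required anywhere — tests assert that
mutating ATG↔GTG at position 1 never flips a call. Ancestors shorter than
`short_ancestor_fraction` (0.50) of the human ORF are `ignored_short`:
treated as intact by the origin scan so they do not break runs, but flagged
when the origin lands on one, since a half-length fragment should not
anchor an age. Boundary behaviour is exact: ratio exactly at the cutoff is
intact; length exactly at half the human ORF is judged normally.

### Origin and mode

`date_orf_origin()` scans calls from recent to ancient: the origin is the
most ancient intact ancestor, and the mode is `de_novo` exactly when a
disrupted ancestor is strictly more ancient — positive evidence that the
ORF arose out of non-ORF sequence. With no disrupted ancestor the mode is
`undetermined` (the scan reached the root, or older regions could not be
recovered). An intact–disrupted–intact pattern is handled by the literal
most-ancient-intact rule and flagged `non_monotone` for review. Outgroup
proteome hits (E ≤ 1e−5, identity ≥ 40%, coverage ≥ 50%) expand the species
set, can move the origin root-ward, and remove de novo status; human
self-proteome hits at ≥ 50% identity/coverage are flagged for manual review
but never reassign automatically.

## Dating transcription

Three presence channels are combined by union, each with its own cutoff
from `pipeline_config()`: annotated-transcript exon overlap ≥ 0.80,
transcript-database sequence match with coverage ≥ 0.60 and E ≤ 0.001
(boundaries inclusive), and expression with any-tissue TPM ≥ 0.1. The human
leaf is unconditionally present: its ORF is transcribed by construction.
The origin is the Dollo-parsimony MRCA of the positive set — a single gain
with any number of losses — which brute-force enumeration over all gain
placements confirms on every presence subset of 8-leaf trees.

The expression threshold escalates from 0.1 to 1 TPM only when the lenient
pattern is *sparse and phylogenetically inconsistent*: the number of
sampled-but-silent species descending from the presence MRCA must fall by
at least 50% under the stricter threshold (ties at exactly 50% escalate,
per the "at least" reading), and fewer than 80% of the present species may
share one expressed tissue — a shared tissue argues for a genuinely
conserved, tissue-specific transcript, and the lenient cutoff is kept. The
silent-descendant count A(t) is computed against the MRCA induced at the
same threshold t; counting against the 0.1-MRCA instead was considered and
rejected as double-penalising patterns the stricter threshold has already
cleaned up. Unsampled species contribute neither presence nor absence,
so missing data can only make the estimate younger — transcription ages
are lower bounds by design.

## Combining the two origins

The putative microprotein origin is the more recent of the ORF and
transcription nodes. One exception: when the ORF is older than the
transcription evidence *and* the codon alignment restricted to species
descending from the ORF-origin node scores above 10 decibans, the ORF node
is used — transcript catalogues outside human are incomplete enough that a
positive coding signal outweighs missing transcription evidence. The
exception threshold is strict (`> 10`), and the putative origin can never
be more ancient than the ORF origin.

## Coding signatures

Codon alignments are built origin-aware and frame-preserving: sequences are
translated in frame +1 (internal stops become a 21st symbol scoring −5
against everything, so disrupted orthologs still align), peptides are
aligned progressively, and nucleotides are threaded back (residue → its 3
source nt, peptide gap → 3 nt gaps). Every internal gap run is a multiple
of 3 and ungapping any row — plus its recorded 1–2 nt tail when the input
was not a codon multiple — reproduces the input exactly; reference-gap
removal is a separate, deliberately destructive operation applied before
scoring. Codon columns containing a stop in any row are removed
(idempotently) before selection analyses.

The built-in coding score is a likelihood-ratio test under a GY-style codon
model with uniform codon frequencies and transition/transversion ratio
fixed at 2 — the smallest model with a meaningful ω. The alternative
optimises ω and a tree-scale factor, the null fixes ω = 1, and the score is
10·log₁₀ of the ratio, the deciban scale on which the conventional coding
thresholds (41 to call coding, 10 for the combination exception) are
expressed. Whether this minimal LRT is calibrated comparably to externally
trained phylogenetic codon models is unknown; the thresholds are
configurable, and `coding_score(scorer = "external")` ingests precomputed
score files as the authoritative route for cross-study comparisons.
Six-frame scanning re-threads and re-strips each frame independently.
Pairwise dN/dS uses Nei–Gojobori counting with minimal-pathway averaging
(stop-passing pathways excluded; changes *to* stops excluded from site
counts), counts summed over all pairs, and returns flagged `NA` when there
are no synonymous differences. A maximum-likelihood single-ω estimate comes
free with the LRT scorer.

Hexamer (dicodon) scores are the mean over in-frame hexamers, step 3, of
`log(coding_freq / noncoding_freq)` with pseudocount-smoothed tables;
positive means coding-like usage.

## The synthetic benchmark

`simulate_bundle()` generates the full study scenario with known truth:

* a pectinate labelled tree (every internal node on the human path, so any
  ancestor can host an event), exponential branch lengths with mean 0.02 by
  default and 0.01–0.05 substitutions/site in the benchmark — the low-
  divergence regime in which ancestral reconstruction of a young ORF is
  meaningful;
* a 90 nt ORF (the observed lengths centre near this; the minimum accepted
  is 33 nt) born at a chosen ancestor: the root carries an in-frame stop in
  its first 70%, the branch into the birth node removes all in-frame stops
  by minimal third-position edits, descendants stay stop-free, outgroup
  lineages are kept disrupted; the human lineage receives no indels (the
  human ORF is an intact reference by definition) while other branches get
  geometric-length single-nt indels (rate 0.005/site/unit), exercising
  frameshifts;
* a single transcription gain: species below the gain node draw lognormal
  TPM (meanlog log 5, sdlog 1, clamped up to the 0.1 floor) in a random
  non-empty tissue subset unless dropped out; outgroups draw sub-threshold
  noise, or between-threshold noise in "confusion mode" to exercise the
  escalation rule.

On 50 such bundles the pipeline recovers the planted birth node in ~90–95%
of replicates. The characteristic failures are informative: a birth node
directly below the root leaves a single outgroup leaf as the only witness
of the ancestral disruption, which marginal reconstruction cannot resolve
against the intact majority (the case is then honestly `undetermined`),
and stops planted near the 70% boundary can flip one node under
reconstruction noise. What the benchmark does *not* emulate: realistic
codon usage or selection (dN/dS ≠ 1), alignment error at high divergence,
assembly/annotation artefacts, or paralogy — passing it shows the
inference machinery is correct under the model's own assumptions, not that
those assumptions hold for any particular locus.

## Numerical and interface choices

* All internal coordinates are 0-based half-open; GTF input is converted at
  the boundary. Ambiguity codes other than `N` are rejected; `N` is missing
  data in every likelihood.
* Duplicate expression triples keep the maximum TPM (with a warning),
  matching how overlapping-transcript expression is assigned; duplicate
  (paralogous) alignment rows keep the longest aligned span, with a logged
  message — the tie-break is a package choice where practice is silent.
* Branch lengths are floored at 1e−9 during optimisation and reported as 0
  below 1.5e−8; likelihoods guard against exact zeros with a 1e−300 floor.
* Statistical tests are the standard ones: `wilcox.test` (exact for small
  tie-free samples, normal approximation with correction otherwise, as
  verified against full permutation enumeration for n ≤ 8), Spearman via
  `cor.test`, and `chisq.test` with Yates correction on by default for 2×2
  tables (the correction only reduces the statistic). No multiple-testing
  correction is applied by `compare_groups()`; raw p-values are reported.
* Problem sizes in the shipped tests — 50 dating replicates, 8–16 species,
  90 nt ORFs, 20 ASR oracle instances at ≤ 30 sites, exhaustive Dollo
  checks on ≤ 8 leaves — were chosen as the smallest sizes at which each
  property is meaningfully exercised.

## Known limitations

Only frame +1 of the human microprotein is scanned for intactness, so
overprinting and frameshift-preserved homology are invisible. Ancestral
reconstruction is a point estimate per column; reconstruction uncertainty
is exposed as posteriors but not propagated into the origin call. The
escalation rule's tissue criterion uses the single most-shared tissue, the
most direct operationalisation of "sharing a common tissue". Transcription
absence is never evidence of absence — unsampled tissues and incomplete
catalogues mean all transcription ages, and hence putative origins, are
lower bounds.
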