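---
title: "Assessing T-cell epitope cross-reactivity with tissue-weighted indices"
author: "epicross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing T-cell epitope cross-reactivity with tissue-weighted indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicross)
```

## The model

A therapeutic T cell raised against a query epitope can cross-react with
any *natural epitope* (NE): a proteome segment close enough in sequence to
be confused by the T-cell receptor, provided that segment is actually
produced by antigen processing and presented on MHC class I, and provided
its source protein is expressed in the tissue at risk. `epicross` chains
these three conditions into a single screening score.

**Sequence similarity.** NEs are all length-$l$ windows of the reference
proteome at Hamming distance $k \le K$ from the query. Insertions and
deletions are deliberately excluded: MHC-I epitopes are presented at
fixed register and length, so positional substitution is the relevant
similarity model. $K$ controls the question being asked — $K=0$ probes
on-target/off-tumor risk (the identical peptide elsewhere in the
proteome), $K>0$ probes off-target risk (similar peptides).

**Presentation.** Each NE is scored for the three gates of the class I
pathway and the scores are combined as
$$Q = \frac{P_{CL}}{A_{TAP}\, A_{MHC}},$$
where $P_{CL} \in [0,1]$ is the proteasomal cleavage probability at the
NE's C-terminal bond and the $A$'s are IC50-like affinities (lower =
stronger; a dose displacing half of a competitive ligand). NEs must pass
$Q > q_{thr}$ **and** $P_{CL} \ge c_{thr}$. Whether the cleavage
threshold should act as an independent hard filter or be considered
subsumed by $Q$ is genuinely open; we filter on both, because the two
parameters are exposed independently and a peptide that is never cleaved
cannot be rescued by strong binding. With $c_{thr} = 0$ the behaviour
reverts to a pure $Q$ filter.

The neural-network predictors normally used for these three quantities
are not re-implemented here. The package provides (a) log-additive
position-specific scoring matrices with the same contracts — a logistic
window model centred on the cleaved bond for $P_{CL}$; a TAP consensus
in which the C-terminal residue counts fully and the three N-terminal
residues are scaled by the TAP weight; a position-additive
$\log_{10}$-affinity for MHC — and (b) an ingestion path for precomputed
per-NE scores from any external predictor, with $Q$ always recomputed
from the three components rather than trusted from the file.

**Abundance and mismatch weighting.** For each expression database the
per-tissue profile is
$$S(t) = \sum_{k=0}^{K} v(k)\,\log_{10}\!\Big[1 + \sum_{i=1}^{M(k)} a(i,t)\Big],$$
with $a(i,t)$ the abundance of the $i$-th (unique, filter-passing) NE's
source entity in tissue $t$. The mismatch weight
$$v(k) = \frac{1/P(k)}{\sum_{k'} 1/P(k')},\qquad
  P(k) = 1 - \big(1 - 0.05^{\,l-k}\big)^{N-l+1}$$
down-weights strata in which matches arise easily by chance: $P(k)$ is
the probability that a random $l$-mer occurs somewhere in an $N$-residue
proteome with $k$ mismatches, under a uniform 20-letter alphabet
(per-position match probability 0.05). For $l = 9$, $K = 3$,
$N = 6.5 \times 10^7$ the weights are approximately
$0.95, 0.0475, 0.0024, 0.0002$ — exact matches dominate, as they should.

**Tissue weighting.** The index
$$I_{CR} = \frac{\sum_t w(t)\,S(t)}{\sum_t w(t)}$$
averages the profile with weights reflecting how catastrophic damage to
each tissue would be, in the spirit of the SOFA organ-failure score:
weight 1 for tissues whose damage is immediately life threatening
(lung/respiratory, brain/nervous, blood/immune, heart, liver), 0.8 for
life-threatening (digestive system excluding appendix, soft tissue,
skin), 0.5 for not immediately life-threatening (urinary bladder, glands,
prostate, kidney, eye — eye is kept at 0.5 because T cells can infiltrate
it), 0.3 for surgically manageable tissues (reproductive organs, mammary
tissue, tonsils), and 0 for immunologically irrelevant or non-healthy
samples (testis, fetal tissue, appendix, gall bladder, spleen, cancer
cell lines). The scheme ships as an editable YAML config
(`inst/extdata/tissue_weights.yaml`).

The index's uncertainty is the standard deviation of $I_{CR}$ over 10
recomputations on random 90% subsamples of the NE list, and indices from
several databases are combined by an unweighted arithmetic mean —
protein-level and transcript-level databases measure different things,
and averaging indices (not abundances) sidesteps their incomparable
units.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `K` | 2 | mismatches | search radius; 0 = on-target only |
| `qThreshold` | 1e-4 | — | minimum combined presentation score (exclusive) |
| `cleavageThreshold` | 0.7 | probability | minimum $P_{CL}$ (inclusive) |
| `tapWeight` | 0.2 | — | N-terminal contribution to the TAP score |
| `reps` / `frac` | 10 / 0.9 | — | bootstrap replicates / subsample fraction |
| `defaultWeight` | 0.5 | — | weight for tissues missing from the scheme |

The defaults are the interactive-use defaults; `crDefaults("study")`
selects the stricter $K = 1$ setting used for group comparisons (combine
with `qThreshold = 0.02` to restrict to the most immunogenic NEs).
Unknown tissues defaulting to 0.5 is deliberate: silently assigning 0
would let an unrecognised but vital tissue vanish from the index, so
unknowns land in the middle category with a warning.

## Design choices

* **Uniqueness per (sequence, gene).** Two isoforms of one gene carrying
  the same NE would otherwise double-count a single expression signal;
  the same sequence in two distinct genes is kept twice because each gene
  contributes its own $a(i,t)$. When no gene symbol is available the
  accession stands in. The first occurrence by (accession, start) is the
  retained representative.
* **Entity resolution, gene first.** NEs are protein segments but
  transcript databases key on genes; lookup therefore tries the gene
  symbol first and falls back to the accession. An entity absent from a
  database contributes abundance 0 — absence of evidence of expression is
  treated as no expression — with one warning per entity so the fallback
  is never silent.
* **$\log_{10}(1+x)$ rather than $\log_{10}(x)$.** The raw
  $\log_{10}\sum a$ is undefined for an empty stratum and negative for
  sums below one abundance unit (sub-FPKM expression would *reduce* the
  index). The offset form is 0 at 0, non-negative, and asymptotically
  equal to the raw form where abundances are large. This is the package's
  one deliberate deviation from the plain formula; it is isolated in a
  single internal function, and `convention = "raw"` restores the
  unmodified form (with empty/zero sums contributing 0) for comparison.
* **`X` counts as a mismatch.** Ambiguity codes in the proteome can never
  be confirmed matches; queries themselves must be unambiguous.
* **Bootstrap over NEs.** The subsampled unit is the NE (not tissues, not
  databases): the NE list is the noisy, search-dependent part of the
  computation, while tissues and databases are fixed structure. Subsample
  size is floored but never below one NE; the standard deviation uses the
  $n-1$ denominator; replicate index sets drawn with identical seeds are
  identical, making the error reproducible.
* **Coordinates.** Internally 0-based half-open; exported tables carry
  both conventions (`start0`/`end0`, `start1`/`end1`).

## Numerical conventions

$P(k)$ is evaluated as `-expm1((N-l+1) * log1p(-0.05^(l-k)))`: for a
9-mer, $0.05^9 \approx 2\times10^{-12}$, and the naive
$1-(1-p)^{n}$ loses most of its significant digits in double precision.
All aggregations iterate in deterministic order (sorted tissue names,
NE rows sorted by $(k,$ accession, start$)$), so a run is bit-reproducible
given the same inputs and seed — including every output file the pipeline
writes. Degenerate inputs have defined behaviour: an empty NE set yields
an all-zero profile, index 0 and bootstrap error 0; an all-zero weight
vector is an error (the weighted average is undefined) rather than a
silent 0; affinities must be strictly positive.

## What the synthetic fixtures emulate — and what they do not

The generators produce uniform-random proteomes with near-matches planted
at exact Hamming distance, abundance tables in the three unit conventions
(log-uniform ppm/FPKM backgrounds, ordinal 0–3 IHC) with planted
gene-tissue cells, and scoring matrices optionally biased so a chosen
peptide clears the presentation filters. Everything is a pure function of
one integer seed, and the uniform residue background makes the $0.05$
per-position match probability of $P(k)$ exactly true, so the mismatch
model is exercised self-consistently.

They are not biological simulators: real proteomes have biased residue
composition, repeats and paralog families (so real $P(k)$ is only
approximate), real tissue expression is correlated across tissues and
databases, and IHC intensities are antibody-dependent. Passing tests
demonstrate the correctness of the machinery — search completeness,
score arithmetic, weighting, determinism, planted-signal recovery — not
the clinical accuracy of any particular index value on real data.

Test problem sizes are desk-scale by choice: oracle-equivalence checks
run 100 random instances against proteomes of a few thousand residues,
invariants are property-tested on over a thousand random cases, and the
planted-signal study uses 20 independent seeds with 30-protein proteomes;
the algorithms are the same at any scale, with runtime linear in $N$.

## Limitations

* The matrix scorers are structural stand-ins with the correct contracts,
  not trained predictors; for real screening, plug in per-NE scores from
  dedicated cleavage/TAP/MHC tools via `loadPrecomputedScores()`.
* MHC class II, indel-tolerant matching and nucleotide-space search are
  out of scope.
* The index is a screening summary, not a safety guarantee: a zero index
  only reflects the databases supplied, and tissue categories are not
  exhaustive — a hit in a low-weight tissue type may also exist in an
  uncovered vital one. Inspect the per-tissue profiles and NE tables
  behind any index before acting on it.
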