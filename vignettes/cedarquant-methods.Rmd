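---
title: "Strain-level abundance estimation with cedarquant: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-level abundance estimation with cedarquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cedarquant)
```

## The problem

Shotgun metagenomic reads rarely identify a single genome. Strains of
the same species (and sometimes different species) are so similar that
a large fraction of reads align equally well to several references,
and references absent from the sample still attract reads from their
close relatives. A quantifier that simply splits ambiguous reads, or
that discards multi-mapped reads, either inflates the reported
community with false positives or throws away signal. cedarquant
estimates per-strain fragment counts by maximum likelihood over the
whole alignment pattern, and resolves the pathological case — groups
of near-identical, low-abundance references whose every read is
ambiguous within the group ("multi-mapping islands") — with an
explicit, mass-preserving set-cover step.

## The generative model and its likelihood

Each sequenced fragment is modeled as arising by first selecting a
reference $r_i$ (among $M$ references) with probability
$\Pr(r_i \mid \theta)$ and then producing the observed fragment with
conditional probability $\Pr(f \mid r_i)$. Fragments aligning to
exactly the same set of references are exchangeable under this model,
so the data are reduced to equivalence classes: class $q$ has label
$\Omega(q)$ (the reference set), fragment count $N^q$, and
per-reference weights $w_{qi}$, giving the class-level likelihood

$$
\mathcal{L}(\theta) \;\propto\; \prod_{q}
\Big( \sum_{i \in \Omega(q)} \Pr(r_i \mid \theta)\, w_{qi} \Big)^{N^q}.
$$

The weights come from alignment scores. If $s$ is a fragment's score
on a reference and $s^{*}$ its best score anywhere, the conditional
probability is $\exp\{\alpha (s - s^{*})\}$ with rate $\alpha$
(default 1 per score unit); the best alignment always has weight 1.
The exponential-in-score-difference form is the standard choice for
selective-alignment quantifiers; $\alpha$ is exposed because score
units depend on the scoring scheme.

**Range factorization.** Two fragments can share a label yet have very
different alignment-quality profiles (one barely tolerated by a
reference, the other equally good everywhere). Classes are therefore
split by a bin signature: each conditional probability is assigned to
one of `bins` equal-width bins over $(0, 1]$ (default 4), and
fragments sharing label *and* signature share a class. Weights are
arithmetic means over member fragments, which preserves per-class
likelihood mass. `bins = 1` recovers the classical reduction; binning
probabilities (rather than raw scores) keeps the bin geometry
independent of read length. Equal-width bins are the simplest scheme
consistent with the factorization idea; the bin count trades
resolution against class-count growth.

## EM, and how the priors enter

The engine iterates expectation and maximization over the classes.
Internally the mixture is parameterized by read fractions
$\pi_i = \hat{c}_i / N$ (estimated fragments over total). The E-step
responsibility of reference $i$ for class $q$ is

$$
\rho_{qi} \;\propto\; \pi_i \, \frac{\kappa_i}{\tilde\ell_i} \, w_{qi},
$$

normalized within the class label, where $\tilde\ell_i$ is the
effective length and $\kappa_i$ a coverage ratio (below). The M-step
sets $\hat{c}_i = \sum_q N^q \rho_{qi}$. This is algebraically the
same update as placing the prior
$\Pr(r_i \mid \theta) \propto \theta_i \kappa_i$ with
$\theta_i \propto \hat{c}_i / \tilde\ell_i$ (the nucleotide-fraction
parameterization reported to users), but the $\pi$ form makes the EM
guarantee transparent: with $\kappa$ fixed, each iteration is an exact
EM step for $\sum_q N^q \log \sum_i \pi_i \kappa_i w_{qi} / \tilde\ell_i$,
so that log-likelihood is non-decreasing between thresholding rounds.
The test suite asserts this monotonicity to $10^{-8}$.

**Effective length** is $\max(1, \ell_i - \bar{f} + 1)$ with mean
fragment length $\bar{f}$ (default 300 bp, the simulator's default):
the number of positions a fragment can start from.

**Coverage ratio.** The prior for selecting a reference also reflects
how much of it is covered: a reference claiming many reads that pile
into a tiny region is suspect. The equivalence-class representation
carries no positional information (by design — it is what makes the
EM tractable and the text format self-contained), so the fraction of
covered positions cannot be computed exactly from the engine's input.
cedarquant uses a uniform-occupancy approximation instead:
$\kappa_i = 1 - \exp(-\hat{c}_i / \tilde\ell_i)$, the expected covered
fraction if $\hat{c}_i$ fragments start uniformly over
$\tilde\ell_i$ positions. $\kappa$ is recomputed once per thresholding
round and held fixed during the EM iterations in between, which keeps
the monotonicity argument intact. `use_coverage_prior = FALSE`
restores the pure-$\theta$ model.

## Iterative mass-preserving thresholding

Every `k_between_setcover` EM iterations (default 10) the engine runs
four steps:

1. **Mark.** References with $\hat{c}_i \le$ `cutoff` (default 2
   fragments, inclusive) are *potentially removable* (PR).
2. **Safe removal.** A PR reference is removed immediately if every
   class containing it also contains a non-PR reference — its reads
   always have somewhere else to go.
3. **Set cover.** Classes whose members are all PR are *critical*:
   deleting all their members would lose reads. The minimum set of PR
   references covering all critical classes is approximated greedily
   (most uncovered classes first; ties prefer the higher current
   count, then the lexicographically smaller id, for determinism).
   Only the retained references survive this step.
4. **Update.** Removed references are deleted from labels and weights
   (surviving weights rescaled so the best is 1 — responsibilities are
   invariant to per-class rescaling, so this is cosmetic), and classes
   whose surviving label and bin signature coincide are merged with
   counts summed.

Removed mass is redistributed by renormalizing $\pi$ over the
survivors, so the total expected count is conserved exactly; the
suite checks $\sum_i \hat{c}_i = N$ to $10^{-6}$ after every iteration
and every round. When a round removes nothing, EM runs to convergence
(maximum per-reference change $\le$ `convergence_tol`, default 0.01
fragments — conservative at desk scale and cheap) or to
`max_iterations` (default 1000). Each removing round deletes at least
one reference, so at most as many rounds as references can occur;
termination follows.

**Final cutoff.** After convergence, references with
$\hat{c}_i \le$ `cutoff` are dropped and logged. This is the only
step that discards mass, and the discarded amount is reported. The
boundary is inclusive, matching the engine's worked-example semantics
("equal to or less than"); `cutoff_inclusive = FALSE` switches to the
strict reading, since the two appear interchangeably in descriptions
of this family of methods. The PR-marking cutoff and the final cutoff
are deliberately the same parameter.

A caveat the tests document: the thresholding only engages for
references at or below the cutoff. Two *well-covered* identical
references remain an even split — no data can distinguish them, and
the engine does not pretend otherwise.

```{r island}
refs <- data.frame(id = c("A", "B"), length = 10000L,
                   effective_length = 9701, taxid = NA)
cedar(class_collection(list(eq_class(c("A", "B"), 4)), refs))$est_reads
```

## The simplified selective-alignment mapper

The mapper exists so the engine is testable end-to-end from FASTQ; it
reproduces the *semantics* of selective alignment at desk scale
without the industrial index. Design choices:

- **Plain canonical k-mer hash** (default $k = 19$) instead of a
  compacted de Bruijn graph with a perfect hash: identical mapping
  results, no compressed index machinery. Maximal exact matches are
  found as diagonal runs of consecutive k-mer hits.
- **Chaining.** MEMs on one (reference, strand) are chained by a
  monotone DP maximizing matched bases minus a small gap penalty
  (0.01 per gap base), so long co-linear matches win.
- **Between-MEM alignment.** Only the gaps between chained MEMs and
  the read ends are aligned, with an affine-gap global aligner
  (match 2, mismatch −4, gap open 5, gap extend 3; a gap of length
  $g$ costs $5 + 3g$). The scheme is conventional for short reads and
  fully configurable; scores, not the scheme, are what the engine
  consumes. The aligner is hand-written because the aligned segments
  are typically 1–5 bases and per-call overhead dominates otherwise.
- **Score filter.** A mapping is kept only if its score is at least
  65% (inclusive — "at least") of the best possible score,
  `match × fragment length`, with mate lengths summed for pairs.
  Summing mates is a convention this package fixes explicitly; the
  per-fragment alternative changes only borderline chimeric pairs.
- **Pairing.** Mates must hit the same reference in opposite
  orientations within `frag_span` (default 1000 bp). Orphans are
  dropped by default; `keep_orphans = TRUE` keeps them scored and
  filtered against the mapped mate only (half weight).

Alignments travel as SAM with `AS:i:` tags (secondary records for
multi-mappings), so externally produced SAM can be quantified as long
as it carries `AS:i:`.

## The community simulator

`simulate_genomes()` + `simulate_reads()` emulate exactly the
phenomena the engine is built for: islands of near-identical genomes
(each island member mutated independently from a shared ancestor at
rate $1 - \text{identity}$), many absent genomes kept in the
reference, paired-end fragments with normal length (defaults 300 ± 50
bp, matching common library preparations), uniform substitution
errors (default 0.002), provenance-encoding read names, and global
shuffling. What it does *not* emulate: indels and platform-specific
error profiles, quality-score structure, GC/coverage bias, and host
contamination. Passing tests therefore demonstrate the estimator's
behavior under its own model assumptions — correct resolution of
multi-mapping structure — not robustness to every artifact of real
sequencers.

Two distinct identity notions deserve care: members are mutated at
rate $m = 1-\text{identity}$ *relative to the ancestor*, so two
members differ pairwise at expected rate $2m(1-m) + \tfrac{2}{3}m^2$
(both mutated, 1/3 chance of coinciding). Tests assert the pairwise
Hamming distance against this expectation.

## Evaluation metrics

MSLE is $\frac{1}{N}\sum_i (\log(y_i+1) - \log(\hat{y}_i+1))^2$ with
natural logarithms (the base is a flag; it only rescales). Filtering
variants: dropping taxa zero in both vectors, and a read-threshold
sweep where a taxon is dropped when `max(y, yhat) < t` — the "max"
rule removes a taxon only when it is small in *both* vectors, which
is the reading consistent with removing it "from both vectors";
`estimated` and `either` are available since the governing vector is
a genuine ambiguity. False positives at threshold $t$ are taxa with
zero truth and estimate strictly greater than $t$. Rank-table
concordance is Spearman's rho after outer-joining on taxid and
dropping taxa zero in both tables.

## Taxonomy aggregation

NCBI dump files (`nodes.dmp`/`names.dmp`) are parsed directly;
`merged.dmp`/`delnodes.dmp` are not consulted, keeping fixtures
self-contained. Counts aggregate to the first ancestor (including the
reference's own taxid) at the requested rank. Mass is never dropped:
references whose lineage lacks the rank are reported under a reserved
`no-rank-at-level` row, unmapped references under
`unmapped-taxonomy` — conservation is the module's contract, mirroring
the engine's keep-every-read philosophy.

## Numerical and testing choices

- Degenerate inputs fail loudly: empty collections, orphaned classes,
  scores above a fragment's best, broken taxonomy lineages.
- Greedy-cover and final-report determinism comes from explicit tie
  breaks; quantification is invariant to class order, and fixed seeds
  make simulator output byte-identical.
- The test suite runs at deliberate desk scale: random class
  collections up to ~12 references and ~30 classes for the
  conservation, monotonicity and set-cover suites (200, 100 and 500
  instances), and one full pipeline of 30 genomes × 10 kb with three
  identity-0.995 islands and 50,000 error-free read pairs for
  parameter recovery. These sizes exercise every code path while
  keeping the whole suite in the minutes range.

## Known limitations

- Identical references above the abundance cutoff cannot be separated
  (inherent to the model) and are reported as an even split.
- The coverage prior is an occupancy approximation, not a positional
  measurement (see above).
- The mapper is not tuned for speed or for divergent homology: seeds
  require an exact 19-mer, so references more than a few percent
  diverged from the read's source rarely attract spurious mappings —
  which is the regime the engine targets, but means remote-homology
  false positives are under-represented relative to large real
  indices.
- No fragment-length distribution modeling, no GC/sequence-bias
  correction, no posterior uncertainty (point estimates only).
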