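---
title: "Profiling metagenomes with common k-mer palettes: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling metagenomes with common k-mer palettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A training database of M genomes is summarized, for a k-mer size k, by the
common k-mer matrix A^(k): entry (i, j) is the fraction of genome j's
k-mers — counted with overlap and multiplicity — that also occur somewhere
in genome i. This containment score is deliberately asymmetric (a plasmid
is fully contained in its host's k-mer set, not vice versa), lies in
[0, 1], and equals 1 on the diagonal. A metagenomic sample is reduced to
the measurement vector y^(k): the fraction of *all* sample k-mers contained
in each training genome. If reads are drawn uniformly from the genomes of
the community with relative k-mer abundances x, then A^(k) x ≈ y^(k); the
derivation only assumes that k-mers shared between two genomes are also
seen in the sample when either genome is present at reasonable coverage.

Two k-mer sizes are used jointly, k = 30 and k = 50. Their containment
values are empirically linked: across genome pairs,
pckm50 ≈ p(pckm30) for a cubic p through the origin. The default
coefficients (−0.5141, 1.0932, 0.3824) describe divergence among real
bacterial genomes. This link is what makes *novelty* identifiable: an
organism present at 80% of its genome produces y30 and y50 entries that
scale identically, while a *related but distinct* organism at 30-mer
similarity 0.8 produces a 50-mer containment of only p(0.8) < 0.8. A
single k-mer size cannot distinguish these two situations; the pair can.

Unknown organisms are represented explicitly. For each genome i and each
similarity bin h ∈ {0.9, 0.8, …, 0.1}, a hypothetical column is added
whose 30-mer entries are the genome's own column capped at h
(`min(h, ·)`) and whose 50-mer entries are the polynomial image of the
capped column. Entries already below h — the genome's sharing pattern
with more distant outgroup taxa — are left untouched: a near relative of
genome i shares i's core content with the rest of the database. The
stacked system has 2M rows and 10M columns.

### Capping before mapping

The two natural orders of the cap and the polynomial map differ: applying
p first and capping second would make the 50-mer hypothetical column agree
with the reference column everywhere the cap is inactive *and* at the
diagonal, leaving bins distinguishable only through second-order effects.
We cap the 30-mer column first and then map it through p, so the two
k-mer blocks of every hypothetical column describe the same organism.
Because p is increasing, this equals `min(p(h), p(col30))`, preserving
the outgroup-sharing pattern in both blocks. Similarly, we read the bin
operation as a *cap* (round down toward h), never as a raise: raising
dissimilar entries up to h would erase precisely the outgroup structure
that lets the solver tell bins apart.

## The solve

Relatively few database organisms occur in any one sample, and the
10-fold column augmentation makes sparsity essential, so the system is
solved as

minimize ‖z‖₁² + λ² ‖Az − y‖₂² subject to z ≥ 0,

the nonnegative basis-pursuit-denoising surrogate. Appending an all-ones
row to λA (with a 0 appended to λy) turns this exactly into nonnegative
least squares, solved by the Lawson–Hanson active-set algorithm
(`pracma::lsqnonneg`). The active-set path is deterministic, so repeated
runs give identical solutions; ties between equivalent columns are
resolved by the solver's fixed column order and are documented as
implementation-defined but reproducible.

* **λ = 200** (default): trades sparsity against fidelity of the k-mer
  fit. Residuals are non-increasing in λ; we solve once at the default
  rather than continuing λ toward the pure minimum-ℓ₁ limit.
* **Pruning ε = 10⁻⁴** (relative to the largest entry): removes
  numerical dust before renormalizing to proportions. The solution is
  sparse on its own; the threshold only cleans the tail.
* The single stacked 2M-row system is solved once; per-k solves would
  discard the cross-k information that identifies novelty.

## From columns to taxa

Reference-column mass is reported at its genome's strain. Mass on a
hypothetical column (genome i, bin h) is named by finding the partner
genome j whose 30-mer containment with i is closest to h (within
δ = 0.05 when possible; the global nearest otherwise — note the nearest
candidate inside the δ-window *is* the global nearest whenever the window
is nonempty) and assigning the least-common-ancestor rank of lineages i
and j: an organism as similar to i as j is plausibly in their shared
clade. The bins are defined on 30-mer similarity, so matching uses
A^(30). Two hybrid modes bracket the default: *sensitive* takes the
deeper of the LCA rank and a fixed bin-to-rank map (1 → strain,
0.9 → species, 0.8 → genus, …, ≤ 0.3 → superkingdom), *specific* the
shallower. The fixed map and the hybrid rules are this package's concrete
realization of an otherwise underdetermined design space; they are
monotone by construction (sensitive ≥ default ≥ specific in depth).
Assigned mass is summed up the lineage so every ancestor carries at least
its descendants' mass; mass assigned above strain is left unassigned at
deeper ranks rather than attributed to an invented taxon, so per-rank
totals may be below 100%.

For the strain-variation display, the two matrices are averaged and
symmetrized, distance is 1 − similarity (self-similarity 1 maps to
distance 0; no other transform is implied by the containment scale), and
the neighbor-joining tree is built on it. Hypothetical mass attaches on
the path between leaf i and the i–j common ancestor: at the ancestor when
h equals the observed containment, toward the leaf when h exceeds it,
toward the root when it falls short. The tree is midpoint-rooted purely
to orient "above" vs "below", and the 25%-of-edge offset used for strict
placements is a display convention with no quantitative meaning.

## Tunable parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `kmer_sizes` | 30, 50 | bases | containment sizes; the default polynomial is only valid for this pair |
| `bins` | 0.9 … 0.1 | containment | similarity levels of hypothetical columns |
| `lambda` | 200 | — | sparsity/fit trade-off of the deconvolution |
| `delta` | 0.05 | containment | half-width for partner matching in taxon assignment |
| `qmin` | unset | Phred | when set, a sample k-mer counts only if all k bases reach it |
| `canonical` | TRUE | — | strand-collapsed k-mers (reads come from both strands) |
| `prune_eps` | 1e-4 | relative | post-solve abundance pruning |

Counting details that matter for exactness: k-mers never span record
boundaries in multi-record FASTA genomes; any window containing a
non-ACGT letter is dropped (input is uppercased first); the containment
denominator is the count of *valid* windows, not the nominal length
formula, so self-containment is exactly 1 even for genomes with
ambiguity codes. The Phred gate takes the strictest reading — all k bases
of a window must reach the threshold — because a single bad base corrupts
the whole word.

## What the simulator emulates — and what it does not

`random_genome`/`mutate_genome`/`simulate_reads` generate i.i.d. genomes,
substitution-only divergence, and uniformly placed error-bearing reads
with truthful Phred strings. Substitution-only divergence keeps the
survival law exact — a k-mer survives with probability (1−μ)^k — which is
what the test suite calibrates against. Real strain divergence is partly
*segmental* (gene gain/loss) with conserved core regions; the simulator
does not reproduce that, and consequently its 30↔50-mer link differs from
the default polynomial's: under pure substitution, s50 = s30^(5/3),
whereas real pangenomes decay more slowly. The polynomial is a property
of the genome universe it was fitted on, so synthetic-database workflows
refit it by the same no-intercept cubic least-squares procedure on
simulated genome pairs (`calibrate_similarity_polynomial()`), exactly as
the default coefficients were fitted to a large real database. Passing
tests on synthetic data therefore demonstrate the pipeline's internal
consistency (counting, linkage, deconvolution, assignment, placement) —
not that the default coefficients suit an arbitrary real habitat, nor
robustness to indels, repeats, or real error profiles.

Two further simulator-vs-reality gaps are worth naming. First, when
training strains are close relatives, a substitution-diverged novel
organism depresses its containment with *outgroup* genomes
multiplicatively, while the capped-column model expects outgroup sharing
to be conserved; the novelty tests therefore use a strain panel with
graded divergence (substitution rates 0.015–0.075 from a common
ancestor, pairwise 30-mer containments ranging from about 0.26 down to
0.02) so this mismatch stays second-order. Second, read sampling is
uniform with no coverage bias, matching the linear model's assumption by
construction.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the statistical assertions are stable:
100-kb genomes for survival-law and recovery experiments, 50,000
error-free 100-bp reads for the three-genome mixture (L1 recovery error
well under 0.05), 20,000 reads for the held-out-strain experiment, 20
mutation replicates for the 3-standard-error survival checks, and 50
random genome pairs against a brute-force window-scan oracle. Exact
containment counting uses a C++ hash map (strings up to k = 50); no
probabilistic counting is involved, so oracle comparisons are exact, not
approximate. Negative neighbor-joining branch lengths — a known artifact
of the algorithm on non-additive inputs — are clamped to zero. Degenerate
inputs are defined rather than rejected wherever a sensible value exists:
a single-genome tree is a lone leaf, two genomes split their distance
evenly, an all-zero measurement returns the zero solution, and an empty
post-pruning solution yields an empty profile with a warning.

## Known limitations

* Exact in-memory counting targets databases of tens of genomes at
  typical bacterial sizes; billion-k-mer reference collections need
  disk-backed or probabilistic machinery that is deliberately out of
  scope.
* The hybrid sensitive/specific assignment modes are one monotone
  realization of an underdetermined design; alternative hybrids exist.
* Taxonomy handling assumes the fixed eight-rank lineage; no external
  taxonomy service is consulted or validated against.
* Sample-restricted training matrices and coverage-weighted columns are
  documented extension hooks, not implemented features.
* Paired-end mates are treated as independent reads.
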