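---
title: "strainmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strainmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model implemented by `strainmap`,
the parameters that matter in practice, what the bundled simulator does
and does not emulate, and the numerical and design decisions taken where
more than one reasonable choice existed.

## The model

### Approximate mapping by winnowed minimizers

Every reference contig and every read is reduced to its *minimizers*: each
k-mer (default `k = 16`) is hashed together with its reverse complement
under a fixed-seed 64-bit mix function, the numerically smaller
orientation defines the canonical hash, and within every window of `w`
consecutive k-mers the minimum-hash k-mer is kept (leftmost on ties).
Winnowing keeps an expected fraction of about `2/(w + 1)` of all k-mers on
random sequence, which the test suite verifies empirically to within 15%.

The window is auto-tuned from the assumed minimum read length: `w` is the
largest value for which a minimum-length read still contains
`sketch_target` (default 200) minimizers in expectation, i.e.
`w = floor(2 · min_read_length / sketch_target − 1)`. With the defaults
(1000 bases, 200 minimizers) this gives `w = 9`. The tuning rule is an
expected-count heuristic of this package; it reproduces the intended
behavior — density tied to the minimum read length and identity
assumptions — without claiming to be the only possible rule.

Candidate locations are reference windows of read-length extent that share
at least `m_min` distinct minimizers with the read. `m_min` is obtained by
inverting the identity estimator at the minimum identity: an alignment at
identity `id` has expected k-mer Jaccard `J = id^k / (2 − id^k)`, so
`m_min = ceiling(J · sketch_target)` (at least 2). At the defaults
(`id = 0.8`, `k = 16`) this is 3 shared minimizers. Overlapping qualifying
windows are merged, keeping the maximal-count offset; the candidate's
start coordinate is estimated from the reference-minus-read position
differences of the hits nearest the read's entry end (read start on the
forward strand, read end on the reverse strand), where insertion/deletion
drift is smallest. All coordinates are 0-based half-open.

### Identity estimation

For candidate `i` of read `r`, with `S_r` and `S_i` the winnowed minimizer
hash sets of the read and of the candidate reference window, the union
sketch `S_{r∪i}` holds the `s` smallest hashes of `S_r ∪ S_i`, with
`s = min(|S_r|, |S_i|, sketch_target)`. The Jaccard similarity estimate
and the derived alignment identity are

    Ĵ_i  = |S_{r∪i} ∩ S_i ∩ S_r| / |S_{r∪i}|
    îd_i = (2 Ĵ_i / (1 + Ĵ_i))^(1/k).

Candidates with `îd_i` below `min_identity` (default 0.80) are discarded.
The per-read error estimate is `e = 1 − max_i îd_i`, taken over all
candidates before filtering (the maximum is unchanged by the filter
whenever any candidate survives).

### Mapping qualities

Conditional on `e`, the shared-sketch count of a true mapping location is
modelled as Binomial with size `n = |S_{r∪i}|` and success probability
equal to the k-mer survival rate `p = (1 − e)^k`. The mapping quality is
the binomial probability normalized over the read's candidates:

    P_r(i) = Binom(|S_{r∪i} ∩ S_i ∩ S_r|; n_i, p) / Σ_j Binom(·; n_j, p).

Normalization is done in log space, so qualities remain well defined and
sum to exactly 1 even when every binomial probability underflows.

### Sample composition by EM

Let `F_g` be the probability that a random sample read emanates from
database genome `g`, and `E_{r;g}` the count of effective start positions
of read `r` in `g` (contig length minus read length, summed over contigs;
contigs are treated as linear). The likelihood of a mapped read and the
composition-dependent posterior of each of its locations are

    L(r; F)   = Σ_g Σ_{i ∈ map(r,g)} P_r(i) · (1/E_{r;g}) · F_g
    P_r(i; F) = P_r(i) · (1/E_{r;g(i)}) · F_{g(i)} / L(r; F).

`F` is initialized uniformly at `1/|G|` over all database genomes and
updated as `F'_g = Σ_r Σ_i P_r(i; F) / |R|` until the relative
log-likelihood improvement falls below `1e-5` (default) or 500 iterations.
Mapping qualities and `E` are computed once and held fixed; only `F`
changes. The log-likelihood is non-decreasing by construction, which the
test suite asserts on 50 random instances with `1e-9` slack.

After convergence, unmapped reads of sufficient length and sub-length
reads are counted to the special taxon 0 ("unassigned") and the
composition is rescaled over the complete set of input reads; each mapped
read is assigned to its maximum-posterior location, with ties broken by
higher mapping quality, then lexicographic genome, contig and start, so
repeated runs produce identical outputs.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 16 | bases | k-mer size; larger k is more specific, less error-tolerant |
| `min_read_length` | 1000 | bases | reads below this are never mapped (unassigned) |
| `min_identity` | 0.80 | fraction | candidate acceptance cutoff on estimated identity |
| `sketch_target` | 200 | minimizers | expected minimizers per minimum-length read; sketch-size cap |
| `tolerance` | 1e-5 | relative log-lik | EM convergence threshold |
| `max_iter` | 500 | iterations | EM iteration cap |
| `memory_target` | — | index entries | chunked-index budget (see below) |

Raising `min_read_length` halves index density per doubling (through the
window tuning) at the cost of leaving more short reads unassigned;
`min_identity` trades sensitivity to diverged strains against spurious
candidates.

## Memory-limited mapping

`build_index_chunked()` randomly permutes the contigs (seeded) and packs
them into sub-indexes of at most `memory_target` posting entries; a single
contig exceeding the budget gets its own chunk with a warning. Reads are
mapped against every chunk and the candidate sets pooled *before* identity
filtering and quality computation, so chunked classification is exactly
identical to the monolithic run — the union of chunk postings equals the
monolithic index, and all downstream statistics are functions of the
pooled candidate set. The test suite asserts byte-level equality of
assignments and compositions for budgets forcing three or more chunks.

## Taxonomy handling

The NCBI `nodes.dmp`/`names.dmp` dialect is parsed directly. Genomes map
to taxa via a two-column TSV; a taxon mapped by a single genome and
without children keeps the genome attached directly (its strain- and
species-level projections then coincide), while taxa with children or
multiple genomes receive synthetic strain leaves with ids allocated
deterministically from `1e8` upward and recorded in a sidecar table. A
species with one genome but pre-existing strain children also receives a
synthetic leaf — attaching the genome to the internal node would violate
the leaf-only invariant for mappable genomes.

`to_level()` walks upward past unnamed ranks ("no rank"); a node whose
ancestral path lacks the requested rank projects to 0, as does any node
already less specific than the requested rank. At `"strain"` level a node
projects to itself exactly when a mappable genome is attached.

## The simulator: scope and limits

`simulate_genomes()` mutates a random ancestor at a per-base substitution
rate per species (default tiers: `divergence` between species, a tenth of
it within species) and emits a toy taxonomy grouping species round-robin
into genera and families. `simulate_reads()` emulates a pbsim-style CLR
run: log-normal read lengths (default mean 5000, log-sd 0.5, truncated at
500 bases so sub-length reads exist to exercise the unassigned path),
uniform start positions, random strands, flat per-base error rate
`1 − accuracy` (default accuracy 0.88), split 90% substitutions / 10%
indels. All outputs are byte-identical given the same seed.

What it does **not** emulate: platform-specific error structure
(homopolymer compression, non-uniform quality, chimeras), real genome
architecture (repeats, mobile elements, compositional bias, shared genes
between unrelated taxa) and database-scale effects (thousands of closely
related references). Passing tests on simulated data therefore demonstrate
algorithmic correctness — calibration of the identity estimator under its
own error model, EM convergence and recovery, metric arithmetic — not
field performance on real communities.

## Numerical choices

- **Hashes** are 64-bit splitmix64 values masked to 53 bits so they are
  exactly representable as R doubles; at desk scale (≤ 10⁷ distinct
  k-mers) the collision probability is negligible (< 10⁻²).
- **Winnowing of short runs**: maximal runs of fewer than `w` consecutive
  valid k-mers (short contigs, or gaps created by ambiguous bases)
  contribute their single minimum, so short sequences are still
  represented. K-mers containing `N` are never hashed.
- **`E_{r;g}` clamping**: each contig's `length − read_length` term is
  clamped to at least 1, keeping the likelihood defined when a read is
  longer than a contig.
- **Degenerate posteriors**: if every candidate of a read sits on a
  zero-mass genome, the read's posterior is set uniform for that iteration
  with a warning, avoiding 0/0 without inventing a prior.
- **Sub-length reads** are included in the final renormalization
  denominator by default; `finalize_composition(denominator =
  "long-reads")` excludes them for comparison with tools that never see
  them.
- **Compositional metrics** (L1, r²) are computed over columns positive in
  either vector, including the taxon-0 bin; binary presence/absence
  metrics exclude taxon 0 and use a strictly-greater-than-0 presence
  threshold (configurable via `min_abundance`).
- **Median-identity filtering** (`filter_composition_by_identity()`,
  default threshold 0.80) zeroes strain entries whose assigned reads have
  low median estimated identity and moves their mass to the unassigned
  bin; projections to higher levels automatically lose the removed
  contributions.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data generated at test time: genomes
of 20–100 kb, databases of 2–10 genomes, read sets of 50–4000 reads
(up to 20 Mb of sequence for the mixture-recovery check), and a 1 Mb
genome with 500 reads of mean length 5 kb for the identity-calibration
check. These sizes keep any single test file under a couple of minutes on
one CPU while leaving every statistical check well-powered.

## Known limitations

- Identical or near-identical database genomes are not identifiable at
  the strain level: EM splits their mass (the twin-genome test documents
  the ~50/50 split) while the species-level sum remains correct.
- Presence/absence calls from compositional estimates are unreliable for
  low-abundance taxa, particularly under database–sample mismatch; the
  median-identity filter raises binary precision at some cost to recall
  and overall accuracy.
- There is no explicit genomic-divergence term in the model; novel strains
  manifest only indirectly through depressed identity estimates and uneven
  coverage, which `genome_diagnostics()` exposes but does not test
  formally.
- Streaming ("sequence until") operation is out of scope: mapping
  qualities would need dynamic recomputation as the composition estimate
  evolves.
- No base-level alignment is produced (no CIGAR); split/chimeric and
  spliced reads are not modelled.
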