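---
title: "genonav: engine design and filter semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genonav: engine design and filter semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genonav)
```

genonav is a desk-scale genotype-exploration engine: it stores variants and
per-sample genotypes from VCF or HapMap files in a marker-oriented database,
answers count/browse queries under a rich set of filters in real time, and
exports filtered selections to seven population-genetics formats.  This
vignette records the data model, the exact filter semantics, the query
execution strategy and the numerical and design choices a maintainer would
want spelled out.

## Data model

The store is organised the way marker-oriented genotype databases are:

* a **variant collection** holding variant-level features only — ID, type
  (SNP / INDEL / SV-like / other), sequence, 1-based start and stop, and the
  ordered list of known alleles (reference first);
* one **run collection** per (project, run) holding the genotype matrix and
  genotype-level metadata: the verbatim genotype string of every sample
  (allele order and `|` / `/` separators preserved exactly as imported),
  per-call GQ and DP when present, per-call phase groups, and the parsed
  SnpEff effect/gene annotations;
* a **project record** caching what an interface needs instantly: runs,
  individuals, the sample registry, and the distinct sequence-name and
  variant-type lists;
* the verbatim **VCF header** of each run imported from VCF;
* a **tag index**: landmark variant IDs taken every `chunk_size` variants in
  scan order, partitioning the collection into evenly sized chunks;
* a **count cache** keyed by the canonical serialization of (project, store
  version, filter).

An *individual* may be genotyped in several runs; each (individual, run)
genotype column is a *sample*.  The input's sample column name is taken as
the individual ID, so re-importing a panel as a second run attaches new
samples to the existing individuals (incremental loading) with no extra
metadata file.

Variants lacking an input ID get the deterministic ID
`sequence:start:ref:alt1-alt2-...`, which is reproducible and collision-free
within one assembly.  Scan order is byte-wise lexicographic on variant IDs
(radix order, locale-independent); any stable total order works for range
chunking, and this one needs no auxiliary index.

The reference backend is an embedded single-file store (one serialized file
per database under the store directory), loaded into memory on open and
persisted on mutating operations.  The storage contract — indexed lookup on
variant features plus ordered chunked scans of run data — is what the query
layer relies on, not the file layout, so other backends could satisfy it.
One deliberate exception: writing a count-cache entry updates the in-memory
cache immediately but defers the file write to the next mutating operation,
because rewriting the whole database file after every count would make
counting O(database size).

## Filter semantics

A `filter_spec()` bundles every search criterion.  Defaults are chosen so
the all-default filter passes every variant: missing-data ratio threshold
100 % ("accepting all data"), MAF range 0–50 %, no pattern, no thresholds,
no feature constraints.

Evaluation of one variant proceeds in a fixed order:

1. **Variant features** — conjunction of: type membership; sequence
   membership; positional overlap of the variant's `[start, stop]` with the
   query range (1-based, inclusive both ends, so a deletion spanning a range
   boundary matches); number of known alleles; non-empty intersection of
   effect and gene annotations with the requested sets.  Requesting an
   effect/gene filter on a project with no annotated run is an error rather
   than an empty result.
2. **GQ/DP masking** — each *sample call* failing `min_gq` or `min_dp` is
   treated as missing.  A call with no GQ (or DP) field passes the
   corresponding threshold: a call cannot fail on unavailable evidence.
   Threshold-masked calls are distinguished from input-missing calls by a
   `masked` flag, which drives the highlight in the variant detail view.
3. **Consolidation** — each selected individual's masked calls across runs
   are reduced to one genotype: the most frequent genotype, comparing calls
   as unordered allele multisets (`0/1` equals `1|0`); ties are broken by a
   seeded uniform pick.  Masking is applied *before* consolidation, so a
   quality-failing sample cannot outvote a clean one.
4. **Missing ratio** — fraction of selected individuals whose consolidated
   call has no called allele slot; the variant passes when the fraction is
   at most `max_missing_ratio`.  A partially missing call (`./1`) counts as
   called.
5. **MAF** — allele counts over all non-missing allele slots of the
   consolidated calls (a diploid heterozygote contributes one slot to each
   allele); MAF = smaller count / total.  It is only defined for bi-allelic
   variants with at least one called slot.  An undefined MAF does not
   exclude the variant — the criterion is simply not applicable to it (the
   alternative, silently dropping every multi-allelic site whenever a MAF
   range is active, would make the default 0–50 % range lossy).  Range
   bounds are inclusive with a 1e-12 slack so that exact boundary
   frequencies (e.g. 0.5 computed as 3/6) are not lost to floating-point
   representation.
6. **Genotype pattern** — see below.

### The twelve genotype patterns

Pattern evaluation uses the canonical unordered form of each consolidated
call, excludes missing calls, and a variant with zero non-missing calls
matches no pattern except `any` (there is no evidence to support any claim
about its genotype structure, vacuous or not).  "hom" means all called
allele slots equal; "het" means not hom.

| name | true when (over non-missing consolidated calls) |
|---|---|
| `any` | always |
| `all_same` | all calls identical |
| `all_different` | calls pairwise distinct |
| `not_all_same` | at least two distinct calls |
| `mostly_same` | modal call frequency ≥ threshold (default 0.8, must exceed 0.5) |
| `all_hom_ref` / `some_hom_ref` | every / ≥1 call hom for the reference allele |
| `all_hom_var` / `some_hom_var` | every / ≥1 call hom for a non-reference allele |
| `all_het` / `at_least_one_het` | every / ≥1 call het |
| `without_abnormal_het` | no het whose alleles each also appear in a hom call of another selected individual |

`without_abnormal_het` flags the classic signature of collapsed paralogs: a
heterozygote whose two alleles are both fixed (homozygous) in other
individuals.  Patterns are deliberately phase-blind — they describe
zygosity, not haplotypes.

For `n ≥ 1` non-missing calls `not_all_same` is exactly the negation of
`all_same`, and `at_least_one_het` the negation of "all calls hom"; both
duals are exercised in the test suite over exhaustive enumerations.

## Query execution

Counting and browsing use a two-step strategy.  Step one applies the
indexed variant-feature criteria (type, sequence, start) to produce a
variant-ID subset; it is skipped when no feature criterion is set.  Whether
the preliminary step should also use the stop position is not observable
from the result — we keep step one to (type, sequence, start) and apply the
stop-overlap refinement in step two together with allele count and
annotations.

Step two evaluates everything else over evenly sized chunks: ID-membership
chunks of the step-one subset when it ran, otherwise range predicates
between consecutive tag-index landmarks (strictly greater than the previous
landmark, at most the current one).  Chunks are independent and
side-effect-free; any executor is conforming, including the sequential
default, and a forked-process executor (`workers > 1`) is available.  The
engine asserts nothing about scheduling, which is why results are invariant
under `chunk_size` ∈ {1, 7, 1000} and 1 vs 4 workers in the tests.

Progress is reported per completed chunk and is monotone; aborting stops
unscheduled chunks promptly, yields no result and writes no cache entry.
A count result is cached under the canonical filter key plus the project's
store version; every import bumps the version, which both invalidates and
eagerly purges the project's entries.  The default chunk size is 1000 so
that desk-scale datasets still get several chunks and the split path is
genuinely exercised.

Consolidation tie-breaks deserve one paragraph: the filter layer has no
user-supplied seed, and a naive "seed once, iterate" scheme would make
counts depend on chunk order.  Each variant therefore derives its tie-break
seed from a hash of its own ID (plus the export seed at export time), so
any execution order gives the same choice, repeated exports with one seed
are byte-identical, and exports under different seeds can differ only at
genuinely tied calls.

## Export

Export is individual-based: after masking and consolidation, exactly one
genotype per variant per individual is written.  The seven dialects are
pinned as follows (the format family names leave room for variation, and a
testable writer has to choose):

* **VCF v4.2** — verbatim genotype strings with GQ/DP; the stored header of
  the project's first VCF run merged with generated FORMAT lines; phase
  sets written as the `PS` FORMAT tag carrying the stored phase group.
* **Eigenstrat** — `.geno` rows of reference-allele counts (2/1/0, 9 =
  missing or non-diploid), plus `.snp` and `.ind`; bi-allelic variants
  only, others dropped with a warning.
* **GFF3** — 1-based features typed with SO terms (`SNV`, `insertion`,
  `deletion`, `sequence_alteration`); positions and type only.
* **BED** — 0-based half-open `(start-1, stop)` intervals, positions only.
* **HapMap** — 11 standard columns plus two-letter diploid codes, `NN`
  missing; restricted to diploid calls on single-character alleles.
* **DARwin 5** — allelic `.var` table (`@DARwin 5.0 - ALLELIC - ploidy`
  header, unit count line, one row per individual, allele codes =
  index + 1, 999 = missing).  The allelic flavor is pinned because it
  preserves genotypes rather than distances.
* **PLINK** — `.ped`/`.map`, two allele columns per variant, `0 0` missing;
  non-diploid variants dropped with a warning.

Phasing is kept in the database as per-call phase groups and *recalculated
at export time*: two exported records of an individual carry `|` and a
common `PS` iff their stored calls share a group, no matter how many
intermediate variants the filter removed.  When the input VCF lacks `PS`,
contiguous phased stretches get a generated group identified by the
position of the stretch's first variant (the usual PS convention), which
makes export-then-reimport reproduce identical groups.  A threshold-masked
call is exported as a missing genotype of the run's ploidy; an
input-missing call keeps its verbatim string, so an unfiltered round trip
is exact at the record level.

Density summaries histogram matching variant start positions per sequence
and variant type.  Bins span position 1 to the largest stop the *project*
holds on the sequence (not the selection), so an empty selection still
yields well-defined all-zero bins; the default is 150 bins per sequence, a
width at which a density chart remains readable.

## The synthetic-data generator

`fixture_spec()` / `generate_fixture()` emulate a desk-scale resequencing
panel: variants spread uniformly over a few reference sequences (default
1 Mbp each), an alternate-allele frequency drawn per site from a Beta
distribution (default Beta(1, 3), a low-frequency-skewed spectrum of the
kind resequencing panels show), per-call missingness, Gaussian GQ
(default mean 40, sd 15) and DP (mean 20, sd 8) clamped to their legal
ranges, iid per-call phasing assembled into contiguous phased stretches,
and optional ANN- or EFF-style annotations drawn from a small effect/gene
vocabulary.  Alternate seeds change everything; the same seed is
byte-reproducible.  Every file is accompanied by a truth table (true MAF
over all individuals, per-variant missing counts, and the twelve pattern
memberships for the first three individuals) computed during generation
directly from the raw allele arrays — not re-derived through the importer —
so property tests have an implementation-independent oracle.

What the generator does **not** emulate: linkage disequilibrium, population
structure, realistic error covariance between GQ/DP and genotype errors,
multi-nucleotide or overlapping variants, and reference-sequence context.
Passing tests therefore demonstrate the engine's bookkeeping and filter
semantics, not robustness to every artefact of real resequencing data.

## Problem sizes used in the checks

The automated checks run at sizes chosen to exercise every code path while
staying comfortable on a laptop: 200 randomized panels of up to 500
variants × 30 individuals (mixed ploidy 1/2/4, missingness up to 35 %) for
the oracle-equivalence property, and one benchmark-shaped panel of 366
variants × 3000 individuals — the smallest size point of the published
benchmark family this engine is patterned on — for the two canonical query
shapes: a location query (one sequence, 1–5 Mbp) and a MAF 10–30 % query
over the first 2000 individuals.

## Known limitations

* Single-process use; no concurrent multi-writer safety, sharding or
  replication.
* BCF and tabix-indexed access are out of scope; plain and gzipped text are
  read.
* Annotation conflicts between runs are stored per run and never merged;
  the detail view shows each run separately.
* HapMap export cannot represent multi-character alleles; affected variants
  are dropped with a warning rather than silently recoded.
* The MySQL/VCFtools-style timing comparisons that motivated the original
  architecture are not reproduced here; correctness, not wall-clock
  performance, is what the test suite asserts.
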