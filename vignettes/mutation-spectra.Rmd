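---
title: "Mutation spectra from polarized population variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation spectra from polarized population variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutspectra)
```

## The problem

A germline mutation spectrum is the distribution of segregating variants over
mutation types, where a type records both the base change and its flanking
sequence context (for K = 3, the 96 strand-collapsed trinucleotide channels
such as `A[C>T]G`). Spectra differ between populations and species because DNA
replication and repair differ, but three technical effects must be removed
before any biological comparison:

1. **Direction.** A segregating A/G site could be an A→G or a G→A mutation.
   Resolving this needs the ancestral allele, which we take from an ancestral
   genome reconstructed in reference coordinates.
2. **Opportunity.** A genome with more `TCC` 3-mers will show more `TCC`
   mutations at equal per-site rates. Counts are therefore divided by the
   occurrence of each ancestral K-mer in the ancestral genome.
3. **Yield.** Cohorts differ in diversity and depth, so samples carry
   different total mutation counts. A sample-wise median-of-ratios factor
   (the size-factor estimator familiar from count-based expression analysis)
   removes this global scale.

The package implements this pipeline end to end, plus the downstream analyses
used to interpret spectra: PCA, frequency-resolved type fractions ("pulse"
analysis), per-type enrichment tests, and rank-1 signature extraction with
catalogue matching.

## Ancestral genome from alignment blocks

`read_maf()` extracts blocks containing both a named reference row and a
named ancestor row from a MAF alignment; minus-strand reference rows are
converted to forward-strand coordinates, so every block reads 0-based forward
reference positions. `build_ancestral()` then assigns each covered position
the aligned ancestor base.

Alignments can cover a reference position more than once, and the right
conflict rule is genuinely open. We use a **plurality vote**: each covering
block votes with its aligned ancestor symbol, where a gap or any base outside
`{A,C,G,T}` votes `N`; the position gets a base only when that base is the
unique modal vote, otherwise `N`. This is conservative (any unresolvable
disagreement yields "unknown") and deterministic. Soft-masked (lowercase)
bases vote as their uppercase identity, because downstream counting filters on
base identity, not masking. `coverage_report()` returns the exact non-`N`
fraction per chromosome, the standard descriptive statistic for an ancestral
reconstruction.

## Polarization and filtering

`polarize_sites()` applies the pre-processing filters and resolves each
variant's derived allele:

* biallelic SNVs only (multiallelic records are rejected, not split);
* call rate strictly greater than 90% (the boundary is a strict inequality;
  the flag `call_rate_min` is exposed);
* minor allele count of at least 3 (MAC > 2);
* the ancestral-genome base must equal REF or ALT; `N` rejects the site as
  undefined, any other base as a mismatch;
* derived allele frequency strictly below 0.98 (a DAF of exactly 0.98 is
  rejected).

DAF is computed over observed allele copies only: missing genotypes are
excluded from numerator and denominator, and a half-missing diploid call
contributes its single observed allele. No imputation happens inside the
package. Every input site ends up either kept or rejected with a
machine-readable reason; the counts partition the input exactly.

Cohort-wide DAF is used at the filtering stage; per-population DAFs are
recomputed later (`pop_daf()`) wherever an analysis is population-resolved.

## Counting conventions

`mutation_types()` reads the K-mer context from the **ancestral** genome (the
pre-mutation state), never the reference. Contexts whose central base is G or
T are reverse-complemented along with the derived base, so channels always
have a central ancestral A or C — the convention matching the 96-channel SBS
layout after the `as_sbs96()` relabeling. Windows touching a chromosome end
or containing a non-ACGT base are rejected.

`count_spectra()` defaults to **carrier-copy counting**: a sample's cell for
a channel grows by the number of derived copies it carries at each variant
(heterozygote 1, homozygous derived 2). Counting per copy keeps row sums
interpretable (they equal each sample's derived-copy total at usable sites,
an invariant asserted in the tests) and makes hom/het weighting explicit; a
`random-allocation` mode (each variant credited once, to a random carrier
weighted by copies, under a caller-supplied seed) is provided for
sensitivity analyses, default off.

For adjacent pairs, `classify_pairs()` separates one-event from two-event
creation using phased haplotypes: **identical derived-allele carriage** at
both sites is the operational signature of a single event (MNP); anything
else is a sequential dinucleotide mutation (SDM), ordered by DAF on the
grounds that the older change has had longer to rise in frequency. An exact
DAF tie with different carriage leaves the order "unresolved"; such pairs are
counted under an explicit `XY>*>WZ` channel rather than being silently
assigned. Each SDM path (ancestral → intermediate → derived dinucleotide) is
canonicalised against its reverse-complement reading by keeping the
lexicographically smaller label, so every physical event maps to exactly one
channel; the channel set and orientation rule are this package's own
convention, documented here because no printed standard exists for ordered
dinucleotide channels. MNP-classified pairs are excluded from the SDM
spectrum but retained in the pair-classification log.

Haplotypes missing at either site of a pair are dropped from the carriage
comparison, and an unphased heterozygous genotype at a pair site is an error
by default (`unphased = "drop"` discards the affected pairs instead).

## Normalization

`target_normalize()` divides each channel by its ancestral target count
(K-mer counts for SNV channels, canonical dinucleotide counts for SDM
channels). A channel whose target is absent from the ancestral genome is an
error rather than a silent zero-division.

`median_of_ratios()` computes, for each sample *j*, the factor
ŝⱼ = medianᵢ kᵢⱼ / gᵢ with gᵢ the channel's geometric mean across samples,
then divides each row by its factor. Channels with zero geometric mean are
excluded from the median. Two numerical conventions:

* **Zero offset.** Sparse matrices (many zero channels) can make more than
  half a sample's ratios zero, collapsing its median. When any entry is zero,
  `zero_offset()` adds `10^floor(log10(s))` with `s` the smallest positive
  entry (smallest positive 3.5e-9 ⇒ offset 1e-9) to every entry, and only
  then; matrices without zeros are never perturbed. The offset is read off
  the smallest *positive* value because a literal smallest value of zero has
  no decimal exponent.
* **Factor identifiability.** The factors are defined only up to a common
  scale: re-applying the estimator to its own output returns factors all equal
  to the geometric mean of the first-pass factors, and no estimator that
  recomputes gᵢ can keep a single sample's factor exactly proportional under
  rescaling of that sample alone (gᵢ absorbs c^(1/m)). We therefore rescale
  the factors to geometric mean 1 — the same identifiability convention
  count-based expression tools use for their size factors — which makes the
  operation exactly idempotent and leaves every between-sample comparison
  unchanged. `scale_factors = FALSE` gives the raw medians. The invariant
  that *is* exact, and is what the tests assert, is the ratio form: a sample
  that is c times another receives a factor exactly c times larger and an
  identical normalized profile.

Cross-dataset comparison (`combine_datasets()`) row-concatenates
target-normalized matrices sharing a channel set and runs one joint
zero-offset + median-of-ratios pass, placing all samples on a common scale.
The offset is applied per combined matrix whenever zeros are present.

## Downstream analyses

**PCA** (`spectrum_pca()`) is an exact singular value decomposition of the
centred matrix; `standardize = TRUE` (default) scales channels to unit
variance, appropriate when spectra from differently-sized channel rates are
compared across species.

**Pulse analysis** (`daf_fractions()`) recomputes DAF within each population,
drops non-segregating variants, bins the rest into `(lo, hi]` DAF intervals
(log-spaced by default, `daf_bins()`, to resolve structure near 1%
frequency), and reports each type's fraction per bin. A mutation pulse — a
transient rate elevation — appears as one type's fraction peaking in a narrow
frequency band.

**Enrichment** (`enrichment_test()`, `enrichment_scan()`) is the 1-df
chi-square test, without continuity correction, on the 2×2 table of
(type, all other types) × (population A, B), built from per-segregating-
variant counts (`type_counts()`); per-carrier constructions are possible but
per-variant counts are the documented choice here. Expected cells below 5
flag the result rather than suppressing it. Bonferroni adjustment across
channels is the default (BH and none are available).

**Signatures** (`rank1_signature()`) factorizes the nonnegative
channels × samples matrix at rank 1. For a nonnegative matrix the leading
singular pair is itself nonnegative and is the global rank-1 optimum, so we
initialise there and polish with multiplicative updates to a 1e-9 relative
tolerance — deterministic, with no random restarts to reconcile. The
signature is normalized to sum 1; exposures absorb the scale.
`cosine_match()` reports the best catalogue entry and applies a 0.8 cosine
cutoff (a best similarity of 0.79 is a no-match, with the candidate still
named). A small fully synthetic catalogue ships in
`inst/extdata/toy_signatures_synthetic.tsv` for tests and examples; real
catalogues are supplied by the user as channels × signatures TSVs.

## The synthetic-data generator

`sim_cohort()` generates the study conditions every test runs under: an
ancestral genome of configurable length and GC (default 10 kb at GC 0.42, a
mammal-like value), a reference genome diverged from it at fixed sites
(0.2% by default, plus any sites where the reference carries the derived
allele), and per-population variant sets drawn from a channel rate table.
Expected site counts per (population, channel) are proportional to rate ×
ancestral target abundance, so a rate multiplier translates directly into a
normalized-rate ratio. Defaults: two populations of 5 diploids and ~500
sites — small enough for exhaustive brute-force oracles, large enough to
populate all 96 channels.

Design choices, made once:

* **DAF distribution**: derived copies follow a discretised 1/x (neutral-like)
  law between 3 copies and 97% of population haplotypes; a uniform option
  exists. The 3-copy floor keeps default sites above the MAC filter so truth
  tables and pipeline output remain exactly reconcilable.
* **Adjacency**: placements exclude neighbouring positions except for
  explicitly injected pairs, keeping SNV and SDM truth independent. Injected
  MNPs share their carrier haplotype set; injected SDMs have distinct copy
  counts with the younger change's carriers nested inside the older's.
* **Polarization exercise**: 10% of sites put the derived allele in the
  reference (REF = derived, ALT = ancestral), so both polarization directions
  are always tested.
* Everything is deterministic under the single config seed.

What the simulator does **not** emulate: linkage and recombination, gene
conversion, selection, coalescent ancestry, sequencing error, or missing
genotypes. Passing tests therefore demonstrate the correctness of the
counting, classification and normalization machinery under known truth — not
robustness to the error modes of real call sets, which upstream QC is
expected to handle.

## Verification scale and reproducibility

The test suite validates every counting operation against independent
brute-force enumerations on the default 10 kb / 10-sample / ~500-variant
cohort, and the printed normalization formula against a direct
transcription. The parameter-recovery experiment uses two populations of 30
diploids on a 200 kb genome (~11,500 sites) with a 2× `T[C>T]C` rate
elevation confined below 10% population DAF, replicated 20 times; the rate
ratio is measured on the per-population segregating-site spectrum after both
normalization stages, because a low-frequency pulse adds segregating sites
while barely changing carrier-copy totals — measuring sites is what makes
"2× the rate" the recoverable estimand. The enrichment-test calibration uses
1000 multinomial null replicates of 2000 sites per population. These sizes
were chosen so each statistical check has adequate power at its stated
tolerance while the whole suite stays interactive.

`scripts/acceptance.R --seed S --out f.json` reruns the full pipeline under
seed S and writes every headline quantity it computes; all randomness derives
from that one seed.

## Known limitations

* Coding-consequence-resolved sub-spectra (and codon-position-aware SDM
  classes) need an annotation source and are out of scope.
* Unphased data cannot be phased internally; SDM analysis requires phased
  input.
* The SDM channel convention is package-defined (documented above); compare
  SDM spectra only within this package's outputs.
* The enrichment test treats variants as independent; linked sites in real
  data violate this and inflate significance, one reason the package reports
  adjusted p-values rather than making accept/reject decisions for the user.
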