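---
title: "Methods: stability-filtered library design, retention analysis and oligo-pool construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-filtered library design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichlib)
```

# The model

enrichlib operates on the *single-substitution sequence space* of a protein:
the 19·L amino-acid substitutions of an L-residue sequence. The central
assumption is asymmetric predictability: computational stability predictors
(Rosetta-style force fields, antisymmetric neural networks) are unreliable at
ranking *which* mutations improve a target function, but reliable at flagging
mutations that strongly destabilize the fold — and strongly destabilizing
mutations are very rarely beneficial. A library from which the
most-destabilizing fraction of substitutions has been removed therefore keeps
nearly all prospective hits while being substantially smaller.

The package does not run any predictor. It consumes their outputs through
declared formats: an L×20 ΔΔG grid (one row per position, one column per
target residue, wild-type identity cells fixed at zero), a query-anchored
conservation profile from an MSA, and a per-position flexibility profile.
Units (REU or kcal/mol) are declared by the user and carried through
unchanged; the toolkit never converts between energy scales, because filter
thresholds are only meaningful on the scale the predictor was validated on.

## Filtering

`filter_by_ddg_fraction(ddg, keep_fraction)` ranks all 19·L substitutions by
ΔΔG, most destabilizing first, and excludes the top `1 − keep_fraction` of
them. Two conventions required a decision:

* **19·L, not 20·L.** A full per-site scan contains 20·L entries, but the L
  identity cells are all zero by construction and would distort every
  quantile; "removing variants" can only mean true substitutions. The 20·L
  figure is still reported by `ddg_scan_size()` for bookkeeping.
* **Deterministic cut.** The retained count is
  `round(keep_fraction × 19L)` with ties at the percentile boundary broken
  by site ascending, then target residue alphabetical. A 10%-step retention
  grid needs every cut to be reproducible to the single substitution.

Conservation restriction removes, per site, target residues observed fewer
than `min_count` times among aligned homologs (`never_observed()`), on the
rationale that residues absent from natural homologs have usually been purged
by selection. `min_count = 0` is an explicit no-op, so the conservation layer
can be switched off without changing the call structure. Site restriction
(`restrict_to_sites()`) is the injection point for external knowledge —
catalytic pockets, tunnels, hotspot lists. All filters compose by set
intersection, so their order does not matter (a property the tests check),
and each appends to a provenance trail serialized with the allowed set.

A `protected_sites` list exempts chosen sites from ΔΔG exclusion. Campaigns
differ on whether catalytic residues should be saturated or left untouched;
protection supports both by keeping the decision with the user.

## Conservation profiles

MSA columns are anchored on the query row: columns where the query is gapped
are dropped, so profile positions map 1:1 onto query residues. Per-position
residue fractions are computed over the rows that are *not* gapped in that
column — gaps appear in neither numerator nor denominator — and the non-gap
row count is reported as `depth` so shallow columns can be down-weighted by
the user. This query-anchored, gap-excluding convention is a documented
package choice; other tools fold gaps into the denominator, which
systematically deflates observed frequencies in ragged alignments. Consensus
ties are broken alphabetically.

## Retention analysis

`retention_curve()` asks the retrospective question: of the beneficial
mutations an evolution campaign actually found, how many survive each cut?
For each fraction f in a descending grid (default 1.0 to 0.1 in 10% steps),
the allowed set at `keep_fraction = f` is rebuilt and hits inside it are
counted. Percentages are rounded to one decimal, *half away from zero* —
base R's banker's rounding would make grid cells depend on parity.
`retention_grid()` stacks datasets and appends an unweighted-mean `average`
row under the same rounding.

The package bundles the retention rows of four published evolution campaigns
(`campaign_retention_rows()`: ATA-217, HG3.17, DvCA, AciSHC). The per-cell
values summarize full-scale stability scans of those enzymes and their
campaigns' hit lists; they are reference data, not recomputable here. What
the package does recompute — and what the tests pin — is the grid arithmetic
on top of them. Two average-row cells (at fractions 0.2 and 0.1) are known to
sit half a rounding unit away from the column means under any standard
rounding convention and are excluded from exact checks.

The random baseline is analytic — keeping a fraction f of the space at random
retains each hit independently with probability f, so expected retention is
f×100 — plus a seeded binomial Monte-Carlo mean with a normal-approximation
confidence band, which the property tests compare at 3 standard errors.

`hit_ddg_correlation()` reports the Pearson correlation between hit activity
(fold-improvement) and predicted ΔΔG. Within the stability band where hits
concentrate, this correlation is expected to be near zero: the model's claim
is that ΔΔG ranks what to *exclude*, not what to keep. Zero-variance inputs
return an explicit undefined marker rather than NaN.

# Oligo-pool design

## Fragmentation

Array-synthesized oligos are length-capped (default 300 bp), so the gene is
split into the smallest number n of fragments with
`ceil(L/n) + 2·overlap_len ≤ max_oligo_len`. Cores partition the gene with
lengths differing by at most 1 bp (remainders go to the earliest fragments);
adjacent fragments share `overlap_len` bases (default 20 bp) of flanking
wild-type sequence for reassembly by overlap-extension PCR. Minimizing n
minimizes both synthesis cost and the number of SOEing junctions.

## Mutation encoding

Each oligo carries exactly one mutation. Protein-level specs have their
wild-type codon replaced by a codon for the target residue; DNA-level units
are spliced verbatim. Codon choice has two policies, both logged: the default
picks the most frequent codon of the target amino acid in a packaged
E. coli K-12 usage table (normalized per amino acid); `min_edit` picks the
codon fewest nucleotide changes from wild-type, breaking ties by usage then
alphabetically. Expression hosts differ, so the usage table is swappable
(`codon_usage_table()`).

The mutated span must lie wholly inside one fragment core. Overlap copies are
never mutated — a mutation sitting in a SOEing junction would be erased (or
heteroduplexed) during reassembly — and a codon straddling a core boundary is
an error prompting refragmentation rather than a silent reassignment.

## Primers and Tm

Sub-pool amplification primers are anchored at the fragment termini: the
forward primer is a 5′ prefix, the reverse the reverse complement of the 3′
suffix. Lengths between 18 and 30 nt are scored by a nearest-neighbor melting
temperature (unified stacking parameters; terminal initiation terms; entropy
salt correction `0.368·(n−1)·ln[Na+]`; `Tm = 1000·ΔH / (ΔS + R·ln(CT/4)) −
273.15` at 0.25 µM total strand and 50 mM Na+), and the length closest to the
60 °C target wins, ties to the shorter primer. An unreachable target warns
(errors under `strict`) and returns the best effort. The test suite checks
the implementation against an independently coded oracle using the same
published parameters, to 0.5 °C.

Cross-binding between sub-pools is screened by exact match of each primer's
3′ 12-mer against the other fragments (both strands). Full thermodynamic
cross-dimer prediction is out of scope; the seed screen catches the failures
that actually abort a sub-pool isolation.

# Pool QC

Reads (post-basecalling FASTA/FASTQ; qualities ignored) are classified
against the design. Each read is globally aligned — match +1, mismatch −1,
gap open −2, gap extend −1, both ends anchored — to every wild-type fragment
and assigned to the best scorer; equal-length reads above the score floor use
the ungapped alignment, which is optimal under this scoring at high identity.
A designed unit counts as present only if *every* base of the unit matches
the designed replacement with no indel inside it; a partially present unit
contributes its changed bases as extra differences instead. Classes follow
strict accounting: `one_mutation` requires exactly one unit and zero extras;
`wildtype` zero and zero; everything else alignable is `multiple`; reads
below the score floor (default half the fragment length) or shorter than 30
nt are `unalignable` and excluded from the three-way fractions by default so
reports stay comparable across filtering choices.

# The simulators

Two seeded generators exercise the stack; they are first-class, tested code.

`simulate_pool_reads()` emulates the dominant failure modes of oligo-pool PCR
amplification, where truncated products re-prime on other molecules: with
probability `dropout_to_wt_rate` a read's designed mutation is reverted
(wild-type outcome); with probability `chimera_rate` a second designed unit
from another oligo of the same fragment is spliced in (multiple-point
outcome); otherwise the read is the clean oligo. The outcomes are mutually
exclusive per read, so truth labels follow the `(1−d−c, d, c)` mixture
exactly, which is what makes parameter-recovery testing well-posed.
Residual polymerase error adds independent per-base substitutions at
`sub_rate`. Not modeled: indels, length truncations themselves, quality
scores, and polymerase- or cycle-specific error profiles — so a passing
recovery test says the classifier inverts this mixture model, not that it
reproduces any particular wet-lab error rate.

`simulate_ddg_matrix()` generates a stability scan as a two-component
mixture: with probability `p_destab` (default 0.4, the middle of the
empirical 30–50% range) a substitution is destabilizing,
`Normal(15, 3)` REU; otherwise neutral, `Normal(0, 2)`. Hits are sampled
uniformly from substitutions inside `hit_ddg_range` (default −7.5 to 4.7
REU, the band where improved variants are empirically found), with
log-normal activities independent of ΔΔG. This reproduces the qualitative
structure that matters for the method — a well-separated destabilizing band
that cuts remove first, hence a retention plateau at 100% until the cut
reaches the hit band — but not the heavy tails, site-to-site correlation, or
secondary-structure context of real scans, so retention results on synthetic
data demonstrate the machinery, not transferable percentages.

# Numerical and interface conventions

* Coordinates are 1-based inclusive for residues and bases; external tables
  may declare `index_base = 0` at I/O boundaries.
* The 80–600 residue bound common to upstream predictors is a warning by
  default, an error under `strict` — it is an operational constraint, not a
  mathematical one.
* RNA input (U) is transliterated to T with a warning; degenerate IUPAC
  codes are rejected, since oligo design needs concrete parent sequences.
* Replicated ΔΔG columns are aggregated by per-mutation *minimum*, matching
  the convention of keeping the lowest of several relaxation runs.
* The bundled HG3 gene fragment is 156 nt as printed in its source; its
  third QC unit is taken as the three-base region at 93–95 (one earlier
  description gives 93–94; the three-base version is consistent with the
  other units and is adopted).
* Exact sequence-space sizes (`sequence_space_size()`) use arbitrary-
  precision integer arithmetic implemented in base-10^4 limbs, since
  20^L overflows doubles beyond L ≈ 78.

# Problem sizes in the test suite

The tests run brute-force cross-checks where enumeration is feasible —
allowed-set construction and retention on random matrices with L ≤ 5 over all
10% cuts, codon encoding exhaustively over all 61 sense wild-type codons × 19
targets — and statistical checks at sizes chosen so 3-standard-error bands
are tight relative to the effects tested: 5000 reads for mixture recovery,
10^4 replicates for the Monte-Carlo baseline, L = 120–300 with 25–84 hits for
retention-plateau properties. Dominance of the retention curve over the
random baseline holds in expectation; per-sample assertions therefore carry a
3-s.e. binomial slack for the finite hit sample.

# Known limitations

* The package never judges predictor quality; garbage ΔΔG in, garbage
  library out.
* Multi-site (combinatorial) library design, degenerate-codon schemes and
  vendor-specific synthesis constraints beyond the length cap are out of
  scope.
* Classification assumes full-length amplicon consensus reads; raw noisy
  long reads should be consensus-polished upstream.
* The conservation layer reports raw frequencies only; frequency-ratio
  (consensus-design) scoring is deliberately not built in.
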