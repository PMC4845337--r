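---
title: "From transcriptome to marker panel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From transcriptome to marker panel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SSRpanel)
```

# The problem

Microsatellites (simple sequence repeats, SSRs) remain the workhorse
markers for population-genetic monitoring of non-model species: they are
codominant, highly polymorphic, and cheap to genotype on capillary
instruments. When a species has an assembled transcriptome but no
genomic resources, markers can be mined directly from transcripts
(EST-SSRs, "Type I" loci). SSRpanel implements that workflow end to end:
repeat mining, selection of loci amplifiable by PCR, genotype handling,
and the per-locus statistics used to validate a panel in population
samples — including samples from congeneric species, where marker
transferability is the question of interest.

The package grew around panels of the size typical for such studies:
tens of candidate loci genotyped in population samples of roughly 18-21
individuals per species, dinucleotide-dominated motif spectra, and
fragment-size alleles on a 2-bp ladder.

# Repeat mining

`findSSRs()` reports every maximal perfect tandem repeat with a
*primitive* motif of length 2-10 and at least `minUnits` (default 5)
complete units. Primitivity (the motif is not itself a repetition of a
shorter motif) is what prevents double counting: a region that reads as
(AT)~6~ and as (ATAT)~3~ is one dinucleotide locus, and homopolymer runs
are never reported because AA, AAA, ... are not primitive. Repeats are
located as runs of the self-match relation `s[i] == s[i + m]`, so a
locus starts where the period-*m* run starts and extends over as many
full motif copies as fit; trailing partial units stay in the flank.
Maximality is therefore two-sided: the run cannot be shifted one base
left, and one more full copy fits on neither side.

Only perfect repeats are mined. Mismatch-tolerant ("interrupted")
repeat models add parameters that fragment analysis cannot verify
anyway; an interrupted repeat simply appears as two loci when both runs
reach the unit floor. Ambiguity codes break runs by default
(`nPolicy = "break_run"`), since assembled transcripts occasionally
carry Ns; the alternative `skip_transcript` discards the whole sequence.

Motif naming is normalized by `canonicalMotif()`: the lexicographically
smallest rotation of the motif or its reverse complement, so (GA)~n~,
(AG)~n~, (TC)~n~ and (CT)~n~ are one class.

Coordinates are 1-based closed inside R (`GRanges`, the container the
rest of Bioconductor expects); the TSV writers emit 0-based half-open
`start`/`end`, which keeps the length arithmetic
(`end - start == motifLen * repeatCount`, `leftFlank == start`) exact in
the exported tables.

# PAL selection

A mined repeat is only useful if primers can be placed around it.
`selectPALs()` keeps loci with strictly more than `minFlank` (default
50) bp of flank on *each* side — ">50 bp" is read literally, so 51 bp
qualifies and 50 does not — and at least `minUnitsPAL` (default 8)
repeat units, since longer repeats are likelier to be polymorphic. The
two unit thresholds (5 for mining, 8 for PALs) are kept separate so one
mining pass supports both the full census and the primer-design subset.

"Non-redundant" is implemented as exact duplication of canonical motif
plus both full flanking sequences — the signature of the same genomic
locus assembled into multiple transcripts. Similarity-based collapsing
(isoforms, paralogs at high identity) is deliberately out of scope: any
threshold would be arbitrary without genomic context, and downstream
primer testing catches survivors.

# Genotype data and binning

`GenotypeMatrix` stores diploid fragment-size calls for one population;
pairs are kept sorted and missing calls are `NA`, never the on-disk `0`.
`readGenepop()`/`writeGenepop()` speak the standard Genepop format (2-
or 3-digit coding detected from the data; output always 3-digit), the
lingua franca of the population-genetics tools this workflow feeds.

`binAlleles()` converts raw capillary sizes to integer alleles by gap
clustering: sort the sizes, open a new bin when consecutive sizes are
more than `minGap` apart (default half the repeat unit), and centre each
bin on the rounded mean of its members. This is transparent and
per-locus configurable. It is *not* the published least-squares-offset
binner used by some laboratories; with the 0.15-bp size noise typical of
capillary data it recovers the true ladder essentially always at
realistic sample sizes (tens of individuals). One failure mode is worth
knowing: with thousands of observations at one locus, extreme noise
tails can bridge the inter-allele gap and merge bins, because gap
clustering has no notion of ladder periodicity. The statistical
simulations in the test-suite therefore switch size noise off at
n = 10,000 where the quantity under test is the genotype model, and the
binner is validated at realistic n.

# Per-locus statistics

**Heterozygosities.** `observedHet()` is the heterozygote fraction
h/n. `expectedHet()` defaults to the unbiased small-sample estimator
He = 2n/(2n−1) · (1 − Σp~i~²), the form reported by the standard
diversity packages; the plug-in form is available via
`unbiased = FALSE`.

**Exact HWE test.** `hweExactTest()` computes the probability test on
the conditional distribution of genotype tables given allele counts:

$$P(\text{table}) = \frac{n!\,\prod_i a_i!\,2^h}{(2n)!\,\prod_{i\le j} n_{ij}!}$$

with p-value the total conditional probability of tables no more
probable than the observed one. Tables whose probability ties the
observed within relative 10⁻¹² count in the tail, so exact ties (common
in small discrete tables) are never dropped to round-off. `auto` mode
enumerates all tables (the enumeration doubles as a self-check: the
probabilities must sum to 1, asserted to 10⁻⁹ in the tests) and falls
back to Monte Carlo above `enumTableLimit` tables. Monte Carlo samples
from the same conditional null by randomly pairing the fixed allele
multiset — simpler than a Markov-chain walk over tables, unbiased, and
trivially reproducible under a seed, at the cost of needing more draws
for very small tail probabilities; p is the add-one estimator
(1 + hits)/(reps + 1), which never returns 0. The probability-test
definition (not the heterozygote-deficit U-score) is used because it is
the default exact HWE test in the standard online tools this workflow
replaces.

**Null alleles.** `nullAlleleML()` fits, by EM, the frequency r of a
non-amplifying allele under HWE: visible heterozygotes have probability
2p~i~p~j~, visible homozygotes p~i~² + 2p~i~r, blanks r². By default the
likelihood is conditioned on visibility (divide by 1 − r²) and missing
calls are ignored, because failed PCRs have many causes besides null
homozygosity; `includeMissingAsBlanks = TRUE` switches to the full
model. The E-step splits observed homozygotes into true homozygotes and
null carriers with weight p~i~/(p~i~ + 2r) and, in the conditional fit,
imputes the expected blank count n·r²/(1 − r²) (the standard
truncated-multinomial EM); the M-step re-estimates (p, r) from completed
counts. The observed-data log-likelihood is non-decreasing — asserted on
every fixture. Convergence: log-likelihood gain < 10⁻⁸ or 10,000
iterations. One numerical subtlety: when the data show no homozygote
excess the MLE sits on the boundary r = 0, which EM approaches only at
rate 1/t; the fit therefore ends with an explicit boundary comparison
(the r = 0 profile maximum has p equal to the sample allele frequencies)
and returns exactly 0 when the boundary matches or beats the interior
iterate. The tests verify agreement with a 10⁻³-grid likelihood search
to 2×10⁻³ and recovery of simulated r ∈ {0, 0.1, 0.2} within ±0.05 at
n = 1,000.

**Genotypic disequilibrium.** `genotypicLDTest()` builds the
genotype × genotype table for two loci, takes the log-likelihood-ratio
G, and permutes one locus's genotype column (default 10,000 times) for
the null; p = (1 + #{G\* ≥ G})/(B + 1). A permutation G-test was chosen
over a Markov-chain Fisher exact test: at these permutation counts the
two target the same null (no genotypic association) with the
permutation version being exactly reproducible under a seed. Its size
is verified by simulation: rejection at α = 0.05 stays within
[0.03, 0.07] over 1,000 independent locus pairs.

**Multiple testing.** `bonferroni()` compares each defined p-value to
α/k. With 11 polymorphic loci at α = 0.05 the threshold is 0.00455 —
the correction used when a 16-locus panel is screened for HWE
departures.

# Panel reports

`locusStats()` produces the per-locus table (n, size range, Na, Ho, He,
pHWE, null-allele estimate, P/M/F status); `summarizePanel()` and
`panelReport()` assemble the cross-species view. Panel means and SDs of
Na, Ho and He are computed over polymorphic loci only — including
monomorphic loci would answer a different question (on the worked
16-locus panel it drags mean Na from 5.1 to 3.8). SDs use the n−1
denominator throughout. A locus is "transferable" when it is
successfully genotyped (P or M) in every species other than the source;
that definition reproduces the published count of 13/16 for the worked
panel. Display rounding follows the field's tables: allele counts to 1
decimal place, heterozygosities to 2.

# Synthetic data

`simulateTranscriptome()` emulates the mining input: log-normal
transcript lengths (median 600 bp, floor 300 bp — assemblies are
length-filtered), fixed GC, and SSRs planted at uniform positions with
a dinucleotide-dominated motif spectrum (weights ≈ 82% di-, 16% tri-)
and truncated-geometric unit counts starting at 5. The single subtlety
is the guard bases: the base before a planted repeat is forced to
differ from the motif's last base and the base after it from the
motif's first base, so the period-*m* run cannot silently extend into
the background and the truth coordinates are exactly what a maximal
scanner must report. Recall on planted loci is asserted to be 200/200
at exact coordinates.

`simulateGenotypes()` emulates the genotyping output: per locus, two
gametes drawn from the augmented frequency vector (visible alleles plus
null), with the second copying the first with probability F — giving
P(A~i~A~i~) = p~i~² + F·p~i~(1 − p~i~), the inbreeding/Wahlund model.
Null/null genotypes are missing; null/visible appear homozygous.
Gaussian size noise (default SD 0.15 bp) is added and the sizes pass
through `binAlleles()`, the same path real data takes. Defaults mirror
the study conditions the package targets: samples of ~21 individuals,
2-bp ladders, no extra dropout. The generator draws gametes from
exactly the model the null-allele estimator assumes; size-dependent
dropout, stutter, and allelic dropout from low template are *not*
simulated, so passing tests certify the estimators under their own
model, not robustness to those artefacts. All randomness flows from one
top-level seed through named substreams, so the transcriptome and
genotype stages can be regenerated independently.

# Problem sizes and runtime choices

The validation suite uses: 10,000 random sequences (20-500 bp, reduced
alphabets to raise repeat density) for miner/oracle equivalence; 2,000
samples at n = 21 for exact-test calibration; 1,000 locus pairs × 1,000
permutations for LD test size; n = 1,000 × 9 runs for null-allele
recovery. These sizes put the Monte Carlo error of each estimated rate
well inside the asserted bands while keeping the whole suite in a few
minutes on one core.

# Known limitations

* Compound and interrupted SSRs are reported as separate perfect runs,
  not annotated as compounds.
* The binner ignores ladder periodicity (see above); per-locus `minGap`
  is the control knob.
* Redundancy removal is exact-match only.
* No primer design, multiplex grouping, or raw trace calling: the
  package starts at sequences and at called fragment sizes.
* Population-level F-statistics and differentiation measures are out of
  scope; the per-species panel characterization is the deliverable.
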