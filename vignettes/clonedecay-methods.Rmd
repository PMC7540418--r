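---
title: "Methods: inference of mutation accumulation in clonal hybrid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inference of mutation accumulation in clonal hybrid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonedecay)
```

## The inference problem

Sexual–asexual complexes put sexual species and their clonal hybrid
derivatives into the same arena for mutation, selection and drift. If
purifying selection is substantially relaxed in non-recombining genomes,
three signatures should accumulate with clone age: an excess of
nonsynonymous (and premature-stop) changes among the mutations private to
clones, more radical amino-acid replacements, and dN/dS ratios drifting
towards 1. clonedecay implements the data model and the statistics needed
to test these predictions on exome-style SNP data from a three-species
complex (ingroup species E, T, N; outgroup L) with diploid and triploid
gynogenetic clones, and ships a forward-time generator so every estimator
can be validated against planted truth.

## SNP classification model

Classification operates exclusively on the sexual species; hybrid genotypes
never influence the first two categories:

* **intraspecific** — at least one sexual species is polymorphic at the
  site;
* **interspecific fixed** — every species monomorphic, at least one pair
  differing; in a hybrid these sites are *diagnostic*: an intact hybrid must
  be heterozygous there;
* **private asexual** — all sexual species share one allele and at least one
  hybrid carries the other; under clonal reproduction these are post-origin
  mutations;
* **unclassified** — anything else, including sites where a species has no
  called individual (monomorphism is never guessed from zero calls) and
  sites variable only in the outgroup.

Upstream filters: biallelism across all samples; a called fraction of at
least 0.8 (inclusive), computed over the ingroup by default — whether the
outgroup should count towards the 80% rule is genuinely open, so it is a
flag (`include_outgroup`), defaulting to exclusion since the single
outgroup individual carries no information about ingroup call quality.
Contigs where the *same* site is heterozygous in every ingroup species and
the outgroup are flagged as collapsed paralogs and dropped: real shared
polymorphism across distantly related species plus the outgroup is far less
likely than mapping artefact.

Codons containing two or more variable positions cannot be translated
without phase, so all their sites are masked (`synonymity = "masked"`) and
excluded downstream; after masking the package *asserts* that every
analysed codon carries exactly one variable site, which is what makes all
later translation phase-free. Synonymity compares the translations of the
two observed alleles in reference context; an allele creating a stop in a
non-final sense codon is a premature `stop_gain`. A stop arising in the
final sense codon merely shortens the protein by one residue and is counted
nonsynonymous — a deterministic tie-break for a case the simulator never
generates. Stop-gains are *included* in the nonsynonymous class for N/S
ratios and spectra (they are nonsynonymous changes), and also tallied
separately for the stop-incidence analysis.

Polarisation assigns the ancestral state from a sister-taxon map: T and N
polarise each other; E requires the consensus of T and N; whenever the
primary sister is polymorphic or uncalled the outgroup is the fallback.
Sites that still fail stay unpolarised and are excluded from frequency
spectra (with a reported count) rather than guessed.

## Codon metrics

The dN/dS core is the Nei–Gojobori (1986) evolutionary-pathway method.
Synonymous site counts per codon average the synonymous fraction of
one-step changes per position, with changes *to stop codons excluded from
numerator and denominator*; pathway counts between codons differing at k
positions average the synonymous/nonsynonymous step counts over the k!
orderings, excluding pathways that pass through a stop codon, and falling
back to the all-pathways average when every ordering is blocked (possible
only for a handful of codon pairs). These conventions are the classic NG86
practice; the package pins them down with an exhaustive test against an
independent brute-force enumerator over all 61 × 61 sense-codon pairs, plus
the invariant Nd + Sd = positional Hamming distance.

Proportions are corrected with Jukes–Cantor, d = −(3/4)·ln(1 − 4p/3), which
errors (rather than returns NaN) at saturation p ≥ 3/4. Because many gene
pairs differ in only one class of sites, a constant c = 0.01 is added to
both dN and dS before the ratio; identical sequences therefore give a ratio
of exactly 1. Only ORFs with at least 50 intact codons (unmasked, no
missing call in any individual; inclusive threshold) enter, keeping
per-gene estimates from being dominated by a handful of codons. One
subtlety: the spec of the filter is "fully resolved in all individuals";
sites removed by the 80%-call filter are no longer visible at this stage,
so resolution is assessed on retained sites — with the noiseless generator
the two readings coincide.

Hybrids are *not* compared as pairs of phased haplotypes (phase is
unknown). Two modes are provided:

* **within-individual** (default for hybrids): each codon where the
  individual carries ≥ 2 distinct alleles contributes the two distinct
  variants; a triploid with alleles {A, A, G} counts once — genotype calls
  carry no reliable dosage. For an F1 this is *exactly* the
  parental-haplotype pairwise estimate, which the tests assert bitwise (the
  NG86 site sums are averaged per codon precisely so that this identity is
  order-stable in floating point).
* **between-individual**: heterozygous calls are collapsed by seeded
  pseudo-haplotype sampling (one allele drawn per site from the call
  multiset). This is the route used for the simulated-hybrid null — all
  cross-species pairs of sexual individuals, which carry the frozen
  interspecific divergence but no post-origin asexual process. A
  "disjoint-allele-sets" alternative was considered and dropped: it
  discards most informative codons in highly heterozygous hybrids and has
  no counterpart in how the null pairs are formed.

Radicality of an amino-acid replacement is the canonical PAM100 or BLOSUM90
entry for the pair (bundled verbatim, parsed at load; lower = more
radical). The matrices are symmetric, so unpolarised replacements are
scored too; stop-gains are excluded from radicality and analysed as their
own class. mtDNA clone age is the Kimura two-parameter distance to the
nearest sexual haplotype, with transitions and transversions separated and
a saturation error when a logarithm argument becomes non-positive.

## LOH and spectra

LOH is called at diagnostic sites only: homozygosity in a diploid hybrid,
and the conservative all-alleles-from-one-parent rule in triploids, where
partial losses are not identifiable from unphased calls. The quadratic
model of LOH proportion against private-SNP proportion is fitted twice:
unconstrained OLS g(x), and f(x) with the quadratic coefficient forced
non-negative. With a single inequality constraint the solution is either
the free fit (when its quadratic coefficient is already ≥ 0) or the
boundary a₂ = 0, i.e. the best-fitting line — so the constrained solver is
exact, and constrained RSS ≥ unconstrained RSS always. The fit is
restricted to diploids, where LOH detection is unambiguous.

The private-SNP proportion uses a per-sample denominator (sites called in
that sample); a cohort-wide denominator is a configuration away and changes
nothing qualitative on noiseless data. Site-frequency spectra count derived
copies over called chromosomes per stratum (synonymous vs nonsynonymous);
clone-sharing spectra count the members of a clone carrying a private SNP,
which under the trunk/tip generator is bimodal at k = 1 and k = clone size.

## Group statistics

The original analyses lean on mixed models; their exact random-effect
structures live in unavailable supplementary code. The package instead (a)
aggregates counts to the nesting unit before a binomial likelihood-ratio
test, and (b) offers cluster permutation (labels permuted at the
clone/female level), which preserves the dependence the random effects
addressed without re-implementing REML. The permutation p-value uses the
add-one correction p = (1 + #{perm ≥ obs})/(1 + n_perm) and never returns
0; inputs are canonically reordered first so p-values are invariant to row
order. The zero-inflated survival comparison is simplified to a cluster
permutation on per-clutch survival proportions. Calibration of the
binomial LRT, the permutation KS test and the F test is asserted at
5% ± 2% over 1,000 null replicates each.

## The generator: what it emulates, and what it does not

Defaults are chosen once to mirror the studied complex at desk scale: 200
ORFs × 60 codons (36,000 coding sites); ingroup panel E = 8, T = 10, N = 4
diploid individuals plus one L outgroup; fixed interspecific divergence
d_fix = 0.005 per coding site per species pair (placed as independent
per-branch substitutions at d_fix/2; the outgroup branch runs at 2×), with
a nonsynonymous fraction of 0.30 — between-species differences have passed
through selection; segregating polymorphism θ = 0.003 per site with
nonsynonymous fraction 0.55 and a selection shift a = 1 (derived-allele
counts i weighted i^(−1−a) for nonsynonymous, neutral 1/i for synonymous) —
within-species variation is enriched for rare, mildly deleterious variants.
Clones: F1 (τ = 0), Holocene-aged EET/ETT (τ = 10⁴), and ~300 ky EEN/EN
(τ = 3 × 10⁵ generations), with μ = 10⁻⁸ private mutations per site per
generation, nonsynonymous fraction 0.55 with 5% stop-gains, a 0.5
trunk/tip split (the within-clone pedigree is not knowable from the data;
0.5 gives the sharing spectra structure), and λ = 3.5 × 10⁻⁷ per-site LOH
per generation so the oldest clones resolve ≈ 10% of diagnostic sites.
mtDNA: 2 kb locus, 5 × 10⁻⁸ substitutions/site/generation, 2% per-branch
species divergence.

Simplifications to keep in mind when reading passing tests: no genotyping
error or missing data (so classification recovery is exact by design — the
tests validate logic, not robustness to noise); each variant occupies its
own site (codon collisions between *different* sites are allowed after a
bounded retry, feeding the masking logic); LOH is per-site independent
with no tract structure, since only per-site proportions are analysed;
private sites experience the same 1 − exp(−λτ) LOH probability as
diagnostic sites although a mutation arises partway through the clone's
life — the truth ledger records the realised events, and recovery tests
compare against those, so the simplification is self-consistent; sexual
species have no recombination or demography, only a frequency spectrum;
the outgroup is a divergence donor and fallback polariser, nothing more.
Phenotypes are lognormal around allometric expectations for a ~90 mm loach
female with seasonal gonad cycling; the default effects encode the study
conditions (no condition-index differences between clone ages, higher
gonadosomatic index and fecundity in the old lineage, a seasonal flip in
oocyte-size structure).

## Numerical and design choices

* Coordinates are 0-based half-open internally and in BED; the VCF writer
  emits 1-based positions with ploidy-aware GT (2 or 3 alleles). Genotypes
  are unphased allele multisets, stored canonically sorted, so a
  write–read round trip is bit-identical.
* Allele order never matters: synonymity is symmetric in the two observed
  alleles, radicality lookups are symmetric, and the within-individual
  dN/dS is invariant (bitwise) to which variant lands in which pseudo
  sequence.
* `runFull()` reports are pure functions of inputs + seed: no timestamps,
  full-precision JSON, so byte-identical reruns are a regression test.
* Seeds: one integer governs everything; internal stage seeds are derived
  by small offsets after reduction modulo 9 × 10⁸ to stay within R's
  32-bit integer range.
* Test problem sizes were chosen to keep the whole suite in minutes on one
  CPU: the exhaustive NG86 oracle runs all 3,721 codon pairs; recovery
  tests use 20 replicate clones per age class at 36,000 coding sites;
  calibration runs use 1,000 null replicates (400 for the
  selection-signal type-I check, where each replicate is a full
  simulate–classify–test cycle and 50 replicates would leave the
  Monte-Carlo error wider than the acceptance band itself).

## Known limitations

Genotype dosage in triploids is ignored throughout (calls are treated as
allele sets); the classifier cannot separate gene conversion from
hemizygous deletion (neither can the per-site LOH data); the binomial
LRT/permutation layer approximates, not reproduces, mixed-model inference;
and the generator's noiseless calls mean sequencing-error robustness is
untested by design. The mitochondrial relaxed-selection test of the
original workflow is external software and out of scope here; mtDNA enters
only through K2P clone ages.
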