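---
title: "Methods: divergence, gene flow and demographic history from small genome panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence, gene flow and demographic history from small genome panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ChelonScan reconstructs divergence, ancient gene flow and effective
population size histories from a small panel of whole genomes — one diploid
individual per species — the sampling design typical of sea turtle genomics,
where five globally distributed species (olive ridley OL, loggerhead LL,
hawksbill HH, green GG, and the leatherback DC as outgroup) are known to
hybridize. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where a published procedure left
the details open. All numerical results quoted here are the ones the test
suite and `scripts/acceptance.R` compute; none are imported from elsewhere.

## The synthetic-genome generator

Every stage of the pipeline is validated on genomes simulated under known
isolation-with-migration (IM) demographies, so the truth behind every
statistic is available. A `DemographicModel` records populations with
diploid sizes, population splits (times in generations before present),
stepwise size changes, continuous migration epochs, admixture pulses, and
mutation/recombination rates. The coalescent-with-recombination engine
behind `simulateGenotypes()` is msprime, driven through a bundled script;
the package owns scenario construction, validation (e.g. a migration epoch
may not outlive the merge of its two populations), VCF 4.2 / BED emission,
truth records, and bit-exact seeded determinism. Mutations follow an HKY
model with kappa = 4.3, which yields a whole-genome Ts/Tv near 2.15, the
value typical of vertebrate resequencing panels; only biallelic sites
polarizable against the ancestral state are emitted, with REF = ancestral.

The mito surrogate is a single haploid, non-recombining locus (default 16
kb) with every population size scaled by 1/4 (haploid, uniparental) and
migration applied by default — so mitochondrial capture is possible — with a
flag to disable it for scenarios of nuclear gene flow without mtDNA
introgression.

The default truth model (`defaultTurtleModel()`) uses the five-species
topology with nuclear strict-clock split ages (15.5, 18.3, 40.5, 76.5 Ma),
a 24-year generation time, mutation rate 7.9e-9 per site per generation,
recombination 1e-8, extant sizes of 5e4 and ancestral sizes of 1.1–2e5,
matching the pre-divergence plateaus read from pseudo-F1 trajectories.
Replicate-heavy calibration suites use a scaled variant
(`time_scale = 0.25`, `anc_scale = 0.25`, `ne = 25000`, `r = 4e-9`): the
same topology and relative node depths with a quarter of the coalescent
depth, cheap enough that dozens of replicates run in seconds while leaving
the linkage scale (1/(4 Ne r) about 2.5 kb) far below the 0.5–1 Mb jackknife
blocks. What the generator does **not** emulate: read-level errors, mapping
bias, genotype-calling noise, selection, or continuous population structure
— passing tests therefore demonstrate statistical correctness of the
estimators, not robustness to upstream bioinformatic artifacts.

## Variant filtering

`applyFilterChain()` reproduces a GATK-style hard-filter chain: drop any
record that is not a biallelic SNP, or has QUAL < 60, FS > 60, QD < 2,
MQ < 40, MQRankSum < -20, or ReadPosRankSum < -8, plus removal of SNPs
within 5 bp of an indel with QUAL > 60. Three deliberate readings:

* An absent INFO annotation never fires its criterion, because upstream
  callers emit rank-sum annotations only at heterozygous sites; firing on
  absence would discard every homozygous record.
* The MQRankSum cut of -20 is kept as stated even though -12.5 is the more
  common convention; it is a configurable threshold.
* "Within ±4x of average coverage" is ambiguous; `coverageFilter()` adopts
  the log-symmetric reading (exclude depth > 4·mean or < mean/4), with both
  bounds independently configurable.

Masks are 0-based half-open BED intervals; VCF positions are 1-based. The
chain annotates a FILTER string rather than deleting records, and the kept
set is independent of the order the criteria are applied in.

## Windowed diversity and distance dating

Heterozygosity is counted per 100-kb window at sites with depth >= 5 and
reported both per window length (the headline, matching the convention of
dividing by window size) and per callable bp, which corrects for mask gaps
and flagged partial trailing windows. The IBS distance matrix reduces each
sample to its consensus allele per site (heterozygote ties broken by a
seeded coin) and counts disagreement fractions. Generation time is age at
maturity plus half the reproductive longevity.

The dating surrogate is deliberately simple: mean cross-population
mismatch fractions per bp, Jukes–Cantor corrected, fed to UPGMA, with all
node heights rescaled linearly so one calibration node takes a fixed age —
a distance-based strict clock. It exists to test *directional* claims
(e.g. nuclear versus mitochondrial dates) on synthetic data, not to replace
Bayesian dating; no posterior intervals are produced, and the calibration
refuses to proceed if the calibration taxa are not recovered as a clade.

## Patterson's D

For an arrangement (((P1,P2),P3),O), printed on every result to avoid label
ambiguity, one haplotype per diploid is drawn per site (seeded); drawing
the *haplotype* rather than the allele value makes the statistic exactly
invariant to REF/ALT relabelling. A site is ABBA if P2 and P3 carry the
derived allele (defined against the outgroup draw) and P1 the ancestral,
BABA with P1 and P2 exchanged; D = (nABBA - nBABA)/(nABBA + nBABA), with
D > 0 meaning excess P2–P3 sharing. An allele-frequency-weighted mode is
available as an option.

Standard errors come from a weighted delete-one jackknife over physical
blocks (default 5 Mb; the calibration suites use 0.5–1 Mb blocks on their
smaller genomes), blocks weighted by informative-site counts, pseudovalue
variance per Busing's formulation, and Z = D/SE with |Z| > 3 flagged.
`dstatScan()` enumerates every trio whose (P1,P2) is a cherry or nested
pair relative to P3 on the species tree — for the five-species tree this
gives exactly the four classical trios. Under this rule a three-taxon
pectinate ingroup admits a single consistent trio.

## Topology weighting

All rooted binary topologies of the ingroup ((2k-3)!! of them; 15 for four
taxa) are enumerated in a canonical form (leaf sets sorted at every node).
Sites private to the outgroup are removed, the genome is cut into
non-overlapping 50-SNP windows (terminal windows kept at >= 45 SNPs,
midpoint = mean of first and last SNP positions), and a neighbor-joining
tree is built per window from Jukes–Cantor-corrected mismatch fractions
(clamped just below the p = 3/4 saturation point; ties broken by sorted
label order). NJ replaces maximum likelihood here because at 50 SNPs and
ten haplotypes the two nearly always agree on topology and NJ is
deterministic and orders of magnitude faster; a hook accepts externally
computed trees per window for exact parity with other tools.

Weighting is exact ("complete"): every combination of one haplotype per
species (2^5 = 32 for five diploid species) is pruned out, rooted with the
outgroup haplotype, matched against the catalog, and counted. Smoothing is
a tricube-weighted local *linear* fit with a fixed physical span of 1 Mb
(points within span/2 enter each fit), clipped to [0,1] and renormalized
across topologies at every evaluation point.

The suite checks the classic coalescent closed form: with a three-species
ingroup whose internal branch is t coalescent units, the concordant
topology's expected weight is 1 - (2/3)exp(-t). The calibration uses 5,200
independent 50-kb non-recombining loci (one 50-SNP window per locus, so
each window samples one genealogy and locus-length selection bias cannot
creep in) and matches the closed form within 0.01 at t = 1.

## The coalescent HMM

The demographic engine is a PSMC'-style hidden Markov model on one
haplotype pair: the hidden state is the atomic time interval containing the
local TMRCA on a log-spaced grid T_j = 0.1(exp(j/n·log(1+10·t_max))-1),
j = 0..n-1, with the final interval open-ended; per-interval coalescence
intensities lambda are tied into parameter groups by the atomic-interval
pattern (default "4+25*2+4+6": 64 intervals, 28 groups). Emissions are
P(het) = 1 - exp(-theta·t̄_j), with t̄_j the conditional mean TMRCA of the
interval under the current intensities; bins with more than half their
bases outside the callable mask are missing and emit probability one.
Transitions follow the SMC' picture: no recombination with probability
exp(-rho·t), otherwise a uniform recombination height, re-coalescence at
rate 2·lambda(s) below the old TMRCA (half restoring it), and single-lineage
coalescence above; all integrals are closed-form per grid piece and
expressed in cumulative-hazard differences so nothing overflows. Rows of
the transition matrix are renormalized defensively (drift is below 1e-10).

Fitting is EM: a scaled forward–backward pass (compiled) accumulates
expected transitions and emissions; the M-step maximizes the expected
complete-data log-likelihood over log-intensities and log-theta with
L-BFGS-B, making each iteration a generalized EM step — the observed
log-likelihood is non-decreasing, which the tests assert, and a tiny
instance is checked against exhaustive hidden-path enumeration. theta is
re-estimated every iteration; rho is fixed after initialization (set it to
theta by default, or to theta·r/mu via `rho_ratio` when the
recombination-to-mutation ratio is known — on simulated data the informed
setting visibly improves old-time intensity estimates). Scaling: N0 =
theta/(4·mu·bin_size), time_years = t·2·N0·generation time, Ne = N0/lambda.
Bin size defaults to 100 bp within species and 10 bp for pseudo-F1 runs,
where between-species divergence would saturate wider bins. Confidence
envelopes come from resampling fixed-length segments (default 5 Mb) with
replacement to the original length, 20 replicates.

Test problem sizes (the package's own desk-scale choices): constant-Ne
recovery uses 50 Mb at Ne = 20000 with a 10-group pattern, recovering Ne
within 6% across intervals covering 0.2–2 coalescent units; the bottleneck
check uses a 10-fold drop over 10–30 kgen on 50 Mb with single-interval
groups ("14*1", t_max 8), recovering the dip within a factor two at the
right epoch. Sharper bottlenecks (a few tenths of a coalescent unit wide)
are smoothed by the discretization and recovered only partially — a known
property of this model class.

## hPSMC: dating the end of gene flow

Each genome is collapsed to a pseudo-haploid (one random allele per site;
sites under depth 5 or quality 30 become missing), two species'
pseudo-haploids are interleaved into an artificial F1 whose heterozygous
positions are exactly their differences, and the F1 track is fitted with
the same HMM at 10-bp bins. Because the two genomes cannot coalesce more
recently than the last gene flow, the apparent Ne explodes toward the
present; the position of that wall dates the *cessation of gene flow*, not
the split.

The pre-divergence plateau is read by rule rather than by eye: excluding
the two oldest intervals (the open-ended tail and its weakly constrained
neighbour), the rise onset is the oldest interval reaching 1.5x the
geometric mean of the three oldest remaining intervals, and the plateau is
the geometric mean of everything older; a curve rising strictly across all
intervals has no plateau and errors. A manual override is available.

Bracketing compares the empirical curve against clean-split simulations on
a 1-Myr grid that reuse the fitted plateau Ne and the pair's mean
generation time. The comparison window is the contiguous exponential-rise
region — from the foot of the Ne wall (last time above 10x plateau) to the
plateau entry (first time below 1.5x) — evaluated on a dense log-spaced
time grid; restricting to the contiguous rise matters because late-time
estimator drift can push old intervals back above the lower band edge and
would otherwise dilute the comparison. A grid curve is "older" if it
exceeds the empirical curve at 90% of window points, "younger" if below at
90%; the bracket is (largest younger T, smallest older T), with unbounded
ends flagged, and the ordering of grid curves across T is recorded. With
ties (an empirical curve identical to a grid member) neither call fires
and the bracket collapses to the member's neighbours.

Desk-scale validation: ten seeded clean splits at 12 Ma (ancestral Ne 1e5,
4 Mb genomes) bracketed against a 10–15 Ma grid recover the truth in 9/10
seeds. The gene-flow scenario is built as speciation with gene flow: the
ancestral population (1e5) splits at 12 Ma into two connected halves (5e4
each) exchanging about ten lineage migrants per generation until 6 Ma —
this construction keeps the combined size during the connected phase equal
to the ancestral size, so the last-coalescence wall tracks the cessation
time. (Giving each daughter the full ancestral size instead doubles the
effective size of the connected phase and pushes the wall several Myr past
the true cessation — a property of the coalescent, not an estimator
defect.) The bracket midpoint lands at 5 Ma, far closer to the 6 Ma
cessation than to the 12 Ma split. Default TMRCA caps follow the
species-pair conventions (15 coalescent units for HH/LL, 5 for GG/HH, 10
otherwise).

## Mito/nuclear discordance

Under divergence-with-gene-flow and an uncaptured mitochondrion, nuclear
dates should fall below mitochondrial dates: recombining nuclear loci
average over many recent (migrant) coalescences while the single
non-recombining mito locus coalesces no more recently than the split. The
test scenario — split at 250 kgen with migration (5e-5) until 50 kgen, a
calibration outgroup at 1.5 Mgen, 5 Mb of nuclear sequence against a 16-kb
mito locus, root calibrated at its true age — shows the nuclear (A,B) age
below the mito age in 20/20 replicates (about 3.1 vs 4.4–7.0 Ma).

## Pipeline and reproducibility

`runPipeline()` drives simulate → filter → diversity → dstat → topoweight
→ smc → hpsmc → dating from one validated config (YAML or list) with a
single global seed from which every stage derives its own; outputs carry
the package version, seed and a parameter digest, and rerunning a config
reproduces the key tables byte for byte. A thin command-line wrapper with
stage subcommands ships in `inst/scripts/chelonscan.R`; the exported
functions are the primary interface.

## Limitations

* One diploid per species: no within-species allele frequencies, so D uses
  single-draw counting and no f-statistics beyond D are attempted.
* The HMM discretization smooths sharp demographic features; recent-time
  intervals of pseudo-F1 fits are unconstrained (no coalescence there) and
  the two oldest intervals absorb truncation effects — both ends are
  excluded from quantitative reads.
* The distance-based dating surrogate has no substitution-model flexibility
  beyond Jukes–Cantor and no uncertainty quantification.
* Exon/intron partitioning of diversity and annotation-dependent analyses
  are out of scope; masks are consumed, never constructed from mappability.
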