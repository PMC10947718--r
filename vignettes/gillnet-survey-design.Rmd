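---
title: "Evaluating and redesigning multi-mesh gillnet surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and redesigning multi-mesh gillnet surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gillnetTools)
```

## The problem

Fish are a mandatory biotic quality element for the ecological assessment
of European lakes, and the standard sampling gear is the benthic and
pelagic multi-mesh gillnet (DIN EN 14757): twelve geometrically spaced
mesh sizes from 5 to 55 mm, each a 2.5 m panel, set overnight. In large,
deep lakes the protocol's net numbers become prohibitively expensive and
kill large numbers of fish, most of them small individuals of abundant
species that add little information. Two remedies suggest themselves:
a modified net (here called MOD) that halves the small-mesh panels,
drops the 5 and 55 mm meshes and enlarges the rarely saturated large-mesh
panels; and a redesigned stratified campaign that deploys only as many
nets per depth stratum as the survey's stated precision and
species-detection goals actually require.

Both remedies need a quantitative toolkit: catches must be standardized
across heterogeneous panel geometries before designs can be compared;
"the new net catches the same" is an equivalence claim, not a difference
claim; community composition must be compared with permutation
statistics that tolerate semimetric dissimilarities; and the required net
numbers come from species accumulation curves and
coefficient-of-variation precision targets. This package implements that
toolkit, together with a seeded catch simulator so every stage is
testable without field data.

## Catch standardization

The unit of observation is one mesh panel of one deployed net on one
night. With `count` fish caught in a panel of `area` square metres, the
standardized catch is

    NPUE = count * 100 / area

fish per 100 m² of netting, and a net's total NPUE is the sum over its
panels (BPUE is the same with grams of wet weight). Because MOD panels
differ in area mesh by mesh (half the standard area at 6.25--12.5 mm,
twice at 29 mm, four times at 35 mm, eight times at 43 mm), the
standardization makes per-mesh catch rates directly comparable across
designs. Comparisons between the designs are restricted to the meshes
both carry; the 5 and 55 mm panels exist only in the standard net and
would otherwise bias totals.

Mesh sizes are stored as exact decimal strings (`"6.25"`, `"12.5"`),
never floating point, so panel lookups cannot fail by rounding. Catch
tables are sparse: an absent (net, mesh, species) row means zero catch,
which matters in data where one net holds a mass catch and its neighbour
nothing. Nets with no catch records still yield all-zero rows in the
nets-by-species `CatchMatrix`, because a zero catch is an observation,
not missing data.

Two transforms are carried through the analyses: `log1p` (log(x+1)) for
similarity and precision work, and `log0p1` (log(x+0.1)) for users who
need the harsher zero-handling some mixed-model analyses use. The
transform applied is recorded once, in the matrix object itself.

## Design equivalence: TOST

Whether MOD catches "the same" as the standard net is tested with two
one-sided tests (TOST): equivalence is accepted when the 90% confidence
interval of the difference MOD − CEN lies inside the equivalence bounds
(−Δ, +Δ). Tests are unpaired Welch t tests: although nets were set in
pairs, patchy catches (zero in one net, hundreds in its partner) make
the pair differences far noisier than the group contrast, so unpaired
comparison is the more robust choice.

The bounds needed a design decision. The natural reading of "±50% of the
mean difference" makes the bound shrink with the observed effect: a tiny
observed difference then declares equivalence against a tiny bound,
which is circular. We therefore default to anchoring the bound at a
fraction of the *grand mean* of the metric over both designs
(`boundsMode = "fraction_of_grand_mean"`), which fixes the smallest
effect size of interest on the scale of the data; the literal
mean-difference construction remains available
(`"fraction_of_mean_difference"`, using |mean difference|) for
comparability, and explicit bounds can always be passed. Reported with
each test are the achieved power at the realized sample sizes (computed
at a true difference of zero) and the smallest per-group n reaching 80%
power, from the standard noncentral-t expression for TOST power

    power = F_t(-t_{1-a,df}; (d - U)/se) - F_t(t_{1-a,df}; (d + L)/se)

with se = sd·sqrt(2/n) and df = 2(n−1), truncated at zero. The
expression is the usual large-sample approximation (it treats the two
rejection events through the same noncentral t); the test suite checks
it against a 20,000-replicate Monte-Carlo rejection rate and requires
agreement within 0.02. Required-n is found by doubling and integer
bisection, which is safe because power is monotone in n.

One boundary case is worth knowing: two *identical* samples have zero
mean difference but a nonzero confidence interval, so they are declared
equivalent only when the bounds exceed the CI half-width. That is the
CI rule working as intended, not a defect.

Reduction summaries (percent fewer fish, percent lower NPUE, percent
less catch-handling labour) are simple ratios over the replicate pairs,
with the shared-mesh restriction applied by default and percentages
rounded half-away-from-zero when printed as integers. The labour model
weights each fish by a per-mesh handling time (default uniform), since
only disentanglement and documentation scale with catch; setting and
lifting nets do not depend on the net type.

## Community statistics

Catch composition is compared on Bray--Curtis dissimilarities of
log(x+1)-transformed NPUE with a dummy species of constant value 1
appended to every net. The dummy keeps the coefficient defined for
empty nets (two empty nets are identical, dissimilarity 0) and damps
the instability of near-empty ones. These permutation statistics are
implemented in the package rather than delegated, because the exact
conventions (dummy handling, tie ranks, p-value form, centroid scheme)
are the substance being tested; vegan serves as an independent
cross-check in the test suite, not as the implementation.

ANOSIM ranks all pairwise dissimilarities (mid-ranks for ties) and
contrasts between-group and within-group mean ranks,
R = (r̄_between − r̄_within)/(M/2) with M the number of pairs, so R is
invariant under monotone transformation of the dissimilarities. PERMDISP
tests homogeneity of dispersion: samples are embedded by
principal-coordinate analysis (Gower double-centering of −d²/2), axes
with positive and negative eigenvalues are kept separately, and the
distance of a sample to its group centroid uses the semimetric
correction z² = max(0, d²_real − d²_imag). The test statistic is the
one-way ANOVA F on the z values.

Permutation conventions, fixed across both tests:

* p = (b + 1)/(m + 1), where b counts permuted statistics at or above
  the observed one -- the unbiased estimate, with floor 1/(m+1) (999
  permutations give a minimum printable p of 0.001);
* group labels are permuted and, for PERMDISP, centroids and distances
  are recomputed in each permutation (the embedding itself is fixed);
  published PERMDISP implementations do not document their internal
  scheme, so small numerical differences from them are possible;
* groups below a minimum size (default 3) are dropped from PERMDISP
  with a warning, mirroring the exclusion of thinly replicated strata;
* every stochastic operation takes an explicit seed;
* eigenvalues below 1e-10 of the largest magnitude are treated as zero.

The test suite verifies the ANOSIM p against exhaustive enumeration of
all 20 label splits of a 6-sample problem, the PERMDISP distances
against direct centroid geometry and against `vegan::betadisper`, and
the PERMDISP type-I error over 500 equal-dispersion simulations
(the rejection rate at α = 0.05 must fall in [0.03, 0.07]).

## Species accumulation and the detection criterion

For N nets and species occurrence frequencies f_s, the exact
(sample-based rarefaction) expected richness after n nets is

    E[S(n)] = sum_s [ 1 - C(N - f_s, n) / C(N, n) ]

computed with log-space binomial coefficients; its standard deviation
uses the pairwise joint inclusion probabilities. A permutation variant
averages over random net orderings and supplies quantiles.

The design criterion "detect 90% of the observed species with 50%
probability" is not formally defined by a mean curve, so we
operationalize it on the permutation distribution: for each random
ordering, record the first n at which the accumulated species count
reaches ceiling(0.9 · S_obs); the answer is the 50% quantile of these
thresholds (10,000 orderings by default, seed mandatory). A
curve-crossing alternative -- the smallest n whose *expected* richness
reaches the target -- is available behind `method = "expected"`; we
default to the quantile form because "with a probability of 50%" is a
statement about the distribution, not its mean. When the requested
probability sits exactly on an atom of the discrete threshold
distribution (as in tiny textbook examples), the Monte-Carlo quantile
can land on either side of the atom; the tests account for this.

## Precision and prospective net numbers

Precision follows the monitoring standard: per-net NPUE values are
log(x+1)-transformed and CV = SE/mean with SE = SD/√n. The standard
requires CV ≤ 0.1 for dominant species -- those holding at least 30% of
a zone's NPUE (inclusive boundary). Net numbers to reach a target CV
come from the Pringle formula

    n = SD² / (mean² · CV²)

and, as an alternative, from an ordinary two-sample t-test sample size
for detecting a 50% difference in mean NPUE at power 0.8 and α = 0.05
(delegated to `stats::power.t.test`; the standardized effect is
0.5·mean/sd). When a fish community spans several depth strata, the
community's net number is split across strata in proportion to stratum
volume, fractions preserved.

Rounding is deliberately two-faced because survey reports are: a
standalone Pringle quote truncates (157.86 nets is quoted as 157),
while per-stratum minima take the ceiling of the larger of the species
and precision requirements -- the ceiling is applied exactly once, at
the stratum level. In strata whose fish density is too low for any
reasonable effort to estimate abundance (a judgment call, so an
explicit per-stratum `feasible` flag, not a formula), the precision
requirement is waived and the species requirement alone is ceiled. The
design report totals the per-stratum minima per basin and states the
percent reduction against a baseline net count supplied as
configuration (the standard protocol's morphology-based number, which
this package deliberately does not re-derive).

## The catch simulator

The raw per-net data of the motivating campaign are not public, so the
package carries a generator whose defaults encode the campaign's
structure: the `lake_constance_like` template reproduces the deployment
layout (310 benthic and 98 pelagic nets in the upper basin, 76 and 23
in the lower, with 81/26/20/9 paired CEN/MOD replicates per
basin-and-zone), a 25-species pool with one strongly dominant benthic
species (density share 0.8, perch-like) and one dominant pelagic
species (share 0.85, stickleback-like), and densities decaying
exponentially with stratum depth. A `minimal` template (2 strata × 2
designs × 3 nets, 3 species) keeps unit tests fast.

Counts are negative binomial, independent across panels and species:
for species s in a panel of area A,

    mu = density(s, basin.zone.stratum) · selectivity(s, mesh) · A/100

with per-species dispersion k (default 0.3, variance mu + mu²/k). The
small k reproduces the zero-catch/mass-catch patchiness that motivates
unpaired tests; k was chosen as a plausible order of magnitude, not
fitted -- no quantitative dispersion estimate exists to calibrate
against. Paired nets share a site-level log-normal effect (mean 1,
σ = 0.4 by default) so paired designs are testable. Mesh selectivity
vectors are normalized weights concentrated on the small meshes, as in
small-fish-dominated pre-alpine lakes. Biomass fills its column via a
mesh-proportional log-normal length and a cubic length-weight law with
textbook defaults; it is plumbing for BPUE code paths, not biology.
Total surface densities (1000 fish per 100 m² benthic, 30 pelagic in
the large template) were set once to give per-net catches of realistic
magnitude, with volumes as smooth relative weights, since hypsographic
volumes are not published.

Seeding: one master seed is recorded in the config; each net and each
site draws from a substream derived by hashing its identifier with the
master seed, so enlarging a deployment block leaves every existing
net's catch bit-identical. The same config therefore always produces
byte-identical CSV output.

What the simulator does *not* emulate: spatial autocorrelation beyond
the pair effect, diel or seasonal dynamics, size selectivity within a
mesh, species interactions, or gear saturation. Tests that pass on
simulated surveys therefore demonstrate the correctness of the
estimators under the stated stochastic model, not the field validity of
the survey design itself.

## Problem sizes and numerical choices in the test suite

The suite favours depth over breadth: Monte-Carlo checks use 2,500
simulated nets for panel-mean convergence (3 MC standard errors),
20,000 replicates for TOST power (tolerance 0.02), 10,000 orderings for
accumulation means, 500 datasets of 16 samples for the PERMDISP type-I
rate, and 500 resampling replicates for the CV parameter-recovery
check; these sizes make the stochastic assertions sharp while keeping a
full run around a minute and a half. Degenerate inputs are contracts,
not accidents: zero-variance TOST samples are flagged, empty catch
files yield zero matrices, a zero reference catch makes reductions
undefined rather than infinite, and every validation error names the
offending rows.

## Limitations

The package reproduces every published summary number that is
computable from printed inputs, but cannot reproduce analyses that
need the raw per-net records (mixed-model tables, ordination plots,
the published per-stratum accumulation thresholds); where the
motivating study's software left its permutation scheme undocumented,
ours is stated above and may differ in the last digit of a p-value.
The stratum-to-community grouping is accepted as configuration, as is
the feasibility cutoff; both are scientific judgments upstream of the
arithmetic this package owns.
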