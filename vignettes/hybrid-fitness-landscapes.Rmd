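---
title: "Hybrid fitness landscapes: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid fitness landscapes: models, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmhybrid)
```

## The model

Hybrids between two diverged diploid populations P1 and P2 are summarised
by two coordinates: the hybrid index $h$ (the proportion of alleles at
the $d$ divergent sites that come from P2) and the interpopulation
heterozygosity $p_{12}$ (the proportion of divergent sites carrying one
allele from each population).  All hybrids live in the triangle
$p_{12} \le 2\min(h, 1-h)$, with the parents at the lower corners and the
F1 at the apex.

Fitness is modelled through Fisher's geometric model: $n$ quantitative
traits under optimising selection, with trait $i$ weighted by
$\lambda_i$.  A genotype's *breakdown score* is
$S = \sum_i \lambda_i z_i^2$, the weighted squared distance of its
phenotype $z$ from the optimum; breakdown maps to fitness through
$\ln w = -k\,S^{\alpha/2}$.  Because hybrid genomes combine the parental
substitutions in effectively random combinations, the chain of
substitution effects behaves like a constrained random walk, and the
expected breakdown of a hybrid class depends only on its coordinates and
on the parents' own scaled breakdown scores $f_{P1}, f_{P2}$:

$$f = f_{P1} + \beta_1 h (1 - \beta_2 h) - p_{12}, \qquad
  \beta_1 = 4 - 2 f_{P1}, \quad
  \beta_2 = \frac{4 - f_{P1} - f_{P2}}{4 - 2 f_{P1}},$$

where $f$ is scaled so that the worst class between optimal parents has
$f = 1$.  Three regimes are worth naming.  With optimal parents
($f_{P} = 0$) the surface is $4h(1-h) - p_{12}$: the hybrid index is
under symmetric disruptive selection and heterozygosity is always
beneficial.  With fully uncoadapted divergence ($f_P = 2$, the expected
value under an unconstrained random walk) the surface collapses to
$2 - p_{12}$, the classical single-locus inbreeding prediction.
Intermediate $f_P$ interpolates, which is what lets one model explain
both heterosis in crop line crosses and breakdown in species crosses.

### Numerical form of the landscape

`expected_breakdown()` evaluates the algebraically identical symmetric
grouping $f_{P1}(1-h)^2 + f_{P2} h^2 + 4h(1-h) - p_{12}$.  This form is
finite at $f_{P1} = 2$ (where $\beta_2$ has a 0/0 and is reported as
`NA`) and makes the parental corner identities $f(0,0) = f_{P1}$,
$f(1,0) = f_{P2}$ hold to the last floating-point bit, which the test
suite asserts with `expect_identical()`.  Coordinate validation uses a
tolerance of $10^{-9}$ on the triangle constraints and can be disabled
for vectorised grid work.

### Bounds on the derived coefficients

For $f_{P1}, f_{P2} \in [0, 2]$ one can show $\beta_1 \in [0, 4]$ and
$\beta_2 \ge 1/2$ (the lower bound is attained at $f_{P2} = 2$), while
$\beta_2 \le 2$ holds only under the additional constraint
$f_{P2} \ge 3 f_{P1} - 4$; $\beta_2$ diverges as $f_{P1} \to 2$ with
$f_{P2}$ small.  The package therefore *reports* $\beta_1, \beta_2$ but
does not enforce a $\beta_2$ range; users comparing estimates against
the interval $[1/2, 2]$ should be aware that the upper end presumes the
parents are not too asymmetrically maladapted.

### The fitness map and its presets

`fitness_map()` defaults to $\alpha = 2$, $k = 1$ (log fitness
proportional to breakdown), the assumption under which the excess-yield
identity below is exact.  The preset `fitness_map("fig4")` is
$w = \exp(-6 f^2)$ ($\alpha = 4$, $k = 6$), the strongly epistatic map
used for cricket-style cross tables; the published plotting formula is
typographically ambiguous between $\exp(-6f^2)$ and other readings, and
we adopt the squared reading together with the matching parental
calibration $0.5 = \exp(-6 f_{P2}^2)$, i.e.
$f_{P2} = \sqrt{\ln 2 / 6} \approx 0.34$.  This choice only affects the
visual compression of predicted fitness values, never their rank order,
which is the quantity the model constrains.

## Cross predictions and excess yield

Crosses are recursive maternal $\times$ paternal pairs
(`cross_spec()`), with presets for F1, F2 and iterated backcrosses.
Expected coordinates follow from gamete P2-fractions:
$E(h) = (h_M + h_F)/2$ and $E(p_{12}) = h_M(1-h_F) + (1-h_M)h_F$.

`excess_yield_ratio()` implements the classical yield proxy
$(\bar w - w_P)/(w_{F1} - w_P)$ in its first-order (Taylor) form
$(f_P^{\alpha/2} - E[f^{\alpha/2}]) / (f_P^{\alpha/2} -
f_{F1}^{\alpha/2})$ with $f_{F1} = f_P/2$.  We use the Taylor form
deliberately: the single-locus identity (ratio $= p_{12}$ at
$f_P = 2, \alpha = 2$, hence the famous 0.5 for the F2) is exact on this
scale but only a limit of the raw exponential-fitness ratio.  The
default mode averages $f^{\alpha/2}$ by Monte Carlo over simulated
within-cross genotypes ($10^4$ genotypes at $d = 100$ sites, seeded);
`analytic` mode plugs in the class's expected coordinates and ignores
within-cross variance, which matters whenever $\alpha \ne 2$.

## The divergence simulator

`draw_substitutions()` models divergence by effect resampling in the
origin-fixation spirit: each substitution receives an independent
normal heterozygous effect per trait (variance $v_i$; homozygous
effects are exactly twice heterozygous, i.e. phenotypic additivity with
no dominance parameter).  Three modes set the parental condition:
`random_walk` leaves the endpoints free ($E(f_P) = 2$), `coadapted`
mean-centres each lineage's effects so both parents sit exactly at the
optimum (a discrete bridge construction), and `asymmetric` centres
lineage 1 and displaces lineage 2 along the first trait so that
$f_{P2}$ hits its target exactly.  This reproduces the *target* of the
random-walk approximation rather than any particular population-genetic
generating process; explicit Wright-Fisher simulation (drift, linkage,
standing variation) is out of scope, and the closed-form landscape is
insensitive to the divergence process by construction.

Hybrid classes with fixed $(h, p_{12})$ are realised with exact integer
site counts: $n_{12} = \lfloor p_{12} d + 0.5 \rfloor$ heterozygous
sites first, then $n_2 = \lfloor h d - n_{12}/2 + 0.5\rfloor$
P2-homozygous sites (round-half-up, deterministic); $h$ is matched as
closely as the heterozygote count allows and never silently truncated.
`bridge_validation_grid()` compares simulated class means against the
closed form; with more than one divergence replicate the standard error
is taken *across replicate means*, which is essential because the
realised sum of squared effects fluctuates between histories by
$O(\sqrt{2/(dn)})$ — a within-replicate standard error would overstate
the precision of the comparison.

## The incompatibility formulation

The optimal-parents surface can equally be produced by a model of
$\ell$-locus Dobzhansky–Muller incompatibilities in which every
$\ell$-tuple of divergent sites carries a potential incompatibility
whose severity $s_{ijk}$ depends on how many of its loci are homozygous
for each parent ($i$, $j$) or heterozygous ($k$).  Averaging over the
multinomial configuration probabilities and requiring the expected
surface to equal $4h(1-h) - p_{12}$ for every $\ell$ forces, within the
pairwise-quadratic family,

$$s_{ijk} = \frac{4ij + k(i+j)}{\ell(\ell-1)},$$

which is the shipped `"equivalence"` preset.  (Derivation sketch: the
target expands to $4p_1p_2 + 2p_{12}(p_1{+}p_2) + p_{12}^2 - p_{12}$;
matching the multinomial moments $E[IJ]$, $E[K(I{+}J)]$, $E[K(K{-}1)]$,
$E[K]$ term by term and simplifying with $i+j+k=\ell$ gives the stated
form uniquely up to scale.)  The preset embodies exactly the two
dominance conditions that make incompatibility models agree with the
geometric model: partial recessivity on average (a heterozygous locus
counts at quarter strength) and greatest severity when homozygous
alleles from both parents meet.  The `"fully_recessive"` and
`"codominant"` presets break the conditions and are kept as negative
controls — their surfaces are demonstrably *not* proportional to the
landscape.  For finite genomes the configuration distribution is
multivariate hypergeometric rather than multinomial;
`expected_dmi_breakdown(..., d = )` uses the exact finite-$d$ form,
which is what tuple enumeration over all $3^d$ genotypes reproduces.
Expected breakdown is additive over incompatibilities (first moments
only), and the contrast with the geometric model is carried by
`snowball_count()`: $\binom{d}{\ell}$ potential incompatibilities make
log fitness fall like $-d^{\ell\alpha/2}$ instead of $-d^{\alpha/2}$.

## Sex linkage

With heteromorphic sex chromosomes, coordinates become weighted sums
over inheritance classes, $p_{12} = g_X p_{12,X} + g_A p_{12,A}$ and
likewise for $h$.  Hemizygous and silenced site fractions are treated
as expressed single copies: they contribute the expressed allele's
origin to $h$ at full weight and zero to $p_{12}$.  Partial paternal-X
silencing ($\pi$) mixes the silenced (maternal single-copy) and
biparental female-X contributions linearly.  Two qualitative
predictions follow directly and are tested: the heterogametic F1 loses
the heterozygosity benefit on a fraction $g_X$ of its genome, giving
Haldane's rule with a breakdown gap that grows with $g_X$; and in
backcross males the direction of selection on autosomal heterozygosity
flips with the ancestry of the X (`backcross_male_selection()`), which
is the sign structure that the nested `hx_interaction_fit()` models
recover from data.  With complete silencing ($\pi = 1$) an F1 female
becomes effectively hemizygous for her maternal X, erasing the female
advantage — the model's route to Haldane-rule exceptions, with
reciprocal F1 females differing whenever one parent is maladapted.
ZW systems are handled by relabelling (heterogametic sex female; the
single Z of a female is paternal).  `cross_prediction_table()` builds
cricket-style tables for arbitrary cross lists; because the published
supplementary table of expected scores was not available to this
package, the table is computed from the model itself and validated
against the hand-derivable entries and the qualitative ordering claims,
not against a transcription.

## Ancestry estimation from markers

`individual_coords()` estimates $p_{12}$ as the heterozygous fraction
of scored diploid markers and $h$ as the P2-allele fraction of scored
allele copies, per chromosome class; missing calls drop out of the
denominators.  Combination across classes uses supplied partition
weights (e.g. a CDS-based $g_X$ from `gx_from_annotation()`) or each
individual's scored-marker proportions by default.  Markers are
unweighted within a class; with partially diagnostic markers a
frequency-weighted estimator would be natural, but the filtering
workflow (F1-heterozygosity filter, $>0.9$ frequency-difference filter
with panel-based re-orientation) is designed to make weights close to
uniform anyway, so we keep the simpler estimator and note the
alternative here.  Male X calls arriving as homozygous-looking 0/2 are
stored as single-copy states; heterozygous male-X calls are treated as
genotyping errors and set missing (or the individual dropped in strict
mode).  `missingness_qc()` guards the main failure mode of collated
datasets — missingness rank-correlated with heterozygosity or fitness —
at a default threshold of $p < 0.001$.

## Estimating the fitness surface

`fit_surface()` regresses a fitness proxy (Gaussian, binomial-logit, or
proportional-odds ordinal via `MASS::polr`; a two-level ordinal response
reduces exactly to logistic regression) on subsets of
$\{p_{12}, h, h^2\}$, with $h^2$ never entering without $h$, and
selects the minimum-AIC model (ties within $10^{-6}$ resolved toward
fewer parameters).  Fitting is on the fitness scale (higher linear
predictor = higher fitness); the landscape orientation is recovered by
the sign convention in the reparameterisation
$\beta_0 = a_{p_{12}}$, $\beta_1 = -a_h/\beta_0$,
$\beta_2 = a_{h^2}/(-a_h)$, so $\beta_0 > 0$ means heterozygosity is
beneficial.  Collinear designs (a single cross class at a point, or a
pure backcross edge where $h = p_{12}/2$ exactly) raise a
rank-deficiency error naming the offending term rather than returning
arbitrary coefficients.  Random-effect structures (family terms in
wild-pedigree data) are out of scope; fits are fixed-effects GLMs.

Profile intervals exploit linearity: fixing $\beta_1$ induces the
covariate $p_{12} - \beta_1 h$ (plus $h^2$), fixing $\beta_2$ induces
$h - \beta_2 h^2$ (plus $p_{12}$), and fixing $\beta_0$ turns the
$p_{12}$ term into an offset — every profile point is a plain GLM fit,
bracketed and bisected to a tolerance of $10^{-4}$.  The bound
convention needs stating precisely: the constrained refit estimates one
parameter fewer, so its own AIC equals the optimum's when the deviance
has risen by 2, and the reported "$\Delta\mathrm{AIC} = 2$" bounds sit
at a deviance rise of 4 — approximately a 95% interval.  We chose this
model-comparison accounting (rather than charging the fixed parameter
as if estimated, which would give an ~84% interval at the same label)
because it is the reading under which the documented coverage
properties of the intervals hold; simulated coverage of the
$\beta_2$ interval across seeded replicates is checked in the test
suite.  Flat profiles return one-sided intervals with an explicit
infinity.

The accompanying test statistics follow the conventions used in
comparative reanalyses of hybrid datasets: `wilcoxon_het()` is a
one-sample signed-rank test of median $p_{12}$ against 0.5, exact (by
sign-flip convolution, midranks allowed) for up to 25 non-zero
differences and normal-approximated with tie and continuity corrections
beyond; `wald_p()` compares $t$-values to the normal tail;
`mcfadden_r2()` is $1 - \ell_{\rm fit}/\ell_{\rm null}$.  The
in-package signed-rank implementation exists because the required
conventions (exact cutoff and tie handling) differ from
`stats::wilcox.test` defaults; where the conventions coincide the two
agree to machine precision, which the tests verify.

## What the synthetic generator does and does not emulate

`synth_scenario()` fixes the study conditions: an F2 design of 132
individuals at 43 diagnostic markers mirrors the mussel cross that
motivated the selection-on-heterozygosity tests; wild-hybrid scenarios
default to $N = 800$ individuals scattered over the triangle (a mixture
of F2, first and second backcrosses, and uniformly drawn coordinates),
the scale of the wild-poplar survival analysis; binary responses use a
logistic link with slope 3 on breakdown, a moderate-selection regime in
which surface recovery is informative but not trivial.  Genotypes
segregate independently (free recombination), X markers follow X
inheritance with hemizygous males, missingness is independent per call,
and contamination makes a marker shared-polymorphic with minor-allele
frequency uniform on $[0, 0.3]$ — giving the diagnostic filter a known
ground truth.  Viability-selection mode retains individuals with
probability $w$, reproducing the implicit selection of
survival-to-genotyping designs.

What passing tests on these data do *not* show: robustness to linkage
(blocks of correlated ancestry inflate coordinate variance and induce
apparent snowballing), to genotyping error beyond the modelled male-X
toggle, to population structure within the parental panels, or to
fitness proxies that are nonmonotone in true fitness.  Real datasets
need the QC steps (`missingness_qc()`, the diagnostic filters) before
the estimators can be trusted.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; seeded helpers
save and restore the caller's RNG state, and the same seed reproduces a
dataset byte-identically (R's default Mersenne-Twister stream).  The
shipped validation uses desk-scale sizes chosen to keep every Monte
Carlo comparison's standard error well inside the tolerance it is
tested at: divergence replicates of $d = 100$–$200$ substitutions,
class simulations of 1500–3000 genotypes across up to 15 grid points
and 6 divergence histories, $10^4$ F2 genotypes for the heterozygosity
expectation, and 50 seeded replicates of the $N = 800$ wild-hybrid
recovery pipeline (marker simulation at $d = 600$, ancestry estimation,
binomial surface fit, profile interval).

## Known limitations

Linkage and recombination-distance modelling are intentionally absent;
all divergent sites segregate freely.  The DMI module computes expected
breakdown only (no higher moments or epistasis between
incompatibilities).  Dosage compensation is modelled solely as uniform
paternal-X silencing; autosomal imprinting is not supported.  The
ordinal fitter counts all estimated cutpoints in the AIC penalty; if a
published comparison used a different bookkeeping for cutpoints, AIC
differences between families (not within a family) could shift.
Finally, the $\beta$ reparameterisation is undefined when the selected
model omits the required terms — the package reports `NA` rather than
extrapolating, and F2-only designs will typically do exactly that for
$\beta_1, \beta_2$, which is itself a model prediction (little
variation in $4h(1-h)$ within an F2).
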