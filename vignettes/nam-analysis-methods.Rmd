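---
title: "Models and methods behind NAMtools"
author: "NAMtools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind NAMtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NAMtools)
```

# Scope

NAMtools implements the full quantitative-genetic analysis chain for a
soybean-style nested association mapping (NAM) population: a hub
(common) parent mated to a diverse panel of founders, producing
half-sib families of recombinant inbred lines (RILs) that are evaluated
in multi-environment augmented incomplete-block trials. The package
covers five stages — synthetic population and trial generation, marker
preparation, two-stage mixed-model BLUP analysis, a family-nested
random allele-substitution genome scan, and post-processing of
marker-trait associations (MTAs) into 5-cM regions — so every stage can
be exercised and validated at desk scale without field data.

# The synthetic population generator

The generator is first-class, tested code: it defines the conditions
under which the statistical machinery is validated.

**Founders.** One fully homozygous common parent plus, by default, 17
elite (EL), 15 exotic-ancestry breeding line (BX) and 8 plant
introduction (PI) founders — the 40-family design. The common parent
carries the reference allele everywhere; founders draw the alternate
allele per marker at a configurable frequency (default 0.5 per group).

**RILs.** Each founder is mated to the common parent and RILs are
advanced by single-seed descent from F2 to, by default, F5: one F2
individual per line, selfed forward with a single offspring per
generation. Meiosis uses the Haldane map function,
$r = (1 - e^{-2d/100})/2$, i.e. no crossover interference — the
standard closed-form-testable choice. Residual heterozygosity at
generation $g$ is $(1/2)^{g-1}$ per locus in expectation (0.0625 at
F5), and the test suite verifies both this decay and the agreement of
simulated recombination fractions with the Haldane form at 1, 10 and
50 cM.

**Trait architecture.** Each trait receives a set of QTL markers and a
complete founders-by-QTL table of allele-substitution effects drawn
from group-specific normal distributions, the common parent's effects
being zero by construction. Effects are expressed on the
*homozygous-substitution* scale: the trait difference between a line
homozygous for the founder allele and one homozygous for the common
allele, so a homozygous founder RIL receives the full effect and a
residual heterozygote half of it. On top of the QTL, a polygenic
component is built from small normal effects at every non-QTL marker,
scaled so its variance matches the configured value. Because this
background is genomic, it is *locally linked* signal (see the
calibration discussion below).

**Trials.** Each family's RILs are split into sets of 35 and augmented
with the family's two parents and three checks (40 entries per set;
short sets are padded with check plots, mirroring practice when seed
runs out). Each evaluated set forms one incomplete block within an
environment; coverage across environments can be unbalanced (all sets
at some sites, a configured number elsewhere). A plot value is

$$y = \mu + E_e + B_b + g_i + \beta_{pd}(t - \bar t) + \varepsilon,$$

with independent normal environment, block and residual effects, a
Julian planting-date covariate centred at the study mean date (the
centring is a package convention; nothing downstream depends on it),
fixed true values for checks, and completely-at-random plot dropout. A
trait named `lodging` is truncated to the 1–5 scoring scale.

What the generator deliberately does not emulate: genotype-by-
environment interaction (the downstream models have none), epistasis,
non-random missingness, spatial field trend, and the marker-panel
ascertainment of real SNP chips (markers pre-selected to segregate in
most families). Passing tests therefore demonstrate correctness of the
machinery under the stated generating model, not robustness to those
real-data features.

# Marker preparation

* `filterMarkers()` classifies each marker within each family as
  segregating, monomorphic or `low_MAF` (minor allele frequency
  strictly below 10%, computed on non-missing allele counts). The
  boundary is strict: a family MAF of exactly 0.10 is kept. A
  genome-wide eliminated list collects markers failing in *any*
  family; the pipeline's scan instead uses the union of per-family
  segregating sets, because with few simulated families a marker
  monomorphic in one family reflects the cross design rather than
  segregation distortion, and families in which a marker does not
  segregate are simply not estimable in the scan.
* `qcRILs()` flags lines identical to either parent at every
  non-missing marker (likely self-pollinations) or carrying an allele
  absent from both parents, with the non-parental flag taking
  precedence; families in which more than half the RILs carry
  non-parental alleles are reported for removal (the signature of a
  mating made with an unintended line). The 50% cutoff generalises the
  observed removal of one full family; the QC identity rule uses
  equality at 100% of non-missing markers, as no tolerance is
  established.
* `interpolateCM()` linearly interpolates genetic positions from
  physical positions on any per-chromosome (bp, cM) anchor frame,
  clamping queries outside the terminal anchors to the terminal cM so
  positions can never extrapolate negative. Anchors are hit exactly;
  ties at an anchor resolve to the left flank.
* `projectDenseMarkers()` transfers founder-only dense markers onto
  RILs through the framework markers' parental-origin calls: a dense
  marker flanked by two concordant homozygous origin calls receives
  that parent's genotype; recombinant, heterozygous or missing
  intervals stay missing; dense markers beyond the outermost framework
  markers inherit the nearest call. The projection can only emit
  parental alleles, and its empirical accuracy on masked-truth
  simulations (>= 95% at the test densities) is *reported by the test*,
  not assumed — accuracy degrades with recombination density.

# Two-stage mixed-model analysis

**Stage 1 (checks and blocks).** On check plots only:

$$y = X\beta + C\kappa + B\pi + \varepsilon,\qquad
\pi \sim N(0, I\sigma^2_{blk}),\ \varepsilon \sim N(0, I\sigma^2_{res}),$$

with fixed check means ($\kappa$, BLUEs), a fixed planting-date slope,
and random block effects whose BLUPs are *shrunken* block values —
preferable to raw block means under unbalanced check allocation.
Blocks contributing no check data are shrunk fully to zero. The fit
uses REML via lme4; on balanced toy designs the block BLUPs equal the
closed-form shrinkage
$\hat\pi_b = \frac{\hat\sigma^2_{blk}}{\hat\sigma^2_{blk} +
\hat\sigma^2_{res}/n_b}(\bar y_b - \bar y)$ to 1e-6, which the tests
assert. A design whose check/block incidence graph is disconnected
(e.g. each check confined to its own block) is rejected as
unidentifiable.

**Stage 2 (entries).** On non-check plots (RILs and parents):

$$y = X\beta + Z\upsilon + \varepsilon,\qquad
\upsilon \sim N(0, I\sigma^2_g),$$

where $X$ carries two fixed covariates — planting date and the stage-1
shrunken block value — each with its own estimated slope, and
$\upsilon$ are random entry effects. The entry BLUPs $\hat\upsilon$
feed the genome scan. Entries seen in a single plot are retained
(strongly shrunk); entries with no data are absent rather than
zero-filled. Founder parents are included as random entries alongside
RILs, matching the description of the response as covering RILs and
their parents.

**Heritability.** Broad-sense, entry-mean basis:
$H = \sigma^2_g / (\sigma^2_g + \sigma^2_{res}/\bar e)$ with $\bar e$
the harmonic mean of per-entry environment counts — the right
replication summary under unbalanced coverage. Family-mean basis:
$H_{fam} = \sigma^2_{among} / (\sigma^2_{among} +
\sigma^2_{within}/\bar n + \sigma^2_{res}/(\bar n \bar e))$ with
$\bar n$ the harmonic mean family size (the formula is the package's
own, as only the basis is established). Confidence bounds use the
F-quantile construction: $(1-H)F_{obs} \sim F(df_1, df_2)$ with
$F_{obs} = 1/(1-\hat H)$, $df_1$ = entries − 1 and $df_2$ =
entries × $(\bar e - 1)$, clamped to [0, 1]. Simulations at the
reported H range (0.82–0.93) must cover the generating value in at
least 90% of replicates.

**Variance partition and correlations.** The proportion of genotypic
variance among families is a one-way random-effects decomposition of
entry BLUPs (REML), returning among/(among+within). Genotypic
correlations are product-moment correlations of entry BLUPs on the
intersection of entries — a deliberate approximation to bivariate
REML, adequate for the single-number deliverable and noted as such.

# The genome scan

Per tested marker, on the entry BLUPs $\upsilon$:

$$\upsilon = X_f\mu + W\alpha + \varphi + \varepsilon,\qquad
\alpha \sim N(0, I\sigma^2_\alpha),\
\varphi \sim N(0, K\sigma^2_\varphi),\
\varepsilon \sim N(0, I\sigma^2_\varepsilon),$$

* $W$ is the family-nested marker design: within each family, the dose
  of the founder (non-common) allele, on the 0/½/1 founder-genome
  scale so that $\hat\alpha_f$ estimates the homozygous substitution
  effect relative to the common-parent allele — the same scale as the
  generator's trait architecture. A family in which the marker does
  not segregate contributes no column: its effect is *not estimable*
  and is reported as NA, never zero.
* $X_f$ holds per-family intercepts. A single grand intercept would
  let between-family mean differences load onto the uncentred family
  dose columns and masquerade as marker effects wherever the kinship
  term absorbs them imperfectly; with family intercepts,
  $\hat\alpha_f$ is identified by within-family dose contrasts — the
  linkage information the NAM design is built on. This choice is what
  makes the experiment-wide false-positive bound below attainable.
* $K$ is the VanRaden genomic relationship matrix from column-centred
  doses scaled by $\sum 2p(1-p)$, rebuilt for every tested marker with
  all markers inside a 5-cM *linkage window* around it excluded —
  keeping local signal out of the polygenic covariance preserves power
  at the tested locus, while the genome-wide remainder still controls
  structure. A window of 0 means no exclusion.
* Estimation is REML. A significance call tests
  $\sigma^2_\alpha = 0$ by restricted likelihood ratio against the
  boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; the method
  label is written into the scan metadata. MTAs are declared at
  $-\log_{10}(p) \ge 3$, which Bonferroni-bounds the experiment-wide
  false-positive probability at 0.1 for up to 100 tested 5-cM regions.

**Numerics.** Rather than refactorising a dense covariance per marker,
the scan eigendecomposes the full genomic cross-product once per
(population, trait) pair and treats each marker's window exclusion as
a low-rank downdate, evaluated through Woodbury and determinant-lemma
identities in compiled code; each REML evaluation is then
$O(n\,r^2)$ with $r$ = estimable families + window markers. The
variance ratios are optimised on the log scale (Brent for the null
model, Nelder-Mead for the full model), residual variance is profiled
out, and boundary estimates are clamped at zero. The per-marker
$\sigma^2_\varphi$ and $\sigma^2_\varepsilon$ are re-estimated at
every marker (no fixed-background shortcut). Entries with a missing
genotype at the tested marker are dropped for that marker's fit.
Degenerate inputs produce flagged records rather than aborting the
scan: a constant phenotype gives $p = 1$ with zero effects, a marker
segregating in no family gives $p = 1$ with all effects NA.

**Calibration at desk scale.** The scan's null hypothesis is "no
marker-linked effect beyond the windowed polygenic term". A
marker-built polygenic background concentrates roughly
(window length)/(genome length) of its variance inside each linkage
window — about 5% on a two-chromosome 200-cM desk genome, versus about
0.2% on a real 2300-cM, 4000-marker genome — and the window exclusion
*deliberately* leaves that local share detectable: on small genomes
background loci are genuine local signal, not false positives. The
null-calibration test therefore generates its global null as
family-structured background (family effects, sd 120 trait units) plus
iid noise (sd 100), which contains population structure but no
marker-linked effects; under that null the observed probability of
declaring any significant 5-cM region stays below the 0.1 bound.

# Post-processing of MTAs

Significant markers are chained into regions per trait by
single-linkage within chromosome: a gap strictly greater than 5 cM
starts a new region, a gap of exactly 5 cM does not (matching the
convention that peaks "greater than 5 cM apart" separate). Region
peaks are the maximum $-\log_{10}(p)$ markers, ties broken by lower cM
then lexicographic marker id. Cross-trait bins chain region peaks
across traits with the same rule, flagging multi-trait bins. The
chaining is order-independent and is tested against a brute-force
transitive-closure oracle. Allele-effect sign patterns at a peak are
classified over estimable effects only (all_negative,
all_but_k_negative, mixed, and their positive mirrors; zeros count as
neither sign), and founder-group summaries average all estimable
(family, marker) pairs with equal weight, additionally flagging
positive-effect alleles present in BX/PI founders at markers where no
EL founder shows one.

# Pipeline and reproducibility

`runPipeline()` executes simulate → prep → blup → gwas → bins from a
single YAML-serialisable config with one master seed; stage seeds are
derived deterministically so stages rerun identically, and the
manifest records the config hash, per-file MD5 checksums and record
counts. Reruns with the same config are bit-identical, which the test
suite asserts through the manifest. `validateInputs()` checks map
sortedness, dose coding, plot-table referential integrity and the 1–5
lodging range before any analysis. A thin command-line wrapper over
these functions ships in `inst/scripts/nam-pipeline.R`; the package
functions are the primary interface.

# Problem sizes used in validation

The shipped validation uses desk-scale problems chosen to keep the
whole suite comfortably interactive: design-count checks derive the
full 5,600-RIL germplasm on a sparse 20-marker map; the null
calibration uses 200 datasets of 10 families × 50 RILs on two
100-cM chromosomes (40 tested 5-cM regions); power and effect-recovery
scenarios use the same population shape with a single planted QTL
(150 or 239 trait units); heritability coverage uses 100 replicates of
250 entries × 4 environments. These sizes are the package's validation
conditions, not statements about the limits of the methods.

# Known limitations

* Genotypic correlations are correlations of BLUPs, not bivariate
  REML estimates; they inherit BLUP shrinkage.
* The scan's empirical-Bayes/REML machinery matches the *model*, not
  any particular historical implementation's output.
* The projection of dense markers is deterministic and interval-based;
  no probabilistic imputation of recombinant intervals is attempted.
* No genotype-by-environment interaction, epistasis, dominance (lines
  are inbred) or spatial modelling anywhere in the chain.
* Multiple testing uses the fixed $-\log_{10}(p) \ge 3$ region
  threshold; no FDR layer is added.
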