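---
title: "Dissecting genetic influence on methylation-trait associations with twin models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting genetic influence on methylation-trait associations with twin models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
```

## The question

An epigenome-wide association between DNA methylation at a CpG site and an
anthropometric trait (BMI, waist circumference, waist-to-hip ratio) can arise
in several ways: the two may be linked by environmental exposure, they may
both be downstream of the same genetic variation, or genetic effects may even
mask a real environmental association. Twin cohorts allow these explanations
to be separated, because monozygotic (MZ) co-twins share their genome while
dizygotic (DZ) co-twins share on average half of segregating alleles, and
within an MZ pair every between-family and genetic confounder is held
constant.

`twinmeth` implements both halves of that argument:

1. a **bivariate Cholesky twin model** per CpG, quantifying how much of the
   CpG-trait correlation is carried by genes versus environment, and
2. a pair of **association designs** — full-population and MZ within-pair —
   whose joint significance pattern classifies each association into one of
   four outcomes (independent of genetics, genetically driven, genetically
   confounded, or null).

## The bivariate ACE/ADE model

For two variables per person (methylation $X$, trait $Y$), phenotypic
(co)variance is decomposed into additive genetic (A), either common
environment (C) or dominance (D), and unique environment (E) components.
Each component is parameterized by a lower-triangular $2\times 2$ loading
matrix, e.g.

$$L_a = \begin{pmatrix} a_{11} & 0 \\ a_{21} & a_{22} \end{pmatrix},
\qquad \Sigma_A = L_a L_a^\top,$$

so $a_{11}^2$ is the genetic variance of $X$, $a_{21}^2 + a_{22}^2$ that of
$Y$, and $a_{11}a_{21}$ their genetic covariance. The model-implied
covariance of the pair quadruple $(X_1, Y_1, X_2, Y_2)$ stacks a shared
within-twin block $\Sigma_A + \Sigma_{C/D} + \Sigma_E$ with a cross-twin
block that weights $\Sigma_A$ by 1 (MZ) or 0.5 (DZ) and $\Sigma_C$ by 1, or
$\Sigma_D$ by 1 (MZ) / 0.25 (DZ); E never crosses twins. C and D cannot be
estimated jointly from twins reared together, so ACE and ADE are fitted
separately and compared by AIC (ties broken toward ACE; a non-converged
competitor concedes with a warning flag).

Component correlations follow from the paths: for component $K$,
$r_K = k_{11}k_{21} / \sqrt{k_{11}^2\,(k_{21}^2 + k_{22}^2)}$ (defined as 0
when either component variance is below $10^{-10}$), and the phenotypic
correlation $R_{ph}$ is the total cross-covariance over the product of total
SDs. All correlations are reported **signed**; every downstream threshold is
applied to absolute values, which sidesteps the ambiguity between signed
estimates and the folded magnitudes often quoted in summaries.

### Estimation

Mean structure is removed before fitting: each variable is residualized on
age and sex by OLS (`adjust_covariates()`), then centred; a full FIML mean
model would add cost without changing the covariance questions asked here.
Complete cases are used per CpG-trait combination. Variables are scaled to
unit variance for optimizer conditioning (correlations are scale-invariant;
paths are reported on both scales). The likelihood is evaluated from
per-zygosity scatter matrices, so one evaluation costs the same regardless
of cohort size, and L-BFGS-B with analytic gradients maximizes it under
non-negativity bounds on the diagonal loadings ($e_{11}, e_{22} \ge 10^{-6}$:
measurement noise never vanishes). Five starts are used by default: a
moment-based start solved from the empirical within- and cross-twin blocks
(e.g. $\hat\Sigma_A = 2(R_{MZ} - R_{DZ})$ for ACE, projected to positive
semi-definite), plus perturbed restarts controlled by a seed. Convergence is
the optimizer status plus a finite likelihood; a per-fit Hessian check is
deliberately omitted at genome scale. The genome scan derives per-CpG child
seeds by counter from one root seed, so results are identical for any worker
count and CpG ordering.

### One-sided constraint tests

Whether a cross path can be dropped is judged by a likelihood-ratio test of
the nested submodel ($\Lambda = 2\,\Delta\ell$, clipped at 0; a materially
negative statistic flags an optimizer failure, which warm-starting the
submodel from the full solution makes rare). Two one-sided conventions are
implemented, and the distinction matters:

* **mixture** — $p = \tfrac12 P(\chi^2_{df} \ge \Lambda)$, the 50:50
  $\chi^2_0{:}\chi^2_1$ boundary correction that twin software traditionally
  applies when a variance-type parameter is dropped. For a *sign-free cross
  path* such as $a_{21}$ the parameter is interior, $\Lambda$ is
  asymptotically $\chi^2_1$ under the null, and this p-value rejects at
  roughly **twice** the nominal level (we measure ~0.10 at $\alpha = 0.05$,
  378/159 pairs).
* **directional** (scan default) — a genuinely one-sided test of the freed
  path in a reference direction: $p = P\!\left(Z \ge s_{\mathrm{ref}}
  \, s_{\mathrm{obs}} \sqrt{\Lambda}\right)$, where $s_{\mathrm{obs}}$ is the
  sign of the freed path in the full fit and $s_{\mathrm{ref}}$ defaults to
  the sign of the fitted phenotypic correlation — i.e. "does this component
  contribute to the observed association, in its direction?". It coincides
  with the mixture p whenever the estimate lies in the reference direction,
  and holds its nominal size (63/1000 rejections at $\alpha=0.05$ in the
  suite's calibration test, within the exact binomial 99% interval).

`constraint_test()` defaults to the mixture form (the convention most
readers will expect from the twin literature); `twinsem_scan()` uses the
directional form for `p_ra` and `p_re` precisely because calibration of the
genetic-path test is what the downstream grouping consumes. Significance of
$R_{ph}$ (`p_rph`) uses the joint df = 3 test of all three cross paths with
the halved tail; a marginal Pearson-correlation test is a reasonable
alternative a user can substitute.

An important caveat surfaced by the calibration experiments: when the
*other* variance components sit on the boundary (e.g. a truth with zero C),
the finite-sample LRT for $a_{21}$ is itself distorted and both conventions
drift conservative. The suite's size test therefore keeps all non-tested
paths interior, which is also the regime in which the asymptotic argument
applies.

## Association designs

**Full population.** `fit_full_population()` fits
`beta ~ trait + age + sex + smoking + drinking + zygosity + (1 | pair)` with
lme4. Zygosity enters as a fixed covariate: a random intercept over a
two-level factor has an unidentifiable variance, so the verbal "zygosity as a
random term" recipe is statistically degenerate; a nested random intercept
(pair within zygosity) is available as a sensitivity switch. Wald p-values
use the large-sample normal approximation — at genome scale the per-CpG
degrees-of-freedom machinery is the cost driver, and with ~500 pairs the
difference is negligible. A singular mixed fit falls back to ordinary
regression with pair-clustered robust standard errors, flagged in the output.

**MZ within-pair.** The trait is decomposed into the pair mean and the
within-pair deviation: each MZ twin contributes a row with
$X_{diff} = X_{self} - X_{cotwin}$ (antisymmetric within pair) and the
shared $X_{mean}$; `fit_mz_within_pair()` fits
`beta ~ x_diff + x_mean + smoking + drinking + (1 | pair)` and reports the
$X_{diff}$ coefficient, which is free of genetic and shared-family
confounding. Both twins' rows are included, so the arbitrary choice of which
twin is "first" cannot matter. Age and sex need no adjustment here (co-twins
share both); own-level smoking and drinking remain.

Benjamini-Hochberg FDR is applied within one family per trait-by-design
analysis (the scan's CpG set); a genome-wide family is obtained by passing
the full CpG list in one call.

## Grouping and the four outcomes

CpGs are stratified on the SEM evidence (thresholds configurable, defaults
as printed in the headline analysis): G1, significant $|R_{ph}| \ge 0.2$;
G2, significant $|R_{ph}| > 0.1$ with significant $|R_a| > 0.5$; G3,
significant $|R_{ph}| > 0.1$ with non-significant $R_a$ *and* point estimate
$|R_a| < 0.1$ (a conjunction); G4, significant $|R_{ph}| > 0.1$ plus at
least one meQTL SNP shared with the trait's GWAS list (exact identifier
intersection). Memberships may overlap, except G2/G3 which are disjoint by
construction.

Each CpG-trait association is then labelled from the two designs'
FDR-significance flags: significant in both — *independent* of genetic
effects; only in the full population — *genetically driven*; only within
pairs — genetically *confounded*; neither — *null*.

## The simulator

`simulate_cohort()` generates cohorts with exactly the covariance structure
the models assume, by drawing the latent A/C/D/E factors per pair with their
defining cross-twin correlations (1, 1, 0.25 for DZ dominance, 0) and
combining them through the Cholesky loadings — a different computational
route than the fitting side's matrix algebra, which is what makes
simulation-vs-`expected_twin_covariance()` agreement a meaningful two-route
check. Defaults mirror a registry-style adult cohort: 378 MZ + 159 DZ pairs,
age 49.9 (SD 12.2) shared within pair, 31.8% female (MZ co-twins share sex;
DZ co-twins are drawn independently, so both same- and opposite-sex DZ pairs
occur — no sex-limitation model is fitted), smoking 32.9/13.0/54.1% and
drinking 42.5/6.8/50.7% current/former/never with **zero true effect**, so
association nulls stay clean. Trait scales: BMI 24.8 (3.9) kg/m², WC 86.9
(10.8) cm, WHR 0.90 (0.10) — stored as a unitless ratio. Default age effect
0.01 SD/year and male-female shift 0.2 SD on both variables exercise the
covariate adjustment without dominating the signal.

Four scenario templates encode the outcome classes, with the obesity trait
as Cholesky variable 1 (heritability 0.6, no shared environment — consistent
with MZ/DZ correlation patterns for adult adiposity) so its latent factors
can be shared across every CpG of a cohort; correlations are invariant to
this orientation. The CpG side has total variance 1 and heritability 0.5
where applicable:

| scenario | cross paths | $R_{ph}$ | $R_a$ | $R_e$ |
|---|---|---|---|---|
| independent | $e_{21} \ne 0$ | 0.18 | 0 | 0.40 |
| genetically_driven | $a_{21} \ne 0$ | 0.33 | 0.60 | 0 |
| confounded | $a_{21}, e_{21}$ opposite | 0.04 | 0.49 | -0.29 |
| null | none | 0 | 0 | 0 |

The confounded template deserves a note, because its design point is not
where one might first put it. Zeroing the *marginal* cross-covariance
($a_{11}a_{21} = -e_{11}e_{21}$) does **not** null the full-population test:
the pair random intercept makes the mixed model weight within-pair evidence
roughly threefold relative to between-family evidence, so a marginally
cancelled CpG is still detected most of the time through its environmental
channel — genetic masking of the *analysis* is not the same as masking of
the raw correlation. The template therefore sets the genetic cross path to
1.25 times the marginal-cancellation value, the point (calibrated once on
large simulated cohorts, ~10,000 pairs) where the full-population mixed
model's estimand itself vanishes. The marginal $R_{ph}$ that results is
still near zero (~0.04), the component correlations keep opposite signs,
and the operational signature — null in the full population, clearly
significant within MZ pairs — is what defines the confounded outcome.

Effect magnitudes are documented defaults chosen to give clear but not
unrealistic signals at the default cohort size; no public per-CpG effect
sizes exist to calibrate against. Methylation is emitted on the beta scale
through `baseline + 0.08 * latent`, clipped to [0.001, 0.999]
(identity-clip default keeps the simulated truth linear, so recovery tests
are exact in expectation; an inverse-logit link with matched slope at
baseline is available for realism). The optional SNP layer adds
Hardy-Weinberg genotypes (MZ identical; DZ via simulated parental
transmission), meQTL and GWAS tables, and designated SNPs with linear
effects on both one CpG and the trait — the shared-genetic-basis structure
behind G4.

What the simulator does *not* emulate: probe-level array chemistry, batch
effects, cell-type composition, spatial correlation among CpGs, or
non-normal latent distributions. Passing recovery and calibration tests on
these cohorts therefore validates the statistical machinery, not robustness
to array artefacts — preprocessing is assumed done upstream.

## Numerical choices and degenerate inputs

* Optimizer tolerance `factr = 1e7` (~1e-9 relative on the likelihood);
  LRT statistics more negative than -1e-4 raise an optimizer-failure
  warning and are clipped at 0.
* Singular implied covariances during optimization return a large penalized
  objective instead of crashing the scan; per-CpG failures (zero variance,
  no complete pairs) become failure records and the scan continues.
* Pair-count floors (30 MZ / 10 DZ by default) refuse fits the data cannot
  identify; a missing zygosity group is an error, not a warning.
* `average_repeated()` tie-break: with three symmetric measurements both
  candidate pairs contain the median, and the median itself is returned.
* WHR is stored as a ratio (values near 0.9), never as a percentage.
* Annotation positions are 1-based as in array manifests; no strand
  handling (beta values are strand-resolved upstream).

## Problem sizes used by the validation suite

The test suite exercises the documented study conditions directly: oracle
equivalence on 1000 random path sets; Ra recovery over 200 CpGs at
2000/800 pairs; test-size calibration over 1000 null replicates at 378/159;
AIC selection consistency over 200 replicates per truth at 5000/2000; the
four scenario contracts over 200 single-CpG replicates each at 378/159; and
an end-to-end 200-CpG demo cohort. These sizes are the package's validation
design: large enough that the binomial/Monte-Carlo intervals in the
assertions are meaningful, small enough to run routinely.

## Known limitations

* No sex-limitation, gene-environment interaction, longitudinal, or
  trivariate models; no FIML handling of partial missingness (complete-case
  per CpG).
* The mixture one-sided p is anticonservative for sign-free cross paths
  (see above); users who need the traditional convention can request it
  explicitly, but should interpret its nominal level accordingly.
* The within-pair design controls shared genetics and family environment,
  not twin-specific reverse causation.
* G4 membership is only as good as the supplied meQTL/GWAS tables; the
  package intersects identifiers and does not re-derive meQTL evidence.
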