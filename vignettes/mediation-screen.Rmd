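---
title: "Screening the circulating proteome for mediators with Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening the circulating proteome for mediators with Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(protscreen)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instruments
for an exposure. For variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be
its association with the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$)
its association with the outcome, estimated in non-overlapping samples.
Under the instrumental-variable assumptions (relevance, no confounding of
the variant–outcome relation, no path to the outcome other than through the
exposure), each ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same
causal effect $\theta$.

The package's main estimator is the inverse-variance-weighted model as a
weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through the origin
with weights $w_j = 1/\sigma_{Yj}^2$:

$$\hat\theta = \frac{\sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj}}
                    {\sum_j w_j \hat\beta_{Xj}^2},\qquad
  Q = \sum_j w_j(\hat\beta_{Yj}-\hat\theta\hat\beta_{Xj})^2 .$$

The multiplicative-random-effects variant (IVW-MRE) scales the variance by
$\hat\phi = Q/(k-1)$, so heterogeneity — balanced pleiotropy — widens the
interval without shifting the point estimate:
$\mathrm{se}(\hat\theta) = \sqrt{\hat\phi / \sum_j w_j\hat\beta_{Xj}^2}$.
`mr_ivw_mre()` uses the unfloored $\hat\phi$ by default (the pure weighted
regression); `floor_phi = TRUE` floors it at 1, the fixed-effects lower
bound. Inside the decision engine the floored variant is used
(`screen_config(floor_phi = TRUE)`): with two instruments whose ratios agree
closely by chance, the unfloored $\hat\phi$ can collapse toward zero and
manufacture absurdly small p-values, which in a screen of thousands of
reverse-direction arms would surface as spurious "conflicts". Single-SNP
instruments fall back to the Wald ratio with delta-method standard error
$\sigma_{Yj}/|\hat\beta_{Xj}|$.

### Sensitivity estimators

The exclusion-restriction assumption is untestable, so the screen requires
directional agreement across estimators with different failure modes
(computed once at least three instruments are available):

* **MR-Egger** regresses $\hat\beta_Y$ on $\hat\beta_X$ *with* an
  intercept; the intercept estimates directional pleiotropy, the slope the
  causal effect. Because the regression is not invariant to allele
  re-orientation, pairs are first oriented so every $\hat\beta_X \ge 0$.
  Standard errors carry the multiplicative scale $\max(1,\hat\sigma)$ and
  p-values use a $t_{k-2}$ reference. With identical instruments the design
  is rank-deficient and `mr_egger()` refuses to fit (degenerate-instrument
  error) — the one estimator that cannot collapse to the Wald ratio.
* **Weighted median**: the weighted 50th percentile (linear interpolation
  over cumulative weights $s_j = \sum_{i\le j} w'_i - w'_j/2$) of the
  per-variant ratios, with first-order weights
  $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$; consistent while valid
  instruments carry more than half the weight. Its SE is a parametric
  bootstrap (default 1000 replicates, seeded) over the sampling
  distributions of both effect columns.
* **Weighted mode**: the argmax of a normal-kernel weighted density over
  the ratios, bandwidth $h = \phi\,0.9\min(\mathrm{sd},\mathrm{mad})
  k^{-1/5}$; when all ratios coincide the bandwidth degenerates and the
  common ratio is returned directly. Bootstrap SE as for the median.

`mr_leave_one_out()` re-fits IVW omitting each variant, flagging variants
whose omission flips the sign, and `mr_steiger()` compares instrument
variance explained in exposure versus outcome
($r^2_j \approx z_j^2/(z_j^2+n)$, Fisher-z comparison of the summed
$\sqrt{r^2}$) to test whether the instruments act in the assumed direction.
For case-control traits an effective sample size
$n_\mathrm{eff} = 4/(1/n_\mathrm{case}+1/n_\mathrm{control})$ replaces $n$;
a liability-scale refinement using disease prevalence would be more exact
but requires registry inputs, so the $z^2/(z^2+n_\mathrm{eff})$
approximation is the default and a prevalence-based $r^2$ can be supplied
through the same interface if available.

### Multivariable MR

`mvmr_ivw()` regresses the outcome effects on exposure and mediator effects
jointly (no intercept, weights $1/\sigma_Y^2$), giving the *direct* effect
of each exposure. Instrument heterogeneity is summarized by the generalized
Cochran statistic
$Q_a = \sum_j \tilde w_j(\hat\beta_{Yj}-\hat\theta_1\hat\beta_{Xj}-\hat\theta_2\hat\beta_{Mj})^2$
with $\tilde w_j = 1/(\sigma_{Yj}^2+\hat\theta_1^2\sigma_{Xj}^2+\hat\theta_2^2\sigma_{Mj}^2)$
(pairwise covariance taken as zero, as appropriate for non-overlapping
samples), referred to $\chi^2_{k-2}$. Conditional instrument strength for
one exposure given the other minimizes
$Q(\delta)=\sum_j (\hat\beta_{aj}-\delta\hat\beta_{bj})^2/(\sigma_{aj}^2+\delta^2\sigma_{bj}^2)$
over $\delta$ and reports $Q_{\min}/(k-1)$ (a $k-2$ denominator is available
by flag; the two conventions differ by a factor $(k-1)/(k-2)$ and the
package treats $>10$ as adequate under either). Note this statistic is
symmetric between the two exposures by the substitution
$\delta \to 1/\delta$ — a property of the formulation, not a bug. The SE
variance model is not pinned down by the $Q_a$ formula alone; the package
applies multiplicative residual scaling floored at 1, the same convention
as the univariable main model. An all-zero effect column is dropped
(coefficient `NA`, exactly reproducing the univariable estimate for the
other column); genuinely proportional columns raise a collinearity error
rather than returning an arbitrary solution.

### Colocalization

A significant cis-MR association can be driven by a *different* causal
variant in LD. `coloc_abf()` computes the standard single-causal-variant
posterior over five hypotheses (h0 no association, h1/h2 one trait only,
h3 two distinct variants, h4 one shared variant) from per-variant Wakefield
log approximate Bayes factors
$\mathrm{lABF} = \tfrac12[\log(1-r) + r z^2]$, $r = W/(V+W)$, with
effect-scale prior SD 0.15 for continuous traits and 0.2 for log-odds, and
per-variant priors $p_1=p_2=10^{-6}$, $p_{12}=10^{-7}$ (chosen for windows
of a few thousand variants). All accumulation is in log space; the h3 term
$\sum_{i\ne j}BF_{1i}BF_{2j}$ is computed stably as
$\log\!\big(e^{s_1+s_2}-e^{s_{12}}\big)$ with $s_1,s_2,s_{12}$ the
log-sum-exps of lABF₁, lABF₂ and their sum. A single-variant region leaves
h3 with zero mass (logged caveat). `coloc_sensitivity_grid()` repeats the
analysis over 250 kb / 500 kb / 1 Mb / 2 Mb windows around the lead cis
variant (the region is anchored on the lead SNP, not the TSS) and over two
prior sets — $(10^{-6},10^{-6},10^{-7})$ and $(10^{-5},10^{-5},10^{-6})$ —
and calls colocalization *robust* when h4 ≥ 0.8 in the main cell (1 Mb,
tighter priors) and in at least two non-main windows and at least one
non-main prior set. "Robust across multiple windows and priors" is a
qualitative idea; this quantification is the package's own and is recorded
cell by cell so any other rule can be re-evaluated from the grid.

### Effective number of tests

Testing one exposure against thousands of correlated protein levels needs a
multiplicity correction that respects the correlation. From the eigenvalues
$\lambda$ of the protein correlation matrix (estimated by
`estimate_pheno_corr()` as the Pearson correlation of per-variant z-scores
over shared near-null variants, $|z| < 1.96$ in both traits — genuine
associations would otherwise inflate the estimate), `effective_tests()`
reports both spectral estimates: Nyholt
$m_\mathrm{eff} = 1+(m-1)(1-\mathrm{var}(\lambda)/m)$ and Li–Ji
$m_\mathrm{eff} = \sum_i [\mathbb{1}(\lambda_i\ge1)+(\lambda_i-\lfloor\lambda_i\rfloor)]$.
"More conservative" is read as the **larger** $m_\mathrm{eff}$ — the
stricter per-test threshold $\alpha = 0.05/m_\mathrm{eff}$.

## The decision rules

* *Consistent direction* means every computed point estimate shares one
  non-zero sign; an exact zero counts as inconsistent. With fewer than
  three instruments, "all models" means all computable models (Wald or IVW
  only), recorded in the trace.
* A *reverse conflict* requires both sign-consistency across the reverse
  models **and** a reverse main-model p-value below the step's threshold.
  Steps ii and iii use the corrected threshold on both sides. Step i's
  forward rule has no p-threshold of its own, so its reverse arm uses a
  nominal 0.05 (configurable, `reverse_alpha_step_i`).
* Step iv compares UVMR and MVMR on the log-odds scale (odds ratios are
  log-transformed at the interface). The mediation flag is the conjunction:
  unadjusted CI excludes the null, adjusted estimate is attenuated in
  absolute value, adjusted CI overlaps the null. Triples whose sign pattern
  contradicts mediation
  ($\mathrm{sign}(\alpha)\,\mathrm{sign}(\gamma)\ne\mathrm{sign}(\theta_\mathrm{total})$)
  are rejected before MVMR with a trace entry.
* Every verdict carries the rule inputs that produced it (`$reasons`,
  `$trace`, per-step decision tibbles), so each `identified` /
  `mediation_flag` can be re-derived from its recorded components.
* Sex-specific analyses are plain re-runs of the same screen over
  stratum-specific tables; no cross-stratum statistics are computed.

## The synthetic study

`simulate_study()` generates summary statistics directly at the summary
level: true joint (causal) standardized effects $b$ are propagated through
each region's AR-1 LD matrix to expected marginals $\mu = Rb$, and observed
z-scores are $\sqrt{n_\mathrm{eff}}\,\mu$ plus LD-correlated noise,
independent across traits (two-sample designs share no noise). Per-allele
effects use $\mathrm{se} = 1/\sqrt{2f(1-f)n_\mathrm{eff}}$, i.e. continuous
traits live on the inverse-rank-normal per-SD scale (`int_transform()`
provides the Blom-offset transform itself) and the binary outcome on the
log-odds scale with
$n_\mathrm{eff} = 4/(1/n_\mathrm{case}+1/n_\mathrm{control})$. Simulating at
the summary level rather than via individual-level genotypes keeps a full
50-protein study below a second while preserving exactly the statistical
structure the estimators consume.

Default study conditions (the `sim_config()` defaults): one continuous
exposure with 30 QTL regions (per-QTL variance 0.2–1.2%, $n = 100{,}000$ —
the scale of a large adiposity GWAS); 50 proteins at $n = 35{,}000$ (the
scale of a large pQTL study), each with one dominant central cis-QTL
(1–2% variance) plus two minor secondaries at one fifth of that and one
trans-QTL in a shared region — cis regions with a single dominant signal
are the regime in which single-causal-variant colocalization is
well-posed; a case-control outcome of 25,000/25,000 with five QTL regions
of its own so reverse MR is testable; AR-1 LD with $\rho = 0.9$ over
50-variant regions on distinct chromosomes (block-diagonal LD, served
compactly by `ld_blocks()`). The planted causal chain is
exposure → P01 (0.2 SD), P01 → outcome (0.3 log-odds/SD), plus a direct
exposure → outcome effect of 0.005 log-odds/SD: a mostly-mediated total
effect of 0.065. The direct path is deliberately small relative to the
MVMR standard error at these sample sizes because the screen's step-iv
signature — attenuation with the adjusted CI overlapping the null — is the
signature of near-complete mediation; a study whose planted truth
contradicts its own detection criterion would validate nothing. Even so,
the adjusted CI excludes the null in a few percent of replicates (the test
of a true near-null direct effect rejects at its nominal size), which is
why the end-to-end properties are stated as rates over replicates, not
certainties.

What the generator does **not** emulate: realistic human LD maps,
allele-frequency/effect-size coupling, sample overlap between cohorts,
ancestry structure, palindromic alleles (the panel avoids A/T and C/G
pairs; harmonization's palindromic logic is exercised by dedicated
hand-built cases instead), winner's-curse from discovery-stage selection,
and liability-scale subtleties of binary traits. Passing tests therefore
demonstrate the *statistical logic* of the pipeline under its stated
assumptions, not robustness to every pathology of real GWAS data.

## Numerical choices and degenerate inputs

* Harmonization drops palindromic variants whose EAF lies within 0.08 of
  0.5 in either study (or whose EAF is missing); otherwise palindromes are
  oriented by frequency matching. The 0.08 band is a common conservative
  default; the policy is declared, not inferred from any source.
* Proxy lookup uses $r^2 \ge 0.8$ ("LD ≥ 0.8" read as $r^2$; the signed r
  orients the proxy's effect). Both the threshold and the reading are
  configurable.
* Variants missing from the LD matrix are *dropped* during clumping —
  un-assessable is treated as unsafe, not as independent.
* Clumping windows: 10,000 kb at $r^2 = 0.001$ genome-wide; the cis window
  itself (±1 Mb of the TSS, coordinates 1-based) for cis sets. Clump of a
  clump is a no-op; ties in p are resolved by table order.
* Instrument sets with mean F ≤ 10 are flagged weak, not excluded — the
  screen keeps coverage and exposes weakness in the output.
* MVMR clumping priority ranks each variant by the smaller of its exposure
  and mediator p-values.
* Bootstrap SEs default to 1000 replicates; all seeds derive from the run
  configuration and are logged. The mode's bootstrap evaluates its density
  on a 128-point grid (the point estimate uses 512) — the argmax
  quantization this introduces is far below the bootstrap spread.
* Collinearity in MVMR is declared at a weighted-design condition number
  above $10^8$.
* `coloc_priors()` warns (rather than fails) when $p_{12}>\min(p_1,p_2)$.

## Validation

The test suite checks each operation against an independent oracle
(brute-force greedy clumping; `lm()`-based weighted regression; direct
weighted-percentile scans; quadrature of the Bayes-factor integrand;
svd-based spectra), property-style invariants (harmonization involution,
clumping idempotence, orientation and permutation invariances, posterior
normalization, monotonicity of h4 in $p_{12}$), and calibration suites at
moderate replicate counts: IVW CI coverage over 500 correctly specified
replicates, Egger intercept recovery of a planted pleiotropy offset,
weighted-median robustness with 40% invalid instruments, colocalization
medians over 200 shared-variant and 200 null regions, and 100-replicate
end-to-end screens (planted-mediator recovery and global-null control) on
the default 50-protein study. The acceptance script re-runs the same
computations from scratch and writes the resulting numbers as JSON.

## Known limitations

* Single-causal-variant colocalization is brittle when a region carries
  several comparably strong causal variants; no SuSiE-style multi-signal
  extension is provided.
* No MR-PRESSO, contamination-mixture, or LD-aware (generalized IVW)
  estimators; instruments are assumed independent after clumping.
* The phenotype correlation matrix comes from null-ish z-scores, which is
  adequate for threshold correction but is not a metaCCA-style estimator.
* Proxy substitution assumes the proxy tags the target equally well in
  both studies; no allele-frequency sanity check is applied to proxies.
* The simulator's binary-outcome model is the standard log-odds
  approximation with effective sample size, not logistic-regression
  simulation.
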