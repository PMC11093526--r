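---
title: "Genome partitioning of genetic variance with vcpart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome partitioning of genetic variance with vcpart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcpart)
```

## The model

`vcpart` estimates how much of the heritable variation of a quantitative
trait is attributable to each of a set of SNP categories — chromosomes,
functional annotations, MAF bins — which may overlap. It fits the
multi-component linear mixed model

$$
\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{g} + \mathbf{e},\qquad
\mathbf{g} \sim N\!\Big(0,\ \sum_{k=1}^{K}\mathbf{G}_k\eta_k\Big),\qquad
\mathbf{e} \sim N(0,\ \mathbf{R}\sigma_e^2),
$$

where each $\mathbf{G}_k$ is a genomic relationship matrix (GRM)
$\mathbf{Z}_k\mathbf{Z}_k^\top/m_k$ built from the standardized genotypes of
the $m_k$ SNPs in category $k$, and $\mathbf{R}$ is a diagonal residual
structure (all ones by default). The parameter space is *every*
$(\eta_1,\dots,\eta_K,\sigma_e^2)$ for which
$\mathbf{V}=\sum_k\mathbf{G}_k\eta_k+\mathbf{R}\sigma_e^2$ is positive
definite: individual components are allowed to go negative. We deliberately
do not box components at zero — boxing distorts the standard errors and
hides the "exploding gradient" failure signature that genuinely null
components produce (see below).

Estimation is restricted maximum likelihood (REML) by Fisher scoring: the
score of component $k$ is
$\tfrac{\partial \ell}{\partial\theta_k} =
-\tfrac12\left[\mathrm{tr}(\mathbf{P}\mathbf{G}_k) -
\mathbf{y}^\top\mathbf{P}\mathbf{G}_k\mathbf{P}\mathbf{y}\right]$
and the curvature is the Fisher information
$F_{kl}=\tfrac12\,\mathrm{tr}(\mathbf{P}\mathbf{G}_k\mathbf{P}\mathbf{G}_l)$,
with $\mathbf{P}=\mathbf{V}^{-1}-\mathbf{V}^{-1}\mathbf{X}
(\mathbf{X}^\top\mathbf{V}^{-1}\mathbf{X})^{-1}\mathbf{X}^\top\mathbf{V}^{-1}$
and the residual treated as the $(K{+}1)$-th component with structure matrix
$\mathbf{R}$. Standard errors come from the inverse Fisher information at
the optimum; per-category heritability shares are
$h_k^2=\eta_k \bar d_k / (\sum_j \eta_j \bar d_j + \sigma_e^2 \bar d_R)$
with $\bar d$ the mean diagonal of each structure matrix (for standardized
GRMs $\bar d_k\approx 1$), and their standard errors follow from the delta
method. This target population of methods (GCTA-style REML, Haseman–Elston
regression, LD-score regression) is aimed at data with strong, long-range
LD and substantial relatedness — livestock-type populations — where
summary-statistic approximations lose statistical efficiency.

## Stochastic trace estimation

Exact evaluation of the $K{+}1$ trace terms and the $(K{+}1)^2$ Fisher
entries needs dense products with $\mathbf{P}$ and costs $O(KN^3)$ per
iteration, which dominates run time for many components. `vcpart` therefore
offers a stochastic trace mode (the default for large analyses) in the
Monte-Carlo REML family. With $\mathbf{V}=\mathbf{L}\mathbf{L}^\top$ we draw
$B$ model probes $\mathbf{y}_b=\mathbf{L}\mathbf{z}_b$,
$\mathbf{z}_b\sim N(0,\mathbf{I})$, so that $\mathrm{Cov}(\mathbf{y}_b) =
\mathbf{V}$, and use $\mathbf{P}\mathbf{V}\mathbf{P}=\mathbf{P}$ to obtain
unbiased estimators

$$
\widehat{\mathrm{tr}}(\mathbf{P}\mathbf{G}_k)=\frac1B\sum_b
\mathbf{y}_b^\top\mathbf{P}\mathbf{G}_k\mathbf{P}\mathbf{y}_b,\qquad
\widehat{\mathrm{tr}}(\mathbf{P}\mathbf{G}_k\mathbf{P}\mathbf{G}_l)
=\frac1B\sum_b(\mathbf{G}_k\mathbf{P}\mathbf{y}_b)^\top\mathbf{P}
(\mathbf{G}_l\mathbf{P}\mathbf{y}_b).
$$

Model draws were chosen over plain Rademacher probes because the Fisher
estimate is then a Gram matrix — symmetric positive semidefinite by
construction — which keeps every Fisher-scoring step well defined;
Rademacher probes are retained (`probe_set(kind = "rademacher")`,
`stochastic_trace()`) for unit-level checks, where they are exact on
diagonal matrices. Probes are redrawn each iteration from a deterministic
seed sequence, so runs are reproducible while no single probe set can lock
in its Monte-Carlo error. The data-dependent quadratic forms
$\mathbf{y}^\top\mathbf{P}\mathbf{G}_k\mathbf{P}\mathbf{y}$ always use the
actual phenotype and are exact. The default is $B=100$ probes; the
benchmark analyses below use $B=32$, which places the Monte-Carlo jitter of
the estimates at roughly $\mathrm{SE}/\sqrt{B}\approx 0.2$ analytical
standard errors — small relative to sampling noise.

A point worth stating explicitly: the restricted log-likelihood itself,
$-\tfrac12[\log|\mathbf{V}|+\log|\mathbf{X}^\top\mathbf{V}^{-1}\mathbf{X}|
-\log|\mathbf{X}^\top\mathbf{X}|
+\mathbf{y}^\top\mathbf{P}\mathbf{y}]$, contains no trace terms and is
cheap once $\mathbf{V}$ is factorized. The solver therefore evaluates it
*exactly in both trace modes* and uses it for step acceptance and
convergence; only the gradient and curvature are stochastic. (The
$\log|\mathbf{X}^\top\mathbf{X}|$ term makes the criterion exactly
invariant under reparameterizations $\mathbf{X}\to\mathbf{XA}$.)

## Trust-region dogleg safeguarding

Raw Fisher steps frequently leave the positive-definite parameter space in
complex partitionings — especially when a true component is zero, where the
optimum sits on the boundary. Each iteration maximizes the local quadratic
model $g^\top p-\tfrac12 p^\top F p$ over the dogleg path (Cauchy point →
Newton point) within a trust radius; proposals that leave the parameter
space or decrease the exact restricted likelihood shrink the radius
($\times 0.25$) and retry. In exact mode the radius follows the classical
actual/predicted-gain rule (expand $\times 2$ above 0.75 on a boundary
step, shrink below 0.25). In stochastic mode the predicted gain is biased
upward by gradient noise, which would make the classical ratio
systematically under-expand, so the radius instead doubles after any
first-attempt boundary acceptance and shrinks only on rejection. The
initial radius is one tenth of the norm of the starting values.

Defaults: equal "naive" starts ($\eta_k$ summing to half the phenotypic
variance, $\sigma_e^2$ the other half, i.e. a heritability-0.5 start),
at most 50 iterations, convergence on an absolute likelihood gain below
`tol_loglik` (default $10^{-4}$; in stochastic mode a post-rejection crumb
gain does not count — two consecutive sub-tolerance gains, a clean one, or
a collapsed radius are required) or on a scaled Newton step below
`tol_grad`. A gradient norm growing more than tenfold across three
consecutive iterations stops the run with `failure_reason =
"exploding_gradient"`; this heuristic is our operational definition of the
divergence that truly-null variance components produce, and such replicates
are *flagged*, never silently returned. Duplicated or collinear components
(including a component proportional to $\mathbf{R}$, which makes the model
non-identifiable) are detected up front by pairwise cosine similarity of
the structure matrices and reported as `degenerate_model` with the
offending pair named.

## Comparison estimators

For the statistical-efficiency analyses the package implements the
method-of-moments baselines in their projected (Rao) form, with the
quadratic forms taken through
$\tilde{\mathbf{P}} = \tilde{\mathbf{V}}^{-1}-\tilde{\mathbf{V}}^{-1}
\mathbf{X}(\mathbf{X}^\top\tilde{\mathbf{V}}^{-1}\mathbf{X})^{-1}
\mathbf{X}^\top\tilde{\mathbf{V}}^{-1}$ for a working covariance
$\tilde{\mathbf{V}}$:

* `minque(model, prior_vc)` solves
  $\sum_l \mathrm{tr}(\tilde{\mathbf{P}}\mathbf{G}_k\tilde{\mathbf{P}}
  \mathbf{G}_l)\,\theta_l =
  \mathbf{y}^\top\tilde{\mathbf{P}}\mathbf{G}_k\tilde{\mathbf{P}}\mathbf{y}$.
  Its efficiency is best when the prior ratios match the true ones, and
  evaluated at the REML estimates the equations are stationary — iterated
  MINQUE converges to REML. The projected form is what makes both of these
  identities hold exactly; with raw $\tilde{\mathbf{V}}^{-1}$ products on
  pre-adjusted phenotypes they hold only up to $O(p/n)$.
* `he_reg(model)` is MINQUE with an identity working covariance — the
  Haseman–Elston normal equations on covariate-adjusted phenotypes. The
  identity prior is near-optimal only for near-zero heritability or
  near-unrelated samples, which is exactly why it loses efficiency on
  family-structured data.
* `ld_scores()` / `gwas_z()` / `ldsc_fit()` implement the idealized
  LD-score regression chain: in-sample LD scores
  $\ell_j=\sum_m r^2_{jm}$ (optionally bias-adjusted by $(m-1)/N$),
  z-scores $\mathbf{s}=\mathbf{Z}^\top\mathbf{y}/\sqrt{N\hat\sigma_p^2}$,
  and an iteratively reweighted least-squares fit of
  $s_j\sim N(0,\ N\ell_j h^2/M + (1-h^2))$ with weights
  $1/(2(N\ell_jh^2/M+1-h^2)^2)$, iterated to $10^{-6}$ with non-positive
  fitted variances clamped (with a warning). This is the diagonal
  approximation of the full z-score covariance; it is accurate when LD
  decays fast, and degrades under the strong long-range LD the simulator
  can generate — which is the comparison the efficiency suite makes. No
  confounding intercept or reference-panel machinery is included.

## The simulator

`simulate_genotypes()` emulates the statistical features that matter for
these comparisons, not sequence-level biology. Haplotypes are drawn from a
chromosome-wise first-order autoregressive latent Gaussian copula: adjacent
SNPs have latent correlation `ld_rho`, chromosomes are independent, and
each haplotype allele is the indicator of the latent variable falling below
the allele-frequency quantile. This gives cheap, tunable short-range LD and
a uniform MAF spectrum on `maf_range`. Relatedness is optional full-sib
blocks: two unobserved parents per family, each sib inheriting one whole
parental chromosome haplotype per chromosome (no within-chromosome
recombination). `simulate_phenotypes()` draws SNP effects per category $g$
as $N(0, v_g/m_g)$ (a SNP in several categories sums its effects), and sets
the residual variance to $(1-h^2)/h^2\sum_g v_g$ so the heritability equals
its target *in expectation* — per-replicate rescaling would distort the VC
ratios the benchmarks estimate. What this simulator does **not** model:
realistic long-range LD beyond the AR(1) decay, MAF-dependent effect
architectures, selection, non-additive effects, genotyping error. Passing
the recovery suites therefore demonstrates the estimator's correctness
under its own assumptions, not robustness to every feature of real data.

## Benchmark designs and problem sizes

The recovery suites (also recomputed by `scripts/acceptance.R`) follow the
three chromosome scenarios — per-chromosome VCs of (1, 0), (1, 1) and
(1, 2) on the two genome halves, 30 chromosomes, heritability 0.5 — and a
two-category design with a random SNP split and VCs 1 : 4. We run them at
desk scale, chosen so the whole suite fits comfortably in a single-CPU
session while leaving the Monte-Carlo tests well powered: n = 1000
individuals, 3000 SNPs on 30 chromosomes and 30 replicate traits for the
chromosome scenarios; n = 1500, 4000 SNPs and 50 traits for the
two-category design; `ld_rho = 0.5`, MAF ≥ 1%, stochastic trace mode with
B = 32 and `tol_loglik = 1e-3` (a looser-than-default stopping rule whose
residual jitter is an order of magnitude below sampling noise). The
efficiency comparison uses 100 full-sib families of five sibs
(n = 500), 1000 SNPs in two categories, `ld_rho = 0.9` and 100 traits —
strong LD plus relatedness is precisely the regime where the moment
estimators shed efficiency. Checks compare recovered quantities to their
simulated truth within three Monte-Carlo standard errors across replicate
traits; ratios of group means carry delta-method standard errors that
account for the numerator–denominator covariance.

## Numerical and interface choices

* Genotypes are standardized by $\sqrt{2p(1-p)}$ with observed allele
  frequency $p$ (not the observed SD), keeping the expected GRM diagonal at
  1 under Hardy–Weinberg equilibrium; missing genotypes are mean-imputed
  before centering, and monomorphic SNPs are a named error.
* $\mathbf{V}$ is never inverted explicitly; all products go through its
  Cholesky factor. Non-positive-definite proposals are a signalled
  condition that the solver catches — not an error surfaced to the user.
* GRMs are stored packed (row-major lower triangle, float64) in a small
  self-describing binary format with magic `MPHG`; `read_grm(mode =
  "streamed")` exposes row-block access so REML can assemble $\mathbf{V}$
  and form GRM–vector products without ever materializing a GRM
  (`--memory-save` in the CLI), with bit-identical results.
* Individuals are matched across files by PLINK IID string, which must be
  unique; row order never matters. The FID column is preserved as the
  family label but is not part of the key.
* The `exec/vcpart` script exposes the pipeline as subcommands
  (`simulate`, `make-grm`, `reml`, `he-reg`, `minque`, `ldsc`, `compare`);
  every run writes a provenance JSON (seed, options, input digests)
  sufficient to re-execute it.

## Limitations

Single-trait REML only (no bivariate/multivariate models), no AI- or
EM-REML variants, no likelihood-ratio machinery, no sparse or low-rank
$\mathbf{V}$ exploitation. The LDSC implementation is the idealized
in-sample form and is not a re-implementation of published LDSC software.
The exploding-gradient detector is a heuristic; its 10×-over-3-iterations
threshold was fixed a priori and flags rather than repairs boundary
failures — excluding the offending component is the documented remedy.

## A small worked example

```{r example, eval = FALSE}
g <- simulate_genotypes(500, 1500, n_chrom = 10, ld_rho = 0.5, seed = 1)
Z <- standardize(g)
gm <- chrom_group_map(g)
grms <- make_grms(Z, gm)
ph <- simulate_phenotypes(Z, gm,
  sim_scenario(scenario_preset("s2", 10), h2_target = 0.5,
               n_traits = 1, seed = 2))
model <- mixed_model(setNames(ph$trait_1, ph$id), grms)
fit <- run_reml(model, solver_options(trace_mode = "stochastic",
                                      probes = probe_set(100, seed = 3)))
print(fit)
```
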