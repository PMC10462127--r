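---
title: "Detecting differential regulation from spliced and unspliced RNA-seq counts"
author: "diffreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential regulation from spliced and unspliced RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffreg)
```

## The problem

RNA-seq reads can be classified as spliced (mature mRNA) or unspliced
(precursor mRNA).  The relative abundance of unspliced reads within a gene or
transcript, $\pi_U$, is a proxy for nascent transcription: a gene whose
$\pi_U$ is higher in condition B than in condition A is being up-regulated in
B — its expression is about to rise — even if the current spliced abundance
is identical.  **diffreg** tests, per transcript (bulk RNA-seq) or per gene
and cell cluster (single-cell RNA-seq), whether $\pi_U$ differs between two
groups of samples.

The statistical difficulty is quantification uncertainty.  Carrying both
splice versions of every feature doubles the reference, and many reads are
compatible with several (feature, version) pairs.  Aligners summarize this as
*equivalence classes* (ECs): the set of pairs a read is compatible with,
together with a count per sample.  Rather than working with point estimates
of abundance, diffreg treats the origin of every EC read as a latent
variable and integrates over it by MCMC.

## The model

For one group of $N$ samples and $T$ features, two models are combined.
The overall abundance of feature $t$ in sample $i$,
$Y_i(t) = \sum_v X_{vi}(t)$, follows a multinomial across features with
per-sample relative abundances $\rho_i$ (conjugate symmetric Dirichlet(1)
prior; no hierarchy on $\rho$, which is well identified by the data).  The
split of $Y_i(t)$ into splice versions is hierarchical:

* bulk: $X_{Si}(t) \mid \pi_{Si}(t) \sim \mathrm{Bin}(Y_i(t), \pi_{Si}(t))$
  and $\pi_{Si}(t) \mid \delta(t) \sim
  \mathrm{Beta}(\delta_S(t), \delta_U(t))$;
* single-cell: a Dirichlet-multinomial over the three categories spliced /
  unspliced / ambiguous $(S, U, A)$, where ambiguous reads (compatible with
  both versions of the *same* gene) form their own category and are never
  re-allocated between $S$ and $U$ — the probability that an ambiguous read
  is spliced is not identifiable from the data.

The hyper-parameters carry the quantities of interest: the precision
$\delta_+ = \sum_v \delta_v$ measures sample-to-sample stability, and
$\bar\pi = \delta / \delta_+$ is the group-level mean proportion vector.
Groups are compared on $\tilde\pi_U = \bar\pi_U$ (bulk) or
$\tilde\pi_U = \bar\pi_U + 0.5\,\bar\pi_A$ (single-cell; the even split of
ambiguous mass is a convention, which is why the Wald alternative below does
not use it).

Multi-mapping reads are allocated inside the sampler: an EC read compatible
with members $(t_1, v_1), \dots, (t_k, v_k)$ is assigned to member $j$ with
probability proportional to $\rho_i(t_j)\,w_i(t_j, v_j)$.  In the bulk model
the weight is the splice proportion divided by the version's *effective
length*, $w = \pi / \ell$, so that long transcripts are not favoured simply
because they produce more reads; in the single-cell model gene-level
effective lengths are not well defined and $w = \pi$ is used unchanged.
Allocation probabilities are invariant to a global rescaling of the
effective lengths.

## Inference

A Metropolis-within-Gibbs sampler sweeps four blocks:
$\delta \mid \pi$ (adaptive random-walk Metropolis),
$\pi \mid X, \delta$ (exact beta/Dirichlet conjugate draw),
$\rho \mid X$ (exact Dirichlet conjugate draw), and
$X \mid Z, \pi, \rho$ (one multinomial draw per EC and sample).
Defaults: 2,000 iterations with a burn-in of 500.

Numerical and design choices a user may care about:

* **Undersampling.**  The latent allocation is by far the most expensive
  block, and the chain moves little between successive allocations; $X$ is
  therefore refreshed every 10th iteration (`latent_update_every`), while
  the other blocks run every iteration against the last allocation.
* **$\delta$ proposal.**  The random walk operates on
  $(\log \delta_+, \mathrm{alr}(\bar\pi))$ with a per-feature proposal
  covariance adapted from the chain history (scaled empirical covariance,
  $2.38^2/d$, plus $10^{-6}$ jitter), frozen at the end of burn-in so the
  post-burn-in kernel is fixed.  Acceptance ratios include the Jacobian of
  the transform; the prior is Normal on $\log\delta_+$ and flat on
  $\bar\pi$.
* **Boundary handling.**  Proportion draws are clamped to
  $[10^{-12}, 1 - 10^{-12}]$ before the $\delta$-likelihood is evaluated;
  the beta/Dirichlet log-density diverges on the simplex boundary.
* **Empirical-Bayes prior.**  $\log\delta_+$ gets a Normal prior whose
  moments come from up to 1,000 randomly selected features.  Per feature,
  the intraclass correlation $\rho_{\mathrm{ICC}} = 1/(1+\delta_+)$ is
  estimated by a weighted moment estimator with a finite-sample correction,
  from naive counts (EC counts split equally among members — used only
  here).  Maximum likelihood was rejected for this step: with 3–6
  replicates it overstates $\log\delta_+$ by $\approx 0.4$ and diverges to
  the box bound for features that are under-dispersed by chance; the moment
  estimator, aggregated on the correlation scale, is close to unbiased.
  The prior sd is floored at 0.5 and estimates are bounded to
  $\delta_+ \in [10^{-2}, 10^6]$, so the prior stays mild — no single
  feature moves it appreciably.
* **Convergence.**  A Heidelberger–Welch stationarity test runs on the
  post-burn-in trace of $\log p(\delta \mid \pi)$: a Cramér–von Mises
  statistic of the Brownian-bridge functional with the long-run variance
  estimated by a Bartlett lag-window spectral density at zero
  (bandwidth $\approx \sqrt{n}$ lags), discarding 10% prefixes up to 50%.
  The lag-window estimator is used deliberately: AR-fit spectral estimates
  explode on trending traces and make the test blind exactly when it is
  needed.  On failure the burn-in escalates to half the chain; on a second
  failure one chain with doubled length is run; a chain still failing is
  returned flagged `converged = FALSE` — never silently passed.
  Zero-variance traces pass by definition.  `plot_traceplot()` shows the
  per-feature $\tilde\pi_U$ chains for visual inspection.
* **Determinism.**  All randomness flows from one seed; per-group and
  per-cluster seeds are derived from it and from the group/cluster *label*
  (`derive_seed()`), so cluster results are independent of processing
  order, and swapping the two group arguments swaps the chains exactly.

## Comparing groups

Two rankings are produced from the per-group posterior chains:

* $p = \Pr(\tilde\pi_U^B > \tilde\pi_U^A)$, estimated by comparing chains at
  matched iterations (ties count $1/2$, making $p(A,B) = 1 - p(B,A)$ exact;
  an all-pairs estimator is available).  Features are ranked by
  $\max(p, 1-p)$: values near 0 or 1 first, 0.5 last.
* a Wald test from the normal approximation of the posterior of the
  group-level proportions, using posterior means and sample covariances of
  the chains (a mode + Hessian would be ill-defined on an MCMC cloud).  In
  the single-cell model the retained coordinates are
  $(\bar\pi_S, \bar\pi_U)$ — $\bar\pi_A$ is determined by them — giving a
  $\chi^2_2$ statistic.  In the bulk model $\bar\pi_S + \bar\pi_U = 1$, so
  the bivariate covariance is singular by construction and the equivalent
  univariate $\chi^2_1$ test on $\bar\pi_U$ is performed.  Near-singular
  covariances are ridge-regularized with a warning.  Benjamini–Hochberg
  adjusted p-values are attached as a convenience; the method is designed
  for ranking rather than thresholding.

## The synthetic benchmark generator

`sim_scenario()` / `simulate_counts()` generate count-level data with known
truth, and `emulate_multimapping_ecs()` adds EC-level ambiguity, replacing a
read-level simulation.  What is emulated:

* negative-binomial count variability across biological replicates
  (log-normal dispersion, default $\ln \sigma \sim N(-2, 0.5^2)$ — a
  typical bulk RNA-seq range, chosen here as a default rather than
  re-estimated from external data) on top of log-normal baseline abundances;
* beta/Dirichlet sample-level splice proportions with log-normal precision
  (default $\log\delta_+ \sim N(\log 30, 0.5^2)$);
* **DR**: the spliced and unspliced proportions are swapped
  ($\pi_U \to 1 - \pi_U$) in one randomly chosen group — by default 2,000
  transcripts in bulk mode and 20% of genes per cell cluster (distinct
  genes per cluster), matching the benchmark conditions;
* **DGE** (nuisance): one group's mean is multiplied by
  $1 + \mathrm{Exp}(\text{mean\_fc} - 1)$ for 10% of features, so realized
  fold changes average 3, 6 or 9; only the average is pinned down by the
  study design — the exponential shape and the 10% fraction are this
  package's choices;
* **DAS** (nuisance, bulk): within-gene transcript abundances are cyclically
  permuted in one group, preserving gene totals and per-transcript $\pi_U$;
* **batch**: a balanced 2-batch design orthogonal to the groups, with a
  multiplicative abundance shift and a logit shift of $\pi_U$ on a feature
  subset;
* **sparsity** (single-cell): per-sample gene totals are spread
  multinomially over a $(1 - z)$ fraction of cells, $z \in
  \{0.90, 0.95, 0.99\}$, keeping pseudo-bulk totals fixed — which is also
  why results are invariant to $z$ by construction once totals agree;
* **EC ambiguity**: each (feature, version)'s reads split per sample into a
  unique part (probability $1 - p_{\mathrm{multi}}$, default 0.3) and a
  multi-mapping part assigned to an EC joining 2–4 random partners,
  including same-feature spliced/unspliced pairs; reads are conserved
  exactly.

What the generator does **not** emulate: positional/sequence biases, true
read-level alignment noise (EC member sets here are random rather than
driven by sequence similarity), doublets or ambient RNA in single-cell
data, and covariate structure beyond the 2-batch design.  Passing tests on
these simulations therefore demonstrate correctness of the inference
machinery under the model and robustness to the listed nuisances — not
end-to-end performance on real reads.

Default problem sizes in the shipped tests and acceptance script (a few
hundred features, 3+3 or 2+2 samples, 2,000 iterations) were chosen so the
whole suite runs in minutes on one core; power and calibration conclusions
at these sizes transfer qualitatively, not numerically, to genome-scale
data.

## Validation strategy

The test suite checks every layer against something external to it:
conjugate draws against closed-form beta/Dirichlet moments; the
$\delta$-density against `dbeta` and quadrature; the adaptive kernel against
a known Gaussian target; the full chain, in the no-multimapping limit, both
against exact conjugate posteriors (with pinned $\delta$, where stored draws
are iid and a Kolmogorov–Smirnov distance below 0.05 at 1,500 draws is
required) and against an independent random-walk MH sampler written in a
different parameterization; allocation frequencies against analytic
probabilities; ranking and AUROC against brute-force $O(n^2)$ oracles; and
the whole pipeline against its statistical promises — null calibration
(mean $p \approx 0.5$; Wald p-values uniform at the 1/5/10% tails) and
recovery of strong DR effects (AUROC $\geq 0.8$ at 200 features).

## Known limitations

* Covariates are not modelled; batch effects enter only through the
  simulation benchmark.  Because the target is a *relative* abundance,
  overall-expression nuisances (DGE) have limited influence, which the
  DR+DGE scenarios exercise.
* Wald p-values are well calibrated in the rejection tails but their
  mid-range (around 0.5) is rough at small sample sizes — the normal
  approximation to a posterior on a simplex is crude there.  Ranking, the
  intended use, is unaffected.
* The single-cell model is pseudo-bulk: cell-level variability beyond what
  survives aggregation is not used.
* One chain per group is run (with the escalation protocol above); there is
  no multi-chain R-hat diagnostic.

## A worked example

```{r example, eval = FALSE}
scn <- sim_scenario(mode = "bulk", n_features = 200, dr_fraction = 0.1,
                    pi_u = 0.2, seed = 1)
sim <- simulate_counts(scn)
ds  <- emulate_multimapping_ecs(sim, p_multi = 0.3, seed = 1)
fit <- diffreg(ds, mcmc_config(seed = 1))
head(summary(fit))
plot(fit)                      # traceplot of the top-ranked transcript
tr <- sim$truth[match(results(fit)$feature_id, sim$truth$feature_id), ]
score_methods(results(fit)$rank_score, tr$is_dr)$auroc
```
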