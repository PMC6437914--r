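---
title: "Confident effect sizes: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confident effect sizes: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A differential expression analysis of a well-powered experiment routinely
declares thousands of genes significant at 5% FDR. A list ordered by
p-value then front-loads genes whose fold changes are estimated *precisely*,
not genes whose fold changes are *large* — and ordering by the estimated
log2 fold change (LFC) instead front-loads noisy genes, because per-gene
variances in RNA-seq differ by orders of magnitude. This package ranks
genes by a quantity that respects both concerns: a per-gene lower
confidence bound on |LFC|, constructed so that the bounds hold
simultaneously at a chosen FDR.

## The model and the statistic

For gene $i$, let $x_i$ be the estimated LFC, $s_i$ its standard error and
$d$ the degrees of freedom, from the usual per-gene linear model (here, a
two-group mean difference with pooled variance, optionally moderated; see
below). The threshold test with null hypothesis $|\beta_i| \le e$ has
p-value

$$p_i(e) = 1 - F\left(\frac{|x_i| - e}{s_i}\right)
         + 1 - F\left(\frac{|x_i| + e}{s_i}\right),$$

with $F$ the t CDF on $d$ degrees of freedom (`treat_pvalue()`). At
$e = 0$ this is the ordinary two-sided t-test; it is non-decreasing in
$e$ and tends to 1. Because of the monotonicity, the test inverts into a
confidence bound: the largest $e$ with $p_i(e) \le \alpha$ establishes,
with confidence $1 - \alpha$, that the LFC exceeds $e$ (or lies below
$-e$; the sign claim is folded into the bound statement, a small liberty
the construction adopts deliberately). `treat_bound()` performs this
inversion by bisection; "no bound" (`NA`) is distinct from a bound of
exactly zero.

## From fixed $\alpha$ to simultaneous FDR control

`confects()` replaces the fixed $\alpha$ with a dynamic one. For each
threshold $e$ on a grid $0, h, 2h, \dots$ it finds the largest gene set

$$S(e) = \left\{ i : p_i(e) \le \frac{|S(e)|}{n_{\text{gene}}}\, q \right\},$$

which is exactly the Benjamini–Hochberg step-up selection at FDR $q$
applied to the $p_i(e)$. Since every $p_i(e)$ is non-decreasing in $e$,
the sets nest, and the **confect** of gene $i$ is the largest $e$ at
which it is still selected, signed by the sign of $x_i$. Three properties
follow by construction and are enforced as tests:

* $\{i : |c_i| \ge e\} = S(e)$ for every grid threshold: slicing the
  ranking at any depth reproduces a TREAT + BH analysis at that
  threshold, with no threshold chosen in advance.
* $p_i(|c_i|) \le |S(|c_i|)|\, q / n_{\text{gene}}$, which by the
  selected-intervals rule of Benjamini and Yekutieli makes the bounds of
  any such selection valid at false coverage-statement rate $q$
  (`check_fcr()` re-verifies this on every fit).
* $|c_i| \le |x_i|$ whenever $q \le 1/2$, since $p_i(|x_i|) \ge 1/2$.

The total order is: decreasing $|c_i|$; among ties, the p-value at the
first grid threshold at which the gene dropped out of the selection;
genes never selected follow, ordered by $p_i(0)$; genes with no usable
statistics come last. Residual ties break on gene id, so the order is a
deterministic strict total order.

## Tunable parameters

* `fdr` (default 0.05): the only scientifically load-bearing parameter —
  the FDR of every selection the ranking induces, and the FCR of its
  bounds.
* `step` (default 0.01 log2 units): grid resolution. It affects only the
  resolution at which confects are reported; membership of the selection
  at shared grid values is unchanged under refinement (tested). 0.01 is
  below any biologically meaningful LFC distinction.
* `max_e` (default 30 log2 units, a billion-fold change): a safety cap
  guaranteeing termination on degenerate inputs; reaching it flags the
  fit and warns, and the affected genes report a confect truncated at the
  cap (still a valid, merely conservative, bound).

The scan exploits the nesting: each grid step re-tests only the genes
still selected, using the step-up rule with the correction kept relative
to the full $n_{\text{gene}}$, which provably yields the same set as a
full BH pass. The test suite nevertheless compares the scan against an
independent per-threshold BH oracle (and the step-up rule against
brute-force subset enumeration), rather than trusting the argument.

## Variance moderation

With few replicates, per-gene variances are poorly estimated;
`gene_stats()` therefore applies empirical Bayes moderation by default:
a scaled inverse chi-square prior is fitted to the sample variances by
matching moments of their logarithms (the digamma/trigamma inversion
implemented in limma's `squeezeVar`), and each gene's variance is
replaced by the posterior mean
$(d_0 v_0 + d s_g^2) / (d_0 + d)$ on $d + d_0$ degrees of freedom. The
contract guaranteed here — and tested — is the squeezing property (each
posterior variance lies between the sample variance and the prior
variance), recovery of generative prior parameters within 15% at $10^4$
genes, and a smaller mean squared error against true variances than the
raw sample variances. When the log-variance spread is no larger than
expected under a common variance the prior df is infinite; the moderated
df is then capped at $10^6$, where the t distribution is numerically
normal. With fewer than 10 genes moderation is skipped (with a warning):
there is too little information to fit a prior. Genes with zero sample
variance are rescued by the prior when moderation is on; with it off
they have no standard error and rank last, with a warning.

## The simulation harness

`sim_config()` / `run_benchmark()` generate two-group experiments with
the statistical structure the moderated linear model assumes, plus
heteroscedasticity: true variances
$\sigma_i^2 \sim d_w s_w^2 / \chi^2_{d_w}$, true LFCs either scaled-t
($\beta_i / s_b \sim t(d_b)$, power-law tails — preset `sim1`:
$d_w = 2$, $s_w = 0.75$, $d_b = 3$, $s_b = 0.5$, an extreme
heteroscedasticity regime chosen to separate ranking methods) or
Laplace ($\beta_i \sim \mathrm{Laplace}(0, s_b)$, exponential tails —
preset `sim2`: $d_w = 5$, $s_w = 0.5$, $s_b = 0.8$, parameters of the
kind fitted to large tumour–normal comparisons). Observations are
gene-wise independent normals with a group-mean shift — the minimal
observation model consistent with the linear-model framework; the
generative laws do not state baseline means or a noise law beyond this,
so normality is a design choice, documented here. No gene has LFC
exactly zero: the simulations take the estimation view (how large is the
effect?) rather than the dichotomous view (is there an effect?).

The benchmark scores, per ranking method: the proportion of the true
top-$k$ genes (by $|\beta_i|$) recovered in the method's top $k$ — set
overlap, position within the top list not scored, a deliberate reading
of "proportion correct" — and, for bound-producing methods, the achieved
FDR (selected genes whose true $|\beta|$ does not exceed the threshold)
and FCR (wrong sign, or bound magnitude exceeding $|\beta|$) at
thresholds $\{0, 0.5, 1, 1.5, 2\}$. A run with no discoveries
contributes a rate of 0, the convention under which the average over
runs estimates the controlled expectation. Default problem sizes are
desk-scale — 2000 genes, 20 Monte Carlo runs, chosen so a full benchmark
completes in about a minute on one core while keeping Monte Carlo
standard errors a small fraction of the 5% nominal level; all sizes
scale up through `sim_config()` arguments.

What passing these benchmarks does *not* show about real data: real
RNA-seq has correlated genes (the harness assumes independence, as does
the BH argument), mean–variance dependence handled upstream by
count-model pipelines, library-size and composition effects, and
outliers; the harness validates the inferential machinery, not those
preprocessing steps, which are out of scope here.

## Seven rankings compared

`rank_genes()` implements, under one registry: p-value order; confect
order; inner ends of unadjusted and of Bonferroni (5% FWER) confidence
intervals, with interval-spans-zero genes falling back to p-value order;
TREAT p-value order at fixed thresholds 1 and 5; and |estimated LFC|
order. Tie rules (absolute effect, then standard error, then gene id)
are not part of any method's definition; they are fixed here so
benchmarks are exactly reproducible. The benchmark reproduces the
qualitative picture that motivates the method: unadjusted CI bounds do
not control FDR/FCR under strong heteroscedasticity (achieved FCR
several-fold above nominal in the `sim1` regime), FWER-adjusted bounds
control both but over-correct, and the confect ranking recovers more of
the truly largest genes than either the p-value or the |LFC| ranking
when variances are heterogeneous.

## Numerical choices

* Tail terms use the t survival function directly, never $1 - F$, so
  p-values near $10^{-300}$ remain meaningful ranking keys.
* Bisection for `treat_bound()` runs on $[0, |x| + 50 s]$ (the p-value
  at the right end provably exceeds any $\alpha < 0.5$; the bracket is
  doubled otherwise) to absolute tolerance $10^{-6}$.
* A selection threshold queried between grid points rounds *up* to the
  next grid point: the selection never claims a gene cleared a threshold
  it was not tested at.
* A confect of exactly zero is a real statement (the gene is in $S(0)$:
  nonzero LFC of known sign, but no magnitude claim) and is kept
  distinct from "no confect" (`NA`).
* An effect of exactly zero that is nonetheless selected at $e = 0$
  would have sign 0; this requires $p_i(0) = 1$ to pass the BH cut and
  is effectively impossible, but the code tolerates it.

## Known limitations

Only the two-group design is built in; arbitrary design matrices,
paired designs, precision weights and count-model normalisation belong
to upstream tooling, whose per-gene effect/se/df output this package
accepts as a statistics table. The FDR guarantee inherits the BH
independence assumption. The method is conservative by construction —
achieved error rates in the benchmark sit well below the nominal level —
because the threshold test must guard the worst case at the null
boundary and the bounds must be simultaneously valid across all
thresholds; the cost is missed borderline discoveries, not false ones.
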