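---
title: "Multi-trait subset scanning: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait subset scanning: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## The problem

A single genetic variant (or a weighted genetic score such as a polygenic
risk score or imputed gene expression) is tested against many traits at
once — dozens to thousands, as in a deeply phenotyped biobank. PheWAS-style
one-trait-at-a-time testing with Bonferroni correction answers "is any trait
associated?", but loses power when several traits carry modest signal and
gives no principled notion of *which subset* of traits is jointly most
anomalous. `pleioscan` scans over trait subsets: it finds the subset that
maximizes an anomalousness score and tests whether that maximum is larger
than expected under the global null of no association.

## Model and decorrelation

For trait $j = 1, \dots, p$ the marginal GWAS model is $y_j = x\beta_j +
\epsilon_j$ with rows of the error matrix iid $\mathrm{MVN}(0, \Sigma)$.
Only summary statistics are needed: the Wald z-scores $z_j =
\hat\beta_j / \mathrm{se}(\hat\beta_j)$. Because traits are correlated and
cohorts overlap, the $z_j$ are correlated under the null; their correlation
equals the trait correlation scaled by sample overlap,
$\mathrm{cor}(z_{j_1}, z_{j_2}) = (n_{12}/\sqrt{n_1 n_2})\,\sigma_{j_1 j_2}$,
and is estimated empirically as the Pearson correlation of z-scores over
*null SNPs* (variants with $p > 0.05$ for every trait). Binary traits enter
through the small-effect Taylor linearization of the logistic model, so
their z-scores are used exactly like continuous ones.

The estimated correlation matrix $R$ is repaired to positive definiteness by
eigenvalue clipping (floor $10^{-8}$, then diagonal renormalization) — the
whitening step needs an invertible square root. The z-vector is then
whitened with the ZCA-cor transform $z^* = R^{-1/2} z$, the unique
*symmetric* inverse square root. Among all whitening transforms $Q R^{-1/2}$
(any rotation $Q$), the symmetric one maximizes $\sum_j
\mathrm{cor}(z^*_j, z_j) = \mathrm{tr}(Q R^{1/2})$, keeping each whitened
coordinate maximally attached to its original trait. The per-trait
correlation $\mathrm{cor}(z^*_j, z_j) = (R^{1/2})_{jj}$ is always reported;
traits below a configurable threshold (default 0.7) are *flagged* as hard to
interpret, never silently removed. Users scanning heavily correlated trait
collections can optionally prune near-duplicates (`max_abs_cor`), which
trades interpretability for the power that is otherwise lost when whitening
shifts the means of correlated associated traits toward zero; pruning is off
by default because no universal threshold exists.

## Score functions and the linear-time scan

Two score functions operate on the whitened values over a shared grid of
thresholds: a geometric sequence of $L = 200$ p-value thresholds
$\alpha_1 = 0.05/p, \dots, \alpha_{200} = 0.05$, with matched z-thresholds
$\gamma_i = \Phi^{-1}(1 - \alpha_i/2)$. The lower endpoint makes the scan at
least as powerful as Bonferroni PheWAS for independent traits; the upper
endpoint caps the search space.

**Higher criticism (HC).** With $N_\alpha(S) = \#\{j \in S : p^*_j <
\alpha\}$ (strict), $F_{HC,\alpha}(S) = (N_\alpha(S) - \alpha|S|) /
\sqrt{|S|\alpha(1-\alpha)}$: the standardized excess of small p-values.
Powerful for sparse signal.

**Truncated chi-squared (TC).** With $M_\gamma(S) = \sum_{j \in S}
I(|z^*_j| > \gamma)\, z^{*2}_j$, the score is $F_{TC,\gamma}(S) = -\log
P(M \ge m \mid H_0)$, which also weighs the *strength* of the exceedances;
more robust when signal is denser.

Both priority functions ($I(p^* < \alpha)$ and $I(|z^*| > \gamma) z^{*2}$)
satisfy the strong linear-time-subset-scan property: at each grid value the
optimal subset is a prefix of the priority-sorted traits, so the $2^p - 1$
subsets collapse to $p$ prefixes per threshold. The test suite verifies
this against a genuinely exhaustive search at $p \le 8$ over the full grid,
demanding bitwise score equality. Ties in the priority sort are broken by
ascending $p^*$ (HC) / descending $z^{*2}$ (TC), then ascending trait index;
grid-level ties keep the smallest grid index. The selected subset always
contains at least one trait, so an all-null vector returns a singleton with
statistic 0 (TC) or the negative no-signal value (HC).

### Evaluating the TC null tail

$F_{TC}$ needs $P(M_k \ge m)$ where $M_k$ sums $k$ iid terms, each 0 with
probability $1 - a$ ($a = P(|z| > \gamma)$) and otherwise a
$\gamma^2$-left-truncated $\chi^2_1$. The default evaluator is a
deterministic binomial mixture over the number of exceedances $j$:

* $j = 1$ in closed form, $P = 2(1 - \Phi(\max(\gamma, \sqrt m)))/a$;
* $2 \le j \le 25$ by $j$-fold convolution of the truncated density on a
  4096-point lattice (power-of-two padded FFT), with linear interpolation of
  the survival function and all off-lattice mass assigned to the tail. The
  lattice span depends only on $(\gamma,$ a power-of-two bucket of $m)$, so
  evaluations are history-free and reproducible;
* $j > 25$ by a three-moment shifted-gamma approximation (exact partial
  moments of the truncated $\chi^2_1$).

A seeded Monte-Carlo evaluator (`method = "mc"`, 200 000 draws per cell) is
kept as a cross-validation oracle; the two agree within Monte-Carlo error.
Absolute accuracy of the tail only affects the *ranking* of subsets — final
p-values are calibrated by the outer Monte-Carlo null — so the lattice
resolution is chosen for speed with accuracy to spare.

## Significance

Under $H_0$ the whitened scores are iid standard normal, so the null law of
$(H_{HC}, H_{TC})$ depends only on $(p, \text{grid})$. It is simulated once
($B = 10\,000$ by default), cached in memory and optionally on disk, and
reused across variants.

**Tie handling (a deliberate deviation).** Both statistics are discrete.
$H_{HC}$ in particular has an atom of mass $1 - (1 - 0.05/p)^p \approx
0.049$ at its top value — the event that exactly one $p^*$ falls below
$\alpha_1$ — sitting immediately below the 5% boundary. A tie-inclusive
empirical p-value $(\#\{h_b \ge h\} + 1)/(B+1)$ pushes that entire atom just
above 0.05 and collapses the size of the HC test at level 0.05 to a few per
mille. The default convention is therefore the strict-exceedance count
$(\#\{h_b > h\} + 1)/(B+1)$, whose measured size at level 0.05 is ~0.053 at
$p = 20$; the tie-inclusive `"conservative"` convention and the literal
complement form (`eq13`) remain available. A corollary: mid-range p-values
are lumpy (an all-zero z-vector at $p = 5$ gets $p \approx 0.23$, the
probability that a null draw has any exceedance at all), which is irrelevant
at conventional significance levels but visible if you expect $p \approx 1$.

The HC p-value can also be computed analytically: $H_{HC} > h$ iff the
uniform-order-statistics counting process crosses the boundary
$N_{\alpha_i} \ge \lfloor h^2 \alpha_i/(1 - \alpha_i)\rfloor + 1$ at some
grid threshold, a non-crossing probability evaluated exactly by a Markov
recursion on the counts (conditionally binomial increments between
thresholds, only constraining thresholds processed). It matches the
Monte-Carlo tail within 3 standard errors at $B = 10^5$ for
$p \in \{5, 20, 50\}$ and is the default for $p \le 5000$.

**Combined test.** The reported combined statistic is $\min(p_{HC},
p_{TC})$. Its null preserves the HC/TC dependence: every null draw is
converted to a pair of pooled pseudo p-values (strict exceedance counts
against all $B$ draws — a draw is never its own tie, keeping the observed
variant exchangeable with the draws) and the per-draw minima form the
combined null. Equal $p_{HC}$ and $p_{TC}$ award the selected subset to HC
(a fixed, documented rule). The combined p-value is bounded below by
$1/(B+1)$.

## Genetic scores

For a score $X_{gs} = \sum_l c_l X_l$ over $q$ SNPs, the score-level
regression statistics for each trait are reconstructed from per-SNP summary
statistics plus a reference panel: $X_{gs}^T X_{gs} = n\, c^T \hat C c$ with
$\hat C$ the covariance of centred reference dosages ($1/(n_{ref}-1)$
denominator), $(X^T y)_l = n \hat s_l^2 \hat\beta_{jl}$, and $y^T y$ from
the per-SNP OLS identity $n^2 \hat s_l^2 \mathrm{se}^2_l + n \hat s_l^2
\hat\beta_l^2$ aggregated by the median over the score's SNPs (a wider SNP
list can be supplied). The residual degrees of freedom are $n - q$ as in
the summary-statistic derivation (a flag switches to $n - 1$, the value a
single-predictor regression would use; at GWAS sample sizes the difference
is negligible). Binary traits are first moved to the linear scale by the
factor $r/(1+r)^2$, $r = n_{control}/n_{case}$, which leaves z-scores
exactly invariant. Because the score behaves as a single composite variant,
the same trait correlation matrix calibrates the scan. Inconsistent inputs
that would make the implied residual variance negative raise a diagnostic
error rather than a complex standard error. Allele harmonization flips
dosages ($d \to 2 - d$) and effect signs when effect/other alleles are
swapped; strand-ambiguous (A/T, C/G) sites are kept with a warning since,
without frequency information, no automatic resolution is safe.

## The synthetic-data generator

One replicate draws $x \sim \mathrm{Binomial}(2, \mathrm{maf})$ per
individual, errors row-iid $\mathrm{MVN}(0, \Sigma)$, sets $Y = x\beta +
\epsilon$ with centred columns, and computes marginal OLS (or logistic)
summary statistics. Binary traits threshold the latent column at a
configurable prevalence (default 0.5, the least-information case). The
generator emulates: correlated trait errors, genuine genotype sampling
noise, and designated truly-associated subsets. It does **not** emulate
linkage disequilibrium between variants, confounding/stratification,
heritability heterogeneity, or real biobank trait distributions — so a
green simulation test establishes calibration and relative power under the
stated model, not performance on any particular cohort. The shipped
754-trait covariance stand-in (`synthetic_biobank_sigma()`) is synthetic:
random correlated blocks plus weak global correlation, matching dimensions
only.

Scenario defaults (`scenario_config()`): the sparse preset uses 2
associated traits among $p = 50$ exchangeable traits ($\rho = 0.3$) with
per-trait expected $|z| = 4$ — strong but unsaturated, so power differences
are visible; the dense preset gives all 50 traits homogeneous effects with
expected $|z| = 2.5$, individually sub-significant. The underlying
evaluation design fixes only the qualitative orderings these presets
reproduce (scan tests beat PheWAS under sparsity; PheWAS wins under dense
homogeneous effects); the numeric effect sizes are this package's own
choices, stated in z-units because that is the scale on which power is
determined ($\beta = z/\sqrt{n \cdot 2\,\mathrm{maf}(1 - \mathrm{maf})}$).
Power is the rejection rate against a null distribution simulated once and
shared across replicates; per-replicate seeds derive from the master seed
by a counter.

## Numerical and API conventions

* Strict inequalities $p^* < \alpha$, $|z^*| > \gamma$ throughout, as the
  indicator definitions require; boundary values are excluded.
* $p^*$ is clipped below at the smallest positive normalized double so
  logs stay finite.
* Missing z at the scanned variant: the trait is dropped with a warning and
  the default grid lower bound is recomputed for the effective $p$.
* Null-SNP selection defaults to the all-traits filter ($p > 0.05$ for
  every trait); a pairwise (`per_trait`) mask is available. Null SNPs are
  assumed approximately independent; optional every-$m$-th thinning is
  exposed, no LD pruning is performed.
* Everything is a pure function of (inputs, seed); the CLI emits a JSON
  manifest (inputs digests, options, seed, version, timing) per run.

## Known limitations

* The strict tie convention makes the tests very slightly anti-conservative
  at exactly the atom boundaries (size ~0.053 at level 0.05 for $p = 20$);
  the `"conservative"` flag restores guaranteed validity at the price of
  near-zero power at level 0.05 for HC.
* The analytic HC tail falls back to Monte-Carlo above $p = 5000$.
* TC tail values for subsets with more than 25 exceedances use a
  moment-matched approximation; rankings there are approximate, p-values
  remain exactly calibrated by the Monte-Carlo null.
* No harmonization against variant databases, no liftover, no INFO-score
  filtering; VCF dosages use hard genotypes unless a DS field is present.
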