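---
title: "Adaptive testing with testlets: model, selection rule, and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive testing with testlets: model, selection rule, and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Large-scale assessments bundle items into *testlets* — sets of items sharing a
stimulus such as a reading passage. Items within a testlet remain correlated
after conditioning on the measured abilities (*local item dependence*, LID).
Scoring such data with a model that ignores LID overstates test information
and understates standard errors. Multidimensional adaptive testing (MAT), in
turn, is the most efficient way to measure several correlated abilities at
once, but its classical selection rules are defined at the item level and have
no notion of a testlet.

`testletMAT` implements the combination of the two: a multidimensional 3PL
model with person-specific random testlet effects, used both for D-optimal
selection of whole testlets and for ability estimation.

## The response model

For person $j$ with ability vector $\theta_j \in \mathbb{R}^P$, an item $i$
with loading vector $a_i$, difficulty $b_i$, guessing parameter $c_i$, nested
in testlet $d(i)$:

$$P(U_{ij}=1) \;=\; c_i + (1-c_i)\,
  \mathrm{logistic}\!\left\{a_i'(\theta_j - b_i\mathbf{1} -
  \gamma_{jd(i)}\mathbf{1})\right\}.$$

The testlet effect $\gamma_{jd}$ is a person-specific nuisance dimension
shared by the items of testlet $d$; $\gamma_{jd} \sim N(0, \sigma^2_{\gamma
d})$, independent across testlets and of $\theta$. $\sigma^2_{\gamma d}$
indexes the severity of LID in testlet $d$. Setting all $\gamma = 0$ recovers
the ordinary multidimensional 3PL; fixing $c=0$ and $a \in \{0,1\}^P$ gives
the Rasch version used in the simulation design. Note that $b$ and $\gamma$
are multiplied by $\mathbf{1}$, so for an item loading on several dimensions
the exponent is $a'\theta - (b+\gamma)\sum_p a_p$; the package implements this
literal form (`prob_mtirt()`), so multidimensionally loading items are
supported even though the shipped generators use simple structure.

## Testlet selection by D-optimality

After $v$ testlets have been answered the parameter vector is
$(\theta, \gamma_1, \dots, \gamma_v)$. Two matrices grow with the test:

* the **expanded prior covariance** $\Phi_v$ (`expand_prior()`): the $P \times
  P$ ability covariance $\Phi$ in the upper-left block and the answered
  testlets' variances on the remaining diagonal; all cross blocks are zero
  because the effects are independent of the abilities;
* the **expanded information matrix** $I_v(\theta,\gamma)$ (`info_matrix()`):
  Fisher information of the answered items at the provisional estimates, with
  an ability block, a diagonal testlet block (no item belongs to two
  testlets), and a signed cross block. All blocks use the outer product of
  first derivatives over the Bernoulli variance, $(\partial P/\partial
  \xi_r)(\partial P/\partial \xi_s)/(PQ)$ — the negative expected Hessian of
  the log-likelihood, validated against finite-difference Hessians in the
  test suite. Because $\gamma$ enters the exponent negatively, the
  $\gamma$-by-$\theta$ cross entries are negative for positively loading
  items.

The next testlet is the candidate $d^*$ maximizing

$$\left|\,\Phi_v^{-1} + I_v(\theta,\gamma) + I_v(\theta, u_{d^*})\,\right|,$$

the determinant rule that shrinks the credibility ellipsoid of the current
estimate the most. A candidate's own effect is unknown before it is answered,
so its information is evaluated at $\gamma_{d^*}=0$ — for candidate scoring
the testlet model and the plain multidimensional model coincide, which keeps
selection no more expensive than classical MAT. Candidate item information is
aggregated by the sum by default; `info_mode = "mean"` is provided for pools
mixing testlet sizes, where the sum mechanically favours long testlets.

Numerical choices: the determinant is computed as a log-determinant of the
rank-$P$ update $\det(I_P + C\,[W^{-1}]_{\theta\theta})$, where $C$ is the
candidate's ability-block information — algebraically identical to the full
determinant (verified against brute-force enumeration in the tests) and
stable; exact ties break to the lowest testlet id so that seeded runs are
bit-reproducible; a candidate whose update is not positive definite scores
$-\infty$. Exponents are clipped at $\pm 35$ before exponentiation.

## Estimation

**During the test** (`bayes_modal()`): the provisional $(\hat\theta,
\hat\gamma)$ is the posterior mode under the $N(0, \Phi_v)$ prior, found by
Fisher scoring, $x \leftarrow x + (\Phi_v^{-1} + I_v)^{-1}\nabla$, with step
halving. The grid-search and general-purpose-optimizer oracles in the test
suite pin this down to $10^{-3}$. The generating $\Phi$ and
$\sigma^2_{\gamma d}$ are treated as known during administration, mirroring
operational practice where item and population parameters come from a prior
calibration; a zero testlet variance is floored at $10^{-6}$ when inverting
$\Phi_v$, which pins the corresponding effect at zero and reduces the
machinery to the no-LID case.

**Final scaling** (`mcmc_scale()`): a Metropolis-within-Gibbs sampler with
item parameters fixed. Abilities are updated component-wise by adaptive
random-walk Metropolis (only the rows loading on the updated dimension are
touched, so a full sweep costs one pass over the data); each person-testlet
effect likewise. The ability covariance has an inverse-Wishart prior
(identity scale, 9 degrees of freedom — the df the study design names; the
scale must be proper, and the identity is the weakest standard choice) and is
drawn from its conjugate full conditional. Each testlet variance has an
$\mathrm{IG}(k, s)$ prior with $k = s = 0.001$ (the standard reading of
"shape and rate near zero") and a conjugate draw.

Two departures from a textbook Gibbs sampler are deliberate:

* **Interweaving.** With only 3–9 items per person-testlet cell the centered
  conjugate update for $\sigma^2_{\gamma d}$ mixes very slowly. After each
  conjugate draw the sampler therefore re-proposes $\log \sigma^2_{\gamma d}$
  with $\eta = \gamma/\sigma$ held fixed (the non-centered parameterization),
  rescaling all of the testlet's effects at once. This changes nothing about
  the target distribution — the suite cross-checks the whole sampler against
  an independent JAGS fit of the identical model on identical data.
* **Prior truncation.** $\mathrm{IG}(0.001, 0.001)$ is nearly scale-invariant.
  A testlet answered by a handful of persons whose response patterns carry no
  information about its variance then has an almost flat posterior in $\log
  \sigma^2$, and its chain drifts without bound. The prior is truncated at
  `sigma2_max = 100` — far above any realistic LID variance, inert for any
  identified testlet, and it keeps the prior proper.

Burn-in is extended in blocks until the Geweke statistic (first 10% vs last
50% of the current candidate window, spectral variance from an AR fit) is
inside $\pm 1.96$ for every monitored parameter — all reportable testlet
variances, the ability covariance entries, and ten sentinel abilities — or a
cap is reached. With on the order of a hundred monitored parameters a
simultaneous $\pm 1.96$ band is rarely satisfied at short cap settings; the
sampler then warns, reports the failure in its convergence summary, and emits
estimates from the capped burn-in, which is the documented contract. Point
estimates are means over the retained window (500 iterations by default).
`chain_config(n_sweeps = )` runs extra latent scans per stored iteration,
which lowers the autocorrelation of the retained draws and hence the
Monte-Carlo noise of EAP summaries at proportional cost.

**Difficulty recalibration** (`mml_calibrate_difficulties()`): when
testlet-generated data are scored with the no-testlet model, the difficulty
scale shrinks. The scaling factor is obtained exactly as a practitioner
would: simulate full-pool data, recalibrate difficulties under the plain
model by Bock–Aitkin marginal maximum likelihood (EM over Gauss–Hermite
quadrature, run per dimension — valid under simple structure with standard
normal marginals; 41 nodes by default), and regress the recalibrated on the
generating difficulties. The slope is compared in the tests both with the
published factors and with the logit-probit closed form $(1 +
\sigma^2_\gamma/1.7^2)^{-1/2}$.

## The synthetic study

`generate_pool()` builds the design's pool: three ability dimensions, 108
Rasch items each, simple structure, difficulties uniform on $(-4, 4)$ —
a pool a test developer would aim for, with items available across the
ability range. Items are ranked by difficulty within their dimension and
chunked into consecutive groups of 3, 6 and 9 to form the three testlet
partitions; testlet-mates therefore share a dimension and have homogeneous
difficulties, which maximizes the adaptivity a testlet-level selector can
achieve. Rank chunking is done within dimension: the alternative (ranking
across dimensions) would create testlets mixing dimensions, contradicting the
between-item multidimensional structure of the design. Abilities are
multivariate normal with unit variances and latent correlations of 0.80, a
conservative representation of the correlations among achievement domains;
testlet effects are $N(0, \sigma^2_\gamma)$ with $\sigma^2_\gamma \in \{0,
0.5, 1.0, 1.5\}$, from no LID to strong-but-realistic LID. Tests are 54 items
long (18, 9 or 6 testlets), i.e. 17% of the pool.

`run_condition()` executes one design cell: generate truth, administer every
person adaptively (MAT) or by drawing whole testlets uniformly without
replacement (RAN), then final-scale the collected responses by MCMC and
summarize the dimension-averaged mean squared error of the EAP abilities and
the recovery of the testlet variances. Under the misspecified scoring model
("MIRT") the responses are still generated from the testlet model, but
selection, provisional scoring and final scaling use the shrinkage-rescaled
difficulties and no $\gamma$ dimensions. Under random selection the
provisional estimates never influence which testlet comes next, so
`run_condition()` switches provisional scoring off there; a test verifies the
administered record is identical either way.

Replication summaries report the across-replication mean and standard
deviation. `run_study(matched_seeds = TRUE)` (the default) gives the same
replication of every condition the same generating seed, so between-condition
contrasts — the study's actual questions — are paired comparisons.

### Scaled-down profiles and what they show

The full design (5 000 persons, 10 replications, burn-in determined by the
Geweke criterion up to 80 000 iterations) is a cluster-scale computation. The
shipped test suite and `scripts/acceptance.R` run the identical machinery at
reduced scale: 200–500 persons per condition under adaptive selection (up to
1 000 under random selection), 1–2 replications, burn-in capped at 2 500–5 000
with the last 500 iterations retained. Difficulty-recalibration checks run at
the full N = 5000, where they are cheap.

Two small-sample phenomena are worth knowing about when reading reduced-scale
results, because they are properties of the posterior, not of the code — both
persist identically under an independent JAGS fit:

* with 3-item testlets each person-testlet cell pins its effect down only
  weakly, so posterior means of $\sigma^2_\gamma$ are pulled toward the
  prior's bulk: upward when the truth is 0, downward by roughly 0.1 at truth
  0.5 under random selection at a few hundred persons. Adaptive selection
  suffers less (it administers testlets where they are informative).
  The condition summary therefore weights each testlet's posterior mean by
  the number of persons answering it and skips testlets below
  `monitor_min_persons` (default 20), whose near-flat posteriors have no
  meaningful mean; at full scale every testlet is abundantly answered and the
  summary reduces to the plain average;
* EAP estimates from a 500-iteration window carry Monte-Carlo noise
  proportional to the posterior variance times the draw autocorrelation,
  which inflates reduced-scale MSEs by several percent in the hardest cells
  (large testlets, large effect variance); `n_sweeps = 2` halves this at
  modest cost and is used for the acceptance runs.

## Limitations

Polytomous items, the bi-factor parameterization with free testlet slopes,
alternative selection rules (Kullback–Leibler, mutual information), exposure
control and content balancing are out of scope. Item parameters are treated
as known throughout administration and final scaling; the package calibrates
difficulties (for the shrinkage correction) but not discriminations or
guessing parameters. The sampler requires a proper, if weak, prior scale for
the ability covariance; users who need the covariance fixed can compare runs
at different priors, but a hard-fix switch is not part of the sampler's
surface.
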