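---
title: "Methods: cumulative logistic multidimensional data analysis"
author: "clmda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative logistic multidimensional data analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clmda)
```

## The model family

For N observations on R ordinal responses, response $r$ having ordered
categories $1,\dots,C_r$, the package assumes a continuous logistic latent
variable behind every cell: $z_{ir} = \theta_{ir} + \epsilon_{ir}$ with
standard-logistic errors, observed as $y_{ir} = c$ when $z_{ir}$ falls
between the thresholds $\tau_{r,c-1}$ and $\tau_{rc}$
($\tau_{r0}=-\infty$, $\tau_{rC_r}=+\infty$).  Hence

$$P(y_{ir} \le c) = F(\tau_{rc} - \theta_{ir}),$$

the cumulative logit / proportional-odds form: thresholds are category
specific, the structural part is variable specific, and cumulative
log-odds ratios between two observations do not depend on $c$.

The structural part is geometric.  *Dominance* responses (monotone in the
latent trait; cognitive items) use inner products,
$\theta_{ir} = u_i'v_r$; *proximity* responses (single-peaked; attitude
items) use negated Euclidean distances, $\theta_{ir} = -\|u_i - v_r\|$,
which are nonpositive by construction — so for proximity models the coding
direction of the categories matters, while for dominance models reversing
the coding only flips signs.  With predictors the row scores are
restricted to $U = XB$, giving the reduced-rank (CLRRR) and restricted
unfolding (CLRMDU) variants.  Because distances shrink the structural
part toward zero from above, proximity thresholds live on the negative
half-axis; the population fixtures below reflect that.

## The EMM algorithm

The observed-data deviance $-2\sum_{ir}\log p_{ir,y_{ir}}$ is minimized
by an expectation–majorization–minimization loop; each outer iteration
has three parts.

**E-step.**  Conditional on $y_{ir}=c$ the latent variable is logistic
truncated to $(\tau_{r,c-1},\tau_{rc})$.  Since $F(z-\theta)$ is uniform
on $(\lambda_{ir,c-1},\lambda_{irc})$ given the interval, the expected
gradient of the complete-data negative log density has the closed form

$$g_{ir} = 1 - \lambda_{ir,c-1} - \lambda_{irc},
  \qquad \lambda_{irc} = F(\tau_{rc}-\theta_{ir}).$$

The test suite verifies this against adaptive quadrature of the
truncated-logistic integrand to $10^{-8}$.

**Majorization.**  The second derivative of the complete-data objective is
$2f(z-\theta) \le 1/2$ because the logistic density is at most $1/4$.
Bounding the curvature turns the expected objective into the quadratic
$\tfrac14\sum_{ir}(\tilde z_{ir} - \theta_{ir})^2 + \text{const}$ with
working responses

$$\tilde z_{ir} = \theta_{ir} - 2\,g_{ir},$$

so the M-step is ordinary least squares.  The suite checks that this
quadratic touches the quadrature-evaluated expected objective at the
current point and dominates it elsewhere.

**M-step.**  One least-squares update per representation:

* *CLPCA*: truncated SVD $\tilde Z = P\Phi Q'$, $U = P_S\Phi_S$,
  $V = Q_S$ (Eckart–Young).
* *CLRRR*: generalized SVD in the $X'X$ metric via the thin QR
  decomposition $X = QR$: SVD of $Q'\tilde Z$, then
  $B = R^{-1}P_S\Phi_S$, $V = Q_{2,S}$.  With $X = I$ this reduces
  exactly to the CLPCA update — the reason for splitting the singular
  values into the left factor.
* *CLMDU*: the working dissimilarities $\delta_{ir} = -\tilde z_{ir}$ can
  be negative; the raw-STRESS majorization is extended by the
  negative-dissimilarity device: adjusted dissimilarities
  $a_{ir}=\max(\delta_{ir},0)$ and weights
  $w_{ir} = 1 + |\delta_{ir}|/\max(d_{ir},\varepsilon)$ where
  $\delta_{ir}<0$ (else 1), both recomputed every iteration, followed by
  one Guttman-type alternating update of $U$ then $V$.  When all
  dissimilarities are nonnegative this is the standard least-squares
  unfolding system.
* *CLRMDU*: the $U$-update is replaced by the normal-equation solve for
  $B$ in the column space of $X$, then $U = XB$ before the $V$-update.

Thresholds are then re-estimated per response by maximum likelihood with
$\theta_r$ as a fixed offset (coefficient one, no other covariates) — a
Newton iteration in the unconstrained $(\tau_1,\log\text{-gaps})$
parametrization with analytic gradient and tridiagonal Hessian, step
halving, and a gradient-norm tolerance of $10^{-8}$; `MASS::polr` with an
offset serves as the cross-check oracle in the tests.  Each part weakly
decreases the observed deviance, so the trace is monotone; the suite
asserts this per iteration across all four families.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tol` | 1e-6 | relative deviance change declaring convergence |
| `maxit` | 5000 | outer EMM iterations |
| `inner` | 1 | structural sweeps per outer iteration (distance models) |
| `starts_proximity` | 10 | 1 deterministic + 9 random starts (local optima) |
| `starts_dominance` | 1 | inner-product fits are start-invariant |
| `eps` | 1e-8 | guard in the negative-dissimilarity weight redefinition |
| `accelerate` | off | safeguarded step expansion (see below) |
| threshold cap | ±30 | bound on fitted thresholds (empty/separated categories) |

The probability floor $10^{-12}$ inside logarithms keeps the deviance
finite on degenerate cells; the logistic CDF is evaluated with the
numerically stable branch so $|\tau-\theta|$ up to several hundred is
safe.  Halving `eps` moves a converged proximity configuration by less
than $10^{-4}$ on the test fixture.

The deterministic proximity start is correspondence-analysis flavored
(SVD of the double-centered integer-coded response matrix, item locations
spread outward); random-start seeds are derived from a single user seed.

## Model selection

AIC $= D + 2k$ and BIC $= D + k\log N$ with $k$ the parameter count net
of indeterminacies: thresholds contribute $\sum_r (C_r-1)$; the
structural part contributes $S(N+R)-S^2$ (CLPCA), $S(P+R)-S^2$ (CLRRR),
$S(N+R)-S(S+1)/2$ (CLMDU: rotations and translations leave distances
unchanged) and $S(P+R)-S(S-1)/2$ (CLRMDU: with no intercept column in
$X$, translation is not free).  The CLRRR formula is pinned by a worked
example: $S=2$, $P=10$, $R=10$, $C_r=3$ gives $20 + 36 = 56$ parameters,
against $120$ for ten separate proportional-odds fits — which is also the
full-rank ($S=10$) count, as it must be.  `clmda_step()` implements the
two-stage search: dimensionality first with all predictors, then backward
elimination of predictor groups at the chosen $S$.

## Biplots and triplots

Dominance items are drawn as variable axes through the origin with
direction $v_r$.  The point calibrated with latent value $\mu$ is
$(\mu/v_r'v_r)\,v_r$; placing markers at the thresholds and labelling
them `c|c+1` partitions the plane by decision lines orthogonal to the
axis — every threshold is represented, including those of "hidden"
categories.  Proximity items are points with circles of radius
$-\tau_{rc}$: inside, $P(y>c) > 1/2$; circles with nonpositive radius are
not drawn.  Predicted categories follow the latent rule
($\hat y = c$ iff $\tau_{r,c-1} \le \hat\theta < \tau_{rc}$); the suite
checks on a $200\times200$ grid that the marker/circle geometry induces
exactly that assignment.  Triplots add interpolation axes for numeric
predictors (solid over the observed range, value markers back-transformed
to the original scale) and points for dummy-coded categories with the
reference at the origin; profile positions are vector additions $x'B$.
Identification for display: dominance solutions keep $V'V$ diagonal as
delivered by the SVD with a deterministic sign convention;
unrestricted proximity solutions are centered at the joint centroid —
biplots are invariant to either choice.

## Synthetic data and simulation studies

`clmda_population()` ships a fixed, documented population: $P=5$
predictors with AR(1) correlation 0.3, a $5\times2$ coefficient matrix of
mixed signs and moderate magnitudes, four items on the axes (dominance:
unit-length directions; proximity: a circle of radius 1.5), the
eight-item set obtained by rotating the four-item set by 45° (so the new
items are isometric images), and thresholds placed to spread mass over
3 or 5 categories — on the negative half-axis for proximity models
because $\theta = -d \le 0$.  `generate_dataset()` draws predictors as
correlated normals, moment-matched uniforms, or a five-point Likert
discretization (all centered, unit variance, correlation carried through
the Gaussian copula), forms $\Theta$, and draws each response from the
implied multinomial.  Draws are reproducible from (master seed, replicate
index) alone.

Recovery is measured by the Stress-1-type statistic

$$Q = \sqrt{\sum_{ir}(\hat\theta_{ir}-\theta_{ir})^2 \Big/
            \sum_{ir}\theta_{ir}^2},$$

which compares $\Theta$ directly and is therefore invariant to rotation
and reflection; $Q=0$ at perfect recovery and $Q=1$ for the all-zero
estimate.  The shipped studies run at deliberately scaled sizes: 20
replicates per condition over $N\in\{250,1000\}$, $R\in\{4,8\}$,
$C\in\{3,5\}$ for recovery (median $Q$ must fall with $N$ in every
condition, for both families), and 20 replicates at $N=1000$, $R=4$,
$C=3$ for dimension selection (data generated at $S=2$, fitted at
$S\in\{1,2,3\}$; BIC recovers $S=2$ in the majority, and AIC never picks
fewer dimensions than BIC since its penalty is smaller for $N\ge8$).
Proximity study fits start from the population configuration, as the
study protocol prescribes; random extra starts can be added.  What these studies do *not* show: behaviour under
misspecification (non-proportional odds, missing data, item-side
covariates), nor exact figures from any external dataset — the population
here is the package's own fixture.

## Numerical choices and degenerate inputs

* Empty response categories push their thresholds to infinity; they are
  capped at ±30 on the latent scale with a warning so long fits survive
  sparse categories.
* A response whose threshold Newton stalls mid-run (possible at
  near-boundary configurations) keeps its last iterate; the deviance
  trace stays monotone because the step-halving never accepts an
  increase.
* Ties among singular values are broken by taking the factors as
  delivered with the sign convention "largest-magnitude loading
  positive".
* Rank-deficient predictor matrices error immediately with instructions
  to drop collinear columns; a working-response matrix of rank below the
  requested dimensionality triggers a warning and a reduced effective
  rank.

### Boundary optima and the `accelerate` option

Joint fixed-effects ordinal likelihoods with few items often have their
supremum on the boundary of the parameter space: some row or item can be
separated perfectly, so scores or loadings grow without bound while the
deviance creeps toward its infimum.  Plain majorization steps shrink in
the saturated tails (the deviance then falls like $1/t$), which is why
`clmda_control(accelerate = TRUE)` offers safeguarded step expansion: the
update direction is extrapolated with a doubling multiplier, plus a
line search along the global scale direction, each candidate accepted
only if the deviance still decreases, with the plain step as fallback —
monotonicity is preserved by construction.

This matters for the one-dimensional equivalence check between CLPCA and
a jointly estimated graded-response model (the two are the same
likelihood; the package verifies they agree cell-for-cell at matched
parameters).  Comparing *fitted* deviances additionally requires a
fixture whose shared supremum both optimizers can approach at finite
parameter values of the capped model; random small fixtures fail this
(each optimizer stalls at a different point of the boundary), so the
check uses a perfectly scalable Guttman-type pattern — four latent
levels, a common cut structure — where the infimum is zero, the
accelerated fit reaches it to $4\times10^{-5}$, and the independent
BFGS fit reaches it to machine precision.

## Known limitations

Missing responses are not supported (cells must be complete); there are
no standard errors (a bootstrap would be the natural add-on); a-priori
zero constraints on $B$ or $V$ and item-side predictors are out of scope;
probit or adjacent-category links are deliberately not offered.  The
stepwise search is greedy and does not guarantee the globally optimal
predictor subset.
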