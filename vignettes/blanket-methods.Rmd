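---
title: "Methods: exact Markov-blanket analysis of linear OU systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact Markov-blanket analysis of linear OU systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blanketlab)
```

## The model and its assumptions

Everything in this package lives in the class of linear (Ornstein–Uhlenbeck)
stochastic differential equations

$$\mathrm{d}x = M x\,\mathrm{d}t + \mathrm{d}W,$$

with a Hurwitz drift matrix $M$ (all eigenvalue real parts negative, the
linear equivalent of ergodicity), white Gaussian noise, and a fixed
coordinate partition $x = (\psi, s, a, \lambda)$ into external, sensory,
active and internal blocks. Restricting to the linear class is not a
convenience but the point: here the diffusion matrix $\Gamma$ and the
solenoidal matrix $R$ are exactly constant, the stationary density is
exactly Gaussian with precision $U$, and every structural claim about the
free-energy argument — dependency patterns of the drift, conditional
independence, rewritings of the flow in terms of partial gradients,
existence of a suitable variational density — becomes a decidable statement
about finitely many matrices. A counterexample found in this class
invalidates the general claim a fortiori. Nonlinear systems, where $\Gamma$
and $R$ become coordinate-dependent and the gradient decomposition holds
only approximately, are deliberately out of scope, as are non-Gaussian
noise and discrete-state formulations.

## Noise normalisation

The literature this package engages with never states the covariance of the
fluctuations explicitly, yet the algebra only closes for one choice. We fix
the noise autocovariance to $2\Gamma\,\delta(t-t')$, so that the stationary
covariance solves $MC + CM^\top + 2\Gamma = 0$ and, simultaneously, the
gradient/solenoidal decomposition $f(x) = (\Gamma+R)\nabla\ln p^*(x)$ gives
$U = -(\Gamma+R)^{-1}M$ with $U = C^{-1}$. This consistency is not assumed:
`stationary_precision()` computes $U$ by both routes and raises a
`consistency_error` beyond $10^{-8}$ relative disagreement, and the
simulation module checks empirically that the sampled covariance matches
$U^{-1}$ rather than $(2U)^{-1}$ or $(U/2)^{-1}$. States are column
vectors; the stationary mean is zero throughout.

## Tolerance policy

All matrices handled here are $O(1)$, so structural zeros are tested in the
max-absolute-entry norm with a single absolute tolerance:

* **satisfaction**: a required-zero block counts as zero below $10^{-10}$;
* **violation**: a block counts as genuinely nonzero only above $10^{-3}$;
* **cross-checks** between independent algebraic routes: $10^{-8}$ relative;
* **Hurwitz margin**: largest eigenvalue real part below $-10^{-8}$.

The four-orders-of-magnitude gap between satisfaction and violation is what
makes boolean verdicts robust: generators *resample* any draw whose
residual lands in the ambiguous band instead of letting floating-point
noise decide a verdict. The max-entry norm has a second virtue: it is
invariant under the independent-copies lift (the lift of a block is
$I_n \otimes B$, whose largest entry is that of $B$), so lifted systems
reproduce base residuals exactly rather than up to a $\sqrt{n}$ factor.

## Solving the matrix equations

The solenoidal equation $MR + RM^\top = M\Gamma - \Gamma M^\top$ and the
Lyapunov equation are solved by the dense Kronecker-product route
($d^2 \times d^2$ linear systems). The package targets $d \lesssim 50$,
where this is simple, exact and fast; no structured Bartels–Stewart solver
is warranted at these sizes. Solvability is guarded explicitly: when two
eigenvalues of $M$ sum to zero the equation is singular, which cannot occur
for Hurwitz drifts but must be caught for user-supplied matrices
(`solvability_error`). Antisymmetry of the returned $R$ is a theorem (the
right-hand side is antisymmetric and the solution unique), so it is
asserted in tests rather than enforced by projection.

Conditionals and marginals of the stationary Gaussian use precision
sub-blocks and Schur complements; when a conditional involves only a subset
of blocks, the remaining blocks are first marginalised through the
covariance. Both routes are cross-checked against brute-force full-matrix
inversion in the test suite.

## Deciding the rewriting identities

For a linear system every rewriting of $(f_a, f_\lambda)$ in terms of
partial gradients of $\ln p^*$ is an equality of linear maps. We therefore
compare coefficient matrices — exact and basis-independent — and never
sample points (a property test confirms that pointwise and coefficient
mismatches coincide). The marginal gradient
$\nabla \ln p^*(s,a,\lambda) = -V\,(s,a,\lambda)$ comes from the marginal
precision $V$, not from symbolic differentiation. The marginalised
families are gated on Condition 1: without it $(f_a, f_\lambda)$ are not
functions of $(s,a,\lambda)$ and the comparison is meaningless, so the
report says `not_applicable` rather than guessing. The fully general
marginalised family (keeping all solenoidal couplings within the blanket
block) is treated as the end of the simplification road; no further
reduction is attempted.

## The chain implication and its extra hypothesis

Combining the drift dependency pattern (Condition 1) with the solenoidal
coupling pattern (Condition 3) under block-diagonal $\Gamma$ forces
$M_{\lambda s} = 0$ and $M_{\psi a} = 0$ via the time-reversal identity
$M = (\Gamma+R)M^\top(\Gamma-R)^{-1}$ — but only if the sensory–active
solenoidal coupling vanishes as well. With $R_{sa} \neq 0$ the identity
mixes the $s$ and $a$ columns and yields
$M_{\lambda s}(\Gamma_{ss}-R_{ss}) = M_{\lambda a}R_{as}$, which is
generically nonzero; the formulations that assume Condition 3 also assume
$R_{as} = 0$, and that assumption is where the chain conclusion actually
comes from. `verify_chain_implication()` therefore checks $R_{sa} = 0$ as
a named precondition and refuses (`not_applicable`) rather than reporting a
spurious verdict. The pseudoinverse branch of the identity (for singular
$\Gamma - R$) is implemented but unreachable when $\Gamma$ is positive
definite; a flag records if it was taken.

## The variational family and lemma feasibility

The variational density is Gaussian with mean affine in the internal
coordinates and constant covariance:
$q(\Psi|\lambda) = \mathcal{N}(A\lambda + b,\, S)$. A finite-dimensional
family is needed for computation, and this one is exhaustive for the task
at hand: the conditional $p^*(\Psi|s,a,\lambda)$ of a stationary Gaussian
has constant covariance and mean affine in the conditioning variables, so
if *any* density parameterised by $\lambda$ alone can match it, an
affine-Gaussian one can. Infeasibility verdicts are nevertheless explicitly
scoped to this family in the reports; whether a non-Gaussian $q$ could
succeed where the Gaussian-linear family fails is noted as open, not
resolved. By construction $q$ never sees $(s,a)$ — the "at face value"
reading of a belief parameterised by internal coordinates. Allowing
$q(\Psi|s,a,\lambda)$ would make the lemma trivially true (set $q$ equal to
the conditional); that reference construction exists in the code as the
witness for the strongest feasibility case and achieves divergence zero
identically.

The KL divergence of this family from the conditional is a
$G$-weighted quadratic in the mean mismatch
$\Delta(A)\,y - b$, with $y = (s,a,\lambda)$, $G = U_{\psi\psi}$ the
conditional precision, and $\Delta(A) = K - [0\;0\;A]$ the gap between the
conditional's gain $K$ and the variational gain. The lemma requires the
$R$-weighted gradient combinations $W\,\nabla_y D \equiv 0$ to vanish
identically, where $W$ is the coefficient operator of whichever rewriting
family the system satisfies. Although this constraint looks bilinear in
$A$, positive definiteness of $G$ collapses it: $W(\Delta^\top G\Delta) = 0$
holds iff $\Delta W^\top = 0$ (a Gram-matrix nullspace argument), which is
*linear* in $A$, and the $b$- and $S$-dependent terms drop out entirely.
Feasibility is therefore an exact linear least-squares problem, solved by
SVD with rank revelation: feasible below $10^{-8}$ scale-normalised
residual, infeasible above $10^{-2}$, ambiguous in between (never observed
on generated systems). The report always records that $b$ is free, that
$S$ is free — $S$ enters the divergence only through point-independent
terms — and the dimensions of the nullspaces of $(\Gamma+R)_{aa}$ and
$(\Gamma+R)_{\lambda\lambda}$, which are provably trivial for positive
definite $\Gamma$ (whether ergodic blanket systems can ever have
nontrivial ones is left open in the literature; we only report the
dimensions).

The unbounded-divergence witness scales the covariance, $S = t\,\Sigma_c$,
adding $\tfrac{1}{2}n_\psi(t - 1 - \ln t)$ to the divergence at every point
while leaving every gradient untouched; $t$ solves
$\tfrac{1}{2}n_\psi(t-1-\ln t) = c + 1$ by bisection (for large thresholds
$t \approx 2c/n_\psi$). The newer lemma parameterised by the most likely
internal coordinate $\bar\lambda(s,a)$ is outside this critique and is
implemented only as the data-processing-inequality check
$I(\Lambda;\bar\Lambda) \le I(\Lambda;(S,A))$, with both informations in
Gaussian closed form. For Gaussians the conditional mean is a sufficient
statistic, so the inequality is typically attained with equality — the
margin is zero to machine precision, which the check accepts.

## What the generators emulate — and what they do not

The counterexample classes are reconstructed from their defining
constraints, not copied from any published matrix, so only class
membership, never numerical identity with a specific instance, is claimed.
The sampling route fixes the bilinearity the constraints would otherwise
have: draw the antisymmetric $R$ first (uniform $[-1,1]$ entries, required
zero pairs imposed), draw a symmetric candidate $U_0$ (off-diagonal uniform
$[-1,1]$, diagonal inflated by $+d$ to favour positive definiteness without
touching structural zeros), then orthogonally project $U_0$ onto the linear
solution set of the required drift zero blocks $[(\Gamma+R)U]_{\text{block}} = 0$
with $R$ held fixed — no alternating optimisation, so generation is
deterministic given the seed and simple to reason about, at the cost of not
exploring the full constraint variety. Draws are rejected if $U$ is not
positive definite (margin $10^{-6}$), if a required zero block fails, or if
a required-nonzero block falls below the violation threshold; rejection
causes are counted and reported on failure. Default partitions are the
minimal $(1,1,1,1)$ — the claims are existential, so the smallest witness
is the best witness — with a $(2,1,1,1)$ fallback where a scalar external
block could make the constraint solve degenerate.

These synthetic systems are exactly what the theory quantifies over:
stationary linear diffusions. What they do *not* emulate is anything beyond
that class — nonlinearity, state-dependent diffusion, non-Gaussian noise,
nonstationarity. Passing tests therefore establish the counterexamples and
identities within the linear-Gaussian class (which suffices to refute
general claims), and say nothing about how real neural or biological
systems behave.

## Generalised coordinates

The lift to generalised coordinates is realised as $n$ independent copies
of the base system, reordered partition-major so that the lifted system
carries an ordinary four-block partition and every checker runs unchanged.
The construction is conceptually infinite-dimensional; we use finite
orders and assert exact preservation for every $n$, which is the
computationally meaningful content since all stated properties are
per-copy. Serial coupling between derivative orders is deliberately not
modelled — the construction transports counterexamples, it does not embed
derivative chains.

## Simulation cross-validation

The Euler–Maruyama integrator is intentionally plain: update
$x \leftarrow x + Mx\,\mathrm{d}t + \sqrt{2\,\mathrm{d}t}\,L\xi$ with
$LL^\top = \Gamma$, a stability guard $\mathrm{d}t < 0.5/\max|\mathrm{eig}(M)|$,
an overflow trap, burn-in of 2000 steps, and autocorrelation-corrected
effective sample sizes for all standard errors. Covariance agreement is
accepted within 3–4 standard errors; empirical conditional-independence
checks use the partial correlation of $\psi$ and $\lambda$ given $(s,a)$
with standard error $\mathrm{ESS}^{-1/2}$. Because the detectability of a
violated independence depends on its effect size, empirical power checks
select a counterexample whose analytic partial correlation exceeds 0.1 —
the claim being tested is about systems with genuine violations, not
borderline ones. Default problem sizes — $2\times10^5$ steps at
$\mathrm{d}t = 0.01$, $10^5$ Monte-Carlo KL samples, 200 systems for the
algebraic battery, 100 for the chain property, 50 for the information
inequality — were chosen so that every stochastic acceptance margin sits
at several standard errors while a full run stays in the seconds-to-a-minute
range. Every stochastic operation takes an explicit seed and restores the
global RNG state on exit.

## Known limitations

* All algebra is dense; dimensions beyond $d \approx 50$ are untargeted.
* Rank-deficient $\Gamma$ is rejected, not analysed: the nontrivial-nullspace
  regime is reported on but never instantiated.
* Feasibility verdicts are scoped to the Gaussian-linear variational family
  (see above).
* Euler–Maruyama has $O(\mathrm{d}t)$ weak bias; the stability guard and
  the 3–4 standard-error acceptance bands absorb it at the default step
  size, and the analytic route is always the reference.
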