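# blanketlab

Exact, machine-checked analysis of the structural claims behind the free
energy principle (FEP), in the one setting where every step is computable in
closed form: linear Ornstein–Uhlenbeck (OU) systems carrying an
(external, sensory, active, internal) coordinate partition
`x = (ψ, s, a, λ)`.

The FEP argument starts from an ergodic stochastic differential equation
`dx = f(x) dt + ω` and a "Markov blanket", and concludes that the internal
coordinates appear to perform Bayesian inference about the external ones by
minimising a variational free energy. Each step of that argument is, for a
linear system, a statement about matrices — and can therefore be *decided*
rather than argued about. That is what this package does, for researchers in
theoretical/computational neuroscience and stochastic thermodynamics who
want the algebra pinned down.

## The machinery

For a linear drift `f(x) = M x` with Hurwitz `M` and noise autocovariance
`2Γ δ(t−t′)` (Γ symmetric positive definite, block-diagonal), the stationary
density is a zero-mean Gaussian with precision `U`, and the drift decomposes
into gradient and solenoidal flow:

```
f(x) = (Γ + R) ∇ ln p*(x),     M R + R Mᵀ = M Γ − Γ Mᵀ  (R antisymmetric),
U = −(Γ + R)⁻¹ M,              M C + C Mᵀ + 2Γ = 0,      C = U⁻¹.
```

On top of this the package decides, as block-zero patterns with explicit
residual norms:

* **Condition 1** (drift dependency pattern): `M_aψ = M_λψ = M_sλ = M_ψλ = 0`;
* **Condition 2** (conditional independence in the stationary density):
  `U_ψλ = 0`;
* **Condition 3** (solenoidal coupling pattern): the blocks of `R` coupling
  `ψ` to everything else and `(s,a)` to `λ` vanish;
* which rewritings of `(f_a, f_λ)` in terms of partial gradients of
  `ln p*(s,a,λ)` hold, as exact equalities of coefficient matrices;
* whether a Gaussian variational density `q(Ψ|λ) = N(Aλ + b, S)` can satisfy
  the free energy lemma (`F(s,a,λ) = −ln p*(s,a,λ) + KL[q ‖ p*(Ψ|s,a,λ)]`),
  via an exact linear least-squares feasibility problem in `A`;
* witnesses of arbitrarily large KL divergence with identically vanishing
  KL gradients;
* the data-processing inequality `I(Λ; Λ̄) ≤ I(Λ; (S,A))` for the
  most-likely-internal belief parameterisation `λ̄(s,a)`.

Seeded generators produce counterexample systems for each of these claims
(conditions independent of each other; restricted rewritings failing under
both conditions; lemma infeasible; lemma feasible but divergence unbounded),
each wrapped in a certificate of re-verified reports. A lift to generalised
coordinates (independent copies) transports every verdict exactly, and an
Euler–Maruyama simulator cross-validates the algebra empirically.

## Worked example

The chain-structured gradient-flow counterexample (`R = 0`, `Γ = I`, `U`
coupling only `ψ–s`, `s–a`, `a–λ`): both blanket conditions hold, every
drift rewriting holds, the free energy lemma is feasible — and still the
variational density is not the posterior, with unbounded divergence.

```r
library(blanketlab)
cert <- generate_counterexample("obs5", seed = 0)
check_condition(cert$system, 1)
check_condition(cert$system, 2)
identity_residuals(cert$system)
feas <- lemma_feasibility(cert$system, "29,30")
probe <- kl_supremum_probe(cert$system, feas, 1e6)
```

```
<counterexample_certificate> obs5 (seed 0, 1 attempt(s), d = 4)
<condition_report> Condition 1: satisfied (max residual 0.000e+00, tol 1.0e-10)
<condition_report> Condition 2: satisfied (max residual 0.000e+00, tol 1.0e-10)
<identity_report>
  (13,14): holds (residual 0.000e+00)
  (17,18): holds (residual 4.069e-18)
  (19,20): holds (residual 4.069e-18)
  (21,22): holds (residual 4.069e-18)
<lemma_feasibility_report> family (29,30): feasible (LS residual 0.000e+00, A-solution-set dim 0, b and S free)
witness KL at the probe point: 1000001 (threshold 1e6)
witness KL-gradient maps, largest coefficient: 0
conditional mean gain on s: 0.099 (so q != p*(Psi|s,a,lambda))
```

Reading the output: the only variational gain compatible with vanishing KL
gradients is `A = 0` (a belief that ignores the internal state), `b` and `S`
are completely free, and scaling `S` drives the divergence past any
threshold (here 10⁶) while every constrained gradient stays exactly zero.
Since the conditional mean of `ψ` moves with `s` (gain 0.099) and the
variational mean cannot, the two densities are never equal — vanishing
gradients do not deliver Bayesian inference.

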