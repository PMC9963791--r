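# neurocal

Neural parameter calibration for differential-equation models of
interacting agents.

## What problem this solves

Models of epidemics, economic activity, flocking, or opinion dynamics are
often written as coupled (stochastic) differential equations
`dφ = f(φ; λ) dt [+ g(φ) ∘ dB]` whose parameters `λ` — transmission
rates, recovery times, preference exponents — cannot be measured directly
and must be estimated from observed trajectories or steady states.
Classical Bayesian machinery (MCMC) does this at considerable
computational cost; `neurocal` implements a fast alternative for
practitioners who want parameter *densities*, not just point estimates,
in seconds-to-minutes on a laptop CPU.

The core idea: a shallow neural network `u_θ` (one hidden layer of 20
modulus-activated neurons) maps an observed state frame to a parameter
estimate `λ̂`; a differentiable numerical solver turns `λ̂` into a
predicted trajectory segment; the batch-averaged squared error

    J = (1/B) Σⱼ ‖φ̂ⱼ − φⱼ‖²

is backpropagated *through the solver* to train the network. As training
traverses parameter space it records every visited pair `(λ̂, J)`,
tracing out a loss potential from which a posterior is read off as
`π(λ̂ | T) ∝ exp(−J)·π⁰(λ̂)`. Marginal densities of each parameter are
`exp(−J)`-weighted Gaussian kernel densities of the visited values; the
network is initialised so `π⁰` is uniform over a stated prior box, and
training is repeated from many initialisations so that nonconvex
potentials with several minima are sampled in full.

Two model systems ship fully worked, each with a synthetic-data
generator, so everything runs offline:

* **Diffusive SIR epidemic** — an agent-based model (N agents on a
  periodic square, contact infection within radius `r`, recovery after
  `τ` steps) generates ground-truth compartment densities `S(t), I(t),
  R(t)`; a Stratonovich SDE surrogate with parameters `(β, τ, σ)` is
  calibrated to them, noise amplitude learned.
* **Harris–Wilson demand flow** — `M` destination-zone sizes on a
  bipartite origin–destination network follow coupled logistic SDEs
  driven by flows `T_ij ∝ W_j^α c_ij^β O_i`; `(α, β, κ)` are calibrated
  from steady-state data. For identifiable data (inequality statistic
  `0 < ν < 1`) the loss has at most two global minima — the generating
  parameters and the trivial solution `(1, 0, ΣO/ΣW)` — and the pooled
  loss potential exhibits both, with `κ` always unique.

## Worked example

Generate an epidemic with the agent-based model and calibrate the SDE
surrogate to it, using the reference protocol (20 network
initialisations, 70 epochs, batch size 90):

```r
library(neurocal)

abm <- simulate_sir_abm(sir_abm_config(seed = 11))   # N = 3000, 100 steps
fit <- calibrate(abm, "sir",
                 train_config(epochs = 70, batch_size = 90, n_init = 20,
                              solver_noise = "learned", seed = 101))

density_summary(marginal(fit$samples, "beta"))
density_summary(marginal(fit$samples, "tau"))
density_summary(marginal(fit$samples, "sigma"))
```

On this seed the run prints (abridged):

    beta :  mle 0.218   tau :  mle 14.60   sigma :  mle 0.019, mean 0.088

Read: the surrogate's most likely transmission rate is close to the
agent model's infection probability `p = 0.2`; the recovery time is
recovered near the true `τ = 14`; the most likely noise level is
essentially zero with a small positive expectation absorbing the
agent-model/SDE mismatch. `autoplot(marginal(fit$samples, "beta"))`
draws the marginal, `plot_loss_potential(fit)` the sampled potential,
and `predict_ensemble()` produces forward simulations with ensemble
error bands from the per-initialisation estimates.

The Harris–Wilson pipeline is one call away from the same pattern:

```r
gen <- generate_hw_data(hw_params(alpha = 1.2, beta = 4, kappa = 2), seed = 1)
fit <- calibrate(gen$frames, "harris_wilson",
                 train_config(epochs = 10000, batch_size = 1, n_init = 20,
                              learning_rate = 3e-4, seed = 22),
                 network = gen$network)
peak_widths(marginal(fit$samples, "alpha"))
```

which finds the two minima of the potential — the trivial solution near
`α = 1` and the generating value near `α = 1.2` — and a single `κ` peak
at the true cost parameter.

A thin command-line front end with `generate`, `calibrate`, `density`
and `run` subcommands is installed under `inst/cli/neurocal`.

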