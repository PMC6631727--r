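# ldmf — latent dynamics modelling and filtering for IMU movement data

Smartphone inertial sensors record walking and running as noisy,
high-dimensional time series: three-axis angular velocity, three-axis
acceleration, and their two Euclidean magnitudes, sampled at 30 Hz. `ldmf`
maps these sequences to smooth trajectories in a two- or three-dimensional
latent space, so that a person's gait becomes a compact, interpretable
curve. It is aimed at researchers in digital health and biomechanics who
want subject-level movement signatures from phone-grade sensors.

## The model

Observations are stacked windows **y**_t = [**x**_t, **x**_{t−1},
**x**_{t−2}] of min–max-scaled 8-dimensional feature frames (8 × 3 = 24
dimensions), which softens the Markov assumption on the latent chain. The
backbone is a deep Markov model over latent states **z**_t ∈ ℝ^d:

    p_θ(y_{0:T}, z_{0:T}) = p_θ(z_0) p_θ(y_0 | z_0)
                            ∏_{t=1}^T p_θ(y_t | z_t) p_θ(z_t | z_{t−1})

with a mixture-density network for the transition p_θ(z_t | z_{t−1}), an
MLP emitter for p_θ(y_t | z_t), and a diagonal-Gaussian initial prior.
Training happens in two stages:

1. **Latent dynamics modelling.** A GRU encoder running backwards in time
   implements the variational posterior q_φ(z_t | y_{t:T}); θ and φ are
   trained jointly by maximising the evidence lower bound
   ELBO(θ, φ) = Σ_t E_q[log p_θ(y_t | z_t)] − KL(q(z_0) ‖ p(z_0)) −
   Σ_t E[KL(q(z_t) ‖ p_θ(z_t | z_{t−1}))].
2. **Causal filtering.** With θ frozen, a combiner network maps the
   predicted state, predicted variance and the current window to the
   filtered posterior — the learned analogue of the Kalman
   predict–correct cycle — so latent trajectories can be estimated
   sequentially, in real time, without future observations.

Around the core sit a continuous normalizing-flow (neural-ODE) density
estimator that turns pooled latent samples into a thresholded "normal
region" of typical movement, and an incremental-PCA baseline scored by the
reconstruction-MSE ratio MSE_IPCA / MSE_LDMF on cross-validated held-out
recordings. All networks are trained with a small reverse-mode automatic
differentiation engine included in the package.

## Worked example

```r
library(ldmf)

cohort <- generate_cohort(2, 3, seed = 42, motions = "walk", duration = 10)
spec   <- fit_minmax(cohort$recordings)           # one interval, whole cohort
obs    <- lapply(cohort$recordings, build_observations, spec = spec)

fit <- ldmf(obs[1:4], latent_dim = 2, hidden = c(16), rnn_hidden = 16,
            epochs = c(8, 8), lr = c(5e-3, 5e-3), subseq_len = 50,
            stride = 25, seed = 1, scaling = spec)
print(fit)
#> Two-stage latent dynamics model
#>   latent dim 2, obs dim 24, transition mixture K=1, emitter gaussian
#>   stage-1 ELBO: -2103.35 (epoch 1) -> -383.36 (epoch 8)
#>   stage-2 objective: -256.18 -> -26.90 (epoch 8)

traj <- predict(fit, obs[[5]])                    # causal filtering
print(traj)
#> <latent_trajectory> subject=S02 motion=walk T+1=298 d=2
round(head(traj$mu, 3), 3)
#>       [,1]   [,2]
#> [1,] 0.437  0.072
#> [2,] 0.270 -0.272
#> [3,] 0.132 -0.173
```

The rising ELBO shows both reconstruction and transition consistency
improving; `traj$mu` is the filtered latent mean at each window, the curve
that characterises this subject's gait. `plot(fit, obs[[5]])` draws it.
With longer training schedules (see `run_cross_validation`) the model's
held-out reconstruction error drops below the incremental-PCA baseline's,
i.e. the MSE ratio exceeds one. Density estimation over pooled latents:

```r
dm     <- fit_density(traj$mu, list(n_iter = 300, seed = 1))
region <- normal_region(dm, mass = 0.95)
contains(region, traj$mu[1, ])                    # TRUE for typical windows
```

A command-line interface over the same functions ships as
`system.file("cli", "ldmf.R", package = "ldmf")` with subcommands
`simulate | scale | train-stage1 | train-stage2 | filter | density |
evaluate | run`.

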