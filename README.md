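# aptwin

Patient-specific digital twins and offline reinforcement learning for
closed-loop insulin dosing in type 1 diabetes.

People with type 1 diabetes dose insulin with a pump (continuous basal
rate, meal boluses, temporary overrides) while a continuous glucose
monitor (CGM) records glucose every few minutes.  Designing an automated
dosing policy ("artificial pancreas") by trial and error on a patient is
unsafe; `aptwin` implements the offline alternative:

1. **Preprocess** pump, meal and heart-rate records into three forcing
   signals — insulin infusion `u1(t)` (mU/min), meal glucose appearance
   `u2(t) = 0.0083 Σⱼ mⱼ exp(0.0083 (tⱼ − t))` (g/min), and above-basal
   exercise intensity `u3(t) = max(0.888·HR − 71.91 − 8, 0)`.
2. **Simulate** a six-state modified Roy–Parker glucose–insulin model with
   exercise as the patient's digital twin:
   `dI/dt = −nI + p₄u₁ − Iₑ`, `dX/dt = −p₂X + p₃(I − I_b)`,
   `dG/dt = −p₁(G − G_b) − XG + (W/Vol_G)(G_prod − G_up) + u₂/Vol_G`,
   with three exercise states driven by `u3` and decaying at rates
   `a₂, a₄, a₆`.
3. **Infer** patient-specific parameters and hidden states from CGM alone
   with a systems-biology-informed network (SBINN): a feature-basis state
   network trained on data misfit + ODE residual + initial-condition loss
   under self-adaptive loss weights, parameters constrained to
   `[0.2, 1.8]·xref` by a sigmoid transform.
4. **Learn dosing offline** from a replay buffer of
   (glucose-window, insulin-rate, reward) transitions with continuous BCQ
   (VAE-constrained) and TD3+BC (behavior-cloning-regularized), reward
   `−((G−120)/120)²` inside 80–180 mg/dl and −10 outside, actions capped
   at `min(2·max observed rate, 90)` mU/min.
5. **Score** with Clarke error-grid regions, time-in/above/below-range
   and Wilcoxon comparisons of episode returns.

A built-in scenario generator (meals, multi-mode boluses, basal steps,
exercise bouts, CGM noise/gaps) makes the whole pipeline runnable with no
external data; an OhioT1DM-style XML reader ingests real records where
available.

## Worked example

Train a dosing agent for a hyperglycemia-prone synthetic patient whose
logged therapy systematically underdoses (50% of the required bolus):

```r
library(aptwin)

p  <- patient_params(Gb = 155)                     # hyperglycemia-prone
sc <- make_scenario(21, duration_days = 7, params = p,
                    cfg = scenario_config(dose_fraction = 0.5))
sim    <- simulate_patient(sc, p)                  # CGM from the twin
coarse <- coarse_grain(sim$table)                  # 1-hour decision grid
buf    <- build_buffer(coarse)                     # replay buffer
env    <- twin_env(p, sc$forcing, w = buf$w, a_max = buf$a_max)

behavior <- function(window, step) coarse$u1[min(step, nrow(coarse))]
ev_b <- evaluate_policy(behavior, env, seed = 1)
mean(ev_b$returns)
#> [1] -55.42522
range_fractions(ev_b$trajectory$G)[["tir"]]
#> [1] 0.7440476

agent <- train_td3bc(buf, list(iters = 1500L), seed = 1, env = env)
ev_a  <- evaluate_policy(agent, env, seed = 1)
mean(ev_a$returns)
#> [1] -34.23973
range_fractions(ev_a$trajectory$G)[["tir"]]
#> [1] 0.8452381
```

The agent reads only the last five hourly glucose values — no meal or
exercise announcements — and still raises time-in-range from 74% to 85%
while improving the mean discounted return, by dosing more insulin when
the recent glucose history runs high.

Parameter inference works the same way from any aligned record:

```r
cgm <- uniform_series(sim$table$G, t0 = 0, dt = 5, unit = "mg/dl")
fit <- sbinn_train(cgm, sc$forcing, W = p$W, u1b = p$u1b,
                   Gb = p$Gb, Ib = p$Ib)
fit$params            # inferred kinetic parameters
rec <- sbinn_reconstruct(fit, sc$forcing)   # forward validation
table(clarke_region(sim$table$G, rec$G[seq_len(nrow(sim$table))]))
```

See `vignettes/artificial-pancreas-twin.Rmd` for the model, the loss
construction, the numerical choices and their rationale.

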