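# mcpgigr

Regression for **correlated, overdispersed multivariate count data**.

Public-health, actuarial and traffic-safety panels routinely record several
counts per unit (e.g. maternal and neonatal deaths per district) that are
(i) overdispersed — the variance exceeds the Poisson mean — and
(ii) positively correlated across outcomes. `mcpgigr` fits a model that
handles both at once:

* **Dependence** comes from a *common shock*: with independent
  Z_j ~ Poisson(λ_j), the observed counts are Y₁ = Z₁ and
  Y_j = Z₁ + Z_j for j ≥ 2, so every pair of responses shares the latent
  component Z₁ (Cov(Y_j, Y_k) = λ₁).
* **Overdispersion** comes from a shared *generalized inverse Gaussian (GIG)
  frailty* ν multiplying every rate. The GIG density used here is

  g(ν; τ, ξ, γ) = ξ^{−γ} / (2 K_γ(ϖ)) · ν^{γ−1} exp(−(ϖ/2)(ν/ξ + ξ/ν)),
  with ϖ = √(τ² + ξ²) − ξ,

  where K_γ is the modified Bessel function of the second kind. Integrating
  the common-shock Poisson pmf against g yields a closed-form mixed pmf
  built from Bessel factors K_{T+γ}(√(ϖψ)) with T = y₁ + Σ_{j≥2}(y_j − y₁)
  and ψ = 2ξΣλ + ϖ.
* **Covariates and exposure** enter through the log link
  E(Y_ij) = q_ij exp(x_iᵀ β_j), one coefficient vector per response, with the
  rate reparametrization λ_ij = (μ_ij − μ_i1)/(ξ R_γ(ϖ)) (shock:
  λ_i1 = μ_i1/(ξ R_γ(ϖ))), where R_γ(ϖ) = K_{γ+1}(ϖ)/K_γ(ϖ).

Estimation is maximum likelihood by the **BHHH algorithm** (outer product of
per-observation scores, ascent line search, ε = 10⁻⁷ stopping rule on the
parameter change, plus a Newton polish once the OPG gain stagnates). Inference
is a simultaneous likelihood-ratio test (G² = 2(lnL_full − lnL_null) against
χ² with p·m df), per-coefficient Wald Z tests, and small-sample-corrected AIC
(AICc) comparison against the unmixed multivariate Poisson baseline (MPR).

## Worked example

Simulate a 300-district bivariate panel at the package's default study truth
(β₁ = (−5, −0.05, 0.4), β₂ = (1, 0.07, 0.05), τ = 0.5, ξ = 1, γ = −1/2,
predictors uniform on (0, 10)) and fit both models:

```r
library(mcpgigr)

design <- sim_design(300, seed = 7)
panel  <- simulate_panel(design, sim_truth(), family = "mcpgig", seed = 8)

fit <- fit_mcpgigr(panel, gamma = -1/2)
print(fit)
#> MCPGIGR fit: 300 units, 2 responses, loglik -760.2834, 7 iteration(s)
#>   gamma = -0.5 (fixed), tau = 0.4786, xi = 0.9554
#> Coefficients:
#>                  y1     y2
#> (Intercept) -4.9563 1.6891
#> x1           0.0084 0.0123
#> x2           0.3832 0.0028

base <- fit_mpr(panel)
c(AICc_mixed = aicc(fit), AICc_baseline = aicc(base))
#> AICc mixed: 1537.06   baseline: 6343.37

mlrt(fit, alpha = 0.05)
#> Simultaneous LR test: G^2 = 24.8409 on 4 df, p = 5.415e-05
#>   (critical 9.488 at alpha = 0.05) -> reject H0

wald_tests(fit)
#> # A tibble: 4 x 7
#>   response term  estimate std.error statistic  p.value significant
#> 1 y1       x1     0.00841    0.102     0.0821 0.935    FALSE
#> 2 y1       x2     0.383      0.104     3.68   0.000236 TRUE
#> 3 y2       x1     0.0123     0.0457    0.269  0.788    FALSE
#> 4 y2       x2     0.00275    0.0420    0.0656 0.948    FALSE
```

Reading the output: the frailty parameters recover the generating values
(τ̂ ≈ 0.48 vs 0.5; ξ̂ ≈ 0.96 vs 1), the AICc gap of ~4800 points reflects how
badly a pure Poisson model fits counts whose variance is dozens of times
their mean, and the LR test correctly rejects "no covariate effects". On a
single draw of n = 300 the per-response slope estimates are individually
noisy (the shock response is near-zero for most units), which is why the
package ships a replication harness: `run_recovery_study()` shows the bias of
every coefficient shrinking towards zero as n grows.

Fitted objects are tidyverse-friendly: `tidy(fit)` returns the coefficient
table as a tibble, `glance(fit)` one row of fit statistics, and
`autoplot(fit)` the (monotone) optimization trace. Real data come in through
`read_panel("file.csv", responses = ..., exposures = ..., predictors = ...)`,
and `inst/cli/mcpgigr.R` wraps fitting, testing and simulation as a small
command-line tool (`fit`, `test`, `simulate`, `aicc`, `pmf` verbs).

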