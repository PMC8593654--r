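# stormPMF

Tools for analysing continuous high-frequency (20-minute) multi-compound
pesticide concentration time series from small agricultural streams. The
package is aimed at environmental chemists and water-quality scientists who
want to (i) classify a monitoring period into storm events and dry periods,
(ii) decompose a multi-species concentration matrix into contamination
sources by uncertainty-weighted robust positive matrix factorization (PMF),
and (iii) quantify how strongly time-composite regulatory sampling
underestimates short concentration peaks and exceedances of acute quality
standards.

## The methods in brief

**Event classification.** Storm events are maximal wet spells in the
10-minute rainfall record separated by at least 2 h without rain; an event is
*large* when its maximum intensity exceeds 1 mm/10 min and *small* otherwise.
*Dry* days have zero rain and a water-level standard deviation below a
configurable threshold.

**Uncertainty-weighted robust PMF.** The n x m concentration matrix X is
factorized as X = G F + E with G (n x p) and F (p x m) nonnegative, by
minimizing

    Q = sum_ij [ (x_ij - sum_k g_ik f_kj) / u_ij ]^2

where the per-cell uncertainty is u_ij = sqrt((a_j x_ij)^2 + LOQ_j^2) above
the limit of quantification and (5/6) LOQ_j at or below it (a_j is the
per-compound relative measurement error). Before fitting, censored values are
replaced by LOQ/2, species are classed by signal-to-noise ratio
(bad <= 0.2 < weak <= 1 < good), bad species are dropped and weak species'
uncertainties tripled. Fitting uses multi-start (20 runs) weighted
nonnegative hierarchical alternating least squares in a robust mode: cells
whose scaled residual |e/u| exceeds 4 are down-weighted during fitting and
excluded from the reported Q_robust. The factor count p is chosen where
Q_robust/Q_exp — with Q_exp = n m_good - p (n + m_good) — stops decreasing
substantially; block-bootstrap refits quantify factor stability.

**Exposure assessment.** Time-composite samples (3.5-day or 14-day windows,
censored values set to the LOQ) are emulated from the high-frequency record;
the *underestimation factor* is the maximum 20-minute concentration divided
by the composite mean of its window. Exceedances of acute quality standards
(AQS) and regulatory acceptable concentrations (RAC) are tallied at both
resolutions, per sample, per episode and per compound.

A synthetic-catchment module (`simulateCampaign()` and friends) generates
rainfall, a linear-reservoir water level and concentration series with known
factor structure — including a dilution-dominated legacy compound, LOQ
censoring and the multiplicative + LOQ noise model — so every stage is
testable without external data.

## Worked example

The package ships a published summary of AQS-exceeding compounds from a
41-day high-frequency campaign (maximum 20-minute concentration, 3.5-day
composite, standards; all ng/l):

```r
library(stormPMF)
res <- assessAcuteSummary()
res$factors
#>              compound    factor bound
#> 1        azoxystrobin 12.857143 FALSE
#> 2              diuron 32.666667  TRUE
#> 3           fluopyram 11.486989 FALSE
#> 4        nicosulfuron  8.750000 FALSE
#> 5         thiacloprid  8.444444 FALSE
#> 6         carbendazim        NA FALSE
#> 7 chlorpyrifos-methyl        NA FALSE
unlist(res$counts)
#>     ppp_aqs_20min     ppp_rac_20min ppp_aqs_composite ppp_rac_composite
#>                 5                 4                 3                 1
```

Azoxystrobin's 6300 ng/l peak is 12.9 times higher than the 490 ng/l
composite covering the same 3.5 days; diuron's composite was below its LOQ
(15 ng/l), so its factor is a flagged lower bound (> 32.7). Five compounds
exceed their AQS at 20-minute resolution but only one (thiacloprid) exceeds
its RAC in the composite record — the bias the high-frequency record is
designed to expose.

A fully synthetic end-to-end run:

```r
sim <- simulateCampaign(seed = 1)          # 41 days, 6 factors, 17 species
pin <- preparePmfInput(sim$cm)             # screening + uncertainties
mod <- fitPmfMulti(pin$X, pin$U, p = 6, seed = 7, m_good = pin$m_good)
mod
#> PMFModel: p = 6 factors, n = 2657 samples, m = 17 species
#>   Q (true) = 2.174e+04, Q (robust) = 2.174e+04, Q_exp = 2.117e+04, Q_robust/Q_exp = 1.027
#>   converged: TRUE after 1430 iterations (20 runs, seed 19)
fingerprints(mod)                          # factor/species pairs >= 25%
```

or from a shell: `Rscript inst/scripts/run_pipeline.R --out run1 --seed 1`.

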