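# lintflux

A quantitative model of belly button lint (navel fluff) production, for
anyone studying ratchet transport on biological substrates — directed
particle drift produced by symmetric oscillatory forcing on a surface with
asymmetric friction — or who simply wants the physics of navel fluff done
properly.

## The model

Breathing slides worn fabric back and forth over the abdominal skin. Body
hair is covered in overlapping cuticle scales that point root-to-tip —
toward the navel — so a lint fiber sandwiched between shirt and hair feels
directional friction: the hair–lint kinetic coefficient tip-to-root,
μ⁻, is about twice the root-to-tip value μ⁺. Balancing the net traction
(μ_SL − μ_HL)·F_N against Stokes-scale air drag ηlU in each half-cycle and
averaging over a breath gives a net drift toward the navel

    ū = (U⁺ − U⁻)/2 = (μ⁻ − μ⁺)·F_N / (2ηl),   F_N = p·α·d·l,

with the skin pressure p tied to the garment tension by the Laplace
relation p = γ/R. The fiber number density n(x,t) along the chest-to-navel
line then obeys a 1-D advection equation with a constant source A
(fibers abraded off the shirt),

    ∂n/∂t + ū ∂n/∂x = A,   n(x,0) = n₀(x),

solved by characteristics as n = At + n₀(x − ūt). The navel at x = L
absorbs at rate ū·n(L,t), so the accreted count is
N_B(t) = Aūt²/2 + ∫ₗ₋ᵤₜᴸ n₀ dx and the accreted mass m_B = m_L·N_B with
m_L = ρπd²l/4. Lint mass grows linearly at first (the fibers initially
present) and quadratically at long times (the source), reaching about a
milligram over a 10-hour day — the observed order of magnitude.

The package provides three independent embodiments that the test suite
holds to mutual agreement: the closed form above, a conservative
finite-volume upwind solver (`solve_transport()`), and a stochastic
per-breathing-cycle fiber simulator (`run_sim()`).

## Worked example

```r
library(lintflux)
m <- lint_model()          # nominal parameters
m
#> Navel lint accretion model (friction-ratchet transport)
#>   drift velocity u_bar  2.717e-05 m/s (0.000163 m per 6 s breath)
#>   fill time L/u_bar     3680 s (1.02 hr)
#>   fiber mass m_L        3.534e-11 kg
#>   initial profile       constant, 10 fibers total

predict(m, times = c(600, 3600, 36000))
#>     t_s n_at_navel_per_m   N_B_fibers       m_B_kg regime
#> 1   600              700     6.521739 2.304973e-10  short
#> 2  3600             3700   185.869565 6.569173e-09  short
#> 3 36000            36000 17618.695652 6.226961e-07   long

reproduce_paper()
#> Headline estimates (order-of-magnitude model)
#>   fabric tension gamma        47 N/m
#>   drift velocity u_bar        2.717e-05 m/s  [floor power of ten: 1e-05]
#>   source rate A               1 /m/s (heuristic 1 fiber/breath: 1.67)  [nearest: 1]
#>   fill time L/u_bar           3680 s = 1.02 hr  [rounds to 1 hr]
#>   m_B after 10 hr (t^2 law)   0.622 mg  [nearest power of ten: 1 mg]
#>   m_B at fill time (linear)   0.353 ug  [floor power of ten: 0.1 ug]
#>   reported experimental mean lint mass: 1.82 mg (context only, not computed)
```

Reading the numbers: a fiber advances 0.16 mm per breath, so the 10 cm
domain empties its initial population into the navel in about an hour
(3680 s). After that the shirt's own shedding dominates: by hour ten the
quadratic law has accreted ~17,600 fibers, 0.62 mg of lint — the same
order as the measured mean mass of real specimens (1.82 mg). The fibers
deposited by a drying towel contribute well under a microgram, which is
why lint color matches the shirt worn, not the towel.

`simulate(m, nsim = 200, seed = 1)` runs the discrete-fiber ratchet;
`solve_transport(default_params(), grid = grid_spec(512, t_end = 3680))`
runs the upwind solver; both land on the closed-form N_B within their
stated tolerances (2% for the solver at 512 cells, 3 standard errors for
the ensemble mean). The methods vignette
(`vignettes/lint-transport-model.Rmd`) documents the model, the boundary
conventions and all numerical choices.

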