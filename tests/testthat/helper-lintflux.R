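# Shared fixtures for the suite. All reference numbers below were frozen
# from independent hand evaluation of the closed-form expressions
# (u_bar = 1/36800 m/s exactly at nominal parameters, so the fill time is
# exactly 3680 s).

ref <- list(
  F_N = 1e-11,                    # 100 * 1e-5 * 1e-5 * 1e-3
  U_plus = 1.0869565217391304e-4, # 0.2 * 1e-11 / 1.84e-8
  u_bar = 1 / 36800,              # 0.1 * 1e-11 / (2 * 1.84e-8)
  dx_cycle = 6 / 36800,
  m_L = 3.5342917352885173e-11,   # 450 * pi * 1e-10 * 1e-3 / 4
  fill_s = 3680,
  m10h_kg = 6.223426751268909e-7, # m_L * 1 * u_bar * 36000^2 / 2
  m_fill_kg = 3.5342917352885173e-10  # m_L * 100 * 0.1
)

default_n0 <- function(params = default_params()) {
  density_profile("constant", level = params$transport$n0_level,
                  L = params$transport$L)
}

# tabulated copy of a profile, sampled on a uniform grid
tabulate_profile <- function(profile, n_points = 401L) {
  x <- seq(0, profile$L, length.out = n_points)
  density_profile("tabulated",
                  table = data.frame(x = x, n = profile_eval(profile, x)),
                  L = profile$L)
}
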