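test_that("a fiber near the navel is captured within two cycles", {
  p <- default_params()
  cfg <- sim_config(p, n_cycles = 2, initial_mode = "none",
                    source_mode = "deterministic")
  cfg$params$transport$A <- 0   # no injection at all
  state <- list(positions = 0.1 - ref$dx_cycle / 2, absorbed = 0L,
                injected = 0L, cycle = 0L, ever_clamped = FALSE)
  state <- step_cycle(state, cfg)
  state <- step_cycle(state, cfg)
  expect_equal(state$absorbed, 1)
  expect_length(state$positions, 0)
})

test_that("symmetric friction gives no net drift at cycle boundaries", {
  p <- default_params()
  p$friction <- friction_set(0.3, 0.1, 0.1)   # U+ = U-, no ratchet
  p$transport$A <- 0
  cfg <- sim_config(p, n_cycles = 1, initial_mode = "none")
  x0 <- c(0.02, 0.05, 0.08)
  state <- list(positions = x0, absorbed = 0L, injected = 0L, cycle = 0L,
                ever_clamped = rep(FALSE, 3))
  state <- step_cycle(state, cfg)
  expect_equal(state$positions, x0)
})

test_that("interior fibers advance exactly u_bar * T per cycle", {
  p <- default_params()
  p$transport$A <- 0
  cfg <- sim_config(p, n_cycles = 1, initial_mode = "none")
  x0 <- seq(0.01, 0.08, length.out = 12)
  state <- list(positions = x0, absorbed = 0L, injected = 0L, cycle = 0L,
                ever_clamped = rep(FALSE, length(x0)))
  state <- step_cycle(state, cfg)
  expect_equal(state$positions - x0, rep(ref$dx_cycle, length(x0)),
               tolerance = 1e-12)
})

test_that("absorbed count does not depend on fiber processing order", {
  p <- default_params()
  p$transport$A <- 0
  cfg <- sim_config(p, n_cycles = 1, initial_mode = "none")
  x0 <- seq(0.09, 0.0999, length.out = 30)
  run_once <- function(x) {
    s <- list(positions = x, absorbed = 0L, injected = 0L, cycle = 0L,
              ever_clamped = rep(FALSE, length(x)))
    step_cycle(s, cfg)$absorbed
  }
  set.seed(2)
  expect_equal(run_once(sample(x0)), run_once(x0))
})

test_that("identical seeds reproduce trajectories; different seeds differ", {
  p <- default_params()
  cfg <- sim_config(p, n_cycles = 80, n_replicates = 4, seed = 99)
  s1 <- run_sim(cfg); s2 <- run_sim(cfg)
  expect_identical(s1$absorbed, s2$absorbed)
  expect_identical(s1$live, s2$live)
  cfg2 <- sim_config(p, n_cycles = 80, n_replicates = 4, seed = 100)
  expect_false(identical(run_sim(cfg2)$live, s1$live))
})

test_that("the caller's RNG state survives a simulation run", {
  set.seed(1234)
  before <- .Random.seed
  invisible(run_sim(sim_config(default_params(), n_cycles = 10, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("count conservation holds exactly every cycle in both domain modes", {
  p <- default_params()
  for (mode in c("open", "closed")) {
    cfg <- sim_config(p, n_cycles = 200, n_replicates = 3, seed = 17,
                      domain_mode = mode)
    sim <- run_sim(cfg)
    # at the final cycle: live + absorbed = initial + injected, per replicate
    final <- sim$live[201, ] + sim$absorbed[201, ]
    expect_identical(as.integer(final),
                     as.integer(sim$initial_counts + sim$injected_counts))
    # absorbed and live+absorbed are non-decreasing cycle over cycle
    expect_true(all(apply(sim$absorbed, 2, function(a) all(diff(a) >= 0))))
    expect_true(all(apply(sim$live + sim$absorbed, 2,
                          function(tot) all(diff(tot) >= 0))))
  }
})

test_that("with no source every replicate eventually absorbs its initial fibers", {
  p <- default_params()
  p$transport$A <- 0
  n_cycles <- ceiling(ref$fill_s / 6) + 2
  cfg <- sim_config(p, n_cycles = n_cycles, n_replicates = 5, seed = 31)
  sim <- run_sim(cfg)
  expect_equal(sim$initial_counts, rep(10L, 5))
  expect_equal(sim$absorbed[n_cycles + 1, ], sim$initial_counts)
  expect_equal(sim$live[n_cycles + 1, ], rep(0L, 5))
})

test_that("ensemble mean accretion tracks the closed form within 3 standard errors", {
  p <- default_params()
  n_rep <- 60
  cyc <- round(0.5 * ref$fill_s / 6)
  sim <- run_sim(sim_config(p, n_cycles = cyc, n_replicates = n_rep,
                            seed = 4))
  fin <- sim$absorbed[cyc + 1, ]
  exact <- accreted_count(cyc * 6, 1, ref$u_bar, default_n0())
  se <- stats::sd(fin) / sqrt(n_rep)
  expect_lt(abs(mean(fin) - exact), 3 * se)
})

test_that("closed-domain clamping leaves pre-fill accretion essentially unchanged", {
  p <- default_params()
  cyc <- round(0.5 * ref$fill_s / 6)
  n_rep <- 40
  means <- vapply(c("open", "closed"), function(mode) {
    sim <- run_sim(sim_config(p, n_cycles = cyc, n_replicates = n_rep,
                              seed = 8, domain_mode = mode))
    mean(sim$absorbed[cyc + 1, ])
  }, numeric(1))
  exact <- accreted_count(cyc * 6, 1, ref$u_bar, default_n0())
  expect_lt(abs(means["closed"] - exact) / exact, 0.1)
  expect_lt(abs(means["open"] - exact) / exact, 0.1)
})

test_that("drift velocity is recovered from tracked trajectories within 1%", {
  p <- default_params()
  p$transport$A <- 0
  p$transport$n0_level <- 300   # 30 tracked fibers: a few reach the navel
  cfg <- sim_config(p, n_cycles = 40, n_replicates = 1, seed = 12,
                    track = TRUE)
  sim <- run_sim(cfg)
  u_hat <- estimate_u_bar(sim$tracked[[1]][1:31, , drop = FALSE],
                          sim$times[1:31])
  expect_equal(u_hat, ref$u_bar, tolerance = 0.01)

  # doubled pressure doubles the recovered velocity
  p2 <- default_params(); p2$garment$p <- 200; p2$transport$A <- 0
  p2$transport$n0_level <- 300
  sim2 <- run_sim(sim_config(p2, n_cycles = 20, n_replicates = 1, seed = 12,
                             track = TRUE))
  u_hat2 <- estimate_u_bar(sim2$tracked[[1]][1:16, , drop = FALSE],
                           sim2$times[1:16])
  expect_equal(u_hat2, 2 * ref$u_bar, tolerance = 0.01)

  # no ratchet, no drift
  p3 <- default_params(); p3$friction <- friction_set(0.3, 0.1, 0.1)
  p3$transport$A <- 0
  p3$transport$n0_level <- 300
  sim3 <- run_sim(sim_config(p3, n_cycles = 15, n_replicates = 1, seed = 12,
                             track = TRUE))
  u_hat3 <- estimate_u_bar(sim3$tracked[[1]], sim3$times)
  expect_equal(u_hat3, 0, tolerance = 1e-12)
})

test_that("velocity recovery demands enough data", {
  m <- matrix(0.05, nrow = 30, ncol = 4)
  expect_error(estimate_u_bar(m, seq_len(30)), ">= 10 tracked fibers")
  m2 <- matrix(0.05, nrow = 5, ncol = 20)
  expect_error(estimate_u_bar(m2, seq_len(5)), ">= 10 cycles")
})

test_that("deterministic source injects round(A * len * T) fibers per cycle", {
  p <- default_params()
  cfg <- sim_config(p, n_cycles = 50, seed = 3, initial_mode = "none",
                    source_mode = "deterministic", domain_mode = "closed")
  sim <- run_sim(cfg)
  expect_equal(sim$injected_counts, 50L * as.integer(round(1 * 0.1 * 6)))
})
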