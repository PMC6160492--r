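test_that("density field reduces to the initial profile at t = 0 and translates it", {
  n0 <- default_n0()
  x <- seq(0, 0.1, length.out = 11)
  expect_equal(concentration(x, 0, A = 1, u_bar = ref$u_bar, n0 = n0),
               profile_eval(n0, x))
  # pure translation of the zero-extended constant: a step at x = u_bar * t
  t <- 1000
  front <- ref$u_bar * t
  n <- concentration(x, t, A = 0, u_bar = ref$u_bar, n0 = n0)
  expect_equal(n[x >= front], rep(100, sum(x >= front)))
  expect_equal(n[x < front], rep(0, sum(x < front)))
  # all initial mass past the navel once t > L/u_bar
  expect_equal(concentration(0.1, 1.5 * ref$fill_s, A = 0,
                             u_bar = ref$u_bar, n0 = n0), 0)
  expect_error(concentration(0.2, 0, 1, ref$u_bar, n0), "within")
  expect_error(concentration(0.05, -1, 1, ref$u_bar, n0), "t must")
})

test_that("accreted count has the plateau, the source branch and the zero origin", {
  n0 <- default_n0()
  expect_equal(accreted_count(0, 1, ref$u_bar, n0), 0)
  # at the fill time all 10 initial fibers (100/m * 0.1 m) have arrived
  expect_equal(accreted_count(ref$fill_s, 0, ref$u_bar, n0), 10)
  expect_equal(accreted_count(5 * ref$fill_s, 0, ref$u_bar, n0), 10)
  # source-only parabola
  z <- density_profile("zero", L = 0.1)
  t <- c(100, 1000, 5000)
  expect_equal(accreted_count(t, 1, ref$u_bar, z), ref$u_bar * t^2 / 2)
  expect_error(accreted_count(-1, 1, ref$u_bar, n0), "t must")
})

test_that("quadrature and closed form agree to machine precision for constant profiles", {
  set.seed(23)
  n0 <- default_n0()
  for (t in c(runif(6, 0, 2 * ref$fill_s), ref$fill_s)) {
    A <- runif(1, 0, 2)
    closed <- accreted_count(t, A, ref$u_bar, n0, method = "closed")
    quad <- accreted_count(t, A, ref$u_bar, n0, method = "quadrature")
    expect_equal(quad, closed, tolerance = 1e-12)
  }
})

test_that("accreted count is continuous at the fill time", {
  n0 <- default_n0()
  tf <- ref$fill_s
  below <- accreted_count(tf * (1 - 1e-12), 1, ref$u_bar, n0)
  at <- accreted_count(tf, 1, ref$u_bar, n0)
  above <- accreted_count(tf * (1 + 1e-12), 1, ref$u_bar, n0)
  expect_equal(below, at, tolerance = 1e-9)
  expect_equal(above, at, tolerance = 1e-9)
})

test_that("initial accretion rate equals u_bar * n0(L)", {
  n0 <- default_n0()
  h <- 1e-3 * ref$fill_s
  rate <- accreted_count(h, 0, ref$u_bar, n0) / h
  expect_equal(rate, ref$u_bar * profile_eval(n0, 0.1), tolerance = 1e-6)
})

test_that("with no source, navel count plus domain content is conserved", {
  gau <- density_profile("gaussian", L = 0.1)
  tab <- tabulate_profile(gau, 801L)
  total0 <- profile_integral(tab, 0, 0.1, method = "quadrature")
  for (t in c(500, 2000, 3680, 6000)) {
    in_domain <- stats::integrate(function(x)
      concentration(x, t, 0, ref$u_bar, tab), 0, 0.1,
      abs.tol = 1e-10, subdivisions = 500L)$value
    n_b <- accreted_count(t, 0, ref$u_bar, tab, method = "quadrature")
    expect_equal(n_b + in_domain, total0, tolerance = 1e-4)
  }
})

test_that("mass law is m_L times the count, with the frozen 10-hour value", {
  p <- default_params()
  expect_equal(accreted_mass(0, p), 0)
  t <- c(600, 3680, 36000)
  n0 <- default_n0()
  expect_equal(accreted_mass(t, p) / accreted_count(t, 1, ref$u_bar, n0),
               rep(ref$m_L, 3))
  expect_equal(longtime_mass(36000, p), ref$m10h_kg)
  # the long-time law equals the exact solution with no initial fibers
  expect_equal(accreted_mass(36000, p, n0 = density_profile("zero", L = 0.1)),
               longtime_mass(36000, p))
  expect_equal(longtime_mass(2 * 36000, p), 4 * ref$m10h_kg)
})

test_that("asymptotic laws bracket the exact solution", {
  p <- default_params()
  # long time: ratio -> 1
  expect_equal(accreted_mass(100 * ref$fill_s, p) /
                 longtime_mass(100 * ref$fill_s, p), 1, tolerance = 1e-2)
  # short time: linear law, and exact branch identity when A = 0
  expect_equal(shorttime_mass(ref$fill_s, p), ref$m_fill_kg)
  expect_equal(shorttime_mass(0, p), 0)
  t <- c(100, 1000, 3000)
  expect_equal(accreted_mass(t, p, A = 0), shorttime_mass(t, p))
  expect_equal(accreted_mass(1e-4 * ref$fill_s, p) /
                 shorttime_mass(1e-4 * ref$fill_s, p), 1, tolerance = 1e-2)
})

test_that("fill time is L over u_bar and scales as expected", {
  p <- default_params()
  expect_equal(fill_time(p), 3680)
  p2 <- default_params(); p2$transport$L <- 0.05
  expect_equal(fill_time(p2), 1840)
  p3 <- default_params(); p3$garment$p <- 200
  expect_equal(fill_time(p3), 1840)
  p4 <- default_params()
  p4$friction <- friction_set(0.3, 0.1, 0.1)
  expect_error(fill_time(p4), "u_bar")
})

test_that("order-of-magnitude conventions behave", {
  expect_equal(order_of_magnitude(0.62, "nearest"), 1)
  expect_equal(order_of_magnitude(0.35, "floor"), 0.1)
  expect_equal(order_of_magnitude(1, "nearest"), 1)
  expect_equal(order_of_magnitude(1, "floor"), 1)
  expect_equal(order_of_magnitude(c(9, 11), "nearest"), c(10, 10))
  expect_error(order_of_magnitude(0), "value")
})
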