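test_that("protraction factors reach their analytic limits", {
  mu <- f10b16$mu
  # one acute subfraction: no protraction
  expect_equal(g_mu(mu, 1, 7), 1, tolerance = 1e-9)
  expect_equal(g_mu(mu, 2, 0), 1, tolerance = 1e-9)
  # fully repaired subfractions: G -> 1/n
  for (n in c(2, 4, 8)) {
    expect_equal(g_mu(mu, n, 1e6), 1 / n, tolerance = 1e-9)
  }
  # instantaneous continuous exposure
  expect_equal(g_brenner(mu, 0), 1, tolerance = 1e-9)
  expect_equal(survival_basic(f10b16, 0), 1, tolerance = 1e-9)
})

test_that("two-subfraction incomplete-repair G matches its closed form", {
  # for n = 2 the pairwise sum collapses to G = (1 + theta)/2
  for (mu in c(0.3, f10b16$mu, t4_1$mu, 5)) {
    for (dt in c(0.1, 0.5, 1, 4)) {
      expect_equal(g_mu(mu, 2, dt), (1 + exp(-mu * dt)) / 2,
                   tolerance = 1e-12)
    }
  }
  expect_equal(g_mu(f10b16$mu, 2, 4), 0.50252, tolerance = 1e-5)
})

test_that("g_mu equals the brute-force pairwise theta-sum oracle", {
  set.seed(42)
  for (n in 1:16) {
    for (dt in c(0.05, 0.3, 1.7)) {
      mu <- runif(1, 0.2, 4)
      expect_equal(g_mu(mu, n, dt), oracle_g_pairwise(mu, n, dt),
                   tolerance = 1e-10)
    }
  }
})

test_that("g_brenner matches quadrature of the defining double integral", {
  x_grid <- exp(seq(log(1e-3), log(30), length.out = 25))
  for (x in x_grid) {
    expect_equal(g_brenner(mu = 1, tau = x), oracle_g_continuous(1, x),
                 tolerance = 1e-8)
  }
  # large-argument expansion 2(x - 1)/x^2
  expect_equal(g_brenner(1, 20), 2 * (20 - 1) / 400, tolerance = 1e-8)
})

test_that("g_keall reduces to g_brenner for a single exposure", {
  set.seed(7)
  for (i in 1:50) {
    mu <- runif(1, 0.1, 5)
    tau <- runif(1, 0.01, 2)
    expect_equal(g_keall(mu, 1, tau, runif(1, 0, 5)),
                 g_brenner(mu, tau), tolerance = 1e-9)
  }
})

test_that("g_keall converges to g_mu as exposures become instantaneous", {
  set.seed(11)
  for (i in 1:50) {
    mu <- runif(1, 0.2, 4)
    n <- sample(2:10, 1)
    dt <- runif(1, 0.05, 5)
    expect_equal(g_keall(mu, n, tau = 1e-6, delta_t = dt),
                 g_mu(mu, n, dt), tolerance = 1e-4)
  }
  # and delegates exactly at tau = 0, where the kernel is singular
  expect_identical(g_keall(2, 3, 0, 1), g_mu(2, 3, 1))
})

test_that("g_keall matches the pairwise finite-exposure integral oracle", {
  for (n in c(2, 3, 4)) {
    for (cfg in list(c(mu = 1.3228, tau = 0.0412, dt = 0.5),
                     c(mu = 2.015, tau = 0.02, dt = 2),
                     c(mu = 0.8, tau = 0.3, dt = 0.1))) {
      expect_equal(
        g_keall(cfg[["mu"]], n, cfg[["tau"]], cfg[["dt"]]),
        oracle_g_finite_train(cfg[["mu"]], n, cfg[["tau"]], cfg[["dt"]]),
        tolerance = 1e-8
      )
    }
  }
  # widely separated exposures: cross term dies, only the averaged
  # per-exposure kernel survives
  expect_equal(g_keall(1.3228, 4, 0.05, 1e4),
               g_brenner(1.3228, 0.05) / 4, tolerance = 1e-12)
})

test_that("all G values and survivals stay in (0, 1]", {
  set.seed(3)
  for (i in 1:100) {
    mu <- runif(1, 0.05, 6)
    n <- sample(1:12, 1)
    tau <- runif(1, 1e-4, 0.5)
    dt <- runif(1, 0, 8)
    gs <- c(g_mu(mu, n, dt), g_brenner(mu, tau), g_keall(mu, n, tau, dt))
    expect_true(all(gs > 0 & gs <= 1 + 1e-12))
  }
  sch <- fraction_scheme(6, 4, 90)
  for (m in c("basic", "mu", "brenner", "keall")) {
    s <- survival_complete(t4_1, sch, m)$survival
    expect_true(s > 0 && s <= 1)
  }
})

test_that("g_mu decreases and survival rises with the interval", {
  dts <- seq(0.1, 6, by = 0.35)
  for (n in c(2, 4, 8)) {
    g <- g_mu(t4_1$mu, n, dts)
    expect_true(all(diff(g) < 0))
  }
  s <- vapply(c(15, 30, 60, 120, 180, 240), function(Tm) {
    survival_complete(f10b16, fraction_scheme(4, 2, Tm), "mu")$survival
  }, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("acute 4 Gy survival agrees with the published values", {
  expect_equal(survival_basic(f10b16, 4), 0.513, tolerance = 0.005)
  expect_equal(survival_basic(t4_1, 4), 0.445, tolerance = 0.005)
  expect_error(survival_basic(f10b16, -1),
               class = "lqfrac_validation_error")
})

test_that("survival_complete dispatches and stores consistent fields", {
  sch <- fraction_scheme(4, 2, 240)
  basic <- survival_complete(f10b16, sch, "basic")
  expect_identical(basic$g_value, 1)
  expect_equal(basic$survival, survival_basic(f10b16, 4))

  mu_pred <- survival_complete(f10b16, sch, "mu")
  expect_equal(mu_pred$survival, 0.591, tolerance = 0.005)
  expect_equal(survival_complete(t4_1, sch, "mu")$survival, 0.613,
               tolerance = 0.005)
  # the stored pieces satisfy S = exp(-aD - G b D^2)
  expect_equal(mu_pred$survival,
               exp(-f10b16$alpha * 4 - mu_pred$g_value * f10b16$beta * 16),
               tolerance = 1e-12)

  # one subfraction: mu model is the acute limit
  cont <- fraction_scheme(4, 1, 5)
  expect_identical(survival_complete(f10b16, cont, "mu")$g_value, 1)
  expect_error(survival_complete(f10b16, sch, "nope"))
})

test_that("the shorter-half-time, higher-beta line gains more from protraction", {
  sch <- fraction_scheme(4, 2, 240) # delta_t = 4 h
  gain <- function(p) {
    survival_complete(p, sch, "mu")$survival / survival_basic(p, 4)
  }
  expect_gte(gain(t4_1), gain(f10b16))
})
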