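test_that("deterministic division returns exactly the mean waiting time", {
  expect_identical(sample_waiting_time(Inf, 1), 1)
  expect_identical(sample_waiting_time("inf", 2), 0.5)
  expect_identical(sample_waiting_time(Inf, 0.25, n = 3), rep(4, 3))
})

test_that("gamma waiting times have mean 1/rate and variance 1/(k rate^2)", {
  set.seed(31)
  n <- 2e4
  for (k in c(1, 2, 8)) {
    for (rate in c(1, 2)) {
      w <- sample_waiting_time(k, rate, n)
      se_mean <- 1 / (rate * sqrt(k * n))
      expect_lt(abs(mean(w) - 1 / rate), 4 * se_mean)
      v_true <- 1 / (k * rate^2)
      se_var <- v_true * sqrt((2 + 6 / k) / n)
      expect_lt(abs(stats::var(w) - v_true), 4 * se_var)
    }
  }
})

test_that("invalid rates and shapes are rejected", {
  expect_error(sample_waiting_time(1, 0), "positive")
  expect_error(sample_waiting_time(1, -2), "positive")
  expect_error(sample_waiting_time(0, 1), "positive")
  expect_error(sample_residual_waiting_time(1, 1, -0.5), "nonnegative")
  expect_error(sample_residual_waiting_time(100, 1, 1e6), "tail mass")
})

test_that("exponential division is memoryless: residuals ignore tau", {
  set.seed(32)
  w <- vapply(1:5000, function(i) sample_residual_waiting_time(1, 1, 5),
              numeric(1))
  ks <- suppressWarnings(stats::ks.test(w, stats::pexp, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("residual draws at tau = 0 follow the unconditioned gamma", {
  set.seed(33)
  a <- vapply(1:4000, function(i) sample_residual_waiting_time(8, 2, 0),
              numeric(1))
  b <- sample_waiting_time(8, 2, 4000)
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("conditioned residual mean matches numerical quadrature", {
  k <- 100; rate <- 1; tau <- 0.9
  # residual density: gamma(total | k, k*rate) truncated at total > tau
  tail_mass <- stats::pgamma(tau, k, rate = k * rate, lower.tail = FALSE)
  mean_resid <- stats::integrate(function(x) {
    (x - tau) * stats::dgamma(x, k, rate = k * rate) / tail_mass
  }, lower = tau, upper = Inf)$value
  set.seed(34)
  w <- vapply(1:2e4, function(i) {
    sample_residual_waiting_time(k, rate, tau)
  }, numeric(1))
  expect_lt(abs(mean(w) - mean_resid), 4 * stats::sd(w) / sqrt(length(w)))
})

test_that("overdue deterministic divisions fire immediately", {
  expect_identical(sample_residual_waiting_time(Inf, 1, 0.25), 0.75)
  expect_equal(sample_residual_waiting_time(Inf, 1, 2), 1e-9)
})

test_that("rates compose multiplicatively and monotonically", {
  expect_identical(compose_rate(1, 1, 1, 1, 1), 1)
  expect_identical(compose_rate(1, 0, 1, 1, 1), 0)  # a TDC never divides
  expect_identical(compose_rate(2, 1, 100, 1, 0.5), 100)
  set.seed(35)
  for (i in 1:20) {
    x <- runif(5, 0, 3)
    bump <- sample.int(5, 1)
    y <- x
    y[bump] <- y[bump] + runif(1)
    expect_gte(do.call(compose_rate, as.list(y)),
               do.call(compose_rate, as.list(x)))
  }
})

test_that("driver effects multiply as prod(1 + s), clamped at zero", {
  expect_identical(driver_effect_product(numeric(0)), 1)
  expect_identical(driver_effect_product(99), 100)
  expect_equal(driver_effect_product(c(0.2, 0.5)), 1.8)
  expect_identical(driver_effect_product(-2), 0)  # lethal-equivalent
  set.seed(36)
  for (i in 1:20) {
    s <- stats::rnorm(sample.int(6, 1))
    expect_equal(driver_effect_product(s),
                 driver_effect_product(s[sample.int(length(s))]))
    s2 <- stats::rnorm(3)
    expect_equal(driver_effect_product(c(s, s2)),
                 driver_effect_product(s) * driver_effect_product(s2))
  }
})

test_that("density coefficient implements constant/step/linear models", {
  expect_identical(e2_coefficient("constant", 0), 1)
  expect_identical(e2_coefficient("step", 0), 0)
  expect_identical(e2_coefficient("step", 0.3), 1)
  expect_identical(e2_coefficient("linear", 0.25), 0.25)
})

test_that("driver mutations arrive at rate mu per division per class", {
  cfg0 <- sim_config(mu_beta = 0, mu_delta = 0, mu_rho = 0)
  set.seed(37)
  for (i in 1:20) {
    m <- draw_new_mutations(cfg0)
    expect_identical(lengths(m), c(beta = 0L, delta = 0L, rho = 0L))
  }
  cfg1 <- sim_config(mu_beta = 1, sbar_beta = 0.2, sigma_beta = 0)
  m <- draw_new_mutations(cfg1)
  expect_identical(m$beta, 0.2)
  expect_length(m$delta, 0)
  cfgp <- sim_config(mu_beta = 0.1, sbar_beta = 0.5, sigma_beta = 0.1)
  hits <- sum(vapply(1:2000, function(i) {
    length(draw_new_mutations(cfgp)$beta)
  }, integer(1)))
  expect_lt(abs(hits / 2000 - 0.1), 4 * sqrt(0.1 * 0.9 / 2000))
})

test_that("coupled division/death outcome is Bernoulli(alpha)", {
  set.seed(38)
  expect_identical(coupled_division_death_outcome(0), "division")
  expect_identical(coupled_division_death_outcome(1), "death")
  deaths <- mean(vapply(1:4000, function(i) {
    coupled_division_death_outcome(0.2) == "death"
  }, logical(1)))
  expect_lt(abs(deaths - 0.2), 4 * sqrt(0.2 * 0.8 / 4000))
})
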