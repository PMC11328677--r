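test_that("first-passage density matches a large-sample simulation histogram", {
  n <- 1e6
  tt <- sim_crossings(n, A = 2, b = 2.5, v = 2.5, s = 1, seed = 42)
  crossed <- !is.na(tt)
  br <- seq(0.12, 4, length.out = 101)
  inside <- tt[crossed & tt >= br[1] & tt <= br[101]]
  h <- hist(inside, breaks = br, plot = FALSE)
  expected <- n * fpt_bin_masses(br, A = 2, b = 2.5, v = 2.5, s = 1)
  se <- sqrt(pmax(expected, 9))
  expect_true(all(abs(h$counts - expected) <= 4 * se))
})

test_that("density integrates to the crossing probability", {
  n <- 1e6
  tt <- sim_crossings(n, A = 2, b = 2.5, v = 2.5, s = 1, seed = 7)
  p_sim <- mean(!is.na(tt))
  p_int <- integrate(dlba_fpt, 0, Inf, A = 2, b = 2.5, v = 2.5, s = 1,
                     rel.tol = 1e-9)$value
  expect_gte(p_int, 0)
  expect_lte(p_int, 1)
  expect_lt(abs(p_int - p_sim), 3 * sqrt(p_sim * (1 - p_sim) / n) + 1e-6)
  # strongly positive drift: crossing is near-certain
  p_sure <- integrate(dlba_fpt, 0, Inf, A = 1, b = 1.5, v = 4, s = 0.5)$value
  expect_equal(p_sure, 1, tolerance = 1e-6)
})

test_that("distribution function is consistent with the density and simulation", {
  # vanishing decision time
  expect_equal(dlba_fpt(1e-9, A = 2, b = 2.5, v = 2.5, s = 1), 0,
               tolerance = 1e-12)
  expect_equal(plba_fpt(1e-9, A = 2, b = 2.5, v = 2.5, s = 1), 0,
               tolerance = 1e-12)
  expect_identical(dlba_fpt(c(-1, 0), A = 2, b = 2.5, v = 2.5, s = 1),
                   c(0, 0))
  # numerical derivative of the CDF recovers the density
  h <- 1e-4
  for (t in c(0.5, 0.9, 1.4, 2.2)) {
    num <- (plba_fpt(t + h, 2, 2.5, 2.5, 1) -
              plba_fpt(t - h, 2, 2.5, 2.5, 1)) / (2 * h)
    ana <- dlba_fpt(t, 2, 2.5, 2.5, 1)
    expect_equal(num, ana, tolerance = 1e-5)
  }
  # CDF at t = 1 vs empirical defective CDF
  n <- 1e6
  tt <- sim_crossings(n, A = 2, b = 2.5, v = 2.5, s = 1, seed = 3)
  F_sim <- mean(!is.na(tt) & tt <= 1)
  F_an <- plba_fpt(1, 2, 2.5, 2.5, 1)
  expect_lt(abs(F_an - F_sim), 3 * sqrt(F_sim * (1 - F_sim) / n))
})

test_that("distribution function is monotone nondecreasing", {
  grid <- seq(1e-3, 10, length.out = 1000)
  for (acc in list(c(A = 2, b = 2.5, v = 2.5, s = 1),
                   c(A = 0.5, b = 3, v = -0.5, s = 1.5),
                   c(A = 1, b = 4.5, v = 0.8, s = 0.4))) {
    F <- plba_fpt(grid, acc["A"], acc["b"], acc["v"], acc["s"])
    expect_true(all(diff(F) >= -1e-12))
    expect_true(all(F >= 0 & F <= 1))
  }
})

test_that("defective trial densities account for all terminating mass", {
  p <- table1_params()
  # the defective density has a 1/t^2 tail (near-zero positive drifts),
  # so the integral needs the infinite upper limit
  mass <- sapply(c("true", "false"), function(ch) {
    integrate(function(t) dlba_trial(t, rep(ch, length(t)), p),
              p[["t0"]], Inf, rel.tol = 1e-9)$value
  })
  p_none <- pnorm(-p[["v_true"]] / p[["sv"]]) * pnorm(-p[["v_false"]] / p[["sv"]])
  expect_lte(sum(mass), 1)
  expect_equal(sum(mass), 1 - p_none, tolerance = 1e-4)
  # renormalized densities integrate to exactly 1
  mass_rn <- sapply(c("true", "false"), function(ch) {
    integrate(function(t) dlba_trial(t, rep(ch, length(t)), p,
                                     renormalize = TRUE),
              p[["t0"]], Inf, rel.tol = 1e-9)$value
  })
  expect_equal(sum(mass_rn), 1, tolerance = 1e-4)
})

test_that("quadrature choice probability matches simulated choice proportions", {
  p <- table1_params()
  p_true <- integrate(function(t) dlba_trial(t, rep("true", length(t)), p),
                      p[["t0"]], Inf, rel.tol = 1e-9)$value
  n <- 2e5
  tr <- rlba(p, n, seed = 9)
  prop <- mean(tr$choice == "true")
  # simulation redraws double-negative-drift trials; condition the
  # analytic probability on termination for comparability
  p_none <- pnorm(-p[["v_true"]] / p[["sv"]]) * pnorm(-p[["v_false"]] / p[["sv"]])
  expect_lt(abs(p_true / (1 - p_none) - prop),
            3 * sqrt(prop * (1 - prop) / n))
})

test_that("trial log-likelihood handles the rt <= t0 boundary", {
  p <- table1_params()
  expect_identical(lba_trial_loglik(p[["t0"]], "true", p), -Inf)
  expect_identical(lba_trial_loglik(c(1, 0.2), c("true", "false"), p), -Inf)
  expect_true(is.finite(lba_trial_loglik(1.0, "true", p)))
})

test_that("compiled likelihood agrees with the pure-R reference", {
  set.seed(21)
  for (rep in 1:5) {
    p <- lba_params(A = runif(1, 0.3, 2.5), B = runif(1, 0.3, 3),
                    v_true = runif(1, 1.3, 3.5), v_false = runif(1, 0.1, 1.5),
                    sv = runif(1, 0.3, 2), t0 = runif(1, 0.1, 0.4))
    tr <- rlba(p, 200, seed = 100 + rep)
    llR <- lba_trial_loglik(tr$rt, tr$choice, p)
    theta <- matrix(p, 1, dimnames = list(NULL, names(p)))
    llC <- hlba:::lba_loglik_chains(theta, tr$rt,
                                    as.integer(tr$choice == "true"), FALSE)
    expect_equal(llC, llR, tolerance = 1e-10)
    llR_rn <- lba_trial_loglik(tr$rt, tr$choice, p, renormalize = TRUE)
    llC_rn <- hlba:::lba_loglik_chains(theta, tr$rt,
                                       as.integer(tr$choice == "true"), TRUE)
    expect_equal(llC_rn, llR_rn, tolerance = 1e-10)
  }
})

test_that("trial simulation is reproducible and degenerates to a known race", {
  p <- table1_params()
  expect_identical(rlba(p, 100, seed = 5), rlba(p, 100, seed = 5))
  # vanishing start-point range and drift noise: deterministic race
  p0 <- lba_params(A = 1e-9, B = 2.5, v_true = 2.5, v_false = 0.8,
                   sv = 1e-9, t0 = 0.3)
  tr <- rlba(p0, 50, seed = 1)
  expect_true(all(tr$choice == "true"))
  expect_equal(tr$rt, rep(2.5 / 2.5 + 0.3, 50), tolerance = 1e-6)
})

test_that("generating parameters beat perturbed parameters in likelihood", {
  p <- table1_params()
  tr <- rlba(p, 1e4, seed = 13)
  p_bad <- p
  p_bad["v_true"] <- p[["v_true"]] + 0.5
  expect_gt(lba_trial_loglik(tr$rt, tr$choice, p),
            lba_trial_loglik(tr$rt, tr$choice, p_bad))
})

test_that("parameter validation rejects invalid accumulators", {
  expect_error(dlba_fpt(1, A = 2, b = 1.5, v = 2, s = 1), "exceed")
  expect_error(dlba_fpt(1, A = 2, b = 2.5, v = 2, s = -1), "positive")
  expect_error(lba_params(A = 2, B = -0.1, v_true = 2, v_false = 1,
                          sv = 1, t0 = 0.3), "positive")
  expect_error(dlba_trial(1, "maybe", table1_params()), "choice")
})
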