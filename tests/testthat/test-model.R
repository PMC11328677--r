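test_that("scaled Beta priors are proper and uniform when alpha = beta = 1", {
  pr <- scaled_beta(1, 1, 0, 3)
  expect_equal(dscaled_beta(1.5, pr), 1 / 3)
  expect_equal(dscaled_beta(c(-0.1, 3.1), pr), c(0, 0))
  expect_equal(integrate(dscaled_beta, 0, 3, prior = pr)$value, 1,
               tolerance = 1e-8)
  pr2 <- scaled_beta(2, 5, -1, 2)
  expect_equal(integrate(dscaled_beta, -1, 2, prior = pr2)$value, 1,
               tolerance = 1e-8)
  set.seed(1)
  expect_true(all(rscaled_beta(1000, pr) >= 0 & rscaled_beta(1000, pr) <= 3))
})

test_that("scale-setting policies shape the model as specified", {
  pm <- c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, t0 = 0.3)
  new <- hlba_model("new", pm)
  expect_true("sv" %in% new$free)
  expect_s3_class(new$mu_priors$sv, "scaled_beta")
  expect_equal(c(new$mu_priors$sv$lo, new$mu_priors$sv$hi), c(0.999, 1.001))
  expect_equal(new$mu_priors$sv$alpha, 1)
  expect_equal(new$mu_priors$sv$beta, 1)
  for (p in new$free) {
    expect_equal(c(new$sigma_priors[[p]]$lo, new$sigma_priors[[p]]$hi),
                 c(0, 3))
  }
  classic <- hlba_model("classic", pm)
  expect_false("sv" %in% classic$free)
  expect_equal(classic$fixed[["sv"]], 1)
  expect_error(hlba_model("other", pm))
  fixed_t0 <- hlba_model("new", pm, fix_t0 = TRUE)
  expect_false("t0" %in% fixed_t0$free)
  expect_equal(fixed_t0$fixed[["t0"]], 0.3)
})

test_that("study-1 prior-mean noise has the stated distribution", {
  tm <- c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, t0 = 0.3, sv = 1)
  expect_identical(noisy_prior_means_study1(tm, seed = 1),
                   noisy_prior_means_study1(tm, seed = 1))
  expect_equal(noisy_prior_means_study1(tm, seed = 1, noise_sd = 0), tm)
  # sv is never perturbed: its prior is the scale constraint
  expect_equal(noisy_prior_means_study1(tm, seed = 2)[["sv"]], 1)
  devs <- vapply(1:4000, function(s) {
    abs(noisy_prior_means_study1(tm, seed = s)[["A"]] - 2)
  }, numeric(1))
  # half-normal mean: sd * sqrt(2/pi)
  expect_equal(mean(devs), 0.1 * sqrt(2 / pi),
               tolerance = 4 * 0.1 * sqrt(1 - 2 / pi) / sqrt(4000) /
                 (0.1 * sqrt(2 / pi)))
})

test_that("study-2 prior means are uniform within two standard errors", {
  tm <- c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, t0 = 0.3)
  sds <- c(A = 0.6, B = 0.6, v_true = 0.8, v_false = 0.8, t0 = 0.1)
  n <- 50
  draws <- vapply(1:3000, function(s) {
    noisy_prior_means_study2(tm, sds, n, seed = s)[["v_true"]]
  }, numeric(1))
  se <- 0.8 / sqrt(n)
  expect_true(all(draws >= 2.5 - 2 * se & draws <= 2.5 + 2 * se))
  ks <- suppressWarnings(
    ks.test(draws, "punif", 2.5 - 2 * se, 2.5 + 2 * se))
  expect_gt(ks$p.value, 0.01)
  expect_identical(noisy_prior_means_study2(tm, sds, n, seed = 9),
                   noisy_prior_means_study2(tm, sds, n, seed = 9))
  # n growing: prior means converge on the truth
  far <- noisy_prior_means_study2(tm, sds, n = 1e8, seed = 10)
  expect_equal(far, tm, tolerance = 1e-3)
})

test_that("log posterior decomposes into likelihood, link and hyper terms", {
  trials <- data.frame(dataset_id = "d", participant_id = 1, group = "all",
                       trial = 1, choice = "true", rt = 1.2,
                       stringsAsFactors = FALSE)
  pm <- c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, t0 = 0.3)
  model <- hlba_model("new", pm)
  p <- table1_params()
  ind <- matrix(p, 1, dimnames = list(NULL, names(p)))
  mu <- c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, sv = 1, t0 = 0.3)
  sigma <- c(A = 0.6, B = 0.6, v_true = 0.8, v_false = 0.8, sv = 0.4,
             t0 = 0.1)
  lp <- log_posterior(ind, mu, sigma, trials, model)
  # independent scalar recomputation of each term
  ltn <- function(x, m, s) dnorm(x, m, s, log = TRUE) - pnorm(m / s, log.p = TRUE)
  lik <- lba_trial_loglik(1.2, "true", p)
  link <- sum(vapply(model$free, function(q) ltn(p[[q]], mu[[q]], sigma[[q]]),
                     numeric(1)))
  hyper <- sum(vapply(setdiff(model$free, "sv"), function(q)
    ltn(mu[[q]], pm[[q]], 1), numeric(1))) +
    log(1 / 0.002) + length(model$free) * log(1 / 3)
  expect_equal(lp, lik + link + hyper, tolerance = 1e-8)
})

test_that("log posterior respects the scale-setting support", {
  trials <- tiny_trials(n_sub = 1, n_trials = 5)
  pm <- c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, t0 = 0.3)
  model <- hlba_model("new", pm)
  p <- table1_params()
  ind <- matrix(p, 1, dimnames = list(NULL, names(p)))
  mu <- c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, sv = 1.5, t0 = 0.3)
  sigma <- c(A = 0.6, B = 0.6, v_true = 0.8, v_false = 0.8, sv = 0.4,
             t0 = 0.1)
  expect_identical(log_posterior(ind, mu, sigma, trials, model), -Inf)
  mu["sv"] <- 1.0005
  expect_true(is.finite(log_posterior(ind, mu, sigma, trials, model)))
})

test_that("classic and new policies share the likelihood when sv = 1", {
  trials <- tiny_trials(n_sub = 2, n_trials = 20)
  pm <- c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, t0 = 0.3)
  new <- hlba_model("new", pm)
  classic <- hlba_model("classic", pm)
  p <- table1_params()  # sv = 1
  theta <- matrix(p, 1, dimnames = list(NULL, names(p)))
  d <- new$data_prep(trials)
  for (i in seq_along(d)) {
    expect_identical(new$loglik(theta, d[[i]]), classic$loglik(theta, d[[i]]))
  }
})

test_that("log posterior is invariant to participant ordering", {
  trials <- tiny_trials(n_sub = 3, n_trials = 10)
  pm <- c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, t0 = 0.3)
  model <- hlba_model("new", pm)
  set.seed(31)
  ind <- matrix(rep(table1_params(), each = 3), 3,
                dimnames = list(NULL, names(table1_params())))
  ind[, "v_true"] <- ind[, "v_true"] + runif(3, -0.2, 0.2)
  mu <- c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, sv = 1, t0 = 0.3)
  sigma <- c(A = 0.6, B = 0.6, v_true = 0.8, v_false = 0.8, sv = 0.4,
             t0 = 0.1)
  lp1 <- log_posterior(ind, mu, sigma, trials, model)
  perm <- c(3, 1, 2)
  trials2 <- do.call(rbind, lapply(perm, function(i)
    trials[trials$participant_id == i, ]))
  lp2 <- log_posterior(ind[perm, ], mu, sigma, trials2, model)
  expect_equal(lp1, lp2, tolerance = 1e-10)
})

test_that("the individual-level prior is a proper density", {
  ltn <- function(x, m, s) exp(dnorm(x, m, s, log = TRUE) -
                                 pnorm(m / s, log.p = TRUE))
  for (par in list(c(2, 0.6), c(0.8, 0.8), c(1, 0.4), c(0.3, 0.1))) {
    Z <- integrate(ltn, 0, Inf, m = par[1], s = par[2], rel.tol = 1e-10)$value
    expect_equal(Z, 1, tolerance = 1e-6)
  }
})
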