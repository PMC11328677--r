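test_that("Pearson recovery matches the product-moment formula", {
  x <- c(1.2, 2.1, 0.7, 3.3, 2.8, 1.9, 0.4, 2.2, 3.1, 1.5)
  y <- c(1.0, 2.4, 1.1, 3.0, 2.5, 2.2, 0.9, 2.0, 3.5, 1.2)
  out <- pearson_recovery(x, y)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_brute, tolerance = 1e-12)
  t_brute <- r_brute * sqrt(8) / sqrt(1 - r_brute^2)
  expect_equal(out$p, 2 * pt(-abs(t_brute), 8), tolerance = 1e-12)
  expect_equal(pearson_recovery(x, x)$r, 1)
  expect_equal(pearson_recovery(x, 2 * x + 3)$r, 1)
  expect_warning(z <- pearson_recovery(x, rep(1, 10)), "variance")
  expect_true(is.na(z$r))
})

test_that("ICC(2,1) matches a two-way ANOVA decomposition", {
  x <- c(9, 6, 8, 7, 10, 6, 5, 8)
  y <- c(2, 1, 4, 1, 5, 2, 1, 3)
  out <- icc_2_1(x, y)
  # independent route: crossed two-way ANOVA via aov()
  df <- data.frame(score = c(x, y),
                   subject = factor(rep(1:8, 2)),
                   rater = factor(rep(c("t", "e"), each = 8)))
  tab <- anova(aov(score ~ subject + rater, data = df))
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- 8; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(out$icc, icc_oracle, tolerance = 1e-10)
  expect_equal(out$msr, msr, tolerance = 1e-10)
  expect_equal(out$mse, mse, tolerance = 1e-10)
  expect_equal(out$p, pf(msr / mse, n - 1, (n - 1) * (k - 1),
                         lower.tail = FALSE), tolerance = 1e-10)
  expect_lt(out$ci[1], out$icc)
  expect_gt(out$ci[2], out$icc)
})

test_that("ICC(2,1) penalises absolute disagreement that Pearson ignores", {
  set.seed(3)
  x <- rnorm(40, 2, 0.8)
  expect_equal(icc_2_1(x, x)$icc, 1, tolerance = 1e-9)
  shifted <- icc_2_1(x, x + 2)
  expect_lt(shifted$icc, pearson_recovery(x, x + 2)$r)
  # property: ICC <= r (+eps) whenever a systematic shift exists
  for (s in c(0.5, 1, 3)) {
    y <- x + s + rnorm(40, 0, 0.2)
    expect_lte(icc_2_1(x, y)$icc, pearson_recovery(x, y)$r + 1e-9)
  }
})

test_that("Fisher-Z averaging behaves as tanh(mean(atanh))", {
  expect_equal(fisher_z_mean(rep(0.37, 5)), 0.37, tolerance = 1e-12)
  expect_equal(fisher_z_mean(c(0.5, -0.5)), 0, tolerance = 1e-12)
  expect_equal(fisher_z_mean(c(0.9, 0.5)),
               tanh((atanh(0.9) + atanh(0.5)) / 2), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    rs <- runif(6, -0.95, 0.95)
    fz <- fisher_z_mean(rs)
    expect_gte(fz, min(rs))
    expect_lte(fz, max(rs))
  }
  expect_warning(fisher_z_mean(c(1, 0.5)), "clipped")
})

test_that("PSRF filtering removes exactly the non-converged participants", {
  conv <- data.frame(participant = as.character(1:6),
                     max_psrf = c(1.0, 1.3, 1.05, 1.09, 2.0, 1.02),
                     converged = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  m <- matrix(1:12, 6, 2, dimnames = list(1:6, c("a", "b")))
  kept <- filter_by_psrf(m, conv)
  expect_equal(nrow(kept), 4)
  expect_identical(attr(kept, "excluded"), c("2", "5"))
  all_ok <- conv; all_ok$converged <- TRUE
  expect_equal(nrow(filter_by_psrf(m, all_ok)), 6)
  v <- filter_by_psrf(setNames(1:6, 1:6), conv)
  expect_equal(as.numeric(v), c(1, 3, 4, 6))
})

# build an hlba-classed object around hand-made draws so the DIC routine
# can be checked against known cases
manual_fit <- function(draws_array, trials, model, log_lik) {
  d <- fake_draws(draws_array, free = model$free, fixed = model$fixed,
                  log_lik = log_lik)
  d$par_names <- model$par_names
  structure(list(draws = d, model = model, trials = trials,
                 coef = posterior_means(d)), class = "hlba")
}

test_that("DIC reduces to the deviance at a degenerate posterior", {
  p <- table1_params()
  trials <- tiny_trials(n_sub = 2, n_trials = 30)
  model <- hlba_model("new", c(A = 2, B = 2.5, v_true = 2.5,
                               v_false = 0.8, t0 = 0.3))
  nch <- 4; nit <- 20
  ind <- array(rep(p[model$free], each = nch * nit * 2),
               c(nch, nit, 2, length(model$free)),
               dimnames = list(NULL, NULL, NULL, model$free))
  data <- model$data_prep(trials)
  theta <- matrix(p, 1, dimnames = list(NULL, names(p)))
  ll <- vapply(1:2, function(i) model$loglik(theta, data[[i]]), numeric(1))
  log_lik <- array(rep(ll, each = nch * nit), c(nch, nit, 2))
  fit <- manual_fit(ind, trials, model, log_lik)
  out <- dic(fit)
  expect_equal(out$per_participant$pd, c(0, 0), tolerance = 1e-8)
  expect_equal(out$per_participant$dic, -2 * ll, tolerance = 1e-8)
  expect_equal(out$total, sum(out$per_participant$dic))
})

test_that("DIC effective parameters approximate the true count on a normal model", {
  # one free location parameter per participant, flat-ish posterior spread
  # sigma^2/n around the MLE: pD should be close to 1 per participant
  set.seed(6)
  nobs <- 50
  toy <- hnorm_model(obs_sd = 1, mu_prior_mean = 5, mu_prior_sd = 3)
  ys <- list(rnorm(nobs, 4.8, 1), rnorm(nobs, 5.4, 1))
  draws <- run_mcmc(ys, toy,
                    sampler_settings(n_burn = 300, n_samples = 2000,
                                     thin = 2, n_chains = 8, seed = 23))
  fit <- structure(list(draws = draws, model = toy, trials = ys,
                        coef = posterior_means(draws)), class = "hlba")
  out <- dic(fit)
  expect_true(all(out$per_participant$pd > 0.5 & out$per_participant$pd < 1.6))
  expect_equal(out$total, sum(out$per_participant$dic))
})

test_that("DIC prefers the generating parameters over misspecified ones", {
  model <- hlba_model("new", c(A = 2, B = 2.5, v_true = 2.5,
                               v_false = 0.8, t0 = 0.3))
  nch <- 4; nit <- 15
  wins <- 0
  for (rep in 1:20) {
    p <- table1_params()
    trials <- tiny_trials(n_sub = 1, n_trials = 150, seed = 200 + rep)
    data <- model$data_prep(trials)
    make_ll <- function(centre) {
      set.seed(900 + rep)
      th <- matrix(rep(centre[model$free], each = nch * nit),
                   nch * nit, length(model$free),
                   dimnames = list(NULL, model$free))
      th <- th * matrix(exp(rnorm(length(th), 0, 0.02)), nrow(th))
      full <- matrix(rep(centre, each = nrow(th)), nrow(th),
                     length(centre), dimnames = list(NULL, names(centre)))
      full[, model$free] <- th
      ll <- model$loglik(full, data[[1]])
      list(ind = array(th, c(nch, nit, 1, length(model$free)),
                       dimnames = list(NULL, NULL, NULL, model$free)),
           ll = array(ll, c(nch, nit, 1)))
    }
    good <- make_ll(p)
    p_bad <- p; p_bad["v_true"] <- p[["v_true"]] + 1
    bad <- make_ll(p_bad)
    dic_good <- dic(manual_fit(good$ind, trials, model, good$ll))$total
    dic_bad <- dic(manual_fit(bad$ind, trials, model, bad$ll))$total
    if (dic_good < dic_bad) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("pooled t-tests match the textbook formula and df bookkeeping", {
  x <- c(5.1, 4.8, 5.6, 5.0)
  y <- c(4.2, 4.5, 4.1, 4.6)
  est <- matrix(c(x, y), 8, 1, dimnames = list(1:8, "sv"))
  groups <- rep(c("g1", "g2"), each = 4)
  out <- group_ttest(est, groups)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_brute <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(out$t, t_brute, tolerance = 1e-12)
  expect_equal(out$df, 6)
  expect_equal(out$p, 2 * pt(-abs(t_brute), 6), tolerance = 1e-12)
  expect_equal(out$mean_group1, mean(x))
  # identical groups: t = 0
  est0 <- matrix(rep(c(1, 2, 3, 4), 2), 8, 1,
                 dimnames = list(1:8, "sv"))
  expect_equal(group_ttest(est0, groups)$t, 0, tolerance = 1e-12)
  # 97 retained participants -> df = 95
  set.seed(7)
  est97 <- matrix(rnorm(97), 97, 1, dimnames = list(1:97, "sv"))
  g97 <- rep(c("g1", "g2"), c(49, 48))
  expect_equal(group_ttest(est97, g97)$df, 95)
})

test_that("recovery aggregation Fisher-averages across configurations", {
  mk <- function(r_a, icc_a) {
    structure(data.frame(parameter = "A", pearson_r = r_a, pearson_p = 0.01,
                         icc21 = icc_a, icc21_p = 0.01,
                         icc21_lo = icc_a - 0.1, icc21_hi = icc_a + 0.1),
              class = c("recovery_report", "data.frame"),
              n_retained = 10, excluded = character(0))
  }
  agg <- aggregate_recovery(list(mk(0.9, 0.8), mk(0.5, 0.4)))
  pe <- agg[agg$statistic == "Pearson", ]
  expect_equal(pe$lower, 0.5)
  expect_equal(pe$upper, 0.9)
  expect_equal(pe$mean, tanh((atanh(0.9) + atanh(0.5)) / 2),
               tolerance = 1e-12)
})
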