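# shared fixtures, all generated in code

table1_params <- function() {
  lba_params(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, sv = 1, t0 = 0.3)
}

# micro sampler settings for structural tests (not convergence checks)
micro_settings <- function(seed = 1, ...) {
  desk_settings(seed = seed, n_burn = 30, n_samples = 90, thin = 3, ...)
}

tiny_trials <- function(n_sub = 3, n_trials = 40, seed = 11,
                        p = table1_params()) {
  do.call(rbind, lapply(seq_len(n_sub), function(i) {
    tr <- rlba(p, n_trials, seed = seed + i)
    data.frame(dataset_id = "tiny", participant_id = i, group = "all",
               tr, stringsAsFactors = FALSE)
  }))
}

# single-accumulator crossing times; defective (NA = never crosses)
sim_crossings <- function(n, A, b, v, s, seed) {
  set.seed(seed)
  u <- runif(n, 0, A)
  d <- rnorm(n, v, s)
  ifelse(d > 0, (b - u) / d, NA_real_)
}

# hand-built posterior-draw object for metric tests
fake_draws <- function(ind, free = dimnames(ind)[[4]],
                       fixed = numeric(0), log_lik = NULL) {
  nsub <- dim(ind)[3]
  structure(list(
    individual = ind,
    hyper = array(0, c(dim(ind)[1], dim(ind)[2], 2 * length(free))),
    log_lik = if (is.null(log_lik)) {
      array(0, dim(ind)[1:3])
    } else log_lik,
    free = free, fixed = fixed,
    par_names = free,
    participants = as.character(seq_len(nsub)),
    groups = rep("all", nsub),
    accept_rate = c(individual = 0.3, hyper = 0.3),
    n_chains = dim(ind)[1],
    settings = micro_settings(), method = "new"
  ), class = "hlba_draws")
}

# numerical-integration oracle for the hierarchical normal testbed:
# p(Mu, Sigma | y) on a grid, individual effects integrated out
hnorm_quadrature <- function(ys, obs_sd = 1, mu_prior = c(5, 2),
                             sigma_hi = 3,
                             mu_grid = seq(0.6, 9.4, length.out = 441),
                             sig_grid = seq(0.02, 3, length.out = 150)) {
  n_i <- lengths(ys)
  ybar <- vapply(ys, mean, numeric(1))
  lpost <- matrix(0, length(mu_grid), length(sig_grid))
  for (j in seq_along(sig_grid)) {
    sig <- sig_grid[j]
    for (i in seq_along(ys)) {
      th <- seq(ybar[i] - 6 * obs_sd / sqrt(n_i[i]),
                ybar[i] + 6 * obs_sd / sqrt(n_i[i]), length.out = 241)
      lik <- exp(-n_i[i] * (th - ybar[i])^2 / (2 * obs_sd^2))
      link <- dnorm(outer(th, mu_grid, "-"), 0, sig) /
        rep(pnorm(mu_grid / sig), each = length(th))
      m_i <- colSums(lik * link) * (th[2] - th[1])
      lpost[, j] <- lpost[, j] + log(m_i)
    }
    lpost[, j] <- lpost[, j] +
      dnorm(mu_grid, mu_prior[1], mu_prior[2], log = TRUE) -
      pnorm(mu_prior[1] / mu_prior[2], log.p = TRUE)
  }
  w <- exp(lpost - max(lpost))
  w <- w / sum(w)
  mu_m <- sum(rowSums(w) * mu_grid)
  sig_m <- sum(colSums(w) * sig_grid)
  list(mu_mean = mu_m,
       mu_sd = sqrt(sum(rowSums(w) * (mu_grid - mu_m)^2)),
       sigma_mean = sig_m,
       sigma_sd = sqrt(sum(colSums(w) * (sig_grid - sig_m)^2)))
}

# analytic bin masses of the first-passage density (quadrature per bin,
# avoids midpoint-rule bias on steep flanks)
fpt_bin_masses <- function(br, A, b, v, s) {
  vapply(seq_len(length(br) - 1), function(i) {
    integrate(dlba_fpt, br[i], br[i + 1], A = A, b = b, v = v, s = s,
              rel.tol = 1e-9)$value
  }, numeric(1))
}
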