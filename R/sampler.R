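#' Sampler settings for hierarchical DE-MCMC
#'
#' Defaults follow the convention of multi-chain differential-evolution
#' MCMC for hierarchical evidence-accumulation models: the number of chains
#' is three times the number of free parameters (never fewer than 4, since
#' the Gelman-Rubin diagnostic needs multiple chains), a burn-in of 1,000
#' sweeps is followed by 12,000 sampling sweeps thinned by 12 (1,000 kept
#' draws per chain).
#'
#' @param n_burn burn-in sweeps (discarded).
#' @param n_samples post-burn-in sweeps; `n_samples / thin` are kept.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param n_chains number of interacting chains; `NULL` means
#'   `max(4, 3 * n_free)`.
#' @param seed integer seed; every random element of the run derives from it.
#' @param gamma DE step size; `NULL` means `2.38 / sqrt(2 d)` with `d` the
#'   block dimension.
#' @param jitter half-width of the uniform perturbation added to crossover
#'   proposals (keeps chains from collapsing onto a lattice).
#' @param p_migrate probability that a sweep during burn-in uses a
#'   migration (cyclic chain-swap) update instead of crossover; helps
#'   outlier chains rejoin the pack and is disabled after burn-in to keep
#'   the kept draws a fixed-kernel sample.
#' @return an object of class `"sampler_settings"`.
#' @export
sampler_settings <- function(n_burn = 1000, n_samples = 12000, thin = 12,
                             n_chains = NULL, seed = 1, gamma = NULL,
                             jitter = 0.001, p_migrate = 0.05) {
  stopifnot(n_burn >= 0, n_samples >= 1, thin >= 1,
            n_samples %% thin == 0, jitter >= 0,
            p_migrate >= 0, p_migrate <= 1)
  if (!is.null(n_chains)) stopifnot(n_chains >= 4)
  structure(list(n_burn = n_burn, n_samples = n_samples, thin = thin,
                 n_chains = n_chains, seed = seed, gamma = gamma,
                 jitter = jitter, p_migrate = p_migrate),
            class = "sampler_settings")
}

#' Desk-scale sampler settings
#'
#' A reduced preset (burn-in 500, 3,000 sweeps thinned by 3) for runs that
#' should finish in minutes rather than hours while keeping the model and
#' update scheme identical to the full settings.
#' @param seed integer seed.
#' @param ... overrides passed to [sampler_settings()].
#' @export
desk_settings <- function(seed = 1, ...) {
  args <- modifyList(list(n_burn = 500, n_samples = 3000, thin = 3,
                          seed = seed), list(...))
  do.call(sampler_settings, args)
}

#' Hierarchical differential-evolution MCMC
#'
#' Samples the joint posterior of individual-level parameters and
#' population-level (`Mu`, `Sigma`) hyper-parameters by blocked DE-MCMC:
#' each sweep updates every participant's parameter block conditional on
#' the hyper-parameters (one likelihood evaluation per participant per
#' chain), then the hyper block conditional on all individuals (no
#' likelihood evaluations). Crossover proposals perturb chain `k` by
#' `gamma * (x_m - x_n)` for two other randomly chosen chains plus a small
#' uniform jitter; strictly positive parameters are proposed on the log
#' scale (with the Jacobian included in the acceptance ratio) so domain
#' constraints hold by construction. During burn-in an occasional migration
#' sweep cyclically swaps states among a random subset of chains.
#'
#' @param trials the data: a trial table for LBA models (see
#'   [simulate_cohort()]), or whatever the model's `data_prep` accepts.
#' @param model an [hlba_model()] (or any model object exposing the same
#'   interface, e.g. [hnorm_model()]).
#' @param settings a [sampler_settings()].
#' @param init_means optional named numeric: centres of the individual
#'   initial values (defaults to the `Mu` prior centres).
#' @return an object of class `"hlba_draws"`: a list with arrays
#'   `individual` (chain x kept-iteration x participant x free parameter,
#'   natural scale), `hyper` (chain x kept-iteration x hyper-parameter) and
#'   `log_lik` (chain x kept-iteration x participant), plus bookkeeping
#'   (`free`, `fixed`, `participants`, `groups`, `accept_rate`, `settings`,
#'   `method`).
#' @export
run_mcmc <- function(trials, model, settings = sampler_settings(),
                     init_means = NULL) {
  data <- model$data_prep(trials)
  if (is.null(names(data))) names(data) <- as.character(seq_along(data))
  nsub <- length(data)
  free <- model$free
  d <- length(free)
  nch <- if (is.null(settings$n_chains)) max(4L, 3L * d) else settings$n_chains
  gamma <- if (is.null(settings$gamma)) 2.38 / sqrt(2 * d) else settings$gamma
  gamma_h <- 2.38 / sqrt(2 * 2)
  logged <- model$log_scale[free]
  par_names <- model$par_names
  col_free <- match(free, par_names)
  nkept <- settings$n_samples %/% settings$thin
  use_cpp <- isTRUE(model$cpp)
  if (use_cpp) {
    fixed_template <- setNames(numeric(length(par_names)), par_names)
    for (p in names(model$fixed)) fixed_template[p] <- model$fixed[[p]]
  }

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(settings$seed)

  centres <- init_centres(model, init_means)

  # hyper state (natural scale)
  mu <- matrix(0, nch, d, dimnames = list(NULL, free))
  sigma <- matrix(0, nch, d, dimnames = list(NULL, free))
  for (j in seq_len(d)) {
    pr <- model$mu_priors[[free[j]]]
    mu[, j] <- if (inherits(pr, "scaled_beta")) {
      rscaled_beta(nch, pr)
    } else {
      pmax(centres[free[j]] + rnorm(nch, 0, 0.05), 0.01)
    }
    sigma[, j] <- pmin(pmax(0.5 + rnorm(nch, 0, 0.05), 0.05),
                       model$sigma_priors[[free[j]]]$hi - 1e-6)
  }

  # individual state, transformed scale; one matrix (chains x free) per subject
  x <- vector("list", nsub)
  nat <- vector("list", nsub)   # chains x full parameter vector, natural
  ll <- matrix(0, nch, nsub)
  linklp <- matrix(0, nch, nsub)
  jac <- matrix(0, nch, nsub)
  for (i in seq_len(nsub)) {
    st <- init_subject(model, data[[i]], centres, nch, free, logged, par_names)
    x[[i]] <- st$x; nat[[i]] <- st$nat
    ll[, i] <- st$ll
    linklp[, i] <- link_logdens(st$nat[, free, drop = FALSE], mu, sigma)
    jac[, i] <- jac_term(st$x, logged)
  }
  keep_ind <- array(NA_real_, c(nch, nkept, nsub, d),
                    dimnames = list(NULL, NULL, names(data), free))
  keep_hyper <- array(NA_real_, c(nch, nkept, 2 * d),
                      dimnames = list(NULL, NULL,
                                      c(paste0("mu_", free), paste0("sigma_", free))))
  keep_ll <- array(NA_real_, c(nch, nkept, nsub),
                   dimnames = list(NULL, NULL, names(data)))

  acc_ind <- 0; try_ind <- 0; acc_hyp <- 0; try_hyp <- 0
  total <- settings$n_burn + settings$n_samples
  kept <- 0L
  for (iter in seq_len(total)) {
    migrate <- iter <= settings$n_burn && runif(1) < settings$p_migrate

    for (i in seq_len(nsub)) {
      if (!migrate && use_cpp) {
        g <- gamma * runif(1, 0.5, 1)
        res <- lba_block_update(x[[i]], nat[[i]], mu, sigma,
                                unname(logged), col_free - 1L,
                                fixed_template,
                                data[[i]]$rt, data[[i]]$choice,
                                isTRUE(model$renormalize),
                                ll[, i], linklp[, i], jac[, i],
                                g, settings$jitter)
        x[[i]] <- res$x
        colnames(res$nat) <- par_names
        nat[[i]] <- res$nat
        ll[, i] <- res$ll
        linklp[, i] <- res$linklp
        jac[, i] <- res$jac
        acc_ind <- acc_ind + res$nacc; try_ind <- try_ind + nch
        next
      }
      if (migrate) {
        set <- sample.int(nch, sample.int(nch, 1))
        if (length(set) < 2) next
        from <- c(set[length(set)], set[-length(set)])
        xp <- x[[i]]
        xp[set, ] <- x[[i]][from, , drop = FALSE] +
          runif(length(set) * d, -settings$jitter, settings$jitter)
        rows <- set
      } else {
        rr <- de_partners(nch)
        # mildly randomised step size: trades a few large moves for many
        # accepted medium ones
        g <- gamma * runif(1, 0.5, 1)
        xp <- x[[i]] + g * (x[[i]][rr[, 1], , drop = FALSE] -
                              x[[i]][rr[, 2], , drop = FALSE]) +
          matrix(runif(nch * d, -settings$jitter, settings$jitter), nch, d)
        rows <- seq_len(nch)
      }
      natp <- nat[[i]]
      natp[rows, free] <- back_transform(xp[rows, , drop = FALSE], logged)
      llp <- ll[, i]
      llp[rows] <- model$loglik(natp[rows, , drop = FALSE], data[[i]])
      linkp <- link_logdens(natp[, free, drop = FALSE], mu, sigma)
      jacp <- jac_term(xp, logged)
      logr <- (llp + linkp + jacp) - (ll[, i] + linklp[, i] + jac[, i])
      logr[is.na(logr)] <- -Inf
      acc <- rows[log(runif(length(rows))) < logr[rows]]
      if (length(acc)) {
        x[[i]][acc, ] <- xp[acc, , drop = FALSE]
        nat[[i]][acc, ] <- natp[acc, , drop = FALSE]
        ll[acc, i] <- llp[acc]
        linklp[acc, i] <- linkp[acc]
        jac[acc, i] <- jacp[acc]
      }
      if (!migrate) { acc_ind <- acc_ind + length(acc); try_ind <- try_ind + nch }
    }

    # hyper block: one 2-D crossover update of (Mu_p, Sigma_p) per free
    # parameter; cheap (no likelihood evaluations) and far better mixed
    # than a joint update of all hyper-parameters at once
    natj <- lapply(seq_len(d), function(j) {
      vapply(nat, function(m) m[, col_free[j]], numeric(nch))
    })
    for (j in seq_len(d)) {
      rr <- de_partners(nch)
      h <- cbind(mu[, j], sigma[, j])
      hp <- h + gamma_h * (h[rr[, 1], , drop = FALSE] - h[rr[, 2], , drop = FALSE]) +
        matrix(runif(nch * 2, -settings$jitter, settings$jitter), nch, 2)
      mupj <- hp[, 1]; sigpj <- hp[, 2]
      prior_p <- hyper_logdens_one(mupj, sigpj, model, j)
      prior_c <- hyper_logdens_one(mu[, j], sigma[, j], model, j)
      linkp_j <- matrix(-Inf, nch, nsub)
      ok <- which(is.finite(prior_p) & sigpj > 0)
      if (length(ok)) {
        linkp_j[ok, ] <- dtnorm0(natj[[j]][ok, , drop = FALSE],
                                 mupj[ok], sigpj[ok], log = TRUE)
      }
      link_c <- dtnorm0(natj[[j]], mu[, j], sigma[, j], log = TRUE)
      logr <- (rowSums(linkp_j) + prior_p) - (rowSums(link_c) + prior_c)
      logr[is.na(logr)] <- -Inf
      acc <- which(log(runif(nch)) < logr)
      if (length(acc)) {
        mu[acc, j] <- mupj[acc]
        sigma[acc, j] <- sigpj[acc]
        linklp[acc, ] <- linklp[acc, , drop = FALSE] +
          linkp_j[acc, , drop = FALSE] - link_c[acc, , drop = FALSE]
      }
      acc_hyp <- acc_hyp + length(acc); try_hyp <- try_hyp + nch
    }

    post <- iter - settings$n_burn
    if (post > 0 && post %% settings$thin == 0) {
      kept <- kept + 1L
      for (i in seq_len(nsub)) {
        keep_ind[, kept, i, ] <- nat[[i]][, col_free]
        keep_ll[, kept, i] <- ll[, i]
      }
      keep_hyper[, kept, ] <- cbind(mu, sigma)
    }
  }

  structure(list(individual = keep_ind, hyper = keep_hyper, log_lik = keep_ll,
                 free = free, fixed = model$fixed, par_names = par_names,
                 participants = names(data),
                 groups = vapply(data, function(s)
                   if (is.null(s$group)) "all" else s$group, character(1)),
                 accept_rate = c(individual = acc_ind / max(try_ind, 1),
                                 hyper = acc_hyp / max(try_hyp, 1)),
                 n_chains = nch, settings = settings, method = model$method),
            class = "hlba_draws")
}

#' @export
print.hlba_draws <- function(x, ...) {
  dm <- dim(x$individual)
  cat("hlba_draws: ", dm[1], " chains x ", dm[2], " kept iterations, ",
      dm[3], " participants, free parameters: ",
      paste(x$free, collapse = ", "), "\n", sep = "")
  cat(sprintf("acceptance rates: individual %.2f, hyper %.2f\n",
              x$accept_rate[["individual"]], x$accept_rate[["hyper"]]))
  invisible(x)
}

de_partners <- function(nch) {
  r1 <- (seq_len(nch) + sample.int(nch - 1, nch, replace = TRUE) - 1L) %% nch + 1L
  r2 <- (seq_len(nch) + sample.int(nch - 1, nch, replace = TRUE) - 1L) %% nch + 1L
  clash <- r2 == r1
  while (any(clash)) {
    k <- which(clash)
    r2[k] <- (k + sample.int(nch - 1, length(k), replace = TRUE) - 1L) %% nch + 1L
    clash <- r2 == r1
  }
  cbind(r1, r2)
}

back_transform <- function(x, logged) {
  out <- x
  if (any(logged)) out[, logged] <- exp(x[, logged, drop = FALSE])
  out
}

jac_term <- function(x, logged) {
  if (!any(logged)) return(rep(0, nrow(x)))
  rowSums(x[, logged, drop = FALSE])
}

link_logdens <- function(nat_free, mu, sigma) {
  lp <- rep(0, nrow(nat_free))
  for (j in seq_len(ncol(nat_free))) {
    lp <- lp + dtnorm0(nat_free[, j], mu[, j], sigma[, j], log = TRUE)
  }
  lp
}

hyper_logdens_one <- function(mu_j, sigma_j, model, j) {
  pr <- model$mu_priors[[model$free[j]]]
  lp <- if (inherits(pr, "scaled_beta")) {
    dscaled_beta(mu_j, pr, log = TRUE)
  } else {
    dtnorm0(mu_j, pr$mean, pr$sd, log = TRUE)
  }
  lp + dscaled_beta(sigma_j, model$sigma_priors[[model$free[j]]], log = TRUE)
}

init_centres <- function(model, init_means) {
  centres <- vapply(model$free, function(p) {
    pr <- model$mu_priors[[p]]
    if (inherits(pr, "scaled_beta")) (pr$lo + pr$hi) / 2 else pr$mean
  }, numeric(1))
  if (!is.null(init_means)) {
    hit <- intersect(names(init_means), names(centres))
    centres[hit] <- init_means[hit]
  }
  centres
}

# Initial individual state for one participant: a cheap penalized-MLE
# point (participant likelihood plus a weak prior at the init centres,
# maximised by Nelder-Mead on the transformed scale) plus per-chain
# jitter; re-jittered (bounded attempts) until the likelihood is finite
# and above the numerical floor for every chain.
init_subject <- function(model, data_i, centres, nch, free, logged, par_names) {
  d <- length(free)
  cap_t0 <- if (!is.null(data_i$rt) && "t0" %in% free) {
    0.9 * min(data_i$rt)
  } else Inf
  centres <- pmax_logged(centres, logged)
  if (is.finite(cap_t0)) centres["t0"] <- min(centres["t0"], cap_t0)
  centres <- map_start(model, data_i, centres, free, logged, par_names)
  draw <- function(rows) {
    m <- matrix(rep(centres, each = length(rows)), length(rows), d,
                dimnames = list(NULL, free))
    m <- m + matrix(rnorm(length(rows) * d, 0, 0.1), length(rows), d)
    # the population link truncates every parameter below 0
    m <- pmax(m, 0.01)
    if (is.finite(cap_t0)) m[, "t0"] <- pmin(m[, "t0"], cap_t0)
    m
  }
  natf <- draw(seq_len(nch))
  nat <- matrix(0, nch, length(par_names), dimnames = list(NULL, par_names))
  nat[, free] <- natf
  for (p in names(model$fixed)) nat[, p] <- model$fixed[[p]]
  ll <- model$loglik(nat, data_i)
  for (attempt in seq_len(100)) {
    bad <- which(!is.finite(ll) | ll <= -1e9)
    if (!length(bad)) break
    nat[bad, free] <- draw(bad)
    ll[bad] <- model$loglik(nat[bad, , drop = FALSE], data_i)
  }
  if (any(!is.finite(ll) | ll <= -1e9)) {
    stop("could not initialize finite posterior for a participant; ",
         "check data/parameter compatibility (e.g. rt <= t0)")
  }
  xm <- nat[, free, drop = FALSE]
  xm[, logged] <- log(xm[, logged, drop = FALSE])
  list(x = xm, nat = nat, ll = ll)
}

pmax_logged <- function(v, logged) {
  v[logged] <- pmax(v[logged], 0.01)
  v
}

# Penalized individual-level mode used as the chains' common start point:
# maximises loglik + weak truncated-normal penalty at the prior centres.
map_start <- function(model, data_i, centres, free, logged, par_names) {
  x0 <- centres
  x0[logged] <- log(x0[logged])
  fill <- function(xv) {
    natv <- xv
    natv[logged] <- exp(xv[logged])
    full <- setNames(numeric(length(par_names)), par_names)
    full[free] <- natv
    for (p in names(model$fixed)) full[p] <- model$fixed[[p]]
    full
  }
  obj <- function(xv) {
    full <- fill(xv)
    ll <- model$loglik(matrix(full, 1, dimnames = list(NULL, par_names)),
                       data_i)
    pen <- sum(dtnorm0(full[free], centres, 1, log = TRUE))
    v <- ll + pen
    if (!is.finite(v)) -1e12 else v
  }
  opt <- tryCatch(
    suppressWarnings(stats::optim(x0, obj, method = "Nelder-Mead",
                                  control = list(fnscale = -1, maxit = 400))),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value <= -1e9) {
    return(centres)
  }
  out <- opt$par
  out[logged] <- exp(out[logged])
  pmax_logged(setNames(out, free), logged)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF over post-thinning draws:
#' `sqrt(((n - 1) / n * W + B / n) / W)` with `W` the mean within-chain
#' variance and `B / n` the variance of the chain means, for `n` kept
#' iterations. Values below 1.1 are conventionally taken as converged.
#'
#' @param draws numeric matrix, iterations x chains (at least 2 chains and
#'   10 iterations).
#' @return scalar R-hat; `+Inf` with a warning when the within-chain
#'   variance is zero.
#' @export
psrf <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (m < 2) stop("PSRF needs at least 2 chains")
  if (n < 10) stop("PSRF needs at least 10 kept iterations")
  W <- mean(apply(draws, 2, var))
  B_over_n <- var(colMeans(draws))
  if (W == 0) {
    warning("zero within-chain variance; PSRF undefined, returning Inf")
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Per-participant convergence assessment
#'
#' Computes the PSRF of every individual-level parameter for every
#' participant and flags a participant as converged when the worst
#' (largest) PSRF across that participant's parameters falls below 1.1.
#'
#' @param draws an [run_mcmc()] result.
#' @param threshold convergence cut-off (1.1 by convention).
#' @return data.frame with columns `participant`, `max_psrf`, `converged`.
#' @export
participant_convergence <- function(draws, threshold = 1.1) {
  stopifnot(inherits(draws, "hlba_draws"))
  nsub <- dim(draws$individual)[3]
  worst <- vapply(seq_len(nsub), function(i) {
    max(vapply(seq_along(draws$free), function(j) {
      psrf(t(draws$individual[, , i, j]))
    }, numeric(1)))
  }, numeric(1))
  data.frame(participant = draws$participants,
             max_psrf = worst,
             converged = worst < threshold,
             stringsAsFactors = FALSE)
}

#' Posterior means of individual parameters
#'
#' Pools all chains and kept iterations per participant and free parameter;
#' fixed parameters are appended as constant columns.
#'
#' @param draws an [run_mcmc()] result.
#' @return numeric matrix, participants x parameters.
#' @export
posterior_means <- function(draws) {
  stopifnot(inherits(draws, "hlba_draws"))
  nsub <- dim(draws$individual)[3]
  est <- sapply(seq_along(draws$free), function(j) {
    vapply(seq_len(nsub), function(i) mean(draws$individual[, , i, j]),
           numeric(1))
  })
  est <- matrix(est, nrow = nsub, dimnames = list(draws$participants, draws$free))
  for (p in names(draws$fixed)) {
    est <- cbind(est, setNames(rep(draws$fixed[[p]], nsub), NULL))
    colnames(est)[ncol(est)] <- p
  }
  est
}

#' Hierarchical normal testbed model
#'
#' A one-parameter hierarchical Gaussian model with the same interface as
#' [hlba_model()]: each participant contributes observations
#' `y ~ Normal(theta_i, obs_sd)` with `theta_i ~ Normal(Mu, Sigma)`
#' truncated below at 0, `Mu ~ Normal(mu_prior_mean, mu_prior_sd)`
#' truncated at 0 and `Sigma` uniform on `[0, sigma_hi]`. Its posterior is
#' low-dimensional enough to integrate numerically, which makes it the
#' standard correctness check for the sampler.
#'
#' @param obs_sd known observation SD.
#' @param mu_prior_mean,mu_prior_sd `Mu` prior (truncated normal).
#' @param sigma_hi upper end of the uniform `Sigma` prior.
#' @return a model object accepted by [run_mcmc()]; its `data_prep` expects
#'   a list of numeric vectors (one per participant).
#' @export
hnorm_model <- function(obs_sd = 1, mu_prior_mean = 5, mu_prior_sd = 2,
                        sigma_hi = 3) {
  structure(list(
    method = "toy",
    par_names = "theta",
    free = "theta",
    fixed = numeric(0),
    log_scale = c(theta = FALSE),
    mu_priors = list(theta = list(mean = mu_prior_mean, sd = mu_prior_sd)),
    sigma_priors = list(theta = scaled_beta(1, 1, 0, sigma_hi)),
    loglik = function(theta, data) {
      vapply(seq_len(nrow(theta)), function(k) {
        sum(dnorm(data$y, theta[k, 1], obs_sd, log = TRUE))
      }, numeric(1))
    },
    data_prep = function(ys) {
      lapply(ys, function(y) list(y = as.numeric(y), group = "all"))
    }
  ), class = "hlba_model")
}
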