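#' Scaled Beta prior on an interval
#'
#' A Beta(`alpha`, `beta`) density affinely remapped from `[0, 1]` to
#' `[lo, hi]`. With `alpha = beta = 1` this is the uniform distribution on
#' `[lo, hi]` — the form used both for the population-SD (Sigma) priors
#' (uniform on 0–3) and for the near-degenerate population-mean prior that
#' pins the population mean of `sv` to the interval `[0.999, 1.001]`.
#'
#' @param alpha,beta positive shape parameters.
#' @param lo,hi interval endpoints, `hi > lo`.
#' @return an object of class `"scaled_beta"`.
#' @export
scaled_beta <- function(alpha = 1, beta = 1, lo = 0, hi = 1) {
  stopifnot(alpha > 0, beta > 0, hi > lo)
  structure(list(alpha = alpha, beta = beta, lo = lo, hi = hi),
            class = "scaled_beta")
}

#' @rdname scaled_beta
#' @param x quantile(s).
#' @param prior a `scaled_beta` object.
#' @param log return log density.
#' @export
dscaled_beta <- function(x, prior, log = FALSE) {
  z <- (x - prior$lo) / (prior$hi - prior$lo)
  d <- ifelse(z >= 0 & z <= 1,
              stats::dbeta(z, prior$alpha, prior$beta) / (prior$hi - prior$lo),
              0)
  if (log) base::log(d) else d
}

#' @rdname scaled_beta
#' @param n number of draws.
#' @export
rscaled_beta <- function(n, prior) {
  prior$lo + (prior$hi - prior$lo) * stats::rbeta(n, prior$alpha, prior$beta)
}

# Truncated-normal (lower bound 0) log density; the individual-level link
# and the population-mean priors both use it.
dtnorm0 <- function(x, mean, sd, log = FALSE) {
  ld <- ifelse(x > 0,
               dnorm(x, mean, sd, log = TRUE) - pnorm(mean / sd, log.p = TRUE),
               -Inf)
  if (log) ld else exp(ld)
}

rtnorm0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Specify a hierarchical LBA model with a scale-setting policy
#'
#' Builds the model specification for hierarchical Bayesian estimation of
#' the two-choice LBA. Each free parameter `p` has population-level
#' hyper-parameters `Mu_p` (mean) and `Sigma_p` (SD); individual values are
#' conditionally `Normal(Mu_p, Sigma_p)` truncated below at 0. `Sigma`
#' priors are uniform (scaled Beta(1,1)) on `[0, 3]` for every parameter.
#'
#' The `method` argument selects how the evidence scale is set:
#' \describe{
#'   \item{`"new"`}{`sv` is a free parameter for every participant, and the
#'     scale is set at the population level: the `Mu_sv` prior is uniform on
#'     the near-degenerate interval `[0.999, 1.001]`, de facto fixing the
#'     population mean of `sv` at about 1 while leaving individual `sv`
#'     values free to differ.}
#'   \item{`"classic"`}{`sv` is fixed at 1 for every participant and is not
#'     estimated.}
#' }
#'
#' `Mu` priors for the remaining parameters are normal densities centred at
#' `prior_means` with SD `mu_prior_sd`, truncated below at 0.
#'
#' @param method `"new"` or `"classic"`.
#' @param prior_means named numeric of prior means for the non-`sv`
#'   parameters (`A`, `B`, `v_true`, `v_false`, and `t0` unless fixed);
#'   typically produced by [noisy_prior_means_study1()] or
#'   [noisy_prior_means_study2()].
#' @param mu_prior_sd SD of the truncated-normal `Mu` priors (weakly
#'   informative at the scale of the generating means).
#' @param fix_t0 fix non-decision time at `t0_value` instead of estimating
#'   it; shortens small-scale runs.
#' @param t0_value value used when `fix_t0 = TRUE`.
#' @param sv_fixed_value individual `sv` under the classic method.
#' @param renormalize condition trial densities on termination (see
#'   [dlba_trial()]).
#' @return an object of class `"hlba_model"` with elements `method`, `free`
#'   (ordered free-parameter names), `fixed` (named fixed values),
#'   `mu_priors`, `sigma_priors`, `log_scale` (which free parameters are
#'   proposed on the log scale) and `loglik` (vectorised likelihood over
#'   chains).
#' @export
hlba_model <- function(method = c("new", "classic"), prior_means,
                       mu_prior_sd = 1, fix_t0 = FALSE, t0_value = 0.3,
                       sv_fixed_value = 1, renormalize = FALSE) {
  method <- match.arg(method)
  free <- c("A", "B", "v_true", "v_false")
  fixed <- numeric(0)
  if (method == "new") free <- c(free, "sv") else fixed <- c(sv = sv_fixed_value)
  if (fix_t0) fixed <- c(fixed, t0 = t0_value) else free <- c(free, "t0")
  need <- setdiff(free, "sv")
  if (!all(need %in% names(prior_means))) {
    stop("'prior_means' must name: ", paste(need, collapse = ", "))
  }
  mu_priors <- vector("list", length(free))
  names(mu_priors) <- free
  for (p in free) {
    mu_priors[[p]] <- if (p == "sv") {
      scaled_beta(1, 1, 0.999, 1.001)
    } else {
      list(mean = prior_means[[p]], sd = mu_prior_sd)
    }
  }
  sigma_priors <- setNames(rep(list(scaled_beta(1, 1, 0, 3)), length(free)), free)
  structure(list(
    method = method,
    par_names = LBA_PARS,
    free = free,
    fixed = fixed,
    log_scale = setNames(free %in% c("A", "B", "sv", "t0"), free),
    mu_priors = mu_priors,
    sigma_priors = sigma_priors,
    renormalize = renormalize,
    cpp = TRUE,
    loglik = function(theta, data) {
      lba_loglik_chains(theta, data$rt, data$choice, renormalize)
    },
    data_prep = prep_lba_data
  ), class = "hlba_model")
}

#' @export
print.hlba_model <- function(x, ...) {
  cat("Hierarchical LBA model, scale policy: ", x$method, "\n", sep = "")
  cat("  free parameters: ", paste(x$free, collapse = ", "), "\n", sep = "")
  if (length(x$fixed)) {
    cat("  fixed: ", paste(names(x$fixed), x$fixed, sep = " = ",
                           collapse = ", "), "\n", sep = "")
  }
  for (p in x$free) {
    pr <- x$mu_priors[[p]]
    if (inherits(pr, "scaled_beta")) {
      cat(sprintf("  Mu[%s] ~ Beta(%g,%g) scaled to [%g, %g]\n",
                  p, pr$alpha, pr$beta, pr$lo, pr$hi))
    } else {
      cat(sprintf("  Mu[%s] ~ Normal(%.3f, %g) truncated at 0\n",
                  p, pr$mean, pr$sd))
    }
  }
  cat("  Sigma[.] ~ uniform on [0, 3]\n")
  invisible(x)
}

prep_lba_data <- function(trials) {
  ids <- unique(trials$participant_id)
  out <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, ]
    list(rt = as.numeric(tr$rt),
         choice = as.integer(as_choice(tr$choice)),
         group = tr$group[1])
  })
  names(out) <- as.character(ids)
  out
}

#' Prior means for fitting, perturbed away from the generating truth
#'
#' `noisy_prior_means_study1` adds independent `Normal(0, sd)` noise to
#' each non-`sv` generating mean, emulating priors that are in the
#' neighbourhood of the truth but not exactly at it.
#' `noisy_prior_means_study2` instead draws each prior mean uniformly
#' within two standard errors of the generating mean, `SE = sd / sqrt(n)`
#' with `n` the per-group sample size — emulating well-informed guessing.
#'
#' @param true_means named numeric generating means (should include `t0`
#'   when it is estimated).
#' @param seed integer seed.
#' @param noise_sd SD of the additive perturbation (study-1 style).
#' @param sds named numeric population SDs (study-2 style).
#' @param n sample size from which the standard error is computed.
#' @return named numeric of perturbed prior means (any `sv` entry is left
#'   untouched: its prior is the scale-setting constraint, not a guess).
#' @export
noisy_prior_means_study1 <- function(true_means, seed, noise_sd = 0.1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  out <- true_means
  tweak <- setdiff(names(out), "sv")
  out[tweak] <- out[tweak] + rnorm(length(tweak), 0, noise_sd)
  out
}

#' @rdname noisy_prior_means_study1
#' @export
noisy_prior_means_study2 <- function(true_means, sds, n, seed) {
  stopifnot(n >= 2)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  out <- true_means
  tweak <- intersect(setdiff(names(out), "sv"), names(sds))
  se <- sds[tweak] / sqrt(n)
  out[tweak] <- runif(length(tweak), out[tweak] - 2 * se, out[tweak] + 2 * se)
  out
}

# Hyper-prior log density for one chain's (mu, sigma) vectors.
log_hyper_prior <- function(mu, sigma, model) {
  lp <- 0
  for (p in model$free) {
    pr <- model$mu_priors[[p]]
    lp <- lp + if (inherits(pr, "scaled_beta")) {
      dscaled_beta(mu[[p]], pr, log = TRUE)
    } else {
      dtnorm0(mu[[p]], pr$mean, pr$sd, log = TRUE)
    }
    lp <- lp + dscaled_beta(sigma[[p]], model$sigma_priors[[p]], log = TRUE)
  }
  lp
}

#' Joint log posterior of a hierarchical LBA state
#'
#' Evaluates, for a single state, the sum of (i) every participant's trial
#' log-likelihood, (ii) the log density of each individual free parameter
#' under its truncated-normal population distribution `Normal(Mu, Sigma)`
#' (lower bound 0), and (iii) the log hyper-prior densities of `Mu` and
#' `Sigma`. Returns `-Inf` outside the support (e.g. a `Mu_sv` outside the
#' scale-setting interval under the `"new"` policy). Mainly a reference /
#' diagnostic entry point: the sampler evaluates the same quantities
#' blockwise with caching.
#'
#' @param individual numeric matrix, one row per participant, columns named
#'   by the six LBA parameters (natural scale). Fixed parameters are
#'   overridden by the model's fixed values.
#' @param mu,sigma named numeric hyper-parameter vectors over the model's
#'   free parameters.
#' @param trials a trial table (see [simulate_cohort()]).
#' @param model an [hlba_model()].
#' @return scalar log posterior density (unnormalised).
#' @export
log_posterior <- function(individual, mu, sigma, trials, model) {
  stopifnot(inherits(model, "hlba_model"))
  data <- model$data_prep(trials)
  n <- length(data)
  if (nrow(individual) != n) stop("one row per participant required")
  if (any(sigma[model$free] <= 0)) return(-Inf)
  theta <- individual[, LBA_PARS, drop = FALSE]
  for (p in names(model$fixed)) theta[, p] <- model$fixed[[p]]
  lp <- log_hyper_prior(as.list(mu), as.list(sigma), model)
  if (!is.finite(lp)) return(-Inf)
  for (i in seq_len(n)) {
    lp <- lp + model$loglik(theta[i, , drop = FALSE], data[[i]])
    for (p in model$free) {
      lp <- lp + dtnorm0(theta[i, p], mu[[p]], sigma[[p]], log = TRUE)
    }
  }
  if (!is.finite(lp)) -Inf else unname(lp)
}
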