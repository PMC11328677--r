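#' Fit a hierarchical Bayesian LBA to a trial table
#'
#' The main entry point: builds the model specification for the requested
#' scale-setting policy, runs blocked differential-evolution MCMC, and
#' returns a fitted-model object with posterior summaries and per-
#' participant convergence flags.
#'
#' @param trials trial table with columns `participant_id`, `group`,
#'   `choice` ("true"/"false") and `rt` in seconds (see
#'   [simulate_cohort()] / [read_trials()]).
#' @param method scale-setting policy, `"new"` (population-mean `sv`
#'   pinned near 1, individual `sv` free) or `"classic"` (`sv = 1` for
#'   every participant). See [hlba_model()].
#' @param prior_means named prior means for the non-`sv` parameters; when
#'   `NULL`, crude starting guesses are derived from the data (boundary
#'   parameters at 2, drifts from accuracy, `t0` just under the fastest
#'   response).
#' @param settings a [sampler_settings()]; defaults to the full-scale
#'   preset.
#' @param ... further arguments to [hlba_model()] (`fix_t0`,
#'   `mu_prior_sd`, `renormalize`, ...).
#' @return an object of class `"hlba"` with components `draws`
#'   (an `hlba_draws`), `model`, `coef` (posterior means, participants x
#'   parameters), `hyper` (posterior mean and SD per hyper-parameter),
#'   `convergence` (from [participant_convergence()]) and `trials`.
#' @examples
#' \donttest{
#' cohort <- draw_cohort(study1_grid()[[14]], seed = 1)
#' trials <- simulate_cohort(cohort, seed = 2, n_trials = 100)
#' trials <- trials[trials$participant_id <= 5, ]
#' fit <- hlba(trials, method = "new",
#'             settings = desk_settings(seed = 3, n_burn = 50,
#'                                      n_samples = 300, thin = 3))
#' coef(fit)
#' }
#' @export
hlba <- function(trials, method = c("new", "classic"), prior_means = NULL,
                 settings = sampler_settings(), ...) {
  method <- match.arg(method)
  check_trial_table(trials)
  if (is.null(prior_means)) prior_means <- default_prior_means(trials)
  model <- hlba_model(method = method, prior_means = prior_means, ...)
  draws <- run_mcmc(trials, model, settings, init_means = prior_means)
  conv <- participant_convergence(draws)
  hyper_mean <- apply(draws$hyper, 3, mean)
  hyper_sd <- apply(draws$hyper, 3, sd)
  structure(list(draws = draws, model = model,
                 coef = posterior_means(draws),
                 hyper = cbind(mean = hyper_mean, sd = hyper_sd),
                 convergence = conv,
                 prior_means = prior_means,
                 trials = trials,
                 call = match.call()),
            class = "hlba")
}

default_prior_means <- function(trials) {
  acc <- mean(trials$choice == "true")
  c(A = 2, B = 2, v_true = 2 + acc, v_false = 1.5 - acc,
    t0 = max(0.05, 0.8 * min(trials$rt)))
}

#' @export
print.hlba <- function(x, ...) {
  cat("Hierarchical Bayesian LBA fit (", x$model$method,
      " scale-setting)\n", sep = "")
  dm <- dim(x$draws$individual)
  cat(dm[3], "participants,", dm[1], "chains x", dm[2], "kept draws\n")
  cat(sum(x$convergence$converged), "of", nrow(x$convergence),
      "participants converged (PSRF < 1.1)\n")
  cat("Population-level posterior means:\n")
  print(round(x$hyper[, "mean"], 3))
  invisible(x)
}

#' @export
summary.hlba <- function(object, ...) {
  est <- object$coef
  out <- list(method = object$model$method,
              hyper = object$hyper,
              individual = data.frame(participant = rownames(est),
                                      group = object$draws$groups,
                                      est,
                                      max_psrf = object$convergence$max_psrf,
                                      converged = object$convergence$converged,
                                      row.names = NULL),
              accept_rate = object$draws$accept_rate)
  class(out) <- "summary.hlba"
  out
}

#' @export
print.summary.hlba <- function(x, ...) {
  cat("Hierarchical Bayesian LBA (", x$method, " scale-setting)\n\n", sep = "")
  cat("Hyper-parameters (posterior mean, SD):\n")
  print(round(x$hyper, 3))
  cat("\nIndividual posterior means (first rows):\n")
  print(utils::head(x$individual, 6), digits = 3)
  cat("...\n")
  cat(sprintf("\nacceptance rates: individual %.2f, hyper %.2f\n",
              x$accept_rate[["individual"]], x$accept_rate[["hyper"]]))
  invisible(x)
}

#' @export
coef.hlba <- function(object, level = c("individual", "population"), ...) {
  level <- match.arg(level)
  if (level == "individual") object$coef else object$hyper[, "mean"]
}

#' Posterior-predictive simulation from a fitted hierarchical LBA
#'
#' Simulates trial tables at the posterior-mean individual parameters.
#'
#' @param object an [hlba()] fit.
#' @param nsim number of replicate trial tables.
#' @param seed integer seed.
#' @param n_trials trials per participant (defaults to the observed
#'   per-participant counts' median).
#' @param ... unused.
#' @return a list of `nsim` trial tables.
#' @export
simulate.hlba <- function(object, nsim = 1, seed = 1, n_trials = NULL, ...) {
  est <- object$coef
  if (is.null(n_trials)) {
    n_trials <- stats::median(table(object$trials$participant_id))
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  lapply(seq_len(nsim), function(r) {
    do.call(rbind, lapply(seq_len(nrow(est)), function(i) {
      tr <- rlba(est[i, LBA_PARS], n_trials)
      data.frame(dataset_id = sprintf("postpred%02d", r),
                 participant_id = rownames(est)[i],
                 group = unname(object$draws$groups[i]),
                 tr, stringsAsFactors = FALSE, row.names = NULL)
    }))
  })
}

#' Predicted accuracy and mean response time per participant
#'
#' Monte-Carlo predictions at the posterior-mean parameters.
#'
#' @param object an [hlba()] fit.
#' @param n_trials simulated trials per participant used to form the
#'   prediction.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with `participant`, predicted `accuracy` (fraction
#'   of "true" responses) and `mean_rt` (seconds).
#' @export
predict.hlba <- function(object, n_trials = 2000, seed = 1, ...) {
  sim <- simulate.hlba(object, nsim = 1, seed = seed, n_trials = n_trials)[[1]]
  acc <- tapply(sim$choice == "true", sim$participant_id, mean)
  mrt <- tapply(sim$rt, sim$participant_id, mean)
  ids <- rownames(object$coef)
  data.frame(participant = ids,
             accuracy = as.numeric(acc[ids]),
             mean_rt = as.numeric(mrt[ids]),
             row.names = NULL)
}

#' Diagnostic and recovery plots for a fitted hierarchical LBA
#'
#' `type = "trace"` draws trace plots of the population-level parameters;
#' `type = "psrf"` a per-participant convergence dot chart.
#'
#' @param x an [hlba()] fit.
#' @param type plot type.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.hlba <- function(x, type = c("trace", "psrf"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    hp <- x$draws$hyper
    nh <- dim(hp)[3]
    op <- graphics::par(mfrow = grDevices::n2mfrow(nh), mar = c(2, 4, 2, 1))
    on.exit(graphics::par(op))
    for (j in seq_len(nh)) {
      graphics::matplot(t(hp[, , j]), type = "l", lty = 1,
                        ylab = dimnames(hp)[[3]][j], xlab = "", ...)
    }
  } else {
    conv <- x$convergence
    graphics::plot(conv$max_psrf, xlab = "participant",
                   ylab = "max PSRF across parameters", ...)
    graphics::abline(h = 1.1, lty = 2)
  }
  invisible(x)
}
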