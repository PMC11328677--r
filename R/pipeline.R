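#' Scale presets for replication runs
#'
#' `"full"` reproduces the published study sizes (100 participants, 1,000
#' trials, burn-in 1,000, 12,000 sweeps thinned by 12) and takes hours per
#' fit on one CPU. `"desk"` is a reduced preset (20 participants, 300
#' trials, burn-in 500, 3,000 sweeps thinned by 3) that keeps the model
#' and update scheme identical while finishing in minutes; it never changes
#' model structure, only problem size.
#'
#' @param scale `"full"` or `"desk"`.
#' @param seed integer master seed.
#' @return list with `n_participants`, `n_trials` and a
#'   [sampler_settings()].
#' @export
scale_preset <- function(scale = c("desk", "full"), seed = 1) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(n_participants = 100, n_trials = 1000,
         settings = sampler_settings(seed = seed))
  } else {
    list(n_participants = 20, n_trials = 300,
         settings = desk_settings(seed = seed))
  }
}

#' Replicate one configuration of the single-group recovery study
#'
#' Runs the full simulate/fit/score loop for one generating configuration:
#' draws true individual parameters, simulates trials, perturbs the prior
#' means with `Normal(0, 0.1)` noise, fits the hierarchical LBA under the
#' requested scale-setting policy, and scores recovery after dropping
#' non-converged participants.
#'
#' @param config_index row of the 21-configuration grid ([study1_grid()]).
#' @param method scale-setting policy (`"new"` or `"classic"`).
#' @param scale `"desk"` or `"full"` (see [scale_preset()]).
#' @param seed integer master seed; cohort, trials, prior noise and the
#'   sampler all derive their seeds from it.
#' @param fix_t0 fix non-decision time at its generating value instead of
#'   estimating it. Defaults to `TRUE` at desk scale: the generating `t0`
#'   is a constant, so its population SD collapses toward zero and the
#'   resulting funnel needs full-length chains to traverse.
#' @param ... passed on to [hlba()].
#' @return list with `cohort`, `trials`, `fit` and `recovery`.
#' @export
replicate_study1 <- function(config_index = 14, method = "new",
                             scale = "desk", seed = 1,
                             fix_t0 = identical(scale, "desk"), ...) {
  preset <- scale_preset(scale, seed = seed)
  config <- study1_grid()[[config_index]]
  config$n_participants <- preset$n_participants
  config$n_trials <- preset$n_trials
  cohort <- draw_cohort(config, seed = seed)
  trials <- simulate_cohort(cohort, seed = seed + 1L)
  true_means <- c(config$means, t0 = config$t0_fixed)
  prior_means <- noisy_prior_means_study1(true_means, seed = seed + 2L)
  fit <- hlba(trials, method = method, prior_means = prior_means,
              settings = preset$settings, fix_t0 = fix_t0, ...)
  list(cohort = cohort, trials = trials, fit = fit,
       recovery = recovery_report(fit, cohort))
}

#' Replicate the two-group method-discrimination study
#'
#' Simulates the two-group design (groups differing only in the `sv`
#' generating mean, 1.5 vs 0.5), fits the data under one or both
#' scale-setting policies, and reports per-method recovery, DIC and
#' pooled-variance group t-tests on the posterior means (after dropping
#' non-converged participants).
#'
#' @param methods which policies to fit (default both).
#' @param scale `"desk"` or `"full"`; the desk preset uses 15 participants
#'   per group.
#' @param seed integer master seed.
#' @param n_per_group,n_trials optional explicit sizes overriding the
#'   preset.
#' @param fix_t0 as in [replicate_study1()].
#' @param ... passed on to [hlba()].
#' @return list with `cohort`, `trials`, and per-method sublists (`new`,
#'   `classic`) each holding `fit`, `recovery`, `dic` and `ttests`; when
#'   both methods are fitted, also `dic_comparison` with the summed-DIC
#'   difference and the fraction of participants better fit by the new
#'   method.
#' @export
replicate_study2 <- function(methods = c("new", "classic"), scale = "desk",
                             seed = 1, n_per_group = NULL, n_trials = NULL,
                             fix_t0 = identical(scale, "desk"), ...) {
  preset <- scale_preset(scale, seed = seed)
  if (is.null(n_per_group)) {
    n_per_group <- if (scale == "full") 50 else 15
  }
  if (is.null(n_trials)) n_trials <- preset$n_trials
  config <- study2_config(n_per_group = n_per_group, n_trials = n_trials)
  cohort <- draw_cohort(config, seed = seed)
  trials <- simulate_cohort(cohort, seed = seed + 1L)
  true_means <- c(config$means, t0 = config$t0_fixed)
  prior_means <- noisy_prior_means_study2(true_means, sds = config$sds,
                                          n = n_per_group, seed = seed + 2L)
  out <- list(cohort = cohort, trials = trials)
  for (m in methods) {
    settings <- preset$settings
    settings$seed <- settings$seed + match(m, c("new", "classic"))
    fit <- hlba(trials, method = m, prior_means = prior_means,
                settings = settings, fix_t0 = fix_t0, ...)
    est <- filter_by_psrf(fit$coef, fit$convergence)
    groups <- filter_by_psrf(fit$draws$groups, fit$convergence)
    pars <- setdiff(colnames(fit$coef), names(fit$model$fixed))
    out[[m]] <- list(fit = fit,
                     recovery = recovery_report(fit, cohort),
                     dic = dic(fit),
                     ttests = group_ttest(est, groups, parameters = pars))
  }
  if (all(c("new", "classic") %in% methods)) {
    pp_new <- out$new$dic$per_participant
    pp_cls <- out$classic$dic$per_participant
    out$dic_comparison <- list(
      total_new = out$new$dic$total,
      total_classic = out$classic$dic$total,
      diff = out$new$dic$total - out$classic$dic$total,
      frac_new_better = mean(pp_new$dic < pp_cls$dic))
  }
  out
}

# ---- file-based workflow used by the command-line wrapper ----------------

#' Simulate-to-files workflow step
#'
#' Draws a cohort from a configuration, simulates its trial table and
#' writes `trials.csv`, `true_params.csv` and a small `manifest.txt`
#' recording the configuration and seed, into `outdir`.
#'
#' @param config an [lba_population()].
#' @param seed master seed.
#' @param outdir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
cmd_simulate <- function(config, seed, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- draw_cohort(config, seed = seed)
  trials <- simulate_cohort(cohort, seed = seed + 1L)
  paths <- c(trials = file.path(outdir, "trials.csv"),
             params = file.path(outdir, "true_params.csv"),
             manifest = file.path(outdir, "manifest.txt"))
  write_trials(trials, paths[["trials"]])
  write_cohort(cohort, paths[["params"]])
  writeLines(c(
    paste0("dataset_id: ", config$dataset_id),
    paste0("seed: ", seed),
    paste0("n_participants: ", config$n_participants),
    paste0("n_trials: ", config$n_trials),
    paste0("means: ", paste(names(config$means), config$means,
                            sep = "=", collapse = " ")),
    paste0("sds: ", paste(names(config$sds), config$sds,
                          sep = "=", collapse = " "))),
    con = paths[["manifest"]])
  invisible(paths)
}

#' Fit-from-files workflow step
#'
#' Reads a trial table written by [cmd_simulate()], fits the hierarchical
#' LBA and writes a posterior summary (`summary_<method>.csv`: posterior
#' mean per participant and parameter plus PSRF flags) and a convergence
#' report.
#'
#' @param trials_path path to `trials.csv`.
#' @param method scale-setting policy.
#' @param settings a [sampler_settings()].
#' @param outdir output directory.
#' @param prior_means optional named prior means.
#' @param ... passed to [hlba()].
#' @return the fitted [hlba()] object, invisibly; files are the side
#'   effect.
#' @export
cmd_fit <- function(trials_path, method, settings, outdir,
                    prior_means = NULL, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  trials <- read_trials(trials_path)
  fit <- hlba(trials, method = method, prior_means = prior_means,
              settings = settings, ...)
  sm <- summary(fit)$individual
  con <- file(file.path(outdir, paste0("summary_", method, ".csv")),
              open = "wb")
  write.csv(sm, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)
  invisible(fit)
}

#' Report workflow step
#'
#' Produces the recovery table (and, for grouped data, DIC totals and group
#' t-tests) for one or more fits, writing `recovery_<method>.csv` and a
#' human-readable `report.txt`.
#'
#' @param fits named list of [hlba()] fits (names = methods).
#' @param cohort the generating cohort.
#' @param outdir output directory.
#' @return (invisibly) the list of recovery reports.
#' @export
cmd_report <- function(fits, cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lines <- character(0)
  reports <- list()
  for (m in names(fits)) {
    fit <- fits[[m]]
    rec <- recovery_report(fit, cohort)
    reports[[m]] <- rec
    con <- file(file.path(outdir, paste0("recovery_", m, ".csv")), open = "wb")
    write.csv(as.data.frame(rec), con, row.names = FALSE, quote = FALSE,
              eol = "\n")
    close(con)
    lines <- c(lines, paste0("== method: ", m, " =="),
               utils::capture.output(print(rec)))
    if (length(unique(fit$draws$groups)) == 2) {
      est <- filter_by_psrf(fit$coef, fit$convergence)
      groups <- filter_by_psrf(fit$draws$groups, fit$convergence)
      pars <- setdiff(colnames(fit$coef), names(fit$model$fixed))
      tt <- group_ttest(est, groups, parameters = pars)
      dd <- dic(fit)
      lines <- c(lines, "group t-tests (pooled variance):",
                 utils::capture.output(print(tt, digits = 4)),
                 sprintf("summed DIC: %.1f", dd$total))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(reports)
}
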