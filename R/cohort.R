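#' Population configuration for simulated LBA cohorts
#'
#' Describes the generating population for a parameter-recovery cohort:
#' normal population distributions per parameter (mean, SD), lower-bound
#' corrections applied to individual draws, a fixed non-decision time, and
#' optionally a group structure whose groups override selected means.
#'
#' Default SDs are 0.6 for `A` and `B`, 0.8 for the two drift rates and 0.4
#' for `sv`; default lower bounds are 0.05 for `A`, `B` and `v_false`, 1.3
#' for `v_true` and 0.01 for `sv`. Draws violating a bound are raised to it,
#' and afterwards any draw with `v_true - v_false < 0.2` has `v_false`
#' replaced by `v_true - 0.2` (the replacement is unconditional and is not
#' re-checked against the floor).
#'
#' @param means named numeric: population means for `A`, `B`, `v_true`,
#'   `v_false`, `sv`.
#' @param sds named numeric population SDs (defaults above).
#' @param lower_bounds named numeric lower bounds (defaults above).
#' @param t0_fixed non-decision time, constant across participants (sec).
#' @param n_participants,n_trials cohort size and trials per participant.
#' @param groups optional list of groups, each a list with elements `label`,
#'   `size` and optionally `means` (named overrides of the shared means).
#'   Group sizes must sum to `n_participants`.
#' @param dataset_id label written into trial tables.
#' @return an object of class `"lba_population"`.
#' @seealso [study1_grid()], [study2_config()], [draw_cohort()]
#' @export
lba_population <- function(means,
                           sds = c(A = 0.6, B = 0.6, v_true = 0.8,
                                   v_false = 0.8, sv = 0.4),
                           lower_bounds = c(A = 0.05, B = 0.05, v_true = 1.3,
                                            v_false = 0.05, sv = 0.01),
                           t0_fixed = 0.3,
                           n_participants = 100,
                           n_trials = 1000,
                           groups = NULL,
                           dataset_id = "dataset1") {
  pars <- setdiff(LBA_PARS, "t0")
  stopifnot(all(pars %in% names(means)), all(pars %in% names(sds)),
            all(sds[pars] > 0), t0_fixed > 0,
            n_participants >= 1, n_trials >= 1)
  if (!is.null(groups)) {
    sizes <- vapply(groups, function(g) g$size, numeric(1))
    if (sum(sizes) != n_participants) {
      stop("group sizes must sum to 'n_participants'")
    }
  }
  structure(list(means = means[pars], sds = sds[pars],
                 lower_bounds = lower_bounds, t0_fixed = t0_fixed,
                 n_participants = n_participants, n_trials = n_trials,
                 groups = groups, dataset_id = dataset_id),
            class = "lba_population")
}

#' @export
print.lba_population <- function(x, ...) {
  cat("LBA population config (", x$dataset_id, "): ",
      x$n_participants, " participants x ", x$n_trials, " trials\n", sep = "")
  m <- rbind(mean = x$means, sd = x$sds)
  print(round(m, 3))
  cat("t0 fixed at", x$t0_fixed, "s\n")
  if (!is.null(x$groups)) {
    for (g in x$groups) {
      ov <- if (length(g$means)) {
        paste(names(g$means), unlist(g$means), sep = "=", collapse = ", ")
      } else "no overrides"
      cat("  group ", g$label, ": n=", g$size, " (", ov, ")\n", sep = "")
    }
  }
  invisible(x)
}

#' Generating configurations of the 21-dataset recovery study
#'
#' Returns the 21 population-mean combinations of the first recovery study:
#' start-point range mean fixed at 2, boundary gap and correct-drift means
#' crossed over \{2.3, 2.5, 2.7\}, incorrect-drift mean over
#' \{0.6, 0.8, 1.0\} in a partial-factorial pattern (full 3x3 cross for
#' `v_false` 0.6 and 0.8; only `v_true` = 2.3 for `v_false` = 1.0), and
#' `sv` mean 1 throughout. Each configuration specifies 100 participants
#' and 1,000 trials.
#'
#' @return list of 21 [lba_population()] objects, named `config01` ...
#'   `config21`.
#' @export
study1_grid <- function() {
  rows <- list()
  for (vf in c(0.6, 0.8)) {
    for (vt in c(2.3, 2.5, 2.7)) {
      for (B in c(2.3, 2.5, 2.7)) {
        rows[[length(rows) + 1L]] <- c(B = B, v_true = vt, v_false = vf)
      }
    }
  }
  for (B in c(2.3, 2.5, 2.7)) {
    rows[[length(rows) + 1L]] <- c(B = B, v_true = 2.3, v_false = 1.0)
  }
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    out[[i]] <- lba_population(
      means = c(A = 2, B = r[["B"]], v_true = r[["v_true"]],
                v_false = r[["v_false"]], sv = 1),
      dataset_id = sprintf("config%02d", i))
  }
  names(out) <- vapply(out, function(x) x$dataset_id, character(1))
  out
}

#' Generating configuration of the two-group discrimination study
#'
#' Two groups whose generating populations are identical except for the
#' `sv` mean: 1.5 in the first group and 0.5 in the second. Shared means
#' are `A` = 2, `B` = 2.5, `v_true` = 2.5, `v_false` = 0.8, with `t0` fixed
#' at 0.3 s and the same SDs and corrections as the single-group study.
#'
#' @param n_per_group participants per group (50 in the full design).
#' @param n_trials trials per participant.
#' @return an [lba_population()] with two groups.
#' @export
study2_config <- function(n_per_group = 50, n_trials = 1000) {
  lba_population(
    means = c(A = 2, B = 2.5, v_true = 2.5, v_false = 0.8, sv = 1),
    n_participants = 2 * n_per_group, n_trials = n_trials,
    groups = list(list(label = "group1", size = n_per_group,
                       means = c(sv = 1.5)),
                  list(label = "group2", size = n_per_group,
                       means = c(sv = 0.5))),
    dataset_id = "study2")
}

#' Draw true individual parameters for a cohort
#'
#' Draws each participant's parameter vector from independent normal
#' population distributions, then applies the corrections described in
#' [lba_population()] (lower-bound floors, then the
#' `v_false := v_true - 0.2` replacement when the drift gap is below 0.2).
#' `t0` is set to the configured constant. Each participant consumes an
#' independent L'Ecuyer RNG substream spawned from the master seed, so
#' enlarging a cohort leaves earlier participants' draws unchanged.
#'
#' @param config an [lba_population()].
#' @param seed master integer seed.
#' @return an object of class `"lba_cohort"`: a data.frame with columns
#'   `participant`, `group` and the six parameters, carrying the config and
#'   seed as attributes.
#' @export
draw_cohort <- function(config, seed) {
  stopifnot(inherits(config, "lba_population"))
  n <- config$n_participants
  group_of <- cohort_groups(config)
  streams <- rng_substreams(seed, n)
  pars <- names(config$means)
  draws <- matrix(NA_real_, n, length(pars), dimnames = list(NULL, pars))
  for (i in seq_len(n)) {
    means <- config$means
    g <- group_of[i]
    if (!is.null(config$groups)) {
      ov <- config$groups[[match(g, vapply(config$groups, `[[`, "", "label"))]]$means
      if (length(ov)) means[names(ov)] <- ov
    }
    draws[i, ] <- with_rng_stream(streams[[i]], function() {
      rnorm(length(pars), means[pars], config$sds[pars])
    })
  }
  draws <- correct_draws(draws, config$lower_bounds)
  out <- data.frame(participant = seq_len(n), group = group_of,
                    draws, t0 = config$t0_fixed,
                    stringsAsFactors = FALSE)
  structure(out, class = c("lba_cohort", "data.frame"),
            config = config, seed = seed)
}

# Floors first, then the unconditional v_false replacement (not re-floored).
correct_draws <- function(draws, lb) {
  for (p in colnames(draws)) {
    if (p %in% names(lb)) draws[, p] <- pmax(draws[, p], lb[[p]])
  }
  low <- draws[, "v_true"] - draws[, "v_false"] < 0.2
  draws[low, "v_false"] <- draws[low, "v_true"] - 0.2
  draws
}

cohort_groups <- function(config) {
  if (is.null(config$groups)) {
    rep("all", config$n_participants)
  } else {
    unlist(lapply(config$groups, function(g) rep(g$label, g$size)))
  }
}

#' Simulate a trial table from a cohort
#'
#' Simulates `n_trials` LBA trials per participant (via [rlba()]) from the
#' cohort's true parameters. Trials for participant i are drawn from their
#' own RNG substream of the master seed, independently of the parameter
#' draws.
#'
#' @param cohort an [draw_cohort()] result.
#' @param seed master integer seed for the trial-level randomness.
#' @param n_trials optional override of the configured trials/participant.
#' @return a data.frame with columns `dataset_id`, `participant_id`,
#'   `group`, `trial`, `choice`, `rt`.
#' @export
simulate_cohort <- function(cohort, seed, n_trials = NULL) {
  stopifnot(inherits(cohort, "lba_cohort"))
  config <- attr(cohort, "config")
  if (is.null(n_trials)) n_trials <- config$n_trials
  n <- nrow(cohort)
  streams <- rng_substreams(seed, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- unlist(cohort[i, LBA_PARS])
    tr <- with_rng_stream(streams[[i]], function() rlba(p, n_trials))
    out[[i]] <- data.frame(dataset_id = config$dataset_id,
                           participant_id = cohort$participant[i],
                           group = cohort$group[i],
                           tr, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read and write trial tables
#'
#' Trial tables are plain CSV with header
#' `dataset_id,participant_id,group,trial,choice,rt`; `choice` holds the
#' winning-accumulator label (`"true"`/`"false"`) and `rt` is in seconds,
#' written with 6 decimals.
#'
#' @param trials a trial table data.frame.
#' @param path file path.
#' @return `read_trials` returns the validated data.frame.
#' @export
write_trials <- function(trials, path) {
  check_trial_table(trials)
  trials$rt <- sprintf("%.6f", trials$rt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(trials, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE)
  check_trial_table(trials)
  trials
}

check_trial_table <- function(trials) {
  need <- c("dataset_id", "participant_id", "group", "trial", "choice", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(trials$choice %in% c("true", "false"))) {
    stop("'choice' must be \"true\" or \"false\"")
  }
  if (!is.numeric(trials$rt) || any(trials$rt <= 0)) {
    stop("'rt' must be positive numeric seconds")
  }
  invisible(TRUE)
}

#' Write a cohort's true parameters to CSV
#' @param cohort an [draw_cohort()] result.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  config <- attr(cohort, "config")
  out <- data.frame(dataset_id = config$dataset_id,
                    participant_id = cohort$participant,
                    group = cohort$group,
                    cohort[, LBA_PARS], stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

# --- reproducible per-participant RNG substreams --------------------------

rng_substreams <- function(seed, n) {
  old_state <- get_rng_state()
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    restore_rng_state(old_state)
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

with_rng_stream <- function(stream, f) {
  old_state <- get_rng_state()
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    restore_rng_state(old_state)
  })
  assign(".Random.seed", stream, envir = globalenv())
  f()
}
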