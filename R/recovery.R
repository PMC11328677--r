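#' Pearson recovery correlation
#'
#' Product-moment correlation between true (generating) and estimated
#' (posterior-mean) parameter values across participants, with a two-sided
#' test against zero. Thin wrapper over [stats::cor.test()] returning the
#' pieces the recovery report needs.
#'
#' @param true_vals,est_vals numeric vectors of equal length (>= 3
#'   participants, nonzero variance on both sides).
#' @return list with `r` and `p`; both `NA` (with a warning) when either
#'   side has zero variance.
#' @export
pearson_recovery <- function(true_vals, est_vals) {
  stopifnot(length(true_vals) == length(est_vals), length(true_vals) >= 3)
  if (sd(true_vals) == 0 || sd(est_vals) == 0) {
    warning("zero variance; Pearson correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- cor.test(true_vals, est_vals)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Intraclass correlation ICC(2,1): absolute agreement
#'
#' Two-way random-effects, single-measure, absolute-agreement intraclass
#' correlation between two sets of scores (here: true and recovered
#' parameter values), computed from the two-way ANOVA decomposition
#' (Shrout & Fleiss):
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))`
#' with `MSR`, `MSC`, `MSE` the row (participant), column (rater) and error
#' mean squares, `k = 2` raters and `n` participants. Unlike the Pearson
#' correlation it penalises systematic shifts and scale changes, not only
#' scatter. The significance test is `F = MSR / MSE` on
#' `(n - 1, (n - 1)(k - 1))` degrees of freedom; the 95% confidence
#' interval is the Shrout-Fleiss F-based interval (the p-value and the CI
#' therefore derive from different approximations and can disagree near 0).
#'
#' @param true_vals,est_vals numeric vectors of equal length.
#' @param conf confidence level of the interval.
#' @return list with `icc`, `p`, `ci` (length-2 vector) and the mean
#'   squares (`msr`, `msc`, `mse`).
#' @export
icc_2_1 <- function(true_vals, est_vals, conf = 0.95) {
  stopifnot(length(true_vals) == length(est_vals), length(true_vals) >= 3)
  if (sd(true_vals) == 0 || sd(est_vals) == 0) {
    warning("zero variance; ICC undefined")
    return(list(icc = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_),
                msr = NA_real_, msc = NA_real_, mse = NA_real_))
  }
  n <- length(true_vals)
  k <- 2
  y <- cbind(true_vals, est_vals)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  grand <- mean(y)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((y - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  Fobs <- msr / mse
  p <- pf(Fobs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  # Shrout-Fleiss interval for ICC(2,1)
  alpha <- 1 - conf
  Fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2 /
    ((k - 1) * k^2 * icc^2 * Fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2)
  FL <- qf(1 - alpha / 2, n - 1, vn)
  FU <- qf(1 - alpha / 2, vn, n - 1)
  lower <- n * (msr - FL * mse) /
    (FL * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (FU * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * FU * msr)
  list(icc = icc, p = p, ci = c(lower, upper), msr = msr, msc = msc, mse = mse)
}

#' Average correlations through Fisher's Z transformation
#'
#' `tanh(mean(atanh(r)))`; correlations at exactly +/-1 are clipped just
#' inside the open interval with a warning.
#'
#' @param rs vector of correlations in `[-1, 1]`; `NA`s are dropped.
#' @return the back-transformed mean correlation.
#' @export
fisher_z_mean <- function(rs) {
  rs <- rs[!is.na(rs)]
  if (!length(rs)) return(NA_real_)
  if (any(abs(rs) >= 1)) {
    warning("correlation(s) at +/-1 clipped before Fisher-Z averaging")
    rs <- pmin(pmax(rs, -(1 - 1e-12)), 1 - 1e-12)
  }
  tanh(mean(atanh(rs)))
}

#' Exclude non-converged participants
#'
#' Restricts a vector/matrix/data.frame of per-participant quantities to
#' the participants whose worst-case PSRF falls below the threshold.
#'
#' @param x per-participant object (rows = participants for matrices).
#' @param convergence a [participant_convergence()] data.frame.
#' @return `x` restricted to converged participants; the excluded
#'   participant ids are attached as attribute `"excluded"`.
#' @export
filter_by_psrf <- function(x, convergence) {
  keep <- convergence$converged
  out <- if (is.null(dim(x))) x[keep] else x[keep, , drop = FALSE]
  attr(out, "excluded") <- convergence$participant[!keep]
  out
}

#' Deviance information criterion, per participant and summed
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance
#' (`-2 log L` averaged over kept draws) and `pD = Dbar - D(theta_bar)`
#' the effective number of parameters, where `D(theta_bar)` is the deviance
#' at the posterior-mean parameters. Both are computed per participant from
#' that participant's own likelihood; summing per-participant DICs gives
#' the dataset-level criterion. Lower is better.
#'
#' @param fit an [hlba()] fit (its draws carry the per-participant
#'   log-likelihood trace).
#' @return list with `per_participant` (data.frame: `participant`, `dbar`,
#'   `d_at_mean`, `pd`, `dic`) and `total`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "hlba"))
  draws <- fit$draws
  data <- fit$model$data_prep(fit$trials)
  est <- fit$coef
  nsub <- dim(draws$log_lik)[3]
  out <- data.frame(participant = draws$participants,
                    dbar = NA_real_, d_at_mean = NA_real_,
                    pd = NA_real_, dic = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nsub)) {
    dev <- -2 * as.vector(draws$log_lik[, , i])
    ok <- is.finite(dev)
    if (!all(ok)) {
      warning(sum(!ok), " non-finite deviance draws excluded for participant ",
              draws$participants[i])
    }
    dbar <- mean(dev[ok])
    theta_bar <- matrix(est[i, fit$model$par_names], nrow = 1,
                        dimnames = list(NULL, fit$model$par_names))
    d_mean <- -2 * fit$model$loglik(theta_bar, data[[i]])
    out$dbar[i] <- dbar
    out$d_at_mean[i] <- d_mean
    out$pd[i] <- dbar - d_mean
    out$dic[i] <- dbar + out$pd[i]
  }
  list(per_participant = out, total = sum(out$dic))
}

#' Pooled-variance two-sample t-tests on posterior means by group
#'
#' For each parameter, compares the per-participant posterior means between
#' the two groups with a pooled-variance (equal-variance) t-test,
#' `df = n1 + n2 - 2`.
#'
#' @param est matrix of posterior means (participants x parameters), e.g.
#'   `coef(fit)`, already filtered for convergence if desired.
#' @param groups group label per row of `est` (exactly 2 distinct labels,
#'   each with >= 2 participants).
#' @param parameters which columns to test (default: all).
#' @return data.frame with one row per parameter: group means, `t`, `df`,
#'   `p`.
#' @export
group_ttest <- function(est, groups, parameters = colnames(est)) {
  labs <- unique(groups)
  stopifnot(length(labs) == 2, min(table(groups)) >= 2)
  out <- lapply(parameters, function(p) {
    x <- est[groups == labs[1], p]
    y <- est[groups == labs[2], p]
    if (sd(c(x, y)) == 0) {
      return(data.frame(parameter = p, mean_group1 = mean(x),
                        mean_group2 = mean(y), t = 0,
                        df = length(x) + length(y) - 2, p = 1))
    }
    tt <- t.test(x, y, var.equal = TRUE)
    data.frame(parameter = p, mean_group1 = mean(x), mean_group2 = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "group_labels") <- labs
  out
}

#' Score parameter recovery of a fitted cohort
#'
#' Joins the cohort's true parameter values with the fit's posterior means,
#' drops participants whose PSRF exceeds 1.1, and reports the Pearson
#' correlation and ICC(2,1) (with tests and the ICC's 95% CI) per recovered
#' parameter.
#'
#' @param fit an [hlba()] fit of data simulated from `cohort`.
#' @param cohort the generating [draw_cohort()] cohort.
#' @param parameters parameters to score; defaults to the fit's free
#'   parameters without `t0` (whose generating value is a constant, so
#'   recovery is not meaningful).
#' @return an object of class `"recovery_report"`: data.frame with columns
#'   `parameter`, `pearson_r`, `pearson_p`, `icc21`, `icc21_p`,
#'   `icc21_lo`, `icc21_hi`; attributes `n_retained` and `excluded`.
#' @export
recovery_report <- function(fit, cohort,
                            parameters = setdiff(fit$draws$free, "t0")) {
  stopifnot(inherits(fit, "hlba"), inherits(cohort, "lba_cohort"))
  est <- fit$coef
  idx <- match(rownames(est), as.character(cohort$participant))
  if (anyNA(idx)) stop("fit and cohort participants do not match")
  true_mat <- as.matrix(cohort[idx, parameters, drop = FALSE])
  est <- filter_by_psrf(est, fit$convergence)
  true_mat <- filter_by_psrf(true_mat, fit$convergence)
  if (nrow(est) < 3) {
    warning("fewer than 3 participants passed the PSRF gate; ",
            "recovery statistics are undefined for this dataset")
    out <- data.frame(parameter = parameters, pearson_r = NA_real_,
                      pearson_p = NA_real_, icc21 = NA_real_,
                      icc21_p = NA_real_, icc21_lo = NA_real_,
                      icc21_hi = NA_real_, stringsAsFactors = FALSE)
    return(structure(out, class = c("recovery_report", "data.frame"),
                     n_retained = nrow(est), excluded = attr(est, "excluded")))
  }
  rows <- lapply(parameters, function(p) {
    pe <- pearson_recovery(true_mat[, p], est[, p])
    ic <- icc_2_1(true_mat[, p], est[, p])
    data.frame(parameter = p, pearson_r = pe$r, pearson_p = pe$p,
               icc21 = ic$icc, icc21_p = ic$p,
               icc21_lo = ic$ci[1], icc21_hi = ic$ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("recovery_report", "data.frame"),
            n_retained = nrow(est),
            excluded = attr(est, "excluded"))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery (", attr(x, "n_retained"), " participants retained",
      sep = "")
  exc <- attr(x, "excluded")
  if (length(exc)) cat("; excluded: ", paste(exc, collapse = ", "), sep = "")
  cat(")\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Aggregate recovery reports across generating configurations
#'
#' Averages per-configuration Pearson correlations and ICCs through
#' Fisher's Z transformation and reports the min/max range, one row per
#' parameter x statistic — the layout used for multi-configuration
#' recovery summaries.
#'
#' @param reports list of [recovery_report()] objects.
#' @return data.frame with columns `parameter`, `statistic`, `lower`,
#'   `upper`, `mean`.
#' @export
aggregate_recovery <- function(reports) {
  pars <- unique(unlist(lapply(reports, function(r) r$parameter)))
  out <- list()
  for (p in pars) {
    for (stat in c("pearson_r", "icc21")) {
      vals <- vapply(reports, function(r) r[[stat]][r$parameter == p],
                     numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        parameter = p,
        statistic = if (stat == "pearson_r") "Pearson" else "ICC(2,1)",
        lower = min(vals), upper = max(vals), mean = fisher_z_mean(vals),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
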