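#' Linear Ballistic Accumulator first-passage density and distribution
#'
#' Closed-form density (`dlba_fpt`) and distribution function (`plba_fpt`)
#' of the time at which a single linear ballistic accumulator first crosses
#' its boundary. The accumulator starts at a point drawn uniformly on
#' `[0, A]`, accrues evidence at a rate drawn once per trial from
#' `Normal(v, s)`, and terminates on reaching the absolute boundary
#' `b = A + B`. Because the trial drift can be negative, the accumulator may
#' never cross: the density is defective and integrates to the crossing
#' probability, not to 1.
#'
#' Decision times `t` are measured from the start of evidence accumulation;
#' non-decision time is handled by the trial-level functions. z-scores are
#' clipped at +/-38 before evaluating the normal CDF/PDF for numerical
#' stability, and the distribution function is clipped to `[0, 1]`.
#'
#' @param t vector of decision times in seconds. Non-positive times yield
#'   density 0 / probability 0.
#' @param A upper end of the uniform start-point range (evidence units),
#'   strictly positive. Values below `1e-10` use the zero-start-point limit.
#' @param b absolute boundary (evidence units), must exceed `A`.
#' @param v mean drift rate (evidence units per second); may be negative.
#' @param s between-trial standard deviation of the drift rate, positive.
#' @return `dlba_fpt`: nonnegative densities; `plba_fpt`: probabilities in
#'   `[0, 1]`. Both are vectorised over `t`.
#' @examples
#' tt <- seq(0.05, 3, length.out = 200)
#' f <- dlba_fpt(tt, A = 2, b = 2.5, v = 2.5, s = 1)
#' # defective: integrates to the probability of ever crossing
#' integrate(dlba_fpt, 0, Inf, A = 2, b = 2.5, v = 2.5, s = 1)$value
#' @export
dlba_fpt <- function(t, A, b, v, s) {
  check_accumulator(A, b, v, s)
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tp <- t[pos]
  if (A < 1e-10) {
    # deterministic start at 0: T = b / drift, drift ~ N(v, s) truncated to > 0
    out[pos] <- (b / (tp^2 * s)) * dnorm(clip_z((b - tp * v) / (tp * s)))
  } else {
    ts <- tp * s
    z1 <- clip_z((b - tp * v) / ts)
    z2 <- clip_z((b - A - tp * v) / ts)
    f <- (-v * pnorm(z2) + s * dnorm(z2) + v * pnorm(z1) - s * dnorm(z1)) / A
    out[pos] <- pmax(f, 0)
  }
  out
}

#' @rdname dlba_fpt
#' @export
plba_fpt <- function(t, A, b, v, s) {
  check_accumulator(A, b, v, s)
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tp <- t[pos]
  if (A < 1e-10) {
    out[pos] <- pnorm(clip_z((tp * v - b) / (tp * s)))
  } else {
    ts <- tp * s
    z1 <- clip_z((b - tp * v) / ts)
    z2 <- clip_z((b - A - tp * v) / ts)
    F <- 1 + ((b - A - tp * v) / A) * pnorm(z2) -
      ((b - tp * v) / A) * pnorm(z1) +
      (ts / A) * dnorm(z2) - (ts / A) * dnorm(z1)
    out[pos] <- pmin(pmax(F, 0), 1)
  }
  out
}

clip_z <- function(z) pmin(pmax(z, -38), 38)

check_accumulator <- function(A, b, v, s) {
  if (!is.finite(A) || A < 0) stop("'A' must be a nonnegative finite number")
  if (!is.finite(b) || b <= A) stop("'b' must be finite and exceed 'A'")
  if (!is.finite(v)) stop("'v' must be finite")
  if (!is.finite(s) || s <= 0) stop("'s' must be a positive finite number")
  invisible(TRUE)
}

#' Participant-level LBA parameter vectors
#'
#' Constructs and validates the six-parameter vector describing one
#' participant in the two-choice LBA: start-point range `A`, boundary gap
#' `B` (absolute boundary `b = A + B`), mean drift rates of the correct
#' (`v_true`) and incorrect (`v_false`) accumulators, shared between-trial
#' drift SD `sv`, and non-decision time `t0` in seconds.
#'
#' @param A,B,v_true,v_false,sv,t0 scalar parameter values; `A`, `B`, `sv`
#'   and `t0` must be strictly positive.
#' @return a named numeric vector in canonical parameter order.
#' @export
lba_params <- function(A, B, v_true, v_false, sv, t0) {
  p <- c(A = A, B = B, v_true = v_true, v_false = v_false, sv = sv, t0 = t0)
  check_lba_params(p)
  p
}

check_lba_params <- function(p) {
  if (!all(LBA_PARS %in% names(p))) {
    stop("parameter vector must contain: ", paste(LBA_PARS, collapse = ", "))
  }
  if (!all(is.finite(p[LBA_PARS]))) stop("parameters must be finite")
  bad <- p[c("A", "B", "sv", "t0")] <= 0
  if (any(bad)) {
    stop("parameters must be strictly positive: ",
         paste(names(bad)[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Defective density and log-likelihood of an observed LBA trial
#'
#' `dlba_trial` evaluates the joint density of observing response `choice`
#' at response time `rt`: the first-passage density of the winning
#' accumulator at decision time `rt - t0`, times the probability that the
#' losing accumulator has not yet crossed. `lba_trial_loglik` sums the log
#' density over a table of trials; it is the reference (pure R) counterpart
#' of the compiled likelihood used inside the sampler.
#'
#' Trials on which both sampled drift rates are negative never terminate;
#' by default the corresponding probability mass is simply missing from the
#' defective densities (they sum to less than 1 over choices and time).
#' `renormalize = TRUE` instead conditions on termination by dividing by
#' `1 - P(both drifts <= 0)`.
#'
#' @param rt response time(s) in seconds, including non-decision time.
#' @param choice `"true"`/`"false"` (or logical) label(s) of the winning
#'   accumulator.
#' @param p named participant parameter vector (see [lba_params()]).
#' @param renormalize condition the density on trial termination.
#' @return `dlba_trial`: vector of nonnegative densities (0 when
#'   `rt <= t0`); `lba_trial_loglik`: scalar log-likelihood, `-Inf` when any
#'   `rt <= t0`.
#' @export
dlba_trial <- function(rt, choice, p, renormalize = FALSE) {
  check_lba_params(p)
  choice <- as_choice(choice)
  stopifnot(length(choice) == length(rt))
  b <- p[["A"]] + p[["B"]]
  t <- rt - p[["t0"]]
  vw <- ifelse(choice, p[["v_true"]], p[["v_false"]])
  vl <- ifelse(choice, p[["v_false"]], p[["v_true"]])
  d <- numeric(length(t))
  for (i in seq_along(t)) {
    d[i] <- dlba_fpt(t[i], p[["A"]], b, vw[i], p[["sv"]]) *
      (1 - plba_fpt(t[i], p[["A"]], b, vl[i], p[["sv"]]))
  }
  if (renormalize) {
    p_none <- pnorm(-p[["v_true"]] / p[["sv"]]) * pnorm(-p[["v_false"]] / p[["sv"]])
    d <- d / (1 - p_none)
  }
  d
}

#' @rdname dlba_trial
#' @export
lba_trial_loglik <- function(rt, choice, p, renormalize = FALSE) {
  d <- dlba_trial(rt, choice, p, renormalize = renormalize)
  if (any(d == 0)) return(-Inf)
  sum(log(d))
}

as_choice <- function(choice) {
  if (is.logical(choice)) return(choice)
  if (is.character(choice) || is.factor(choice)) {
    ch <- as.character(choice)
    if (!all(ch %in% c("true", "false"))) {
      stop("'choice' labels must be \"true\" or \"false\"")
    }
    return(ch == "true")
  }
  stop("'choice' must be logical or \"true\"/\"false\" labels")
}

#' Simulate LBA trials for one participant
#'
#' Simulates `n` two-choice trials: each accumulator draws an independent
#' start point from `U[0, A]` and a trial drift from `Normal(v_i, sv)`; the
#' response is the accumulator whose crossing time `(b - start) / drift`
#' (among positive drifts) is smallest, and the response time adds `t0`.
#' Trials on which both drifts come up non-positive never terminate and are
#' redrawn, matching the default (non-renormalized) likelihood's treatment
#' of that mass as negligible at typical parameter values.
#'
#' @param p named participant parameter vector (see [lba_params()]).
#' @param n number of trials.
#' @param seed optional integer seed for reproducibility (the caller's RNG
#'   state is restored on exit).
#' @return a data.frame with columns `trial`, `choice` ("true"/"false") and
#'   `rt` (seconds).
#' @export
rlba <- function(p, n, seed = NULL) {
  check_lba_params(p)
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  b <- p[["A"]] + p[["B"]]
  choice <- logical(n)
  rt <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    d1 <- rnorm(m, p[["v_true"]], p[["sv"]])
    d2 <- rnorm(m, p[["v_false"]], p[["sv"]])
    u1 <- runif(m, 0, p[["A"]])
    u2 <- runif(m, 0, p[["A"]])
    t1 <- ifelse(d1 > 0, (b - u1) / d1, Inf)
    t2 <- ifelse(d2 > 0, (b - u2) / d2, Inf)
    ok <- is.finite(pmin(t1, t2))
    idx <- todo[ok]
    choice[idx] <- t1[ok] <= t2[ok]
    rt[idx] <- pmin(t1, t2)[ok] + p[["t0"]]
    todo <- todo[!ok]
  }
  data.frame(trial = seq_len(n),
             choice = ifelse(choice, "true", "false"),
             rt = rt,
             stringsAsFactors = FALSE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
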