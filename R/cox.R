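# Efron-approximation partial likelihood, gradient and information for a
# Cox proportional-hazards model. Month-resolution exit ages make ties
# pervasive in these cohorts, so the Efron correction (rather than
# Breslow, which is visibly biased under heavy ties) is used throughout.
efron_loglik <- function(beta, times, status, X, want = c("all", "loglik")) {
  want <- match.arg(want)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  event_times <- sort(unique(times[status]))
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (t in event_times) {
    risk <- times >= t
    dead <- status & times == t
    d <- sum(dead)
    s0R <- sum(w[risk])
    s0D <- sum(w[dead])
    xw_R <- colSums(X[risk, , drop = FALSE] * w[risk])
    xw_D <- colSums(X[dead, , drop = FALSE] * w[dead])
    ll <- ll + sum(eta[dead])
    if (want == "all") {
      XR <- X[risk, , drop = FALSE]
      XD <- X[dead, , drop = FALSE]
      s2R <- crossprod(XR * w[risk], XR)
      s2D <- crossprod(XD * w[dead], XD)
      grad <- grad + colSums(XD)
    }
    for (l in seq_len(d) - 1) {
      frac <- l / d
      denom <- s0R - frac * s0D
      ll <- ll - log(denom)
      if (want == "all") {
        m_l <- (xw_R - frac * xw_D) / denom
        grad <- grad - m_l
        info <- info + (s2R - frac * s2D) / denom - tcrossprod(m_l)
      }
    }
  }
  if (want == "loglik") return(list(loglik = ll))
  list(loglik = ll, gradient = grad, information = info)
}

#' Fixed-effects Cox proportional-hazards model
#'
#' Maximises the Efron-corrected partial likelihood by Newton-Raphson
#' (convergence when the gradient's maximum norm falls below `tol`,
#' default 1e-8, at most `max_iter` iterations, with step-halving when a
#' step fails to increase the likelihood). Standard errors are Wald
#' errors from the inverse observed information. A positive coefficient
#' means a higher hazard of removal.
#'
#' Monotone likelihoods (complete separation of events by a covariate)
#' are reported via `converged = FALSE` rather than an error.
#'
#' @param durations Lifetimes in days.
#' @param events Logical event indicators (`FALSE` = right-censored).
#' @param covariates Numeric matrix (or vector, for one covariate), one
#'   row per subject; no constant columns. The cohort convention is
#'   female = 0 / male = 1 and suburban = 0 / urban = 1, litter size as
#'   counted.
#' @param tol,max_iter Newton-Raphson controls.
#' @return Object of class `cox_fit`: `coefficients`, `se`,
#'   `loglik_null`, `loglik_fit`, `converged`, `iterations`, `n`,
#'   `n_events`.
#' @seealso [cox_lrt()], [cox_score_test()]
#' @export
cox_fit <- function(durations, events, covariates, tol = 1e-8,
                    max_iter = 50L) {
  times <- as.numeric(durations)
  status <- as.logical(events)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (length(times) != nrow(X) || length(times) != length(status)) {
    stop_pupsurv("durations, events and covariates must be matched",
                 class = "pupsurv_input_error")
  }
  if (!all(is.finite(X))) {
    stop_pupsurv("covariates must be finite",
                 class = "pupsurv_input_error")
  }
  if (sum(status) < 1L) {
    stop_pupsurv("at least one event is required",
                 class = "pupsurv_input_error")
  }
  const <- apply(X, 2, function(col) var(col) == 0)
  if (any(const)) {
    stop_pupsurv("constant covariate column(s): ",
                 paste(colnames(X)[const], collapse = ", "),
                 class = "pupsurv_input_error")
  }
  p <- ncol(X)
  beta <- numeric(p)
  ll0 <- efron_loglik(beta, times, status, X, want = "loglik")$loglik
  ll_old <- ll0
  converged <- FALSE
  iter <- 0L
  ev <- efron_loglik(beta, times, status, X)
  repeat {
    iter <- iter + 1L
    if (max(abs(ev$gradient)) < tol) {
      converged <- TRUE
      break
    }
    if (iter > max_iter) break
    step <- tryCatch(solve(ev$information, ev$gradient),
                     error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # step-halving: never accept a likelihood decrease
    accepted <- FALSE
    # slack scales with |loglik| so float noise near the optimum never
    # masquerades as a likelihood decrease
    slack <- 1e-8 * (abs(ll_old) + 1)
    for (half in 0:10) {
      cand <- beta + step / 2^half
      ll_new <- efron_loglik(cand, times, status, X,
                             want = "loglik")$loglik
      if (is.finite(ll_new) && ll_new >= ll_old - slack) {
        beta <- cand
        ll_old <- ll_new
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
    ev <- efron_loglik(beta, times, status, X)
    if (max(abs(beta)) > 20) break  # monotone likelihood / separation
  }
  se <- rep(NA_real_, p)
  if (converged) {
    vcv <- tryCatch(solve(ev$information), error = function(e) NULL)
    if (!is.null(vcv)) se <- sqrt(diag(vcv)) else converged <- FALSE
  }
  structure(
    list(coefficients = setNames(beta, colnames(X)),
         se = setNames(se, colnames(X)),
         loglik_null = ll0, loglik_fit = ll_old,
         converged = converged, iterations = iter,
         n = length(times), n_events = sum(status)),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (Efron ties): n = %d, events = %d%s\n",
              x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  z <- x$coefficients / x$se
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$se, z = z, p = 2 * pnorm(-abs(z)),
                    check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' Likelihood-ratio test for a Cox fit
#'
#' `chisq = 2 (loglik_fit - loglik_null)` on as many degrees of freedom
#' as covariates.
#'
#' @param fit A converged [cox_fit()].
#' @return List with `chisq`, `df`, `p`.
#' @export
cox_lrt <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) {
    stop_pupsurv("likelihood-ratio test requires a converged fit",
                 class = "pupsurv_input_error")
  }
  chisq <- max(0, 2 * (fit$loglik_fit - fit$loglik_null))
  df <- length(fit$coefficients)
  list(chisq = chisq, df = df,
       p = pchisq(chisq, df = df, lower.tail = FALSE))
}

#' Cox partial-likelihood score test at beta = 0
#'
#' `U(0)' I(0)^{-1} U(0)`, chi-square on `ncol(covariates)` degrees of
#' freedom. For a single binary covariate and untied event times this is
#' identical to the two-sample log-rank statistic.
#'
#' @inheritParams cox_fit
#' @return List with `chisq`, `df`, `p`.
#' @export
cox_score_test <- function(durations, events, covariates) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  ev <- efron_loglik(numeric(ncol(X)), as.numeric(durations),
                     as.logical(events), X)
  chisq <- drop(crossprod(ev$gradient,
                          solve(ev$information, ev$gradient)))
  list(chisq = chisq, df = ncol(X),
       p = pchisq(chisq, df = ncol(X), lower.tail = FALSE))
}

#' Cox model frame for a cohort
#'
#' Assembles the duration/event/covariate data for the standard cohort
#' model (litter size, sex, habitat), dropping pups of unknown sex, with
#' the coding female = 0 / male = 1 and suburban = 0 / urban = 1.
#'
#' @param cohort A `pup_cohort`.
#' @return Data frame with columns `duration`, `event`, `litter_size`,
#'   `sex_male`, `habitat_urban`.
#' @export
cohort_cox_frame <- function(cohort) {
  stopifnot(inherits(cohort, "pup_cohort"))
  r <- cohort$records
  size <- cohort$litters$size_at_birth[
    match(r$litter_id, cohort$litters$litter_id)]
  keep <- r$sex != "unknown"
  data.frame(
    duration = r$exit_age_days[keep],
    event = !r$censored[keep],
    litter_size = size[keep],
    sex_male = as.integer(r$sex[keep] == "male"),
    habitat_urban = as.integer(r$habitat[keep] == "urban")
  )
}
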