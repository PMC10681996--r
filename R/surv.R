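#' Derive a time-to-event endpoint from raw follow-up columns
#'
#' Expects per-patient columns `time_lr`, `time_dm`, `time_death` (months
#' to loco-regional recurrence, distant metastasis, death; `NA` when not
#' observed) and `time_last_fu` (last follow-up). Endpoint rules:
#'
#' * `PFS`: event at the first of any recurrence or death; otherwise
#'   censored at last follow-up.
#' * `OS`: event at death; otherwise censored at last follow-up.
#' * `LRC`: event at loco-regional recurrence; death without loco-regional
#'   recurrence censors at the death date (cause-specific convention);
#'   otherwise censored at last follow-up.
#' * `FFDM`: as LRC with distant metastasis as the event.
#'
#' Records with non-positive follow-up are dropped with a warning naming
#' the patient ids.
#'
#' @param cohort tibble with the raw follow-up columns plus `patient_id`.
#' @param endpoint one of `"PFS"`, `"OS"`, `"LRC"`, `"FFDM"`.
#' @return A tibble `patient_id`, `endpoint`, `time`, `event`.
#' @export
derive_endpoint <- function(cohort, endpoint = c("PFS", "OS", "LRC", "FFDM")) {
  endpoint <- match.arg(endpoint)
  need <- c("patient_id", "time_lr", "time_dm", "time_death", "time_last_fu")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  lr <- cohort$time_lr
  dm <- cohort$time_dm
  death <- cohort$time_death
  fu <- cohort$time_last_fu

  pm <- function(...) {
    m <- suppressWarnings(pmin(..., na.rm = TRUE))
    m[!is.finite(m)] <- NA_real_
    m
  }
  res <- switch(
    endpoint,
    PFS = {
      ev_t <- pm(lr, dm, death)
      list(time = ifelse(is.na(ev_t), fu, pmin(ev_t, fu)),
           event = as.integer(!is.na(ev_t) & ev_t <= fu))
    },
    OS = list(time = ifelse(is.na(death), fu, pmin(death, fu)),
              event = as.integer(!is.na(death) & death <= fu)),
    LRC = {
      cens <- ifelse(is.na(death), fu, pmin(death, fu))
      list(time = ifelse(is.na(lr), cens, pmin(lr, cens)),
           event = as.integer(!is.na(lr) & lr <= cens))
    },
    FFDM = {
      cens <- ifelse(is.na(death), fu, pmin(death, fu))
      list(time = ifelse(is.na(dm), cens, pmin(dm, cens)),
           event = as.integer(!is.na(dm) & dm <= cens))
    }
  )
  out <- tibble::tibble(patient_id = cohort$patient_id, endpoint = endpoint,
                        time = res$time, event = res$event)
  bad <- !is.finite(out$time) | out$time <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d records with non-positive follow-up: %s",
                    sum(bad),
                    paste(utils::head(out$patient_id[bad], 5), collapse = ", ")))
    out <- out[!bad, ]
  }
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records tibble with `time` and `event` (1 = event, 0 = censored);
#'   an optional `group` column yields one curve per group.
#' @return A tibble step table: `group` (if supplied), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `lower`, `upper` (log-log 95% CI).
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1, all(c("time", "event") %in% names(records)))
  has_group <- "group" %in% names(records)
  fit <- if (has_group) {
    survival::survfit(survival::Surv(time, event) ~ group, data = records,
                      conf.type = "log-log")
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                      conf.type = "log-log")
  }
  s <- summary(fit, censored = TRUE)
  out <- tibble::tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv,
    lower = if (is.null(s$lower)) NA_real_ else s$lower,
    upper = if (is.null(s$upper)) NA_real_ else s$upper
  )
  if (has_group) {
    out <- tibble::add_column(
      out, group = sub("^group=", "", as.character(s$strata)), .before = 1)
  }
  out
}

#' Cox proportional-hazards fit with Wald summaries
#'
#' Thin, contract-enforcing wrapper around the partial-likelihood fit
#' (Efron tie correction): per covariate the hazard ratio, Wald 95% CI and
#' Wald p-value; monotone-likelihood / separation problems are flagged
#' rather than silently reported as huge finite estimates.
#'
#' @param data tibble holding time, event and covariate columns.
#' @param covariates character vector of covariate column names. Covariates
#'   enter as given (metric); binarize beforehand (e.g. with
#'   [binarize_covariates()]) for cutoff-based coding.
#' @param time,event column names of the endpoint time and indicator.
#' @return An object of class `asp_cox` with methods [tidy()] and
#'   [glance()]; fields `terms` (tibble), `n`, `n_events`, `converged`,
#'   `separation`, `fit` (the underlying `coxph` object).
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event") {
  stopifnot(all(c(time, event, covariates) %in% names(data)))
  dat <- data[stats::complete.cases(data[, c(time, event, covariates)]), ]
  n_events <- sum(dat[[event]])
  if (n_events < 2) stop("need at least 2 events")
  for (cv in covariates) {
    v <- dat[[cv]]
    if (is.numeric(v) && sd(v) == 0) stop("constant covariate: ", cv)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  warn <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- qnorm(0.975)
  separation <- any(grepl("infinite|Loglik converged", warn)) |
    any(abs(beta) > 15)
  terms <- tibble::tibble(
    term = names(beta),
    estimate = as.numeric(beta),
    std_error = as.numeric(se),
    hr = exp(as.numeric(beta)),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se))
  )
  structure(
    list(terms = terms, n = nrow(dat), n_events = n_events,
         converged = fit$iter < fit$control$iter.max,
         separation = isTRUE(separation), warnings = warn, fit = fit),
    class = "asp_cox"
  )
}

#' @export
print.asp_cox <- function(x, ...) {
  cat(sprintf("<asp_cox> n=%d, events=%d%s\n", x$n, x$n_events,
              if (x$separation) " [separation flagged]" else ""))
  print(x$terms)
  invisible(x)
}

#' @rdname cox_fit
#' @param x an `asp_cox` object.
#' @param ... unused.
#' @export
tidy.asp_cox <- function(x, ...) x$terms

#' @rdname cox_fit
#' @export
glance.asp_cox <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    concordance = unname(x$fit$concordance["concordance"]),
    loglik = x$fit$loglik[2],
    converged = x$converged, separation = x$separation
  )
}

# fast single-covariate Cox Wald p (Efron ties) for cutpoint scans;
# returns c(beta, se, p) or NA on degenerate input
fast_cox1 <- function(x, time, event) {
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      matrix(x, ncol = 1), survival::Surv(time, event),
      strata = NULL, offset = NULL, init = 0,
      control = survival::coxph.control(),
      weights = NULL, method = "efron", rownames = NULL
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$coefficients)) return(c(NA, NA, NA))
  beta <- fit$coefficients
  se <- sqrt(fit$var[1, 1])
  c(beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

#' Log-rank test between survival groups
#'
#' @param records tibble with `time`, `event` and `group`.
#' @return A tibble `chisq`, `df`, `p`.
#' @export
logrank <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  if (length(unique(records$group)) < 2) {
    stop("log-rank needs at least 2 nonempty groups")
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = records)
  df <- length(sd_$n) - 1
  tibble::tibble(chisq = sd_$chisq, df = df,
                 p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Validate a fixed (externally published) cutoff
#'
#' Binarizes the marker at the supplied cutoff (strict `>` = high-risk
#' group), fits a univariate Cox model on the indicator and returns it
#' together with the per-group Kaplan-Meier step tables and the log-rank
#' test. No cutoff optimization is involved; this is the validation-mode
#' counterpart of [optimal_cutpoint()]. The conventional asphericity
#' validation cutoff is 19.5 (percent).
#'
#' @param data tibble with marker, time and event columns.
#' @param marker marker column name.
#' @param cutoff fixed cutoff on the marker scale.
#' @param time,event endpoint column names.
#' @return A list of class `asp_fixed_cutoff`: `cutoff`, `cox` (an
#'   `asp_cox`), `km` (grouped step table), `logrank`, `group_sizes`.
#' @export
validate_fixed_cutoff <- function(data, marker, cutoff,
                                  time = "time", event = "event") {
  stopifnot(marker %in% names(data))
  dat <- data[stats::complete.cases(data[, c(marker, time, event)]), ]
  high <- dat[[marker]] > cutoff
  sizes <- c(low = sum(!high), high = sum(high))
  if (any(sizes == 0)) {
    stop(sprintf("cutoff %g leaves an empty group (low=%d, high=%d)",
                 cutoff, sizes["low"], sizes["high"]))
  }
  dat$.group <- ifelse(high, "high", "low")
  dat$.high <- as.integer(high)
  cox <- cox_fit(dat, ".high", time = time, event = event)
  rec <- tibble::tibble(time = dat[[time]], event = dat[[event]],
                        group = dat$.group)
  structure(
    list(cutoff = cutoff, marker = marker, cox = cox,
         km = km_estimate(rec), logrank = logrank(rec),
         group_sizes = sizes),
    class = "asp_fixed_cutoff"
  )
}

#' @export
print.asp_fixed_cutoff <- function(x, ...) {
  cat(sprintf("<asp_fixed_cutoff> %s > %g: n(low)=%d n(high)=%d, log-rank p=%.3g\n",
              x$marker, x$cutoff, x$group_sizes["low"], x$group_sizes["high"],
              x$logrank$p))
  print(x$cox$terms)
  invisible(x)
}
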