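# shared fixtures and independent oracles, all built in code

sphere_phantom <- function(r, spacing = 1, background = 0, tumor = 10,
                           fwhm = 0, noise = 0, seed = 1) {
  n <- ceiling(2 * r / spacing) + 12
  make_phantom(
    shape_spec("sphere", radius = r),
    grid_spec(rep(n, 3), rep(spacing, 3)),
    acquisition_spec(tumor_suv = tumor, background_suv = background,
                     psf_fwhm_mm = fwhm, noise_sd = noise, seed = seed)
  )
}

# hand product-limit estimator (independent of the survival package)
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & event == 1)
    n_risk <- sum(time >= ut[i])
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ut, survival = out)
}

# independent Newton-Raphson maximizer of the Cox partial likelihood for a
# single covariate with no tied event times (Breslow = Efron = exact there)
cox_oracle_1cov <- function(x, time, event, tol = 1e-12) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  stopifnot(!anyDuplicated(time[event == 1]))
  beta <- 0
  for (it in 1:100) {
    U <- 0; I <- 0
    for (i in which(event == 1)) {
      rs <- which(time >= time[i])
      w <- exp(beta * x[rs])
      m1 <- sum(w * x[rs]) / sum(w)
      m2 <- sum(w * x[rs]^2) / sum(w)
      U <- U + x[i] - m1
      I <- I + (m2 - m1^2)
    }
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# brute-force minimum-p cutpoint: ALL unique values, coxph per candidate,
# post-hoc restriction to the type-8 IQR, first minimum wins
cutpoint_oracle <- function(marker, time, event) {
  q <- quantile(marker, c(0.25, 0.75), type = 8, names = FALSE)
  cands <- sort(unique(marker))
  res <- data.frame(cutoff = cands, p = NA_real_)
  for (i in seq_along(cands)) {
    ind <- as.numeric(marker > cands[i])
    if (sum(ind) == 0 || sum(ind) == length(ind)) next
    fit <- tryCatch(
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ ind,
                                       ties = "efron")),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    beta <- coef(fit)[1]
    if (!is.finite(beta) || abs(beta) >= 15) next
    se <- sqrt(vcov(fit)[1, 1])
    res$p[i] <- 2 * pnorm(-abs(beta / se))
  }
  res <- res[res$cutoff >= q[1] & res$cutoff <= q[2] & is.finite(res$p), ]
  best <- which.min(res$p)
  list(cutoff = res$cutoff[best], p = res$p[best])
}

# small survival data set with a planted binary effect, no tied event times
seeded_surv_data <- function(seed, n = 40, beta = 0) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    t_ev <- rexp(n, 0.05 * exp(beta * x))
    cens <- runif(n, 5, 60)
    data.frame(marker = x, time = pmin(t_ev, cens),
               event = as.integer(t_ev <= cens))
  })
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
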