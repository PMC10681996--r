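raw_row <- function(id, lr = NA, dm = NA, death = NA, fu) {
  tibble::tibble(patient_id = id, time_lr = lr, time_dm = dm,
                 time_death = death, time_last_fu = fu)
}

test_that("endpoint derivation applies the four endpoint rules", {
  # distant relapse at month 6, alive at month 30
  p <- raw_row("a", dm = 6, fu = 30)
  expect_equal(derive_endpoint(p, "PFS")[, c("time", "event")],
               tibble::tibble(time = 6, event = 1L))
  expect_equal(derive_endpoint(p, "FFDM")$event, 1L)
  expect_equal(derive_endpoint(p, "FFDM")$time, 6)
  expect_equal(derive_endpoint(p, "LRC")$time, 30)
  expect_equal(derive_endpoint(p, "LRC")$event, 0L)
  expect_equal(derive_endpoint(p, "OS")$time, 30)
  expect_equal(derive_endpoint(p, "OS")$event, 0L)

  # event-free, last seen at 24: censored everywhere
  q <- raw_row("b", fu = 24)
  for (ep in c("PFS", "OS", "LRC", "FFDM")) {
    r <- derive_endpoint(q, ep)
    expect_equal(r$time, 24)
    expect_equal(r$event, 0L)
  }

  # death at 12 without recurrence: PFS/OS events, LRC/FFDM censored at 12
  s <- raw_row("c", death = 12, fu = 12)
  expect_equal(derive_endpoint(s, "PFS")$event, 1L)
  expect_equal(derive_endpoint(s, "OS")$event, 1L)
  expect_equal(derive_endpoint(s, "LRC")$time, 12)
  expect_equal(derive_endpoint(s, "LRC")$event, 0L)
  expect_equal(derive_endpoint(s, "FFDM")$event, 0L)

  # non-positive follow-up dropped with the id named
  bad <- dplyr::bind_rows(raw_row("ok", fu = 10), raw_row("zero", fu = 0))
  expect_warning(r <- derive_endpoint(bad, "OS"), "zero")
  expect_identical(r$patient_id, "ok")
})

test_that("Kaplan-Meier matches hand-computed product limits exactly", {
  # no events: flat at 1
  r0 <- tibble::tibble(time = c(3, 7, 9), event = c(0, 0, 0))
  expect_true(all(km_estimate(r0)$survival == 1))

  # n=4, one event at t=5
  r1 <- tibble::tibble(time = c(5, 6, 7, 8), event = c(1, 0, 0, 0))
  k1 <- km_estimate(r1)
  expect_equal(k1$survival[k1$time == 5], 0.75)

  # n=3: censor at 2, event at 5 -> 1 * (1 - 1/2)
  r2 <- tibble::tibble(time = c(2, 5, 9), event = c(0, 1, 0))
  k2 <- km_estimate(r2)
  expect_equal(k2$survival[k2$time == 5], 0.5)

  # 5-patient fixture with a tie, against the independent hand oracle
  r3 <- tibble::tibble(time = c(1, 3, 3, 4, 6), event = c(1, 1, 1, 0, 1))
  k3 <- km_estimate(r3)
  o3 <- km_oracle(r3$time, r3$event)
  got <- k3$survival[k3$time %in% o3$time & k3$n_event > 0]
  expect_equal(got, o3$survival, tolerance = 1e-12)
  # hand values: S(1)=4/5, S(3)=4/5*2/4, S(6)=2/5*0
  expect_equal(o3$survival, c(0.8, 0.4, 0), tolerance = 1e-12)
})

test_that("Cox fits agree with an independent partial-likelihood oracle", {
  for (seed in c(2, 13, 44)) {
    d <- seeded_surv_data(seed, n = 40, beta = 0.5)
    fit <- cox_fit(d, "marker")
    beta_ref <- cox_oracle_1cov(d$marker, d$time, d$event)
    expect_equal(fit$terms$estimate, beta_ref, tolerance = 1e-6,
                 label = sprintf("beta at seed %d", seed))
  }
})

test_that("null covariates give hazard ratios near 1 on large cohorts", {
  d <- seeded_surv_data(7, n = 2000, beta = 0)
  fit <- cox_fit(d, "marker")
  expect_gt(fit$terms$hr, 0.93)
  expect_lt(fit$terms$hr, 1.08)
  expect_false(fit$separation)
})

test_that("perfect separation is flagged, not silently estimated", {
  d <- tibble::tibble(
    x = rep(c(1, 0), each = 10),
    time = c(1:10, 21:30),
    event = rep(c(1L, 0L), each = 10)
  )
  fit <- cox_fit(d, "x")
  expect_true(fit$separation)
})

test_that("cox_fit enforces its preconditions", {
  d <- seeded_surv_data(1, n = 20)
  d$const <- 1
  expect_error(cox_fit(d, "const"), "constant")
  d2 <- d; d2$event <- 0L; d2$event[1] <- 1L
  expect_error(cox_fit(d2, "marker"), "events")
})

test_that("tidy and glance return the broom-style tables", {
  d <- seeded_surv_data(3, n = 60, beta = 0.4)
  fit <- cox_fit(d, "marker")
  expect_tibble_cols(tidy(fit), c("term", "hr", "ci_low", "ci_high", "p"))
  g <- glance(fit)
  expect_tibble_cols(g, c("n", "n_events", "concordance", "separation"))
  expect_true(all(fit$terms$ci_low <= fit$terms$hr &
                    fit$terms$hr <= fit$terms$ci_high))
})

test_that("log-rank behaves at its boundary cases", {
  # identical groups: statistic 0
  base <- tibble::tibble(time = c(2, 4, 6, 9), event = c(1, 1, 0, 1))
  both <- dplyr::bind_rows(dplyr::mutate(base, group = "A"),
                           dplyr::mutate(base, group = "B"))
  lr <- logrank(both)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-9)

  # complete separation in time: tiny p
  far <- tibble::tibble(time = c(1, 2, 3, 4, 50, 60, 70, 80),
                        event = c(1, 1, 1, 1, 1, 1, 1, 1),
                        group = rep(c("A", "B"), each = 4))
  expect_lt(logrank(far)$p, 0.01)

  expect_error(logrank(dplyr::mutate(base, group = "A")), "2 nonempty")
})

test_that("fixed-cutoff validation binarizes, fits and errors correctly", {
  d <- withr::with_seed(5, {
    asp <- rgamma(300, 4, 0.2)
    t_ev <- rexp(300, 0.01 * exp(log(1.06) * asp))
    tibble::tibble(asp = asp, time = pmin(t_ev, 60),
                   event = as.integer(t_ev <= 60))
  })
  v <- validate_fixed_cutoff(d, "asp", 19.5)
  expect_gt(v$cox$terms$hr, 1)  # planted positive effect
  expect_tibble_cols(v$km, c("group", "time", "survival"))
  expect_identical(sum(v$group_sizes), 300L)
  expect_lt(v$logrank$p, 0.05)

  # cutoff below the minimum: empty low group
  expect_error(validate_fixed_cutoff(d, "asp", min(d$asp) - 1), "empty")

  # label swap by negating the marker inverts the hazard ratio
  d2 <- dplyr::mutate(d, neg = -asp)
  v2 <- validate_fixed_cutoff(d2, "neg", -19.5)
  expect_equal(v2$cox$terms$estimate, -v$cox$terms$estimate,
               tolerance = 1e-8)
})
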