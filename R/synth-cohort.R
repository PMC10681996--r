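#' Configuration for a simulated prognostic cohort
#'
#' The simulator draws, per patient, an asphericity value (ASP, percent),
#' an EPPI risk score (optionally correlated with ASP), a UICC-like stage
#' and standard demographics, and then generates latent event times for
#' loco-regional recurrence, distant metastasis and death from a
#' proportional-hazards model with linear predictor
#' `eta = beta_asp * ASP + beta_eppi * EPPI + beta_stage * I(stage III)`.
#' All three processes are exponential with rates
#' `mix * baseline_hazard * exp(eta)`; Cox regression is baseline-agnostic,
#' so the constant baseline does not restrict what recovery tests can show.
#' Administrative censoring at `censor_time` competes with independent
#' uniform dropout.
#'
#' The default effect sizes plant a hazard ratio of 1.02 per ASP
#' percentage point (the scale reported for NSCLC cohorts) and a
#' unit-scale EPPI effect, with a weak negative ASP-EPPI coupling so the
#' signature-vs-ASP correlation screen has signal to find.
#'
#' @param n_patients cohort size (>= 2).
#' @param beta_asp log-hazard per ASP percentage point.
#' @param beta_eppi log-hazard per EPPI-score unit.
#' @param beta_stage log-hazard for advanced (stage III) disease.
#' @param baseline_hazard events per month for an eta = 0 patient.
#' @param censor_time administrative censoring horizon, months.
#' @param dropout_max upper bound of the uniform dropout time, months.
#' @param asp_distribution list(mean, sd) of the gamma ASP distribution
#'   (percent).
#' @param eppi_distribution list(mean, sd) of the normal EPPI distribution.
#' @param rho_asp_eppi correlation between ASP and EPPI on the latent scale.
#' @param stage_probs probabilities of stages I, II, III.
#' @param event_mix relative hazard shares of loco-regional recurrence,
#'   distant metastasis and death (sums to 1).
#' @param expression `NULL` to skip count simulation, or a list with
#'   `n_genes` (total gene count), `dispersion` (NB dispersion, so
#'   size = 1/dispersion), `coupling` (log2 mean shift of each signature
#'   gene per EPPI unit), `lib_sd` (log-normal library size SD) and
#'   optionally `signature_genes` / `signature_sign` (defaulting to the
#'   genes of [synthetic_eppi_model()] with shifts signed like its
#'   coefficients, so the fitted score moves with the latent risk).
#' @param cohort label stored with every patient.
#' @param seed integer RNG seed; the cohort is a pure function of the
#'   config and this seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200,
                          beta_asp = log(1.02),
                          beta_eppi = log(2),
                          beta_stage = log(1.5),
                          baseline_hazard = 0.01,
                          censor_time = 60,
                          dropout_max = 240,
                          asp_distribution = list(mean = 20, sd = 12),
                          eppi_distribution = list(mean = 0, sd = 1),
                          rho_asp_eppi = -0.3,
                          stage_probs = c(0.5, 0.3, 0.2),
                          event_mix = c(lr = 0.3, dm = 0.4, death = 0.3),
                          expression = NULL,
                          cohort = "synthetic",
                          seed = 1L) {
  stopifnot(n_patients >= 2, baseline_hazard > 0, censor_time > 0,
            dropout_max > 0, abs(sum(stage_probs) - 1) < 1e-8,
            abs(sum(event_mix) - 1) < 1e-8, abs(rho_asp_eppi) <= 1)
  structure(
    list(n_patients = as.integer(n_patients), beta_asp = beta_asp,
         beta_eppi = beta_eppi, beta_stage = beta_stage,
         baseline_hazard = baseline_hazard, censor_time = censor_time,
         dropout_max = dropout_max, asp_distribution = asp_distribution,
         eppi_distribution = eppi_distribution,
         rho_asp_eppi = rho_asp_eppi, stage_probs = stage_probs,
         event_mix = event_mix, expression = expression, cohort = cohort,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate a cohort with known hazard structure
#'
#' See [cohort_config()] for the generative model. The returned table
#' carries both the raw latent event columns (`time_lr`, `time_dm`,
#' `time_death`, `time_last_fu`, `NA` when the event never happened before
#' censoring) and pre-derived time/event pairs for the four endpoints
#' PFS, OS, LRC and FFDM (via [derive_endpoint()]).
#'
#' @param cfg a [cohort_config()].
#' @return A list with `cohort` (tibble, one row per patient) and `counts`
#'   (a raw-stage [expr_matrix()], or `NULL` when expression simulation is
#'   off).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_local_seed(cfg$seed, {
    n <- cfg$n_patients
    ad <- cfg$asp_distribution
    shp <- (ad$mean / ad$sd)^2
    asp <- stats::rgamma(n, shape = shp, rate = shp / ad$mean)
    ed <- cfg$eppi_distribution
    z_asp <- (asp - mean(asp)) / max(sd(asp), 1e-12)
    eppi <- ed$mean + ed$sd * (cfg$rho_asp_eppi * z_asp +
                                 sqrt(1 - cfg$rho_asp_eppi^2) * rnorm(n))
    stage <- sample(c("I", "II", "III"), n, TRUE, prob = cfg$stage_probs)
    sex <- sample(c("male", "female"), n, TRUE, prob = c(0.65, 0.35))
    age <- round(rnorm(n, 67, 9))
    histology <- sample(c("SCC", "ADC"), n, TRUE, prob = c(0.45, 0.55))

    eta <- cfg$beta_asp * asp + cfg$beta_eppi * eppi +
      cfg$beta_stage * (stage == "III")
    if (!all(is.finite(eta))) stop("non-finite linear predictor")
    rate <- cfg$baseline_hazard * exp(eta)

    t_lr <- rexp(n, cfg$event_mix[["lr"]] * rate)
    t_dm <- rexp(n, cfg$event_mix[["dm"]] * rate)
    t_death <- rexp(n, cfg$event_mix[["death"]] * rate)
    t_cens <- pmin(cfg$censor_time, runif(n, 0, cfg$dropout_max))

    obs <- function(t) ifelse(t <= t_cens, t, NA_real_)
    cohort <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      cohort = cfg$cohort,
      sex = sex, age = age, stage = stage, histology = histology,
      asp = asp, eppi = eppi,
      time_lr = obs(t_lr), time_dm = obs(t_dm), time_death = obs(t_death),
      time_last_fu = ifelse(is.na(obs(t_death)), t_cens, t_death)
    )
    for (ep in c("PFS", "OS", "LRC", "FFDM")) {
      rec <- derive_endpoint(cohort, ep)
      cohort[[paste0(tolower(ep), "_time")]] <- rec$time
      cohort[[paste0(tolower(ep), "_event")]] <- rec$event
    }

    counts <- NULL
    if (!is.null(cfg$expression)) {
      counts <- simulate_expression(cfg$expression, eppi, cohort$patient_id)
    }
    list(cohort = cohort, counts = counts)
  })
}

# negative-binomial counts; each signature gene's log2 mean shifts with the
# latent EPPI value, signed like its model coefficient, so the linear score
# is recoverable from the matrix
simulate_expression <- function(spec, eppi, sample_ids) {
  default_model <- is.null(spec$signature_genes)
  sig_genes <- spec$signature_genes %||% synthetic_eppi_model()$genes
  sig_sign <- spec$signature_sign %||%
    (if (default_model) sign(synthetic_eppi_model()$coefficients)
     else rep(1, length(sig_genes)))
  n_genes <- spec$n_genes %||% 200
  dispersion <- spec$dispersion %||% 0.2
  coupling <- spec$coupling %||% 0.4
  lib_sd <- spec$lib_sd %||% 0.3
  if (n_genes < length(sig_genes)) {
    stop("n_genes smaller than the signature gene count")
  }
  n_noise <- n_genes - length(sig_genes)
  genes <- c(sig_genes, sprintf("NOISE_G%03d", seq_len(n_noise)))
  n <- length(eppi)

  base_mean <- exp(runif(n_genes, log(20), log(2000)))
  libf <- exp(rnorm(n, 0, lib_sd))
  shift <- matrix(0, n_genes, n)
  shift[seq_along(sig_genes), ] <- outer(coupling * sig_sign,
                                         eppi - mean(eppi))
  mu <- (base_mean %o% libf) * 2^shift
  counts <- matrix(rnbinom(n_genes * n, mu = mu, size = 1 / dispersion),
                   n_genes, n, dimnames = list(genes, sample_ids))
  expr_matrix(counts, stage = "raw")
}

#' Synthetic EPPI model shipped with the package
#'
#' The published EPPI coefficients are an external input that this package
#' does not redistribute; for examples and simulation the package ships a
#' clearly synthetic 29-gene stand-in (gene symbols `EPPI_G01..EPPI_G29`
#' with fixed pseudo-random coefficients). It is never a reproduction of
#' the published model.
#'
#' @return An [eppi_model()].
#' @export
synthetic_eppi_model <- function() {
  read_eppi_model(system.file("extdata", "eppi_model_synthetic.csv",
                              package = "aspstrat"))
}

#' Write a simulated cohort to disk
#'
#' The cohort goes to CSV (one row per patient) and the counts, when
#' present, to TSV (genes x samples).
#'
#' @param sim result of [simulate_cohort()].
#' @param cohort_csv,counts_tsv output paths (`counts_tsv` ignored when no
#'   expression was simulated).
#' @return Invisibly, the cohort CSV path.
#' @export
write_cohort <- function(sim, cohort_csv, counts_tsv = NULL) {
  utils::write.csv(sim$cohort, cohort_csv, row.names = FALSE)
  if (!is.null(sim$counts) && !is.null(counts_tsv)) {
    write_counts_tsv(sim$counts, counts_tsv)
  }
  invisible(cohort_csv)
}
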