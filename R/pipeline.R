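#' Add binarized risk-group columns from a cutoff map
#'
#' For every marker in the cutoff map a `<marker>_group` factor column
#' (`"low"` / `"high"`) is added with the strict rule `marker > cutoff =
#' high`; values equal to the cutoff are low. Missing marker values give
#' `NA` groups. Cutoff provenance (fixed vs optimized) is recorded in the
#' `cutoff_provenance` attribute; optimized cutoffs are endpoint-specific
#' and must never be silently reused across endpoints.
#'
#' @param table cohort tibble.
#' @param cutoffs named numeric vector, e.g. `c(asp = 19.5, eppi = 8.72)`.
#' @param provenance character vector (recycled) labeling each cutoff,
#'   e.g. `"fixed"` or `"optimized:PFS"`.
#' @return The table with one group column per marker.
#' @export
binarize_covariates <- function(table, cutoffs, provenance = "fixed") {
  stopifnot(length(cutoffs) >= 1, !is.null(names(cutoffs)))
  provenance <- rep_len(provenance, length(cutoffs))
  for (i in seq_along(cutoffs)) {
    mk <- names(cutoffs)[i]
    if (!mk %in% names(table)) stop("missing marker column: ", mk)
    g <- ifelse(table[[mk]] > cutoffs[i], "high", "low")
    n_per <- table(factor(g, levels = c("low", "high")))
    if (any(n_per == 0)) {
      warning(sprintf("marker %s at cutoff %g: degenerate grouping (%s)",
                      mk, cutoffs[i],
                      paste(names(n_per), n_per, sep = "=", collapse = ", ")))
    }
    table[[paste0(mk, "_group")]] <- factor(g, levels = c("low", "high"))
  }
  attr(table, "cutoff_provenance") <-
    tibble::tibble(marker = names(cutoffs), cutoff = unname(cutoffs),
                   provenance = provenance)
  table
}

#' Combined ASP-by-signature risk strata
#'
#' Crosses (or nests) the binarized asphericity and EPPI groups and
#' evaluates the resulting strata with Kaplan-Meier tables and pairwise
#' log-rank tests. Patients without an EPPI value keep their ASP group,
#' get the combined label `"<asp>/NA"`, are excluded from any EPPI split,
#' and still count in ASP-only analyses — the usual situation when gene
#' expression is available only for a cohort subset.
#'
#' Modes:
#' * `four_group` — full 2x2 cross of ASP x EPPI groups;
#' * `nested_within_asp_low` — ASP-low patients split by EPPI;
#' * `nested_within_asp_high` — ASP-high patients split by EPPI;
#' * `nested_within_eppi_high` — EPPI-high patients split by ASP.
#'
#' @param table tibble with `asp_group`, `eppi_group`, time and event
#'   columns (see [binarize_covariates()]).
#' @param mode stratification mode.
#' @param time,event endpoint column names.
#' @return A list of class `asp_strata`: `assignment` (patient_id +
#'   labels), `sizes`, `km`, `logrank` (pairwise tests; empty-stratum
#'   comparisons are skipped with a message).
#' @export
combined_strata <- function(table,
                            mode = c("four_group", "nested_within_asp_low",
                                     "nested_within_asp_high",
                                     "nested_within_eppi_high"),
                            time = "time", event = "event") {
  mode <- match.arg(mode)
  stopifnot(all(c("asp_group", "eppi_group", time, event) %in% names(table)))
  asp_g <- as.character(table$asp_group)
  eppi_g <- as.character(table$eppi_group)
  eppi_lab <- ifelse(is.na(eppi_g), "NA", eppi_g)
  combined <- paste(asp_g, eppi_lab, sep = "/")

  lab <- switch(
    mode,
    four_group = ifelse(is.na(eppi_g), NA_character_, combined),
    nested_within_asp_low = ifelse(asp_g == "low" & !is.na(eppi_g),
                                   paste0("asp_low/eppi_", eppi_g), NA),
    nested_within_asp_high = ifelse(asp_g == "high" & !is.na(eppi_g),
                                    paste0("asp_high/eppi_", eppi_g), NA),
    nested_within_eppi_high = ifelse(!is.na(eppi_g) & eppi_g == "high",
                                     paste0("eppi_high/asp_", asp_g), NA)
  )

  assignment <- tibble::tibble(
    patient_id = table$patient_id,
    asp_group = asp_g, eppi_group = eppi_lab,
    combined_label = combined, stratum = lab
  )
  used <- !is.na(lab) & is.finite(table[[time]])
  rec <- tibble::tibble(time = table[[time]][used],
                        event = table[[event]][used],
                        group = lab[used])
  sizes <- dplyr::count(rec, .data$group, name = "n")
  km <- if (nrow(rec) > 0) km_estimate(rec) else tibble::tibble()

  groups <- sort(unique(rec$group))
  pairs <- if (length(groups) >= 2) utils::combn(groups, 2, simplify = FALSE) else list()
  lr <- purrr::map_dfr(pairs, function(pr) {
    sub <- rec[rec$group %in% pr, ]
    if (length(unique(sub$group)) < 2 || sum(sub$event) == 0) {
      message(sprintf("skipping log-rank %s vs %s (empty or event-free stratum)",
                      pr[1], pr[2]))
      return(tibble::tibble(group1 = pr[1], group2 = pr[2],
                            chisq = NA_real_, p = NA_real_))
    }
    t <- logrank(sub)
    tibble::tibble(group1 = pr[1], group2 = pr[2], chisq = t$chisq, p = t$p)
  })

  structure(list(mode = mode, assignment = assignment, sizes = sizes,
                 km = km, logrank = lr),
            class = "asp_strata")
}

#' @export
print.asp_strata <- function(x, ...) {
  cat(sprintf("<asp_strata> mode=%s\n", x$mode))
  print(x$sizes)
  invisible(x)
}

#' Univariate Cox table across covariates and endpoints
#'
#' One row per requested covariate per endpoint, with HR, 95% CI, Wald p
#' and the per-analysis n (complete cases; missing data are handled
#' complete-case per analysis, so n varies across rows). Covariate specs:
#' plain column names enter metric; entries of the form
#' `list(column =, cutoff =)` are binarized by strict `>` first, and
#' factor/character columns are coded by their non-reference level.
#'
#' @param cohort cohort tibble with `<endpoint>_time` / `<endpoint>_event`
#'   columns (lower-case endpoint names).
#' @param covariates list of covariate specs (see above).
#' @param endpoints endpoint names to analyze.
#' @return Tibble: `endpoint`, `covariate`, `coding`, `n`, `n_events`,
#'   `hr`, `ci_low`, `ci_high`, `p`, `separation`.
#' @export
univariate_table <- function(cohort, covariates,
                             endpoints = c("PFS", "OS", "LRC", "FFDM")) {
  purrr::map_dfr(endpoints, function(ep) {
    tcol <- paste0(tolower(ep), "_time")
    ecol <- paste0(tolower(ep), "_event")
    stopifnot(all(c(tcol, ecol) %in% names(cohort)))
    purrr::map_dfr(covariates, function(cv) {
      prep <- prepare_covariate(cohort, cv)
      dat <- tibble::tibble(x = prep$x, time = cohort[[tcol]],
                            event = cohort[[ecol]])
      dat <- dat[stats::complete.cases(dat), ]
      fail <- function(msg) tibble::tibble(
        endpoint = ep, covariate = prep$label, coding = prep$coding,
        n = nrow(dat), n_events = sum(dat$event), hr = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
        separation = NA, note = msg
      )
      if (nrow(dat) < 3 || sum(dat$event) < 2 || sd(dat$x) == 0) {
        return(fail("insufficient data"))
      }
      fit <- tryCatch(cox_fit(dat, "x"), error = function(e) NULL)
      if (is.null(fit)) return(fail("fit failed"))
      tibble::tibble(
        endpoint = ep, covariate = prep$label, coding = prep$coding,
        n = fit$n, n_events = fit$n_events,
        hr = fit$terms$hr[1], ci_low = fit$terms$ci_low[1],
        ci_high = fit$terms$ci_high[1], p = fit$terms$p[1],
        separation = fit$separation, note = NA_character_
      )
    })
  })
}

# covariate spec -> numeric vector + label + coding tag
prepare_covariate <- function(cohort, cv) {
  if (is.list(cv)) {
    col <- cv$column
    stopifnot(col %in% names(cohort))
    x <- as.numeric(cohort[[col]] > cv$cutoff)
    list(x = x, label = sprintf("%s > %g", col, cv$cutoff),
         coding = "binarized")
  } else {
    stopifnot(cv %in% names(cohort))
    v <- cohort[[cv]]
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) != 2) {
        stop(sprintf("covariate %s has %d levels; binarize explicitly",
                     cv, length(lev)))
      }
      list(x = as.numeric(v == lev[2]),
           label = sprintf("%s = %s", cv, lev[2]), coding = "binarized")
    } else {
      list(x = as.numeric(v), label = cv, coding = "metric")
    }
  }
}

#' Multivariate Cox table for a named covariate preset
#'
#' @param cohort cohort tibble (see [univariate_table()]).
#' @param covariates list of covariate specs entering jointly.
#' @param endpoint endpoint name.
#' @param preset label stored with the rows.
#' @return Tibble with one row per model term.
#' @export
multivariate_table <- function(cohort, covariates, endpoint = "PFS",
                               preset = "custom") {
  tcol <- paste0(tolower(endpoint), "_time")
  ecol <- paste0(tolower(endpoint), "_event")
  preps <- lapply(covariates, prepare_covariate, cohort = cohort)
  dat <- tibble::as_tibble(setNames(
    lapply(preps, `[[`, "x"),
    vapply(preps, `[[`, "", "label")
  ))
  dat$time <- cohort[[tcol]]
  dat$event <- cohort[[ecol]]
  dat <- dat[stats::complete.cases(dat), ]
  fit <- cox_fit(dat, setdiff(names(dat), c("time", "event")))
  dplyr::mutate(fit$terms, endpoint = endpoint, preset = preset,
                n = fit$n, n_events = fit$n_events,
                separation = fit$separation, .before = 1)
}

#' Run the full asphericity-signature analysis from one config
#'
#' Orchestrates: cohort acquisition (simulation via [simulate_cohort()] or
#' a user-supplied table), expression scoring (EPPI plus any signature
#' list), univariate Cox tables per endpoint (metric and binarized),
#' multivariate presets, per-endpoint optimal cutpoints, fixed-cutoff
#' asphericity validation, the signature-vs-ASP correlation screen,
#' stage-II subset reruns and combined ASP-by-EPPI stratification. Every
#' output carries its n; a manifest records config hash and seed so a
#' rerun with the same config is byte-identical.
#'
#' @param config list (or path to a YAML file) with entries:
#'   * `synth`: arguments for [cohort_config()] (or a ready-made config) —
#'     mutually exclusive with `cohort`;
#'   * `cohort`: tibble or CSV path of an existing cohort table;
#'   * `counts`: optional [expr_matrix()] or TSV path;
#'   * `eppi_model`: optional [eppi_model()] or CSV path (defaults to the
#'     packaged synthetic model when counts are present);
#'   * `signatures`: optional list of [signature_def()] or GMT path;
#'   * `endpoints`: endpoints to analyze (default all four);
#'   * `asp_cutoff`: fixed validation cutoff (default 19.5);
#'   * `eppi_cutoff`: fixed EPPI cutoff (default the cohort median);
#'   * `stage_subset`: stage label to re-run on (default `"II"`, `NULL`
#'     to skip);
#'   * `cutpoint_markers`: markers scanned per endpoint (default `"asp"`).
#' @param out_dir optional directory; when given, every table is written
#'   as CSV plus a `manifest.json`.
#' @return A list of class `asp_report` with the tables described above
#'   and a `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  endpoints <- config$endpoints %||% c("PFS", "OS", "LRC", "FFDM")
  asp_cutoff <- config$asp_cutoff %||% 19.5

  failures <- character()
  step <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", label, conditionMessage(e)))
      NULL
    })
  }

  # --- cohort -------------------------------------------------------------
  counts <- NULL
  if (!is.null(config$synth)) {
    cfg <- if (inherits(config$synth, "cohort_config")) config$synth
    else do.call(cohort_config, config$synth)
    sim <- simulate_cohort(cfg)
    cohort <- sim$cohort
    counts <- sim$counts
    seed_used <- cfg$seed
  } else if (!is.null(config$cohort)) {
    cohort <- if (is.character(config$cohort)) {
      tibble::as_tibble(utils::read.csv(config$cohort))
    } else tibble::as_tibble(config$cohort)
    seed_used <- NA_integer_
  } else {
    stop("config needs either `synth` or `cohort`")
  }
  if (!is.null(config$counts)) {
    counts <- if (is.character(config$counts)) read_counts_tsv(config$counts)
    else config$counts
  }

  # --- expression scoring ---------------------------------------------------
  screen <- NULL
  if (!is.null(counts)) {
    model <- config$eppi_model %||% synthetic_eppi_model()
    if (is.character(model)) model <- read_eppi_model(model)
    norm <- normalize_counts(filter_genes(counts))
    esc <- step("eppi_score", eppi_score(norm, model))
    if (!is.null(esc)) {
      cohort$eppi <- esc$eppi[match(cohort$patient_id, esc$sample_id)]
    }
    sigs <- config$signatures
    if (is.character(sigs)) sigs <- read_gmt(sigs)
    if (!is.null(sigs)) {
      scores <- step("score_signatures", score_signatures(norm, sigs))
      if (!is.null(scores)) {
        feats <- dplyr::select(cohort, sample_id = "patient_id",
                               "asp", "cohort")
        screen <- step("correlation_screen",
                       correlation_screen(scores, feats))
      }
    }
  }

  # --- survival tables ------------------------------------------------------
  has_eppi <- "eppi" %in% names(cohort) && any(is.finite(cohort$eppi))
  eppi_cutoff <- config$eppi_cutoff %||%
    (if (has_eppi) median(cohort$eppi, na.rm = TRUE) else NA)

  covs_uni <- list(
    "sex", "histology",
    list(column = "age", cutoff = 70),
    list(column = "stage_advanced", cutoff = 0.5),
    "asp", "mtv_ml", "tlg", "suv_max"
  )
  cohort$stage_advanced <- as.numeric(cohort$stage == "III")
  covs_uni <- covs_uni[vapply(covs_uni, function(cv) {
    col <- if (is.list(cv)) cv$column else cv
    col %in% names(cohort)
  }, TRUE)]
  if (has_eppi) {
    covs_uni <- c(covs_uni, "eppi",
                  list(list(column = "eppi", cutoff = eppi_cutoff)))
  }
  covs_uni <- c(covs_uni, list(list(column = "asp", cutoff = asp_cutoff)))

  univariate <- step("univariate", univariate_table(cohort, covs_uni, endpoints))

  presets <- list(stage_histology_asp = list(
    list(column = "stage_advanced", cutoff = 0.5), "histology", "asp"))
  if (has_eppi) {
    presets$stage_histology_eppi_asp <- list(
      list(column = "stage_advanced", cutoff = 0.5), "histology",
      "eppi", "asp")
  }
  multivariate <- purrr::imap_dfr(presets, function(cv, nm) {
    out <- step(paste0("multivariate:", nm),
                multivariate_table(cohort, cv, endpoint = endpoints[1],
                                   preset = nm))
    if (is.null(out)) tibble::tibble() else out
  })

  cutpoint_markers <- config$cutpoint_markers %||% "asp"
  cutpoints <- purrr::map_dfr(endpoints, function(ep) {
    purrr::map_dfr(cutpoint_markers, function(mk) {
      cp <- step(sprintf("cutpoint:%s:%s", mk, ep), {
        dat <- tibble::tibble(marker = cohort[[mk]],
                              time = cohort[[paste0(tolower(ep), "_time")]],
                              event = cohort[[paste0(tolower(ep), "_event")]])
        optimal_cutpoint(dat, "marker")
      })
      if (is.null(cp)) return(tibble::tibble())
      dplyr::mutate(tidy(cp), marker = mk, endpoint = ep, .before = 1,
                    .keep = "unused")
    })
  })

  fixed <- step("fixed_cutoff_asp", {
    dat <- tibble::tibble(asp = cohort$asp, time = cohort$pfs_time,
                          event = cohort$pfs_event)
    validate_fixed_cutoff(dat, "asp", asp_cutoff)
  })

  # --- stage-II subset ------------------------------------------------------
  stage_subset <- if (is.null(config$stage_subset)) "II" else config$stage_subset
  stage2 <- NULL
  if (!is.na(stage_subset) && nzchar(stage_subset)) {
    sub <- cohort[cohort$stage == stage_subset, ]
    if (nrow(sub) == 0) {
      message(sprintf("no stage-%s patients; skipping subset analysis",
                      stage_subset))
    } else {
      stage2 <- step("stage_subset",
                     univariate_table(sub, covs_uni, endpoints[1]))
    }
  }

  # --- combined stratification ---------------------------------------------
  strata <- NULL
  if (has_eppi) {
    bt <- binarize_covariates(cohort,
                              c(asp = asp_cutoff, eppi = eppi_cutoff),
                              provenance = c("fixed", "fixed"))
    bt$time <- bt$pfs_time
    bt$event <- bt$pfs_event
    strata <- step("combined_strata", combined_strata(bt, "four_group"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("aspstrat")),
    seed = seed_used,
    n_patients = nrow(cohort),
    endpoints = endpoints,
    asp_cutoff = asp_cutoff,
    eppi_cutoff = if (has_eppi) eppi_cutoff else NA,
    config_hash = digest_config(config),
    failures = failures
  )

  report <- structure(
    list(cohort = cohort, univariate = univariate,
         multivariate = multivariate, cutpoints = cutpoints,
         fixed_cutoff = fixed, stage_subset = stage2, screen = screen,
         strata = strata, manifest = manifest),
    class = "asp_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# stable hash of the config (sorted-key JSON, so list order is irrelevant)
digest_config <- function(config) {
  ser <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  sum(utils::head(utf8ToInt(ser) * seq_len(nchar(ser)), 1e6)) %% 1e9
}

#' @export
print.asp_report <- function(x, ...) {
  cat(sprintf("<asp_report> %d patients, endpoints: %s\n",
              nrow(x$cohort), paste(x$manifest$endpoints, collapse = ", ")))
  if (length(x$manifest$failures)) {
    cat("failed stages:\n")
    for (f in x$manifest$failures) cat("  -", f, "\n")
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tbl, name) {
    if (!is.null(tbl) && nrow(tbl) > 0) {
      utils::write.csv(tbl, file.path(out_dir, name), row.names = FALSE)
    }
  }
  wr(report$univariate, "univariate.csv")
  wr(report$multivariate, "multivariate.csv")
  wr(report$cutpoints, "cutpoints.csv")
  wr(report$stage_subset, "stage_subset_univariate.csv")
  wr(report$screen, "screen.csv")
  if (!is.null(report$strata)) {
    wr(report$strata$km, "km_four_group.csv")
    wr(report$strata$logrank, "logrank_four_group.csv")
  }
  if (!is.null(report$fixed_cutoff)) {
    wr(report$fixed_cutoff$km, "km_fixed_asp.csv")
    wr(tidy(report$fixed_cutoff$cox), "fixed_asp_cox.csv")
  }
  jsonlite::write_json(report$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
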