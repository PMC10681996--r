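#' Gene expression count container
#'
#' A genes-by-samples matrix with a processing-stage tag. The stage moves
#' `raw -> filtered -> normalized` through [filter_genes()] and
#' [normalize_counts()]; downstream scoring functions require normalized
#' values.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param stage processing stage of the values.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, stage = c("raw", "filtered", "normalized")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(values < 0)) stop("negative expression values")
  structure(list(values = values, stage = stage), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, stage=%s\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read / write a genes-by-samples count matrix as TSV
#'
#' Plain TSV with a header row of sample ids and gene symbols in the first
#' column.
#'
#' @param path file path.
#' @param m an [expr_matrix()].
#' @return `read_counts_tsv()` returns a raw-stage `expr_matrix`.
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  expr_matrix(as.matrix(tab), stage = "raw")
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene = rownames(m$values), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter genes with insufficient counts
#'
#' Keeps genes whose total count across the whole data set exceeds 1
#' (i.e. row sum of at least 2). This mirrors the common pre-normalization
#' screen that discards all-zero and singleton genes.
#'
#' @param m raw-stage [expr_matrix()].
#' @return A filtered-stage `expr_matrix`.
#' @export
filter_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$stage != "raw") stop("filter_genes() expects a raw-stage matrix")
  keep <- rowSums(m$values) > 1
  if (!any(keep)) stop("no gene passes the total-count > 1 filter")
  removed <- sum(!keep)
  if (removed > 0) {
    message(sprintf("filter_genes: removed %d of %d genes (total count <= 1)",
                    removed, length(keep)))
  }
  expr_matrix(m$values[keep, , drop = FALSE], stage = "filtered")
}

#' Median-of-ratios size factors
#'
#' Per-gene geometric means are computed over the genes with all-positive
#' counts; each sample's size factor is the median, over those genes, of the
#' count-to-geometric-mean ratio. Factors are rescaled to geometric mean 1,
#' so normalized values stay on the raw count scale.
#'
#' @param m filtered-stage [expr_matrix()].
#' @param pseudocount value added to all counts before computing factors
#'   (0 = off). Use a positive value when no gene has all-positive counts.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(m, pseudocount = 0) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$stage != "filtered") stop("size_factors() expects a filtered-stage matrix")
  v <- m$values + pseudocount
  if (ncol(v) == 1L) {
    return(setNames(1, colnames(v)))
  }
  allpos <- rowSums(v > 0) == ncol(v)
  if (!any(allpos)) {
    stop("no gene has all-positive counts; re-run with a pseudocount, ",
         "e.g. size_factors(m, pseudocount = 0.5)")
  }
  lv <- log(v[allpos, , drop = FALSE])
  ref <- rowMeans(lv)                     # log geometric means
  sf <- apply(lv - ref, 2, function(x) exp(median(x)))
  sf <- sf / exp(mean(log(sf)))           # geometric mean 1
  setNames(sf, colnames(v))
}

#' Normalize counts by size factors
#'
#' @param m filtered-stage [expr_matrix()].
#' @param factors positive size factors, one per sample (see
#'   [size_factors()]).
#' @return A normalized-stage `expr_matrix`.
#' @export
normalize_counts <- function(m, factors = size_factors(m)) {
  stopifnot(inherits(m, "expr_matrix"))
  if (length(factors) != ncol(m$values)) {
    stop(sprintf("%d size factors for %d samples", length(factors),
                 ncol(m$values)))
  }
  if (any(factors <= 0)) stop("size factors must be positive")
  expr_matrix(sweep(m$values, 2, factors, "/"), stage = "normalized")
}

#' Gene signature definition
#'
#' @param name signature name.
#' @param genes character vector of gene symbols (nonempty, unique).
#' @param description optional free-text description.
#' @return An object of class `signature_def`.
#' @export
signature_def <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("signature needs at least one gene")
  if (anyDuplicated(genes)) stop("duplicate genes in signature ", name)
  structure(list(name = name, genes = genes, description = description),
            class = "signature_def")
}

#' Read / write signatures in GMT format
#'
#' One signature per line: name, description, then tab-separated gene
#' symbols.
#'
#' @param path file path.
#' @param sigs list of [signature_def()] objects.
#' @return `read_gmt()` returns a named list of `signature_def`s.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    signature_def(parts[1], parts[-(1:2)], description = parts[2])
  })
  setNames(sigs, vapply(sigs, `[[`, "", "name"))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sigs, path) {
  lines <- vapply(sigs, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Score samples against a gene signature
#'
#' The per-sample score is the mean, over the signature's genes present in
#' the matrix, of the per-gene z-scores of log2(normalized + 1) expression.
#' Genes with zero variance across samples contribute a z-score of 0.
#' Missing signature genes are reported with a warning; if no signature
#' gene is present the call errors, listing the missing symbols.
#'
#' @param m normalized-stage [expr_matrix()].
#' @param sig a [signature_def()].
#' @return A tibble with columns `sample_id`, `signature`, `score`.
#' @export
signature_score <- function(m, sig) {
  stopifnot(inherits(m, "expr_matrix"), inherits(sig, "signature_def"))
  if (m$stage != "normalized") {
    stop("signature_score() expects a normalized-stage matrix")
  }
  present <- intersect(sig$genes, rownames(m$values))
  missing <- setdiff(sig$genes, rownames(m$values))
  if (length(present) == 0) {
    stop("no signature gene present in the matrix; missing: ",
         paste(missing, collapse = ", "))
  }
  if (length(missing) > 0) {
    warning(sprintf("signature %s: %d/%d genes missing (%s)", sig$name,
                    length(missing), length(sig$genes),
                    paste(utils::head(missing, 5), collapse = ", ")))
  }
  lx <- log2(m$values[present, , drop = FALSE] + 1)
  z <- t(apply(lx, 1, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  tibble::tibble(
    sample_id = colnames(m$values),
    signature = sig$name,
    score = unname(colMeans(z))
  )
}

#' Score samples against several signatures at once
#'
#' @param m normalized-stage [expr_matrix()].
#' @param sigs list of [signature_def()] objects.
#' @return A long tibble (`sample_id`, `signature`, `score`).
#' @export
score_signatures <- function(m, sigs) {
  purrr::map_dfr(sigs, function(s) signature_score(m, s))
}

#' EPPI linear risk model
#'
#' The extracellular-matrix-related prognostic and predictive indicator
#' (EPPI) is a published 29-gene linear risk score: a weighted sum of
#' transformed per-gene expression. The published coefficients are an
#' external input; the model object carries the gene-to-coefficient map,
#' the expression transform the coefficients expect, and an intercept.
#'
#' @param genes character vector of gene symbols.
#' @param coefficients numeric coefficients, one per gene.
#' @param transform `"log2p1"` for log2(normalized + 1), `"identity"` for
#'   the raw normalized value.
#' @param intercept additive constant (default 0).
#' @param n_genes_expected expected number of genes (default 29, the
#'   published signature size); set to `NA` to skip the check.
#' @return An object of class `eppi_model`.
#' @export
eppi_model <- function(genes, coefficients,
                       transform = c("log2p1", "identity"), intercept = 0,
                       n_genes_expected = 29) {
  transform <- match.arg(transform)
  stopifnot(length(genes) == length(coefficients),
            all(is.finite(coefficients)))
  if (anyDuplicated(genes)) stop("duplicate genes in EPPI model")
  if (!is.na(n_genes_expected) && length(genes) != n_genes_expected) {
    stop(sprintf("EPPI model has %d genes, expected %d", length(genes),
                 n_genes_expected))
  }
  structure(list(genes = as.character(genes),
                 coefficients = as.numeric(coefficients),
                 transform = transform, intercept = intercept),
            class = "eppi_model")
}

#' Read an EPPI coefficient file
#'
#' Plain CSV with columns `gene,coefficient`; lines starting with `#` at
#' the top of the file are parsed as a YAML header and may set `transform`
#' and `intercept`.
#'
#' @param path CSV file path.
#' @param n_genes_expected see [eppi_model()].
#' @return An [eppi_model()].
#' @export
read_eppi_model <- function(path, n_genes_expected = 29) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  if (any(hdr)) {
    meta <- yaml::yaml.load(paste(sub("^#\\s?", "", lines[hdr]),
                                  collapse = "\n"))
    if (is.null(meta)) meta <- list()
  }
  tab <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"))
  eppi_model(tab$gene, tab$coefficient,
             transform = meta$transform %||% "log2p1",
             intercept = meta$intercept %||% 0,
             n_genes_expected = n_genes_expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute the EPPI risk score per sample
#'
#' score = intercept + sum over model genes of coefficient x transformed
#' expression. Strict by default: all model genes must be present; relax
#' with `min_fraction` to score on a warned subset.
#'
#' @param m normalized-stage [expr_matrix()].
#' @param model an [eppi_model()].
#' @param min_fraction minimum fraction of model genes that must be present
#'   (1 = strict).
#' @return A tibble with columns `sample_id`, `eppi`.
#' @export
eppi_score <- function(m, model, min_fraction = 1) {
  stopifnot(inherits(m, "expr_matrix"), inherits(model, "eppi_model"))
  if (m$stage != "normalized") stop("eppi_score() expects a normalized-stage matrix")
  present <- model$genes %in% rownames(m$values)
  if (mean(present) < min_fraction) {
    stop("EPPI genes missing from the matrix: ",
         paste(model$genes[!present], collapse = ", "))
  }
  if (any(!present)) {
    warning(sprintf("eppi_score: %d/%d model genes missing; scoring on the rest",
                    sum(!present), length(present)))
  }
  x <- m$values[model$genes[present], , drop = FALSE]
  tx <- switch(model$transform, log2p1 = log2(x + 1), identity = x)
  score <- model$intercept + drop(crossprod(tx, model$coefficients[present]))
  tibble::tibble(sample_id = colnames(m$values), eppi = as.numeric(score))
}

#' Per-cohort signature-vs-asphericity correlation screen
#'
#' For every signature and cohort, the rank correlation between signature
#' score and tumor asphericity is computed. A signature is flagged
#' `reproducible` when the correlation has the same sign in every cohort
#' and is nominally significant (p < 0.05) in each. Cohorts where either
#' variable is constant yield an undefined correlation (reported `NA`) and
#' an unreproducible flag.
#'
#' @param scores long tibble with `sample_id`, `signature`, `score`
#'   (see [score_signatures()]).
#' @param features tibble with `sample_id`, `asp`, `cohort`.
#' @param method correlation method (default Spearman).
#' @return A tibble with one row per signature x cohort (`signature`,
#'   `cohort`, `n`, `rho`, `p`) plus a per-signature `reproducible` flag.
#' @export
correlation_screen <- function(scores, features,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  dat <- dplyr::inner_join(scores, features, by = "sample_id")
  dat <- dplyr::filter(dat, is.finite(.data$score), is.finite(.data$asp))
  by_cohort <- dat |>
    dplyr::group_by(.data$signature, .data$cohort) |>
    dplyr::summarise(
      n = dplyr::n(),
      rho = if (dplyr::n() < 3 || sd(.data$score) == 0 || sd(.data$asp) == 0) {
        NA_real_
      } else {
        suppressWarnings(cor.test(.data$score, .data$asp,
                                  method = method)$estimate[[1]])
      },
      p = if (dplyr::n() < 3 || sd(.data$score) == 0 || sd(.data$asp) == 0) {
        NA_real_
      } else {
        suppressWarnings(cor.test(.data$score, .data$asp, method = method)$p.value)
      },
      .groups = "drop_last"
    )
  flags <- by_cohort |>
    dplyr::summarise(
      reproducible = !any(is.na(.data$rho)) &&
        length(unique(sign(.data$rho))) == 1 &&
        all(.data$rho != 0) && all(.data$p < 0.05),
      .groups = "drop"
    )
  dplyr::left_join(dplyr::ungroup(by_cohort), flags, by = "signature")
}
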