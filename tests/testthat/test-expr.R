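mk_counts <- function(m, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("G%02d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expr_matrix(m, stage = "raw")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gene filter keeps exactly rows with total count > 1", {
  m <- mk_counts(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 0, 0),
                       c(5, 3, 1)))
  expect_message(f <- filter_genes(m), "removed 2")
  expect_identical(rownames(f$values), c("G03", "G04", "G05"))
  expect_identical(f$stage, "filtered")

  all_pass <- mk_counts(matrix(2, 3, 3))
  f2 <- suppressMessages(filter_genes(all_pass))
  expect_identical(f2$values, all_pass$values)

  expect_error(suppressMessages(filter_genes(mk_counts(matrix(0, 2, 2)))),
               "no gene")
})

test_that("median-of-ratios size factors recover column scalings exactly", {
  base <- c(10, 20, 40, 100, 7, 13)
  m <- mk_counts(matrix(c(base, 2 * base, 4 * base), ncol = 3))
  f <- filter_genes(m)
  sf <- size_factors(f)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  expect_equal(unname(sf[3] / sf[1]), 4, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  # identical samples are symmetric
  m2 <- suppressMessages(filter_genes(mk_counts(matrix(c(5, 9, 3), 3, 4))))
  expect_equal(unname(size_factors(m2)), rep(1, 4))

  # single sample follows the rescaling convention
  m3 <- suppressMessages(filter_genes(mk_counts(matrix(c(5, 9, 3), 3, 1))))
  expect_equal(unname(size_factors(m3)), 1)
})

test_that("size factors are scale-equivariant per sample", {
  withr::with_seed(8, {
    m <- mk_counts(matrix(rnbinom(120, mu = 50, size = 5) + 1, 20, 6))
  })
  f <- suppressMessages(filter_genes(m))
  sf <- size_factors(f)
  v2 <- f$values; v2[, 3] <- v2[, 3] * 5
  f2 <- expr_matrix(v2, stage = "raw")
  f2 <- suppressMessages(filter_genes(f2))
  sf2 <- size_factors(f2)
  # ratios to sample 1 preserved except sample 3 multiplied by 5
  expect_equal(unname(sf2[3] / sf2[1]), unname(5 * sf[3] / sf[1]),
               tolerance = 1e-12)
})

test_that("size factors match the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(21, {
    m <- mk_counts(matrix(rnbinom(300, mu = 80, size = 3), 30, 10) +
                     rbinom(300, 1, 0.5))
  })
  f <- suppressMessages(filter_genes(m))
  ours <- size_factors(f)
  ref <- DESeq2::estimateSizeFactorsForMatrix(f$values)
  ref <- ref / exp(mean(log(ref)))  # same geometric-mean-1 convention
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("normalization divides columns and flags mismatches", {
  base <- c(4, 10, 30)
  m <- suppressMessages(filter_genes(mk_counts(
    matrix(c(base, 2 * base, 4 * base), ncol = 3))))
  norm <- normalize_counts(m)
  expect_identical(norm$stage, "normalized")
  # proportional columns become identical
  expect_equal(norm$values[, 1], norm$values[, 2], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(norm$values[, 1], norm$values[, 3], tolerance = 1e-12,
               ignore_attr = TRUE)

  ident <- normalize_counts(m, factors = rep(1, 3))
  expect_identical(ident$values, m$values)

  # zero counts stay exactly zero after scaling
  mz <- suppressMessages(filter_genes(mk_counts(
    rbind(c(0, 0, 3), c(5, 5, 5), c(2, 4, 8)))))
  expect_true(all(normalize_counts(mz)$values["G01", 1:2] == 0))

  expect_error(normalize_counts(m, factors = c(1, 2)), "factors")
  expect_error(size_factors(suppressMessages(filter_genes(mk_counts(
    rbind(c(2, 0), c(0, 2)))))), "pseudocount")
})

test_that("signature scores are mean z-scores with a zero-variance rule", {
  # identical samples: zero variance everywhere -> all scores 0
  m <- expr_matrix(matrix(7, 4, 3, dimnames = list(paste0("G", 1:4),
                                                   paste0("S", 1:3))),
                   stage = "normalized")
  sig <- signature_def("SIG", c("G1", "G2"))
  sc <- signature_score(m, sig)
  expect_equal(sc$score, c(0, 0, 0))

  # one gene, two samples: symmetric z-scores +-1/sqrt(2)
  m2 <- expr_matrix(matrix(c(1, 3), 1, 2,
                           dimnames = list("G1", c("A", "B"))),
                    stage = "normalized")
  sc2 <- signature_score(m2, signature_def("S1", "G1"))
  expect_equal(sc2$score, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # k perfectly correlated genes equal a single gene's z-score
  v <- c(2, 5, 11, 3)
  vals3 <- rbind(G1 = v, G2 = 2 * v + 1, G3 = 10 * v)
  colnames(vals3) <- paste0("S", 1:4)
  m3 <- expr_matrix(vals3, stage = "normalized")
  one <- signature_score(m3, signature_def("one", "G1"))$score
  all3 <- signature_score(m3, signature_def("all", c("G1", "G2", "G3")))$score
  z1 <- {
    lx <- log2(v + 1); (lx - mean(lx)) / sd(lx)
  }
  expect_equal(one, z1, tolerance = 1e-12)
  # log2 is nonlinear, so positive affine transforms give near- (not
  # exactly) identical z-scores; averaging them stays tightly aligned
  expect_gt(cor(all3, one), 0.99)

  expect_error(signature_score(m3, signature_def("none", c("X1", "X2"))),
               "X1")
  expect_warning(signature_score(m3, signature_def("part", c("G1", "X9"))),
                 "missing")
})

test_that("EPPI scoring is linear and permutation-equivariant", {
  withr::with_seed(3, {
    vals <- matrix(rexp(29 * 6, 0.02), 29, 6,
                   dimnames = list(sprintf("EPPI_G%02d", 1:29),
                                   sprintf("S%d", 1:6)))
  })
  m <- expr_matrix(vals, stage = "normalized")
  model <- synthetic_eppi_model()
  expect_length(model$genes, 29)
  sc <- eppi_score(m, model)

  # all-zero coefficients give the intercept
  zero <- eppi_model(model$genes, rep(0, 29), intercept = 1.5)
  expect_equal(eppi_score(m, zero)$eppi, rep(1.5, 6))

  # single gene, coefficient 2, transformed expression 3 -> 6
  m1 <- expr_matrix(matrix(7, 1, 2, dimnames = list("EPPI_G01",
                                                    c("A", "B"))),
                    stage = "normalized")
  single <- eppi_model("EPPI_G01", 2, n_genes_expected = NA)
  expect_equal(eppi_score(m1, single)$eppi, c(6, 6))  # log2(7+1) = 3

  # doubling one coefficient adds exactly coef * transform(expr)
  mod2 <- model
  mod2$coefficients[4] <- 2 * model$coefficients[4]
  delta <- eppi_score(m, mod2)$eppi - sc$eppi
  expect_equal(delta,
               model$coefficients[4] * log2(vals[model$genes[4], ] + 1),
               tolerance = 1e-12, ignore_attr = TRUE)

  # permuting samples permutes scores identically
  perm <- c(4, 1, 6, 2, 5, 3)
  mp <- expr_matrix(vals[, perm], stage = "normalized")
  expect_equal(eppi_score(mp, model)$eppi, sc$eppi[perm])

  # strict mode errors on missing genes, naming them
  m_miss <- expr_matrix(vals[-2, , drop = FALSE], stage = "normalized")
  expect_error(eppi_score(m_miss, model), "EPPI_G02")
  expect_warning(sc_part <- eppi_score(m_miss, model, min_fraction = 0.9),
                 "missing")
  expect_equal(nrow(sc_part), 6)
})

test_that("EPPI model files round-trip with their YAML header", {
  model <- synthetic_eppi_model()
  expect_identical(model$transform, "log2p1")
  expect_identical(model$intercept, 0)
  f <- tempfile(fileext = ".csv")
  writeLines(c("# transform: identity", "# intercept: 2.5",
               "gene,coefficient", "A,1", "B,-0.5"), f)
  m2 <- read_eppi_model(f, n_genes_expected = NA)
  expect_identical(m2$transform, "identity")
  expect_equal(m2$intercept, 2.5)
  expect_equal(m2$coefficients, c(1, -0.5))
  unlink(f)
})

test_that("GMT signatures round-trip", {
  sigs <- list(signature_def("A", c("G1", "G2"), "set a"),
               signature_def("B", c("G3", "G4", "G5"), "set b"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sigs, f)
  back <- read_gmt(f)
  expect_identical(names(back), c("A", "B"))
  expect_identical(back$B$genes, c("G3", "G4", "G5"))
  unlink(f)
  packaged <- read_gmt(system.file("extdata", "signatures_synthetic.gmt",
                                   package = "aspstrat"))
  expect_length(packaged$EPPI_SET$genes, 29)
})

test_that("correlation screen flags reproducible monotone associations", {
  feats <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:20),
    asp = c(seq(5, 23, by = 2), seq(6, 24, by = 2)),
    cohort = rep(c("c1", "c2"), each = 10)
  )
  perfect <- tibble::tibble(sample_id = feats$sample_id,
                            signature = "NEG", score = -feats$asp)
  scr <- correlation_screen(perfect, feats)
  expect_equal(scr$rho, c(-1, -1))
  expect_true(all(scr$reproducible))

  # opposite signs across cohorts are not reproducible
  flip <- perfect
  flip$score[feats$cohort == "c2"] <- feats$asp[feats$cohort == "c2"]
  scr2 <- correlation_screen(flip, feats)
  expect_false(any(scr2$reproducible))

  # constant score: rho undefined, flag false
  const <- tibble::tibble(sample_id = feats$sample_id,
                          signature = "CONST", score = 1)
  scr3 <- correlation_screen(const, feats)
  expect_true(all(is.na(scr3$rho)))
  expect_false(any(scr3$reproducible))
})

test_that("the screen's null flag rate stays at or below 1%", {
  n_rep <- 300
  flags <- withr::with_seed(17, {
    vapply(seq_len(n_rep), function(i) {
      feats <- tibble::tibble(sample_id = sprintf("S%02d", 1:40),
                              asp = rgamma(40, 4, 0.2),
                              cohort = rep(c("c1", "c2"), each = 20))
      scores <- tibble::tibble(sample_id = feats$sample_id,
                               signature = "NULLSIG", score = rnorm(40))
      any(correlation_screen(scores, feats)$reproducible)
    }, TRUE)
  })
  expect_lte(mean(flags), 0.01)
})
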