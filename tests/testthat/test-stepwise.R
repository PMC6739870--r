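mock_bias_tab <- function() {
  read.delim(system.file("extdata", "vaginal_mock_bias.tsv",
                         package = "mgsbias"), check.names = FALSE)
}

mock_genomics <- function() {
  read.delim(system.file("extdata", "vaginal_mock_genomics.tsv",
                         package = "mgsbias"))
}

test_that("step decomposition reproduces the printed per-step columns", {
  tb <- mock_bias_tab()
  ests <- list(cells = setNames(tb$cells, tb$taxon),
               dna = setNames(tb$dna, tb$taxon),
               pcr_product = setNames(tb$pcr_product, tb$taxon))
  steps <- decompose_steps(ests, step_names = c("extraction", "pcr",
                                                "seq_inf"))
  # extraction = cells/dna, e.g. ~4.7/2.3 ~ 2.0 for L. iners (printed inputs
  # are rounded)
  expect_equal(unname(steps$extraction["Lactobacillus iners"]), 2.0,
               tolerance = 0.05)
  expect_equal(unname(steps$pcr["Lactobacillus iners"]), 1.9,
               tolerance = 0.05)
  printed_pcr <- gstandardize(setNames(tb$pcr, tb$taxon))
  expect_lt(max(abs(log(steps$pcr / printed_pcr))), log(1.12))
  # product of the steps recovers the total (cells) bias
  expect_true(comp_equal(compose_steps(steps),
                         gstandardize(ests$cells), tol = 1e-9))
})

test_that("step decomposition: identity and synthetic round trips", {
  b <- c(a = 2, b = 1, c = 0.5)
  steps <- decompose_steps(list(cells = b, dna = b))
  expect_true(comp_equal(steps[[1]], rep(1, 3)))
  set.seed(51)
  for (i in 1:10) {
    s1 <- gstandardize(exp(rnorm(5))); s2 <- gstandardize(exp(rnorm(5)))
    s3 <- gstandardize(exp(rnorm(5)))
    names(s1) <- names(s2) <- names(s3) <- letters[1:5]
    cum <- list(e1 = perturb(perturb(s1, s2), s3),
                e2 = perturb(s2, s3),
                e3 = s3)
    got <- decompose_steps(cum)
    expect_true(comp_equal(got[[1]], s1, tol = 1e-10))
    expect_true(comp_equal(got[[2]], s2, tol = 1e-10))
    expect_true(comp_equal(got[[3]], s3, tol = 1e-10))
  }
  expect_error(decompose_steps(list(a = c(x = 1, y = 2), b = c(x = 1, z = 2))),
               "same taxa")
})

test_that("copy-number bias by mixture entry point", {
  g <- mock_genomics()
  cells <- cn_bias(g, "cells")
  expect_true(comp_equal(cells, setNames(c(2, 2, 4, 5, 4, 3, 7), g$taxon)))
  pcr <- cn_bias(g, "pcr_product")
  expect_true(all(pcr == 1))
  dna <- cn_bias(g, "dna")
  expect_true(comp_equal(dna, setNames(g$copy_number / g$genome_size_mbp,
                                       g$taxon)))
  expect_error(cn_bias(g, "cells", taxa = c(g$taxon, "Unknown sp.")),
               "missing genomics")
})

test_that("copy-number correction inverts copy-number bias", {
  g <- mock_genomics()
  cnb <- cn_bias(g, "cells")
  obs <- c(a = 0.3, b = 0.7)
  expect_equal(cn_correct(obs, c(a = 1, b = 1)), close_comp(obs))
  expect_equal(unname(cn_correct(c(a = 0.3, b = 0.7), c(a = 4, b = 4))),
               c(0.3, 0.7))
  even <- even_comp(g$taxon)
  expect_equal(cn_correct(predict_observed(even, cnb), cnb), close_comp(even),
               tolerance = 1e-12)
})

test_that("copy-number variation explains ~60% of PCR-step bias variance", {
  tb <- mock_bias_tab()
  g <- mock_genomics()
  pcr <- setNames(tb$pcr, tb$taxon)
  cnb <- cn_bias(g, "dna", taxa = tb$taxon)
  ve <- variance_explained(pcr, cnb)
  expect_equal(ve, 0.60, tolerance = 0.02)
  perm <- permutation_pvalue(pcr, cnb)
  expect_equal(perm$n_perm, factorial(7))
  expect_lt(abs(perm$p_value - 0.021), 0.01)
  expect_gte(perm$p_value, 1 / factorial(7))
  expect_lte(perm$p_value, 1)
  # deterministic: exhaustive enumeration gives the same p twice
  expect_identical(perm$p_value, permutation_pvalue(pcr, cnb)$p_value)
})

test_that("variance explained: endpoints, invariances, errors", {
  b <- c(a = 1, b = 4, c = 0.5, d = 2)
  expect_equal(variance_explained(b, b), 1)
  expect_equal(variance_explained(b, c(a = 1, b = 1, c = 1, d = 1)), 0)
  p <- c(a = 2, b = 3, c = 1, d = 0.5)
  expect_equal(variance_explained(b, p), variance_explained(3 * b, 0.2 * p),
               tolerance = 1e-12)
  relabel <- c(a = "w", b = "x", c = "y", d = "z")
  b2 <- setNames(b, relabel[names(b)])
  p2 <- setNames(p, relabel[names(p)])
  expect_equal(variance_explained(b2, p2), variance_explained(b, p))
  expect_error(variance_explained(c(a = 1, b = 2), c(a = 1, b = 2)),
               "fewer than 3")
  # OLS variant is available and equals 1 for a perfect predictor
  expect_equal(suppressWarnings(variance_explained(b, b, method = "ols")), 1)
})
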