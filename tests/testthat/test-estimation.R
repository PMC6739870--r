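test_that("a single control recovers the bias exactly", {
  fit <- estimate_bias(c(0.04, 0.72, 0.24), even_comp(3))
  expect_true(comp_equal(coef(fit), c(taxon1 = 1, taxon2 = 18, taxon3 = 6)))
  expect_equal(exp(mean(log(coef(fit)))), 1, tolerance = 1e-12)
  expect_true(all(abs(residuals(fit) - 1) < 1e-12))
  expect_equal(fit$objective, 0, tolerance = 1e-20)
})

test_that("complete designs reduce to the element-wise geometric mean", {
  O <- rbind(c(2, 1, 0.5), c(8, 1, 0.125))
  A <- rbind(c(1, 1, 1), c(1, 1, 1))
  fit <- estimate_bias(O, A)
  expect_true(comp_equal(coef(fit),
                         c(taxon1 = 4, taxon2 = 1, taxon3 = 0.25),
                         tol = 1e-10))
  set.seed(21)
  for (i in 1:10) {
    inst <- random_instance(5, 4, noise_sd = 0.3)
    inst$observed[is.na(inst$observed)] <- 0.1  # make the design complete
    inst$actual[is.na(inst$actual)] <- 0.1
    fit <- estimate_bias(inst$observed, inst$actual)
    gm <- exp(colMeans(log(inst$observed / inst$actual)))
    expect_true(comp_equal(coef(fit), gm, tol = 1e-10))
  }
})

test_that("partial-overlap designs combine controls into one estimate", {
  O <- rbind(s1 = c(a = 4, b = 1, c = NA), s2 = c(a = NA, b = 1, c = 0.25))
  A <- rbind(s1 = c(a = 1, b = 1, c = NA), s2 = c(a = NA, b = 1, c = 1))
  fit <- estimate_bias(O, A)
  expect_true(comp_equal(coef(fit), c(a = 4, b = 1, c = 0.25), tol = 1e-9))
})

test_that("solver matches a brute-force minimizer on random partial overlaps", {
  set.seed(22)
  worst <- 0
  for (i in 1:50) {
    inst <- random_instance(sample(3:6, 1), sample(3:6, 1))
    fit <- estimate_bias(inst$observed, inst$actual)
    pkg_obj <- oracle_objective(inst$observed, inst$actual, coef(fit))
    expect_equal(pkg_obj, fit$objective, tolerance = 1e-8)
    brute <- oracle_minimum(inst$observed, inst$actual)
    gap <- abs(pkg_obj - brute) / max(brute, 1e-8)
    worst <- max(worst, gap)
  }
  expect_lt(worst, 1e-6)
})

test_that("identifiability partitions taxa by sample co-occurrence", {
  expect_length(check_identifiability(list(c("A", "B", "C"), c("A", "B"))), 1)
  comps <- check_identifiability(list(c("A", "B"), c("C", "D")))
  expect_length(comps, 2)
  expect_true(any(vapply(comps, setequal, TRUE, c("A", "B"))))
  expect_length(check_identifiability(list(c("A", "B"), c("B", "C"))), 1)
  O <- rbind(s1 = c(a = 1, b = 2, c = NA, d = NA),
             s2 = c(a = NA, b = NA, c = 1, d = 2))
  A <- rbind(s1 = c(a = 1, b = 1, c = NA, d = NA),
             s2 = c(a = NA, b = NA, c = 1, d = 1))
  expect_error(estimate_bias(O, A), "identifiable.*2 components")
})

test_that("residual errors are identity on noiseless data and optimal at the fit", {
  set.seed(23)
  bias <- c(a = 1, b = 2, c = 4, d = 8)
  design <- make_even_subset_design(names(bias),
                                    list(c("a", "b", "c"), c("b", "c", "d")),
                                    bias = bias)
  noiseless <- simulate_experiment(design)
  r <- residual_errors(noiseless$observed, noiseless$actual, bias)
  expect_true(all(abs(r[!is.na(r)] - 1) < 1e-10))

  inst <- random_instance(5, 5)
  fit <- estimate_bias(inst$observed, inst$actual)
  at_fit <- oracle_objective(inst$observed, inst$actual, coef(fit))
  for (i in 1:25) {
    b_pert <- coef(fit) * exp(rnorm(5, 0, 0.2))
    expect_gte(oracle_objective(inst$observed, inst$actual, b_pert),
               at_fit - 1e-10)
  }
})

test_that("estimates are equivariant under perturbing the observations", {
  set.seed(24)
  inst <- random_instance(5, 4)
  fit <- estimate_bias(inst$observed, inst$actual)
  cc <- exp(rnorm(5))
  O2 <- sweep(inst$observed, 2, cc, `*`)
  fit2 <- estimate_bias(O2, inst$actual)
  expect_true(comp_equal(coef(fit2), coef(fit) * cc, tol = 1e-9))
})

test_that("zero-handling policy: out-of-design reads dropped, zeros get pseudocounts", {
  O <- rbind(s1 = c(a = 10, b = 20, c = 5))   # c not in the design
  A <- rbind(s1 = c(a = 1, b = 1, c = NA))
  expect_warning(fit <- estimate_bias(O, A), "outside the sample design")
  expect_setequal(fit$taxa, c("a", "b"))

  O2 <- rbind(s1 = c(a = 10, b = 0, c = 30), s2 = c(a = 5, b = 5, c = 5))
  A2 <- rbind(s1 = c(a = 1, b = 1, c = 1), s2 = c(a = 1, b = 1, c = 1))
  expect_warning(fit2 <- estimate_bias(O2, A2, pseudocount = 0.5),
                 "pseudocount 0.5")
  expect_equal(fit2$observed["s1", "b"], 0.5)

  # samples with fewer than two defined taxa contribute nothing
  O3 <- rbind(s1 = c(a = 3, b = 1), s2 = c(a = 2, b = NA))
  A3 <- rbind(s1 = c(a = 1, b = 1), s2 = c(a = 1, b = NA))
  expect_warning(fit3 <- estimate_bias(O3, A3), "fewer than 2")
  expect_true(comp_equal(coef(fit3), c(a = 3, b = 1)))
})

test_that("parameter recovery under clr-normal noise with 20 controls", {
  set.seed(25)
  bias <- gstandardize(exp(rnorm(7, 0, 1)))
  names(bias) <- paste0("t", 1:7)
  design <- make_even_subset_design(names(bias),
                                    rep(list(names(bias)), 20),
                                    bias = bias, noise_sd = 0.3)
  bound <- 3 * 0.3 / sqrt(20)
  ok <- vapply(1:200, function(i) {
    ex <- simulate_experiment(design)
    err <- log(coef(estimate_bias(ex$observed, ex$actual))) - log(bias)
    max(abs(err - mean(err))) < bound
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("differential bias behaves like bias with a reference protocol", {
  set.seed(26)
  a <- matrix(exp(rnorm(12)), 3, 4,
              dimnames = list(paste0("s", 1:3), letters[1:4]))
  a <- a / rowSums(a)
  bp <- exp(rnorm(4)); bq <- exp(rnorm(4)); br <- exp(rnorm(4))
  obs <- function(b) t(apply(a, 1, function(x) predict_observed(x, b)))
  # same protocol as reference: identity differential bias
  self <- estimate_differential_bias(obs(bp), obs(bp))
  expect_true(comp_equal(coef(self), rep(1, 4), tol = 1e-9))
  # chain property on noiseless data
  pq <- coef(estimate_differential_bias(obs(bp), obs(bq)))
  qr <- coef(estimate_differential_bias(obs(bq), obs(br)))
  pr <- coef(estimate_differential_bias(obs(bp), obs(br)))
  expect_true(comp_equal(perturb(pq, qr), pr, tol = 1e-9))
})

test_that("printed per-protocol efficiency columns give the printed differential bias", {
  tab <- read.delim(system.file("extdata", "fecal_spikein_bias.tsv",
                                package = "mgsbias"), check.names = FALSE)
  mock <- tab$taxon != "Contaminant"
  hw <- gstandardize(setNames(tab$H[mock] / tab$W[mock], tab$taxon[mock]))
  printed <- setNames(tab$H_W[mock], tab$taxon[mock])
  expect_lt(max(abs(log(hw / gstandardize(printed)))), log(1.25))
  expect_equal(unname(hw["Prevotella melaninogenica"]), 2.05,
               tolerance = 0.025)
})

test_that("bootstrap: exact fits give gm_se 1 and seeds reproduce replicates", {
  O <- rbind(s1 = c(2, 1, 0.5), s2 = c(2, 1, 0.5))
  A <- rbind(s1 = c(1, 1, 1), s2 = c(1, 1, 1))
  fit <- bootstrap_bias(estimate_bias(O, A), n_reps = 50, seed = 5)
  expect_true(all(abs(fit$gm_se - 1) < 1e-8))
  expect_true(all(fit$gm_se >= 1))
  fit2 <- bootstrap_bias(estimate_bias(O, A), n_reps = 50, seed = 5)
  expect_identical(fit$replicates, fit2$replicates)
})

test_that("multinomial bootstrap precision improves with more trials", {
  set.seed(27)
  bias <- gstandardize(c(t1 = 1, t2 = 3, t3 = 0.4, t4 = 2))
  design <- make_even_subset_design(names(bias), rep(list(names(bias)), 8),
                                    bias = bias, noise_sd = 0.3)
  ex <- simulate_experiment(design)
  fit <- estimate_bias(ex$observed, ex$actual)
  se2 <- bootstrap_bias(fit, n_reps = 1000, weighting = "multinomial",
                        n_trials = 2, seed = 6)$gm_se
  se8 <- bootstrap_bias(fit, n_reps = 1000, weighting = "multinomial",
                        n_trials = 8, seed = 7)$gm_se
  expect_lt(median(se8), median(se2))
})

test_that("bootstrap redraws multinomial weights that break identifiability", {
  O <- rbind(s1 = c(a = 4, b = 1, c = NA), s2 = c(a = NA, b = 1, c = 0.25))
  A <- rbind(s1 = c(a = 1, b = 1, c = NA), s2 = c(a = NA, b = 1, c = 1))
  fit <- estimate_bias(O, A)
  expect_warning(
    boot <- bootstrap_bias(fit, n_reps = 30, weighting = "multinomial",
                           n_trials = 2, seed = 8),
    "disconnected")
  expect_false(anyNA(boot$replicates))
})
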