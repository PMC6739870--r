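# Independent oracles for the estimator tests.  These recompute the
# least-squares objective and its minimum from scratch (plain log/centering
# arithmetic plus optim), without touching the package's solver.

# Sum over samples of the squared restricted Aitchison norm of the residuals
# at efficiency vector `b` (positive, over colnames of O).
oracle_objective <- function(O, A, b) {
  lb <- log(b)
  total <- 0
  for (s in seq_len(nrow(O))) {
    idx <- which(!is.na(O[s, ]) & !is.na(A[s, ]))
    if (length(idx) < 2) next
    r <- log(O[s, idx]) - log(A[s, idx]) - lb[idx]
    r <- r - mean(r)
    total <- total + sum(r^2)
  }
  total
}

# Derivative-free/numeric minimization over log-efficiencies with the last
# coordinate pinned at 0 (the objective is invariant to a common factor).
oracle_minimum <- function(O, A) {
  K <- ncol(O)
  fn <- function(par) oracle_objective(O, A, exp(c(par, 0)))
  fit <- stats::optim(rep(0, K - 1), fn, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit$value
}

# Random control instance: n_taxa <= 6, n_samples <= 6, random missingness
# retried until the taxon overlap graph is connected.
random_instance <- function(n_taxa, n_samples, noise_sd = 0.4) {
  taxa <- letters[seq_len(n_taxa)]
  bias <- exp(stats::rnorm(n_taxa, 0, 1))
  repeat {
    present <- matrix(stats::runif(n_samples * n_taxa) < 0.7,
                      n_samples, n_taxa)
    if (any(rowSums(present) < 2)) next
    sets <- apply(present, 1, function(r) taxa[r], simplify = FALSE)
    if (length(check_identifiability(sets)) == 1 &&
        setequal(unlist(sets), taxa)) break
  }
  A <- O <- matrix(NA_real_, n_samples, n_taxa,
                   dimnames = list(paste0("s", seq_len(n_samples)), taxa))
  for (s in seq_len(n_samples)) {
    idx <- which(present[s, ])
    a <- stats::runif(length(idx), 0.2, 1)
    eps <- exp(stats::rnorm(length(idx), 0, noise_sd))
    A[s, idx] <- a / sum(a)
    o <- a * bias[idx] * eps
    O[s, idx] <- o / sum(o)
  }
  list(observed = O, actual = A, bias = bias)
}

# Pairwise form of the Aitchison norm, as an independent check on anorm().
pairwise_anorm <- function(x) {
  x <- x[!is.na(x)]
  k <- length(x)
  lr <- outer(log(x), log(x), "-")
  sqrt(sum(lr[lower.tri(lr)]^2) / k)
}
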