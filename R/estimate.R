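# Bias estimation from control samples.  The estimate minimizes the summed
# squared Aitchison norm of the per-sample residuals
#   sum_s || O(s) / (A(s) * B) ||^2 ,
# each norm restricted to the taxa present in sample s.  In log space this is
# a linear least-squares problem in the log-efficiencies with per-sample
# centering, solved exactly by (rank-deficient) normal equations; the
# log-efficiency vector is identified only up to an additive constant, fixed
# by the sum-to-zero (geometric mean 1) convention.  When every sample
# contains every covered taxon the solution reduces to the element-wise
# geometric mean of O(s)/A(s).

# Coerce a vector/data.frame/matrix to a samples x taxa numeric matrix.
as_abundance_matrix <- function(x, name = "x") {
  if (is.data.frame(x)) {
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list("sample1", names(x)))
  }
  if (!is.numeric(x)) {
    stop("`", name, "` must be numeric", call. = FALSE)
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("taxon", seq_len(ncol(x)))
  }
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("sample", seq_len(nrow(x)))
  }
  if (anyDuplicated(colnames(x)) || anyDuplicated(rownames(x))) {
    stop("duplicate sample or taxon labels in `", name, "`", call. = FALSE)
  }
  if (any(x[!is.na(x)] < 0)) {
    stop("negative values in `", name, "`", call. = FALSE)
  }
  x
}

# Connected components of the taxon co-occurrence graph, by union-find.
# `sets` is a list of character vectors (taxa present per sample).
taxon_components <- function(sets, taxa = NULL) {
  if (is.null(taxa)) {
    taxa <- unique(unlist(sets, use.names = FALSE))
  }
  parent <- seq_along(taxa)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (s in sets) {
    idx <- match(s, taxa)
    idx <- idx[!is.na(idx)]
    if (length(idx) > 1) {
      r <- find(idx[1])
      for (k in idx[-1]) {
        parent[find(k)] <- r
      }
    }
  }
  roots <- vapply(seq_along(taxa), find, integer(1))
  unname(split(taxa, match(roots, unique(roots))))
}

#' Check identifiability of bias from a control design
#'
#' Relative efficiencies are only estimable between taxa connected through
#' shared samples: build the graph whose nodes are taxa, with an edge between
#' two taxa whenever some sample contains both, and take its connected
#' components.  Efficiency ratios are identifiable within components but not
#' between them.
#'
#' @param presence A list of per-sample taxon sets (character vectors), or a
#'   logical/abundance matrix (samples x taxa) in which `NA` (or `FALSE`)
#'   marks absence.
#' @return A list of character vectors, one per connected component.  A
#'   design is fully identifiable when the list has length 1.
#' @export
check_identifiability <- function(presence) {
  if (is.matrix(presence) || is.data.frame(presence)) {
    m <- as.matrix(presence)
    taxa <- colnames(m)
    if (is.null(taxa)) {
      taxa <- paste0("taxon", seq_len(ncol(m)))
    }
    presence <- apply(m, 1, function(r) {
      taxa[if (is.logical(r)) which(!is.na(r) & r) else which(!is.na(r))]
    }, simplify = FALSE)
  }
  if (!length(presence) || !any(lengths(presence) > 0)) {
    stop("empty presence sets", call. = FALSE)
  }
  taxon_components(presence)
}

# Apply the zero/undefined policy and return aligned matrices plus the
# per-sample log-ratio matrix D = log(O/A) (NA where undefined).
prepare_controls <- function(observed, actual, pseudocount = 0.5) {
  O <- as_abundance_matrix(observed, "observed")
  A <- as_abundance_matrix(actual, "actual")
  if (!setequal(rownames(O), rownames(A))) {
    stop("`observed` and `actual` must share sample labels", call. = FALSE)
  }
  A <- A[rownames(O), , drop = FALSE]
  taxa <- union(colnames(O), colnames(A))
  expand <- function(m) {
    out <- matrix(NA_real_, nrow(m), length(taxa),
                  dimnames = list(rownames(m), taxa))
    out[, colnames(m)] <- m
    out
  }
  O <- expand(O)
  A <- expand(A)

  n_dropped <- 0L
  n_pseudo <- 0L
  for (s in seq_len(nrow(O))) {
    a <- A[s, ]
    o <- O[s, ]
    design <- !is.na(a) & a > 0
    o[is.na(o)] <- 0
    drop_idx <- !design & o > 0
    if (any(drop_idx)) {
      n_dropped <- n_dropped + sum(drop_idx)
    }
    o[!design] <- NA_real_
    zero_idx <- design & o == 0
    if (any(zero_idx)) {
      if (pseudocount > 0) {
        o[zero_idx] <- pseudocount
        n_pseudo <- n_pseudo + sum(zero_idx)
      } else {
        o[zero_idx] <- NA_real_
        a[zero_idx] <- NA_real_
      }
    }
    a[is.na(o)] <- NA_real_
    O[s, ] <- o
    A[s, ] <- a
  }
  if (n_dropped > 0) {
    warning(n_dropped, " observed value(s) for taxa outside the sample ",
            "design were ignored", call. = FALSE)
  }
  if (n_pseudo > 0) {
    warning("pseudocount ", pseudocount, " added to ", n_pseudo,
            " undetected designed-in value(s)", call. = FALSE)
  }

  n_def <- rowSums(!is.na(O))
  if (any(n_def < 2)) {
    warning(sum(n_def < 2), " sample(s) with fewer than 2 defined taxa ",
            "contribute nothing to the fit", call. = FALSE)
  }
  used <- n_def >= 2
  if (!any(used)) {
    stop("no sample has at least 2 defined taxa", call. = FALSE)
  }
  covered <- colnames(O)[colSums(!is.na(O[used, , drop = FALSE])) > 0]
  O <- O[, covered, drop = FALSE]
  A <- A[, covered, drop = FALSE]
  list(observed = O, actual = A, D = log(O) - log(A), used = used)
}

# Solve the weighted least-squares problem in log space.  D is the log-ratio
# matrix (NA = undefined); returns centered log-efficiencies.
solve_log_bias <- function(D, weights = NULL) {
  K <- ncol(D)
  M <- matrix(0, K, K)
  v <- numeric(K)
  for (s in seq_len(nrow(D))) {
    idx <- which(!is.na(D[s, ]))
    m <- length(idx)
    if (m < 2) next
    w <- if (is.null(weights)) 1 else weights[s]
    if (w <= 0) next
    M[idx, idx] <- M[idx, idx] + w * (diag(m) - 1 / m)
    v[idx] <- v[idx] + w * (D[s, idx] - mean(D[s, idx]))
  }
  b <- drop(MASS::ginv(M) %*% v)
  b - mean(b)
}

# Objective: sum over samples of squared restricted Aitchison norm of the
# residuals at log-efficiencies b.
log_bias_objective <- function(D, b, weights = NULL) {
  total <- 0
  for (s in seq_len(nrow(D))) {
    idx <- which(!is.na(D[s, ]))
    if (length(idx) < 2) next
    w <- if (is.null(weights)) 1 else weights[s]
    r <- D[s, idx] - b[idx]
    total <- total + w * sum((r - mean(r))^2)
  }
  total
}

#' Estimate multiplicative bias from control samples
#'
#' Fits the measurement model `observed ~ actual * bias * noise` to control
#' samples of known composition, estimating the vector of relative
#' efficiencies that minimizes the summed squared Aitchison norm of the
#' per-sample residual errors (each restricted to the taxa present in that
#' sample).  When every control contains every covered taxon, the estimate is
#' the element-wise geometric mean of `observed/actual` across samples.
#' Controls covering different taxon subsets are combined into one estimate
#' provided the taxon co-occurrence graph is connected (see
#' [check_identifiability()]).
#'
#' Zero handling: observed reads for taxa not in a sample's design are
#' ignored with a warning; designed-in taxa with observed value 0 receive
#' `pseudocount` (on the scale of the observed values, intended for counts)
#' before closure.
#'
#' @param observed Samples x taxa matrix (or single named vector) of observed
#'   counts or proportions.  `NA` marks a taxon not measured in that sample.
#' @param actual Matrix of the same shape giving the known (control)
#'   compositions; `NA` or 0 marks a taxon absent from the sample's design.
#' @param pseudocount Value added to designed-in taxa observed as 0.
#' @return An object of class `bias_fit` with components `coefficients`
#'   (relative efficiencies, geometric mean 1 over covered taxa),
#'   `residuals` (per-sample residual compositions, geometric mean 1 per
#'   sample), `observed`/`actual` (processed matrices), `objective` (summed
#'   squared residual norm), and after [bootstrap_bias()] also `replicates`
#'   and `gm_se`.  Supports `print()`, `summary()`, `coef()`, `residuals()`,
#'   `predict()`, `plot()`, `confint()` and `simulate()`.
#' @examples
#' fit <- estimate_bias(c(0.04, 0.72, 0.24), even_comp(3))
#' coef(fit) / coef(fit)[1]  # ~ (1, 18, 6)
#' @seealso [calibrate()], [bootstrap_bias()], [estimate_differential_bias()]
#' @export
estimate_bias <- function(observed, actual, pseudocount = 0.5) {
  cl <- match.call()
  prep <- prepare_controls(observed, actual, pseudocount)
  D <- prep$D[prep$used, , drop = FALSE]

  presence <- apply(D, 1, function(r) colnames(D)[!is.na(r)],
                    simplify = FALSE)
  comps <- taxon_components(presence, colnames(D))
  if (length(comps) > 1) {
    stop("bias is not identifiable: the taxon overlap graph has ",
         length(comps), " components:\n",
         paste(vapply(comps, paste, "", collapse = ", "), collapse = "\n"),
         call. = FALSE)
  }

  b <- solve_log_bias(D)
  point <- stats::setNames(exp(b), colnames(D))

  res <- D
  for (s in seq_len(nrow(D))) {
    idx <- which(!is.na(D[s, ]))
    r <- D[s, idx] - b[idx]
    res[s, idx] <- exp(r - mean(r))
  }

  structure(list(
    coefficients = point,
    log_coefficients = stats::setNames(b, colnames(D)),
    residuals = res,
    observed = prep$observed,
    actual = prep$actual,
    taxa = colnames(D),
    n_samples = nrow(D),
    objective = log_bias_objective(D, b),
    pseudocount = pseudocount,
    type = "bias",
    replicates = NULL,
    gm_se = NULL,
    call = cl
  ), class = "bias_fit")
}

#' Estimate differential bias between two protocols
#'
#' The systematic compositional difference between measurements of the same
#' samples by protocol P and a reference protocol R is `B(P)/B(R)`, the
#' differential bias.  It is estimated exactly like bias, with the reference
#' protocol's measurements standing in for the actual compositions — the true
#' compositions need not be known.
#'
#' @param observed Protocol P's measurements (samples x taxa).
#' @param reference Protocol R's measurements of the same samples.
#' @inheritParams estimate_bias
#' @return A `bias_fit` whose coefficients estimate `B(P/R)`.
#' @export
estimate_differential_bias <- function(observed, reference,
                                       pseudocount = 0.5) {
  fit <- estimate_bias(observed, reference, pseudocount = pseudocount)
  fit$type <- "differential bias"
  fit$call <- match.call()
  fit
}

#' Residual errors of a bias vector on control samples
#'
#' The per-sample residual composition `observed / (actual * bias)`,
#' restricted to each sample's defined taxa and standardized to geometric
#' mean 1.  At the least-squares estimate these are the fitted residuals;
#' for any other bias vector their summed squared Aitchison norm is larger.
#'
#' @inheritParams estimate_bias
#' @param bias Efficiency vector (or `bias_fit`) covering every sample's
#'   taxa.
#' @return Samples x taxa matrix of residual compositions (`NA` where
#'   undefined).
#' @export
residual_errors <- function(observed, actual, bias, pseudocount = 0.5) {
  prep <- prepare_controls(observed, actual, pseudocount)
  bias <- resolve_bias(bias, colnames(prep$D))
  b <- log(align_comp(stats::setNames(rep(1, ncol(prep$D)), colnames(prep$D)),
                      bias, "taxa", "bias"))
  res <- prep$D
  for (s in seq_len(nrow(res))) {
    idx <- which(!is.na(res[s, ]))
    if (length(idx) < 2) next
    r <- res[s, idx] - b[idx]
    res[s, idx] <- exp(r - mean(r))
  }
  res
}

#' Bootstrap uncertainty for a bias estimate
#'
#' Re-estimates the bias under random per-sample weights (Dirichlet with unit
#' concentration, or multinomial with `n_trials` draws over the samples) and
#' summarizes the spread of the replicates as per-taxon geometric standard
#' errors: `gm_se[i] = exp(sd over replicates of log replicate[i])`, with
#' each replicate standardized to geometric mean 1.  Multinomial weighting
#' with `n_trials = m` mimics the precision attainable from `m` control
#' samples.  Multinomial replicates whose zero weights disconnect the taxon
#' overlap graph are redrawn (with a warning) up to `retry_cap` times.
#'
#' @param fit A `bias_fit` from [estimate_bias()].
#' @param n_reps Number of bootstrap replicates (>= 2).
#' @param weighting `"dirichlet"` (default) or `"multinomial"`.
#' @param n_trials Multinomial trial count; defaults to the number of
#'   samples.
#' @param seed Optional integer seed for reproducibility.
#' @param retry_cap Maximum redraws per disconnected multinomial replicate.
#' @return The fit, augmented with `replicates` (n_reps x taxa matrix) and
#'   `gm_se` (per-taxon geometric standard error, >= 1).
#' @export
bootstrap_bias <- function(fit, n_reps = 1000,
                           weighting = c("dirichlet", "multinomial"),
                           n_trials = NULL, seed = NULL, retry_cap = 100) {
  stopifnot(inherits(fit, "bias_fit"), n_reps >= 2)
  weighting <- match.arg(weighting)
  if (!is.null(seed)) {
    set.seed(seed)
  }
  D <- log(fit$observed) - log(fit$actual)
  n <- nrow(D)
  if (is.null(n_trials)) {
    n_trials <- n
  }
  presence <- apply(D, 1, function(r) colnames(D)[!is.na(r)],
                    simplify = FALSE)
  reps <- matrix(NA_real_, n_reps, ncol(D),
                 dimnames = list(NULL, colnames(D)))
  n_redrawn <- 0L
  for (r in seq_len(n_reps)) {
    for (try in seq_len(retry_cap + 1L)) {
      w <- if (weighting == "dirichlet") {
        stats::rgamma(n, shape = 1)
      } else {
        drop(stats::rmultinom(1, n_trials, rep(1 / n, n)))
      }
      ok <- length(taxon_components(presence[w > 0], colnames(D))) == 1
      if (ok) break
      n_redrawn <- n_redrawn + 1L
      if (try > retry_cap) {
        stop("bootstrap replicate weights kept disconnecting the taxon ",
             "overlap graph (", retry_cap, " retries)", call. = FALSE)
      }
    }
    reps[r, ] <- exp(solve_log_bias(D, weights = w))
  }
  if (n_redrawn > 0) {
    warning(n_redrawn, " bootstrap replicate(s) redrawn because their ",
            "weights disconnected the taxon overlap graph", call. = FALSE)
  }
  fit$replicates <- reps
  fit$gm_se <- exp(apply(log(reps), 2, stats::sd))
  fit$bootstrap <- list(n_reps = n_reps, weighting = weighting,
                        n_trials = n_trials, seed = seed)
  fit
}
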