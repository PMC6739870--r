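# S3 methods for bias_fit objects.

#' @export
print.bias_fit <- function(x, digits = 3, ...) {
  cat("Multiplicative", x$type, "estimate\n")
  cat(" ", length(x$taxa), "taxa,", x$n_samples, "control sample(s)\n")
  cat("  relative efficiencies (geometric mean 1):\n")
  print(round(x$coefficients, digits))
  if (!is.null(x$gm_se)) {
    cat("  geometric standard errors (", x$bootstrap$n_reps,
        " ", x$bootstrap$weighting, "-weighted bootstrap replicates):\n",
        sep = "")
    print(round(x$gm_se, digits))
  }
  invisible(x)
}

#' Summarize a bias fit
#'
#' Returns the per-taxon efficiency table plus the pairwise summary
#' statistics used to compare protocols: maximum pairwise bias (geometric
#' range of the efficiencies), average pairwise bias, and average pairwise
#' noise of the residuals.
#'
#' @param object A `bias_fit`.
#' @param ... Unused.
#' @export
summary.bias_fit <- function(object, ...) {
  tab <- data.frame(
    taxon = object$taxa,
    efficiency = unname(object$coefficients),
    gm_se = if (is.null(object$gm_se)) NA_real_ else unname(object$gm_se),
    row.names = NULL
  )
  stats <- c(
    max_pairwise_bias = max_pairwise_bias(object$coefficients),
    avg_pairwise_bias = avg_pairwise_bias(object$coefficients),
    avg_pairwise_noise = avg_pairwise_noise(object$residuals)
  )
  structure(list(coefficients = tab, stats = stats, type = object$type,
                 n_samples = object$n_samples, call = object$call),
            class = "summary.bias_fit")
}

#' @export
print.summary.bias_fit <- function(x, digits = 3, ...) {
  cat("Multiplicative", x$type, "estimate from", x$n_samples,
      "control sample(s)\n\n")
  print(x$coefficients, digits = digits, row.names = FALSE)
  cat("\n")
  print(round(x$stats, digits))
  invisible(x)
}

#' @export
coef.bias_fit <- function(object, ...) {
  object$coefficients
}

#' @export
residuals.bias_fit <- function(object, ...) {
  object$residuals
}

#' Predict observed compositions from a fitted bias
#'
#' Applies the fitted relative efficiencies to actual compositions via the
#' measurement model, returning the predicted observed proportions.
#'
#' @param object A `bias_fit`.
#' @param actual Actual compositions: a named vector or a samples x taxa
#'   matrix.  Defaults to the control compositions used in the fit.
#' @param ... Unused.
#' @return Matrix (or vector, matching the input) of predicted proportions.
#' @export
predict.bias_fit <- function(object, actual = object$actual, ...) {
  if (is.null(dim(actual))) {
    return(predict_observed(actual, object$coefficients))
  }
  A <- as_abundance_matrix(actual, "actual")
  out <- A
  for (s in seq_len(nrow(A))) {
    a <- A[s, ]
    a[!is.na(a) & a == 0] <- NA
    out[s, ] <- predict_observed(a, object$coefficients)
  }
  out
}

#' Confidence intervals for relative efficiencies
#'
#' Percentile intervals from the bootstrap replicates; requires
#' [bootstrap_bias()] to have been run on the fit.
#'
#' @param object A `bias_fit` with bootstrap replicates.
#' @param parm Taxa to include (names or indices); default all.
#' @param level Confidence level.
#' @param ... Unused.
#' @export
confint.bias_fit <- function(object, parm = object$taxa, level = 0.95, ...) {
  if (is.null(object$replicates)) {
    stop("no bootstrap replicates; run bootstrap_bias() first", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  q <- t(apply(object$replicates[, parm, drop = FALSE], 2,
               stats::quantile, probs = c(alpha, 1 - alpha)))
  colnames(q) <- paste0(format(100 * c(alpha, 1 - alpha), trim = TRUE), " %")
  q
}

#' Plot estimated relative efficiencies
#'
#' Dot plot of the efficiencies on a log scale, with bars spanning two
#' geometric standard errors in each direction when bootstrap results are
#' present.
#'
#' @param x A `bias_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bias_fit <- function(x, ...) {
  ord <- order(x$coefficients)
  eff <- x$coefficients[ord]
  k <- length(eff)
  lo <- hi <- eff
  if (!is.null(x$gm_se)) {
    se <- x$gm_se[ord]
    lo <- eff / se^2
    hi <- eff * se^2
  }
  graphics::plot(eff, seq_len(k), log = "x", xlim = range(lo, hi),
                 yaxt = "n", ylab = "", pch = 19,
                 xlab = "relative efficiency (log scale)", ...)
  graphics::axis(2, at = seq_len(k), labels = names(eff), las = 1,
                 cex.axis = 0.8)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  if (!is.null(x$gm_se)) {
    graphics::segments(lo, seq_len(k), hi, seq_len(k))
  }
  invisible(x)
}

#' Simulate control experiments from a fitted bias
#'
#' Generates new observed tables for the fit's control design using the
#' estimated efficiencies and a log-scale (clr-normal) noise level estimated
#' from the pooled fitted residuals.
#'
#' @param object A `bias_fit`.
#' @param nsim Number of simulated experiments.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` observed proportion matrices.
#' @export
simulate.bias_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    set.seed(seed)
  }
  lr <- log(object$residuals)
  noise_sd <- stats::sd(lr[!is.na(lr)])
  if (is.na(noise_sd)) {
    noise_sd <- 0
  }
  design <- simulation_design(taxa = object$taxa, actual = object$actual,
                              bias = object$coefficients,
                              noise_sd = noise_sd)
  lapply(seq_len(nsim), function(i) simulate_experiment(design)$observed)
}
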