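# Scalar summaries of bias magnitude and noise for protocol evaluation.
# All are functions of pairwise efficiency ratios, hence invariant to
# rescaling and to taxon relabeling.

pairwise_abs_logratios <- function(x) {
  def <- check_comp(x, positive = TRUE)
  lx <- log(x[def])
  if (sum(def) < 2) {
    stop("need at least 2 defined taxa", call. = FALSE)
  }
  d <- outer(lx, lx, "-")
  abs(d[lower.tri(d)])
}

#' Maximum pairwise bias
#'
#' The geometric range of the relative efficiencies, `max(B) / min(B)`: the
#' largest fold-error that bias causes in the ratio of any two taxa.
#'
#' @param bias Efficiency vector (or `bias_fit`), >= 2 positive defined
#'   entries.
#' @return Scalar >= 1.
#' @export
max_pairwise_bias <- function(bias) {
  bias <- resolve_bias(bias)
  def <- check_comp(bias, positive = TRUE, name = "bias")
  if (sum(def) < 2) {
    stop("need at least 2 defined taxa", call. = FALSE)
  }
  max(bias[def]) / min(bias[def])
}

#' Average pairwise bias
#'
#' The multiplicative error in taxon ratios averaged over all unordered pairs
#' of taxa: `exp(mean over i<j of |log(B_i/B_j)|)`.
#'
#' @inheritParams max_pairwise_bias
#' @return Scalar >= 1, between 1 and [max_pairwise_bias()].
#' @export
avg_pairwise_bias <- function(bias) {
  bias <- resolve_bias(bias)
  exp(mean(pairwise_abs_logratios(bias)))
}

#' Average pairwise noise
#'
#' The analogous average pairwise measure of random error, computed from the
#' per-sample residual compositions: the absolute pairwise log-ratios of the
#' residuals, pooled over all samples and pairs, then averaged and
#' exponentiated.  Equals 1 when every residual is a uniform composition
#' (perfect fit).  The mean-absolute form mirrors [avg_pairwise_bias()] and
#' is the default convention; `method = "rms"` uses the root-mean-square of
#' the log-ratios instead.
#'
#' @param residuals Samples x taxa matrix of residual compositions (`NA`
#'   where undefined), e.g. `residuals(fit)`, or a single residual vector.
#' @param method `"mean_abs"` (default) or `"rms"`.
#' @return Scalar >= 1.
#' @export
avg_pairwise_noise <- function(residuals, method = c("mean_abs", "rms")) {
  method <- match.arg(method)
  if (is.null(dim(residuals))) {
    residuals <- matrix(residuals, nrow = 1,
                        dimnames = list(NULL, names(residuals)))
  }
  vals <- unlist(lapply(seq_len(nrow(residuals)), function(s) {
    r <- residuals[s, ]
    if (sum(!is.na(r)) < 2) {
      return(numeric(0))
    }
    pairwise_abs_logratios(r)
  }))
  if (!length(vals)) {
    stop("no sample with at least 2 defined residual entries", call. = FALSE)
  }
  if (method == "rms") {
    exp(sqrt(mean(vals^2)))
  } else {
    exp(mean(vals))
  }
}

#' Protocol summary table
#'
#' One row per statistic (max pairwise bias, average pairwise bias, average
#' pairwise noise), mirroring the summary rows of a bias-comparison table.
#'
#' @param bias Efficiency vector or `bias_fit`.
#' @param residuals Optional residual matrix; taken from the fit when `bias`
#'   is a `bias_fit`.
#' @return Data frame with columns `statistic` and `value`.
#' @export
bias_summary <- function(bias, residuals = NULL) {
  if (inherits(bias, "bias_fit") && is.null(residuals)) {
    residuals <- bias$residuals
  }
  b <- resolve_bias(bias)
  out <- data.frame(
    statistic = c("max_pairwise_bias", "avg_pairwise_bias"),
    value = c(max_pairwise_bias(b), avg_pairwise_bias(b))
  )
  if (!is.null(residuals)) {
    out <- rbind(out, data.frame(statistic = "avg_pairwise_noise",
                                 value = avg_pairwise_noise(residuals)))
  }
  out
}
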