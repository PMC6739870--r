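# Forward measurement model: observed ~ actual * bias, element-wise, with
# only ratios meaningful.  Bias may be supplied as a single efficiency
# vector, a fitted `bias_fit`, or an ordered list of per-step efficiency
# vectors, which compose by element-wise multiplication.

# Resolve a bias argument to a named (or bare) efficiency vector covering
# `taxa`; accepts a numeric vector, a bias_fit, a data.frame with
# taxon/efficiency columns, or a list of per-step vectors.
resolve_bias <- function(bias, taxa = NULL) {
  if (inherits(bias, "bias_fit")) {
    bias <- stats::coef(bias)
  } else if (is.data.frame(bias)) {
    if (!all(c("taxon", "efficiency") %in% names(bias))) {
      stop("bias data frame needs `taxon` and `efficiency` columns",
           call. = FALSE)
    }
    bias <- stats::setNames(bias$efficiency, bias$taxon)
  } else if (is.list(bias)) {
    bias <- Reduce(perturb, bias)
  }
  if (!is.null(taxa) && is.null(names(bias)) && length(bias) == length(taxa)) {
    names(bias) <- taxa
  }
  if (!is.null(taxa) && !is.null(names(bias))) {
    missing <- setdiff(taxa, names(bias))
    if (length(missing)) {
      stop("no efficiency available for taxa: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    bias <- bias[taxa]
  }
  bias
}

#' Predict the observed composition under multiplicative bias
#'
#' Applies the measurement model: the observed proportions are the closed
#' element-wise product of the actual composition and the protocol's
#' relative-efficiency (bias) vector.
#'
#' @param actual Actual composition (relative abundances; `NA` = taxon not in
#'   the sample).
#' @param bias Relative-efficiency vector, a [estimate_bias()] fit, or an
#'   ordered list of per-step efficiency vectors (composed by element-wise
#'   multiplication).  Must be defined and positive for every taxon defined
#'   in `actual`.
#' @return Observed proportions (defined entries sum to 1).
#' @examples
#' predict_observed(even_comp(3), c(1, 18, 6))  # 0.04 0.72 0.24
#' @export
predict_observed <- function(actual, bias) {
  bias <- resolve_bias(bias, names(actual))
  close_comp(perturb(actual, bias))
}

#' Sample mean efficiency
#'
#' The abundance-weighted average relative efficiency of a sample,
#' `sum_j Pr(actual)_j * B_j`.  It is the denominator of the observed
#' proportions and sets whether each taxon's proportion is over- or
#' under-estimated: the fold-error in taxon i's proportion equals
#' `B_i / sample_mean_efficiency`.  Because efficiencies are only relative,
#' the value depends on the bias normalization; it is computed here with the
#' bias standardized to geometric mean 1 over the sample's taxa (the
#' "relative to the average taxon" convention).
#'
#' @inheritParams predict_observed
#' @return Positive scalar.
#' @export
sample_mean_efficiency <- function(actual, bias) {
  bias <- resolve_bias(bias, names(actual))
  bias <- align_comp(actual, bias, "actual", "bias")
  def <- !is.na(actual)
  b <- gstandardize(bias[def])
  p <- close_comp(actual[def])
  sum(p * b)
}

#' Fold-change in the ratio of two taxa between samples
#'
#' `(x_s[i]/x_s[j]) / (x_t[i]/x_t[j])`.  Under multiplicative bias this
#' fold-change is invariant: it is identical whether computed on actual or on
#' observed compositions measured by the same protocol, because the
#' efficiencies cancel.
#'
#' @param x_s,x_t Compositions for the two samples (aligned by name).
#' @param i,j Taxon labels or indices, defined and positive in both samples.
#' @return Positive scalar.
#' @export
ratio_foldchange <- function(x_s, x_t, i, j) {
  x_t <- align_comp(x_s, x_t, "x_s", "x_t")
  vals <- c(x_s[i], x_s[j], x_t[i], x_t[j])
  if (anyNA(vals) || any(vals[c(2, 3, 4)] == 0)) {
    stop("taxa `i` and `j` must be defined and non-zero in both samples",
         call. = FALSE)
  }
  unname((x_s[[i]] / x_s[[j]]) / (x_t[[i]] / x_t[[j]]))
}
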