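# Calibration: compositional removal of an estimated bias from target
# measurements.  Because only ratios matter, dividing by the bias and
# re-closing automatically handles any difference in composition between the
# controls and the target samples, and calibrating a taxon subset equals the
# closed subcomposition of the full calibration.

#' Calibrate an observed composition with an estimated bias
#'
#' The calibrated estimate of the actual composition is the closed
#' compositional difference `observed / bias`.  Taxa observed in the target
#' but lacking an efficiency estimate cannot be calibrated: they are excluded
#' and the result is the calibrated subcomposition over the covered taxa
#' (listed in the `"excluded"` attribute).
#'
#' @param observed Observed composition: a named vector, or a samples x taxa
#'   matrix, of counts or proportions (`NA` = undefined).
#' @param bias Efficiency vector, `bias_fit`, or data frame with
#'   taxon/efficiency columns.  For matrices/named vectors, taxa are matched
#'   by label.
#' @return Calibrated proportions over the covered taxa, same shape as the
#'   input.
#' @examples
#' calibrate(c(0.04, 0.72, 0.24), c(1, 18, 6))  # 1/3 1/3 1/3
#' @export
calibrate <- function(observed, bias) {
  bias <- resolve_bias(bias)
  if (is.null(dim(observed))) {
    return(calibrate_one(observed, bias))
  }
  O <- as_abundance_matrix(observed, "observed")
  keep <- if (is.null(names(bias))) {
    colnames(O)
  } else {
    intersect(colnames(O), names(bias))
  }
  if (!length(keep)) {
    stop("no overlap between observed taxa and bias-covered taxa",
         call. = FALSE)
  }
  out <- O[, keep, drop = FALSE]
  for (s in seq_len(nrow(out))) {
    out[s, ] <- calibrate_one(out[s, ], bias)
  }
  excluded <- setdiff(colnames(O), keep)
  if (length(excluded)) {
    warning("taxa without an efficiency estimate excluded from ",
            "calibration: ", paste(excluded, collapse = ", "), call. = FALSE)
    attr(out, "excluded") <- excluded
  }
  out
}

calibrate_one <- function(observed, bias) {
  if (!is.null(names(observed)) && !is.null(names(bias))) {
    keep <- intersect(names(observed), names(bias))
    if (!length(keep)) {
      stop("no overlap between observed taxa and bias-covered taxa",
           call. = FALSE)
    }
    excluded <- setdiff(names(observed)[!is.na(observed)], keep)
    observed <- observed[keep]
    bias <- bias[keep]
    out <- close_comp(cdiff(observed, bias))
    if (length(excluded)) {
      attr(out, "excluded") <- excluded
    }
    return(out)
  }
  close_comp(cdiff(observed, bias))
}

#' Calibrate to a reference protocol
#'
#' Dividing by a differential-bias estimate `B(P/R)` converts a protocol-P
#' measurement into an estimate of the measurement the reference protocol R
#' would have produced on the same sample.  This makes measurements from
#' differently biased experiments comparable even when the true compositions
#' are unknown.
#'
#' @param observed Protocol P's measurement(s).
#' @param diff_bias Differential bias `B(P/R)` (vector or `bias_fit` from
#'   [estimate_differential_bias()]).
#' @return Calibrated proportions, as in [calibrate()].
#' @export
calibrate_to_reference <- function(observed, diff_bias) {
  calibrate(observed, diff_bias)
}

#' Calibration accuracy metrics
#'
#' Compares observed and calibrated proportion tables against the actual
#' compositions: mean squared error of proportions (over all samples and
#' defined taxa) and mean Bray-Curtis dissimilarity (per sample, averaged).
#' All tables are aligned by sample and taxon labels and restricted to the
#' taxa covered by the calibrated table; each row is closed before
#' comparison.
#'
#' @param actual,observed,calibrated Samples x taxa tables of proportions.
#' @return Data frame with one row per comparison (`observed`, `calibrated`)
#'   and columns `mse` and `bray_curtis`, with the proportional MSE reduction
#'   in the `"mse_reduction"` attribute.
#' @export
evaluate_calibration <- function(actual, observed, calibrated) {
  A <- as_abundance_matrix(actual, "actual")
  O <- as_abundance_matrix(observed, "observed")
  C <- as_abundance_matrix(calibrated, "calibrated")
  if (!setequal(rownames(A), rownames(O)) ||
      !setequal(rownames(A), rownames(C))) {
    stop("tables must share sample labels", call. = FALSE)
  }
  taxa <- colnames(C)
  if (!all(taxa %in% colnames(A)) || !all(taxa %in% colnames(O))) {
    stop("tables must share the calibrated taxa", call. = FALSE)
  }
  O <- O[rownames(A), taxa, drop = FALSE]
  C <- C[rownames(A), taxa, drop = FALSE]
  A <- A[, taxa, drop = FALSE]
  one <- function(est) {
    sq <- 0
    nsq <- 0
    bc <- numeric(nrow(A))
    for (s in seq_len(nrow(A))) {
      ok <- !is.na(A[s, ]) & !is.na(est[s, ])
      if (!any(ok)) {
        stop("sample ", rownames(A)[s], " has no comparable taxa",
             call. = FALSE)
      }
      pa <- close_comp(A[s, ok])
      pe <- close_comp(est[s, ok])
      sq <- sq + sum((pe - pa)^2)
      nsq <- nsq + sum(ok)
      bc[s] <- as.numeric(vegan::vegdist(rbind(pa, pe), method = "bray"))
    }
    c(mse = sq / nsq, bray_curtis = mean(bc))
  }
  m_obs <- one(O)
  m_cal <- one(C)
  out <- data.frame(comparison = c("observed", "calibrated"),
                    mse = c(m_obs["mse"], m_cal["mse"]),
                    bray_curtis = c(m_obs["bray_curtis"],
                                    m_cal["bray_curtis"]),
                    row.names = NULL)
  attr(out, "mse_reduction") <- 1 - m_cal[["mse"]] / m_obs[["mse"]]
  out
}
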