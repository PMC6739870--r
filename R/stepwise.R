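# Partitioning total-protocol bias into per-step biases, and predicting the
# component of bias due to marker-gene (16S) copy-number variation.
#
# Experiments that enter the same workflow at different points (cell
# mixtures, DNA mixtures, PCR-product mixtures) measure cumulative biases of
# nested step sets: B(cells) = B(extraction)*B(pcr)*B(seq), B(dna) =
# B(pcr)*B(seq), B(pcr_product) = B(seq).  Each step bias is therefore the
# compositional quotient of the cumulative biases of adjacent entry points,
# and the last entry point's bias is the final step itself.

#' Decompose cumulative biases into per-step biases
#'
#' @param estimates Ordered named list of cumulative relative-efficiency
#'   vectors (or `bias_fit`s), from the earliest entry point (traversing all
#'   steps) to the latest (traversing only the final steps).  All must cover
#'   the same taxa.
#' @param step_names Optional names for the resulting steps; defaults to
#'   `"entry_i/entry_(i+1)"` for the quotients and the last entry's own name.
#' @return Named list of per-step efficiency vectors, each standardized to
#'   geometric mean 1.  Their element-wise product is compositionally
#'   equivalent to the first entry point's total bias.
#' @examples
#' b_seq <- c(a = 1, b = 2)
#' b_dna <- perturb(c(a = 3, b = 1), b_seq)
#' decompose_steps(list(dna = b_dna, pcr_product = b_seq))
#' @export
decompose_steps <- function(estimates, step_names = NULL) {
  if (!is.list(estimates) || length(estimates) < 2) {
    stop("`estimates` must be a list of at least two cumulative bias ",
         "vectors", call. = FALSE)
  }
  vecs <- lapply(estimates, resolve_bias)
  taxa <- names(vecs[[1]])
  for (v in vecs[-1]) {
    if (!is.null(taxa) && !setequal(names(v), taxa)) {
      stop("entry-point estimates must cover the same taxa", call. = FALSE)
    }
  }
  n <- length(vecs)
  labels <- names(estimates)
  if (is.null(labels)) {
    labels <- paste0("entry", seq_len(n))
  }
  steps <- vector("list", n)
  for (i in seq_len(n - 1)) {
    steps[[i]] <- gstandardize(cdiff(vecs[[i]], align_comp(
      vecs[[i]], vecs[[i + 1]], labels[i], labels[i + 1])))
  }
  steps[[n]] <- gstandardize(vecs[[n]])
  names(steps) <- if (!is.null(step_names)) {
    step_names
  } else {
    c(paste0(labels[-n], "/", labels[-1]), labels[n])
  }
  steps
}

#' Compose per-step biases into a total bias
#'
#' @param steps List of per-step efficiency vectors.
#' @return Their element-wise product, standardized to geometric mean 1.
#' @export
compose_steps <- function(steps) {
  gstandardize(Reduce(perturb, steps))
}

#' Bias predicted from 16S copy number
#'
#' The bias that marker-gene copy-number (CN) variation alone would impose,
#' by mixture entry point: for cell mixtures it is the compositional vector
#' of 16S copies per genome; for DNA mixtures, copies per bp (copy number
#' divided by genome size); for PCR-product mixtures, the identity vector
#' (no CN bias).
#'
#' @param genomics Data frame with columns `taxon`, `copy_number` (16S copies
#'   per genome) and `genome_size_mbp` (both strictly positive).
#' @param mixture_type `"cells"`, `"dna"`, or `"pcr_product"`.
#' @param taxa Optional taxon subset/order; all must be present in
#'   `genomics`.
#' @return Named efficiency vector, geometric mean 1.
#' @export
cn_bias <- function(genomics, mixture_type = c("cells", "dna", "pcr_product"),
                    taxa = NULL) {
  mixture_type <- match.arg(mixture_type)
  req <- c("taxon", "copy_number", "genome_size_mbp")
  if (!all(req %in% names(genomics))) {
    stop("`genomics` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(taxa)) {
    taxa <- genomics$taxon
  }
  idx <- match(taxa, genomics$taxon)
  if (anyNA(idx)) {
    stop("missing genomics rows for taxa: ",
         paste(taxa[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  cn <- genomics$copy_number[idx]
  size <- genomics$genome_size_mbp[idx]
  if (any(cn <= 0) || any(size <= 0)) {
    stop("copy numbers and genome sizes must be strictly positive",
         call. = FALSE)
  }
  v <- switch(mixture_type,
              cells = cn,
              dna = cn / size,
              pcr_product = rep(1, length(taxa)))
  gstandardize(stats::setNames(v, taxa))
}

#' Copy-number correction of an observed composition
#'
#' Divides the observed composition by the CN-predicted bias and re-closes,
#' the standard "16S copy-number correction".
#'
#' @param observed Observed composition (vector or samples x taxa matrix).
#' @param cnb CN bias vector from [cn_bias()].
#' @return CN-corrected proportions.
#' @export
cn_correct <- function(observed, cnb) {
  calibrate(observed, cnb)
}

#' Fraction of bias variance explained by a predictor
#'
#' Compares an estimated bias vector to a predicted one (e.g. copy-number
#' bias) on the log relative-efficiency scale, using the predictor as-is with
#' no fitted coefficients:
#' `1 - ||target/predictor||^2 / ||target||^2` in the Aitchison norm over the
#' shared taxa.  Equals 1 when the predictor matches the target exactly, 0
#' when it predicts nothing (identity vector), and can be negative when it
#' predicts in the wrong direction.  `method = "ols"` instead reports the R
#' squared of an ordinary regression of clr(target) on clr(predictor).
#'
#' @param target Estimated bias vector.
#' @param predictor Predicted bias vector over the same taxa (>= 3 shared).
#' @param method `"aitchison"` (slope-free, default) or `"ols"`.
#' @return Scalar fraction (possibly negative).
#' @export
variance_explained <- function(target, predictor,
                               method = c("aitchison", "ols")) {
  method <- match.arg(method)
  if (!is.null(names(target)) && !is.null(names(predictor))) {
    shared <- intersect(names(target)[!is.na(target)],
                        names(predictor)[!is.na(predictor)])
    target <- target[shared]
    predictor <- predictor[shared]
  }
  predictor <- align_comp(target, predictor, "target", "predictor")
  if (sum(!is.na(target)) < 3) {
    stop("fewer than 3 shared taxa", call. = FALSE)
  }
  if (method == "ols") {
    return(summary(stats::lm(clr(target) ~ clr(predictor)))$r.squared)
  }
  1 - anorm(cdiff(target, predictor))^2 / anorm(target)^2
}

# All permutations of 1..n as a matrix (n! rows).
all_perms <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1, 1))
  }
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(rep.int(i, nrow(sub)), sub + (sub >= i))
  }))
}

#' Permutation test for variance explained
#'
#' Tests whether the predictor explains more of the target bias than chance
#' by permuting the predictor's taxon assignment.  With `K <= 8` shared taxa
#' all `K!` permutations are enumerated exhaustively; otherwise `n_perm`
#' random permutations are drawn.  The one-sided p-value is the fraction of
#' permutations (the identity included) whose variance explained is at least
#' the observed value.
#'
#' @inheritParams variance_explained
#' @param n_perm Number of random permutations when `K > 8`.
#' @param seed Optional seed for the random-permutation case.
#' @return List with `statistic` (observed variance explained), `p_value`,
#'   and `n_perm` (permutations evaluated).
#' @export
permutation_pvalue <- function(target, predictor, n_perm = 2000, seed = NULL,
                               method = c("aitchison", "ols")) {
  method <- match.arg(method)
  if (!is.null(names(target)) && !is.null(names(predictor))) {
    shared <- intersect(names(target)[!is.na(target)],
                        names(predictor)[!is.na(predictor)])
    target <- target[shared]
    predictor <- predictor[shared]
  }
  predictor <- align_comp(target, predictor, "target", "predictor")
  k <- length(target)
  if (k < 3) {
    stop("fewer than 3 shared taxa", call. = FALSE)
  }
  obs <- variance_explained(target, predictor, method = method)
  if (k <= 8) {
    perms <- all_perms(k)
  } else {
    if (!is.null(seed)) {
      set.seed(seed)
    }
    perms <- rbind(seq_len(k),
                   t(replicate(n_perm - 1, sample.int(k))))
  }
  vals <- apply(perms, 1, function(ix) {
    p <- unname(predictor[ix])
    names(p) <- names(target)
    variance_explained(target, p, method = method)
  })
  list(statistic = obs,
       p_value = mean(vals >= obs - 1e-12),
       n_perm = nrow(perms))
}
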