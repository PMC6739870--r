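# Compositional vectors are plain numeric vectors, usually named by taxon,
# in which only the ratios among entries carry meaning.  NA marks a taxon
# that is not part of the sample's design ("undefined"), which is distinct
# from 0, a designed-in taxon that was not detected.  Operations align by
# taxon label whenever names are present; a label mismatch is an error,
# never a silent reindexing.

# Align y to x's taxon order.  Both named (same label set) or both unnamed
# (same length); anything else is an error.
align_comp <- function(x, y, xname = "x", yname = "y") {
  nx <- names(x)
  ny <- names(y)
  if (is.null(nx) != is.null(ny)) {
    # one bare vector against a named one: align positionally
    if (length(x) == length(y)) {
      names(y) <- nx
      return(y)
    }
    stop("compositions `", xname, "` and `", yname,
         "` must both be named or both unnamed", call. = FALSE)
  }
  if (is.null(nx)) {
    if (length(x) != length(y)) {
      stop("unnamed compositions must have equal length", call. = FALSE)
    }
    return(y)
  }
  if (anyDuplicated(nx) || anyDuplicated(ny)) {
    stop("duplicate taxon labels", call. = FALSE)
  }
  if (!setequal(nx, ny)) {
    stop("taxon labels of `", xname, "` and `", yname, "` do not match (",
         paste(union(setdiff(nx, ny), setdiff(ny, nx)), collapse = ", "),
         ")", call. = FALSE)
  }
  y[nx]
}

check_comp <- function(x, positive = FALSE, name = "x") {
  if (!is.numeric(x) || length(x) == 0) {
    stop("`", name, "` must be a non-empty numeric vector", call. = FALSE)
  }
  def <- !is.na(x)
  if (!any(def)) {
    stop("`", name, "` has no defined entries", call. = FALSE)
  }
  if (any(x[def] < 0)) {
    stop("`", name, "` has negative entries", call. = FALSE)
  }
  if (positive) {
    if (any(x[def] == 0)) {
      stop("`", name, "` must be strictly positive on defined entries",
           call. = FALSE)
    }
  } else if (!any(x[def] > 0)) {
    stop("all defined entries of `", name, "` are zero", call. = FALSE)
  }
  invisible(def)
}

#' Close a composition to proportions
#'
#' Divides the defined (non-`NA`) entries of a compositional vector by their
#' sum so that they sum to 1.  Undefined entries stay `NA`.  Closure does not
#' change the meaning of a composition: the result is compositionally
#' equivalent to the input.
#'
#' @param x Numeric vector of non-negative relative abundances; `NA` marks a
#'   taxon that is not part of the sample.
#' @return A vector of proportions with the same names and defined mask.
#' @examples
#' close_comp(c(1, 18, 6))            # 0.04 0.72 0.24
#' close_comp(c(a = 2, b = NA, c = 6))
#' @export
close_comp <- function(x) {
  def <- check_comp(x, name = "x")
  x[def] <- x[def] / sum(x[def])
  x
}

#' Even composition over a set of taxa
#'
#' @param taxa Character vector of taxon labels, or a single integer count.
#' @return Closed composition with equal proportions.
#' @export
even_comp <- function(taxa) {
  if (is.numeric(taxa) && length(taxa) == 1) {
    taxa <- paste0("taxon", seq_len(taxa))
  }
  stats::setNames(rep(1 / length(taxa), length(taxa)), taxa)
}

#' Perturb a composition by another (element-wise product)
#'
#' The perturbation `x * y` is the compositional analogue of translation; a
#' measurement model in which bias acts multiplicatively writes the observed
#' composition as the actual composition perturbed by the protocol's bias.
#'
#' @param x,y Compositional vectors over the same taxa (aligned by name when
#'   named).  Every taxon defined in `x` must be defined in `y`.
#' @return Element-wise product; `NA` where `x` is undefined.
#' @export
perturb <- function(x, y) {
  y <- align_comp(x, y, "x", "y")
  def <- check_comp(x, name = "x")
  if (any(def & is.na(y))) {
    bad <- which(def & is.na(y))
    stop("efficiency undefined for taxa present in `x`: ",
         paste(if (is.null(names(x))) bad else names(x)[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- x * y
  out[!def] <- NA_real_
  out
}

#' Compositional difference (element-wise quotient)
#'
#' `cdiff(x, y)` inverts [perturb()]: `cdiff(perturb(a, b), b)` is
#' compositionally equivalent to `a`.  The compositional difference between
#' observed and actual compositions is the protocol's bias.
#'
#' @inheritParams perturb
#' @return Element-wise quotient `x / y`; `NA` where `x` is undefined.
#' @export
cdiff <- function(x, y) {
  y <- align_comp(x, y, "x", "y")
  def <- check_comp(x, name = "x")
  if (any(def & (is.na(y) | y <= 0))) {
    bad <- which(def & (is.na(y) | y <= 0))
    stop("division by zero or undefined entry of `y` for taxa: ",
         paste(if (is.null(names(x))) bad else names(x)[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- x / y
  out[!def] <- NA_real_
  out
}

#' Centered log-ratio (clr) coordinates
#'
#' Log of each defined entry minus the mean log over defined entries.  The
#' clr coordinates sum to zero, and their Euclidean norm equals the Aitchison
#' norm of the composition.
#'
#' @param x Composition, strictly positive on defined entries.
#' @return Numeric vector over the defined taxa only (undefined taxa are
#'   dropped), named when `x` is named.
#' @export
clr <- function(x) {
  def <- check_comp(x, positive = TRUE, name = "x")
  lx <- log(x[def])
  lx - mean(lx)
}

#' Aitchison norm of a composition
#'
#' The log-ratio magnitude of a composition: the Euclidean norm of its clr
#' coordinates, equivalently `sqrt(1/K * sum_{i<j} log(x_i/x_j)^2)` over the
#' K defined entries.  It is zero exactly for uniform compositions and is
#' invariant to rescaling.  Undefined entries are excluded (with K adjusted
#' accordingly), which is how residuals of samples missing some taxa are
#' measured.
#'
#' @inheritParams clr
#' @return Non-negative scalar.
#' @export
anorm <- function(x) {
  sqrt(sum(clr(x)^2))
}

#' Standardize a composition to geometric mean 1
#'
#' Divides the defined entries by their geometric mean.  This is the
#' reporting convention for relative efficiencies ("relative to the average
#' taxon") and the canonical representative of a composition's equivalence
#' class.
#'
#' @inheritParams clr
#' @return Composition equivalent to `x` with geometric mean 1 over defined
#'   entries.
#' @export
gstandardize <- function(x) {
  def <- check_comp(x, positive = TRUE, name = "x")
  x[def] <- x[def] / exp(mean(log(x[def])))
  x
}

#' Test compositional equivalence
#'
#' Two compositions are equivalent when their defined masks match and their
#' defined entries are proportional (`x = a * y` for some `a > 0`).
#'
#' @inheritParams perturb
#' @param tol Relative tolerance on the closed proportions.
#' @return Logical scalar.
#' @export
comp_equal <- function(x, y, tol = 1e-9) {
  y <- align_comp(x, y, "x", "y")
  if (!identical(is.na(x), is.na(y))) {
    return(FALSE)
  }
  cx <- close_comp(x)
  cy <- close_comp(y)
  def <- !is.na(cx)
  all(abs(cx[def] - cy[def]) <= tol)
}
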