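# Simulation of mock-community control experiments with known bias, so that
# every estimation and calibration path can be validated without external
# data.  Observed compositions follow the model
#   O(s) ~ A(s) * B * eps(s),
# where eps(s) is a random composition with identity geometric mean:
# clr-normal (log-scale, zero-centered) noise, optionally followed by
# multinomial read sampling at a fixed depth.

#' Construct a simulation design
#'
#' @param taxa Character vector of taxon labels.
#' @param actual Samples x taxa matrix of true compositions (`NA` = taxon not
#'   in that sample's design).
#' @param bias True relative-efficiency vector covering `taxa`.
#' @param noise_sd Standard deviation of the clr-normal noise, in log units
#'   (0 = deterministic measurement).
#' @param depth Optional reads per sample; when given, observed tables are
#'   multinomial counts at this depth, otherwise noisy proportions.
#' @param known Logical matrix like `actual`: which actual values are
#'   disclosed to the estimator (e.g. only spike-in taxa).  Default: all
#'   defined values.
#' @return Object of class `sim_design`; its `identifiable` field reports
#'   whether the design's taxon overlap graph is connected.
#' @export
simulation_design <- function(taxa, actual, bias, noise_sd = 0, depth = NULL,
                              known = NULL) {
  A <- as_abundance_matrix(actual, "actual")
  if (!setequal(colnames(A), taxa)) {
    stop("`actual` columns must match `taxa`", call. = FALSE)
  }
  A <- A[, taxa, drop = FALSE]
  bias <- resolve_bias(bias, taxa)
  if (any(is.na(bias)) || any(bias <= 0)) {
    stop("`bias` must be strictly positive over `taxa`", call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  if (!is.null(depth) && (depth < 1 || depth != round(depth))) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  if (is.null(known)) {
    known <- !is.na(A)
  }
  comps <- check_identifiability(ifelse(known & !is.na(A), A, NA))
  structure(list(taxa = taxa, actual = A, bias = gstandardize(bias),
                 noise_sd = noise_sd, depth = depth, known = known,
                 identifiable = length(comps) == 1, components = comps),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Simulation design:", nrow(x$actual), "samples x", length(x$taxa),
      "taxa\n  noise_sd =", x$noise_sd,
      if (is.null(x$depth)) "(proportions)" else paste("depth =", x$depth),
      "\n  identifiable:", x$identifiable, "\n")
  invisible(x)
}

#' Simulate a control experiment
#'
#' Draws observed tables from a [simulation_design()]: each sample's true
#' composition is perturbed by the true bias, multiplied by centered
#' log-normal (clr-normal) noise, closed to proportions, and optionally
#' sampled multinomially at the design's read depth.
#'
#' @param design A `sim_design`.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   tables.
#' @return List of class `control_experiment` with elements `observed`
#'   (proportions or counts), `actual` (true compositions, `NA` where not
#'   disclosed by the design), `truth` (full true compositions), and `bias`.
#' @export
simulate_experiment <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) {
    set.seed(seed)
  }
  A <- design$actual
  O <- A
  for (s in seq_len(nrow(A))) {
    def <- which(!is.na(A[s, ]))
    mu <- A[s, def] * design$bias[def]
    if (design$noise_sd > 0 && length(def) > 1) {
      z <- stats::rnorm(length(def), 0, design$noise_sd)
      mu <- mu * exp(z - mean(z))
    }
    p <- mu / sum(mu)
    O[s, def] <- if (is.null(design$depth)) {
      p
    } else {
      drop(stats::rmultinom(1, design$depth, p))
    }
  }
  actual_out <- A
  actual_out[!design$known] <- NA_real_
  structure(list(observed = O, actual = actual_out, truth = A,
                 bias = design$bias, design = design),
            class = "control_experiment")
}

#' Even-mixture control design over taxon subsets
#'
#' Each sample is an even mixture of a subset of the taxa (undefined
#' elsewhere), the classic mock-community design in which 2-7 taxa are mixed
#' at equal nominal abundance.
#'
#' @param taxa All taxon labels.
#' @param subsets List of character vectors (each of size >= 2), one sample
#'   per subset.
#' @inheritParams simulation_design
#' @return A `sim_design`; check its `identifiable` field before estimating
#'   from disjoint subsets.
#' @export
make_even_subset_design <- function(taxa, subsets, bias, noise_sd = 0,
                                    depth = NULL) {
  if (any(lengths(subsets) < 2)) {
    stop("every subset must contain at least 2 taxa", call. = FALSE)
  }
  bad <- setdiff(unlist(subsets), taxa)
  if (length(bad)) {
    stop("subset taxa not in `taxa`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  A <- matrix(NA_real_, length(subsets), length(taxa),
              dimnames = list(paste0("sample", seq_along(subsets)), taxa))
  for (s in seq_along(subsets)) {
    A[s, subsets[[s]]] <- 1 / length(subsets[[s]])
  }
  simulation_design(taxa, A, bias, noise_sd = noise_sd, depth = depth)
}

#' Spike-in control design with variable background
#'
#' Emulates adding a fixed mock community ("spike-in") of known composition
#' to natural samples whose background composition varies and is unknown.
#' Each sample mixes the closed mock composition (weight = the sample's spike
#' fraction) with a random background composition.  Only the mock taxa's
#' actual values are disclosed to the estimator; because ratios within the
#' spike-in are unaffected by the background, its subcomposition suffices to
#' estimate bias for the mock taxa.
#'
#' @param mock_taxa Labels of the spike-in taxa.
#' @param mock_composition Known spike-in composition; default spans 2.5
#'   orders of magnitude log-uniformly across the mock taxa.
#' @param background_taxa Labels of the background taxa.
#' @param n_samples Number of samples.
#' @param spike_fraction_range Range (in (0, 1]) from which each sample's
#'   spike-in proportion is drawn uniformly.
#' @param bias True efficiency vector over all taxa.
#' @param background_sampler Function of one argument (number of background
#'   taxa) returning positive abundances; default log-normal with sd 2 log
#'   units, mimicking order-of-magnitude variation across natural
#'   communities.
#' @param seed Optional seed for the background/spike-fraction draws.
#' @inheritParams simulation_design
#' @return A `sim_design` whose `known` matrix discloses only mock taxa.
#' @export
make_spikein_design <- function(mock_taxa, mock_composition = NULL,
                                background_taxa, n_samples,
                                spike_fraction_range = c(0.05, 0.5),
                                bias, noise_sd = 0, depth = NULL,
                                background_sampler = NULL, seed = NULL) {
  if (!is.null(seed)) {
    set.seed(seed)
  }
  if (is.null(mock_composition)) {
    mock_composition <- stats::setNames(
      10^seq(0, 2.5, length.out = length(mock_taxa)), mock_taxa)
  }
  if (any(is.na(mock_composition)) || any(mock_composition <= 0)) {
    stop("`mock_composition` must be strictly positive", call. = FALSE)
  }
  f_lo <- spike_fraction_range[1]
  f_hi <- spike_fraction_range[2]
  if (f_lo <= 0 || f_hi > 1 || f_lo > f_hi) {
    stop("`spike_fraction_range` must lie in (0, 1]", call. = FALSE)
  }
  if (!length(background_taxa) && f_hi < 1) {
    stop("empty background requires spike fraction 1", call. = FALSE)
  }
  if (is.null(background_sampler)) {
    background_sampler <- function(k) exp(stats::rnorm(k, 0, 2))
  }
  taxa <- c(mock_taxa, background_taxa)
  mock_p <- close_comp(mock_composition[mock_taxa])
  A <- matrix(NA_real_, n_samples, length(taxa),
              dimnames = list(paste0("sample", seq_len(n_samples)), taxa))
  for (s in seq_len(n_samples)) {
    f <- stats::runif(1, f_lo, f_hi)
    A[s, mock_taxa] <- f * mock_p
    if (length(background_taxa)) {
      bg <- background_sampler(length(background_taxa))
      A[s, background_taxa] <- (1 - f) * bg / sum(bg)
    }
  }
  known <- matrix(FALSE, n_samples, length(taxa),
                  dimnames = dimnames(A))
  known[, mock_taxa] <- TRUE
  simulation_design(taxa, A, bias, noise_sd = noise_sd, depth = depth,
                    known = known)
}
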