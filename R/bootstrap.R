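# Bootstrap bias correction, standard errors and basic (reverse-percentile)
# confidence intervals.  Plug-in entropy estimators over-fit sparse count
# tables, so raw mutual-information-based indices are typically biased upward
# on small samples; subtracting the bootstrap-estimated bias (mean replicate
# minus raw) gives the corrected estimate 2*raw - mean(replicates).

# One multinomial resample.  scheme = "within": each group's column is redrawn
# with its total fixed (groups are the fixed design axis — their weights are
# supplied, not estimated).  scheme = "joint": the grand total is redrawn from
# the joint count distribution, so group totals vary too.
.bc_resample <- function(ensemble, scheme = "within") {
  counts <- ensemble$counts
  if (scheme == "within") {
    new_counts <- vapply(seq_len(ncol(counts)), function(j) {
      n_j <- sum(counts[, j])
      drop(stats::rmultinom(1, n_j, counts[, j] / n_j))
    }, numeric(nrow(counts)))
    dimnames(new_counts) <- dimnames(counts)
  } else {
    new_counts <- counts
    new_counts[] <- stats::rmultinom(1, sum(counts), as.vector(counts))
    # a group column can come back empty under joint resampling; redraw
    while (any(colSums(new_counts) == 0))
      new_counts[] <- stats::rmultinom(1, sum(counts), as.vector(counts))
  }
  bc_ensemble(new_counts, weights = ensemble$weights)
}

.check_integer_counts <- function(ensemble) {
  if (any(abs(ensemble$counts - round(ensemble$counts)) > 1e-8))
    stop("bootstrap resampling needs raw integer counts; ",
         "pre-normalized frequency tables cannot be resampled",
         call. = FALSE)
}

# b x n_stat matrix of index replicates sharing one resample stream.
.bc_boot_matrix <- function(ensemble, b, seed = NULL, scheme = "within",
                            marginal = "weights") {
  if (!is.null(seed)) set.seed(seed)
  t(vapply(seq_len(b), function(r) {
    .bc_stat_vector(bc_frequencies(.bc_resample(ensemble, scheme),
                                   marginal = marginal))
  }, .bc_stat_vector(bc_frequencies(ensemble, marginal = marginal))))
}

# Summarize one replicate column into the bias-corrected estimate, SE and
# basic CI, clipping corrected value and CI endpoints to the statistic's
# theoretical range (pre-clip values retained).
.bc_boot_summary <- function(raw, reps, alpha, range) {
  reps_ok <- reps[!is.na(reps)]
  corrected_raw <- 2 * raw - mean(reps_ok)
  q <- stats::quantile(reps_ok, c(alpha / 2, 1 - alpha / 2),
                       names = FALSE, type = 7)
  ci_raw <- c(2 * raw - q[2], 2 * raw - q[1])
  list(raw = raw,
       bias = mean(reps_ok) - raw,
       corrected = min(max(corrected_raw, range[1]), range[2]),
       corrected_unclipped = corrected_raw,
       se = stats::sd(reps_ok),
       ci = pmin(pmax(ci_raw, range[1]), range[2]),
       ci_unclipped = ci_raw,
       n_na = sum(is.na(reps)))
}

#' Bootstrap a biocultural index
#'
#' Generates `b` resampled ensembles — by default redrawing each group's
#' counts multinomially with the group total fixed — recomputes the chosen
#' statistic on each, and returns the bias-corrected estimate
#' (`2 * raw - mean(replicates)`), the standard error (SD of replicates) and
#' the basic bootstrap confidence interval
#' `(2*raw - upper percentile, 2*raw - lower percentile)` at level
#' `1 - alpha`.  Corrected estimate and CI endpoints are clipped to the
#' statistic's theoretical range (e.g. `[1, c]` for the complexity); the
#' unclipped values are kept alongside.
#'
#' @param ensemble a [bc_ensemble] (or count matrix) with integer counts.
#' @param statistic which index to bootstrap: `"BC"` (complexity, default),
#'   `"I"` (mutual information), or a per-unit index named as
#'   `"spec:<taxon>"`, `"rspec:<taxon>"`, `"specia:<group>"`,
#'   `"rspecia:<group>"`, `"sdiv:<group>"`.  Alternatively a function
#'   `ensemble -> scalar` (no clipping applied).
#' @param b number of bootstrap replicates (default 1000).
#' @param alpha significance level for the CI (default 0.05).
#' @param seed optional integer seed; identical inputs and seed give a
#'   bit-identical result.
#' @param scheme `"within"` (default) keeps each group's total fixed;
#'   `"joint"` resamples the grand total from the joint distribution.
#' @param marginal passed to [bc_frequencies()].
#' @return an object of class `"bc_boot"`: raw estimate, bias, corrected
#'   estimate, se, ci (length 2), their unclipped counterparts, replicate
#'   count, seed, scheme and the replicate vector.
#' @examples
#' bc_bootstrap(artificial_ensemble(), "BC", b = 200, seed = 1)
#' @export
bc_bootstrap <- function(ensemble, statistic = "BC", b = 1000, alpha = 0.05,
                         seed = NULL, scheme = c("within", "joint"),
                         marginal = c("weights", "counts")) {
  ensemble <- .as_ensemble(ensemble)
  scheme <- match.arg(scheme)
  marginal <- match.arg(marginal)
  .check_integer_counts(ensemble)
  if (b < 2) stop("'b' must be at least 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)

  s <- length(ensemble$species); c_ <- length(ensemble$groups)
  if (is.function(statistic)) {
    if (!is.null(seed)) set.seed(seed)
    raw <- statistic(ensemble)
    reps <- vapply(seq_len(b),
                   function(r) statistic(.bc_resample(ensemble, scheme)),
                   numeric(1))
    rng <- c(-Inf, Inf)
    stat_name <- "custom"
  } else {
    fr <- bc_frequencies(ensemble, marginal = marginal)
    full <- .bc_stat_vector(fr)
    if (!statistic %in% names(full))
      stop("unknown statistic '", statistic, "'; available: ",
           paste(names(full), collapse = ", "), call. = FALSE)
    raw <- full[[statistic]]
    reps <- .bc_boot_matrix(ensemble, b, seed, scheme, marginal)[, statistic]
    rng <- .bc_stat_range(statistic, s, c_)
    stat_name <- statistic
  }
  out <- .bc_boot_summary(raw, reps, alpha, rng)
  out$statistic <- stat_name
  out$replicates <- b
  out$alpha <- alpha
  out$seed <- seed
  out$scheme <- scheme
  out$values <- reps
  class(out) <- "bc_boot"
  out
}

#' @export
print.bc_boot <- function(x, digits = 4, ...) {
  cat("Bootstrap of '", x$statistic, "' (", x$replicates, " replicates, ",
      x$scheme, "-group resampling",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), ")\n", sep = "")
  cat("  raw ", round(x$raw, digits),
      "  bias ", round(x$bias, digits),
      "  corrected ", round(x$corrected, digits),
      "  se ", round(x$se, digits), "\n", sep = "")
  cat("  ", format(100 * (1 - x$alpha)), "% basic CI [",
      round(x$ci[1], digits), ", ", round(x$ci[2], digits), "]\n", sep = "")
  if (x$n_na > 0)
    cat("  (", x$n_na, " replicates dropped: statistic undefined)\n", sep = "")
  invisible(x)
}

#' Bootstrap every index of an ensemble from one shared replicate stream
#'
#' Runs the same resampling engine as [bc_bootstrap()] but recomputes *all*
#' indices (specificities, relative specificities, specializations, relative
#' specializations, per-group Shannon diversities, mutual information and
#' complexity) on each of the `b` resampled ensembles, so the corrected
#' values and standard errors of different indices are mutually consistent.
#'
#' @inheritParams bc_bootstrap
#' @return a list of class `"bc_boot_report"` with one [bc_bootstrap()]-style
#'   summary per statistic (element names as in the `statistic` argument of
#'   [bc_bootstrap()]), plus `replicates`, `alpha`, `seed`, `scheme`.
#' @examples
#' rep <- bc_bootstrap_report(artificial_ensemble(), b = 200, seed = 1)
#' rep$stats[["BC"]]$corrected
#' @export
bc_bootstrap_report <- function(ensemble, b = 1000, alpha = 0.05, seed = NULL,
                                scheme = c("within", "joint"),
                                marginal = c("weights", "counts")) {
  ensemble <- .as_ensemble(ensemble)
  scheme <- match.arg(scheme)
  marginal <- match.arg(marginal)
  .check_integer_counts(ensemble)
  if (b < 2) stop("'b' must be at least 2", call. = FALSE)

  s <- length(ensemble$species); c_ <- length(ensemble$groups)
  full <- .bc_stat_vector(bc_frequencies(ensemble, marginal = marginal))
  mat <- .bc_boot_matrix(ensemble, b, seed, scheme, marginal)
  stats_list <- lapply(names(full), function(nm) {
    if (is.na(full[[nm]]))  # undefined raw statistic (all-zero taxon)
      return(list(raw = NA_real_, bias = NA_real_, corrected = NA_real_,
                  se = NA_real_, ci = c(NA_real_, NA_real_), n_na = b))
    .bc_boot_summary(full[[nm]], mat[, nm], alpha,
                     .bc_stat_range(nm, s, c_))
  })
  names(stats_list) <- names(full)
  structure(list(stats = stats_list, replicates = b, alpha = alpha,
                 seed = seed, scheme = scheme),
            class = "bc_boot_report")
}
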