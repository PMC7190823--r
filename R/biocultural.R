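#' Fit the biocultural-complexity model to a count table
#'
#' The main entry point of the package.  Given a taxa-by-groups interaction
#' count table (and optional group weights), it computes the full set of
#' information indices in the canonical order — per-taxon specificities,
#' per-group specializations, the mutual information `I(S;C)` via the
#' specificity decomposition, and the biocultural complexity `BC = 2^I` —
#' together with per-group Shannon diversities and the relative (normalized)
#' indices, and, by default, bootstrap bias corrections, standard errors and
#' a basic confidence interval for every one of them from a single shared
#' replicate stream.
#'
#' Both decompositions of the mutual information,
#' \eqn{I = \sum_i f_{i.} S_i = \sum_j f_{.j} \delta_j}, are computed and
#' cross-checked internally (tolerance 1e-9).
#'
#' @param x a [bc_ensemble], a count matrix/data frame (taxa in rows), or a
#'   file path accepted by [read_ensemble()].
#' @param weights optional positive group weights (ignored when `x` is
#'   already an ensemble); default equiprobable.
#' @param boot logical; run the bootstrap (default TRUE).  Requires integer
#'   counts.
#' @param b,alpha,scheme bootstrap settings, see [bc_bootstrap()].
#' @param seed optional integer seed governing all randomness of the fit.
#' @param marginal group-marginal source, see [bc_frequencies()].
#' @param ... passed to [read_ensemble()] when `x` is a file path.
#' @return an object of class `"biocultural"`: a list with elements
#'   `ensemble`, `frequencies`, `species` (per-taxon data frame:
#'   `specificity`, `rel_specificity` and their `cor_`/`se_` columns),
#'   `groups` (per-group data frame: `specialization`, `rel_specialization`,
#'   `shannon_diversity` and `cor_`/`se_` columns), `mutual_information`,
#'   `complexity`, `boot` (the [bc_bootstrap_report()] result or NULL),
#'   `b`, `alpha`, `seed`, `scheme` and `call`.  Methods: [print()],
#'   [summary()], [coef()], [confint()], [simulate()], [plot()],
#'   [residuals()].
#' @examples
#' fit <- biocultural(artificial_ensemble(), b = 200, seed = 42)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
biocultural <- function(x, weights = NULL, boot = TRUE, b = 1000,
                        alpha = 0.05, seed = NULL,
                        scheme = c("within", "joint"),
                        marginal = c("weights", "counts"), ...) {
  cl <- match.call()
  scheme <- match.arg(scheme)
  marginal <- match.arg(marginal)
  ensemble <- if (is.character(x) && length(x) == 1L) read_ensemble(x, ...)
              else if (inherits(x, "bc_ensemble")) x
              else bc_ensemble(x, weights = weights)
  if (any(ensemble$zero_species))
    warning("taxa with zero total count have undefined specificity: ",
            paste(ensemble$species[ensemble$zero_species], collapse = ", "),
            call. = FALSE)

  fr <- bc_frequencies(ensemble, marginal = marginal)
  S <- taxon_specificity(fr)
  d <- group_specialization(fr, specificities = S)
  H <- group_diversity(fr)
  c_ <- length(ensemble$groups)
  lc <- log2(c_)

  I_species <- sum(fr$species_marginal * S, na.rm = TRUE)
  I_groups <- sum(fr$group_marginal * d)
  if (abs(I_species - I_groups) > 1e-9)
    stop("internal error: the two decompositions of the mutual information ",
         "disagree (", I_species, " vs ", I_groups, ")")
  I <- I_species
  BC <- 2^I

  rel <- function(v) if (lc > 0) v / lc else rep(NA_real_, length(v))
  species <- data.frame(row.names = ensemble$species,
                        specificity = unname(S),
                        rel_specificity = unname(rel(S)))
  groups <- data.frame(row.names = ensemble$groups,
                       specialization = unname(d),
                       rel_specialization = unname(rel(d)),
                       shannon_diversity = unname(H))

  boot_rep <- NULL
  if (boot) {
    boot_rep <- bc_bootstrap_report(ensemble, b = b, alpha = alpha,
                                    seed = seed, scheme = scheme,
                                    marginal = marginal)
    pull <- function(prefix, labels, field)
      vapply(paste0(prefix, labels),
             function(nm) boot_rep$stats[[nm]][[field]], numeric(1))
    sl <- ensemble$species; gl <- ensemble$groups
    species$cor_specificity <- unname(pull("spec:", sl, "corrected"))
    species$se_specificity <- unname(pull("spec:", sl, "se"))
    species$cor_rel_specificity <- unname(pull("rspec:", sl, "corrected"))
    species$se_rel_specificity <- unname(pull("rspec:", sl, "se"))
    groups$cor_specialization <- unname(pull("specia:", gl, "corrected"))
    groups$se_specialization <- unname(pull("specia:", gl, "se"))
    groups$cor_rel_specialization <- unname(pull("rspecia:", gl, "corrected"))
    groups$se_rel_specialization <- unname(pull("rspecia:", gl, "se"))
    groups$cor_shannon_diversity <- unname(pull("sdiv:", gl, "corrected"))
    groups$se_shannon_diversity <- unname(pull("sdiv:", gl, "se"))
  }

  structure(
    list(ensemble = ensemble, frequencies = fr,
         species = species, groups = groups,
         mutual_information = I, complexity = BC,
         boot = boot_rep, b = if (boot) b else NULL, alpha = alpha,
         seed = seed, scheme = scheme, marginal = marginal, call = cl),
    class = "biocultural")
}

#' @export
print.biocultural <- function(x, digits = 2, ...) {
  s <- length(x$ensemble$species); c_ <- length(x$ensemble$groups)
  cat("Biocultural complexity model: ", s, " taxa x ", c_,
      " cultural groups\n", sep = "")
  cat("  Mutual information I(S;C): ",
      round(x$mutual_information, max(digits, 4)), " bits (max ",
      round(log2(c_), max(digits, 4)), ")\n", sep = "")
  cat("  Biocultural complexity:    ", round(x$complexity, digits),
      " effective units (of ", c_, " groups)\n", sep = "")
  if (!is.null(x$boot)) {
    bt <- x$boot$stats[["BC"]]
    cat("  Bias-corrected complexity: ", round(bt$corrected, digits),
        "  (", format(100 * (1 - x$alpha)), "% CI ",
        round(bt$ci[1], digits), "-", round(bt$ci[2], digits),
        ", b = ", x$boot$replicates, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.biocultural <- function(object, ...) {
  c(mutual_information = object$mutual_information,
    complexity = object$complexity)
}

#' Confidence interval for the biocultural complexity
#'
#' Returns the basic-bootstrap interval computed by the fit, clipped to the
#' theoretical range `[1, c]`.
#'
#' @param object a fitted [biocultural] model with `boot = TRUE`.
#' @param parm statistic name as in [bc_bootstrap()]; default `"BC"`.
#' @param level ignored: the level is fixed by `alpha` at fit time.
#' @param ... unused.
#' @return a 1 x 2 matrix of interval endpoints.
#' @export
confint.biocultural <- function(object, parm = "BC", level, ...) {
  if (is.null(object$boot))
    stop("the model was fitted with boot = FALSE; no intervals available",
         call. = FALSE)
  out <- t(vapply(parm, function(p) object$boot$stats[[p]]$ci, numeric(2)))
  colnames(out) <- paste0(100 * c(object$alpha / 2, 1 - object$alpha / 2),
                          " %")
  out
}

#' Draw bootstrap-resampled ensembles from a fitted model
#'
#' Each simulation redraws every group's counts multinomially with the group
#' total fixed (or jointly, matching the fit's `scheme`) — the same engine
#' the fit's bootstrap uses.
#'
#' @param object a fitted [biocultural] model.
#' @param nsim number of ensembles to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `nsim` [bc_ensemble] objects.
#' @export
simulate.biocultural <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  .check_integer_counts(object$ensemble)
  lapply(seq_len(nsim), function(i)
    .bc_resample(object$ensemble, object$scheme))
}

#' Pearson residuals of the fitted count table under independence
#'
#' `(O - E) / sqrt(E)` with expected counts from the product of the margins
#' of the raw table; large absolute residuals mark the taxon-group cells
#' driving the association (and hence the complexity).
#'
#' @param object a fitted [biocultural] model.
#' @param ... unused.
#' @return a taxa-by-groups matrix of Pearson residuals.
#' @export
residuals.biocultural <- function(object, ...) {
  counts <- object$ensemble$counts
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  (counts - E) / sqrt(E)
}

#' Barplots of taxon specificity and group specialization
#'
#' Two side-by-side barplots with the theoretical maximum `log2(c)` drawn as
#' a dashed line.
#'
#' @param x a fitted [biocultural] model.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.biocultural <- function(x, ...) {
  lc <- log2(length(x$ensemble$groups))
  op <- graphics::par(mfrow = c(1, 2), mar = c(6, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(stats::setNames(x$species$specificity,
                                    rownames(x$species)),
                    las = 2, ylim = c(0, lc * 1.05),
                    ylab = "Specificity (bits)", main = "Taxa", ...)
  graphics::abline(h = lc, lty = 2)
  graphics::barplot(stats::setNames(x$groups$specialization,
                                    rownames(x$groups)),
                    las = 2, ylim = c(0, lc * 1.05),
                    ylab = "Specialization (bits)",
                    main = "Cultural groups", ...)
  graphics::abline(h = lc, lty = 2)
  invisible(x)
}

#' @export
summary.biocultural <- function(object, digits = 2, ...) {
  structure(list(tables = report_tables(object, digits = digits),
                 digits = digits, fit = object),
            class = "summary.biocultural")
}

#' @export
print.summary.biocultural <- function(x, ...) {
  tb <- x$tables
  writeLines(tb$header)
  cat("\nTaxon specificity:\n")
  print(tb$species, row.names = FALSE)
  cat("\nCultural specialization and taxonomic diversity:\n")
  print(tb$groups, row.names = FALSE)
  cat("\n")
  writeLines(tb$summary_lines)
  invisible(x)
}
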