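#' Derived frequency model of a biocultural ensemble
#'
#' Computes every frequency structure the information indices are built on.
#' Within each group the species distribution is conditional on the group,
#' \eqn{f_{i|j} = n_{ij} / n_{.j}}; the group marginal \eqn{f_{.j}} comes from
#' the supplied weights (normalized), or optionally from column totals.  The
#' joint distribution is then \eqn{f_{ij} = f_{i|j} f_{.j}}, the species
#' marginal \eqn{f_{i.} = \sum_j f_{ij}}, and the reverse conditional follows
#' by Bayes' theorem, \eqn{f_{j|i} = f_{ij} / f_{i.}}.
#'
#' Group marginals default to weights rather than column totals because
#' column totals reflect sampling effort: a table whose groups were surveyed
#' unevenly should not have its group representation estimated from the
#' counts.  Users without design weights can set `marginal = "counts"`.
#'
#' @param ensemble a [bc_ensemble] (or a bare count matrix, taxa in rows).
#' @param marginal `"weights"` (default) to take the group marginal from the
#'   ensemble weights, `"counts"` to use column totals.
#' @return an object of class `"bc_frequencies"`: a list with matrices
#'   `cond_species_given_group` (\eqn{f_{i|j}}), `joint` (\eqn{f_{ij}}),
#'   `cond_group_given_species` (\eqn{f_{j|i}}; rows of all-zero taxa are NA
#'   and flagged), vectors `group_marginal` (\eqn{f_{.j}}) and
#'   `species_marginal` (\eqn{f_{i.}}), flags `equiprobable` and
#'   `zero_species`, and the label vectors.
#' @examples
#' fr <- bc_frequencies(artificial_ensemble())
#' fr$group_marginal                       # 0.25 each: equiprobable groups
#' colSums(fr$cond_species_given_group)    # each group's frequencies sum to 1
#' @export
bc_frequencies <- function(ensemble, marginal = c("weights", "counts")) {
  ensemble <- .as_ensemble(ensemble)
  marginal <- match.arg(marginal)
  counts <- ensemble$counts
  n_col <- colSums(counts)

  cond_sg <- sweep(counts, 2, n_col, "/")
  f_g <- if (marginal == "weights") ensemble$weights / sum(ensemble$weights)
         else n_col / sum(n_col)
  joint <- sweep(cond_sg, 2, f_g, "*")
  f_s <- rowSums(joint)
  zero <- f_s == 0

  cond_gs <- joint / ifelse(f_s == 0, NA_real_, f_s)
  structure(
    list(cond_species_given_group = cond_sg,
         group_marginal = f_g,
         joint = joint,
         species_marginal = f_s,
         cond_group_given_species = cond_gs,
         equiprobable = all(abs(f_g - f_g[1]) < 1e-12),
         zero_species = zero,
         species = ensemble$species,
         groups = ensemble$groups),
    class = "bc_frequencies")
}

.as_frequencies <- function(x, ...) {
  if (inherits(x, "bc_frequencies")) x else bc_frequencies(x, ...)
}

#' @export
print.bc_frequencies <- function(x, digits = 4, ...) {
  cat("Frequency model: ", length(x$species), " taxa x ", length(x$groups),
      " groups; group marginal ",
      if (x$equiprobable) "equiprobable" else "weighted", "\n", sep = "")
  print(round(x$joint, digits), ...)
  invisible(x)
}
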