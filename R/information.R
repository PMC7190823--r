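# Information indices on a biocultural ensemble.  All logarithms are base 2;
# every index is reported in bits (or effective units for the complexity).
# The 0 * log2(0) = 0 convention applies throughout.

.h2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of a probability vector, in bits
#'
#' @param freqs numeric vector of non-negative entries summing to 1
#'   (tolerance 1e-9).  Zero entries contribute nothing.
#' @return entropy in bits, in `[0, log2(length(freqs))]`.
#' @examples
#' shannon_entropy(rep(0.25, 4))  # 2 bits
#' shannon_entropy(1)             # 0 bits
#' @export
shannon_entropy <- function(freqs) {
  freqs <- as.numeric(freqs)
  if (anyNA(freqs) || any(freqs < 0))
    stop("'freqs' must be non-negative and free of NA", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("'freqs' must sum to 1 (got ", format(sum(freqs)), ")", call. = FALSE)
  .h2(freqs)
}

#' Mutual information between taxa and cultural groups, in bits
#'
#' \deqn{I(S;C) = -\sum_j f_{.j}\log_2 f_{.j} + \sum_{ij} f_{ij}\log_2 f_{j|i},}
#' the reduction in uncertainty about the cultural group once the taxon is
#' known (and, by symmetry, vice versa).  Zero when every group uses the taxa
#' in identical proportions; `log2(c)` when each group has a fully private
#' taxon set.  All-zero taxa contribute nothing.
#'
#' @param x a [bc_frequencies], a [bc_ensemble], or a count matrix.
#' @param ... passed to [bc_frequencies()] when `x` needs converting.
#' @return mutual information in bits, in `[0, log2(c)]`.
#' @examples
#' mutual_information(artificial_ensemble())  # 0.936 bits
#' @export
mutual_information <- function(x, ...) {
  fr <- .as_frequencies(x, ...)
  pos <- which(fr$joint > 0)
  .h2(fr$group_marginal) + sum(fr$joint[pos] *
                                 log2(fr$cond_group_given_species[pos]))
}

#' Biocultural complexity: the effective number of biocultural units
#'
#' `BC = 2^I(S;C)`.  It equals the number of idealized cultural groups, each
#' with a fully private taxon set, that would carry the same mutual
#' information as the observed ensemble; it ranges from 1 (a homogeneous
#' ensemble, a single biocultural unit) to `c` (fully stratified).
#'
#' @inheritParams mutual_information
#' @return effective number of biocultural units, in `[1, c]`.
#' @examples
#' biocultural_complexity(artificial_ensemble())  # 1.91
#' @export
biocultural_complexity <- function(x, ...) 2^mutual_information(x, ...)

#' Taxon specificity, in bits
#'
#' \deqn{S_i = H(C) - H(C \mid S_i) = -\sum_j f_{.j}\log_2 f_{.j} +
#'       \sum_j f_{j|i}\log_2 f_{j|i}:}
#' the information a taxon carries about the identity of the groups using it.
#' 0 for a taxon used uniformly across groups, `log2(c)` for a taxon private
#' to one group.  Undefined (NA) for taxa with zero total count.
#'
#' @inheritParams mutual_information
#' @param species optional labels or indices selecting taxa; default all.
#' @return named numeric vector of specificities in `[0, log2(c)]`, NA for
#'   all-zero taxa.
#' @examples
#' taxon_specificity(artificial_ensemble())          # sp1 hits log2(4) = 2 bits
#' taxon_specificity(artificial_ensemble(), "sp2")   # near 0: used everywhere
#' @export
taxon_specificity <- function(x, species = NULL, ...) {
  fr <- .as_frequencies(x, ...)
  hC <- .h2(fr$group_marginal)
  s_all <- vapply(seq_along(fr$species), function(i) {
    if (fr$zero_species[i]) return(NA_real_)
    hC - .h2(fr$cond_group_given_species[i, ])
  }, numeric(1))
  names(s_all) <- fr$species
  if (is.null(species)) s_all else s_all[species]
}

#' Cultural-group specialization, in bits
#'
#' \deqn{\delta_j = \sum_i f_{i|j} S_i,} the within-group frequency-weighted
#' average specificity of the taxa a group uses.  0 when every taxon the
#' group uses has zero specificity; `log2(c)` when all of them are private to
#' the group.
#'
#' @inheritParams mutual_information
#' @param groups optional labels or indices selecting groups; default all.
#' @param specificities optional precomputed result of [taxon_specificity()]
#'   (saves recomputation in loops).
#' @return named numeric vector of specializations in `[0, log2(c)]`.
#' @examples
#' group_specialization(artificial_ensemble())  # c2 is the most specialized
#' @export
group_specialization <- function(x, groups = NULL, specificities = NULL, ...) {
  fr <- .as_frequencies(x, ...)
  if (is.null(specificities)) specificities <- taxon_specificity(fr)
  d_all <- vapply(seq_along(fr$groups), function(j) {
    f <- fr$cond_species_given_group[, j]
    use <- f > 0  # all-zero taxa have f = 0 in every group: no contribution
    sum(f[use] * specificities[use])
  }, numeric(1))
  names(d_all) <- fr$groups
  if (is.null(groups)) d_all else d_all[groups]
}

#' Relative (normalized) information index
#'
#' Divides a specificity, specialization or mutual-information value by its
#' theoretical maximum `log2(c)`, mapping it onto `[0, 1]`.  Undefined for a
#' single group (`log2(1) = 0`); NA is returned with a warning.
#'
#' @param value index value(s) in bits, each in `[0, log2(c)]`.
#' @param c_groups the number of cultural groups.
#' @return `value / log2(c_groups)`, or NA when `c_groups == 1`.
#' @examples
#' relative_index(2, 4)  # 1: the maximum for four groups
#' @export
relative_index <- function(value, c_groups) {
  if (c_groups < 1) stop("'c_groups' must be >= 1", call. = FALSE)
  if (c_groups == 1) {
    warning("relative index undefined for a single group (log2(1) = 0)",
            call. = FALSE)
    return(rep(NA_real_, length(value)))
  }
  value / log2(c_groups)
}

#' Per-group Shannon diversity of taxa, in bits
#'
#' The base-2 entropy of the within-group taxon frequencies \eqn{f_{i|j}} —
#' the taxonomic diversity of each group's interactions.
#'
#' @inheritParams mutual_information
#' @return named numeric vector, one entropy per group, in `[0, log2(s)]`.
#' @examples
#' group_diversity(artificial_ensemble())
#' @export
group_diversity <- function(x, ...) {
  fr <- .as_frequencies(x, ...)
  h <- apply(fr$cond_species_given_group, 2, .h2)
  names(h) <- fr$groups
  h
}

# Full named vector of every index the bootstrap tracks, computed in the
# canonical order: specificities, specializations, then I from the
# specificity decomposition, then BC.  Used by the fit and by resampling so
# replicate columns stay mutually consistent.
.bc_stat_vector <- function(fr) {
  S <- taxon_specificity(fr)
  d <- group_specialization(fr, specificities = S)
  H <- group_diversity(fr)
  lc <- log2(length(fr$groups))
  I <- sum(fr$species_marginal * S, na.rm = TRUE)  # zero-marginal taxa: 0
  rel <- function(v) if (lc > 0) v / lc else rep(NA_real_, length(v))
  c(stats::setNames(S, paste0("spec:", fr$species)),
    stats::setNames(rel(S), paste0("rspec:", fr$species)),
    stats::setNames(d, paste0("specia:", fr$groups)),
    stats::setNames(rel(d), paste0("rspecia:", fr$groups)),
    stats::setNames(H, paste0("sdiv:", fr$groups)),
    I = I, BC = 2^I)
}

# Theoretical range of each tracked statistic; used to clip corrected
# estimates and CI endpoints.
.bc_stat_range <- function(name, s, c_) {
  lc <- log2(c_)
  switch(sub(":.*$", "", name),
         spec = , specia = c(0, lc),
         rspec = , rspecia = c(0, 1),
         sdiv = c(0, log2(s)),
         I = c(0, lc),
         BC = c(1, c_),
         c(-Inf, Inf))
}
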