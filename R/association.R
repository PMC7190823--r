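#' Monte Carlo chi-square test of taxon-by-group association
#'
#' Tests independence between taxa and cultural groups on the raw count
#' table.  The observed Pearson statistic \eqn{\sum (O - E)^2 / E} (expected
#' counts from the product of margins) is compared with a null distribution
#' of `B` random tables having exactly the observed row and column totals
#' (Patefield's algorithm, via [stats::r2dtable()]).  The p-value uses the
#' add-one rule `(1 + m) / (1 + B)`, where `m` counts null statistics at
#' least as large as the observed one, so p is never exactly zero and is
#' bounded below by `1/(1+B)`.
#'
#' Group weights play no role here: the test asks whether the *counts* are
#' compatible with independence, while the information indices measure the
#' structure of the weighted frequency model — two related but distinct
#' questions.
#'
#' @param x a [bc_ensemble] or count matrix with integer counts; taxa with a
#'   zero row total are dropped with a warning before testing.
#' @param B number of null tables (default 2000).
#' @param seed optional integer seed for reproducibility.
#' @return an object of classes `"bc_chisq"` and `"htest"` with `statistic`,
#'   `p.value`, `B`, `exceed_count` (m above) and `seed`.
#' @examples
#' bc_chisq_test(artificial_ensemble(), B = 999, seed = 1)
#' @export
bc_chisq_test <- function(x, B = 2000, seed = NULL) {
  ensemble <- .as_ensemble(x)
  .check_integer_counts(ensemble)
  counts <- round(ensemble$counts)
  dropped <- rowSums(counts) == 0
  if (any(dropped)) {
    warning("dropping zero-total taxa before testing: ",
            paste(ensemble$species[dropped], collapse = ", "), call. = FALSE)
    counts <- counts[!dropped, , drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("association is undefined for a table with a single row or column",
         call. = FALSE)
  if (B < 1) stop("'B' must be at least 1", call. = FALSE)

  pearson <- function(tab, E) sum((tab - E)^2 / E)
  rs <- rowSums(counts); cs <- colSums(counts)
  E <- outer(rs, cs) / sum(counts)
  observed <- pearson(counts, E)

  if (!is.null(seed)) set.seed(seed)
  null_stats <- vapply(stats::r2dtable(B, rs, cs), pearson, numeric(1), E = E)
  m <- sum(null_stats >= observed)

  structure(
    list(statistic = c("X-squared" = observed),
         parameter = c(B = B),
         p.value = (1 + m) / (1 + B),
         exceed_count = m,
         B = B,
         seed = seed,
         method = paste("Pearson's Chi-squared test with simulated p-value",
                        "\n\t (both margins fixed, based on", B, "replicates)"),
         data.name = deparse(substitute(x))),
    class = c("bc_chisq", "htest"))
}
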