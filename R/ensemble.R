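#' Construct a biocultural ensemble
#'
#' A biocultural ensemble is a table of interaction counts between `s`
#' biological taxa (rows) and `c` cultural groups (columns), together with a
#' vector of positive group weights describing how strongly each group is
#' represented in the study region.  Weights all coded 1 (the default) mean
#' the groups are treated as equiprobable; the group marginal frequencies are
#' always derived from the weights, never from column totals, because sampling
#' effort per group is rarely proportional to the group's real representation.
#'
#' Counts may be non-negative reals so that pre-normalized frequency tables
#' can be analyzed; resampling functions ([bc_bootstrap()], [bc_chisq_test()])
#' additionally require integer counts.  Taxa with an all-zero row are
#' retained (dropping them would change `s`) but flagged; their specificity is
#' undefined.  A group whose column sums to zero is an error.
#'
#' @param counts numeric matrix or data frame, taxa in rows, groups in
#'   columns; non-negative.
#' @param weights positive numeric vector of length `ncol(counts)`, one per
#'   group; defaults to all 1 (equiprobable groups).
#' @param species,groups character labels; default to the dimnames of
#'   `counts`, or `sp1..sps` / `c1..cc` when absent.
#' @return an object of class `"bc_ensemble"`: a list with elements `counts`
#'   (named matrix), `weights` (named vector), `species`, `groups`, and
#'   `zero_species` (logical flag per taxon for all-zero rows).
#' @seealso [read_ensemble()], [bc_frequencies()], [biocultural()]
#' @examples
#' counts <- matrix(c(0, 110, 0, 0,
#'                    25, 10, 26, 11), nrow = 2, byrow = TRUE,
#'                  dimnames = list(c("sp1", "sp2"), c("c1", "c2", "c3", "c4")))
#' bc_ensemble(counts)
#' @export
bc_ensemble <- function(counts, weights = NULL, species = NULL, groups = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (taxa in rows, groups in columns)",
         call. = FALSE)
  s <- nrow(counts); c_ <- ncol(counts)
  if (s < 1L || c_ < 1L)
    stop("ensemble needs at least one taxon and one group", call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA", call. = FALSE)

  if (is.null(species)) species <- rownames(counts)
  if (is.null(species)) species <- paste0("sp", seq_len(s))
  if (is.null(groups)) groups <- colnames(counts)
  if (is.null(groups)) groups <- paste0("c", seq_len(c_))
  species <- as.character(species); groups <- as.character(groups)
  if (length(species) != s || length(groups) != c_)
    stop("label length does not match the count matrix", call. = FALSE)
  if (anyDuplicated(species))
    stop("duplicate taxon labels: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(groups))
    stop("duplicate group labels: ",
         paste(unique(groups[duplicated(groups)]), collapse = ", "),
         call. = FALSE)

  if (is.null(weights)) weights <- rep(1, c_)
  weights <- as.numeric(weights)
  if (length(weights) != c_ || anyNA(weights) || any(weights <= 0))
    stop("'weights' must be ", c_, " positive numbers", call. = FALSE)

  col_tot <- colSums(counts)
  if (any(col_tot == 0))
    stop("group column(s) with zero total count: ",
         paste(groups[col_tot == 0], collapse = ", "), call. = FALSE)

  dimnames(counts) <- list(species, groups)
  names(weights) <- groups
  structure(
    list(counts = counts, weights = weights,
         species = species, groups = groups,
         zero_species = rowSums(counts) == 0),
    class = "bc_ensemble")
}

#' @export
print.bc_ensemble <- function(x, ...) {
  cat("Biocultural ensemble: ", length(x$species), " taxa x ",
      length(x$groups), " cultural groups, total count ",
      format(sum(x$counts)), "\n", sep = "")
  w <- x$weights / sum(x$weights)
  cat(if (all(abs(w - w[1]) < 1e-12)) "Equiprobable group weights\n" else
        paste0("Group weights: ", paste(format(x$weights), collapse = ", "), "\n"))
  if (any(x$zero_species))
    cat("All-zero taxa (specificity undefined): ",
        paste(x$species[x$zero_species], collapse = ", "), "\n", sep = "")
  print(x$counts, ...)
  invisible(x)
}

#' @export
as.matrix.bc_ensemble <- function(x, ...) x$counts

.as_ensemble <- function(x) {
  if (inherits(x, "bc_ensemble")) x else bc_ensemble(x)
}

#' Read a biocultural count table from a delimited text file
#'
#' The expected layout follows the conventional field format: groups in rows,
#' a first column of group labels, a header row of taxon labels, and an
#' optional weight column (named `weight_col`) giving each group's
#' representation; weights all coded 1 denote equiprobable groups.  Use
#' `transpose = TRUE` for files with taxa in rows and groups in columns (the
#' weight column is then a weight *row* labelled `weight_col`).
#'
#' @param path path to a CSV or TSV file (UTF-8; the delimiter is inferred
#'   from the extension unless `sep` is given).
#' @param weight_col name of the optional weight column (case-insensitive);
#'   default `"Representation"`.
#' @param transpose logical; `FALSE` (default) for groups-in-rows files.
#' @param sep field separator; `NULL` to infer (`","` unless the extension is
#'   `.tsv`/`.txt`, then tab).
#' @return a validated [bc_ensemble] (taxa in rows internally).  All-zero
#'   taxa raise a warning but are retained.
#' @examples
#' path <- system.file("extdata", "artificial_use_counts.csv", package = "bcx")
#' read_ensemble(path)
#' @export
read_ensemble <- function(path, weight_col = "Representation",
                          transpose = FALSE, sep = NULL) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 1L)
    stop("no data columns found in ", path, call. = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m))
    stop("non-numeric entries in ", path, call. = FALSE)

  if (transpose) m <- t(m)  # now groups in rows either way
  wi <- which(tolower(colnames(m)) == tolower(weight_col))
  if (length(wi) > 1L)
    stop("multiple '", weight_col, "' columns in ", path, call. = FALSE)
  weights <- if (length(wi)) m[, wi] else NULL
  if (length(wi)) m <- m[, -wi, drop = FALSE]

  ens <- bc_ensemble(t(m), weights = weights)
  if (any(ens$zero_species))
    warning("taxa with zero total count retained but flagged: ",
            paste(ens$species[ens$zero_species], collapse = ", "),
            call. = FALSE)
  ens
}

#' Write a biocultural ensemble back to a delimited text file
#'
#' Emits the same groups-in-rows layout that [read_ensemble()] accepts,
#' including the weight column, so that a write/read round trip reproduces
#' counts and weights exactly.
#'
#' @param ensemble a [bc_ensemble].
#' @param path output file path.
#' @param weight_col name for the weight column.
#' @param sep field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, weight_col = "Representation",
                           sep = ",") {
  ensemble <- .as_ensemble(ensemble)
  out <- data.frame(ensemble$weights, t(ensemble$counts),
                    check.names = FALSE)
  names(out)[1] <- weight_col
  utils::write.table(cbind(Culture = ensemble$groups, out), path,
                     sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
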