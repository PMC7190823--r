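test_that("constructor validates counts, labels, weights and group totals", {
  m <- worked_counts()
  ens <- bc_ensemble(m)
  expect_s3_class(ens, "bc_ensemble")
  expect_equal(ens$weights, c(c1 = 1, c2 = 1, c3 = 1, c4 = 1))
  expect_equal(unname(ens$counts["sp1", ]), c(0, 110, 0, 0))

  # minimal 1 x 1 ensemble is legal
  one <- bc_ensemble(matrix(7, 1, 1))
  expect_equal(length(one$species), 1L)
  expect_equal(length(one$groups), 1L)

  bad <- m; bad[1, 1] <- -1
  expect_error(bc_ensemble(bad), "non-negative")
  expect_error(bc_ensemble(m, weights = c(1, 1, 0, 1)), "positive")
  expect_error(bc_ensemble(m, species = c("a", "a", "b", "c", "d")),
               "duplicate")
  zero_col <- m; zero_col[, "c3"] <- 0
  expect_error(bc_ensemble(zero_col), "c3")

  # all-zero taxon rows are retained but flagged
  zr <- m; zr["sp5", ] <- 0
  flagged <- bc_ensemble(zr)
  expect_true(flagged$zero_species[["sp5"]])
  expect_equal(length(flagged$species), 5L)
})

test_that("file round trip reproduces counts and weights exactly", {
  ens <- bc_ensemble(worked_counts(), weights = c(2, 1, 1, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(back$counts, ens$counts, ignore_attr = FALSE)
  expect_equal(back$weights, ens$weights)

  # taxa-in-rows orientation via the transpose flag
  tpath <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(t(ens$counts), check.names = FALSE)
  utils::write.table(cbind(Species = rownames(ens$counts), t(tab)),
                     tpath, sep = "\t", row.names = FALSE, quote = FALSE)
  tback <- read_ensemble(tpath, transpose = TRUE)
  expect_equal(tback$counts, ens$counts)
  expect_equal(unname(tback$weights), rep(1, 4))  # no weight row: equiprobable

  expect_error(read_ensemble("no/such/file.csv"), "not found")
  zr <- worked_counts(); zr["sp2", ] <- 0
  zpath <- withr::local_tempfile(fileext = ".csv")
  write_ensemble(bc_ensemble(zr), zpath)
  expect_warning(read_ensemble(zpath), "sp2")
})

test_that("frequency model satisfies simplex, Bayes and weighting invariants", {
  set.seed(11)
  for (rep in 1:10) {
    s <- sample(2:6, 1); c_ <- sample(2:4, 1)
    w <- stats::runif(c_, 0.5, 3)
    ens <- bc_ensemble(random_counts(s, c_), weights = w)
    fr <- bc_frequencies(ens)

    expect_equal(unname(colSums(fr$cond_species_given_group)), rep(1, c_))
    expect_equal(sum(fr$group_marginal), 1)
    expect_equal(sum(fr$joint), 1)
    expect_equal(sum(fr$species_marginal), 1)
    expect_equal(unname(fr$group_marginal), unname(w / sum(w)))

    # Bayes consistency: f_{j|i} = f_{i|j} f_.j / sum_k f_{i|k} f_.k
    for (i in which(!fr$zero_species)) {
      bayes <- fr$cond_species_given_group[i, ] * fr$group_marginal
      expect_equal(unname(fr$cond_group_given_species[i, ]),
                   unname(bayes / sum(bayes)), tolerance = 1e-12)
      expect_equal(sum(fr$cond_group_given_species[i, ]), 1)
    }
  }

  # scaling all counts within a group leaves the model unchanged
  ens <- bc_ensemble(worked_counts())
  scaled <- worked_counts(); scaled[, "c2"] <- scaled[, "c2"] * 13
  expect_equal(bc_frequencies(bc_ensemble(scaled))$joint,
               bc_frequencies(ens)$joint)

  # zero-taxon rows are flagged, not silently NaN
  zr <- worked_counts(); zr["sp4", ] <- 0
  fr0 <- bc_frequencies(bc_ensemble(zr))
  expect_true(fr0$zero_species[["sp4"]])
  expect_true(all(is.na(fr0$cond_group_given_species["sp4", ])))

  # under equal weights the species marginal is the mean of conditionals
  fr <- bc_frequencies(ens)
  expect_true(fr$equiprobable)
  expect_equal(unname(fr$species_marginal),
               unname(rowMeans(fr$cond_species_given_group)))
  expect_equal(unname(fr$species_marginal[1]), 0.229167, tolerance = 1e-5)

  # count-proportional marginals on request
  frc <- bc_frequencies(ens, marginal = "counts")
  expect_equal(unname(frc$group_marginal),
               unname(colSums(ens$counts) / sum(ens$counts)))
  expect_false(frc$equiprobable)
})
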