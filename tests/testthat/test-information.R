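test_that("entropy matches closed forms, the worked table, and vegan", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(1), 0)
  expect_equal(round(shannon_entropy(c(0, 25, 39, 27, 9) / 100), 2), 1.85)
  expect_equal(round(shannon_entropy(c(110, 10, 0, 0, 0) / 120), 2), 0.41)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")

  # independent oracle: vegan's Shannon index in base 2
  set.seed(4)
  for (rep in 1:5) {
    p <- stats::runif(6); p <- p / sum(p)
    expect_equal(shannon_entropy(p),
                 unname(vegan::diversity(p, index = "shannon", base = 2)))
  }
})

test_that("worked example reproduces the published index values", {
  ens <- bc_ensemble(worked_counts())
  expect_equal(unname(round(taxon_specificity(ens), 2)),
               c(2.00, 0.22, 0.61, 1.00, 1.01))
  expect_equal(unname(round(group_specialization(ens), 2)),
               c(0.65, 1.85, 0.66, 0.58))
  expect_equal(unname(round(group_diversity(ens), 2)),
               c(1.85, 0.41, 1.91, 0.42))
  expect_equal(mutual_information(ens), 0.9360, tolerance = 1e-4)
  expect_equal(round(biocultural_complexity(ens), 2), 1.91)
  expect_equal(unname(relative_index(taxon_specificity(ens, "sp1"), 4)), 1)
  expect_equal(unname(round(relative_index(taxon_specificity(ens, "sp4"),
                                           4), 2)), 0.50)
})

test_that("mutual information equals the brute-force double sum and both
           entropy decompositions on random ensembles", {
  set.seed(23)
  for (rep in 1:20) {
    s <- sample(2:6, 1); c_ <- sample(2:4, 1)
    counts <- random_counts(s, c_)
    w <- if (rep %% 2) rep(1, c_) else stats::runif(c_, 0.5, 3)
    ens <- bc_ensemble(counts, weights = w)
    I <- mutual_information(ens)

    expect_equal(I, mi_double_sum(counts, w), tolerance = 1e-9)
    dec <- mi_decompositions(counts, w)
    expect_equal(I, unname(dec["groups_first"]), tolerance = 1e-9)
    expect_equal(I, unname(dec["species_first"]), tolerance = 1e-9)
    expect_gte(I, -1e-12)
    expect_lte(I, log2(c_) + 1e-12)
  }
})

test_that("I decomposes into weighted specificities and specializations,
           with the equal-weight reduction and bounds", {
  set.seed(31)
  for (rep in 1:15) {
    s <- sample(3:6, 1); c_ <- sample(2:4, 1)
    w <- if (rep %% 2) rep(1, c_) else stats::runif(c_, 0.5, 3)
    ens <- bc_ensemble(random_counts(s, c_), weights = w)
    fr <- bc_frequencies(ens)
    S <- taxon_specificity(fr)
    d <- group_specialization(fr, specificities = S)
    I <- mutual_information(fr)

    expect_equal(I, sum(fr$species_marginal * S, na.rm = TRUE),
                 tolerance = 1e-9)
    expect_equal(I, sum(fr$group_marginal * d), tolerance = 1e-9)
    if (fr$equiprobable)
      expect_equal(I, sum(d) / c_, tolerance = 1e-9)

    # the upper bound log2(c) holds for any weighting; the lower bound 0
    # is guaranteed only for equiprobable groups, where H(C) is maximal
    lc <- log2(c_)
    expect_true(all(S[!is.na(S)] <= lc + 1e-12))
    expect_true(all(d <= lc + 1e-12))
    if (fr$equiprobable) {
      expect_true(all(S[!is.na(S)] >= -1e-12))
      expect_true(all(d >= -1e-12))
    }
    bc <- biocultural_complexity(fr)
    expect_gte(bc, 1 - 1e-12)
    expect_lte(bc, c_ + 1e-12)

    # equal weights: the averaged-conditional specificity formula agrees
    if (fr$equiprobable) {
      for (i in seq_len(s)) {
        fi <- fr$species_marginal[i]
        if (fi == 0) next
        f_cond <- fr$cond_species_given_group[i, ]
        pos <- f_cond > 0
        s_alt <- sum(f_cond[pos] * log2(f_cond[pos] / fi)) / (c_ * fi)
        expect_equal(unname(S[i]), unname(s_alt), tolerance = 1e-9)
      }
    }
  }
})

test_that("limiting ensembles pin the indices to their extremes", {
  # identical conditional frequencies in every group: a single unit
  base <- c(5, 3, 2)
  hom <- bc_ensemble(cbind(c1 = base, c2 = base * 4, c3 = base * 2))
  expect_equal(mutual_information(hom), 0, tolerance = 1e-12)
  expect_equal(biocultural_complexity(hom), 1, tolerance = 1e-12)
  expect_equal(unname(taxon_specificity(hom)), rep(0, 3), tolerance = 1e-12)

  # fully private taxon sets: the maximum log2(c), BC = c
  priv <- bc_ensemble(private_counts(4))
  expect_equal(mutual_information(priv), 2, tolerance = 1e-12)
  expect_equal(biocultural_complexity(priv), 4, tolerance = 1e-12)
  expect_equal(unname(group_specialization(priv)), rep(2, 4))

  # a taxon private to one of five equiprobable groups: log2(5) bits;
  # with equal column totals the uniformly used taxon carries no information
  m5 <- rbind(sp1 = c(4, 0, 0, 0, 0),
              sp2 = c(0, 4, 4, 4, 4),
              sp3 = c(2, 2, 2, 2, 2))
  priv5 <- bc_ensemble(m5)
  expect_equal(round(taxon_specificity(priv5, 1)[[1]], 2), 2.32)
  expect_equal(unname(relative_index(taxon_specificity(priv5, 1), 5)), 1)
  expect_equal(taxon_specificity(priv5, 3)[[1]], 0, tolerance = 1e-12)

  # single group: everything collapses to zero and relative is undefined
  g1 <- bc_ensemble(matrix(c(3, 5), 2, 1))
  expect_equal(mutual_information(g1), 0)
  expect_equal(biocultural_complexity(g1), 1)
  expect_warning(out <- relative_index(0.0, 1), "single group")
  expect_true(is.na(out))

  # merging a duplicated group (same conditionals) leaves I unchanged
  m2 <- worked_counts()
  dup <- cbind(m2, c5 = m2[, "c4"] * 3)
  expect_equal(mutual_information(bc_ensemble(dup)),
               mutual_information(bc_ensemble(m2,
                                              weights = c(1, 1, 1, 2))),
               tolerance = 1e-9)
})

test_that("indices are invariant under relabeling of taxa and groups", {
  set.seed(47)
  counts <- random_counts(6, 4)
  w <- stats::runif(4, 0.5, 2)
  ens <- bc_ensemble(counts, weights = w)
  pi_s <- sample(6); pi_c <- sample(4)
  perm <- bc_ensemble(counts[pi_s, pi_c], weights = w[pi_c])

  expect_equal(mutual_information(perm), mutual_information(ens),
               tolerance = 1e-12)
  expect_equal(taxon_specificity(perm)[order(pi_s)],
               taxon_specificity(ens), tolerance = 1e-12)
  expect_equal(group_specialization(perm)[order(pi_c)],
               group_specialization(ens), tolerance = 1e-12)
})
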