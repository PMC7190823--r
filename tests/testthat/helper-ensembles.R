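# Shared fixtures and independent oracles.  The oracles deliberately avoid
# the package's code paths: mutual information via the direct double sum
# over joint frequencies, and the two entropy-difference decompositions
# assembled from a local entropy helper.

# The worked five-taxa, four-group example (equiprobable groups).
worked_counts <- function() {
  matrix(c(0,  110, 0,  0,
           25, 10,  26, 11,
           39, 0,   24, 119,
           27, 0,   28, 0,
           9,  0,   10, 0),
         nrow = 5, byrow = TRUE,
         dimnames = list(paste0("sp", 1:5), paste0("c", 1:4)))
}

# Random integer ensemble with no zero group column.
random_counts <- function(s, c_, lambda = 3) {
  m <- matrix(stats::rpois(s * c_, lambda), s, c_,
              dimnames = list(paste0("sp", seq_len(s)),
                              paste0("c", seq_len(c_))))
  for (j in which(colSums(m) == 0)) m[sample.int(s, 1), j] <- 1
  m
}

# Each group uses one private taxon only: the fully stratified limit.
private_counts <- function(c_, total = 10) {
  diag(total, c_, c_) |>
    `dimnames<-`(list(paste0("sp", seq_len(c_)), paste0("c", seq_len(c_))))
}

h_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Joint/marginal frequencies from counts + weights, built from scratch.
freqs_oracle <- function(counts, weights = rep(1, ncol(counts))) {
  fj <- weights / sum(weights)
  cond_sg <- sweep(counts, 2, colSums(counts), "/")
  joint <- sweep(cond_sg, 2, fj, "*")
  fi <- rowSums(joint)
  list(fj = fj, cond_sg = cond_sg, joint = joint, fi = fi)
}

# Oracle 1: mutual information as the direct double sum
# sum_ij f_ij log2(f_ij / (f_i. f_.j)).
mi_double_sum <- function(counts, weights = rep(1, ncol(counts))) {
  fr <- freqs_oracle(counts, weights)
  tot <- 0
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts)))
      if (fr$joint[i, j] > 0)
        tot <- tot + fr$joint[i, j] *
          log2(fr$joint[i, j] / (fr$fi[[i]] * fr$fj[[j]]))
  unname(tot)
}

# Oracle 2: the two entropy-difference decompositions,
# H_C - H_{C|S} and H_S - H_{S|C}.
mi_decompositions <- function(counts, weights = rep(1, ncol(counts))) {
  fr <- freqs_oracle(counts, weights)
  h_c_given_s <- sum(vapply(seq_len(nrow(counts)), function(i) {
    if (fr$fi[i] == 0) return(0)
    fr$fi[i] * h_bits(fr$joint[i, ] / fr$fi[i])
  }, numeric(1)))
  h_s_given_c <- sum(fr$fj * apply(fr$cond_sg, 2, h_bits))
  c(groups_first = unname(h_bits(fr$fj) - h_c_given_s),
    species_first = unname(h_bits(fr$fi) - h_s_given_c))
}
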