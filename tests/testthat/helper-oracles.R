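# Independent oracles used across test files.

# Transition probabilities from the rate generator, via numerical matrix
# exponential (independent of the closed forms in the package).
expm_transition <- function(m, T) {
  Q <- matrix(c(-m, 1 - m, m, -(1 - m)), 2L, 2L)
  as.matrix(Matrix::expm(Q * T))
}

# Brute-force tree likelihood: explicit sum over all internal-state
# assignments of the joint probability with internals given.
brute_force_gene_likelihood <- function(tree, tip_states, tumor_states = NULL) {
  nnode <- tree$phy$Nnode
  total <- 0
  for (code in 0:(2^nnode - 1)) {
    internals <- as.integer(intToBits(code)[seq_len(nnode)])
    total <- total + gene_likelihood_given_internals(tree, tip_states,
                                                     internals, tumor_states)
  }
  total
}

# All binary patterns over given labels, as a list of named vectors.
all_patterns <- function(labels) {
  n <- length(labels)
  lapply(0:(2^n - 1), function(code) {
    stats::setNames(as.integer(intToBits(code)[seq_len(n)]), labels)
  })
}

# Random rooted tree with branch lengths, tips labeled N1..Nk.
random_dup_tree <- function(ntip, m, extended = FALSE) {
  phy <- ape::rtree(ntip, rooted = TRUE,
                    br = function(n) stats::runif(n, 0.05, 1.5))
  phy$tip.label <- sprintf("N%d", seq_len(ntip))
  ext <- if (extended) {
    data.frame(tip = phy$tip.label,
               m_e = stats::runif(ntip, 0.01, 0.99),
               T_e = stats::runif(ntip, 0.05, 1))
  } else NULL
  dup_tree(phy, m, extended = ext)
}
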