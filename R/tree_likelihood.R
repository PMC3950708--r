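#' Fixed phylogeny with tumor-leading extended branches
#'
#' Wraps a rooted `ape::phylo` tree of the normal genomes, whose branches
#' share the main-tree duplication fraction `m`, together with optional
#' extended branches: one per designated tip, leading from the normal
#' genome to that patient's tumor genome, each with its own duplication
#' fraction `m_e` and scaled length `T_e`.  Branch lengths are in scaled
#' units `T = (a + b) t`.
#'
#' @param phy a rooted `ape::phylo` object with branch lengths.
#' @param m main-tree duplication fraction, in `[0, 1]`.
#' @param extended optional data.frame with columns `tip` (tip label),
#'   `m_e`, `T_e`; at most one row per tip.
#' @return an object of class `dup_tree`.
#' @examples
#' phy <- ape::read.tree(text = "((N1:0.1,N2:0.1):0.05,N3:0.15);")
#' tr <- dup_tree(phy, m = 0.01,
#'                extended = data.frame(tip = c("N1", "N2", "N3"),
#'                                      m_e = 0.01, T_e = 0.25))
#' @export
dup_tree <- function(phy, m, extended = NULL) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo", call. = FALSE)
  if (is.null(phy$edge.length)) stop("tree must have branch lengths",
                                     call. = FALSE)
  if (any(phy$edge.length < 0)) stop("negative branch length", call. = FALSE)
  check_m(m)
  if (!is.null(extended)) {
    if (!all(c("tip", "m_e", "T_e") %in% names(extended))) {
      stop("'extended' needs columns tip, m_e, T_e", call. = FALSE)
    }
    if (anyDuplicated(extended$tip)) {
      stop("each extended branch attaches to exactly one tip", call. = FALSE)
    }
    if (!all(extended$tip %in% phy$tip.label)) {
      stop("unknown tip in 'extended': ",
           setdiff(extended$tip, phy$tip.label)[1L], call. = FALSE)
    }
    for (i in seq_len(nrow(extended))) {
      check_m(extended$m_e[i])
      check_T(extended$T_e[i])
    }
  }
  structure(list(phy = phy, m = m, extended = extended), class = "dup_tree")
}

#' Read the extended-branch sidecar mapping
#'
#' TSV with columns `tip`, `tumor` (tumor genome label, informational),
#' `m_e`, `T_e`, declaring the tumor-leading branch attached to each tip
#' of a newick main tree.
#'
#' @param path file path.
#' @return data.frame suitable for the `extended` argument of [dup_tree()].
#' @export
read_extended_map <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("tip", "m_e", "T_e") %in% names(d))) {
    stop("extended map needs columns tip, m_e, T_e", call. = FALSE)
  }
  d
}

check_state <- function(s) {
  if (!all(s %in% c(0, 1))) stop("states must be 0/1", call. = FALSE)
  as.integer(s)
}

#' Transition probability along one branch
#'
#' The `(parent, child)` entry of [transition_matrix()]; the elementary
#' factor of the tree likelihood.
#'
#' @param parent,child states at the two ends of the branch, 0 or 1.
#' @inheritParams transition_matrix
#' @return a probability.
#' @export
branch_probability <- function(parent, child, m, T) {
  parent <- check_state(parent)
  child <- check_state(child)
  stopifnot(length(parent) == 1L, length(child) == 1L)
  transition_matrix(m, T)[parent + 1L, child + 1L]
}

#' Gene likelihood with internal states given
#'
#' The probability of a complete state assignment for one gene: the
#' stationary probability of the root state times the product of branch
#' transition probabilities over all main-tree branches and all extended
#' branches.
#'
#' @param tree a [dup_tree()].
#' @param tip_states named 0/1 vector over all tip labels (normal
#'   genomes).
#' @param internal_states 0/1 vector over internal nodes, indexed in
#'   `ape`'s node order (`Ntip + 1` is the root).
#' @param tumor_states named 0/1 vector over the tips carrying extended
#'   branches (tumor genomes); required iff `tree$extended` is non-NULL.
#' @return the joint probability.
#' @export
gene_likelihood_given_internals <- function(tree, tip_states, internal_states,
                                            tumor_states = NULL) {
  stopifnot(inherits(tree, "dup_tree"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  tip_states <- check_state(tip_states[phy$tip.label])
  if (length(internal_states) != nnode) {
    stop("need one internal state per internal node", call. = FALSE)
  }
  internal_states <- check_state(internal_states)
  state_of <- c(tip_states, internal_states)  # node index -> state
  prob <- stationary_distribution(tree$m)[[state_of[ntip + 1L] + 1L]]
  for (e in seq_len(nrow(phy$edge))) {
    prob <- prob * branch_probability(state_of[phy$edge[e, 1L]],
                                      state_of[phy$edge[e, 2L]],
                                      tree$m, phy$edge.length[e])
  }
  prob * extended_factor_given_tips(tree, tip_states, tumor_states)
}

# product over extended branches of P(normal tip state -> tumor state)
extended_factor_given_tips <- function(tree, tip_states, tumor_states) {
  if (is.null(tree$extended)) return(1)
  if (is.null(tumor_states)) {
    stop("tree has extended branches: 'tumor_states' required", call. = FALSE)
  }
  prob <- 1
  for (i in seq_len(nrow(tree$extended))) {
    tip <- tree$extended$tip[i]
    idx <- match(tip, tree$phy$tip.label)
    if (!tip %in% names(tumor_states)) {
      stop("missing tumor state for tip '", tip, "'", call. = FALSE)
    }
    prob <- prob * branch_probability(tip_states[idx],
                                      check_state(tumor_states[[tip]]),
                                      tree$extended$m_e[i],
                                      tree$extended$T_e[i])
  }
  prob
}

#' Gene likelihood by pruning
#'
#' The probability of the observed states at the normal tips (and, where
#' extended branches are declared, the tumor genomes) with the unobserved
#' internal states summed out.  Computed by Felsenstein's pruning
#' (post-order peeling); equals the explicit sum of
#' [gene_likelihood_given_internals()] over all internal assignments.
#'
#' @inheritParams gene_likelihood_given_internals
#' @return the pattern probability.
#' @export
gene_likelihood <- function(tree, tip_states, tumor_states = NULL) {
  stopifnot(inherits(tree, "dup_tree"))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  tip_states <- check_state(tip_states[phy$tip.label])
  # partial likelihoods L[node, state]
  L <- matrix(0, ntip + phy$Nnode, 2L)
  L[cbind(seq_len(ntip), tip_states + 1L)] <- 1
  L[ntip + seq_len(phy$Nnode), ] <- 1
  if (!is.null(tree$extended)) {
    if (is.null(tumor_states)) {
      stop("tree has extended branches: 'tumor_states' required",
           call. = FALSE)
    }
    for (i in seq_len(nrow(tree$extended))) {
      tip <- tree$extended$tip[i]
      idx <- match(tip, phy$tip.label)
      if (!tip %in% names(tumor_states)) {
        stop("missing tumor state for tip '", tip, "'", call. = FALSE)
      }
      ts <- check_state(tumor_states[[tip]])
      Pe <- transition_matrix(tree$extended$m_e[i], tree$extended$T_e[i])
      L[idx, ] <- L[idx, ] * Pe[, ts + 1L]
    }
  }
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]
    child <- po$edge[e, 2L]
    P <- transition_matrix(tree$m, po$edge.length[e])
    L[parent, ] <- L[parent, ] * (P %*% L[child, ])
  }
  sum(stationary_distribution(tree$m) * L[ntip + 1L, ])
}

#' Dataset log-likelihood on a fixed tree
#'
#' Genes are independent, so the dataset log-likelihood is the sum of
#' per-gene log pattern probabilities.
#'
#' @param tree a [dup_tree()].
#' @param tip_states matrix of 0/1 states, genes in rows, columns named by
#'   tip label.
#' @param tumor_states optional matrix of tumor states, columns named by
#'   the extended tips.
#' @return list with `loglik` and `zero_genes`, the row indices (if any)
#'   whose pattern probability underflowed to zero (their contribution is
#'   `-Inf`).
#' @export
dataset_loglik <- function(tree, tip_states, tumor_states = NULL) {
  stopifnot(inherits(tree, "dup_tree"))
  if (is.null(tip_states) || nrow(tip_states) == 0L) {
    return(list(loglik = 0, zero_genes = integer()))
  }
  lik <- vapply(seq_len(nrow(tip_states)), function(j) {
    gene_likelihood(tree,
                    stats::setNames(tip_states[j, ], colnames(tip_states)),
                    if (is.null(tumor_states)) NULL
                    else stats::setNames(tumor_states[j, ],
                                         colnames(tumor_states)))
  }, numeric(1L))
  zero <- which(lik <= 0)
  if (length(zero)) {
    warning("zero pattern probability for gene row(s) ",
            paste(utils::head(zero, 5L), collapse = ", "), call. = FALSE)
  }
  list(loglik = sum(log(lik)), zero_genes = zero)
}
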