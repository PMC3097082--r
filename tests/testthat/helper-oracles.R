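# Independent oracles used across the suite. These deliberately use brute
# force / direct counting, never the package's own fast paths.

# Mk likelihood by explicit summation over all internal-node state
# assignments (feasible for <= 5 leaves)
enum_mk_loglik <- function(tree, x, model, prior = rep(1 / model$k, model$k)) {
  k <- model$k
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    mk_transition_probs(model, tree$edge.length[e]))
  obs <- match(x[tree$tip.label], model$levels)
  grid <- expand.grid(rep(list(seq_len(k)), nn))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign_ <- c(obs, as.integer(grid[g, ]))
    p <- prior[assign_[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign_[tree$edge[e, 1L]]
      b <- assign_[tree$edge[e, 2L]]
      pe <- if (is.na(b)) {          # missing tip state: sum over states = 1
        1
      } else if (is.na(a)) NA else Ps[[e]][a, b]
      p <- p * pe
    }
    tot <- tot + p
  }
  log(tot)
}

# marginal ancestral probabilities by the same explicit enumeration
enum_mk_marginals <- function(tree, x, model, prior = rep(1 / model$k, model$k)) {
  k <- model$k
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    mk_transition_probs(model, tree$edge.length[e]))
  obs <- match(x[tree$tip.label], model$levels)
  grid <- expand.grid(rep(list(seq_len(k)), nn))
  w <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    assign_ <- c(obs, as.integer(grid[g, ]))
    p <- prior[assign_[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign_[tree$edge[e, 1L]]
      b <- assign_[tree$edge[e, 2L]]
      if (!is.na(b)) p <- p * Ps[[e]][a, b]
    }
    w[g] <- p
  }
  out <- matrix(0, nn, k)
  for (v in seq_len(nn)) for (s in seq_len(k))
    out[v, s] <- sum(w[grid[, v] == s])
  sweep(out, 1, rowSums(out), "/")
}

# clade frequencies in a tree sample by direct counting
count_clade_freq <- function(trees, clade) {
  mean(vapply(trees, function(tr) {
    is_monophyletic(tr, clade) && length(clade) < length(tr$tip.label)
  }, logical(1)))
}

# all non-trivial splits (canonical keys) displayed by a binary tree
displayed_split_keys <- function(tree) {
  vapply(extract_splits(tree, min_support = NULL), split_key, character(1))
}

# a random character state vector over given levels
random_states <- function(taxa, levels, seed) {
  set.seed(seed)
  stats::setNames(sample(levels, length(taxa), replace = TRUE), taxa)
}
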