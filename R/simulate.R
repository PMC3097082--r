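# Seeded generators. Each takes an explicit `seed`; RNG state of the caller
# is saved and restored so generators are reproducible and side-effect free.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a random rooted binary tree
#'
#' Sequential random leaf attachment: starting from a two-leaf tree,
#' each further leaf is grafted onto a uniformly chosen edge.
#' Branch lengths are exponential with mean 0.1. Deterministic per seed.
#'
#' @param n_leaves Number of leaves (>= 3).
#' @param seed Integer seed.
#' @param mean_bl Mean branch length (default 0.1).
#' @param labels Optional leaf labels (default \code{t1..tn}).
#' @return A rooted binary \code{phylo} with branch lengths.
#' @export
sim_tree <- function(n_leaves, seed = NULL, mean_bl = 0.1, labels = NULL) {
  stopifnot(n_leaves >= 3L)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_leaves))
  stopifnot(length(labels) == n_leaves, !anyDuplicated(labels))
  .with_seed(seed, {
    tr <- ape::read.tree(text = paste0("(", labels[1L], ",", labels[2L], ");"))
    tr$edge.length <- stats::rexp(2, 1 / mean_bl)
    for (i in seq(3L, n_leaves)) {
      edge <- sample.int(nrow(tr$edge), 1L)
      tr <- ape::bind.tree(
        tr,
        structure(list(edge = matrix(c(2L, 1L), 1, 2),
                       tip.label = labels[i],
                       edge.length = stats::rexp(1, 1 / mean_bl),
                       Nnode = 1L),
                  class = "phylo"),
        where = tr$edge[edge, 2L],
        position = stats::runif(1) * tr$edge.length[edge])
    }
    tr$node.label <- NULL
    # bind.tree splits edges; redraw all branch lengths for clean exponentials
    tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean_bl)
    validate_tree(tr)
    tr
  })
}

#' Simulate a nuclear/chloroplast tree pair with planted rogue taxa
#'
#' The chloroplast tree is the species tree; the nuclear tree is the
#' species tree with each "moved" clade pruned and re-grafted onto a
#' different, recorded edge - the topological signature left by
#' hybridization (or chloroplast capture / lineage sorting). Supports
#' are assigned by policy: 1.0 on every internal node by default.
#'
#' @param species_tree A rooted \code{phylo}; or \code{NULL} to draw one
#'   with [sim_tree()] (\code{n_leaves} leaves).
#' @param moved_clades List of taxon sets to move, each a clade of the
#'   species tree; or an integer \code{n_moves} to move that many
#'   randomly chosen leaves.
#' @param seed Integer seed.
#' @param n_leaves Leaves of the drawn species tree when
#'   \code{species_tree} is \code{NULL} (default 64).
#' @param n_moves Number of random single-leaf moves when
#'   \code{moved_clades} is \code{NULL} (default 1).
#' @param support Support value written on internal nodes (default 1.0).
#' @return List with \code{nuclear}, \code{chloroplast} (both
#'   \code{phylo} with supports) and \code{truth} (list of moved taxon
#'   sets).
#' @export
sim_hybrid_pair <- function(species_tree = NULL, moved_clades = NULL, seed = NULL,
                            n_leaves = 64L, n_moves = 1L, support = 1.0) {
  .with_seed(seed, {
    if (is.null(species_tree))
      species_tree <- sim_tree(n_leaves, seed = NULL)
    validate_tree(species_tree)
    tips <- species_tree$tip.label
    if (is.null(moved_clades)) {
      # draw single-leaf moves that leave independent, unambiguous signals:
      # each leaf is re-grafted well away from its origin (distance >= 3
      # edges), and no moved leaf may end up locally adjacent to another
      # moved leaf in either tree, else two planted events would merge
      nuc_built <- NULL
      for (attempt in seq_len(200L)) {
        moved <- as.list(sample(tips, n_moves))
        nuc_try <- species_tree
        for (cl in moved) nuc_try <- .regraft(nuc_try, cl)
        flat <- unlist(moved)
        local_clash <- function(tr) {
          any(vapply(flat, function(m) {
            sib <- .sibling_group(tr, m)
            length(sib) <= 3L && any(sib %in% setdiff(flat, m))
          }, logical(1)))
        }
        if (!local_clash(nuc_try) && !local_clash(species_tree)) {
          nuc_built <- nuc_try
          break
        }
      }
      if (is.null(nuc_built))
        stop("could not place ", n_moves, " non-interacting moves")
      lab <- function(tr) {
        tr$node.label <- rep(format(support), tr$Nnode)
        tr
      }
      return(list(nuclear = lab(nuc_built), chloroplast = lab(species_tree),
                  truth = lapply(moved, sort)))
    } else {
      moved <- lapply(moved_clades, as.character)
      for (cl in moved) {
        if (length(cl) == 1L) {
          if (!cl %in% tips) stop("moved taxon not in tree: ", cl)
        } else if (!is_monophyletic(species_tree, cl)) {
          stop("moved set is not a clade: ", paste(cl, collapse = ", "))
        }
      }
    }
    if (length(moved) > 1L) {
      flat <- unlist(moved)
      if (anyDuplicated(flat)) stop("moved clades overlap")
    }
    nuc <- species_tree
    for (cl in moved) nuc <- .regraft(nuc, cl)
    lab <- function(tr) {
      tr$node.label <- rep(format(support), tr$Nnode)
      tr
    }
    list(nuclear = lab(nuc), chloroplast = lab(species_tree),
         truth = lapply(moved, sort))
  })
}

# prune clade `cl` and re-graft it onto a random edge at topological
# distance >= 3 from its original attachment, guaranteeing an unambiguous
# topology change (short moves are confoundable with a move of the old or
# new neighbour)
.regraft <- function(tree, cl) {
  rest <- setdiff(tree$tip.label, cl)
  if (length(rest) < 3L) stop("tree too small to regraft ", paste(cl, collapse = ","))
  sub <- if (length(cl) == 1L) {
    structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = cl,
                   edge.length = 0.1, Nnode = 1L), class = "phylo")
  } else {
    ape::keep.tip(tree, cl)
  }
  back <- ape::drop.tip(tree, cl, collapse.singles = TRUE)
  # node of `back` marking the old attachment: the root of cl's former
  # sibling group (the pruned edge was absorbed into the edge above it)
  sib <- intersect(.sibling_group(tree, cl), back$tip.label)
  forbid <- integer(0)
  if (length(sib) > 0) {
    node <- if (length(sib) == 1L) match(sib, back$tip.label)
    else ape::getMRCA(back, sib)
    # all edges with an endpoint within graph distance 2 of `node`
    near <- node
    for (d in 1:2) {
      inc <- back$edge[, 1L] %in% near | back$edge[, 2L] %in% near
      near <- unique(c(near, as.vector(back$edge[inc, ])))
    }
    forbid <- which(back$edge[, 1L] %in% near & back$edge[, 2L] %in% near |
                      back$edge[, 1L] %in% near | back$edge[, 2L] %in% near)
  }
  ok <- setdiff(seq_len(nrow(back$edge)), forbid)
  pool <- if (length(ok) > 0) ok else seq_len(nrow(back$edge))
  e <- pool[sample.int(length(pool), 1L)]
  out <- ape::bind.tree(back, sub, where = back$edge[e, 2L],
                        position = 0.5 * back$edge.length[e])
  out$node.label <- NULL
  validate_tree(out)
  out
}

# the leaf set descending from the sibling edge(s) of clade cl
.sibling_group <- function(tree, cl) {
  n_tip <- length(tree$tip.label)
  node <- if (length(cl) == 1L) match(cl, tree$tip.label) else ape::getMRCA(tree, cl)
  parent <- tree$edge[tree$edge[, 2L] == node, 1L]
  if (length(parent) == 0L) return(character(0))
  kids <- tree$edge[tree$edge[, 1L] == parent, 2L]
  kids <- setdiff(kids, node)
  unlist(lapply(kids, function(kk) {
    if (kk <= n_tip) tree$tip.label[kk]
    else ape::extract.clade(tree, kk)$tip.label
  }))
}

#' Simulate discrete characters under an Mk model
#'
#' Root states are drawn from the uniform prior; states then evolve
#' edge-wise with the model's transition probabilities. Deterministic
#' per seed.
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param model An \code{mk_model} from [mk_rate_matrix()].
#' @param n_chars Number of independent characters.
#' @param seed Integer seed.
#' @return Character matrix (taxa x characters) over the model's state
#'   labels.
#' @export
sim_mk_characters <- function(tree, model, n_chars, seed = NULL) {
  stopifnot(inherits(model, "mk_model"), n_chars >= 1)
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  .with_seed(seed, {
    k <- model$k
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    Pfun <- .mk_expm_fun(model$Q)
    po <- ape::reorder.phylo(tree, "postorder")
    state <- matrix(NA_integer_, n_node, n_chars)
    root <- n_tip + 1L
    state[root, ] <- sample.int(k, n_chars, replace = TRUE)
    for (e in rev(seq_len(nrow(po$edge)))) {   # preorder
      p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
      P <- Pfun(po$edge.length[e])
      ps <- state[p, ]
      for (s in unique(ps)) {
        idx <- which(ps == s)
        state[ch, idx] <- sample.int(k, length(idx), replace = TRUE, prob = P[s, ])
      }
    }
    out <- matrix(model$levels[state[seq_len(n_tip), , drop = FALSE]],
                  nrow = n_tip, dimnames = list(tree$tip.label, NULL))
    out
  })
}

#' Simulate an alignment with planted gap runs
#'
#' Baseline random nucleotide sequences with gap runs planted at stated
#' positions in stated taxa - ground truth for exercising simple indel
#' coding.
#'
#' @param n_taxa Number of taxa.
#' @param length Alignment length.
#' @param gap_events List of events, each
#'   \code{list(start =, end =, taxa =)} (taxa as names or indices).
#' @param seed Integer seed.
#' @return A list: \code{alignment} and \code{truth} (data.frame of
#'   planted start, end, taxa).
#' @export
sim_indel_alignment <- function(n_taxa, length, gap_events = list(), seed = NULL) {
  stopifnot(n_taxa >= 2L, length >= 1L)
  .with_seed(seed, {
    taxa <- paste0("t", seq_len(n_taxa))
    m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * length, replace = TRUE),
                n_taxa, length, dimnames = list(taxa, NULL))
    truth <- data.frame(start = integer(0), end = integer(0), taxa = character(0))
    for (ev in gap_events) {
      stopifnot(ev$start >= 1, ev$end <= length, ev$start <= ev$end)
      who <- if (is.numeric(ev$taxa)) taxa[ev$taxa] else as.character(ev$taxa)
      for (w in who) m[w, seq(ev$start, ev$end)] <- "-"
      truth <- rbind(truth, data.frame(start = ev$start, end = ev$end,
                                       taxa = paste(who, collapse = ",")))
    }
    list(alignment = as_alignment(m), truth = truth)
  })
}
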