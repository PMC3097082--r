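#' Parse a Newick tree with posterior-probability node labels
#'
#' Reads a single rooted Newick statement into an \code{ape} \code{phylo}
#' object. Numeric internal-node labels are interpreted as clade supports
#' (posterior probabilities) in \[0, 1\], the dominant convention for
#' Bayesian consensus trees. Bracketed comments and other exotic
#' annotations are rejected.
#'
#' @param text A character scalar holding one well-formed Newick
#'   statement terminated by \code{";"}.
#' @return A \code{phylo} object. Supports, where present, are stored in
#'   \code{node.label} and can be recovered with [node_supports()].
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2)0.98:0.05,C:0.3);")
#' node_supports(tr)
#' @seealso [write_newick()], [extract_splits()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("\\[", text)) {
    stop("bracketed comments/annotations are not supported (offset ",
         regexpr("\\[", text)[1], ")")
  }
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi < 0) stop("malformed newick: no terminating ';' (offset ", nchar(text), ")")
  if (nchar(trimws(substring(text, semi + 1L))) > 0L)
    stop("malformed newick: trailing content after ';' (offset ", semi + 1L, ")")
  # cheap structural check with offsets before handing to ape
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed newick: unbalanced ')' at offset ", i)
    }
  }
  if (depth != 0L) stop("malformed newick: ", depth, " unclosed '(' (offset ", nchar(text), ")")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick: could not be parsed")
  validate_tree(tr)
  tr
}

#' Validate the structural invariants of a tree
#'
#' Checks leaf-name uniqueness, non-negative branch lengths and that
#' numeric node labels (supports) lie in \[0, 1\].
#'
#' @param tree A \code{phylo} object.
#' @return The tree, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 0L)
    stop("tree has no tip labels (compressed multiPhylo element?)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stop("empty leaf name")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  s <- node_supports(tree)
  bad <- !is.na(s) & (s < 0 | s > 1)
  if (any(bad)) stop("node supports outside [0, 1]: ", paste(s[bad], collapse = ", "))
  invisible(tree)
}

#' Extract node supports from a tree
#'
#' Numeric internal-node labels are read as supports; empty or
#' non-numeric labels yield \code{NA}.
#'
#' @param tree A \code{phylo} object.
#' @return A numeric vector of length \code{tree$Nnode} (supports in
#'   internal-node order), or all-\code{NA} when the tree has no labels.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  lab <- tree$node.label
  s <- suppressWarnings(as.numeric(lab))
  s[!nzchar(trimws(lab))] <- NA_real_
  s
}

#' Write a tree as a Newick string
#'
#' Deterministic output: children are emitted in stored order and
#' supports appear as internal node labels, so
#' \code{parse_newick(write_newick(t))} reproduces topology, branch
#' lengths and supports.
#'
#' @param tree A \code{phylo} object.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when \code{file} is given.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_tree(tree)
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read one or more trees from a Newick file
#'
#' A file with several statements is returned as a \code{multiPhylo}
#' tree sample; a single statement as a \code{phylo}.
#'
#' @param file Path to a Newick file (one tree per statement).
#' @return \code{phylo} or \code{multiPhylo}.
#' @export
read_trees <- function(file) {
  tr <- ape::read.tree(file)
  if (is.null(tr)) stop("no trees found in ", file)
  if (inherits(tr, "multiPhylo")) lapply(tr, validate_tree) else validate_tree(tr)
  tr
}

# descendant tip labels of every internal node; list indexed by node number - Ntip
.node_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  lapply(pp, function(i) tree$tip.label[i])
}

#' Bipartitions (splits) of a tree above a support threshold
#'
#' One split is produced per internal edge. A split is stored with the
#' clade side (\code{taxa}), the leaf universe and the support of the
#' subtending node; identity between splits is evaluated on the
#' canonical unrooted bipartition (the side containing the
#' lexicographically smallest taxon), so a split and its complement are
#' the same object. Trivial splits (singleton or all-but-one) are
#' excluded. Edges without a support label are excluded unless
#' \code{min_support} is \code{NULL}, mirroring the convention that only
#' clades with a printed posterior probability count as supported.
#'
#' @param tree A \code{phylo} with at least 3 leaves.
#' @param min_support Numeric threshold; splits with support \code{>=}
#'   this value are kept. \code{0} keeps all labelled edges;
#'   \code{NULL} keeps every internal edge including unlabelled ones.
#' @return A list of \code{tree_split} objects (possibly empty).
#' @examples
#' tr <- parse_newick("((A,B)1.0,(C,D)1.0);")
#' extract_splits(tr, 0.95)
#' @export
extract_splits <- function(tree, min_support = 0) {
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  if (n_tip < 3L) return(list())
  universe <- sort(tree$tip.label)
  clades <- .node_clades(tree)
  supports <- node_supports(tree)
  out <- list()
  keys <- character(0)
  for (i in seq_along(clades)) {
    side <- clades[[i]]
    if (length(side) <= 1L || length(side) >= n_tip - 1L) next
    sup <- supports[i]
    if (!is.null(min_support)) {
      if (is.na(sup) || sup < min_support) next
    }
    sp <- new_split(side, universe, sup)
    key <- split_key(sp)
    j <- match(key, keys)
    if (is.na(j)) {
      out[[length(out) + 1L]] <- sp
      keys <- c(keys, key)
    } else {
      # same unrooted split seen twice (e.g. both root children): keep max support
      old <- out[[j]]$support
      if (is.na(old) || (!is.na(sup) && sup > old)) out[[j]]$support <- sup
    }
  }
  out
}

#' Construct a split object
#'
#' @param taxa Character vector, one side of the bipartition (a clade).
#' @param universe Character vector of all leaves.
#' @param support Numeric support in \[0, 1\] or \code{NA}.
#' @return A \code{tree_split}: list with sorted \code{taxa},
#'   \code{universe}, \code{support}.
#' @export
new_split <- function(taxa, universe, support = NA_real_) {
  taxa <- sort(unique(as.character(taxa)))
  universe <- sort(unique(as.character(universe)))
  if (!all(taxa %in% universe)) stop("split side not contained in universe")
  if (length(taxa) == 0L || length(taxa) == length(universe))
    stop("split side must be a proper non-empty subset of the universe")
  structure(list(taxa = taxa, universe = universe, support = as.numeric(support)),
            class = "tree_split")
}

#' @export
print.tree_split <- function(x, ...) {
  cat(sprintf("<split> %s | %d other taxa (support %s)\n",
              paste(x$taxa, collapse = ","),
              length(x$universe) - length(x$taxa),
              ifelse(is.na(x$support), "NA", format(x$support))))
  invisible(x)
}

#' Canonical identity key of a split
#'
#' The canonical side is the one containing the lexicographically
#' smallest taxon of the universe, so a split and its complement share
#' one key.
#'
#' @param split A \code{tree_split}.
#' @return A character scalar.
#' @export
split_key <- function(split) {
  side <- split$taxa
  if (!(split$universe[1L] %in% side)) side <- setdiff(split$universe, side)
  paste(side, collapse = "\r")
}

#' Majority-rule consensus of a tree sample
#'
#' Summarises a sample of rooted trees on one leaf set (e.g. a Bayesian
#' posterior sample) as the consensus containing exactly the clades
#' whose frequency exceeds \code{cutoff} (strictly; unanimous clades are
#' always retained). Each retained clade is annotated with its empirical
#' frequency as the support label, the quantity reported as a posterior
#' probability on consensus trees.
#'
#' @param sample A \code{multiPhylo} or list of \code{phylo} on identical
#'   leaf sets.
#' @param cutoff Inclusion threshold in \[0.5, 1\]; default 0.5 gives the
#'   standard 50 % majority rule.
#' @return A \code{phylo}; node labels carry clade frequencies.
#' @examples
#' trees <- c(replicate(6, parse_newick("((A,B),C,D);"), simplify = FALSE),
#'            replicate(4, parse_newick("((A,C),B,D);"), simplify = FALSE))
#' write_newick(majority_consensus(trees))
#' @export
majority_consensus <- function(sample, cutoff = 0.5) {
  if (inherits(sample, "phylo")) sample <- list(sample)
  sample <- unclass(sample)
  if (length(sample) == 0L) stop("empty tree sample")
  stopifnot(cutoff >= 0.5, cutoff <= 1)
  leaves <- sort(sample[[1L]]$tip.label)
  for (tr in sample) {
    if (!identical(sort(tr$tip.label), leaves))
      stop("trees in the sample have different leaf sets")
  }
  n <- length(sample)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in sample) {
    for (cl in .node_clades(tr)) {
      if (length(cl) < 2L || length(cl) >= length(leaves)) next
      key <- paste(sort(cl), collapse = "\r")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]] / n, numeric(1))
  keep <- freq > cutoff | freq >= 1
  clades <- lapply(keys[keep], function(k) strsplit(k, "\r", fixed = TRUE)[[1L]])
  .build_tree_from_clades(clades, freq[keep], leaves)
}

# assemble a rooted tree (newick text) from a compatible clade set
.build_tree_from_clades <- function(clades, freqs, leaves) {
  ord <- order(vapply(clades, length, integer(1)), decreasing = TRUE)
  clades <- clades[ord]
  freqs <- freqs[ord]
  render <- function(members, avail, label) {
    # avail: indices of clades that are proper subsets of `members`
    maximal <- avail[vapply(avail, function(i) {
      !any(vapply(avail, function(j)
        j != i && all(clades[[i]] %in% clades[[j]]), logical(1)))
    }, logical(1))]
    pieces <- character(0)
    used <- character(0)
    for (i in maximal) {
      cl <- clades[[i]]
      inner <- avail[vapply(avail, function(j)
        j != i && all(clades[[j]] %in% cl) && length(clades[[j]]) < length(cl),
        logical(1))]
      pieces <- c(pieces, render(cl, inner, format(freqs[i])))
      used <- c(used, cl)
    }
    pieces <- c(pieces, sort(setdiff(members, used)))
    paste0("(", paste(pieces, collapse = ","), ")", label)
  }
  avail0 <- which(vapply(clades, function(cl) length(cl) < length(leaves), logical(1)))
  txt <- paste0(render(leaves, avail0, ""), ";")
  ape::read.tree(text = txt)
}

#' Prune a tree to a subset of leaves
#'
#' Removes all leaves outside \code{keep}; unifurcations created by the
#' removal are suppressed with branch lengths summed. When a chain of
#' nodes collapses, the support retained is that of the edge closest to
#' the leaves (the support describing the surviving clade content).
#'
#' @param tree A \code{phylo}.
#' @param keep Character vector of leaf names to retain (at least 2,
#'   all present in the tree).
#' @return The pruned \code{phylo}.
#' @export
prune_tree <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0)
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  if (setequal(keep, tree$tip.label)) return(tree)
  # ape::drop.tip sums branch lengths across suppressed unifurcations and
  # keeps the leafward node label, which is exactly the semantics we want.
  ape::drop.tip(tree, setdiff(tree$tip.label, keep), collapse.singles = TRUE)
}

#' Resolve polytomies deterministically with zero-length branches
#'
#' Multifurcations are resolved left-to-right in stored child order:
#' the first two children are combined, then the third is added, and so
#' on. Inserted branches have length 0 (when the tree has branch
#' lengths) and carry no support, so Mk likelihoods are unchanged.
#'
#' @param tree A \code{phylo}.
#' @return A strictly bifurcating \code{phylo} on the same leaf set.
#' @examples
#' write_newick(resolve_polytomies(parse_newick("(A,B,C);")))
#' @export
resolve_polytomies <- function(tree) {
  validate_tree(tree)
  has_len <- !is.null(tree$edge.length)
  supports <- tree$node.label
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], factor(tree$edge[, 1L], levels = seq_len(n_tip + tree$Nnode)))
  edge_of <- integer(n_tip + tree$Nnode)  # edge index leading to node
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  lab_of <- function(node) {
    if (node <= n_tip) tree$tip.label[node]
    else if (!is.null(supports)) supports[node - n_tip] else ""
  }
  recurse <- function(node) {
    kids <- children[[node]]
    if (length(kids) == 0L) return(tree$tip.label[node])
    sub <- vapply(kids, function(k) {
      s <- recurse(k)
      if (has_len) paste0(s, ":", format(tree$edge.length[edge_of[k]], digits = 15))
      else s
    }, character(1))
    while (length(sub) > 2L) {
      merged <- paste0("(", sub[1L], ",", sub[2L], ")",
                       if (has_len) ":0" else "")
      sub <- c(merged, sub[-(1:2)])
    }
    paste0("(", paste(sub, collapse = ","), ")",
           if (node > n_tip && !is.null(supports)) supports[node - n_tip] else "")
  }
  root <- n_tip + 1L
  txt <- paste0(recurse(root), ";")
  out <- ape::read.tree(text = txt)
  validate_tree(out)
  out
}

#' Test whether a set of taxa is monophyletic
#'
#' True iff some node's descendant leaf set equals \code{taxa} exactly
#' (the tree is treated as rooted as given). A single taxon is trivially
#' monophyletic.
#'
#' @param tree A \code{phylo}.
#' @param taxa Character vector of leaf names.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  validate_tree(tree)
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) == 1L) return(TRUE)
  if (length(taxa) == length(tree$tip.label)) return(TRUE)
  any(vapply(.node_clades(tree), function(cl) setequal(cl, taxa), logical(1)))
}
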