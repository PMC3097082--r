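#' Restrict two trees to their shared taxa
#'
#' Nuclear and chloroplast matrices rarely sample identical taxa, so
#' conflict analysis operates on the leaf-set intersection.
#'
#' @param t1,t2 \code{phylo} trees.
#' @return A list with elements \code{t1}, \code{t2} (pruned trees) and
#'   \code{shared} (the sorted intersection). Fewer than 4 shared taxa is
#'   an error: no non-trivial conflict is possible.
#' @export
restrict_to_shared <- function(t1, t2) {
  validate_tree(t1); validate_tree(t2)
  shared <- sort(intersect(t1$tip.label, t2$tip.label))
  if (length(shared) < 4L)
    stop("only ", length(shared), " shared taxa; need at least 4")
  list(t1 = prune_tree(t1, shared), t2 = prune_tree(t2, shared), shared = shared)
}

#' Do two splits conflict?
#'
#' Two bipartitions of the same taxon set are incompatible iff all four
#' side intersections are non-empty; equivalently, no single tree can
#' display both. The predicate is symmetric and ignores rooting.
#'
#' @param s1,s2 \code{tree_split} objects on an identical universe.
#' @return Logical scalar.
#' @examples
#' u <- LETTERS[1:4]
#' splits_conflict(new_split(c("A","B"), u), new_split(c("A","C"), u)) # TRUE
#' splits_conflict(new_split(c("A","B"), u), new_split(c("A","B","C"), u)) # FALSE
#' @export
splits_conflict <- function(s1, s2) {
  stopifnot(inherits(s1, "tree_split"), inherits(s2, "tree_split"))
  if (!identical(s1$universe, s2$universe))
    stop("splits have different taxon universes")
  a1 <- s1$taxa; b1 <- setdiff(s1$universe, a1)
  a2 <- s2$taxa; b2 <- setdiff(s2$universe, a2)
  length(intersect(a1, a2)) > 0 && length(intersect(a1, b2)) > 0 &&
    length(intersect(b1, a2)) > 0 && length(intersect(b1, b2)) > 0
}

# conflict test on plain character sides over a universe, after removing `drop`
.sides_conflict_after <- function(a1, a2, universe, drop = character(0)) {
  keep <- setdiff(universe, drop)
  a1 <- intersect(a1, keep); a2 <- intersect(a2, keep)
  b1 <- setdiff(keep, a1); b2 <- setdiff(keep, a2)
  length(intersect(a1, a2)) > 0 && length(intersect(a1, b2)) > 0 &&
    length(intersect(b1, a2)) > 0 && length(intersect(b1, b2)) > 0
}

#' Find well-supported conflicting split pairs between two trees
#'
#' Both trees are restricted to their shared taxa; splits with support
#' at or above the per-tree threshold are extracted from each, and every
#' incompatible pair is returned. The default 0.95/0.95 operationalises
#' the rule that a clade counts as contradicted only when opposed by a
#' clade with posterior probability >= 0.95 in the other analysis.
#'
#' @param t1,t2 \code{phylo} trees sharing at least 4 taxa.
#' @param thr1,thr2 Support thresholds for tree 1 / tree 2.
#' @return A list of \code{conflict_pair} objects, ordered by split size
#'   then lexicographically. Each has \code{split1}, \code{split2} and
#'   \code{shared} (the taxon universe used).
#' @export
find_conflicting_pairs <- function(t1, t2, thr1 = 0.95, thr2 = 0.95) {
  r <- restrict_to_shared(t1, t2)
  s1 <- extract_splits(r$t1, thr1)
  s2 <- extract_splits(r$t2, thr2)
  pairs <- list()
  if (length(s1) > 0 && length(s2) > 0) {
    # incompatibility via cell counts on a membership matrix (fast path;
    # equivalent to splits_conflict pair by pair)
    A1 <- t(vapply(s1, function(s) r$shared %in% s$taxa, logical(length(r$shared))))
    A2 <- t(vapply(s2, function(s) r$shared %in% s$taxa, logical(length(r$shared))))
    c11 <- A1 %*% t(A2); c10 <- A1 %*% t(!A2)
    c01 <- (!A1) %*% t(A2); c00 <- (!A1) %*% t(!A2)
    hit <- which(c11 > 0 & c10 > 0 & c01 > 0 & c00 > 0, arr.ind = TRUE)
    for (h in seq_len(nrow(hit))) {
      pairs[[length(pairs) + 1L]] <-
        structure(list(split1 = s1[[hit[h, 1L]]], split2 = s2[[hit[h, 2L]]],
                       shared = r$shared),
                  class = "conflict_pair")
    }
  }
  if (length(pairs) > 1L) {
    ord <- order(vapply(pairs, function(p) length(p$split1$taxa), integer(1)),
                 vapply(pairs, function(p) length(p$split2$taxa), integer(1)),
                 vapply(pairs, function(p) paste(p$split1$taxa, collapse = ","), character(1)),
                 vapply(pairs, function(p) paste(p$split2$taxa, collapse = ","), character(1)))
    pairs <- pairs[ord]
  }
  pairs
}

#' @export
print.conflict_pair <- function(x, ...) {
  cat(sprintf("<conflict> [%s] (%s)  vs  [%s] (%s)\n",
              paste(x$split1$taxa, collapse = ","), format(x$split1$support),
              paste(x$split2$taxa, collapse = ","), format(x$split2$support)))
  invisible(x)
}

# the taxa implicated by one conflicting pair: union of the minimum-cardinality
# intersection cells (removing any one of these cells reconciles the pair)
.pair_core_taxa <- function(pair) {
  a1 <- pair$split1$taxa; b1 <- setdiff(pair$split1$universe, a1)
  a2 <- pair$split2$taxa; b2 <- setdiff(pair$split2$universe, a2)
  cells <- list(intersect(a1, a2), intersect(a1, b2),
                intersect(b1, a2), intersect(b1, b2))
  sizes <- vapply(cells, length, integer(1))
  sort(unique(unlist(cells[sizes == min(sizes)])))
}

#' Cluster conflicting split pairs into discrete incongruence events
#'
#' Implements iterative rogue-clade removal: at each step the candidate
#' clades are the leaf-descendant sets of nodes (including single
#' leaves, excluding the root) of either tree restricted to the taxa not
#' yet removed. Among candidates whose removal reconciles at least one
#' remaining pair, the one with the smallest clade size is chosen (ties:
#' most pairs reconciled, then lexicographically smallest taxon). Each
#' removal is one event; the pairs it reconciles are attributed to it.
#' The loop ends when no conflicts remain, so events partition the
#' input pair list.
#'
#' \code{involved_taxa} of an event is the rogue clade plus, for each
#' attributed pair, the union of its minimum-cardinality conflict cells
#' (computed on the original shared-universe splits) - the taxa whose
#' placement actually generates the contradiction.
#'
#' @param pairs List of \code{conflict_pair} from
#'   [find_conflicting_pairs()] on the same tree pair.
#' @param t1,t2 The same two trees.
#' @return An \code{incongruence_set}: list of events, each with
#'   \code{rogue_clade}, \code{attributed_pairs}, \code{involved_taxa}
#'   and \code{label}.
#' @export
cluster_events <- function(pairs, t1, t2) {
  events <- list()
  if (length(pairs) == 0L)
    return(structure(list(), class = "incongruence_set"))
  r <- restrict_to_shared(t1, t2)
  universe <- r$shared
  n <- length(universe)
  # conflict-cell membership per pair, as 0/1 rows over the universe:
  # a pair still conflicts under a removal set iff all four cells keep >=1 taxon
  cell <- function(p, f1, f2) {
    a1 <- universe %in% p$split1$taxa
    a2 <- universe %in% p$split2$taxa
    as.numeric(f1(a1) & f2(a2))
  }
  idf <- identity; neg <- `!`
  C11 <- t(vapply(pairs, cell, numeric(n), idf, idf))
  C10 <- t(vapply(pairs, cell, numeric(n), idf, neg))
  C01 <- t(vapply(pairs, cell, numeric(n), neg, idf))
  C00 <- t(vapply(pairs, cell, numeric(n), neg, neg))
  removed <- character(0)
  remaining <- seq_along(pairs)
  while (length(remaining) > 0L) {
    keep_now <- setdiff(universe, removed)
    cl <- c(as.list(keep_now),
            .node_clades(prune_tree(r$t1, keep_now)),
            .node_clades(prune_tree(r$t2, keep_now)))
    cl <- cl[vapply(cl, function(x) length(x) < length(keep_now), logical(1))]
    cl <- cl[!duplicated(vapply(cl, function(x)
      paste(sort(x), collapse = "\r"), character(1)))]
    # K: one column per candidate = indicator of taxa kept after removing it
    base_keep <- as.numeric(universe %in% keep_now)
    K <- vapply(cl, function(x) base_keep * as.numeric(!(universe %in% x)),
                numeric(n))
    still <- (C11[remaining, , drop = FALSE] %*% K > 0) &
      (C10[remaining, , drop = FALSE] %*% K > 0) &
      (C01[remaining, , drop = FALSE] %*% K > 0) &
      (C00[remaining, , drop = FALSE] %*% K > 0)
    n_res <- length(remaining) - colSums(still)
    ok <- which(n_res > 0L)
    if (length(ok) == 0L) stop("no candidate clade resolves the remaining conflicts")
    sizes <- vapply(cl[ok], length, integer(1))
    first_tax <- vapply(cl[ok], function(x) sort(x)[1L], character(1))
    pick <- ok[order(sizes, -n_res[ok], first_tax)][1L]
    rogue <- sort(cl[[pick]])
    attributed <- remaining[!still[, pick]]
    involved <- sort(unique(c(rogue, unlist(lapply(pairs[attributed], .pair_core_taxa)))))
    events[[length(events) + 1L]] <- structure(
      list(rogue_clade = rogue,
           attributed_pairs = pairs[attributed],
           involved_taxa = involved,
           label = paste(rogue, collapse = "+")),
      class = "incongruence_event")
    removed <- c(removed, rogue)
    remaining <- setdiff(remaining, attributed)
  }
  structure(events, class = "incongruence_set")
}

#' @export
print.incongruence_event <- function(x, ...) {
  cat(sprintf("<event> rogue: %s | %d conflicting pair(s) | involved: %s%s\n",
              paste(x$rogue_clade, collapse = ", "),
              length(x$attributed_pairs),
              paste(x$involved_taxa, collapse = ", "),
              if (isTRUE(x$polyploid_candidate)) " | ALLOPOLYPLOIDY CANDIDATE" else ""))
  invisible(x)
}

#' @export
print.incongruence_set <- function(x, ...) {
  cat(length(x), "incongruence event(s)\n")
  for (i in seq_along(x)) {
    cat(sprintf("%d) ", i)); print(x[[i]])
  }
  invisible(x)
}

#' @export
summary.incongruence_set <- function(object, ...) {
  n_flag <- sum(vapply(object, function(e) isTRUE(e$polyploid_candidate), logical(1)))
  structure(list(n_events = length(object), n_flagged = n_flag), class = "summary.incongruence_set")
}

#' @export
print.summary.incongruence_set <- function(x, ...) {
  cat(sprintf("%d incongruence event(s), %d flagged as allopolyploidy candidates\n",
              x$n_events, x$n_flagged))
  invisible(x)
}

#' Clades supported in both trees
#'
#' Splits present (as unrooted bipartitions of the shared taxon set) in
#' both trees with support >= \code{thr} in each, sorted by clade size
#' descending. These are the clades on which the two analyses agree.
#'
#' @param t1,t2 \code{phylo} trees sharing at least 4 taxa.
#' @param thr Support threshold applied in both trees.
#' @return List of \code{tree_split} (sides taken from tree 1); the
#'   \code{support} is the minimum of the two supports.
#' @export
shared_supported_clades <- function(t1, t2, thr = 0.95) {
  r <- restrict_to_shared(t1, t2)
  s1 <- extract_splits(r$t1, thr)
  s2 <- extract_splits(r$t2, thr)
  k2 <- vapply(s2, split_key, character(1))
  out <- list()
  for (a in s1) {
    j <- match(split_key(a), k2)
    if (!is.na(j)) {
      a$support <- min(a$support, s2[[j]]$support)
      out[[length(out) + 1L]] <- a
    }
  }
  if (length(out) > 1L)
    out <- out[order(vapply(out, function(s) length(s$taxa), integer(1)), decreasing = TRUE)]
  out
}
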