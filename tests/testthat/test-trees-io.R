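test_that("newick parsing reads leaves, lengths and supports", {
  tr <- parse_newick("(A,B);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_null(tr$edge.length)

  tr2 <- parse_newick("((A:0.1,B:0.2)0.98:0.05,C:0.3);")
  expect_equal(sort(tr2$edge.length), c(0.05, 0.1, 0.2, 0.3))
  expect_true(0.98 %in% node_supports(tr2))

  expect_error(parse_newick("((A,B)"), "unclosed|malformed")
  expect_error(parse_newick("(A,B));"), "offset")
  expect_error(parse_newick("(A,A);"), "duplicate")
  expect_error(parse_newick("(A[&x=1],B);"), "bracket")
})

test_that("parse/write round-trip preserves topology, lengths and supports", {
  for (seed in 1:20) {
    tr <- sim_tree(sample(5:40, 1), seed = seed)
    tr$node.label <- as.character(round(runif(tr$Nnode), 2))
    txt <- write_newick(tr)
    tr2 <- parse_newick(txt)
    expect_identical(write_newick(tr2), txt)
    expect_setequal(tr2$tip.label, tr$tip.label)
    expect_equal(sort(tr2$edge.length), sort(tr$edge.length))
    expect_setequal(tr2$node.label, tr$node.label)
    # same clades with the same supports
    sp <- extract_splits(tr, 0); sp2 <- extract_splits(tr2, 0)
    expect_setequal(vapply(sp2, split_key, character(1)),
                    vapply(sp, split_key, character(1)))
  }
  expect_match(write_newick(parse_newick("((A,B)0.98,C);")), ")0.98", fixed = TRUE)
  expect_equal(write_newick(parse_newick("(A,B);")), "(A,B);")
})

test_that("extract_splits applies thresholds and drops trivial splits", {
  tr <- parse_newick("((A,B)1.0,(C,D)1.0);")
  sp <- extract_splits(tr, 0.95)
  expect_length(sp, 1L)
  expect_setequal(sp[[1]]$taxa, c("A", "B"))

  star <- parse_newick("(A,B,C,D,E);")
  expect_length(extract_splits(star, 0), 0L)

  cat6 <- parse_newick("(((((A,B)1.0,C)1.0,D)1.0,E)1.0,F);")
  expect_length(extract_splits(cat6, 0.95), 3L)

  # unlabelled edges excluded unless min_support is NULL
  mixed <- parse_newick("((((A,B),C)0.9,(D,E)0.4),F);")
  expect_length(extract_splits(mixed, 0.5), 1L)
  expect_length(extract_splits(mixed, 0), 2L)
  expect_length(extract_splits(mixed, NULL), 3L)
  # the two children of the root describe one unrooted split: deduplicated,
  # keeping the larger support
  rooted2 <- parse_newick("(((A,B),C)0.9,(D,E)0.4);")
  sp2 <- extract_splits(rooted2, 0)
  expect_length(sp2, 1L)
  expect_equal(sp2[[1]]$support, 0.9)
})

test_that("splits are canonical: a split equals its complement", {
  u <- LETTERS[1:6]
  s1 <- new_split(c("A", "B"), u)
  s2 <- new_split(setdiff(u, c("A", "B")), u)
  expect_identical(split_key(s1), split_key(s2))
  expect_error(new_split(u, u), "proper")
  expect_error(new_split(c("Z"), u), "universe")
})

test_that("majority consensus matches hand-counted frequencies", {
  t_ab <- parse_newick("((A,B),C,D);")
  t_ac <- parse_newick("((A,C),B,D);")
  trees <- c(replicate(6, t_ab, simplify = FALSE),
             replicate(4, t_ac, simplify = FALSE))
  cons <- majority_consensus(trees)
  expect_true(is_monophyletic(cons, c("A", "B")))
  sp <- extract_splits(cons, 0)
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$support, 0.6)
  expect_equal(sp[[1]]$support, count_clade_freq(trees, c("A", "B")))

  # identical trees: same topology, all supports 1
  same <- replicate(3, parse_newick("((A,B),(C,D));"), simplify = FALSE)
  cs <- majority_consensus(same)
  expect_true(all(vapply(extract_splits(cs, 0), function(s) s$support, numeric(1)) == 1))
  expect_true(is_monophyletic(cs, c("A", "B")))
  expect_true(is_monophyletic(cs, c("C", "D")))

  # cutoff 1 retains only unanimous splits
  c1 <- majority_consensus(trees, cutoff = 1)
  expect_length(extract_splits(c1, 0), 0L)

  expect_error(majority_consensus(list(t_ab, parse_newick("(A,B,X);"))),
               "different leaf sets")
})

test_that("consensus supports equal empirical clade frequencies on random samples", {
  set.seed(11)
  base <- sim_tree(8, seed = 99)
  trees <- lapply(1:20, function(i) {
    if (i <= 14) base else sim_tree(8, seed = 200 + i)
  })
  cons <- majority_consensus(trees)
  for (s in extract_splits(cons, 0)) {
    expect_equal(s$support, count_clade_freq(trees, s$taxa), tolerance = 1e-12)
  }
})

test_that("prune keeps induced topology, sums lengths, keeps leafward support", {
  tr <- parse_newick("(((A:0.1,B:0.2)0.9:0.2,C:0.3)0.8:0.1,(D:1,E:1)0.7:1);")
  p <- prune_tree(tr, c("A", "B", "D", "E"))
  expect_setequal(p$tip.label, c("A", "B", "D", "E"))
  # 0.2 (AB edge) + 0.1 (suppressed ABC edge) merge into 0.3
  ab_node <- ape::getMRCA(p, c("A", "B"))
  expect_equal(p$edge.length[p$edge[, 2] == ab_node], 0.3)
  expect_equal(node_supports(p)[ab_node - 4L], 0.9)

  expect_identical(write_newick(prune_tree(tr, tr$tip.label)), write_newick(tr))
  expect_error(prune_tree(tr, c("A", "Z")), "Z")

  # cherry from 4 leaves
  ch <- prune_tree(parse_newick("((A,B),(C,D));"), c("A", "C"))
  expect_setequal(ch$tip.label, c("A", "C"))
})

test_that("pruning is idempotent and preserves induced splits (brute force, <= 8 leaves)", {
  for (seed in 1:10) {
    tr <- sim_tree(8, seed = seed)
    tr$node.label <- rep("1", tr$Nnode)
    keep <- sort(sample(tr$tip.label, 5))
    p1 <- prune_tree(tr, keep)
    expect_identical(write_newick(prune_tree(p1, keep)), write_newick(p1))
    # every split of the pruned tree is the restriction of an original split
    restr <- unique(vapply(extract_splits(tr, NULL), function(s) {
      side <- intersect(s$taxa, keep)
      if (length(side) < 2 || length(side) > length(keep) - 2) return(NA_character_)
      split_key(new_split(side, keep))
    }, character(1)))
    for (s in extract_splits(p1, NULL)) {
      expect_true(split_key(s) %in% restr)
    }
  }
})

test_that("resolve_polytomies is deterministic, zero-length and likelihood-neutral", {
  expect_equal(write_newick(resolve_polytomies(parse_newick("(A,B,C);"))),
               "((A,B),C);")
  bin <- parse_newick("((A,B),(C,D));")
  expect_equal(write_newick(resolve_polytomies(bin)), write_newick(bin))

  tr <- parse_newick("((A:1,B:1,C:1,D:1)0.9:1,(E:1,F:1)0.8:1);")
  r <- resolve_polytomies(tr)
  expect_true(ape::is.binary(r))
  expect_setequal(r$tip.label, tr$tip.label)
  new_edges <- setdiff(r$edge.length, tr$edge.length)
  expect_true(all(new_edges == 0))

  m <- mk_rate_matrix("SYM", 3, c(0.2, 0.5, 0.9), levels = c("x", "y", "z"))
  x <- c(A = "x", B = "y", C = "z", D = "x", E = "y", F = "z")
  expect_equal(mk_loglik(r, x, m), mk_loglik(tr, x, m), tolerance = 1e-10)
  # agreement with the conventional library resolution too
  r2 <- ape::multi2di(tr, random = FALSE)
  expect_equal(mk_loglik(r2, x, m), mk_loglik(tr, x, m), tolerance = 1e-10)
})

test_that("is_monophyletic is exact for every internal node's descendant set", {
  tr <- parse_newick("((A,B),C);")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
  for (seed in 1:5) {
    t2 <- sim_tree(10, seed = seed)
    pp <- ape::prop.part(t2)
    for (cl in pp) {
      expect_true(is_monophyletic(t2, t2$tip.label[cl]))
    }
    expect_false(is_monophyletic(
      t2, c(t2$tip.label[pp[[2]]][1], setdiff(t2$tip.label, t2$tip.label[pp[[2]]])[1],
            t2$tip.label[pp[[2]]][2])) &&
        length(pp[[2]]) > 2)
  }
})
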