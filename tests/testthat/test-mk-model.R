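test_that("rate matrices have the declared structure and parameter counts", {
  er <- mk_rate_matrix("ER", 2, 0.5)
  expect_equal(unname(er$Q), matrix(c(-0.5, 0.5, 0.5, -0.5), 2, 2))
  expect_equal(mk_n_params("ER", 4), 1L)
  expect_equal(mk_n_params("SYM", 4), 6L)
  expect_equal(mk_n_params("ARD", 4), 12L)

  sym <- mk_rate_matrix("SYM", 4, c(1, 2, 3, 4, 5, 6))
  expect_true(isSymmetric(unname(sym$Q - diag(diag(sym$Q)))))
  expect_equal(unname(sym$Q[1, 2]), 1)
  expect_equal(unname(sym$Q[3, 4]), 6)
  expect_equal(rowSums(sym$Q), rep(0, 4), ignore_attr = TRUE)

  ard <- mk_rate_matrix("ARD", 3, 1:6)
  expect_equal(unname(ard$Q[1, 2]), 1)
  expect_equal(unname(ard$Q[2, 1]), 3)
  expect_equal(rowSums(ard$Q), rep(0, 3), ignore_attr = TRUE)

  expect_error(mk_rate_matrix("SYM", 4, 1:5), "needs 6")
  expect_error(mk_rate_matrix("ER", 3, -1), "positive")
})

test_that("transition probabilities: identity at t=0, closed form, stationarity", {
  m <- mk_rate_matrix("ER", 2, 0.7)
  expect_equal(mk_transition_probs(m, 0), diag(2))
  for (t in c(0.1, 0.5, 2)) {
    P <- mk_transition_probs(m, t)
    expect_equal(P[1, 1], 0.5 + 0.5 * exp(-2 * 0.7 * t), tolerance = 1e-12)
    expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-10)
  }
  m4 <- mk_rate_matrix("ER", 4, 1)
  expect_equal(unname(mk_transition_probs(m4, 500)),
               matrix(0.25, 4, 4), tolerance = 1e-9)
  # general (ARD) exponential also has stochastic rows
  ard <- mk_rate_matrix("ARD", 3, c(0.2, 1.5, 0.4, 0.9, 2, 0.1))
  expect_equal(unname(rowSums(mk_transition_probs(ard, 0.8))), rep(1, 3), tolerance = 1e-10)
})

test_that("pruning likelihood equals the enumeration oracle", {
  # zero-length 2-leaf tree, both tips in the same state: logL = log(1/k)
  tr2 <- parse_newick("(A:0,B:0);")
  m <- mk_rate_matrix("ER", 3, 0.4, levels = c("p", "q", "r"))
  expect_equal(mk_loglik(tr2, c(A = "p", B = "p"), m), log(1 / 3), tolerance = 1e-12)

  # 4-leaf binary tree, k = 2, against brute force
  tr <- parse_newick("((A:0.3,B:0.1):0.2,(C:0.4,D:0.2):0.1);")
  m2 <- mk_rate_matrix("ARD", 2, c(0.8, 0.3), levels = c("0", "1"))
  x <- c(A = "0", B = "1", C = "1", D = "0")
  expect_equal(mk_loglik(tr, x, m2), enum_mk_loglik(tr, x, m2), tolerance = 1e-10)

  # missing data: an all-"?" leaf on a zero-length pendant changes nothing
  x2 <- c(x, E = "?")
  tr_e <- parse_newick("(((A:0.3,B:0.1):0.2,(C:0.4,D:0.2):0.1):0,E:0);")
  expect_equal(mk_loglik(tr_e, x2, m2), mk_loglik(tr, x, m2), tolerance = 1e-10)
  expect_equal(mk_loglik(tr_e, x2, m2), enum_mk_loglik(tr_e, x2, m2), tolerance = 1e-10)

  expect_error(mk_loglik(tr, c(A = "0", B = "1", C = "0"), m2), "absent")
})

test_that("likelihood is invariant to taxon input order", {
  tr <- sim_tree(8, seed = 5)
  m <- mk_rate_matrix("SYM", 3, c(0.3, 0.6, 0.9))
  x <- random_states(tr$tip.label, m$levels, seed = 6)
  expect_equal(mk_loglik(tr, x[sample(names(x))], m), mk_loglik(tr, x, m))
})

test_that("model nesting orders the maximised likelihoods", {
  tr <- sim_tree(12, seed = 9)
  x <- sim_mk_characters(tr, mk_rate_matrix("SYM", 3, c(0.5, 1.2, 0.8)), 30, seed = 10)
  lv <- sort(unique(as.vector(x)))
  f_er <- fit_mk(tr, x, "ER", levels = lv, n_starts = 2)
  f_sym <- fit_mk(tr, x, "SYM", levels = lv, n_starts = 2)
  f_ard <- fit_mk(tr, x, "ARD", levels = lv, n_starts = 2)
  expect_lte(f_er$loglik, f_sym$loglik + 1e-6)
  expect_lte(f_sym$loglik, f_ard$loglik + 1e-6)
})

test_that("a constant character drives the rate to the lower bound", {
  tr <- sim_tree(10, seed = 11)
  x <- stats::setNames(rep("A", 10), tr$tip.label)
  fit <- fit_mk(tr, x, "ER", levels = c("A", "B"))
  expect_lt(coef(fit), 1e-6)
  # and the likelihood approaches log(1/k) from below
  expect_equal(fit$loglik, log(0.5), tolerance = 1e-4)
})

test_that("ER rate is recovered from simulated data", {
  tr <- sim_tree(32, seed = 12, mean_bl = 0.3)
  m <- mk_rate_matrix("ER", 2, 0.5)
  x <- sim_mk_characters(tr, m, 500, seed = 13)
  fit <- fit_mk(tr, x, "ER", levels = m$levels, n_starts = 2)
  expect_lt(abs(coef(fit) - 0.5) / 0.5, 0.2)
})

test_that("fit agrees with an independent implementation (ape::ace)", {
  tr <- sim_tree(24, seed = 20, mean_bl = 0.5)
  m <- mk_rate_matrix("ER", 3, 0.6, levels = c("a", "b", "c"))
  x <- sim_mk_characters(tr, m, 1, seed = 21)[, 1]
  fit <- fit_mk(tr, x, "ER", levels = m$levels)
  a <- ape::ace(factor(x[tr$tip.label]), tr, type = "discrete", model = "ER")
  expect_equal(unname(coef(fit)), unname(a$rates), tolerance = 1e-3)
  # ace reports the likelihood without the 1/k root weighting
  expect_equal(fit$loglik, a$loglik + log(1 / 3), tolerance = 1e-4)
  asr <- ancestral_states(fit)
  expect_equal(unclass(asr), unclass(a$lik.anc), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("likelihood-ratio tests have the right df, clamping and errors", {
  tr <- sim_tree(10, seed = 30)
  x <- sim_mk_characters(tr, mk_rate_matrix("ER", 4, 0.4, levels = LETTERS[1:4]),
                         20, seed = 31)
  f_er <- fit_mk(tr, x, "ER", levels = LETTERS[1:4], n_starts = 2)
  f_sym <- fit_mk(tr, x, "SYM", levels = LETTERS[1:4], n_starts = 2)
  lrt <- mk_lrt(f_er, f_sym)
  expect_equal(lrt$df, 5L)
  expect_gte(lrt$statistic, 0)
  expect_true(lrt$p.value >= 0 && lrt$p.value <= 1)
  expect_error(mk_lrt(f_sym, f_er), "not nested")
  # anova orders the fits itself
  expect_equal(anova(f_sym, f_er)$df, 5L)
  # equal log-likelihoods give statistic 0, p = 1
  f_dup <- f_sym; f_dup$loglik <- f_er$loglik; f_dup$kind <- "SYM"
  expect_equal(mk_lrt(f_er, f_dup)$statistic, 0)
  expect_equal(mk_lrt(f_er, f_dup)$p.value, 1)
  # ER vs ARD, k = 2 has df 1
  y <- sim_mk_characters(tr, mk_rate_matrix("ER", 2, 0.4), 20, seed = 32)
  g0 <- fit_mk(tr, y, "ER", levels = c("0", "1"), n_starts = 2)
  g1 <- fit_mk(tr, y, "ARD", levels = c("0", "1"), n_starts = 2)
  expect_equal(mk_lrt(g0, g1)$df, 1L)
})

test_that("marginal ancestral states match enumeration and basic symmetry", {
  # symmetric 2-leaf tree, opposite states, ER: root is 50/50
  tr2 <- parse_newick("(A:0.4,B:0.4);")
  m2 <- mk_rate_matrix("ER", 2, 0.6, levels = c("0", "1"))
  fit2 <- list(tree = tr2, states = matrix(c("0", "1"), 2, 1,
                                           dimnames = list(c("A", "B"), NULL)),
               levels = c("0", "1"), kind = "ER", model = m2,
               loglik = NA, df = 1L, root_prior = "uniform")
  class(fit2) <- "mk_fit"
  expect_equal(as.vector(unclass(ancestral_states(fit2))), c(0.5, 0.5))

  # 4- and 5-leaf trees against the enumeration oracle
  for (seed in 1:6) {
    tr <- sim_tree(sample(4:5, 1), seed = seed)
    kind <- sample(c("ER", "SYM", "ARD"), 1)
    k <- sample(2:3, 1)
    m <- mk_rate_matrix(kind, k, runif(mk_n_params(kind, k), 0.2, 1.5))
    x <- random_states(tr$tip.label, m$levels, seed = 100 + seed)
    fit <- list(tree = tr, states = matrix(x, ncol = 1, dimnames = list(names(x), NULL)),
                levels = m$levels, kind = kind, model = m,
                loglik = NA, df = 1L, root_prior = "uniform")
    class(fit) <- "mk_fit"
    asr <- ancestral_states(fit)
    expect_equal(rowSums(asr), rep(1, tr$Nnode), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(unclass(asr), enum_mk_marginals(tr, x, m),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # all tips in one state: that state has the top scaled likelihood everywhere
  tr <- sim_tree(10, seed = 40)
  x <- stats::setNames(rep("B", 10), tr$tip.label)
  m <- mk_rate_matrix("ER", 2, 0.3, levels = c("A", "B"))
  fit <- list(tree = tr, states = matrix(x, ncol = 1, dimnames = list(names(x), NULL)),
              levels = m$levels, kind = "ER", model = m,
              loglik = NA, df = 1L, root_prior = "uniform")
  class(fit) <- "mk_fit"
  asr <- ancestral_states(fit)
  expect_true(all(asr[, "B"] > asr[, "A"]))
})

test_that("ancestral states are invariant to polytomy resolution order", {
  tr <- parse_newick("((A:1,B:1,C:1,D:1)0.9:1,(E:1,F:1)0.8:1);")
  m <- mk_rate_matrix("ER", 2, 0.5, levels = c("0", "1"))
  x <- c(A = "0", B = "0", C = "1", D = "1", E = "0", F = "1")
  r1 <- resolve_polytomies(tr)
  r2 <- ape::multi2di(tr, random = FALSE)
  f <- function(t) {
    fit <- fit_mk(t, x, "ER", levels = c("0", "1"), n_starts = 2)
    root_row <- unclass(ancestral_states(fit))[1, ]
    list(ll = fit$loglik, root = root_row)
  }
  a <- f(r1); b <- f(r2)
  expect_equal(a$ll, b$ll, tolerance = 1e-6)
  expect_equal(a$root, b$root, tolerance = 1e-5)
})

test_that("the fitted-model object behaves like a classed R model", {
  tr <- sim_tree(12, seed = 50)
  x <- sim_mk_characters(tr, mk_rate_matrix("ER", 2, 0.6), 40, seed = 51)
  fit <- fit_mk(tr, x, "ER", n_starts = 2)
  expect_s3_class(fit, "mk_fit")
  expect_named(coef(fit), "rate")
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 1L)
  expect_output(print(fit), "Mk model fit")
  expect_output(print(summary(fit)), "AIC")
  sims <- simulate(fit, nsim = 5, seed = 52)
  expect_equal(dim(sims), c(12L, 5L))
  expect_true(all(sims %in% fit$levels))
  pred <- predict(fit)
  expect_equal(nrow(pred), tr$Nnode)
  # stationary root prior is accepted and uniform for symmetric models
  f2 <- fit_mk(tr, x, "ER", root_prior = "stationary", n_starts = 1)
  expect_equal(f2$loglik, fit$loglik, tolerance = 1e-6)
})
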