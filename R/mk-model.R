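#' Build an Mk rate model
#'
#' Constructs the generator (instantaneous rate matrix) of a k-state
#' continuous-time Markov model of discrete character evolution:
#' \describe{
#'   \item{ER}{equal rates: one shared rate for every transition.}
#'   \item{SYM}{symmetric: each unordered state pair has its own rate,
#'     applying to both directions; parameters fill the upper triangle
#'     row-major: (1,2), (1,3), ..., (2,3), ...}
#'   \item{ARD}{all rates different: every ordered pair has its own
#'     rate; parameters fill the off-diagonals row-major.}
#' }
#' Parameter counts are 1, k(k-1)/2 and k(k-1) respectively. The
#' diagonal is set so rows sum to zero.
#'
#' @param kind One of \code{"ER"}, \code{"SYM"}, \code{"ARD"}.
#' @param k Number of states (>= 2).
#' @param rates Positive rate parameters of the required length.
#' @param levels Optional state labels (length k).
#' @return An \code{mk_model}: list with \code{kind}, \code{k},
#'   \code{rates}, \code{Q}, \code{levels}.
#' @examples
#' mk_rate_matrix("ER", 2, 0.5)$Q
#' @export
mk_rate_matrix <- function(kind = c("ER", "SYM", "ARD"), k, rates, levels = NULL) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  np <- mk_n_params(kind, k)
  if (length(rates) != np)
    stop(kind, " with k = ", k, " needs ", np, " rate(s), got ", length(rates))
  if (any(rates <= 0)) stop("rates must be positive")
  if (is.null(levels)) levels <- as.character(seq_len(k) - 1L)
  stopifnot(length(levels) == k)
  Q <- matrix(0, k, k, dimnames = list(levels, levels))
  if (kind == "ER") {
    Q[] <- rates[1L]
  } else if (kind == "SYM") {
    idx <- 1L
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      Q[i, j] <- Q[j, i] <- rates[idx]
      idx <- idx + 1L
    }
  } else {
    idx <- 1L
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      Q[i, j] <- rates[idx]
      idx <- idx + 1L
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(kind = kind, k = k, rates = as.numeric(rates), Q = Q,
                 levels = levels),
            class = "mk_model")
}

#' Number of free rates of an Mk model kind
#' @param kind \code{"ER"}, \code{"SYM"} or \code{"ARD"}.
#' @param k Number of states.
#' @return Integer.
#' @export
mk_n_params <- function(kind, k) {
  switch(kind,
         ER = 1L,
         SYM = as.integer(k * (k - 1L) / 2L),
         ARD = as.integer(k * (k - 1L)),
         stop("unknown model kind ", kind))
}

#' Transition probabilities over a branch
#'
#' \code{exp(Q t)}: the probability of each ordered state change along
#' a branch of length \code{t}. Symmetric generators (ER, SYM) use a
#' symmetric eigendecomposition; general generators use
#' \code{ape::matexpo}.
#'
#' @param model An \code{mk_model} (or a bare generator matrix).
#' @param t Non-negative branch length.
#' @return A k x k stochastic matrix (rows sum to 1).
#' @export
mk_transition_probs <- function(model, t) {
  Q <- if (inherits(model, "mk_model")) model$Q else model
  stopifnot(t >= 0)
  if (t == 0) return(diag(nrow(Q)))
  P <- if (isSymmetric.matrix(unname(Q), tol = 1e-12)) {
    e <- eigen(Q, symmetric = TRUE)
    e$vectors %*% (exp(e$values * t) * t(e$vectors))
  } else {
    ape::matexpo(Q * t)
  }
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# column maxima of a small-row matrix without apply() overhead
.colmax <- function(m) {
  out <- m[1L, ]
  for (i in seq_len(nrow(m))[-1L]) out <- pmax(out, m[i, ])
  out
}

# Precompute an exponentiator closure for one Q (eigen once, reused per edge).
.mk_expm_fun <- function(Q) {
  if (isSymmetric.matrix(unname(Q), tol = 1e-12)) {
    e <- eigen(Q, symmetric = TRUE)
    V <- e$vectors
    function(t) {
      if (t == 0) return(diag(nrow(Q)))
      P <- V %*% (exp(e$values * t) * t(V))
      P[P < 0] <- 0
      P
    }
  } else {
    function(t) {
      if (t == 0) return(diag(nrow(Q)))
      ape::matexpo(Q * t)
    }
  }
}

# Coerce character data into a tip index matrix (ntip x nchar, NA = missing)
# aligned with tree$tip.label. Accepts a named vector, matrix or data.frame.
.mk_tip_index <- function(tree, states, levels) {
  if (is.data.frame(states)) states <- as.matrix(states)
  if (is.null(dim(states))) states <- matrix(states, ncol = 1,
                                             dimnames = list(names(states), NULL))
  if (is.null(rownames(states)))
    stop("character data must be named by taxon")
  missing <- setdiff(tree$tip.label, rownames(states))
  if (length(missing) > 0)
    stop("tree leaves absent from character data: ", paste(missing, collapse = ", "))
  X <- states[tree$tip.label, , drop = FALSE]
  X[X %in% c("?", "-", "", "NA")] <- NA
  bad <- !is.na(X) & !(X %in% levels)
  if (any(bad))
    stop("states outside declared alphabet: ", paste(unique(X[bad]), collapse = ", "))
  matrix(match(X, levels), nrow = nrow(X), dimnames = dimnames(X))
}

# Felsenstein pruning. Returns per-site log-likelihoods plus the pieces
# needed for marginal ancestral reconstruction.
.mk_prune <- function(tree, tip_idx, model, root_prior, keep_partials = FALSE) {
  k <- model$k
  S <- ncol(tip_idx)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths")
  Pfun <- .mk_expm_fun(model$Q)
  po <- ape::reorder.phylo(tree, "postorder")
  partial <- vector("list", n_node)
  logsc <- matrix(0, n_node, S)
  for (i in seq_len(n_tip)) {
    m <- matrix(1, k, S)
    obs <- tip_idx[i, ]
    has <- !is.na(obs)
    if (any(has)) {
      m[, has] <- 0
      m[cbind(obs[has], which(has))] <- 1
    }
    partial[[i]] <- m
  }
  Pmats <- vector("list", n_node)  # transition matrix of the edge above each node
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    P <- Pfun(po$edge.length[e])
    Pmats[[ch]] <- P
    msg <- P %*% partial[[ch]]
    if (is.null(partial[[p]])) partial[[p]] <- matrix(1, k, S)
    partial[[p]] <- partial[[p]] * msg
    logsc[p, ] <- logsc[p, ] + logsc[ch, ]
    mx <- .colmax(partial[[p]])
    mx[mx == 0] <- 1   # impossible data; keep zeros, logL will be -Inf
    partial[[p]] <- partial[[p]] / rep(mx, each = k)
    logsc[p, ] <- logsc[p, ] + log(mx)
  }
  root <- n_tip + 1L
  prior <- .mk_root_prior(model, root_prior)
  site_loglik <- log(as.vector(prior %*% partial[[root]])) + logsc[root, ]
  out <- list(loglik = sum(site_loglik), site_loglik = site_loglik, prior = prior)
  if (keep_partials) {
    out$partial <- partial
    out$Pmats <- Pmats
    out$tree_po <- po
  }
  out
}

.mk_root_prior <- function(model, root_prior) {
  k <- model$k
  if (identical(root_prior, "uniform")) return(rep(1 / k, k))
  if (identical(root_prior, "stationary")) {
    # left null vector of Q (pi Q = 0), i.e. eigenvector of t(Q) at eigenvalue 0
    e <- eigen(t(model$Q))
    v <- Re(e$vectors[, which.min(abs(Re(e$values)))])
    v <- abs(v)
    return(v / sum(v))
  }
  stop("unknown root prior")
}

#' Mk log-likelihood of discrete character data on a tree
#'
#' Felsenstein pruning likelihood with, by default, a uniform root
#' prior over states. Missing states (\code{"?"} or \code{NA}) enter as
#' all-ones partial vectors; zero-length branches contribute identity
#' transitions. Multifurcating trees are handled directly (a polytomy
#' is the limit of zero-length internal branches, so the likelihood
#' matches any zero-length resolution).
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param states Character states: named vector, or matrix/data.frame
#'   with taxa as rownames and characters as columns.
#' @param model An \code{mk_model} from [mk_rate_matrix()].
#' @param root_prior \code{"uniform"} (default) or \code{"stationary"}.
#' @return Log-likelihood (sum over characters).
#' @export
mk_loglik <- function(tree, states, model, root_prior = "uniform") {
  stopifnot(inherits(model, "mk_model"))
  tip_idx <- .mk_tip_index(tree, states, model$levels)
  .mk_prune(tree, tip_idx, model, root_prior)$loglik
}

#' Fit an Mk model of discrete character evolution by maximum likelihood
#'
#' The workhorse of ancestral-state reconstruction: estimates the
#' transition rates of an ER, SYM or ARD Mk model on a fixed tree by
#' bounded quasi-Newton search on log-rates (bounds \eqn{[10^{-8},
#' 10^{3}]} per rate, five deterministic starting points), and returns
#' a classed model object supporting \code{print}, \code{summary},
#' \code{coef}, \code{logLik}, \code{anova} (likelihood-ratio test
#' against a nested fit), \code{predict}/[ancestral_states()] (per-node
#' scaled marginal state likelihoods), \code{simulate} and \code{plot}.
#'
#' @param tree Rooted \code{phylo} with branch lengths. Polytomies are
#'   allowed (equivalent to zero-length resolutions); use
#'   [resolve_polytomies()] first if a strictly binary tree is wanted.
#' @param states Named character vector or taxa-by-characters matrix;
#'   \code{"?"}/\code{NA} is missing data.
#' @param kind Model kind: \code{"ER"}, \code{"SYM"} or \code{"ARD"}.
#' @param levels State alphabet; defaults to the sorted observed states.
#' @param root_prior \code{"uniform"} (default) or \code{"stationary"}.
#' @param n_starts Number of deterministic multi-starts (default 5).
#' @return An object of class \code{mk_fit}.
#' @examples
#' tr <- sim_tree(16, seed = 1)
#' x <- sim_mk_characters(tr, mk_rate_matrix("ER", 2, 0.5), 50, seed = 2)
#' fit <- fit_mk(tr, x, "ER")
#' coef(fit); logLik(fit)
#' @export
fit_mk <- function(tree, states, kind = c("ER", "SYM", "ARD"), levels = NULL,
                   root_prior = "uniform", n_starts = 5L) {
  kind <- match.arg(kind)
  validate_tree(tree)
  if (is.data.frame(states)) states <- as.matrix(states)
  if (is.null(dim(states))) states <- matrix(states, ncol = 1,
                                             dimnames = list(names(states), NULL))
  if (is.null(levels)) {
    obs <- states[!(states %in% c("?", "-", "", "NA")) & !is.na(states)]
    levels <- sort(unique(as.character(obs)))
  }
  k <- length(levels)
  if (k < 2L) stop("need at least 2 states (observed or declared)")
  tip_idx <- .mk_tip_index(tree, states, levels)
  np <- mk_n_params(kind, k)
  lo <- log(1e-8); hi <- log(1e3)
  nll <- function(logr) {
    m <- mk_rate_matrix(kind, k, exp(logr), levels)
    -(.mk_prune(tree, tip_idx, m, root_prior)$loglik)
  }
  base_starts <- c(0.05, 0.5, 0.01, 2, 10)
  starts <- lapply(seq_len(n_starts), function(s) {
    r0 <- base_starts[((s - 1L) %% length(base_starts)) + 1L]
    log(r0 * (1 + 0.02 * (seq_len(np) - 1L)))   # deterministic stagger
  })
  best <- NULL
  statuses <- integer(0)
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    statuses <- c(statuses, res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("Mk optimisation failed from all starting points")
  model <- mk_rate_matrix(kind, k, exp(best$par), levels)
  rn <- .mk_rate_names(kind, levels)
  rates <- stats::setNames(model$rates, rn)
  structure(list(tree = tree, states = states, levels = levels, kind = kind,
                 rates = rates, model = model, loglik = -best$value,
                 df = np, root_prior = root_prior,
                 converged = any(statuses == 0L), n_starts_ok = length(statuses),
                 call = match.call()),
            class = "mk_fit")
}

.mk_rate_names <- function(kind, levels) {
  k <- length(levels)
  if (kind == "ER") return("rate")
  if (kind == "SYM") {
    nm <- character(0)
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k))
      nm <- c(nm, paste0(levels[i], "<->", levels[j]))
    return(nm)
  }
  nm <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j) nm <- c(nm, paste0(levels[i], "->", levels[j]))
  nm
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk model fit (%s, %d states: %s)\n", x$kind, length(x$levels),
              paste(x$levels, collapse = ", ")))
  cat(sprintf("  log-likelihood: %.4f  (df = %d)\n", x$loglik, x$df))
  cat("  rates:\n")
  print(signif(x$rates, 4))
  if (!x$converged) cat("  warning: optimiser did not report clean convergence\n")
  invisible(x)
}

#' @export
summary.mk_fit <- function(object, ...) {
  structure(list(fit = object,
                 aic = -2 * object$loglik + 2 * object$df,
                 Q = object$model$Q),
            class = "summary.mk_fit")
}

#' @export
print.summary.mk_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  AIC: %.4f\n", x$aic))
  cat("  generator Q:\n")
  print(signif(x$Q, 4))
  invisible(x)
}

#' @export
coef.mk_fit <- function(object, ...) object$rates

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' Likelihood-ratio test between nested Mk fits
#'
#' ER is nested in SYM, and both in ARD. The statistic is
#' \eqn{2(\log L_{general} - \log L_{nested})} (clamped at 0), referred
#' to a chi-square with df equal to the difference in parameter count.
#'
#' @param nested,general \code{mk_fit} objects on the same tree and data.
#' @return A list of class \code{mk_lrt}: \code{statistic}, \code{df},
#'   \code{p.value} plus the two model kinds.
#' @export
mk_lrt <- function(nested, general) {
  stopifnot(inherits(nested, "mk_fit"), inherits(general, "mk_fit"))
  order_ <- c(ER = 1L, SYM = 2L, ARD = 3L)
  if (order_[nested$kind] >= order_[general$kind])
    stop(nested$kind, " is not nested in ", general$kind)
  if (!identical(nested$levels, general$levels))
    stop("fits use different state alphabets")
  df <- general$df - nested$df
  stat <- max(0, 2 * (general$loglik - nested$loglik))
  structure(list(nested = nested$kind, general = general$kind,
                 statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "mk_lrt")
}

#' @export
print.mk_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: %s vs %s\n", x$nested, x$general))
  cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
anova.mk_fit <- function(object, ...) {
  others <- list(...)
  if (length(others) != 1L || !inherits(others[[1L]], "mk_fit"))
    stop("anova.mk_fit compares exactly two mk_fit objects")
  fits <- list(object, others[[1L]])
  ord <- order(vapply(fits, function(f) f$df, integer(1)))
  mk_lrt(fits[[ord[1L]]], fits[[ord[2L]]])
}

#' Scaled marginal likelihoods of ancestral states
#'
#' For every internal node, the marginal likelihood of each state given
#' all tip data, normalised to sum to one - the quantities drawn as
#' pies at nodes in ancestral-state reconstruction figures. Computed by
#' combining the node's subtree partial likelihoods (pruning pass) with
#' the likelihood of the rest of the tree (preorder pass).
#'
#' @param fit An \code{mk_fit}; or use \code{predict()} on the fit.
#' @param site Which character (column) to reconstruct; default 1.
#' @return A matrix (internal nodes x states) of class \code{mk_asr};
#'   rows sum to 1. Row names are node numbers (ape convention); node
#'   labels, when present, are kept in \code{attr(, "node.label")}.
#' @export
ancestral_states <- function(fit, site = 1L) {
  stopifnot(inherits(fit, "mk_fit"))
  tree <- fit$tree
  tip_idx <- .mk_tip_index(tree, fit$states, fit$levels)
  stopifnot(site >= 1L, site <= ncol(tip_idx))
  tip_idx <- tip_idx[, site, drop = FALSE]
  pr <- .mk_prune(tree, tip_idx, fit$model, fit$root_prior, keep_partials = TRUE)
  po <- pr$tree_po
  k <- fit$model$k
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  up <- vector("list", n_node)        # "rest of tree" message per node
  up[[root]] <- matrix(pr$prior, k, 1)
  children <- split(po$edge[, 2L], factor(po$edge[, 1L], levels = seq_len(n_node)))
  # preorder: reverse postorder edge order visits parents before children
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    sibs <- setdiff(children[[p]], ch)
    h <- up[[p]]
    for (s in sibs) h <- h * (pr$Pmats[[s]] %*% pr$partial[[s]])
    g <- t(pr$Pmats[[ch]]) %*% h
    tot <- sum(g)
    if (tot > 0) g <- g / tot
    up[[ch]] <- g
  }
  res <- matrix(NA_real_, tree$Nnode, k,
                dimnames = list(seq(n_tip + 1L, n_node), fit$levels))
  for (v in seq(n_tip + 1L, n_node)) {
    w <- as.vector(pr$partial[[v]]) * as.vector(up[[v]])
    res[v - n_tip, ] <- w / sum(w)
  }
  structure(res, class = c("mk_asr", "matrix"),
            node.label = tree$node.label)
}

#' @export
predict.mk_fit <- function(object, site = 1L, ...) ancestral_states(object, site)

#' @export
print.mk_asr <- function(x, digits = 4, ...) {
  cat("Scaled marginal ancestral-state likelihoods (rows = internal nodes):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
simulate.mk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sim_mk_characters(object$tree, object$model, n_chars = nsim, seed = NULL)
}

#' @export
plot.mk_fit <- function(x, site = 1L, cex_pie = 0.5, ...) {
  asr <- ancestral_states(x, site)
  ape::plot.phylo(x$tree, ...)
  ape::nodelabels(pie = unclass(asr), cex = cex_pie)
  invisible(asr)
}
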