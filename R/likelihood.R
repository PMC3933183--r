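#' Substitution models for the partitioned likelihood engine
#'
#' Three families are supported, each with discrete-gamma rate variation:
#' `"GTR+G"` (general time-reversible, 6 exchangeabilities + 4 frequencies),
#' `"BIN+G"` (2-state binary analogue for RY data), and `"AA+G"` (fixed WAG
#' empirical exchangeabilities). Rate matrices are scaled so the expected
#' substitution rate at equilibrium is 1.
#'
#' @param family `"GTR+G"`, `"BIN+G"` or `"AA+G"`.
#' @param rates exchangeabilities: 6 values in order AC, AG, AT, CG, CT, GT
#'   for GTR; a single value for BIN; ignored for AA (WAG is used).
#' @param freq state frequencies (must be positive and sum to 1); defaults:
#'   uniform for GTR/BIN, the WAG frequencies for AA.
#' @param alpha gamma shape parameter (> 0).
#' @param ncat number of discrete gamma categories (default 4).
#' @return object of class `substitution_model`.
#' @export
substitution_model <- function(family = c("GTR+G", "BIN+G", "AA+G"),
                               rates = NULL, freq = NULL, alpha = 1,
                               ncat = 4L) {
  family <- match.arg(family)
  if (alpha <= 0) stopf("gamma shape alpha must be > 0")
  nstate <- switch(family, `GTR+G` = 4L, `BIN+G` = 2L, `AA+G` = 20L)
  if (is.null(freq))
    freq <- if (family == "AA+G") wag_frequencies() else rep(1 / nstate, nstate)
  if (length(freq) != nstate) stopf("need %d frequencies", nstate)
  if (any(freq <= 0)) stopf("frequencies must be positive")
  freq <- freq / sum(freq)
  if (family == "GTR+G") {
    if (is.null(rates)) rates <- rep(1, 6)
    if (length(rates) != 6L || any(rates <= 0)) stopf("GTR needs 6 positive rates")
  } else if (family == "BIN+G") {
    if (is.null(rates)) rates <- 1
    if (length(rates) != 1L || rates <= 0) stopf("BIN needs 1 positive rate")
  } else rates <- NULL
  structure(list(family = family, rates = rates, freq = unname(freq),
                 alpha = alpha, ncat = as.integer(ncat)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("<substitution_model> %s, alpha=%.4g, %d gamma categories\n",
              x$family, x$alpha, x$ncat))
  invisible(x)
}

#' Discrete-gamma rate categories
#'
#' Equal-probability discretization of the mean-1 gamma distribution
#' (shape = rate = alpha); each category's rate is the conditional mean of
#' its probability bin, so the probability-weighted mean rate is exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param ncat number of categories (>= 1).
#' @return list with `rates` and `probs`.
#' @export
discrete_gamma <- function(alpha, ncat = 4L) {
  if (alpha <= 0) stopf("alpha must be > 0")
  if (ncat < 1L) stopf("ncat must be >= 1")
  if (ncat == 1L) return(list(rates = 1, probs = 1))
  q <- stats::qgamma(seq_len(ncat - 1L) / ncat, shape = alpha, rate = alpha)
  # conditional bin means via the incomplete-gamma identity
  p_up <- stats::pgamma(c(q, Inf), shape = alpha + 1, rate = alpha)
  p_lo <- stats::pgamma(c(0, q), shape = alpha + 1, rate = alpha)
  rates <- ncat * (p_up - p_lo)
  list(rates = rates / sum(rates) * ncat, probs = rep(1 / ncat, ncat))
}

#' Scaled instantaneous rate matrix of a model
#'
#' `Q[i, j] = s_ij * freq[j]` off-diagonal, rows summing to zero, scaled so
#' the equilibrium substitution rate `-sum(freq_i Q_ii)` is 1.
#'
#' @param model a `substitution_model`.
#' @return the rate matrix `Q`.
#' @export
rate_matrix <- function(model) {
  freq <- model$freq
  if (any(freq <= 0)) stopf("frequencies must be positive")
  S <- switch(model$family,
    `GTR+G` = {
      r <- model$rates
      m <- matrix(0, 4, 4)
      m[1, 2] <- m[2, 1] <- r[1]; m[1, 3] <- m[3, 1] <- r[2]
      m[1, 4] <- m[4, 1] <- r[3]; m[2, 3] <- m[3, 2] <- r[4]
      m[2, 4] <- m[4, 2] <- r[5]; m[3, 4] <- m[4, 3] <- r[6]
      dimnames(m) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
      m
    },
    `BIN+G` = matrix(c(0, model$rates, model$rates, 0), 2, 2,
                     dimnames = list(c("R", "Y"), c("R", "Y"))),
    `AA+G` = wag_matrix())
  Q <- S * rep(freq, each = nrow(S))
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q / mu
}

# Reversible eigen-decomposition of Q for fast P(t) = expm(Qt).
decompose_q <- function(Q, freq) {
  d <- sqrt(freq)
  B <- Q * (d / rep(d, each = length(d)))  # diag(d) Q diag(1/d), symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(vals = e$values, vecs = e$vectors, d = d)
}

transition_probs <- function(decomp, t) {
  if (t < 0) stopf("negative time")
  E <- decomp$vecs %*% (exp(decomp$vals * t) * t(decomp$vecs))
  P <- E * rep(decomp$d, each = length(decomp$d)) / decomp$d
  P[P < 0] <- 0
  P
}

# ---- tip-state encodings ----------------------------------------------------

state_space <- function(alphabet) {
  switch(alphabet,
    nt = {
      states <- c("A", "C", "G", "T")
      amb <- list(R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0),
                  W = c(1, 0, 0, 1), K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
                  B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1),
                  V = c(1, 1, 1, 0))
      list(states = states, amb = amb)
    },
    ry = list(states = c("R", "Y"), amb = list()),
    aa = {
      states <- AA_STATES
      amb <- list(B = as.numeric(states %in% c("N", "D")),
                  Z = as.numeric(states %in% c("Q", "E")))
      list(states = states, amb = amb)
    },
    stopf("unknown alphabet '%s'", alphabet))
}

# indicator row vector for one character
char_indicator <- function(ch, ss) {
  k <- length(ss$states)
  i <- match(ch, ss$states)
  if (!is.na(i)) { v <- numeric(k); v[i] <- 1; return(v) }
  if (!is.null(ss$amb[[ch]])) return(as.numeric(ss$amb[[ch]]))
  rep(1, k)  # gap / ? / N / X: missing data
}

# Compress alignment columns into site patterns and per-taxon partial
# matrices (n_patterns x n_states).
prepare_patterns <- function(a, cols = seq_len(aln_ncol(a))) {
  ss <- state_space(a$alphabet)
  sub <- a$mat[, cols, drop = FALSE]
  keys <- apply(sub, 2L, paste, collapse = "")
  u <- !duplicated(keys)
  counts <- as.vector(table(factor(keys, levels = keys[u])))
  pat <- sub[, u, drop = FALSE]
  k <- length(ss$states)
  lookup <- new.env(parent = emptyenv())
  tips <- lapply(rownames(pat), function(t) {
    chars <- pat[t, ]
    m <- matrix(0, nrow = ncol(pat), ncol = k)
    for (ch in unique(chars)) {
      v <- get0(ch, envir = lookup)
      if (is.null(v)) { v <- char_indicator(ch, ss); assign(ch, v, envir = lookup) }
      m[chars == ch, ] <- rep(v, each = sum(chars == ch))
    }
    m
  })
  names(tips) <- rownames(pat)
  list(tips = tips, counts = counts, n_states = k, n_sites = length(cols))
}

# ---- Felsenstein pruning ----------------------------------------------------

# Postorder pruning for one rate category; returns log site likelihoods.
prune_category <- function(tree_pp, tips, decomp, freq, rate, branch_scale) {
  edge <- tree_pp$edge
  elen <- tree_pp$edge.length * rate * branch_scale
  n_tip <- length(tree_pp$tip.label)
  n_node <- n_tip + tree_pp$Nnode
  npat <- nrow(tips[[1]])
  partial <- vector("list", n_node)
  scale <- matrix(0, npat, n_node)
  for (i in seq_len(n_tip)) partial[[i]] <- tips[[tree_pp$tip.label[i]]]
  Ps <- lapply(elen, function(t) transition_probs(decomp, t))
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    contrib <- partial[[chi]] %*% t(Ps[[e]])
    if (is.null(partial[[par]])) {
      partial[[par]] <- contrib
      scale[, par] <- scale[, chi]
    } else {
      partial[[par]] <- partial[[par]] * contrib
      scale[, par] <- scale[, par] + scale[, chi]
    }
    m <- matrixStats_rowMaxs(partial[[par]])
    # a pattern can have zero likelihood in one rate category (e.g. a
    # conflicting pattern at a near-zero category rate); the gamma mixture
    # resolves it, so carry -Inf rather than failing here
    m[m == 0] <- 1
    partial[[par]] <- partial[[par]] / m
    scale[, par] <- scale[, par] + log(m)
  }
  root <- edge[nrow(edge), 1]
  lik <- as.vector(partial[[root]] %*% freq)
  ifelse(lik > 0, log(pmax(lik, .Machine$double.xmin)) + scale[, root], -Inf)
}

# rowMaxs without extra deps
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

# log-likelihood of one partition (gamma mixture over categories)
partition_loglik <- function(tree_pp, pdata, model, branch_scale = 1) {
  Q <- rate_matrix(model)
  decomp <- decompose_q(Q, model$freq)
  g <- discrete_gamma(model$alpha, model$ncat)
  logl_cat <- vapply(seq_along(g$rates), function(i) {
    prune_category(tree_pp, pdata$tips, decomp, model$freq, g$rates[i],
                   branch_scale)
  }, numeric(length(pdata$counts)))
  if (is.null(dim(logl_cat))) logl_cat <- matrix(logl_cat, nrow = 1L)
  mx <- matrixStats_rowMaxs(logl_cat)
  if (any(!is.finite(mx)))
    stopf("zero-likelihood site pattern under the model")
  site <- mx + log(as.vector(exp(logl_cat - mx) %*% g$probs))
  sum(site * pdata$counts)
}

check_tree_taxa <- function(tree, taxa) {
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) stopf("taxa absent from tree: %s", miss[1])
  if (length(setdiff(tree$tip.label, taxa)))
    tree <- ape::keep.tip(tree, taxa)
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  ape::reorder.phylo(tree, "postorder")
}

#' Partitioned log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of an alignment on a tree with branch lengths,
#' one substitution model per partition and a single shared set of branch
#' lengths. Gaps and ambiguity codes are treated as missing data
#' (all-ones tip vectors); site patterns are compressed per partition; the
#' gamma mixture is averaged per site.
#'
#' @param tree an `ape::phylo` tree with branch lengths; its leaves must
#'   include all alignment taxa (extra leaves are pruned).
#' @param a an `aln`.
#' @param scheme a `partition_scheme` over the alignment columns, or `NULL`
#'   for a single partition.
#' @param models a single `substitution_model` (recycled) or a list, one per
#'   partition, families matching the alphabet.
#' @param branch_scale multiplier applied to all branch lengths (shared).
#' @return total log-likelihood, with per-partition values in attribute
#'   `"by_partition"`.
#' @export
log_likelihood <- function(tree, a, scheme = NULL, models, branch_scale = 1) {
  if (is.null(scheme))
    scheme <- partition_scheme("all", list(all = seq_len(aln_ncol(a))),
                               model_family = default_family(a$alphabet))
  if (inherits(models, "substitution_model"))
    models <- rep(list(models), n_partitions(scheme))
  if (length(models) != n_partitions(scheme))
    stopf("need one model per partition")
  tree_pp <- check_tree_taxa(tree, aln_taxa(a))
  lnl <- vapply(seq_along(scheme$partitions), function(i) {
    pdata <- prepare_patterns(a, scheme$partitions[[i]])
    partition_loglik(tree_pp, pdata, models[[i]], branch_scale)
  }, numeric(1))
  structure(sum(lnl), by_partition = stats::setNames(lnl, names(scheme$partitions)))
}

default_family <- function(alphabet) {
  switch(alphabet, nt = "GTR+G", ry = "BIN+G", aa = "AA+G")
}
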