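#' Gene-by-taxon coverage from a supermatrix
#'
#' A taxon "has" a gene iff the fraction of non-missing characters in the
#' gene's column block exceeds `min_frac` (default: at least one non-missing
#' character).
#'
#' @param a an `aln`.
#' @param scheme by-gene `partition_scheme` covering the matrix.
#' @param min_frac presence threshold as a fraction of the gene's columns
#'   (default 0 = any character).
#' @return logical matrix (genes x taxa) of class `coverage_matrix`.
#' @export
coverage_from_matrix <- function(a, scheme, min_frac = 0) {
  ok <- switch(a$alphabet,
               nt = c("A", "C", "G", "T"),
               ry = c("R", "Y"),
               aa = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  cov <- t(vapply(scheme$partitions, function(cols) {
    frac <- rowMeans(matrix(a$mat[, cols, drop = FALSE] %in% ok,
                            nrow = aln_ntaxa(a)))
    if (min_frac == 0) frac > 0 else frac >= min_frac
  }, logical(aln_ntaxa(a))))
  dimnames(cov) <- list(names(scheme$partitions), aln_taxa(a))
  structure(cov, class = c("coverage_matrix", "matrix"))
}

#' Coverage matrix constructor from a plain logical matrix
#' @param m logical genes x taxa matrix with dimnames.
#' @export
coverage_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "logical"
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("coverage matrix needs gene and taxon names")
  structure(m, class = c("coverage_matrix", "matrix"))
}

#' Fraction of taxon k-tuples jointly covered by some gene
#'
#' A k-subset of taxa is covered when at least one gene has data for all of
#' its members. Triplet coverage (k = 3) is the rooted-tree criterion;
#' quadruple coverage (k = 4) the unrooted one. Exact enumeration or uniform
#' Monte-Carlo with a binomial standard error.
#'
#' @param cov a `coverage_matrix`.
#' @param k tuple size (3 or 4).
#' @param mode `"exact"` or `"sample"`.
#' @param n_samples Monte-Carlo sample count.
#' @param seed RNG seed for sampled mode.
#' @return list with `fraction`, `se` (0 in exact mode), `mode`, `k`.
#' @export
tuple_coverage <- function(cov, k = 3L, mode = c("exact", "sample"),
                           n_samples = 1e5, seed = NULL) {
  mode <- match.arg(mode)
  n <- ncol(cov)
  if (k > n) stopf("k (%d) exceeds the number of taxa (%d)", k, n)
  if (mode == "exact") {
    n_tuples <- choose(n, k)
    if (n_tuples > 1e9) stopf("exact mode infeasible for %g tuples; use sampling",
                              n_tuples)
    tuples <- utils::combn(n, k)
    covered <- rep(FALSE, ncol(tuples))
    for (g in seq_len(nrow(cov))) {
      present <- cov[g, ]
      covered <- covered | (colSums(matrix(present[tuples], nrow = k)) == k)
    }
    list(fraction = mean(covered), se = 0, mode = "exact", k = k)
  } else {
    with_seed(seed, {
      hits <- 0L
      draw <- replicate(n_samples, sample.int(n, k))
      for (g in seq_len(nrow(cov))) {
        present <- cov[g, ]
        hit <- colSums(matrix(present[draw], nrow = k)) == k
        if (g == 1L) covered <- hit else covered <- covered | hit
      }
      p <- mean(covered)
      list(fraction = p, se = sqrt(p * (1 - p) / n_samples),
           mode = "sample", k = k)
    })
  }
}

# tips reachable from `to` when coming from `from`, memoized per call
tips_away_factory <- function(tree) {
  n_tip <- length(tree$tip.label)
  adj <- vector("list", n_tip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  memo <- new.env(parent = emptyenv())
  tips_away <- function(from, to) {
    key <- paste(from, to)
    v <- get0(key, envir = memo)
    if (!is.null(v)) return(v)
    v <- if (to <= n_tip) to
         else unlist(lapply(setdiff(adj[[to]], from), function(x) tips_away(to, x)))
    assign(key, v, envir = memo)
    v
  }
  list(adj = adj, tips_away = tips_away, n_tip = n_tip)
}

#' Is a coverage pattern decisive for a given tree?
#'
#' True iff every internal edge of the (binary, unrooted) tree is displayed
#' by some gene: the gene must contain at least one taxon in each of the four
#' subtrees adjacent to the edge, i.e. a quartet crossing the edge.
#'
#' @param tree binary unrooted `ape::phylo` on the coverage taxa.
#' @param cov a `coverage_matrix` whose columns include the tree's tips.
#' @return logical.
#' @export
decisive_for_tree <- function(tree, cov) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  if (!ape::is.binary(tree)) stopf("tree must be binary")
  miss <- setdiff(tree$tip.label, colnames(cov))
  if (length(miss)) stopf("taxon '%s' absent from coverage matrix", miss[1])
  if (n_tip < 4L) return(TRUE)
  ta <- tips_away_factory(tree)
  internal <- tree$edge[tree$edge[, 2] > n_tip, , drop = FALSE]
  covm <- cov[, tree$tip.label, drop = FALSE]
  for (e in seq_len(nrow(internal))) {
    u <- internal[e, 1]; v <- internal[e, 2]
    parts <- c(lapply(setdiff(ta$adj[[v]], u), function(x) ta$tips_away(v, x)),
               lapply(setdiff(ta$adj[[u]], v), function(x) ta$tips_away(u, x)))
    displayed <- FALSE
    for (g in seq_len(nrow(covm))) {
      if (all(vapply(parts, function(p) any(covm[g, p]), logical(1)))) {
        displayed <- TRUE; break
      }
    }
    if (!displayed) return(FALSE)
  }
  TRUE
}

#' Is a coverage pattern decisive for all binary trees?
#'
#' Exact mode enumerates every unrooted binary topology (feasible for small
#' taxon sets); sampled mode checks uniformly generated random topologies.
#'
#' @param cov a `coverage_matrix`.
#' @param mode `"exact"` or `"sample"`.
#' @param n_max_exact largest taxon count allowed in exact mode (default 7).
#' @param n_samples number of sampled topologies.
#' @param seed RNG seed for sampled mode.
#' @return list with `decisive`, `n_trees`, `mode`.
#' @export
decisive_for_all_trees <- function(cov, mode = c("exact", "sample"),
                                   n_max_exact = 7L, n_samples = 100L,
                                   seed = NULL) {
  mode <- match.arg(mode)
  taxa <- colnames(cov)
  n <- length(taxa)
  if (mode == "exact") {
    if (n > n_max_exact)
      stopf("%d taxa too many for exact enumeration; use mode='sample'", n)
    all_t <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    # index explicitly: multiPhylo stores tip labels compressed, and only
    # `[[` restores them
    trees <- lapply(seq_along(all_t), function(i) all_t[[i]])
  } else {
    trees <- with_seed(seed, lapply(seq_len(n_samples), function(i) {
      ape::unroot(ape::rtree(n, tip.label = sample(taxa)))
    }))
  }
  for (tr in trees) {
    if (!decisive_for_tree(tr, cov))
      return(list(decisive = FALSE, n_trees = length(trees), mode = mode))
  }
  list(decisive = TRUE, n_trees = length(trees), mode = mode)
}

#' Decisiveness report for a coverage pattern
#'
#' Computes triplet and quadruple coverage and (when feasible or sampled) the
#' all-trees decisiveness check, reporting all three rather than presuming
#' which criterion a reader wants.
#'
#' @param cov a `coverage_matrix`.
#' @param mode `"exact"` or `"sample"` for the tuple fractions.
#' @param n_samples samples for sampled modes.
#' @param n_max_exact taxon bound for exact tree enumeration.
#' @param seed RNG seed.
#' @return list of class `decisiveness_report`.
#' @export
decisiveness_report <- function(cov, mode = c("exact", "sample"),
                                n_samples = 1e5, n_max_exact = 7L,
                                seed = NULL) {
  mode <- match.arg(mode)
  trip <- tuple_coverage(cov, 3L, mode, n_samples, seed)
  quad <- tuple_coverage(cov, 4L, mode, n_samples, seed)
  tree_mode <- if (ncol(cov) <= n_max_exact) "exact" else "sample"
  alltrees <- decisive_for_all_trees(cov, tree_mode, n_max_exact,
                                     n_samples = 100L, seed = seed)
  structure(list(fraction_triplets_covered = trip$fraction,
                 triplet_se = trip$se,
                 fraction_quadruples_covered = quad$fraction,
                 quadruple_se = quad$se,
                 decisive_all_trees = alltrees$decisive,
                 tree_check_mode = alltrees$mode,
                 mode = mode),
            class = "decisiveness_report")
}

#' @export
print.decisiveness_report <- function(x, ...) {
  cat(sprintf("triplet coverage: %.4f; quadruple coverage: %.4f; decisive for all trees (%s): %s\n",
              x$fraction_triplets_covered, x$fraction_quadruples_covered,
              x$tree_check_mode, x$decisive_all_trees))
  invisible(x)
}
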