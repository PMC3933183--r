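# shared fixtures and independent oracles

# non-stop codons under the plastid code, for fast construction of valid
# codon matrices
NONSTOP_CODONS <- local({
  tab <- Biostrings::getGeneticCode("11")
  names(tab)[tab != "*"]
})

random_codon_aln <- function(n_taxa, n_codons, taxa = sprintf("t%02d", seq_len(n_taxa))) {
  seqs <- vapply(taxa, function(t)
    paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = ""),
    character(1))
  alignment(seqs, "nt", codon_phase = rep_len(1:3, 3L * n_codons))
}

# brute-force connected components by transitive closure on the adjacency
# matrix (independent of igraph)
oracle_components <- function(nodes, edges) {
  n <- length(nodes)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(nodes, nodes)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      adj[edges$a[i], edges$b[i]] <- TRUE
      adj[edges$b[i], edges$a[i]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- apply(adj, 1L, function(r) paste(sort(nodes[r]), collapse = "|"))
  unname(split(nodes, comp))
}

# membership key for comparing partitions of a node set
partition_key <- function(groups) {
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = "|"),
                    character(1))), collapse = " / ")
}

# brute-force log-likelihood by enumerating internal-state assignments;
# transition probabilities from ape::matexpo (independent of the package's
# eigen path). Tips with gaps are marginalized by treating them as free.
oracle_loglik <- function(tree, a, model) {
  Q <- rate_matrix(model)
  g <- discrete_gamma(model$alpha, model$ncat)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  internals <- sort(unique(tr$edge[, 1]))
  ss <- plastidphylo:::state_space(a$alphabet)
  k <- length(ss$states)
  total <- 0
  for (site in seq_len(aln_ncol(a))) {
    chars <- a$mat[tr$tip.label, site]
    site_lik <- 0
    for (ci in seq_along(g$rates)) {
      P <- lapply(seq_len(nrow(tr$edge)), function(e)
        ape::matexpo(Q * tr$edge.length[e] * g$rates[ci]))
      grid <- expand.grid(rep(list(seq_len(k)), length(internals)))
      lik <- 0
      tipsets <- lapply(chars, function(ch) {
        v <- plastidphylo:::char_indicator(ch, ss)
        which(v > 0)
      })
      tipgrid <- expand.grid(tipsets)
      for (gi in seq_len(nrow(grid))) {
        assign_int <- as.integer(grid[gi, ])
        names(assign_int) <- internals
        for (ti in seq_len(nrow(tipgrid))) {
          st <- integer(n_node)
          st[internals] <- assign_int
          st[seq_len(n_tip)] <- as.integer(tipgrid[ti, ])
          p <- model$freq[st[root]]
          for (e in seq_len(nrow(tr$edge)))
            p <- p * P[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
          lik <- lik + p
        }
      }
      site_lik <- site_lik + g$probs[ci] * lik
    }
    total <- total + log(site_lik)
  }
  total
}

# independent decisiveness oracle built on phangorn::Descendants: an internal
# edge is displayed by a gene iff the gene has a taxon in each of the four
# subtrees adjacent to the edge
oracle_decisive <- function(tree, cov) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  rooted <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  all_tips <- rooted$tip.label
  desc <- phangorn::Descendants(rooted, type = "tips")
  edge <- rooted$edge
  for (e in seq_len(nrow(edge))) {
    chi <- edge[e, 2]
    if (chi <= n_tip) next
    kids <- edge[edge[, 1] == chi, 2]
    if (length(kids) != 2L) next
    below <- all_tips[desc[[chi]]]
    if (length(below) < 2L || length(below) > n_tip - 2L) next
    a1 <- all_tips[desc[[kids[1]]]]
    a2 <- all_tips[desc[[kids[2]]]]
    # the other side: split by removing chi's parent edge, then partition the
    # complement by the parent's remaining neighbours
    other <- setdiff(all_tips, below)
    par <- edge[e, 1]
    sibs <- setdiff(edge[edge[, 1] == par, 2], chi)
    b1 <- if (length(sibs)) all_tips[desc[[sibs[1]]]] else character(0)
    b2 <- setdiff(other, b1)
    if (length(b1) == 0L || length(b2) == 0L) next
    ok <- FALSE
    for (g in seq_len(nrow(cov))) {
      pres <- colnames(cov)[cov[g, ]]
      if (any(a1 %in% pres) && any(a2 %in% pres) &&
          any(b1 %in% pres) && any(b2 %in% pres)) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

random_coverage <- function(n_genes, taxa, p = 0.7, seed = NULL) {
  plastidphylo:::with_seed(seed, {
    m <- matrix(runif(n_genes * length(taxa)) < p, nrow = n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)), taxa))
    # ensure no empty gene or taxon
    for (i in seq_len(n_genes)) if (!any(m[i, ])) m[i, sample(length(taxa), 2)] <- TRUE
    for (j in seq_along(taxa)) if (!any(m[, j])) m[sample(n_genes, 1), j] <- TRUE
    coverage_matrix(m)
  })
}

rdirichlet1 <- function(k) { x <- rgamma(k, 2, 1); x / sum(x) }
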