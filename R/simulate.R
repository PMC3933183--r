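#' Simulation configuration for synthetic plastome data
#'
#' Defaults emulate the statistical structure of a plastome phylogenomic
#' data set at desk scale: 40 taxa x 12 protein-coding genes (a scaled-down
#' stand-in for 360 x 78), AT-rich base composition (GC around 0.39),
#' position-specific rates with fast third positions, lineage-heterogeneous
#' GC concentrated at third positions, per-gene taxon occupancy between 0.63
#' and 0.99 calibrated to roughly 15.6 % global missing data, occasional
#' inverted-repeat duplicates and paralogs, and a similarity hit table with
#' configurable false-positive/false-negative rates.
#'
#' @param n_taxa number of taxa.
#' @param n_genes number of genes.
#' @param mean_codons mean codons per gene (lengths are lognormal).
#' @param tree_depth mean root-to-tip path length (substitutions/site).
#' @param rates GTR exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param freq base frequencies (A, C, G, T).
#' @param pos_rates relative rates of codon positions 1-3.
#' @param alpha gamma shape for among-codon rate variation.
#' @param gc_profile list of clade GC shifts, each
#'   `list(frac =, target =, phases =)`: a clade of about `frac` of the taxa
#'   has its class-conditional GC pushed to `target` at the given codon
#'   positions.
#' @param occupancy list `min`, `max`, `shape1`, `shape2`: per-gene taxon
#'   occupancy is `min + (max - min) * Beta(shape1, shape2)`; `min` must be
#'   at least 0.5.
#' @param ir_dup_rate probability a (gene, taxon) cell gets a duplicate copy.
#' @param ir_divergence point mutations on each duplicate copy (0 = exact).
#' @param paralog_rate probability a gene spawns a diverged paralog.
#' @param fp_rate,fn_rate spurious / dropped hit rates in the hit table.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 40L, n_genes = 12L, mean_codons = 240,
                       tree_depth = 0.5,
                       rates = c(1.2, 3.0, 0.8, 0.9, 3.2, 1.0),
                       freq = c(A = 0.305, C = 0.195, G = 0.195, T = 0.305),
                       pos_rates = c(1, 0.5, 4),
                       alpha = 0.8,
                       gc_profile = list(
                         list(frac = 0.25, target = 0.60, phases = 3L),
                         list(frac = 0.15, target = 0.22, phases = 3L)),
                       occupancy = list(min = 0.63, max = 0.99,
                                        shape1 = 3, shape2 = 2),
                       ir_dup_rate = 0.08, ir_divergence = 0L,
                       paralog_rate = 0.1, fp_rate = 0, fn_rate = 0,
                       seed) {
  if (missing(seed)) stopf("a seed is mandatory for simulation runs")
  if (occupancy$min < 0.5) stopf("occupancy minimum must be at least 0.5")
  stopifnot(n_taxa >= 3L, n_genes >= 1L,
            all(c(ir_dup_rate, paralog_rate, fp_rate, fn_rate) >= 0),
            all(c(ir_dup_rate, paralog_rate, fp_rate, fn_rate) <= 1))
  for (g in gc_profile)
    if (g$target > 0.95) stopf("unreachable GC target %.2f", g$target)
  structure(as.list(environment()), class = "sim_config")
}

#' Sample a birth-death (Yule) tree
#'
#' Binary unrooted tree with positive branch lengths, scaled so the mean
#' root-to-tip path equals `depth`; deterministic given the seed.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param depth mean root-to-tip path length after scaling.
#' @param birth Yule speciation rate.
#' @param seed RNG seed.
#' @return an unrooted `ape::phylo` with `2 n - 3` edges.
#' @export
sample_tree <- function(n_taxa, depth = 0.5, birth = 1, seed = NULL) {
  if (n_taxa < 3L) stopf("need at least 3 taxa")
  with_seed(seed, {
    tr <- ape::rphylo(n_taxa, birth = birth, death = 0)
    tr$tip.label <- sprintf("t%03d", seq_len(n_taxa))
    d <- ape::node.depth.edgelength(tr)[seq_len(n_taxa)]
    tr$edge.length <- tr$edge.length * depth / mean(d)
    # small positive jitter guards against zero-length edges
    tr$edge.length <- pmax(tr$edge.length, 1e-6)
    ape::unroot(tr)
  })
}

# replace stop codons by mutating their third position to C or T
fix_stops <- function(nt, code = "plastid") {
  tab <- Biostrings::getGeneticCode(if (code == "plastid") "11" else "1")
  stops <- names(tab)[tab == "*"]
  n <- nchar(nt)
  starts <- seq(1L, n, 3L)
  codons <- substring(nt, starts, starts + 2L)
  bad <- which(codons %in% stops)
  if (length(bad) == 0L) return(nt)
  v <- strsplit(nt, "")[[1]]
  for (b in bad) {
    for (repl in c("C", "T")) {
      cand <- paste0(substr(codons[b], 1, 2), repl)
      if (!cand %in% stops) { v[starts[b] + 2L] <- repl; break }
    }
  }
  paste(v, collapse = "")
}

# mutate k positions of a CDS without creating stop codons
mutate_cds <- function(nt, k, code = "plastid") {
  if (k <= 0L) return(nt)
  tab <- Biostrings::getGeneticCode(if (code == "plastid") "11" else "1")
  stops <- names(tab)[tab == "*"]
  v <- strsplit(nt, "")[[1]]
  done <- 0L; tries <- 0L
  while (done < k && tries < 50L * k) {
    tries <- tries + 1L
    pos <- sample.int(length(v), 1L)
    new <- sample(setdiff(c("A", "C", "G", "T"), v[pos]), 1L)
    cod_i <- (pos - 1L) %/% 3L
    old <- v[pos]; v[pos] <- new
    codon <- paste(v[cod_i * 3L + 1:3], collapse = "")
    if (codon %in% stops) v[pos] <- old else done <- done + 1L
  }
  paste(v, collapse = "")
}

#' Simulate one aligned gene along a tree
#'
#' Evolves `3 * n_codons` sites under a stationary GTR model with
#' position-specific rates and discrete-gamma among-codon rate variation,
#' then applies clade-specific GC shifts as within-class base exchanges
#' (A with G, C with T) at the requested codon positions, so the RY-coded
#' composition is unchanged by construction. Internal stop codons are
#' resolved by third-position edits before any shift. Output is gap-free and
#' aligned by construction.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param n_codons codons to simulate.
#' @param model list with `rates` (GTR) and `freq` (A, C, G, T).
#' @param pos_rates relative rates of the three codon positions.
#' @param alpha gamma shape for among-codon variation (4 categories).
#' @param gc_shift_map list of shifts `list(taxa =, target =, phases =)`.
#' @param seed RNG seed.
#' @param code genetic code for stop screening.
#' @return named character vector of aligned CDS strings.
#' @export
simulate_gene <- function(tree, n_codons, model, pos_rates = c(1, 0.5, 4),
                          alpha = 0.8, gc_shift_map = NULL, seed = NULL,
                          code = "plastid") {
  for (g in gc_shift_map %||% list())
    if (g$target > 0.95) stopf("unreachable GC target %.2f", g$target)
  with_seed(seed, {
    freq <- model$freq / sum(model$freq)
    m <- substitution_model("GTR+G", rates = model$rates, freq = freq,
                            alpha = alpha, ncat = 4L)
    Q <- rate_matrix(m)
    decomp <- decompose_q(Q, freq)
    gam <- discrete_gamma(alpha, 4L)
    n_sites <- 3L * n_codons
    phase <- rep_len(1:3, n_sites)
    cat_of_codon <- sample.int(4L, n_codons, replace = TRUE)
    site_rate <- pos_rates[phase] * gam$rates[rep(cat_of_codon, each = 3L)]
    rate_groups <- split(seq_len(n_sites), site_rate)

    tr <- ape::reorder.phylo(tree, "postorder")
    n_tip <- length(tr$tip.label)
    root <- tr$edge[nrow(tr$edge), 1]
    states <- matrix(0L, nrow = n_tip + tr$Nnode, ncol = n_sites)
    states[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = freq)
    for (e in rev(seq_len(nrow(tr$edge)))) {          # preorder
      par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]; t <- tr$edge.length[e]
      for (rg in seq_along(rate_groups)) {
        idx <- rate_groups[[rg]]
        P <- transition_probs(decomp, t * as.numeric(names(rate_groups)[rg]))
        cur <- states[par, idx]
        nxt <- integer(length(idx))
        for (s in 1:4) {
          w <- which(cur == s)
          if (length(w)) nxt[w] <- sample.int(4L, length(w), replace = TRUE,
                                              prob = P[s, ])
        }
        states[chi, idx] <- nxt
      }
    }
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n_tip), function(i)
      paste(bases[states[i, ]], collapse = ""), character(1))
    names(seqs) <- tr$tip.label
    seqs <- vapply(seqs, fix_stops, character(1), code = code)

    for (shift in gc_shift_map %||% list()) {
      tx <- intersect(shift$taxa, names(seqs))
      phases <- shift$phases %||% 3L
      cols <- which(phase %in% phases)
      mats <- do.call(rbind, strsplit(seqs[tx], ""))
      sub <- mats[, cols, drop = FALSE]
      # purine flips at a third position whose codon starts with T could
      # create a stop (TGG <-> TGA, TAA <-> TAG); those sites stay untouched
      ok_ag <- matrix(TRUE, nrow(sub), ncol(sub))
      third <- which(phase[cols] == 3L)
      if (length(third))
        ok_ag[, third] <- mats[, cols[third] - 2L, drop = FALSE] != "T"
      gR <- sum(sub == "G") / max(1, sum(sub %in% c("A", "G")))
      cY <- sum(sub == "C") / max(1, sum(sub %in% c("C", "T")))
      t <- shift$target
      flip <- function(block, from, to, p0, ok) {
        if (t > p0) {
          i <- which(block == from & ok)
          block[i[stats::runif(length(i)) < (t - p0) / (1 - p0)]] <- to
        } else if (t < p0) {
          i <- which(block == to & ok)
          block[i[stats::runif(length(i)) < (p0 - t) / p0]] <- from
        }
        block
      }
      sub <- flip(sub, "A", "G", gR, ok_ag)
      sub <- flip(sub, "T", "C", cY, TRUE)
      mats[, cols] <- sub
      fixed <- apply(mats, 1L, paste, collapse = "")
      if (!identical(phases, 3L))
        fixed <- vapply(fixed, fix_stops, character(1), code = code)
      seqs[tx] <- fixed
    }
    seqs
  })
}

#' Delete taxa from genes according to an occupancy distribution
#'
#' Per-gene occupancy is drawn from a scaled Beta distribution (minimum at
#' least 0.5, matching post-filter realism); the deleted taxa define the
#' ground-truth coverage matrix, and the realized global missing-data
#' fraction (length-weighted) is reported.
#'
#' @param genes named list of named sequence vectors (one per gene).
#' @param occupancy list `min`, `max`, `shape1`, `shape2`.
#' @param seed RNG seed.
#' @return list with `genes` (pruned), `coverage` (`coverage_matrix`),
#'   `realized_missingness`.
#' @export
apply_missingness <- function(genes, occupancy = list(min = 0.63, max = 0.99,
                                                      shape1 = 3, shape2 = 2),
                              seed = NULL) {
  taxa <- sort(unique(unlist(lapply(genes, names))))
  with_seed(seed, {
    occ <- occupancy$min + (occupancy$max - occupancy$min) *
      stats::rbeta(length(genes), occupancy$shape1, occupancy$shape2)
    cov <- matrix(FALSE, nrow = length(genes), ncol = length(taxa),
                  dimnames = list(names(genes), taxa))
    out <- genes
    for (i in seq_along(genes)) {
      nt <- names(genes[[i]])
      keep <- sort(sample(nt, max(2L, round(occ[i] * length(nt)))))
      out[[i]] <- genes[[i]][keep]
      cov[i, keep] <- TRUE
    }
    w <- vapply(genes, function(g) nchar(g[[1]]), numeric(1))
    miss <- sum(w * (1 - colSums(t(cov)) / length(taxa))) / sum(w)
    list(genes = out, coverage = coverage_matrix(cov),
         realized_missingness = miss)
  })
}

#' Add inverted-repeat duplicates and paralogs
#'
#' Duplicates are exact copies (or copies with `ir_divergence` point
#' mutations, to rehearse the drop-both rule); paralogs are heavily diverged
#' copies of a gene for a subset of taxa, labelled as their own truth gene.
#'
#' @param genes named list of named CDS vectors.
#' @param ir_dup_rate per-(gene, taxon) duplication probability.
#' @param paralog_rate per-gene paralog probability.
#' @param ir_divergence mutations per duplicate copy.
#' @param paralog_frac fraction of the gene's taxa carrying the paralog.
#' @param paralog_divergence fraction of sites mutated in the paralog.
#' @param seed RNG seed.
#' @return data.frame with columns `seq_id`, `taxon_id`, `gene_truth`,
#'   `parent_gene`, `is_duplicate`, `seq`.
#' @export
inject_duplicates_and_paralogs <- function(genes, ir_dup_rate = 0,
                                           paralog_rate = 0,
                                           ir_divergence = 0L,
                                           paralog_frac = 0.4,
                                           paralog_divergence = 0.3,
                                           seed = NULL) {
  with_seed(seed, {
    rows <- list()
    add <- function(seq_id, taxon, gene, parent, dup, seq)
      rows[[length(rows) + 1L]] <<- data.frame(
        seq_id = seq_id, taxon_id = taxon, gene_truth = gene,
        parent_gene = parent, is_duplicate = dup, seq = seq,
        stringsAsFactors = FALSE)
    for (g in names(genes)) {
      for (t in names(genes[[g]])) {
        s <- genes[[g]][[t]]
        add(paste(t, g, sep = "|"), t, g, NA_character_, FALSE, s)
        if (stats::runif(1) < ir_dup_rate) {
          s2 <- if (ir_divergence > 0L) mutate_cds(s, ir_divergence) else s
          add(paste0(t, "|", g, "|ir2"), t, g, NA_character_, TRUE, s2)
        }
      }
      if (stats::runif(1) < paralog_rate) {
        tx <- names(genes[[g]])
        sub <- sort(sample(tx, max(2L, round(paralog_frac * length(tx)))))
        pg <- paste0(g, "_par")
        for (t in sub) {
          L <- nchar(genes[[g]][[t]])
          s2 <- mutate_cds(genes[[g]][[t]], round(paralog_divergence * L))
          add(paste(t, pg, sep = "|"), t, pg, g, FALSE, s2)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Build a synthetic all-vs-all similarity hit table
#'
#' Within-gene pairs get strong hits (e-value at most 1e-6, coverage at least
#' 0.9) except for a `fn_rate` fraction; paralog-to-parent pairs get hits
#' just inside the default e-value cutoff (between 1e-6 and 1e-5), so a
#' one-step stricter re-clustering separates them; spurious cross-gene hits
#' are added at `fp_rate` with e-values above the default cutoff (between
#' 1e-5 and 1e-3). Deterministic given the seed.
#'
#' @param seq_tab data.frame from [inject_duplicates_and_paralogs()] (or with
#'   columns `seq_id`, `taxon_id`, `gene_truth`, optionally `parent_gene`).
#' @param fp_rate expected spurious hits per true within-gene hit.
#' @param fn_rate fraction of within-gene hits dropped.
#' @param seed RNG seed.
#' @return hits data.frame compatible with [filter_hits()].
#' @export
make_hit_table <- function(seq_tab, fp_rate = 0, fn_rate = 0, seed = NULL) {
  with_seed(seed, {
    out <- list()
    emit <- function(q, t, ev, qc, tc)
      out[[length(out) + 1L]] <<- data.frame(
        query_id = q, target_id = t, evalue = ev, bitscore = 200,
        query_cov = qc, target_cov = tc, stringsAsFactors = FALSE)
    by_gene <- split(seq_tab$seq_id, seq_tab$gene_truth)
    for (ids in by_gene) {
      if (length(ids) < 2L) next
      prs <- utils::combn(ids, 2L)
      for (i in seq_len(ncol(prs))) {
        if (fn_rate > 0 && stats::runif(1) < fn_rate) next
        emit(prs[1, i], prs[2, i], 10^stats::runif(1, -40, -12),
             stats::runif(1, 0.9, 1), stats::runif(1, 0.9, 1))
      }
    }
    # paralog-to-parent bridge hits
    if (!is.null(seq_tab$parent_gene)) {
      par_rows <- which(!is.na(seq_tab$parent_gene))
      for (i in par_rows) {
        parent_ids <- seq_tab$seq_id[seq_tab$gene_truth ==
                                       seq_tab$parent_gene[i]]
        link <- sample(parent_ids, min(3L, length(parent_ids)))
        for (p in link)
          emit(seq_tab$seq_id[i], p, 10^stats::runif(1, -5.9, -5.01),
               stats::runif(1, 0.6, 0.9), stats::runif(1, 0.6, 0.9))
      }
    }
    n_true <- length(out)
    if (fp_rate > 0 && n_true > 0) {
      n_fp <- stats::rpois(1, fp_rate * n_true)
      for (i in seq_len(n_fp)) {
        pr <- sample(seq_tab$seq_id, 2L)
        emit(pr[1], pr[2], 10^stats::runif(1, -4.99, -3),
             stats::runif(1, 0.4, 0.9), stats::runif(1, 0.4, 0.9))
      }
    }
    if (length(out) == 0L)
      return(data.frame(query_id = character(0), target_id = character(0),
                        evalue = numeric(0), bitscore = numeric(0),
                        query_cov = numeric(0), target_cov = numeric(0),
                        stringsAsFactors = FALSE))
    do.call(rbind, out)
  })
}

#' Simulate a complete synthetic plastome data set
#'
#' Runs the full generative pipeline: Yule tree, per-gene nonstationary
#' sequence simulation, occupancy-driven taxon deletion, inverted-repeat
#' duplicates and paralogs, and the similarity hit table, with all
#' randomness derived from the configuration seed.
#'
#' @param config a [sim_config()].
#' @return list of class `plastome_sim` with `config`, `tree`, `genes`
#'   (post-missingness aligned CDS), `seq_tab`, `coverage`,
#'   `realized_missingness`, `hits`, `gc_shift_map`.
#' @export
simulate_plastome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  tree <- sample_tree(config$n_taxa, depth = config$tree_depth,
                      seed = seed)
  # choose shifted clades from the tree's own splits
  gc_shift_map <- list()
  if (length(config$gc_profile)) {
    rt <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
    clades <- ape::prop.part(rt)
    sizes <- lengths(clades)
    used <- character(0)
    for (g in config$gc_profile) {
      want <- round(g$frac * config$n_taxa)
      cand <- order(abs(sizes - want))
      for (ci in cand) {
        tx <- rt$tip.label[clades[[ci]]]
        if (length(tx) < config$n_taxa && !any(tx %in% used)) {
          gc_shift_map[[length(gc_shift_map) + 1L]] <-
            list(taxa = tx, target = g$target, phases = g$phases %||% 3L)
          used <- c(used, tx)
          break
        }
      }
    }
  }
  lens <- with_seed(seed + 1L, {
    pmax(50L, round(stats::rlnorm(config$n_genes,
                                  log(config$mean_codons), 0.25)))
  })
  gene_ids <- sprintf("g%02d", seq_len(config$n_genes))
  genes <- lapply(seq_len(config$n_genes), function(i) {
    simulate_gene(tree, lens[i],
                  model = list(rates = config$rates, freq = config$freq),
                  pos_rates = config$pos_rates, alpha = config$alpha,
                  gc_shift_map = gc_shift_map, seed = seed + 10L + i)
  })
  names(genes) <- gene_ids
  am <- apply_missingness(genes, config$occupancy, seed = seed + 2L)
  seq_tab <- inject_duplicates_and_paralogs(
    am$genes, ir_dup_rate = config$ir_dup_rate,
    paralog_rate = config$paralog_rate,
    ir_divergence = config$ir_divergence, seed = seed + 3L)
  hits <- make_hit_table(seq_tab, fp_rate = config$fp_rate,
                         fn_rate = config$fn_rate, seed = seed + 4L)
  structure(list(config = config, tree = tree, genes = am$genes,
                 seq_tab = seq_tab, coverage = am$coverage,
                 realized_missingness = am$realized_missingness,
                 hits = hits, gc_shift_map = gc_shift_map),
            class = "plastome_sim")
}

#' @export
print.plastome_sim <- function(x, ...) {
  cat(sprintf("<plastome_sim> %d taxa, %d genes, %d sequences, %.1f%% missing cells\n",
              x$config$n_taxa, x$config$n_genes, nrow(x$seq_tab),
              100 * x$realized_missingness))
  invisible(x)
}

#' Write a simulated data set to plain-text files
#'
#' Emits per-gene FASTA (nucleotide and amino acid), the hit table in
#' 12-column tabular format, truth tables, the tree in Newick, and a JSON
#' echo of the configuration.
#'
#' @param sim a `plastome_sim`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_sim_data <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nt <- stats::setNames(sim$seq_tab$seq, sim$seq_tab$seq_id)
  write_fasta(nt, file.path(dir, "sequences_nt.fasta"))
  aa <- vapply(nt, translate_cds, character(1))
  write_fasta(aa, file.path(dir, "sequences_aa.fasta"))
  write_hit_table(sim$hits, nchar(aa), file.path(dir, "hits.tsv"))
  utils::write.table(sim$seq_tab[, c("seq_id", "taxon_id", "gene_truth")],
                     file.path(dir, "truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$coverage * 1L, file.path(dir, "truth_coverage.tsv"),
                     sep = "\t", quote = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  cfg <- sim$config
  class(cfg) <- NULL
  cfg$gc_profile <- lapply(cfg$gc_profile, function(g) g[c("frac", "target", "phases")])
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
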