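test_that("tree sampling is deterministic and yields unrooted binary trees", {
  tr <- sample_tree(5, seed = 3)
  expect_equal(length(tr$tip.label), 5L)
  expect_equal(nrow(tr$edge), 7L)  # 2n - 3 edges unrooted
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(sample_tree(5, seed = 3)), ape::write.tree(tr))
  expect_false(identical(ape::write.tree(sample_tree(5, seed = 4)),
                         ape::write.tree(tr)))
  expect_error(sample_tree(2, seed = 1), "at least 3")
  # scaling puts tip depths near the requested mean depth
  tr2 <- sample_tree(30, depth = 0.5, seed = 9)
  d <- ape::node.depth.edgelength(tr2)[1:30]
  expect_gt(mean(d), 0.25)
  expect_lt(mean(d), 1.0)
})

test_that("gene simulation is stationary without shifts and hits GC targets with them", {
  tr <- sample_tree(8, seed = 41)
  jc <- list(rates = rep(1, 6), freq = rep(0.25, 4))
  cds <- simulate_gene(tr, 1000, model = jc, pos_rates = c(1, 1, 1), seed = 5)
  a <- alignment(cds, "nt", codon_phase = rep_len(1:3, 3000))
  expect_lt(abs(mean(composition_table(a)$gc) - 0.5), 0.05)
  # gap-free, aligned, stop-free CDS
  expect_true(all(nchar(cds) == 3000))
  expect_no_error(lapply(cds, translate_cds))

  shift <- list(list(taxa = tr$tip.label[1:4], target = 0.8, phases = 3L))
  cds2 <- simulate_gene(tr, 2000, model = jc, pos_rates = c(1, 1, 1),
                        gc_shift_map = shift, seed = 6)
  a2 <- alignment(cds2, "nt", codon_phase = rep_len(1:3, 6000))
  gc3 <- composition_table(a2, "pos3")$gc
  expect_lt(abs(mean(gc3[shift[[1]]$taxa]) - 0.8), 0.05)
  expect_error(simulate_gene(tr, 10, model = jc,
                             gc_shift_map = list(list(taxa = "x", target = 0.99))),
               "unreachable")
})

test_that("missingness deletion reports coverage truth and calibrated totals", {
  tr <- sample_tree(10, seed = 2)
  jc <- list(rates = rep(1, 6), freq = rep(0.25, 4))
  genes <- lapply(1:3, function(i) simulate_gene(tr, 30, model = jc, seed = i))
  names(genes) <- c("g1", "g2", "g3")
  keep_all <- apply_missingness(genes, occupancy = list(min = 1, max = 1,
                                                        shape1 = 1, shape2 = 1),
                                seed = 1)
  expect_equal(keep_all$realized_missingness, 0)
  expect_true(all(keep_all$coverage))

  am <- apply_missingness(genes, seed = 4)
  for (g in names(genes))
    expect_setequal(names(am$genes[[g]]), colnames(am$coverage)[am$coverage[g, ]])

  # calibration against the ~15.6 % missing-cell condition, at 30 genes for a
  # tight Monte-Carlo check of the occupancy distribution's mean
  genes30 <- stats::setNames(rep(genes, 10), sprintf("g%02d", 1:30))
  am30 <- apply_missingness(genes30, seed = 8)
  expect_lt(abs(am30$realized_missingness - 0.156), 0.02)
})

test_that("duplicate and paralog injection carries truth labels", {
  tr <- sample_tree(6, seed = 11)
  jc <- list(rates = rep(1, 6), freq = rep(0.25, 4))
  genes <- list(g1 = simulate_gene(tr, 40, model = jc, seed = 1))
  tab <- inject_duplicates_and_paralogs(genes, ir_dup_rate = 1,
                                        ir_divergence = 0L, seed = 2)
  expect_equal(sum(tab$is_duplicate), 6L)
  # duplicates are exact copies: the IR rule keeps one per taxon
  taxon_of <- stats::setNames(tab$taxon_id, tab$seq_id)
  seqs <- stats::setNames(tab$seq, tab$seq_id)
  r <- resolve_ir_duplicates(tab$seq_id, seqs, taxon_of)
  expect_equal(length(r$members), 6L)

  tab2 <- inject_duplicates_and_paralogs(genes, ir_dup_rate = 1,
                                         ir_divergence = 1L, seed = 2)
  seqs2 <- stats::setNames(tab2$seq, tab2$seq_id)
  r2 <- resolve_ir_duplicates(tab2$seq_id, seqs2,
                              stats::setNames(tab2$taxon_id, tab2$seq_id))
  expect_equal(length(r2$members), 0L)  # every pair differs: drop both

  tab3 <- inject_duplicates_and_paralogs(genes, paralog_rate = 1, seed = 3)
  expect_setequal(unique(tab3$gene_truth), c("g1", "g1_par"))
  expect_true(all(tab3$parent_gene[tab3$gene_truth == "g1_par"] == "g1"))
})

test_that("hit tables respect construction guarantees for fp and fn rates", {
  tr <- sample_tree(8, seed = 21)
  jc <- list(rates = rep(1, 6), freq = rep(0.25, 4))
  genes <- list(g1 = simulate_gene(tr, 40, model = jc, seed = 1),
                g2 = simulate_gene(tr, 40, model = jc, seed = 2))
  tab <- inject_duplicates_and_paralogs(genes, seed = 3)

  hits_fp <- make_hit_table(tab, fp_rate = 0.5, seed = 4)
  cross <- hits_fp[substr(hits_fp$query_id, 6, 7) !=
                     substr(hits_fp$target_id, 6, 7), ]
  expect_true(all(cross$evalue > 1e-5))           # spurious hits fail the filter
  edges <- filter_hits(hits_fp)
  gene_of <- stats::setNames(tab$gene_truth, tab$seq_id)
  expect_true(all(gene_of[edges$a] == gene_of[edges$b]))

  hits_fn <- make_hit_table(tab, fn_rate = 1, seed = 5)
  cs <- cluster_single_linkage(tab$seq_id, filter_hits(hits_fn))
  expect_true(all(lengths(cs$clusters) == 1L))    # everything singleton
})

test_that("full simulation is deterministic and recovers truth end to end", {
  cfg <- sim_config(seed = 101)
  sim1 <- simulate_plastome(cfg)
  sim2 <- simulate_plastome(cfg)
  expect_identical(sim1$seq_tab, sim2$seq_tab)
  expect_identical(sim1$hits, sim2$hits)
  expect_identical(ape::write.tree(sim1$tree), ape::write.tree(sim2$tree))

  sim <- sim1
  aa_tab <- sim$seq_tab
  aa_tab$seq <- vapply(sim$seq_tab$seq, translate_cds, character(1))
  cs <- cluster_homologs(aa_tab, sim$hits,
                         annotations = stats::setNames(sim$seq_tab$gene_truth,
                                                       sim$seq_tab$seq_id))
  # retained clusters correspond 1:1 to the simulated genes
  gene_of <- stats::setNames(sim$seq_tab$gene_truth, sim$seq_tab$seq_id)
  expect_equal(length(cs$clusters), cfg$n_genes)
  in_cluster <- unlist(cs$clusters, use.names = FALSE)
  # co-membership precision: members of one cluster share one truth gene
  purity <- vapply(cs$clusters, function(m) length(unique(gene_of[m])),
                   integer(1))
  expect_true(all(purity == 1L))
  # co-membership recall: no truth gene is split across clusters
  clust_of <- rep(names(cs$clusters), lengths(cs$clusters))
  names(clust_of) <- in_cluster
  by_gene <- split(clust_of, gene_of[in_cluster])
  expect_true(all(vapply(by_gene, function(x) length(unique(x)), integer(1)) == 1L))
  # paralog clusters fail the 50 % occupancy rule and are absent
  expect_false(any(grepl("_par", gene_of[in_cluster])))

  # supermatrix dimensions: sum of 3 x codons over kept genes (no trimming
  # triggers on gap-free simulated alignments)
  nt_of <- stats::setNames(sim$seq_tab$seq, sim$seq_tab$seq_id)
  taxon_of <- stats::setNames(sim$seq_tab$taxon_id, sim$seq_tab$seq_id)
  gas <- lapply(names(cs$clusters), function(cid) {
    m <- cs$clusters[[cid]]
    aa <- stats::setNames(vapply(nt_of[m], translate_cds, character(1)),
                          taxon_of[m])
    gene_alignment(cid, alignment(aa, "aa"), stats::setNames(nt_of[m], taxon_of[m]))
  })
  cc <- concatenate(gas)
  gene_len <- vapply(sim$genes, function(g) nchar(g[[1]]), integer(1))
  expect_equal(aln_ncol(cc$alignment), sum(gene_len))
  expect_lt(abs(missingness(cc$alignment) - sim$realized_missingness), 0.03)
})
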