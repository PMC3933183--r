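mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query_id = r[[1]], target_id = r[[2]], evalue = as.numeric(r[[3]]),
               bitscore = 100, query_cov = as.numeric(r[[4]]),
               target_cov = as.numeric(r[[5]]), stringsAsFactors = FALSE)))
}

test_that("hit filtering applies e-value and mutual-coverage thresholds", {
  hits <- mk_hits(list("a", "b", 1e-6, 0.5, 0.5),   # kept
                  list("a", "c", 1e-4, 0.9, 0.9),   # e-value too large
                  list("b", "c", 1e-10, 0.39, 0.9), # query coverage below 0.40
                  list("a", "a", 1e-30, 1, 1),      # self-hit
                  list("b", "a", 1e-8, 0.6, 0.6))   # reciprocal of kept pair
  edges <- filter_hits(hits)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$evalue, 1e-8)  # best of the reciprocal pair
  expect_equal(c(edges$a, edges$b), c("a", "b"))
  expect_equal(nrow(filter_hits(hits, max_evalue = 1e-40)), 0L)
})

test_that("single-linkage clusters are connected components", {
  edges <- data.frame(a = c("A", "B"), b = c("B", "C"))
  cs <- cluster_single_linkage(c("A", "B", "C", "D"), edges)
  expect_equal(partition_key(cs$clusters), partition_key(list(c("A", "B", "C"), "D")))
  cs0 <- cluster_single_linkage(c("A", "B"), edges[0, ])
  expect_equal(lengths(cs0$clusters), c(c001 = 1L, c002 = 1L))
})

test_that("single-linkage equals the transitive-closure oracle on random graphs", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    m <- sample(0:(2 * n), 1)
    edges <- if (m > 0)
      data.frame(a = sample(nodes, m, TRUE), b = sample(nodes, m, TRUE))
    else data.frame(a = character(0), b = character(0))
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    got <- cluster_single_linkage(nodes, edges)$clusters
    want <- oracle_components(nodes, edges)
    expect_equal(partition_key(got), partition_key(want))
  }
})

test_that("multi-copy clusters are separated at stricter e-values", {
  taxon_of <- c(x1 = "X", x2 = "X", y1 = "Y", z1 = "Z")
  seqs <- c(x1 = "MA", x2 = "MV", y1 = "MA", z1 = "MA")
  hits <- mk_hits(list("x1", "y1", 1e-20, 1, 1),
                  list("y1", "z1", 1e-22, 1, 1),
                  list("x1", "x2", 5e-6, 0.9, 0.9))
  r <- refine_multicopy(c("x1", "x2", "y1", "z1"), hits, taxon_of, seqs)
  expect_equal(partition_key(r$clusters),
               partition_key(list(c("x1", "y1", "z1"), "x2")))
  expect_equal(r$log[[1]]$action, "reclustered")

  # no multi-copy taxon: unchanged
  r2 <- refine_multicopy(c("x1", "y1", "z1"), hits, taxon_of, seqs)
  expect_equal(r2$clusters, list(c("x1", "y1", "z1")))
  expect_length(r2$log, 0L)

  # inseparable paralogs: offending taxon dropped at the schedule floor
  hits3 <- mk_hits(list("x1", "x2", 1e-35, 1, 1),
                   list("x1", "y1", 1e-35, 1, 1),
                   list("x2", "y1", 1e-35, 1, 1))
  r3 <- refine_multicopy(c("x1", "x2", "y1"), hits3, taxon_of, seqs)
  expect_equal(unlist(r3$clusters), "y1")
  expect_true(any(vapply(r3$log, function(e) e$action == "dropped_taxa_at_floor",
                         logical(1))))
  expect_error(refine_multicopy(c("x1", "x2"), hits3, taxon_of, seqs,
                                schedule = numeric(0)), "empty")
})

test_that("identical IR duplicates collapse and divergent ones are removed", {
  taxon_of <- c(a1 = "A", a2 = "A", b1 = "B")
  same <- c(a1 = "ATG", a2 = "ATG", b1 = "ATG")
  r <- resolve_ir_duplicates(c("a1", "a2", "b1"), same, taxon_of)
  expect_equal(sort(r$members), c("a1", "b1"))
  expect_equal(r$log[[1]]$action, "ir_identical_kept_one")

  diff <- c(a1 = "ATG", a2 = "ATC", b1 = "ATG")
  r2 <- resolve_ir_duplicates(c("a1", "a2", "b1"), diff, taxon_of)
  expect_equal(r2$members, "b1")
  expect_equal(r2$log[[1]]$action, "ir_divergent_removed_all")
})

test_that("split-gene merging requires matching labels and disjoint taxa", {
  taxon_of <- c(s1 = "T1", s2 = "T2", s3 = "T3", s4 = "T1")
  ann <- c(s1 = "rbcL", s2 = "rbcL", s3 = "rbcL", s4 = "rbcL")
  cs <- structure(list(clusters = list(c001 = c("s1", "s2"), c002 = "s3"),
                       provenance = list()), class = "cluster_set")
  m <- merge_split_gene(cs, ann, taxon_of)
  expect_length(m$clusters, 1L)
  expect_equal(sort(m$clusters[[1]]), c("s1", "s2", "s3"))

  cs2 <- structure(list(clusters = list(c001 = c("s1", "s2"), c002 = "s4"),
                        provenance = list()), class = "cluster_set")
  m2 <- merge_split_gene(cs2, ann, taxon_of)  # both clusters contain taxon T1
  expect_length(m2$clusters, 2L)
  expect_equal(m2$provenance[[1]]$action, "flagged_overlapping_candidates")
  expect_identical(merge_split_gene(cs2, NULL, taxon_of)$clusters, cs2$clusters)
})

test_that("occupancy filtering keeps clusters at or above the ceiling threshold", {
  mk <- function(n) sprintf("t%03d|g", seq_len(n))
  taxon_of <- stats::setNames(sub("\\|g$", "", mk(360)), mk(360))
  cs <- structure(list(clusters = list(a = mk(180), b = mk(179)),
                       provenance = list()), class = "cluster_set")
  kept <- occupancy_filter(cs, 360, taxon_of, min_frac = 0.5)
  expect_equal(names(kept$clusters), "a")
  all_kept <- occupancy_filter(cs, 360, taxon_of, min_frac = 0)
  expect_equal(names(all_kept$clusters), c("a", "b"))
  expect_error(occupancy_filter(cs, 0, taxon_of), "positive")
})
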