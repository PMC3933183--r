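test_that("composition counts exclude gaps and ambiguities", {
  a <- alignment(c(t1 = "GGCC", t2 = "G-A?"), "nt")
  rep <- composition_table(a)
  expect_equal(unname(rep$gc["t1"]), 1.0)
  expect_equal(unname(rep$gc["t2"]), 0.5)   # 2 counted states, 1 G
  expect_equal(unname(rep$counts["t2", ]), c(1, 0, 1, 0))

  # stratified counts on a phased 6-mer, checked by hand
  b <- alignment(c(t1 = "ATGGCT"), "nt", codon_phase = rep(1:3, 2))
  expect_equal(unname(composition_table(b, "pos1")$counts[1, ]), c(1, 0, 1, 0))
  expect_equal(unname(composition_table(b, "pos2")$counts[1, ]), c(0, 1, 0, 1))
  expect_equal(unname(composition_table(b, "pos3")$counts[1, ]), c(0, 0, 1, 1))
  expect_equal(unname(composition_table(b, "no3rd")$counts[1, ]), c(1, 1, 1, 1))

  allgap <- alignment(c(t1 = "ACGT", t2 = "----"), "nt")
  expect_equal(composition_table(allgap)$flagged, "t2")
})

test_that("chi-square homogeneity matches hand computation and df convention", {
  r <- chisq_homogeneity(matrix(c(10, 0, 0, 10), 2, 2,
                                dimnames = list(c("a", "b"), c("A", "C"))))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1L)

  same <- matrix(rep(c(5, 10, 15, 20), each = 3), 3, 4, byrow = FALSE,
                 dimnames = list(c("a", "b", "c"), c("A", "C", "G", "T")))
  r2 <- chisq_homogeneity(same)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)

  set.seed(40)
  big <- matrix(rpois(360 * 4, 50) + 1, 360, 4,
                dimnames = list(sprintf("t%03d", 1:360), c("A", "C", "G", "T")))
  expect_equal(chisq_homogeneity(big)$df, 1077L)

  zero <- matrix(c(5, 5, 0, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("A", "C")))
  expect_error(chisq_homogeneity(zero), "state 'C'")
})

test_that("chi-square statistic is permutation invariant and zero iff proportional", {
  set.seed(13)
  m <- matrix(rpois(20, 30) + 1, 4, 5,
              dimnames = list(letters[1:4], LETTERS[1:5]))
  base <- chisq_homogeneity(m)$statistic
  perm <- m[sample(4), sample(5)]
  expect_equal(chisq_homogeneity(perm)$statistic, base)
  prop <- outer(c(1, 2, 3), c(10, 20, 30, 40))
  dimnames(prop) <- list(letters[1:3], LETTERS[1:4])
  expect_equal(chisq_homogeneity(prop)$statistic, 0)
})

test_that("type-I error of the homogeneity test is nominal under the null", {
  set.seed(2024)
  n_rep <- 200; n_taxa <- 15; len <- 400
  probs <- c(.31, .19, .20, .30)
  rejections <- vapply(seq_len(n_rep), function(i) {
    counts <- t(stats::rmultinom(n_taxa, len, probs))
    colnames(counts) <- c("A", "C", "G", "T")
    rownames(counts) <- sprintf("t%02d", 1:n_taxa)
    chisq_homogeneity(counts)$p < 0.05
  }, logical(1))
  lo <- qbinom(0.005, n_rep, 0.05)
  hi <- qbinom(0.995, n_rep, 0.05)
  expect_gte(sum(rejections), lo)
  expect_lte(sum(rejections), hi)
})

test_that("nonstationary GC shifts are detected on nt but invisible after RY", {
  tr <- sample_tree(10, seed = 55)
  model <- list(rates = c(1.2, 3, 0.8, 0.9, 3.2, 1),
                freq = c(.305, .195, .195, .305))
  shift <- list(list(taxa = tr$tip.label[1:5], target = 0.75, phases = 3L))
  base <- simulate_gene(tr, 600, model = model, seed = 99)
  shifted <- simulate_gene(tr, 600, model = model, gc_shift_map = shift, seed = 99)
  a1 <- alignment(shifted, "nt", codon_phase = rep_len(1:3, 1800))
  a0 <- alignment(base, "nt", codon_phase = rep_len(1:3, 1800))
  expect_lt(chisq_homogeneity(composition_table(a1))$p, 0.05)
  r0 <- chisq_homogeneity(composition_table(ry_recode(a0)))
  r1 <- chisq_homogeneity(composition_table(ry_recode(a1)))
  expect_identical(r1$statistic, r0$statistic)  # exactly unchanged
})

test_that("amino-acid class fractions follow the fixed GC/AT-rich classes", {
  expect_error(alignment(c(t1 = "GARP", t2 = "FYMINK---"), "aa"), "same length")
  a <- alignment(c(t1 = "GARPGARPG", t2 = "FYMINK---", t3 = "LLLLLLLLL"), "aa")
  fr <- aa_class_fractions(a)
  expect_equal(fr$gc_rich_frac, c(1, 0, 0))
  expect_equal(fr$at_rich_frac, c(0, 1, 0))
})

test_that("OLS matches the normal equations and flags degenerate input", {
  f <- suppressWarnings(ols_fit(c(0, 1, 2), c(0, 1, 2)))  # exact fit
  expect_equal(f$slope, 1)
  expect_equal(f$r_squared, 1)

  set.seed(17)
  x <- rnorm(30); y <- 2 - 3 * x + rnorm(30)
  f2 <- ols_fit(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f2$slope, beta[2], tolerance = 1e-10)
  expect_error(ols_fit(rep(1, 5), rnorm(5)), "constant")
})

test_that("GC gradients drive amino-acid class fractions in opposite directions", {
  tr <- sample_tree(12, seed = 61)
  model <- list(rates = c(1.2, 3, 0.8, 0.9, 3.2, 1),
                freq = c(.305, .195, .195, .305))
  shift <- list(list(taxa = tr$tip.label[1:4], target = 0.70, phases = 1:3),
                list(taxa = tr$tip.label[5:8], target = 0.20, phases = 1:3))
  cds <- simulate_gene(tr, 800, model = model, gc_shift_map = shift, seed = 21)
  a <- alignment(cds, "nt", codon_phase = rep_len(1:3, 2400))
  aa <- translate_matrix(a)
  gc <- composition_table(a)$gc
  fr <- aa_class_fractions(aa)
  gc <- gc[fr$taxon]
  fit_gc <- ols_fit(gc, fr$gc_rich_frac)
  fit_at <- ols_fit(gc, fr$at_rich_frac)
  expect_gt(fit_gc$slope, 0)
  expect_lt(fit_at$slope, 0)
  expect_lt(fit_gc$p_slope, 0.01)
  expect_lt(fit_at$p_slope, 0.01)
})
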