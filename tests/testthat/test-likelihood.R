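test_that("discrete gamma categories normalize and match a Monte-Carlo oracle", {
  for (alpha in c(0.1, 0.5, 1, 5)) {
    g <- discrete_gamma(alpha, 4)
    expect_equal(sum(g$rates * g$probs), 1)
  }
  g_big <- discrete_gamma(1e8, 4)
  expect_true(all(abs(g_big$rates - 1) < 1e-3))
  expect_error(discrete_gamma(0), "alpha")

  set.seed(99)
  draws <- rgamma(1e6, shape = 0.5, rate = 0.5)
  qs <- quantile(draws, c(0.25, 0.5, 0.75))
  bins <- findInterval(draws, qs)
  mc <- tapply(draws, bins, mean)
  g <- discrete_gamma(0.5, 4)
  expect_equal(unname(g$rates), unname(as.numeric(mc)), tolerance = 5e-3)
})

test_that("rate matrices scale to unit flow and satisfy reversibility", {
  jc <- rate_matrix(substitution_model("GTR+G"))
  expect_equal(unname(jc[1, 2]), 1 / 3)
  expect_equal(unname(rowSums(jc)), rep(0, 4))

  set.seed(3)
  for (rep in 1:5) {
    freq <- as.numeric(rdirichlet1(4))
    m <- substitution_model("GTR+G", rates = runif(6, 0.1, 5), freq = freq)
    Q <- rate_matrix(m)
    expect_equal(-sum(freq * diag(Q)), 1)
    P <- plastidphylo:::transition_probs(plastidphylo:::decompose_q(Q, freq), 0.37)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-10)
    # detailed balance pi_i P_ij = pi_j P_ji
    expect_equal(freq * P, t(freq * P), tolerance = 1e-10)
  }
  expect_error(rate_matrix(substitution_model("GTR+G", freq = c(0, .2, .4, .4))),
               "positive")
})

test_that("pruning log-likelihood matches closed forms", {
  # two identical 1-site sequences at distance 0 under JC: lnL = log(1/4)
  tr <- ape::read.tree(text = "(a:0,b:0);")
  a <- alignment(c(a = "A", b = "A"), "nt")
  jc <- substitution_model("GTR+G", ncat = 1)
  expect_equal(as.numeric(log_likelihood(tr, a, models = jc)), log(0.25))

  # two taxa, site (A, C), branch-length sum t: L = (1/16)(1 - exp(-4t/3))
  for (t in c(0.1, 0.5, 2)) {
    tr2 <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
    a2 <- alignment(c(a = "A", b = "C"), "nt")
    expect_equal(as.numeric(log_likelihood(tr2, a2, models = jc)),
                 log((1 / 16) * (1 - exp(-4 * t / 3))), tolerance = 1e-10)
  }
})

test_that("pruning equals the state-enumeration oracle on small random instances", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:5, 1)
    tr <- ape::rtree(n)
    L <- sample(5:12, 1)
    a <- random_codon_aln(n, ceiling(L / 3), taxa = tr$tip.label)
    a <- aln_subset(a, cols = seq_len(L))
    m <- substitution_model("GTR+G", rates = runif(6, 0.2, 4),
                            freq = as.numeric(rdirichlet1(4)),
                            alpha = runif(1, 0.3, 2), ncat = 2)
    mine <- as.numeric(log_likelihood(tr, a, models = m))
    expect_equal(mine, oracle_loglik(tr, a, m), tolerance = 1e-8)
  }
})

test_that("log-likelihood is invariant under re-rooting for reversible models", {
  set.seed(33)
  tr <- ape::rtree(6)
  a <- random_codon_aln(6, 20, taxa = tr$tip.label)
  m <- substitution_model("GTR+G", rates = runif(6, .2, 4),
                          freq = as.numeric(rdirichlet1(4)), alpha = 0.7)
  l0 <- as.numeric(log_likelihood(tr, a, models = m))
  l1 <- as.numeric(log_likelihood(ape::unroot(tr), a, models = m))
  l2 <- as.numeric(log_likelihood(
    ape::root(ape::unroot(tr), outgroup = tr$tip.label[3], resolve.root = TRUE),
    a, models = m))
  expect_equal(l1, l0, tolerance = 1e-9)
  expect_equal(l2, l0, tolerance = 1e-9)
})

test_that("gaps and ambiguities act as missing data", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.3);")
  jc <- substitution_model("GTR+G", ncat = 1)
  a_gap <- alignment(c(a = "A", b = "-"), "nt")
  # partner fully unknown: site likelihood is the stationary frequency
  expect_equal(as.numeric(log_likelihood(tr, a_gap, models = jc)), log(0.25))
  a_r <- alignment(c(a = "A", b = "R"), "nt")
  P <- plastidphylo:::transition_probs(
    plastidphylo:::decompose_q(rate_matrix(jc), jc$freq), 0.5)
  expect_equal(as.numeric(log_likelihood(tr, a_r, models = jc)),
               log(0.25 * (P[1, 1] + P[1, 3])), tolerance = 1e-10)
})

test_that("parameter counting follows the shared-branch-length convention", {
  s1 <- partition_scheme("onepart", list(all = 1:100), "GTR+G")
  expect_equal(count_parameters(s1, 360), 726)
  s234 <- partition_scheme("codongene",
                           stats::setNames(lapply(1:234, function(i) i),
                                           paste0("p", 1:234)), "GTR+G")
  expect_equal(count_parameters(s234, 360), 2823)
  sb <- partition_scheme("ry", list(all = 1:10), "BIN+G")
  expect_equal(count_parameters(sb, 4), 7)
  expect_error(count_parameters(s1, 2), "at least 3")
})

test_that("AICc follows the small-sample formula and limits", {
  expect_equal(aicc(-100, 5, 100), 210 + 60 / 94)
  expect_equal(aicc(-100, 0, 100), 200)
  expect_equal(aicc(-100, 5, 1e9), 210, tolerance = 1e-6)
  expect_error(aicc(-100, 99, 100), "undefined")
})

test_that("scheme comparison ranks by AICc with a parameter tie-break", {
  res <- rbind(likelihood_result("a", -100, 5, 100),
               likelihood_result("b", -98, 10, 100),
               likelihood_result("c", -101, 4, 100))
  cmp <- compare_schemes(res)
  expect_equal(cmp$delta_aicc[1], 0)
  expect_equal(cmp$scheme, c("c", "a", "b"))

  set.seed(9)
  for (rep in 1:10) {
    r <- data.frame(scheme = letters[1:5], aicc = runif(5, 100, 200), n = 50)
    expect_equal(compare_schemes(r)$scheme[1],
                 r$scheme[which.min(r$aicc)])
  }
  expect_error(compare_schemes(data.frame(scheme = c("a", "b"),
                                          aicc = c(1, 2), n = c(10, 20))),
               "mixed sample sizes")
  expect_equal(compare_schemes(likelihood_result("only", -10, 2, 50))$delta_aicc, 0)
})

test_that("nuisance optimization recovers the gamma shape and never decreases lnL", {
  tr <- sample_tree(6, depth = 0.4, seed = 77)
  truth_alpha <- 0.5
  cds <- simulate_gene(tr, 2000,
                       model = list(rates = c(1, 2.5, 0.7, 0.8, 2.8, 1),
                                    freq = c(.3, .2, .2, .3)),
                       pos_rates = c(1, 1, 1), alpha = truth_alpha, seed = 13)
  a <- alignment(cds, "nt", codon_phase = rep_len(1:3, 6000))
  scheme <- make_scheme(a, "onepart")
  fit <- optimize_nuisance(tr, a, scheme, optimize_rates = TRUE)
  expect_true(all(diff(fit$trace) >= -1e-9))
  alpha_hat <- fit$models[[1]]$alpha
  expect_lt(abs(alpha_hat - truth_alpha) / truth_alpha, 0.20)
})

test_that("strong among-gene heterogeneity favours the by-gene scheme by AICc", {
  wins <- 0L
  n_rep <- 6L
  for (r in seq_len(n_rep)) {
    tr <- sample_tree(6, depth = 0.4, seed = 500 + r)
    scales <- c(0.15, 1, 6)
    freqs <- list(c(.45, .05, .05, .45), c(.25, .25, .25, .25),
                  c(.1, .4, .4, .1))
    genes <- lapply(1:3, function(i) {
      tri <- tr; tri$edge.length <- tri$edge.length * scales[i]
      simulate_gene(tri, 250, model = list(rates = rep(1, 6), freq = freqs[[i]]),
                    pos_rates = c(1, 1, 1), alpha = 1, seed = 600 + 10 * r + i)
    })
    names(genes) <- c("g1", "g2", "g3")
    alns <- lapply(genes, function(g) alignment(g, "nt",
                                                codon_phase = rep_len(1:3, 750)))
    cc <- concatenate(alns)
    fits <- rbind(
      fit_scheme(tr, cc$alignment, make_scheme(cc$alignment, "onepart")),
      fit_scheme(tr, cc$alignment, make_scheme(cc$alignment, "gene",
                                               gene_scheme = cc$scheme)))
    cmp <- compare_schemes(fits)
    if (cmp$scheme[1] == "gene" && cmp$delta_aicc[2] > 10) wins <- wins + 1L
  }
  expect_gte(wins, n_rep - 1L)
})
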