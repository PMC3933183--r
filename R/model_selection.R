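#' Build standard partitioning strategies for a matrix
#'
#' Generates the schemes compared in plastome partitioning studies: a single
#' partition (`onepart`), by codon position (`codon`), by gene (`gene`), and
#' by codon position within gene (`codongene`). Codon-based strategies need
#' `codon_phase`; gene-based strategies need the by-gene scheme produced by
#' [concatenate()] (possibly remapped by [recode_matrix()]).
#'
#' @param a an `aln`.
#' @param strategy one of `"onepart"`, `"codon"`, `"gene"`, `"codongene"`.
#' @param gene_scheme by-gene `partition_scheme` (for `gene` / `codongene`).
#' @param model_family model family; default chosen from the alphabet.
#' @return a `partition_scheme`.
#' @export
make_scheme <- function(a, strategy = c("onepart", "codon", "gene", "codongene"),
                        gene_scheme = NULL,
                        model_family = default_family(a$alphabet)) {
  strategy <- match.arg(strategy)
  n <- aln_ncol(a)
  phases_present <- if (!is.null(a$codon_phase)) sort(unique(a$codon_phase))
  parts <- switch(strategy,
    onepart = list(all = seq_len(n)),
    codon = {
      if (is.null(a$codon_phase)) stopf("codon strategy needs codon_phase")
      stats::setNames(lapply(phases_present, function(p) which(a$codon_phase == p)),
                      paste0("pos", phases_present))
    },
    gene = {
      if (is.null(gene_scheme)) stopf("gene strategy needs gene_scheme")
      gene_scheme$partitions
    },
    codongene = {
      if (is.null(a$codon_phase)) stopf("codongene strategy needs codon_phase")
      if (is.null(gene_scheme)) stopf("codongene strategy needs gene_scheme")
      out <- list()
      for (g in names(gene_scheme$partitions)) {
        cols <- gene_scheme$partitions[[g]]
        for (p in phases_present) {
          sel <- cols[a$codon_phase[cols] == p]
          if (length(sel)) out[[sprintf("%s_pos%d", g, p)]] <- sel
        }
      }
      out
    })
  partition_scheme(strategy, parts, model_family = model_family, n_col = n)
}

#' Count estimable parameters of a partitioning scheme
#'
#' Convention: `2 * n_taxa - 3` shared branch lengths, plus per partition
#' 9 for GTR+G (5 free exchangeabilities + 3 free frequencies + gamma shape),
#' 2 for BIN+G (1 free frequency + shape), and 1 for AA+G (fixed empirical
#' exchangeabilities and frequencies; shape only).
#'
#' @param scheme a `partition_scheme`.
#' @param n_taxa number of taxa (>= 3).
#' @return integer parameter count.
#' @export
count_parameters <- function(scheme, n_taxa) {
  if (n_taxa < 3L) stopf("need at least 3 taxa")
  per <- c(`GTR+G` = 9L, `BIN+G` = 2L, `AA+G` = 1L)
  (2L * n_taxa - 3L) + sum(per[scheme$model_family])
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k + 1) / (n - k - 1)`; undefined unless
#' `n > k + 1`.
#'
#' @param lnl log-likelihood.
#' @param k parameter count.
#' @param n sample size (alignment columns).
#' @export
aicc <- function(lnl, k, n) {
  if (n <= k + 1) stopf("AICc undefined: n must exceed k + 1 (n=%g, k=%g)", n, k)
  -2 * lnl + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Assemble a likelihood result record
#' @param scheme_name scheme label.
#' @param lnl log-likelihood.
#' @param k parameter count.
#' @param n sample size.
#' @param n_partitions number of partitions.
#' @return one-row data.frame with `scheme`, `n_partitions`, `lnl`, `k`, `n`,
#'   `aicc`.
#' @export
likelihood_result <- function(scheme_name, lnl, k, n, n_partitions = NA_integer_) {
  data.frame(scheme = scheme_name, n_partitions = n_partitions,
             lnl = lnl, k = k, n = n, aicc = aicc(lnl, k, n),
             stringsAsFactors = FALSE)
}

#' Rank partitioning schemes by AICc
#'
#' Computes `delta_aicc = AICc - min(AICc)` and orders schemes best-first;
#' ties are broken in favour of fewer parameters.
#'
#' @param results data.frame with at least columns `scheme` and `aicc`;
#'   columns `n` (checked for consistency) and `k` (tie-break) are used when
#'   present.
#' @return the data.frame with a `delta_aicc` column, ordered best-first.
#' @export
compare_schemes <- function(results) {
  if (nrow(results) < 1L) stopf("no results to compare")
  if (!is.null(results$n) && length(unique(results$n)) > 1L)
    stopf("mixed sample sizes across results")
  results$delta_aicc <- results$aicc - min(results$aicc)
  ord <- if (!is.null(results$k)) order(results$aicc, results$k)
         else order(results$aicc)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empirical_freq <- function(a, cols, alphabet = a$alphabet, pseudo = 0.5) {
  ss <- state_space(alphabet)
  tab <- table(factor(a$mat[, cols, drop = FALSE], levels = ss$states))
  f <- as.numeric(tab) + pseudo
  f / sum(f)
}

#' Optimize nuisance parameters of a partitioned model
#'
#' Coordinate-wise bounded search: per-partition gamma shape (and, optionally,
#' GTR exchangeabilities) via golden-section search on a log scale, state
#' frequencies set to partition-wise empirical frequencies, and optionally a
#' shared branch-length scale. Iterates until the log-likelihood improves by
#' less than `tol`; the trajectory is monotone non-decreasing because a
#' coordinate update is only accepted when it improves the likelihood.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param a an `aln`.
#' @param scheme a `partition_scheme`.
#' @param models starting models (default: empirical-frequency models with
#'   `alpha = 1`).
#' @param optimize_rates also optimize GTR exchangeabilities (slower).
#' @param optimize_branch_scale optimize a shared multiplier of all branch
#'   lengths.
#' @param tol convergence tolerance on the log-likelihood (default `1e-4`).
#' @param max_iter maximum sweeps; non-convergence yields a warning and the
#'   best parameters so far.
#' @param ncat gamma categories for default models.
#' @return list with `models`, `branch_scale`, `lnl`, `trace` (lnL per sweep).
#' @export
optimize_nuisance <- function(tree, a, scheme, models = NULL,
                              optimize_rates = FALSE,
                              optimize_branch_scale = TRUE,
                              tol = 1e-4, max_iter = 40L, ncat = 4L) {
  npart <- n_partitions(scheme)
  if (is.null(models)) {
    models <- lapply(seq_len(npart), function(i) {
      fam <- scheme$model_family[i]
      freq <- if (fam == "AA+G") NULL
              else empirical_freq(a, scheme$partitions[[i]])
      substitution_model(fam, freq = freq, alpha = 1, ncat = ncat)
    })
  } else if (inherits(models, "substitution_model"))
    models <- rep(list(models), npart)
  tree_pp <- check_tree_taxa(tree, aln_taxa(a))
  pdata <- lapply(scheme$partitions, function(cols) prepare_patterns(a, cols))
  bscale <- 1
  part_lnl <- function(i, model, bs = bscale)
    partition_loglik(tree_pp, pdata[[i]], model, bs)
  lnls <- vapply(seq_len(npart), function(i) part_lnl(i, models[[i]]), numeric(1))
  trace <- sum(lnls)
  for (iter in seq_len(max_iter)) {
    before <- sum(lnls)
    for (i in seq_len(npart)) {
      m <- models[[i]]
      # gamma shape
      opt <- stats::optimize(function(la) {
        m2 <- m; m2$alpha <- exp(la); part_lnl(i, m2)
      }, interval = log(c(0.02, 50)), maximum = TRUE, tol = 1e-4)
      if (opt$objective > lnls[i]) {
        m$alpha <- exp(opt$maximum); lnls[i] <- opt$objective
      }
      if (optimize_rates && m$family == "GTR+G") {
        for (j in 1:5) {
          opt <- stats::optimize(function(lr) {
            m2 <- m; m2$rates[j] <- exp(lr); part_lnl(i, m2)
          }, interval = log(c(1e-3, 1e3)), maximum = TRUE, tol = 1e-4)
          if (opt$objective > lnls[i]) {
            m$rates[j] <- exp(opt$maximum); lnls[i] <- opt$objective
          }
        }
      }
      models[[i]] <- m
    }
    if (optimize_branch_scale) {
      total <- function(lb) {
        sum(vapply(seq_len(npart),
                   function(i) part_lnl(i, models[[i]], exp(lb)), numeric(1)))
      }
      opt <- stats::optimize(total, interval = log(c(0.05, 20)) + log(bscale),
                             maximum = TRUE, tol = 1e-4)
      if (opt$objective > sum(lnls)) {
        bscale <- exp(opt$maximum)
        lnls <- vapply(seq_len(npart), function(i) part_lnl(i, models[[i]]),
                       numeric(1))
      }
    }
    trace <- c(trace, sum(lnls))
    if (sum(lnls) - before < tol) break
  }
  if (iter == max_iter && sum(lnls) - before >= tol)
    warnf("nuisance optimization did not converge in %d sweeps", max_iter)
  list(models = models, branch_scale = bscale, lnl = sum(lnls), trace = trace)
}

#' Fit one partitioning scheme and record its AICc
#'
#' Optimizes nuisance parameters under the scheme, then assembles the
#' `(lnL, k, n, AICc)` record with `n` equal to the alignment column count.
#'
#' @inheritParams optimize_nuisance
#' @param ... passed to [optimize_nuisance()].
#' @return one-row data.frame as from [likelihood_result()].
#' @export
fit_scheme <- function(tree, a, scheme, ...) {
  fit <- optimize_nuisance(tree, a, scheme, ...)
  k <- count_parameters(scheme, aln_ntaxa(a))
  likelihood_result(scheme$name, fit$lnl, k, aln_ncol(a),
                    n_partitions = n_partitions(scheme))
}
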