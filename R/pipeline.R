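#' Run the full plastome phylogenomics pipeline
#'
#' Orchestrates simulation (or loading of user inputs), homolog clustering,
#' supermatrix assembly, the five character codings, composition diagnostics,
#' AICc partition-scheme comparison, decisiveness analysis and (when a tree
#' set is supplied or simulated) a consensus support summary, writing all
#' artifacts plus a hash-stable run manifest.
#'
#' @param config either a [sim_config()] (simulated inputs), a path to a YAML
#'   file with a `simulate:` block of `sim_config()` arguments, or a list
#'   with elements `seqs` (FASTA path), `hits` (tabular hit path) and `tree`
#'   (Newick path) for user data.
#' @param out_dir output directory for artifacts and the manifest.
#' @param codings character codings to produce.
#' @param model_strategies partitioning strategies compared by AICc on the
#'   all-positions matrix (`NULL` skips model selection).
#' @param remove_taxa taxa to drop from every coded matrix before analysis
#'   (sensitivity-analysis hook).
#' @param tree_set optional list of trees for the consensus summary; for
#'   simulated input, `n_boot` random NNI perturbations of the true tree are
#'   generated instead when this is `NULL`.
#' @param n_boot number of perturbed trees for the simulated tree set.
#' @param max_gap_frac column-trimming threshold.
#' @param code genetic code.
#' @return list of class `pipeline_run` with all stage outputs and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, codings = c("ntAll", "ntNo3rd",
                                                      "nt3rdOnly", "RY", "AA"),
                         model_strategies = c("onepart", "codon", "gene",
                                              "codongene"),
                         remove_taxa = NULL, tree_set = NULL, n_boot = 20L,
                         max_gap_frac = 0.5, code = "plastid") {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$simulate)) config <- do.call(sim_config, cfg$simulate)
    else config <- cfg
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  stages <- character(0)

  # ---- stage: inputs --------------------------------------------------------
  if (inherits(config, "sim_config")) {
    sim <- simulate_plastome(config)
    seq_tab <- sim$seq_tab
    hits <- sim$hits
    tree <- sim$tree
    seed <- config$seed
  } else {
    sim <- NULL
    nt <- read_sequences(config$seqs, alphabet = "nt")
    seq_tab <- data.frame(seq_id = nt$seq_id, taxon_id = nt$taxon_id,
                          gene_truth = NA_character_, seq = nt$seq,
                          stringsAsFactors = FALSE)
    aa_len <- nchar(vapply(nt$seq, translate_cds, character(1), code = code))
    names(aa_len) <- nt$seq_id
    hits <- parse_hit_table(config$hits, aa_len)
    tree <- if (!is.null(config$tree)) parse_newick(readLines(config$tree)) else NULL
    seed <- config$seed %||% 1L
  }
  stages <- c(stages, "inputs")

  # ---- stage: clustering ----------------------------------------------------
  annotations <- if (!is.null(seq_tab$gene_truth))
    stats::setNames(seq_tab$gene_truth, seq_tab$seq_id)
  aa_tab <- seq_tab
  aa_tab$seq <- vapply(seq_tab$seq, translate_cds, character(1), code = code)
  clusters <- cluster_homologs(aa_tab, hits, annotations = annotations)
  utils::write.table(cluster_table(clusters,
                                   stats::setNames(seq_tab$taxon_id,
                                                   seq_tab$seq_id)),
                     file.path(out_dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stages <- c(stages, "cluster")

  # ---- stage: matrix build --------------------------------------------------
  nt_of <- stats::setNames(seq_tab$seq, seq_tab$seq_id)
  taxon_of <- stats::setNames(seq_tab$taxon_id, seq_tab$seq_id)
  genes <- lapply(names(clusters$clusters), function(cid) {
    members <- clusters$clusters[[cid]]
    aa <- stats::setNames(vapply(nt_of[members], translate_cds, character(1),
                                 code = code), taxon_of[members])
    cds <- stats::setNames(nt_of[members], taxon_of[members])
    gene_alignment(cid, alignment(aa, "aa"), cds,
                   max_gap_frac = max_gap_frac, code = code)
  })
  cc <- concatenate(genes)
  stages <- c(stages, "build")

  # ---- stage: codings -------------------------------------------------------
  matrices <- list()
  for (cd in codings) {
    rc <- recode_matrix(cc$alignment, cd, scheme = cc$scheme, code = code)
    if (!is.null(remove_taxa))
      rc$alignment <- remove_taxa(rc$alignment, remove_taxa)
    matrices[[cd]] <- rc
    write_supermatrix(rc$alignment,
                      rc$scheme %||% make_scheme(rc$alignment, "onepart"),
                      out_dir, prefix = cd)
  }
  stages <- c(stages, "recode")

  # ---- stage: composition diagnostics --------------------------------------
  diag <- list()
  if ("ntAll" %in% names(matrices)) {
    ntall <- matrices$ntAll$alignment
    strata <- c("all", "pos1", "pos2", "pos3", "no3rd")
    diag$chisq <- do.call(rbind, lapply(strata, function(s) {
      rep <- composition_table(ntall, s)
      cs <- chisq_homogeneity(rep)
      data.frame(stratum = s, mean_gc = mean(rep$gc, na.rm = TRUE),
                 statistic = cs$statistic, df = cs$df, p = cs$p)
    }))
    if ("RY" %in% names(matrices)) {
      ryrep <- composition_table(matrices$RY$alignment)
      csr <- chisq_homogeneity(ryrep)
      diag$chisq <- rbind(diag$chisq,
                          data.frame(stratum = "RY", mean_gc = NA_real_,
                                     statistic = csr$statistic, df = csr$df,
                                     p = csr$p))
    }
    if ("AA" %in% names(matrices)) {
      fr <- aa_class_fractions(matrices$AA$alignment)
      gc <- composition_table(ntall)$gc[fr$taxon]
      diag$gc_regressions <- list(
        gc_rich = ols_fit(gc, fr$gc_rich_frac),
        at_rich = ols_fit(gc, fr$at_rich_frac))
      diag$aa_class <- fr
    }
    utils::write.table(diag$chisq, file.path(out_dir, "composition_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stages <- c(stages, "diagnose")

  # ---- stage: model selection ----------------------------------------------
  modelsel <- NULL
  if (!is.null(model_strategies) && !is.null(tree) &&
      "ntAll" %in% names(matrices)) {
    a <- matrices$ntAll$alignment
    gs <- matrices$ntAll$scheme
    fits <- lapply(model_strategies, function(st) {
      fit_scheme(tree, a, make_scheme(a, st, gene_scheme = gs))
    })
    modelsel <- compare_schemes(do.call(rbind, fits))
    utils::write.table(modelsel, file.path(out_dir, "model_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages <- c(stages, "modelsel")
  }

  # ---- stage: decisiveness --------------------------------------------------
  cov <- coverage_from_matrix(matrices[[1]]$alignment,
                              matrices[[1]]$scheme %||% cc$scheme)
  dec <- decisiveness_report(cov,
                             mode = if (ncol(cov) <= 25L) "exact" else "sample",
                             seed = seed)
  jsonlite::write_json(unclass(dec), file.path(out_dir, "decisiveness.json"),
                       auto_unbox = TRUE, digits = NA)
  stages <- c(stages, "decisive")

  # ---- stage: tree summary --------------------------------------------------
  summary_out <- NULL
  if (is.null(tree_set) && !is.null(sim) && n_boot > 0L) {
    tree_set <- with_seed(seed + 5L, lapply(seq_len(n_boot), function(i)
      phangorn::rNNI(sim$tree, moves = sample(0:2, 1))))
  }
  if (!is.null(tree_set) && length(tree_set) > 0L) {
    cons <- majority_rule_consensus(tree_set, cutoff = 0.5)
    ape::write.tree(cons, file.path(out_dir, "consensus.nwk"))
    summary_out <- support_summary(cons, threshold = 70)
    stages <- c(stages, "consensus")
  }

  # ---- manifest --------------------------------------------------------------
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("plastidphylo")),
    seed = seed,
    stages = stages,
    config = if (inherits(config, "sim_config")) unclass(config) else config,
    hashes = as.list(tools::md5sum(files)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  names(manifest$hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  structure(list(sim = sim, clusters = clusters, genes = genes,
                 supermatrix = cc, matrices = matrices, diagnostics = diag,
                 model_selection = modelsel, decisiveness = dec,
                 support = summary_out, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> stages: %s\n",
              paste(x$manifest$stages, collapse = " -> ")))
  invisible(x)
}

#' Human-readable summary tables for a pipeline run
#'
#' Assembles the standard report tables: matrix dimensions, GC and
#' chi-square homogeneity by codon-position stratum, the AICc comparison of
#' partitioning strategies (scheme, partitions, lnL, AICc, delta AICc),
#' decisiveness fractions and the bipartition-support summary.
#'
#' @param run a `pipeline_run`.
#' @return named list of data.frames.
#' @export
pipeline_report <- function(run) {
  if (!inherits(run, "pipeline_run")) stopf("need a pipeline_run")
  if (length(run$matrices) == 0L) stopf("run has no matrices; incomplete run")
  dims <- do.call(rbind, lapply(names(run$matrices), function(cd) {
    a <- run$matrices[[cd]]$alignment
    data.frame(matrix = cd, n_taxa = aln_ntaxa(a), n_columns = aln_ncol(a),
               missing_frac = missingness(a))
  }))
  out <- list(dimensions = dims, composition_tests = run$diagnostics$chisq)
  if (!is.null(run$model_selection)) {
    ms <- run$model_selection
    out$model_selection <- ms[, c("scheme", "n_partitions", "lnl", "aicc",
                                  "delta_aicc")]
  }
  out$decisiveness <- data.frame(
    triplet_coverage = run$decisiveness$fraction_triplets_covered,
    quadruple_coverage = run$decisiveness$fraction_quadruples_covered,
    decisive_all_trees = run$decisiveness$decisive_all_trees)
  if (!is.null(run$support))
    out$support <- data.frame(n_resolved = run$support$n_resolved,
                              n_possible = run$support$n_possible,
                              mean_support = run$support$mean_support)
  out
}
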