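#' Homolog clustering from all-vs-all similarity hits
#'
#' The clustering stage turns protein similarity hits into putative
#' single-gene clusters: hits are filtered on e-value and mutual coverage,
#' single-linkage (connected-component) clusters are formed, clusters holding
#' several distinct sequences from one taxon are re-clustered at successively
#' stricter e-values, clusters that appear to split one gene are merged using
#' annotations, inverted-repeat duplicates are resolved, and only clusters
#' covering a minimum fraction of taxa are retained.
#'
#' @name homolog_clustering
NULL

#' Filter similarity hits into an undirected edge list
#'
#' A hit survives iff `evalue <= max_evalue` and both query and target
#' coverage are at least `min_cov`. Self-hits are dropped; reciprocal
#' duplicates are collapsed keeping the best (smallest) e-value.
#'
#' @param hits data.frame as returned by [parse_hit_table()].
#' @param max_evalue maximum e-value (default `1e-5`).
#' @param min_cov minimum query and target coverage (default `0.40`).
#' @return data.frame with columns `a`, `b` (sorted pair), `evalue`.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_cov = 0.40) {
  keep <- hits$evalue <= max_evalue &
    hits$query_cov >= min_cov & hits$target_cov >= min_cov &
    hits$query_id != hits$target_id
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(a = character(0), b = character(0), evalue = numeric(0)))
  a <- pmin(h$query_id, h$target_id)
  b <- pmax(h$query_id, h$target_id)
  ord <- order(a, b, h$evalue)
  e <- data.frame(a = a[ord], b = b[ord], evalue = h$evalue[ord],
                  stringsAsFactors = FALSE)
  e[!duplicated(paste(e$a, e$b, sep = "\r")), , drop = FALSE]
}

#' Single-linkage clusters as graph connected components
#'
#' Sequences sharing a path of retained hits form one cluster; singletons
#' (nodes with no retained edge) are size-1 clusters.
#'
#' @param nodes character vector of all sequence ids (superset of edge ends).
#' @param edges data.frame with columns `a`, `b` as from [filter_hits()].
#' @return object of class `cluster_set`: list with `clusters` (named list of
#'   member-id vectors) and `provenance` (list of log entries).
#' @export
cluster_single_linkage <- function(nodes, edges) {
  nodes <- unique(as.character(nodes))
  extra <- setdiff(unique(c(edges$a, edges$b)), nodes)
  if (length(extra)) stopf("edge endpoints missing from nodes: %s", extra[1])
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  comp <- igraph::components(g)
  members <- split(nodes, comp$membership[nodes])
  # deterministic order: by size (desc) then by first member
  ord <- order(-lengths(members),
               vapply(members, function(m) sort(m)[1], character(1)))
  members <- lapply(members[ord], sort)
  names(members) <- sprintf("c%03d", seq_along(members))
  structure(list(clusters = members, provenance = list()), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), %d sequence(s)\n",
              length(x$clusters), sum(lengths(x$clusters))))
  invisible(x)
}

#' Stringency schedule for multi-copy re-clustering
#'
#' E-value cutoffs starting one step below `start`, dividing by `factor` each
#' step down to `floor`.
#' @param start base e-value cutoff used in the initial clustering.
#' @param factor per-step division factor.
#' @param floor smallest cutoff tried.
#' @export
stringency_schedule <- function(start = 1e-5, factor = 10, floor = 1e-30) {
  out <- numeric(0)
  e <- start / factor
  while (e >= floor * (1 - 1e-12)) {
    out <- c(out, e)
    e <- e / factor
  }
  out
}

# does any taxon contribute >= 2 distinct sequences?
multicopy_taxa <- function(members, taxon_of, seqs = NULL) {
  tx <- taxon_of[members]
  dup <- unique(tx[duplicated(tx)])
  if (is.null(seqs)) return(dup)
  # with sequences available, identical copies (IR duplicates) do not count
  keep <- vapply(dup, function(t) {
    s <- unique(seqs[members[tx == t]])
    length(s) >= 2L
  }, logical(1))
  dup[keep]
}

#' Re-cluster a multi-copy cluster at stricter e-values
#'
#' A cluster is multi-copy when some taxon contributes two or more
#' non-identical sequences. Hits among the cluster members are re-filtered at
#' each cutoff of the stringency schedule until no sub-cluster is multi-copy.
#' If the floor is reached, the offending taxa's sequences are removed from
#' the affected sub-clusters and the action is logged.
#'
#' @param members character vector of cluster member sequence ids.
#' @param hits full hits data.frame.
#' @param taxon_of named character vector mapping seq_id to taxon_id.
#' @param seqs optional named character vector of sequences (identical copies
#'   then do not flag a cluster as multi-copy).
#' @param schedule decreasing e-value cutoffs (see [stringency_schedule()]).
#' @param min_cov coverage threshold reused at every step.
#' @return list with `clusters` (list of member vectors) and `log`.
#' @export
refine_multicopy <- function(members, hits, taxon_of, seqs = NULL,
                             schedule = stringency_schedule(),
                             min_cov = 0.40) {
  if (length(schedule) == 0L) stopf("empty stringency schedule")
  if (length(multicopy_taxa(members, taxon_of, seqs)) == 0L)
    return(list(clusters = list(members), log = list()))
  hsub <- hits[hits$query_id %in% members & hits$target_id %in% members, ,
               drop = FALSE]
  log <- list()
  for (e in schedule) {
    edges <- filter_hits(hsub, max_evalue = e, min_cov = min_cov)
    cs <- cluster_single_linkage(members, edges)
    bad <- lapply(cs$clusters, multicopy_taxa, taxon_of = taxon_of, seqs = seqs)
    if (all(lengths(bad) == 0L)) {
      log <- c(log, list(list(action = "reclustered", evalue = e,
                              n_subclusters = length(cs$clusters))))
      return(list(clusters = unname(cs$clusters), log = log))
    }
  }
  # floor reached: drop offending taxa from still-multi-copy sub-clusters
  out <- lapply(names(cs$clusters), function(id) {
    m <- cs$clusters[[id]]
    offend <- bad[[id]]
    if (length(offend)) {
      log[[length(log) + 1L]] <<- list(action = "dropped_taxa_at_floor",
                                       evalue = schedule[length(schedule)],
                                       taxa = offend)
      m <- m[!(taxon_of[m] %in% offend)]
    }
    m
  })
  list(clusters = out[lengths(out) > 0L], log = log)
}

#' Merge clusters that split a single gene
#'
#' Clusters whose members share the same majority annotation label and whose
#' taxon sets are pairwise disjoint are merged; label groups with overlapping
#' taxon sets are flagged and left unmerged.
#'
#' @param cs a `cluster_set`.
#' @param annotations named character vector mapping seq_id to a gene label
#'   (may cover only part of the sequences); `NULL` makes this a no-op.
#' @param taxon_of named character vector seq_id -> taxon_id.
#' @return a `cluster_set` with merge actions appended to provenance.
#' @export
merge_split_gene <- function(cs, annotations, taxon_of) {
  if (is.null(annotations)) return(cs)
  lab <- vapply(cs$clusters, function(m) {
    a <- annotations[m]
    a <- a[!is.na(a)]
    if (length(a) == 0L) return(NA_character_)
    names(sort(table(a), decreasing = TRUE))[1]
  }, character(1))
  groups <- split(names(cs$clusters), lab)
  clusters <- cs$clusters
  prov <- cs$provenance
  for (g in groups) {
    if (length(g) < 2L) next
    taxsets <- lapply(clusters[g], function(m) unique(taxon_of[m]))
    n_union <- length(unique(unlist(taxsets)))
    if (n_union == sum(lengths(taxsets))) {
      merged <- sort(unlist(clusters[g], use.names = FALSE))
      clusters[[g[1]]] <- merged
      clusters[g[-1]] <- NULL
      prov <- c(prov, list(list(action = "merged_split_gene",
                                label = lab[[g[1]]], merged = g)))
    } else {
      prov <- c(prov, list(list(action = "flagged_overlapping_candidates",
                                label = lab[[g[1]]], clusters = g)))
    }
  }
  structure(list(clusters = clusters, provenance = prov), class = "cluster_set")
}

#' Resolve inverted-repeat duplicates within a cluster
#'
#' When a taxon contributes multiple copies of a gene (as happens for genes in
#' the plastid inverted repeat): identical copies collapse to one retained
#' sequence; copies that differ at any site cause all of that taxon's copies
#' to be removed from the cluster.
#'
#' @param members member sequence ids.
#' @param seqs named character vector of sequences.
#' @param taxon_of named character vector seq_id -> taxon_id.
#' @return list with `members` (kept ids), `log`.
#' @export
resolve_ir_duplicates <- function(members, seqs, taxon_of) {
  tx <- taxon_of[members]
  log <- list()
  keep <- character(0)
  for (t in unique(tx)) {
    ids <- sort(members[tx == t])
    if (length(ids) == 1L) {
      keep <- c(keep, ids)
    } else if (length(unique(toupper(seqs[ids]))) == 1L) {
      keep <- c(keep, ids[1])
      log <- c(log, list(list(action = "ir_identical_kept_one", taxon = t,
                              kept = ids[1], dropped = ids[-1])))
    } else {
      log <- c(log, list(list(action = "ir_divergent_removed_all", taxon = t,
                              dropped = ids)))
    }
  }
  list(members = keep, log = log)
}

#' Retain clusters covering a minimum fraction of taxa
#'
#' A cluster is retained iff its distinct-taxon count is at least
#' `ceiling(min_frac * n_taxa)`, so exactly the threshold fraction qualifies.
#'
#' @param cs a `cluster_set`.
#' @param n_taxa total number of taxa in the study.
#' @param taxon_of named character vector seq_id -> taxon_id.
#' @param min_frac minimum taxon fraction (default `0.5`).
#' @return a filtered `cluster_set`.
#' @export
occupancy_filter <- function(cs, n_taxa, taxon_of, min_frac = 0.5) {
  if (n_taxa <= 0L) stopf("n_taxa must be positive")
  need <- ceiling(min_frac * n_taxa)
  n_tax <- vapply(cs$clusters, function(m) length(unique(taxon_of[m])), integer(1))
  dropped <- names(cs$clusters)[n_tax < need]
  prov <- cs$provenance
  if (length(dropped))
    prov <- c(prov, list(list(action = "occupancy_dropped", threshold = need,
                              clusters = dropped)))
  structure(list(clusters = cs$clusters[n_tax >= need], provenance = prov),
            class = "cluster_set")
}

#' Full homolog-clustering pipeline
#'
#' Runs hit filtering, single-linkage clustering, stringent re-clustering of
#' multi-copy clusters, annotation-driven merging of split genes,
#' inverted-repeat duplicate resolution, and the taxon-occupancy filter.
#'
#' @param seq_tab data.frame with columns `seq_id`, `taxon_id`, `seq` (as from
#'   [read_sequences()] or the simulator).
#' @param hits hits data.frame.
#' @param max_evalue,min_cov hit-filter thresholds.
#' @param min_occupancy minimum taxon fraction per retained cluster.
#' @param annotations optional named seq_id -> gene label vector for merging.
#' @param schedule stringency schedule for re-clustering.
#' @param n_taxa total taxon count (default: distinct taxa in `seq_tab`).
#' @return a `cluster_set`; each entry of `provenance` logs one action.
#' @export
cluster_homologs <- function(seq_tab, hits, max_evalue = 1e-5, min_cov = 0.40,
                             min_occupancy = 0.5, annotations = NULL,
                             schedule = stringency_schedule(max_evalue),
                             n_taxa = length(unique(seq_tab$taxon_id))) {
  taxon_of <- stats::setNames(seq_tab$taxon_id, seq_tab$seq_id)
  seqs <- stats::setNames(seq_tab$seq, seq_tab$seq_id)
  edges <- filter_hits(hits, max_evalue, min_cov)
  cs <- cluster_single_linkage(seq_tab$seq_id, edges)

  refined <- list(); prov <- cs$provenance
  for (m in cs$clusters) {
    r <- refine_multicopy(m, hits, taxon_of, seqs = seqs,
                          schedule = schedule, min_cov = min_cov)
    refined <- c(refined, r$clusters)
    prov <- c(prov, r$log)
  }
  names(refined) <- sprintf("c%03d", seq_along(refined))
  cs <- structure(list(clusters = refined, provenance = prov),
                  class = "cluster_set")

  cs <- merge_split_gene(cs, annotations, taxon_of)

  clusters <- list(); prov <- cs$provenance
  for (id in names(cs$clusters)) {
    r <- resolve_ir_duplicates(cs$clusters[[id]], seqs, taxon_of)
    clusters[[id]] <- r$members
    prov <- c(prov, r$log)
  }
  clusters <- clusters[lengths(clusters) > 0L]
  cs <- structure(list(clusters = clusters, provenance = prov),
                  class = "cluster_set")

  occupancy_filter(cs, n_taxa, taxon_of, min_frac = min_occupancy)
}

#' Cluster membership as a table
#' @param cs a `cluster_set`.
#' @param taxon_of optional named seq_id -> taxon_id map to add a taxon column.
#' @return data.frame with columns `cluster_id`, `seq_id` (and `taxon_id`).
#' @export
cluster_table <- function(cs, taxon_of = NULL) {
  df <- data.frame(
    cluster_id = rep(names(cs$clusters), lengths(cs$clusters)),
    seq_id = unlist(cs$clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!is.null(taxon_of)) df$taxon_id <- unname(taxon_of[df$seq_id])
  df
}
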