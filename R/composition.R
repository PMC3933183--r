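#' Per-taxon base (or residue) composition of an alignment
#'
#' Counts only unambiguous states; gaps, `?` and partial ambiguity codes are
#' excluded. For codon-aware nucleotide matrices the census can be restricted
#' to a codon-position stratum. GC content is `(G + C) / (A + C + G + T)`.
#'
#' @param a an `aln`.
#' @param stratum `"all"`, `"pos1"`, `"pos2"`, `"pos3"` or `"no3rd"`
#'   (position strata need `codon_phase`).
#' @return object of class `composition_report`: list with `counts` (taxa x
#'   states matrix), `gc` (per-taxon GC fraction, nucleotide matrices only),
#'   `stratum`, `flagged` (taxa with no countable states, excluded from
#'   downstream tests).
#' @export
composition_table <- function(a, stratum = c("all", "pos1", "pos2", "pos3", "no3rd")) {
  stratum <- match.arg(stratum)
  states <- switch(a$alphabet,
                   nt = c("A", "C", "G", "T"),
                   ry = c("R", "Y"),
                   aa = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  mat <- a$mat
  if (stratum != "all") {
    if (is.null(a$codon_phase)) stopf("stratum '%s' needs codon_phase", stratum)
    keep <- switch(stratum,
                   pos1 = a$codon_phase == 1L, pos2 = a$codon_phase == 2L,
                   pos3 = a$codon_phase == 3L, no3rd = a$codon_phase != 3L)
    mat <- mat[, keep, drop = FALSE]
  }
  counts <- t(apply(mat, 1L, function(r) {
    tabulate(factor(r, levels = states), nbins = length(states))
  }))
  colnames(counts) <- states
  rownames(counts) <- rownames(mat)
  flagged <- rownames(counts)[rowSums(counts) == 0L]
  gc <- NULL
  if (a$alphabet == "nt") {
    tot <- rowSums(counts)
    gc <- ifelse(tot > 0, (counts[, "G"] + counts[, "C"]) / tot, NA_real_)
    names(gc) <- rownames(counts)
  }
  structure(list(counts = counts, gc = gc, stratum = stratum, flagged = flagged),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("<composition_report> %d taxa x %d states, stratum=%s\n",
              nrow(x$counts), ncol(x$counts), x$stratum))
  if (!is.null(x$gc)) cat(sprintf("  mean GC = %.3f\n", mean(x$gc, na.rm = TRUE)))
  invisible(x)
}

#' Chi-square test of composition homogeneity among taxa
#'
#' Pearson chi-square on the taxa x states count table against expected
#' counts `E_ij = row_i * col_j / N`, with `df = (T - 1)(S - 1)` and the
#' p-value from the upper tail of the chi-square distribution (no continuity
#' correction). Taxa flagged as empty are excluded.
#'
#' @param report a `composition_report`, or a plain counts matrix.
#' @return list of class `chisq_result` with `statistic`, `df`, `p`.
#' @export
chisq_homogeneity <- function(report) {
  counts <- if (inherits(report, "composition_report")) {
    keep <- setdiff(rownames(report$counts), report$flagged)
    report$counts[keep, , drop = FALSE]
  } else as.matrix(report)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stopf("need at least 2 taxa and 2 states")
  zr <- which(rowSums(counts) == 0)
  if (length(zr)) stopf("zero count total for taxon '%s'", rownames(counts)[zr[1]])
  zc <- which(colSums(counts) == 0)
  if (length(zc)) stopf("zero count total for state '%s'", colnames(counts)[zc[1]])
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p = unname(res$p.value)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.6f, df = %d, p = %.4g\n", x$statistic, x$df, x$p))
  invisible(x)
}

#' Fractions of amino acids from GC-rich and AT-rich codon classes
#'
#' The GC-rich class is \{G, A, R, P\} (glycine, alanine, arginine, proline:
#' residues whose codons are GC-rich); the AT-rich class is
#' \{F, Y, M, I, N, K\}. Fractions are over counted residues; `X` and gaps are
#' excluded; empty rows are flagged with `NA`.
#'
#' @param aa_aln an amino-acid `aln`.
#' @return data.frame with columns `taxon`, `gc_rich_frac`, `at_rich_frac`.
#' @export
aa_class_fractions <- function(aa_aln) {
  if (aa_aln$alphabet != "aa") stopf("need an amino-acid matrix")
  rep <- composition_table(aa_aln)
  tot <- rowSums(rep$counts)
  gc_rich <- rowSums(rep$counts[, c("G", "A", "R", "P"), drop = FALSE])
  at_rich <- rowSums(rep$counts[, c("F", "Y", "M", "I", "N", "K"), drop = FALSE])
  data.frame(taxon = rownames(rep$counts),
             gc_rich_frac = ifelse(tot > 0, gc_rich / tot, NA_real_),
             at_rich_frac = ifelse(tot > 0, at_rich / tot, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ordinary least-squares fit with a slope test
#'
#' Simple linear regression `y ~ x` with a two-sided t-test on the slope, as
#' used for GC-content versus amino-acid-class regressions.
#'
#' @param x,y numeric vectors of equal length (at least 3 points, `x` not
#'   constant).
#' @return list with `slope`, `intercept`, `r_squared`, `p_slope`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3L) stopf("need at least 3 points")
  if (stats::sd(x) == 0) stopf("x is constant")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p_slope = s$coefficients[2, 4])
}
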