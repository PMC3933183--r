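#' Trim gappy alignment columns
#'
#' Keeps a column iff its gap fraction (`-` or `?`) is at most `max_gap_frac`.
#' A stand-in for heavier automated trimmers: it records the kept-column mask
#' so an externally produced mask can be substituted via the `mask` argument
#' of [backtranslate()].
#'
#' @param aa_aln an amino-acid `aln`.
#' @param max_gap_frac maximum tolerated gap fraction per column (default 0.5).
#' @return list with `alignment` (trimmed) and `mask` (kept column indices
#'   relative to the input).
#' @export
trim_columns <- function(aa_aln, max_gap_frac = 0.5) {
  if (max_gap_frac < 0 || max_gap_frac > 1) stopf("max_gap_frac must be in [0,1]")
  gap_frac <- colMeans(aa_aln$mat == "-" | aa_aln$mat == "?")
  mask <- which(gap_frac <= max_gap_frac)
  if (length(mask) == 0L) stopf("all columns removed; degenerate gene")
  list(alignment = aln_subset(aa_aln, cols = mask), mask = mask)
}

#' Back-translate an amino-acid alignment to codons
#'
#' Expands each kept amino-acid column of an (untrimmed) protein alignment to
#' the source codon from each taxon's coding sequence; amino-acid gaps become
#' `---`. The translation of each CDS must match the taxon's ungapped
#' alignment row exactly.
#'
#' @param aa_aln untrimmed amino-acid `aln`.
#' @param cds named character vector of ungapped coding sequences, one per
#'   alignment taxon.
#' @param mask kept-column indices (default: all columns), e.g. from
#'   [trim_columns()].
#' @param code genetic code passed to [translate_cds()].
#' @return codon-aware nucleotide `aln` with `codon_phase` set to 1,2,3
#'   repeating.
#' @export
backtranslate <- function(aa_aln, cds, mask = seq_len(aln_ncol(aa_aln)),
                          code = "plastid") {
  taxa <- aln_taxa(aa_aln)
  absent <- setdiff(taxa, names(cds))
  if (length(absent)) stopf("no CDS for taxon '%s'", absent[1])
  rows <- character(length(taxa))
  for (i in seq_along(taxa)) {
    t <- taxa[i]
    aa_row <- aa_aln$mat[t, ]
    prot <- translate_cds(cds[[t]], code = code)
    ungapped <- paste(aa_row[aa_row != "-"], collapse = "")
    if (ungapped != prot) {
      d <- which(strsplit(ungapped, "")[[1]] != strsplit(prot, "")[[1]])[1]
      stopf("CDS/alignment translation mismatch for taxon '%s' at residue %d",
            t, d %||% nchar(prot))
    }
    nt <- toupper(gsub("U", "T", cds[[t]], fixed = TRUE))
    codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
    res_idx <- cumsum(aa_row != "-")            # residue index per column
    col_codon <- ifelse(aa_row == "-", "---", codons[res_idx])
    rows[i] <- paste(col_codon[mask], collapse = "")
  }
  names(rows) <- taxa
  alignment(rows, "nt", codon_phase = rep_len(1:3, 3L * length(mask)))
}

#' A per-gene alignment pair (amino acid + codon nucleotide)
#'
#' Trims the protein alignment and back-translates it against the coding
#' sequences, keeping the trim mask.
#'
#' @param gene_id gene label.
#' @param aa_aln untrimmed amino-acid `aln`.
#' @param cds named ungapped CDS vector.
#' @param max_gap_frac trimming threshold.
#' @param code genetic code.
#' @return object of class `gene_alignment` with fields `gene_id`,
#'   `aa_alignment` (trimmed), `nt_alignment` (codon-aware), `trim_mask`.
#' @export
gene_alignment <- function(gene_id, aa_aln, cds, max_gap_frac = 0.5,
                           code = "plastid") {
  tr <- trim_columns(aa_aln, max_gap_frac)
  nt <- backtranslate(aa_aln, cds, mask = tr$mask, code = code)
  stopifnot(aln_ncol(nt) == 3L * aln_ncol(tr$alignment))
  structure(list(gene_id = gene_id, aa_alignment = tr$alignment,
                 nt_alignment = nt, trim_mask = tr$mask),
            class = "gene_alignment")
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are placed in lexical order of `gene_id`; taxa missing from a gene
#' get an all-gap block. Gene partition ranges are recorded 1-based inclusive
#' and the codon phases (when present) are concatenated.
#'
#' @param genes named list of `aln` objects (names = gene ids), or a list of
#'   `gene_alignment` objects whose `nt_alignment` is used.
#' @param taxa row order of the supermatrix; defaults to the sorted union of
#'   per-gene taxa.
#' @return list with `alignment` (the supermatrix `aln`) and `scheme`
#'   (a by-gene `partition_scheme`).
#' @export
concatenate <- function(genes, taxa = NULL) {
  if (length(genes) == 0L) stopf("no genes to concatenate")
  if (inherits(genes[[1]], "gene_alignment")) {
    names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
    genes <- lapply(genes, `[[`, "nt_alignment")
  }
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    stopf("genes must be uniquely named")
  genes <- genes[order(names(genes))]
  alphabet <- unique(vapply(genes, `[[`, character(1), "alphabet"))
  if (length(alphabet) != 1L) stopf("mixed alphabets across genes")
  for (g in names(genes))
    if (anyDuplicated(aln_taxa(genes[[g]])))
      stopf("duplicate taxon in gene '%s'", g)
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(genes, aln_taxa))))

  widths <- vapply(genes, aln_ncol, integer(1))
  total <- sum(widths)
  mat <- matrix("-", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  phases <- integer(0)
  parts <- list()
  at <- 0L
  for (g in names(genes)) {
    a <- genes[[g]]
    cols <- at + seq_len(aln_ncol(a))
    present <- intersect(taxa, aln_taxa(a))
    mat[present, cols] <- a$mat[present, , drop = FALSE]
    phases <- c(phases, a$codon_phase %||% rep(NA_integer_, aln_ncol(a)))
    parts[[g]] <- cols
    at <- at + aln_ncol(a)
  }
  phase <- if (anyNA(phases)) NULL else phases
  fam <- switch(alphabet, nt = "GTR+G", ry = "BIN+G", aa = "AA+G")
  list(alignment = alignment(mat, alphabet, codon_phase = phase),
       scheme = partition_scheme("gene", parts, model_family = fam,
                                 n_col = total))
}

#' Remove taxa from a supermatrix
#'
#' Rows are dropped; columns are left untouched (no re-trimming), matching the
#' taxon-removal sensitivity analyses this supports.
#'
#' @param a an `aln`.
#' @param taxa taxa to remove.
#' @return the reduced `aln`.
#' @export
remove_taxa <- function(a, taxa) {
  unknown <- setdiff(taxa, aln_taxa(a))
  if (length(unknown)) stopf("unknown taxon: %s", unknown[1])
  keep <- setdiff(aln_taxa(a), taxa)
  if (length(keep) == 0L) stopf("removal would empty the matrix")
  aln_subset(a, taxa = keep)
}

#' Missing-data census of an alignment
#'
#' Fraction of cells that are gaps (`-`), `?`, or (for nucleotide data)
#' ambiguity codes outside `A`, `C`, `G`, `T`.
#' @param a an `aln`.
#' @return fraction in `[0,1]`.
#' @export
missingness <- function(a) {
  ok <- switch(a$alphabet,
               nt = c("A", "C", "G", "T"),
               ry = c("R", "Y"),
               aa = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  mean(!(a$mat %in% ok))
}
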