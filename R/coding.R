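#' Extract codon positions from a codon-aware matrix
#'
#' Keeps columns whose codon phase is in `phases`, in their original order,
#' and remaps a partition scheme's column ranges onto the reduced coordinate
#' system.
#'
#' @param a codon-aware nucleotide `aln` (must carry `codon_phase`).
#' @param phases non-empty subset of `1:3` (e.g. `c(1, 2)` for a no-3rd
#'   matrix, `3` for third positions only).
#' @param scheme optional `partition_scheme` to remap.
#' @return list with `alignment` and (if given) remapped `scheme`.
#' @export
extract_positions <- function(a, phases, scheme = NULL) {
  if (is.null(a$codon_phase)) stopf("matrix has no codon_phase metadata")
  phases <- as.integer(phases)
  if (length(phases) == 0L || !all(phases %in% 1:3))
    stopf("phases must be a non-empty subset of 1:3")
  keep <- which(a$codon_phase %in% phases)
  new_pos <- integer(aln_ncol(a))
  new_pos[keep] <- seq_along(keep)
  out <- aln_subset(a, cols = keep)
  if (setequal(phases, 1:3)) out$codon_phase <- a$codon_phase
  else out$codon_phase <- a$codon_phase[keep]
  res <- list(alignment = out)
  if (!is.null(scheme)) {
    parts <- lapply(scheme$partitions, function(cols) {
      m <- new_pos[intersect(cols, keep)]
      sort(m[m > 0L])
    })
    keep_parts <- lengths(parts) > 0L
    res$scheme <- partition_scheme(scheme$name, parts[keep_parts],
                                   model_family = scheme$model_family[keep_parts],
                                   n_col = length(keep))
  }
  res
}

#' RY-recode a nucleotide matrix
#'
#' Purines (`A`, `G`, `R`) become `R`; pyrimidines (`C`, `T`, `Y`) become
#' `Y`; gaps are preserved; every other ambiguity code becomes `?` since it is
#' not resolvable to a single purine/pyrimidine class. Idempotent.
#'
#' @param a a nucleotide (or already RY) `aln`.
#' @return an `aln` with alphabet `"ry"`; codon phase is carried over.
#' @export
ry_recode <- function(a) {
  if (!a$alphabet %in% c("nt", "ry")) stopf("RY recoding needs a nucleotide matrix")
  mat <- a$mat
  out <- matrix("?", nrow = nrow(mat), ncol = ncol(mat), dimnames = dimnames(mat))
  out[mat %in% c("A", "G", "R")] <- "R"
  out[mat %in% c("C", "T", "Y")] <- "Y"
  out[mat == "-"] <- "-"
  alignment(out, "ry", codon_phase = a$codon_phase)
}

#' Translate a codon supermatrix to amino acids
#'
#' Each complete codon column triple becomes one amino-acid column. Per row,
#' a codon must be either all-gap (giving `-`) or gap-free; any ambiguity in a
#' gap-free codon gives `X`, and an internal stop is an error naming the row
#' and codon.
#'
#' @param a codon-aware nucleotide `aln` with complete triplets.
#' @param code genetic code (see [translate_cds()]).
#' @return amino-acid `aln` with `ncol(a)/3` columns.
#' @export
translate_matrix <- function(a, code = "plastid") {
  if (is.null(a$codon_phase)) stopf("matrix has no codon_phase metadata")
  n <- aln_ncol(a)
  if (n %% 3L != 0L || !all(a$codon_phase == rep_len(1:3, n)))
    stopf("matrix is not made of complete in-frame codons")
  tab <- Biostrings::getGeneticCode(if (code == "plastid") "11" else "1")
  taxa <- aln_taxa(a)
  strings <- aln_strings(a)
  starts <- seq(1L, n, 3L)
  rows <- vapply(taxa, function(t) {
    codons <- substring(strings[[t]], starts, starts + 2L)
    gaps <- vapply(gregexpr("-", codons, fixed = TRUE),
                   function(g) if (g[1] == -1L) 0L else length(g), integer(1))
    mixed <- which(gaps %in% 1:2)
    if (length(mixed))
      stopf("mixed gap codon '%s' for taxon '%s' at codon %d",
            codons[mixed[1]], t, mixed[1])
    aa <- unname(tab[codons])
    aa[gaps == 3L] <- "-"
    aa[is.na(aa)] <- "X"
    stops <- which(aa == "*")
    if (length(stops))
      stopf("internal stop codon for taxon '%s' at codon %d", t, stops[1])
    paste(aa, collapse = "")
  }, character(1))
  alignment(rows, "aa")
}

#' Derive a named character-coding variant of a codon supermatrix
#'
#' Convenience front-end producing the five standard codings: all nucleotide
#' positions (`ntAll`), first and second positions (`ntNo3rd`), third
#' positions (`nt3rdOnly`), RY binary recoding of all positions (`RY`), and
#' amino acids (`AA`).
#'
#' @param a codon-aware nucleotide `aln`.
#' @param coding one of `"ntAll"`, `"ntNo3rd"`, `"nt3rdOnly"`, `"RY"`, `"AA"`.
#' @param scheme optional by-gene `partition_scheme` to remap alongside.
#' @param code genetic code for the AA coding.
#' @return list with `alignment` and `scheme` (remapped, or the input scheme
#'   with the model family adjusted; for `AA` partition coordinates are the
#'   nucleotide ranges divided by 3).
#' @export
recode_matrix <- function(a, coding = c("ntAll", "ntNo3rd", "nt3rdOnly", "RY", "AA"),
                          scheme = NULL, code = "plastid") {
  coding <- match.arg(coding)
  switch(coding,
    ntAll = list(alignment = a, scheme = scheme),
    ntNo3rd = extract_positions(a, c(1L, 2L), scheme),
    nt3rdOnly = extract_positions(a, 3L, scheme),
    RY = {
      s <- scheme
      if (!is.null(s)) s <- partition_scheme(s$name, s$partitions, "BIN+G")
      list(alignment = ry_recode(a), scheme = s)
    },
    AA = {
      s <- NULL
      if (!is.null(scheme)) {
        parts <- lapply(scheme$partitions, function(cols) {
          unique((sort(cols) + 2L) %/% 3L)
        })
        s <- partition_scheme(scheme$name, parts, "AA+G",
                              n_col = aln_ncol(a) %/% 3L)
      }
      list(alignment = translate_matrix(a, code = code), scheme = s)
    })
}
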