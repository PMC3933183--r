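#' Character-matrix alignments
#'
#' An `aln` object is a character matrix (rows = taxa, columns = sites) with
#' an alphabet tag (`"nt"`, `"aa"` or `"ry"`) and, for codon-aware nucleotide
#' matrices, a per-column codon phase in `{1, 2, 3}`. All column coordinates
#' in this package are 1-based and inclusive, matching RAxML partition files.
#'
#' @param x named character vector of equal-length sequence strings, or a
#'   character matrix of single characters with taxa as rownames.
#' @param alphabet one of `"nt"`, `"aa"`, `"ry"`.
#' @param codon_phase optional integer vector (values in 1:3), one per column.
#' @return an object of class `aln`.
#' @examples
#' a <- alignment(c(A = "ATGGCT", B = "ATGGCA"), "nt", codon_phase = rep(1:3, 2))
#' aln_ncol(a)
#' @export
alignment <- function(x, alphabet = c("nt", "aa", "ry"), codon_phase = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.matrix(x)) {
    mat <- x
  } else {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stopf("sequences must have unique names")
    n <- nchar(x)
    if (length(unique(n)) != 1L)
      stopf("all rows must have the same length (got %s)",
            paste(unique(n), collapse = ", "))
    mat <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(mat) <- names(x)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stopf("alignment taxa must be unique and named")
  mat[] <- toupper(mat)
  if (alphabet == "nt") mat[mat == "U"] <- "T"
  if (!is.null(codon_phase)) {
    codon_phase <- as.integer(codon_phase)
    if (length(codon_phase) != ncol(mat))
      stopf("codon_phase length (%d) != column count (%d)",
            length(codon_phase), ncol(mat))
    if (!all(codon_phase %in% 1:3)) stopf("codon_phase values must be in 1:3")
  }
  structure(list(mat = mat, alphabet = alphabet, codon_phase = codon_phase),
            class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("<aln> %d taxa x %d columns, alphabet=%s%s\n",
              nrow(x$mat), ncol(x$mat), x$alphabet,
              if (!is.null(x$codon_phase)) ", codon-aware" else ""))
  invisible(x)
}

#' @rdname alignment
#' @param a an `aln` object.
#' @export
aln_taxa <- function(a) rownames(a$mat)

#' @rdname alignment
#' @export
aln_ncol <- function(a) ncol(a$mat)

#' @rdname alignment
#' @export
aln_ntaxa <- function(a) nrow(a$mat)

#' Alignment rows as strings
#' @param a an `aln` object.
#' @return named character vector of sequence strings.
#' @export
aln_strings <- function(a) {
  s <- apply(a$mat, 1L, paste, collapse = "")
  names(s) <- rownames(a$mat)
  s
}

#' Subset alignment columns (optionally rows), preserving codon phase
#' @param a an `aln` object.
#' @param cols integer column indices (1-based).
#' @param taxa optional taxa to keep.
#' @export
aln_subset <- function(a, cols = NULL, taxa = NULL) {
  mat <- a$mat
  phase <- a$codon_phase
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(mat))
    if (length(missing)) stopf("unknown taxa: %s", paste(missing, collapse = ", "))
    mat <- mat[taxa, , drop = FALSE]
  }
  if (!is.null(cols)) {
    if (any(cols < 1L | cols > ncol(mat))) stopf("column index out of range")
    mat <- mat[, cols, drop = FALSE]
    if (!is.null(phase)) phase <- phase[cols]
  }
  alignment(mat, a$alphabet, codon_phase = phase)
}

#' Partition schemes over alignment columns
#'
#' A partition scheme names disjoint column sets that jointly cover an
#' alignment; each partition carries a model family (`"GTR+G"`, `"BIN+G"`,
#' `"AA+G"`). Branch lengths are shared across partitions when the scheme is
#' scored with the likelihood engine.
#'
#' @param name scheme name.
#' @param partitions named list of integer column-index vectors.
#' @param model_family model family for every partition (recycled), or a
#'   character vector, one per partition.
#' @param n_col total column count of the target alignment (used to check
#'   coverage); if `NULL`, coverage is not checked.
#' @return object of class `partition_scheme`.
#' @export
partition_scheme <- function(name, partitions, model_family = "GTR+G",
                             n_col = NULL) {
  if (length(partitions) < 1L) stopf("scheme needs at least one partition")
  if (is.null(names(partitions)) || anyDuplicated(names(partitions)))
    stopf("partitions must have unique labels")
  model_family <- rep_len(model_family, length(partitions))
  if (!all(model_family %in% c("GTR+G", "BIN+G", "AA+G")))
    stopf("unknown model family")
  cols <- unlist(partitions, use.names = FALSE)
  if (anyDuplicated(cols)) stopf("partitions must be disjoint")
  if (!is.null(n_col) && !setequal(cols, seq_len(n_col)))
    stopf("partitions must cover all %d columns", n_col)
  structure(list(name = name,
                 partitions = lapply(partitions, function(x) sort(as.integer(x))),
                 model_family = model_family),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("<partition_scheme> '%s': %d partition(s), %d columns\n",
              x$name, length(x$partitions),
              length(unlist(x$partitions, use.names = FALSE))))
  invisible(x)
}

#' @rdname partition_scheme
#' @param scheme a `partition_scheme`.
#' @export
n_partitions <- function(scheme) length(scheme$partitions)

# ---- file formats -----------------------------------------------------------

#' Read and write relaxed PHYLIP matrices
#'
#' Relaxed PHYLIP: a header line `ntaxa ncols`, then one `name sequence` line
#' per taxon (names of any length, no 10-character truncation).
#'
#' @param a an `aln` object.
#' @param path file path.
#' @param alphabet alphabet tag to attach on read.
#' @export
write_phylip <- function(a, path) {
  s <- aln_strings(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(s), aln_ncol(a)), con)
  writeLines(paste(names(s), s), con)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path, alphabet = c("nt", "aa", "ry")) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hd <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hd) != 2L || anyNA(hd)) stopf("malformed PHYLIP header: '%s'", lines[1])
  body <- lines[-1]
  if (length(body) != hd[1]) stopf("expected %d sequence lines, found %d", hd[1], length(body))
  parts <- strsplit(trimws(body), "\\s+")
  nm <- vapply(parts, `[`, character(1), 1L)
  sq <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  if (any(nchar(sq) != hd[2]))
    stopf("sequence length disagrees with header (%d columns)", hd[2])
  names(sq) <- nm
  alignment(sq, alphabet)
}

#' Write / read RAxML-dialect partition files
#'
#' Lines have the form `DNA, label = 1-6` or, for codon partitions,
#' `DNA, label = 1-6\3`. The leading keyword encodes the model family:
#' `DNA` for GTR+G, `BIN` for binary+G, `WAG` for the empirical amino-acid
#' model.
#'
#' @param scheme a `partition_scheme`.
#' @param path file path.
#' @export
write_partition_file <- function(scheme, path) {
  key <- c("GTR+G" = "DNA", "BIN+G" = "BIN", "AA+G" = "WAG")
  lines <- mapply(function(label, cols, fam) {
    sprintf("%s, %s = %s", key[[fam]], label, cols_to_rangespec(cols))
  }, names(scheme$partitions), scheme$partitions, scheme$model_family)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_partition_file
#' @param name scheme name to attach on read.
#' @export
read_partition_file <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fam_of <- function(key) {
    key <- toupper(key)
    if (key == "DNA") "GTR+G" else if (key == "BIN") "BIN+G" else "AA+G"
  }
  parts <- list(); fams <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9+]+)\\s*,\\s*(\\S+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 4L) stopf("malformed partition line: '%s'", ln)
    parts[[m[3]]] <- rangespec_to_cols(m[4])
    fams <- c(fams, fam_of(m[2]))
  }
  partition_scheme(name, parts, model_family = fams)
}

#' Write a supermatrix with its partition bookkeeping
#'
#' Writes three files under `dir`: `<prefix>.phy` (relaxed PHYLIP),
#' `<prefix>.partitions.txt` (RAxML partition dialect) and `<prefix>.fasta`.
#' The PHYLIP copy round-trips losslessly through [read_supermatrix()].
#'
#' @param a an `aln` object.
#' @param scheme a `partition_scheme` over `a`'s columns.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_supermatrix <- function(a, scheme, dir, prefix = "supermatrix") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".phy", ".partitions.txt", ".fasta")))
  write_phylip(a, paths[1])
  write_partition_file(scheme, paths[2])
  write_fasta(aln_strings(a), paths[3])
  invisible(paths)
}

#' @rdname write_supermatrix
#' @param phy_path path to the PHYLIP file.
#' @param part_path path to the partition file (optional).
#' @param alphabet alphabet tag.
#' @export
read_supermatrix <- function(phy_path, part_path = NULL,
                             alphabet = c("nt", "aa", "ry")) {
  a <- read_phylip(phy_path, alphabet)
  scheme <- if (!is.null(part_path)) read_partition_file(part_path) else NULL
  list(alignment = a, scheme = scheme)
}
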