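#' Read taxon- and gene-labelled sequences from FASTA
#'
#' Headers follow the convention `taxon|gene` (separator configurable); the
#' gene field may be absent before clustering. Sequences are uppercased on
#' read and, for nucleotide data, `U` is mapped to `T`.
#'
#' @param path FASTA file.
#' @param alphabet `"nt"` or `"aa"`.
#' @param sep header separator between taxon and gene ids.
#' @return a data.frame with columns `seq_id`, `taxon_id`, `gene_id`
#'   (`NA` when the header has no gene field), `seq`, `alphabet`.
#' @export
read_sequences <- function(path, alphabet = c("nt", "aa"), sep = "|") {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("malformed FASTA '%s': %s",
                                            path, conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (alphabet == "nt") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  fields <- strsplit(ids, sep, fixed = TRUE)
  taxon <- vapply(fields, `[`, character(1), 1L)
  gene <- vapply(fields, function(f) if (length(f) >= 2L) f[2] else NA_character_,
                 character(1))
  if (any(grepl("\\s", taxon))) stopf("taxon ids must not contain whitespace")
  if (any(!nzchar(seqs))) stopf("empty sequence for '%s'", ids[!nzchar(seqs)][1])
  key <- paste(taxon, gene, sep = "\r")
  if (anyDuplicated(key[!is.na(gene)]) || anyDuplicated(ids))
    stopf("duplicate (taxon, gene) identifier in %s", path)
  data.frame(seq_id = ids, taxon_id = taxon, gene_id = gene, seq = seqs,
             alphabet = alphabet, stringsAsFactors = FALSE)
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width (0 = single line).
#' @export
write_fasta <- function(seqs, path, width = 0L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (width > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}

#' Parse a 12-column tabular similarity-hit file
#'
#' Expects the standard 12-column tabular dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). Coverages are derived as aligned-region length over
#' full sequence length; minus-orientation rows (end < start) use
#' `|end - start| + 1`.
#'
#' @param path TSV file of hits.
#' @param seq_lengths named integer vector of full sequence lengths, used to
#'   derive query/target coverage.
#' @return data.frame of hits with columns `query_id`, `target_id`, `evalue`,
#'   `bitscore`, `query_cov`, `target_cov`.
#' @export
parse_hit_table <- function(path, seq_lengths) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", rep(NA, 10)))
  if (ncol(tab) != 12L) stopf("expected 12 tab-separated columns, found %d", ncol(tab))
  names(tab) <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  ev <- suppressWarnings(as.numeric(tab$evalue))
  if (anyNA(ev)) stopf("non-numeric e-value at row %d", which(is.na(ev))[1])
  if (any(ev < 0)) stopf("negative e-value at row %d", which(ev < 0)[1])
  unknown <- setdiff(unique(c(tab$qseqid, tab$sseqid)), names(seq_lengths))
  if (length(unknown))
    stopf("unknown sequence id(s) when deriving coverage: %s",
          paste(utils::head(unknown, 3), collapse = ", "))
  span <- function(a, b) abs(b - a) + 1L
  hits <- data.frame(
    query_id = tab$qseqid, target_id = tab$sseqid,
    evalue = ev, bitscore = as.numeric(tab$bitscore),
    query_cov = span(tab$qstart, tab$qend) / seq_lengths[tab$qseqid],
    target_cov = span(tab$sstart, tab$send) / seq_lengths[tab$sseqid],
    stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  if (any(hits$query_cov > 1 | hits$target_cov > 1))
    stopf("derived coverage exceeds 1; check sequence lengths")
  hits
}

#' Write hits in the 12-column tabular dialect
#' @param hits data.frame as returned by [parse_hit_table()].
#' @param seq_lengths named integer vector of sequence lengths.
#' @param path output path.
#' @export
write_hit_table <- function(hits, seq_lengths, path) {
  qlen <- seq_lengths[hits$query_id]
  slen <- seq_lengths[hits$target_id]
  qspan <- pmax(1L, round(hits$query_cov * qlen))
  sspan <- pmax(1L, round(hits$target_cov * slen))
  tab <- data.frame(hits$query_id, hits$target_id, 90.0, qspan, 0L, 0L,
                    1L, qspan, 1L, sspan,
                    format(hits$evalue, scientific = TRUE, digits = 3),
                    hits$bitscore)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Translate a coding sequence
#'
#' Uses the bacterial/plastid genetic code (translation table 11) by default,
#' the standard code on request. A terminal stop codon is stripped; ambiguous
#' codons translate to `X`; an internal stop is an error naming the codon.
#'
#' @param cds ungapped nucleotide string, length divisible by 3.
#' @param code `"plastid"` (table 11, default) or `"standard"`.
#' @return amino-acid string.
#' @examples
#' translate_cds("ATGGCT")  # "MA"
#' @export
translate_cds <- function(cds, code = c("plastid", "standard")) {
  code <- match.arg(code)
  tab <- Biostrings::getGeneticCode(if (code == "plastid") "11" else "1")
  cds <- toupper(gsub("U", "T", cds, fixed = TRUE))
  n <- nchar(cds)
  if (n %% 3L != 0L) stopf("CDS length %d is not divisible by 3", n)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  ncod <- length(aa)
  if (ncod > 0L && aa[ncod] == "*") aa <- aa[-ncod]
  internal <- which(aa == "*")
  if (length(internal))
    stopf("internal stop codon at codon %d", internal[1])
  paste(aa, collapse = "")
}
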