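# internal helpers

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Compress integer column indices into a range specification
#'
#' Produces the compact interval notation used by RAxML-style partition files:
#' consecutive runs become `a-b`, arithmetic runs with step 3 become `a-b\3`.
#' @noRd
cols_to_rangespec <- function(cols) {
  cols <- sort(unique(as.integer(cols)))
  if (length(cols) == 0L) stopf("empty column set")
  # whole set one stride-3 progression?
  if (length(cols) >= 2L && all(diff(cols) == 3L))
    return(sprintf("%d-%d\\3", cols[1], cols[length(cols)]))
  runs <- split(cols, cumsum(c(1L, diff(cols) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r) else sprintf("%d-%d", r[1], r[length(r)])
  }, character(1)), collapse = ", ")
}

#' Expand a range specification back to integer columns
#' @noRd
rangespec_to_cols <- function(spec) {
  parts <- strsplit(spec, ",")[[1]]
  out <- integer(0)
  for (p in trimws(parts)) {
    if (grepl("\\\\3$", p)) {
      ab <- as.integer(strsplit(sub("\\\\3$", "", p), "-")[[1]])
      out <- c(out, seq(ab[1], ab[2], by = 3L))
    } else if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else out <- c(out, as.integer(p))
  }
  out
}
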