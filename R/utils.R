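#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_chr map_dbl map_int map_lgl pmap imap list_rbind
#' @importFrom tidyr unnest nest pivot_longer pivot_wider
#' @importFrom stats cor cor.test p.adjust phyper wilcox.test t.test chisq.test
#'   binom.test sd quantile setNames rbinom runif rnorm complete.cases
#' @importFrom utils head tail
#' @useDynLib linctools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds from one parent seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

#' Normalize a nucleotide string
#'
#' Uppercases and maps U to T so the package works over a single internal
#' DNA-style alphabet \{A, C, G, T, N\}. Any other IUPAC ambiguity code is an
#' error: downstream shuffling and folding are defined over the four bases
#' (plus N runs, which are preserved in place).
#'
#' @param sequence Character vector of nucleotide strings.
#' @param allow_n Should N be accepted? Default TRUE.
#' @return Character vector of normalized sequences.
#' @export
normalize_sequence <- function(sequence, allow_n = TRUE) {
  out <- chartr("u", "U", toupper(sequence))
  out <- chartr("U", "T", out)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, out)
  if (any(bad)) {
    offender <- regmatches(out[bad][1], regexpr(pat, out[bad][1]))
    abort(sprintf(
      "sequence contains unsupported character '%s'; only A, C, G, T/U%s are allowed",
      offender, if (allow_n) ", N" else ""))
  }
  out
}

# T -> U for presentation/folding-facing output.
to_rna <- function(sequence) chartr("T", "U", toupper(sequence))

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be in [0, 1], got %s", name, paste(x, collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}
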