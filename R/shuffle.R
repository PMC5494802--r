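# Dinucleotide-preserving sequence shuffling (Altschul-Erikson).
#
# The null model for every stability statistic in this package is a set of
# random permutations of the native sequence that leave its dinucleotide
# (adjacent-pair) composition exactly intact. Such permutations correspond to
# Eulerian paths on the dinucleotide transition multigraph; sampling one
# uniformly requires first drawing a uniform random "last-edge" arborescence
# into the terminal vertex and then randomizing the order of the remaining
# out-edges (naive edge shuffling without the arborescence step is biased).

#' Dinucleotide counts of a sequence
#'
#' Returns the 16-entry vector of adjacent-pair counts, in fixed AA..TT order.
#' Pairs touching an N are dropped (N splits the sequence into independent
#' segments for shuffling purposes).
#'
#' @param sequence A single nucleotide string over A/C/G/T/N (U accepted).
#' @return Named integer vector of length 16.
#' @export
dinucleotide_counts <- function(sequence) {
  sequence <- normalize_sequence(sequence)
  bases <- c("A", "C", "G", "T")
  lev <- paste0(rep(bases, each = 4), bases) # lexicographic AA, AC, ..., TT
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 2L) return(setNames(integer(16), lev))
  di <- paste0(ch[-n], ch[-1L])
  di <- di[!grepl("N", di, fixed = TRUE)]
  table(factor(di, levels = lev)) |> c() |> setNames(lev)
}

# Core Altschul-Erikson shuffle on a character vector over {A,C,G,T}.
# Preserves the full dinucleotide count multiset plus first and last base;
# draws uniformly over all sequences with those invariants.
ae_shuffle_chars <- function(ch) {
  n <- length(ch)
  if (n <= 2L) return(ch)
  verts <- unique(ch)
  if (length(verts) == 1L) return(ch)
  first <- ch[1L]
  last <- ch[n]
  edges <- split(ch[-1L], factor(ch[-n], levels = verts))

  # Sample a uniform last-edge arborescence into `last` by rejection.
  repeat {
    last_edge <- vapply(verts, function(v) {
      e <- edges[[v]]
      if (v == last || length(e) == 0L) NA_character_
      else e[[sample.int(length(e), 1L)]]
    }, character(1))
    names(last_edge) <- verts
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      cur <- v
      for (step in seq_along(verts)) {
        cur <- last_edge[[cur]]
        if (identical(cur, last)) break
      }
      if (!identical(cur, last)) { ok <- FALSE; break }
    }
    if (ok) break
  }

  # Randomize remaining out-edge order; the chosen last edge stays last.
  out <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (length(e) == 0L) return(character(0))
    if (v == last) return(e[sample.int(length(e))])
    i <- match(last_edge[[v]], e)
    rest <- e[-i]
    if (length(rest)) rest <- rest[sample.int(length(rest))]
    c(rest, last_edge[[v]])
  })
  names(out) <- verts

  # Walk the Eulerian path.
  ptr <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1L] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- out[[cur]][[ptr[[cur]]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  res
}

#' Dinucleotide-preserving shuffle of one sequence
#'
#' Uniformly samples a permutation of `sequence` with identical dinucleotide
#' counts, identical length, and identical first and last base
#' (Altschul-Erikson Eulerian-path construction). Runs of N are kept in
#' place and the N-free segments between them are shuffled independently.
#'
#' @param sequence Single nucleotide string, length >= 2, over A/C/G/T/N
#'   (U is accepted and mapped to T internally).
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @return Shuffled sequence as a single string (DNA alphabet).
#' @seealso [shuffle_controls()] for batches, [mononucleotide_shuffle()].
#' @export
#' @examples
#' dinucleotide_shuffle("ACGTACGTAC", seed = 1)
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) < 2L) abort("`sequence` must have length >= 2")
  with_seed(seed, {
    ch <- seq_chars(sequence)
    is_n <- ch == "N"
    if (!any(is_n)) return(paste(ae_shuffle_chars(ch), collapse = ""))
    r <- rle(is_n)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k]) next
      idx <- starts[k]:stops[k]
      if (length(idx) >= 3L) ch[idx] <- ae_shuffle_chars(ch[idx])
    }
    paste(ch, collapse = "")
  })
}

#' Mononucleotide shuffle of one sequence
#'
#' Uniform random permutation of the bases; preserves base counts exactly
#' (but not dinucleotide counts or endpoints).
#'
#' @inheritParams dinucleotide_shuffle
#' @return Shuffled sequence as a single string.
#' @export
mononucleotide_shuffle <- function(sequence, seed = NULL) {
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) < 2L) abort("`sequence` must have length >= 2")
  with_seed(seed, {
    ch <- seq_chars(sequence)
    paste(ch[sample.int(length(ch))], collapse = "")
  })
}

#' Generate a batch of shuffled control sequences
#'
#' Produces the shuffle-null control set used throughout the stability
#' analyses: by default 100 independent dinucleotide-preserving permutations
#' of the source sequence.
#'
#' @param sequence Source nucleotide string.
#' @param n Number of controls (>= 2); default 100.
#' @param method `"dinucleotide"` (default) or `"mononucleotide"`.
#' @param seed Optional integer seed making the whole batch reproducible.
#' @param source_id Optional id carried into the output.
#' @return A tibble with columns `source_id`, `control` (1..n), `sequence`,
#'   plus attributes `method` and `seed`.
#' @export
#' @examples
#' shuffle_controls("ACGTTGCAACGT", n = 5, seed = 42)
shuffle_controls <- function(sequence, n = 100, method = c("dinucleotide", "mononucleotide"),
                             seed = NULL, source_id = NA_character_) {
  method <- match.arg(method)
  n <- assert_count(n, "n", min = 2L)
  shuf <- switch(method,
    dinucleotide = dinucleotide_shuffle,
    mononucleotide = mononucleotide_shuffle
  )
  seqs <- with_seed(seed, vapply(seq_len(n), function(i) shuf(sequence), character(1)))
  out <- tibble(source_id = source_id, control = seq_len(n), sequence = seqs)
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  out
}
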