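# Independent brute-force oracles used across the test suite. These are
# deliberately naive (enumeration / direct summation) and share no code with
# the package implementations they check.

# All sequences sharing `seq`'s dinucleotide multiset, first and last base:
# depth-first walk over the dinucleotide edge multiset.
enumerate_dinuc_preserving <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 2) return(seq)
  # edge multiset as a 4x4-style count table keyed by "XY"
  edges <- table(paste0(ch[-n], ch[-1]))
  counts <- as.list(edges)
  out <- new.env(parent = emptyenv())
  out$seqs <- character(0)
  recurse <- function(cur, remaining, acc) {
    if (sum(unlist(remaining)) == 0) {
      out$seqs <- c(out$seqs, paste(acc, collapse = ""))
      return(invisible())
    }
    for (key in names(remaining)) {
      if (remaining[[key]] <= 0) next
      if (substr(key, 1, 1) != cur) next
      nxt <- substr(key, 2, 2)
      remaining[[key]] <- remaining[[key]] - 1
      recurse(nxt, remaining, c(acc, nxt))
      remaining[[key]] <- remaining[[key]] + 1
    }
  }
  recurse(ch[1], counts, ch[1])
  unique(out$seqs[substr(out$seqs, n, n) == ch[n]])
}

# All pseudoknot-free structures on 1..n as lists of pair matrices (k x 2),
# honoring min_loop, max_span and a pairability predicate.
enumerate_structures <- function(n, can_pair, min_loop = 3, max_span = Inf) {
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (j - i < min_loop + 1) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- list()
    # i unpaired
    for (s in gen(i + 1, j)) res[[length(res) + 1]] <- s
    # i paired with k
    for (k in seq(i + min_loop + 1, j)) {
      if (k - i > max_span) break
      if (!can_pair(i, k)) next
      inner <- gen(i + 1, k - 1)
      outer <- gen(k + 1, j)
      for (a in inner) for (b in outer) {
        res[[length(res) + 1]] <- rbind(matrix(c(i, k), ncol = 2), a, b)
      }
    }
    memo[[key]] <- res
    res
  }
  gen(1, n)
}

oracle_pairer <- function(seq, model) {
  ch <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  energy <- function(a, b) {
    key <- paste0(sort(c(a, b)), collapse = "")
    switch(key, "CG" = model$gc, "AU" = model$au, "GU" = model$gu, NA_real_)
  }
  list(
    can_pair = function(i, k) !is.na(energy(ch[i], ch[k])),
    struct_energy = function(pairs) {
      if (nrow(pairs) == 0) return(0)
      sum(vapply(seq_len(nrow(pairs)),
                 function(r) energy(ch[pairs[r, 1]], ch[pairs[r, 2]]),
                 numeric(1)))
    }
  )
}

# Exhaustive MFE for short sequences.
oracle_mfe <- function(seq, model = energy_model()) {
  n <- nchar(seq)
  p <- oracle_pairer(seq, model)
  structs <- enumerate_structures(n, p$can_pair, model$min_loop,
                                  if (is.infinite(model$max_span)) Inf else model$max_span)
  min(vapply(structs, p$struct_energy, numeric(1)))
}

# Exhaustive Boltzmann pair probabilities for short sequences.
oracle_pair_probs <- function(seq, model = energy_model()) {
  n <- nchar(seq)
  p <- oracle_pairer(seq, model)
  structs <- enumerate_structures(n, p$can_pair, model$min_loop,
                                  if (is.infinite(model$max_span)) Inf else model$max_span)
  w <- vapply(structs, function(s) exp(-p$struct_energy(s) / model$rt), numeric(1))
  P <- matrix(0, n, n)
  for (t in seq_along(structs)) {
    prs <- structs[[t]]
    if (nrow(prs)) for (r in seq_len(nrow(prs))) {
      P[prs[r, 1], prs[r, 2]] <- P[prs[r, 1], prs[r, 2]] + w[t]
    }
  }
  P <- P + t(P)
  P / sum(w)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A sequence guaranteed to fold: random background with a planted perfect
# inverted repeat (stem `stem` bp, loop `loop` nt) at a random position.
random_hairpin_seq <- function(n, stem = 20, loop = 5, gc = 0.5) {
  arm <- random_dna(stem, gc = 0.6)
  comp <- chartr("ACGT", "TGCA", arm)
  hp <- paste0(arm, random_dna(loop, gc), paste(rev(strsplit(comp, "")[[1]]), collapse = ""))
  rest <- n - nchar(hp)
  if (rest <= 0) return(hp)
  left <- sample.int(rest + 1, 1) - 1
  paste0(random_dna(left, gc), hp, random_dna(rest - left, gc))
}
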