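# RNA secondary-structure statistics: minimum free energy and ensemble
# base-pair probabilities over pseudoknot-free nested structures.
#
# The engine uses simple per-pair energies rather than a full nearest-
# neighbor parameter set: every statistic downstream is comparative (native
# sequence vs shuffled controls of identical composition), so ranking
# behavior is the contract, not absolute kcal/mol. An adapter to an external
# thermodynamic folder (ViennaRNA's RNAfold) is provided for users who want
# Turner energies.

#' Energy model for the built-in folding engine
#'
#' @param gc,au,gu Pair energies (abstract units, must be <= 0); defaults
#'   -3, -2, -1 reflect relative pair stabilities (G-C strongest).
#' @param min_loop Minimum hairpin loop length (unpaired bases enclosed by a
#'   pair), >= 3.
#' @param rt Boltzmann temperature scale RT in the same units (> 0).
#' @param max_span Optional maximum allowed pairing span |j - i|; `Inf`
#'   (default) means unconstrained. Emulates maximal-span-constrained
#'   stem-probability computation for long sequences.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(gc = -3, au = -2, gu = -1, min_loop = 3, rt = 0.6,
                         max_span = Inf) {
  if (any(c(gc, au, gu) > 0)) abort("pair energies must be <= 0")
  min_loop <- assert_count(min_loop, "min_loop", min = 3L)
  if (!is.numeric(rt) || rt <= 0) abort("`rt` must be > 0")
  if (!(is.numeric(max_span) && length(max_span) == 1L && max_span >= 1)) {
    abort("`max_span` must be a single value >= 1 (or Inf)")
  }
  structure(list(gc = gc, au = au, gu = gu, min_loop = min_loop, rt = rt,
                 max_span = max_span), class = "energy_model")
}

model_span <- function(model, n) {
  if (is.infinite(model$max_span)) 0L else as.integer(min(model$max_span, n))
}

#' Minimum free energy fold
#'
#' Computes the minimum total pair energy over all pseudoknot-free nested
#' structures obeying the model's minimum-loop and maximum-span constraints,
#' plus one optimal structure in dot-bracket notation. Sequences too short
#' to form any pair return mfe 0 and an all-dot structure.
#'
#' @param sequence Nucleotide string (U or T accepted; N is unpairable).
#' @param model An [energy_model()].
#' @return A list with `mfe` (<= 0) and `structure` (dot-bracket string).
#' @export
#' @examples
#' fold_mfe("GGGAAAACCC")
fold_mfe <- function(sequence, model = energy_model()) {
  sequence <- normalize_sequence(sequence)
  .fold_mfe_cpp(sequence, model$gc, model$au, model$gu, model$min_loop,
                model_span(model, nchar(sequence)))
}

#' Partition function, base-pair probabilities and folding strength
#'
#' McCaskill-style inside/outside recursions over the same structure space
#' as [fold_mfe()], at Boltzmann weights `exp(-E/RT)`. The folding strength
#' is the expected fraction of paired nucleotides in the ensemble: the mean
#' over sites of `p_i = sum_j P(i pairs j)` (the per-site stem probability).
#' Internally the recursions are rescaled so results stay finite for long
#' or very stable sequences; the scale is chosen from the MFE and adjusted
#' automatically on overflow.
#'
#' @inheritParams fold_mfe
#' @param return_matrix Return the full symmetric pair-probability matrix?
#'   Default TRUE for sequences up to 2000 nt.
#' @return A list of class `folding_result`: `mfe`, `structure`,
#'   `paired_prob` (per-site vector), `folding_strength`, `log_q`
#'   (log partition function), and optionally `pair_prob` (matrix).
#' @export
#' @examples
#' fr <- fold_partition("GGGGAAAACCCC")
#' fr$folding_strength
fold_partition <- function(sequence, model = energy_model(),
                           return_matrix = nchar(sequence) <= 2000) {
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  mf <- .fold_mfe_cpp(sequence, model$gc, model$au, model$gu, model$min_loop,
                      model_span(model, n))
  # initial per-base log-scale from the MFE plus a small entropic allowance;
  # refined by bisection if magnitudes still leave double range
  ls <- if (n > 0) max(0, -mf$mfe / (n * model$rt)) + 0.25 else 0
  lo <- -Inf; hi <- Inf; step <- 0.5
  res <- NULL
  for (attempt in 1:80) {
    res <- .fold_partition_cpp(sequence, model$gc, model$au, model$gu,
                               model$min_loop, model_span(model, n), model$rt,
                               ls, return_matrix)
    if (!isTRUE(res$overflow)) break
    if (res$direction > 0) lo <- ls else hi <- ls
    ls <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
          else if (is.finite(lo)) lo + step
          else max(0, hi - step)
    step <- step * 2
  }
  if (isTRUE(res$overflow)) {
    abort("partition function could not be rescaled into double range")
  }
  structure(
    c(list(sequence = to_rna(sequence), mfe = mf$mfe, structure = mf$structure),
      res[setdiff(names(res), "overflow")]),
    class = "folding_result")
}

#' @export
print.folding_result <- function(x, ...) {
  cat("<folding_result> n =", nchar(x$sequence),
      " mfe =", format(x$mfe, digits = 4),
      " folding_strength =", format(x$folding_strength, digits = 4), "\n")
  invisible(x)
}

#' Fold every sequence in a table
#'
#' Data-frame-first convenience wrapper: folds each sequence with the
#' built-in engine and returns one row per sequence with the summary
#' statistics used by the stability analyses.
#'
#' @param data A data frame with at least an id column and a sequence column.
#' @param seq_col,id_col Column names (strings) holding the sequence and id.
#' @param model An [energy_model()].
#' @param engine `"builtin"` (default) or `"vienna"` (external RNAfold via
#'   [backend_fold()]).
#' @return A tibble: `id`, `length`, `mfe`, `folding_strength`, `log_q`.
#' @export
fold_sequences <- function(data, seq_col = "seq", id_col = "id",
                           model = energy_model(), engine = c("builtin", "vienna")) {
  engine <- match.arg(engine)
  stopifnot(is.data.frame(data), seq_col %in% names(data), id_col %in% names(data))
  rows <- purrr::map2(data[[id_col]], data[[seq_col]], function(id, s) {
    fr <- if (engine == "builtin") {
      fold_partition(s, model, return_matrix = FALSE)
    } else {
      backend_fold(s)
    }
    tibble(id = id, length = nchar(s), mfe = fr$mfe,
           folding_strength = fr$folding_strength,
           log_q = fr$log_q %||% NA_real_)
  })
  purrr::list_rbind(rows)
}

#' Sliding-window folding strength
#'
#' Folds overlapping windows and assigns each site the paired probability
#' from the window whose center is closest to the site, then averages.
#' Intended for long sequences where global folding is not meaningful.
#'
#' @inheritParams fold_mfe
#' @param window Window size in nt (default 400).
#' @param step Step between window starts (default 100).
#' @return A list: `paired_prob` (per-site), `folding_strength`.
#' @export
windowed_folding_strength <- function(sequence, model = energy_model(),
                                      window = 400, step = 100) {
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  if (n <= window) {
    fr <- fold_partition(sequence, model, return_matrix = FALSE)
    return(list(paired_prob = fr$paired_prob,
                folding_strength = fr$folding_strength))
  }
  starts <- unique(c(seq(1L, n - window + 1L, by = step), n - window + 1L))
  centers <- starts + window / 2
  probs <- matrix(NA_real_, nrow = length(starts), ncol = n)
  for (k in seq_along(starts)) {
    a <- starts[k]; b <- a + window - 1L
    fr <- fold_partition(substr(sequence, a, b), model, return_matrix = FALSE)
    probs[k, a:b] <- fr$paired_prob
  }
  p <- vapply(seq_len(n), function(i) {
    cand <- which(!is.na(probs[, i]))
    probs[cand[which.min(abs(centers[cand] - i))], i]
  }, numeric(1))
  list(paired_prob = p, folding_strength = mean(p))
}

#' Fold a sequence with the external ViennaRNA backend
#'
#' Adapter around the `RNAfold -p` command-line tool, returning the same
#' `folding_result` contract as [fold_partition()] (Turner energies,
#' kcal/mol). If RNAfold is not on the PATH a capability error is raised;
#' [fold_sequences()] users can fall back to the built-in engine.
#'
#' @inheritParams fold_mfe
#' @return A `folding_result` list (`pair_prob` matrix included).
#' @export
backend_fold <- function(sequence) {
  sequence <- normalize_sequence(sequence, allow_n = FALSE)
  if (nchar(sequence) < 1) abort("empty sequence")
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    abort("RNAfold backend not available on PATH", class = "linctools_capability_error")
  }
  dir <- tempfile("rnafold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  infile <- file.path(dir, "in.fa")
  writeLines(c(">q", to_rna(sequence)), infile)
  out <- withr_local_dir(dir, system2(exe, c("-p", "--noPS", "in.fa"),
                                      stdout = TRUE, stderr = FALSE))
  # mfe line looks like: "((((...)))) ( -5.20)"
  mfe_line <- grep("\\([ -]*-?[0-9.]+\\)$", out, value = TRUE)[1]
  mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", mfe_line))
  db <- sub("\\s.*$", "", mfe_line)
  n <- nchar(sequence)
  pp <- matrix(0, n, n)
  dp <- file.path(dir, "q_dp.ps")
  if (file.exists(dp)) {
    lines <- grep("ubox$", readLines(dp), value = TRUE)
    lines <- lines[grepl("^[0-9]", lines)]
    if (length(lines)) {
      m <- do.call(rbind, strsplit(lines, "\\s+"))
      i <- as.integer(m[, 1]); j <- as.integer(m[, 2])
      p <- as.numeric(m[, 3])^2 # ubox stores sqrt(p)
      for (k in seq_along(i)) { pp[i[k], j[k]] <- p[k]; pp[j[k], i[k]] <- p[k] }
    }
  }
  psite <- rowSums(pp)
  psite <- pmin(psite, 1)
  structure(list(sequence = to_rna(sequence), mfe = mfe, structure = db,
                 log_q = NA_real_, paired_prob = psite,
                 folding_strength = mean(psite), pair_prob = pp),
            class = "folding_result")
}

# minimal local-dir helper (avoids a withr dependency)
withr_local_dir <- function(dir, expr) {
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE)
  force(expr)
}
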