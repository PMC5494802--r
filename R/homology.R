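# Conservation and paralogy detection: seed-and-extend local similarity
# search with Karlin-Altschul e-values, repeat/low-complexity masking,
# translated-ORF search, and Markov clustering of the similarity graph.
#
# Homologous patches follow the operational definition used throughout:
# a local alignment of more than 100 matched+mismatched columns at an
# e-value below 1e-5.

#' Alignment parameters for the local similarity search
#'
#' Defaults are megablast-like: word size 11, match +1 / mismatch -2,
#' gap open 5 / extend 2 (a gap of length L costs open + L * extend).
#'
#' @param word_size Exact-word seed length.
#' @param match,mismatch Nucleotide scores.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @param xdrop Ungapped extension X-drop.
#' @param gap_trigger Minimum ungapped seed-extension score before the
#'   gapped stage runs.
#' @param max_patches Maximum local-alignment patches reported per pair.
#' @param evalue_max Edge retention threshold on the best patch e-value.
#' @param patch_min Minimum matched+mismatched columns for a qualifying
#'   patch (the >100 nt rule).
#' @param patch_score_min Minimum gapped score for reporting further
#'   patches.
#' @return An `align_params` list, with Karlin-Altschul lambda/K attached.
#' @export
align_params <- function(word_size = 11, match = 1, mismatch = -2,
                         gap_open = 5, gap_extend = 2, xdrop = 30,
                         gap_trigger = 22, max_patches = 5,
                         evalue_max = 1e-5, patch_min = 100,
                         patch_score_min = 20) {
  submat <- matrix(mismatch, 5, 5)
  diag(submat) <- match
  submat[5, ] <- submat[, 5] <- -1e9 # N never aligns
  freqs <- rep(0.25, 4)
  ka <- karlin_params(submat[1:4, 1:4], freqs)
  structure(list(word_size = word_size, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend, xdrop = xdrop,
                 gap_trigger = gap_trigger, max_patches = max_patches,
                 evalue_max = evalue_max, patch_min = patch_min,
                 patch_score_min = patch_score_min,
                 submat = submat, alpha = 4L, lambda = ka$lambda, K = ka$K,
                 level = "nucleotide"),
            class = "align_params")
}

#' Protein alignment parameters (BLOSUM62)
#'
#' BLOSUM62 scoring with gap open 11 / extend 1, word size 3, and
#' Karlin-Altschul parameters computed for BLOSUM62 against
#' Robinson-Robinson background amino-acid frequencies.
#'
#' @inheritParams align_params
#' @return An `align_params` list at protein level.
#' @export
protein_align_params <- function(gap_open = 11, gap_extend = 1, word_size = 3,
                                 xdrop = 16, gap_trigger = 22, max_patches = 3,
                                 evalue_max = 1e-5, patch_min = 0,
                                 patch_score_min = 20) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  B <- BLOSUM62[aa, aa]
  # stop/unknown row: never aligns
  submat <- rbind(cbind(B, `*` = -1e9), `*` = -1e9)
  ka <- karlin_params(B, robinson_frequencies())
  structure(list(word_size = word_size, gap_open = gap_open,
                 gap_extend = gap_extend, xdrop = xdrop,
                 gap_trigger = gap_trigger, max_patches = max_patches,
                 evalue_max = evalue_max, patch_min = patch_min,
                 patch_score_min = patch_score_min,
                 submat = submat, alpha = 20L, lambda = ka$lambda, K = ka$K,
                 level = "protein", residues = aa),
            class = "align_params")
}

# Robinson & Robinson (1991) background amino-acid frequencies, the
# standard background for protein Karlin-Altschul statistics.
robinson_frequencies <- function() {
  c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
    Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
    L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
    S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
}

#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' Solves the Karlin sum equation `sum_ij p_i p_j exp(lambda s_ij) = 1`
#' for lambda, computes the relative entropy H, and evaluates K by the
#' lattice-case convolution series. E-values then follow
#' `E = K m n exp(-lambda S)`.
#'
#' @param submat Integer substitution matrix (square, in residue order).
#' @param freqs Background residue frequencies (sums to 1).
#' @return List: `lambda`, `K`, `H`.
#' @export
karlin_params <- function(submat, freqs) {
  freqs <- freqs / sum(freqs)
  scores <- round(submat)
  lo <- min(scores); hi <- max(scores)
  if (hi <= 0) abort("scoring scheme needs a positive score")
  if (sum(outer(freqs, freqs) * scores) >= 0)
    abort("expected score must be negative for local alignment statistics")
  # score distribution on the integer lattice
  p <- vapply(lo:hi, function(s0) sum(outer(freqs, freqs)[scores == s0]), numeric(1))
  names(p) <- lo:hi
  phi <- function(lambda) sum(p * exp(lambda * (lo:hi))) - 1
  lambda <- stats::uniroot(phi, c(1e-6, 20), tol = 1e-12)$root
  H <- lambda * sum(p * (lo:hi) * exp(lambda * (lo:hi)))
  # lattice span
  d <- span_gcd((lo:hi)[p > 0])
  # sigma = sum_j (1/j) [ sum_{s<=0} P_j(s) e^{lambda s} + P(S_j > 0) ]
  sigma <- 0
  conv <- c(`0` = 1) # distribution of S_0
  support0 <- 0
  for (j in 1:60) {
    conv <- convolve_lattice(conv, p, lo)
    sc <- as.numeric(names(conv))
    term <- sum(conv[sc <= 0] * exp(lambda * sc[sc <= 0])) + sum(conv[sc > 0])
    sigma <- sigma + term / j
    if (term / j < 1e-10) break
  }
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K, H = H)
}

span_gcd <- function(v) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  Reduce(g, abs(v))
}

convolve_lattice <- function(dist, p, lo) {
  sc_d <- as.numeric(names(dist))
  sc_p <- as.numeric(names(p))
  out <- new.env(parent = emptyenv())
  vals <- outer(dist, p)
  sums <- outer(sc_d, sc_p, `+`)
  agg <- tapply(as.vector(vals), as.vector(sums), sum)
  agg
}

encode_nuc <- local({
  lut <- rep(4L, 256)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  lut[utf8ToInt("U")] <- 3L; lut[utf8ToInt("u")] <- 3L
  function(seq) lut[utf8ToInt(seq)]
})

encode_protein <- function(seq, residues) {
  ch <- seq_chars(toupper(seq))
  m <- match(ch, residues)
  m[is.na(m)] <- length(residues) + 1L
  m - 1L
}

evalue_from_score <- function(score, m, n, params) {
  params$K * m * n * exp(-params$lambda * score)
}

#' Local similarity search between two sequences
#'
#' Exact-word seeding with ungapped X-drop extension; if the best ungapped
#' seed extension reaches `gap_trigger`, full affine-gap local alignment
#' runs, and further patches are found by masking the aligned query region
#' and re-aligning (up to `max_patches`). An edge is retained only when the
#' best patch e-value is below `evalue_max` and some patch has more than
#' `patch_min` matched+mismatched columns.
#'
#' @param query,subject Sequence strings (nucleotide, or amino acid with
#'   protein params).
#' @param params [align_params()] or [protein_align_params()].
#' @param query_id,subject_id Ids carried into the edge.
#' @param keep_all Keep edges failing the retention thresholds (flagged
#'   `retained = FALSE`) instead of returning NULL.
#' @return One-row edge tibble (`query_id`, `subject_id`, `best_score`,
#'   `best_evalue`, `n_patches`, `total_patch_length`, `max_patch_length`,
#'   `identity`, `retained`, `patches` list-column) or NULL.
#' @export
local_search <- function(query, subject, params = align_params(),
                         query_id = "query", subject_id = "subject",
                         keep_all = FALSE) {
  if (params$level == "nucleotide") {
    q <- encode_nuc(normalize_sequence(query))
    s <- encode_nuc(normalize_sequence(subject))
  } else {
    q <- encode_protein(query, params$residues)
    s <- encode_protein(subject, params$residues)
  }
  if (all(q == params$alpha) || all(s == params$alpha)) {
    abort("degenerate input: no alignable residues")
  }
  m <- length(q); n <- length(s)
  if (m < params$word_size || n < params$word_size) return(NULL)
  ug <- .best_ungapped_cpp(q, s, params$word_size, params$submat,
                           params$xdrop, params$alpha)
  if (ug < params$gap_trigger) return(NULL)
  patches <- list()
  qwork <- q
  for (k in seq_len(params$max_patches)) {
    al <- .sw_align_cpp(qwork, s, params$submat, params$gap_open, params$gap_extend)
    if (al$score < params$patch_score_min) break
    patch_len <- al$matches + al$mismatches
    patches[[k]] <- tibble(
      q_start = al$q_start, q_end = al$q_end,
      s_start = al$s_start, s_end = al$s_end,
      score = al$score,
      evalue = evalue_from_score(al$score, m, n, params),
      length = patch_len,
      identity = if (al$columns > 0) al$matches / al$columns else NA_real_)
    # mask the aligned query span and look for further patches
    if (al$q_end > al$q_start) {
      qwork[(al$q_start + 1):al$q_end] <- params$alpha
    } else break
  }
  if (length(patches) == 0) return(NULL)
  pt <- purrr::list_rbind(patches)
  retained <- min(pt$evalue) < params$evalue_max && any(pt$length > params$patch_min)
  if (!retained && !keep_all) return(NULL)
  tibble(query_id = query_id, subject_id = subject_id,
         best_score = max(pt$score), best_evalue = min(pt$evalue),
         n_patches = nrow(pt),
         total_patch_length = sum(pt$length),
         max_patch_length = max(pt$length),
         identity = pt$identity[which.max(pt$score)],
         retained = retained,
         patches = list(pt))
}

# DUST-like low-complexity mask: windows of `window` nt scored by the
# standard normalized triplet-collision statistic
# 10 * sum c_t (c_t - 1) / 2 / (T - 1) over triplet counts c_t (T triplets
# in the window); windows above `threshold` (default 20, i.e. score 2.0 on
# the unscaled statistic) are masked. A random window scores ~5, poly-A ~310.
dust_mask <- function(seq, window = 64, threshold = 20) {
  n <- nchar(seq)
  mask <- rep(FALSE, n)
  if (n < 4) return(mask)
  ch <- encode_nuc(seq)
  tri <- ch[1:(n - 2)] * 16 + ch[2:(n - 1)] * 4 + ch[3:n]
  tri[ch[1:(n - 2)] > 3 | ch[2:(n - 1)] > 3 | ch[3:n] > 3] <- NA
  step <- max(1L, window %/% 2L)
  starts <- unique(c(seq(1L, max(1L, n - window + 1L), by = step), max(1L, n - window + 1L)))
  for (a in starts) {
    b <- min(n - 2, a + window - 3)
    if (b - a < 1) next
    counts <- table(tri[a:b])
    score <- 10 * sum(counts * (counts - 1) / 2) / (b - a)
    if (score > threshold) mask[a:min(n, a + window - 1)] <- TRUE
  }
  mask
}

# Replace masked positions (repeat intervals in transcript coordinates and
# DUST low-complexity windows) with N.
mask_sequence <- function(seq, intervals = NULL, dust = TRUE) {
  ch <- seq_chars(seq)
  if (!is.null(intervals) && nrow(intervals)) {
    for (r in seq_len(nrow(intervals))) {
      a <- max(1, intervals$start[r] + 1)
      b <- min(length(ch), intervals$end[r])
      if (b >= a) ch[a:b] <- "N"
    }
  }
  if (dust) ch[dust_mask(paste(ch, collapse = ""))] <- "N"
  paste(ch, collapse = "")
}

# Genomic repeat intervals -> transcript (spliced) coordinates.
repeats_to_transcript_coords <- function(tx_row, repeats) {
  e <- tx_row$exons[[1]]
  rep_c <- filter(repeats, chrom == tx_row$chrom)
  if (nrow(rep_c) == 0) return(tibble(start = numeric(0), end = numeric(0)))
  widths <- e$end - e$start
  offs <- cumsum(c(0, widths))[seq_len(nrow(e))]
  out <- list()
  for (k in seq_len(nrow(e))) {
    ov_start <- pmax(rep_c$start, e$start[k])
    ov_end <- pmin(rep_c$end, e$end[k])
    hit <- ov_end > ov_start
    if (!any(hit)) next
    a <- ov_start[hit] - e$start[k]
    b <- ov_end[hit] - e$start[k]
    if (tx_row$strand == "+") {
      out[[k]] <- tibble(start = offs[k] + a, end = offs[k] + b)
    } else {
      # exon k counted from transcript 5' end on minus strand
      koff <- sum(widths) - offs[k] - widths[k]
      out[[k]] <- tibble(start = koff + (widths[k] - b), end = koff + (widths[k] - a))
    }
  }
  if (length(out) == 0) return(tibble(start = numeric(0), end = numeric(0)))
  purrr::list_rbind(out)
}

#' All-vs-all local similarity search over a transcript table
#'
#' Candidate pairs are screened by exact word sharing, then aligned with
#' [local_search()]. `mode = "cross_species"` keeps pairs from different
#' species; `"within_species"` keeps same-species pairs (self-hits
#' excluded). With `masked = TRUE`, repeat intervals (mapped to transcript
#' coordinates) and DUST low-complexity windows are replaced by N before
#' searching.
#'
#' @param tx Transcript tibble.
#' @param mode `"cross_species"` or `"within_species"`.
#' @param masked Mask repeats/low-complexity first?
#' @param repeats Genomic repeat tibble (required when `masked = TRUE` and
#'   repeat masking is wanted; DUST still applies if NULL).
#' @param params [align_params()].
#' @return Edge tibble (one row per retained unordered pair).
#' @export
all_vs_all <- function(tx, mode = c("cross_species", "within_species"),
                       masked = FALSE, repeats = NULL,
                       params = align_params()) {
  mode <- match.arg(mode)
  if (any(is.na(tx$species))) abort("species label missing")
  seqs <- tx$seq
  if (masked) {
    seqs <- vapply(seq_len(nrow(tx)), function(r) {
      iv <- if (!is.null(repeats)) {
        repeats_to_transcript_coords(tx[r, ],
                                     filter(repeats, species == tx$species[r]))
      } else NULL
      mask_sequence(tx$seq[r], iv, dust = TRUE)
    }, character(1))
  }
  enc <- lapply(seqs, encode_nuc)
  cand <- .word_pairs_cpp(enc, params$word_size, params$alpha)
  if (nrow(cand) == 0) return(empty_edges())
  keep <- if (mode == "cross_species") {
    tx$species[cand[, 1]] != tx$species[cand[, 2]]
  } else {
    tx$species[cand[, 1]] == tx$species[cand[, 2]]
  }
  cand <- cand[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(r) {
    i <- cand[r, 1]; j <- cand[r, 2]
    local_search(seqs[i], seqs[j], params,
                 query_id = tx$id[i], subject_id = tx$id[j])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_edges())
  out <- purrr::list_rbind(rows)
  out$query_species <- tx$species[match(out$query_id, tx$id)]
  out$subject_species <- tx$species[match(out$subject_id, tx$id)]
  out$masked_mode <- masked
  out
}

empty_edges <- function() {
  tibble(query_id = character(0), subject_id = character(0),
         best_score = numeric(0), best_evalue = numeric(0),
         n_patches = integer(0), total_patch_length = numeric(0),
         max_patch_length = numeric(0), identity = numeric(0),
         retained = logical(0), patches = list(),
         query_species = character(0), subject_species = character(0),
         masked_mode = logical(0))
}

#' Markov clustering of a similarity graph
#'
#' Canonical MCL: edge weights -log10(e-value) capped at 200, self-loops
#' set to each node's maximum incident weight, column-stochastic transition
#' matrix, then alternating expansion (matrix squaring) and inflation
#' (entrywise power `inflation`, column renormalization) until the maximum
#' entry change falls below 1e-6 or 100 iterations. Clusters are the
#' connected components of the converged attractor structure; singleton
#' nodes (no retained edges) are not reported.
#'
#' @param edges Edge tibble from [all_vs_all()] (uses `query_id`,
#'   `subject_id`, `best_evalue`).
#' @param inflation Inflation exponent (default 2).
#' @return Tibble: `cluster_id`, `id` — the cluster membership list.
#' @export
mcl_cluster <- function(edges, inflation = 2.0) {
  if (nrow(edges) == 0) return(tibble(cluster_id = integer(0), id = character(0)))
  ids <- sort(unique(c(edges$query_id, edges$subject_id)))
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  w <- pmin(-log10(pmax(edges$best_evalue, 1e-200)), 200)
  w <- pmax(w, 1e-6)
  qi <- match(edges$query_id, ids); si <- match(edges$subject_id, ids)
  for (r in seq_along(qi)) {
    W[qi[r], si[r]] <- max(W[qi[r], si[r]], w[r])
    W[si[r], qi[r]] <- max(W[si[r], qi[r]], w[r])
  }
  diag(W) <- apply(W, 2, max)
  M <- sweep(W, 2, colSums(W), "/")
  for (it in 1:100) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < 1e-12] <- 0
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-6) break
  }
  G <- igraph::graph_from_adjacency_matrix((M > 1e-5) | t(M > 1e-5),
                                           mode = "undirected")
  comp <- igraph::components(G)$membership
  tibble(cluster_id = unname(comp), id = ids) |>
    arrange(cluster_id, id)
}

#' Conservation labels per transcript
#'
#' A transcript is `conserved` when its unmasked cross-species cluster
#' holds at least one transcript from another species;
#' `conserved_after_masking` likewise on the masked clustering;
#' `te_related` when conserved unmasked but not masked (similarity driven
#' by repeats); `orf_conserved` from the translated-ORF clustering; and
#' `paralog` when clustered with another transcript of the same species in
#' the within-species run. Labels are independent; a transcript may hold
#' several.
#'
#' @param tx Transcript tibble (the universe the clusterings ran on).
#' @param clusters,masked_clusters,orf_clusters Cluster tibbles from
#'   [mcl_cluster()] on unmasked, masked, and ORF-level edges (ORF may be
#'   NULL).
#' @param paralog_clusters Cluster tibble from within-species edges (may
#'   be NULL).
#' @return Tibble: `id`, `species`, logical columns `conserved`,
#'   `conserved_after_masking`, `te_related`, `orf_conserved`, `paralog`.
#' @export
classify_conservation <- function(tx, clusters, masked_clusters,
                                  orf_clusters = NULL,
                                  paralog_clusters = NULL) {
  check_universe <- function(cl, nm) {
    if (!is.null(cl) && nrow(cl) && !all(cl$id %in% tx$id))
      abort(sprintf("%s contains ids outside the transcript universe", nm))
  }
  check_universe(clusters, "clusters")
  check_universe(masked_clusters, "masked_clusters")
  check_universe(orf_clusters, "orf_clusters")
  check_universe(paralog_clusters, "paralog_clusters")
  conserved_ids <- function(cl) {
    if (is.null(cl) || nrow(cl) == 0) return(character(0))
    cl$species <- tx$species[match(cl$id, tx$id)]
    cl |> group_by(cluster_id) |>
      filter(n_distinct(species) >= 2) |>
      pull(id)
  }
  paralog_ids <- function(cl) {
    if (is.null(cl) || nrow(cl) == 0) return(character(0))
    cl$species <- tx$species[match(cl$id, tx$id)]
    cl |> group_by(cluster_id, species) |>
      filter(n() >= 2) |> pull(id)
  }
  cons <- tx$id %in% conserved_ids(clusters)
  cons_masked <- tx$id %in% conserved_ids(masked_clusters)
  tibble(id = tx$id, species = tx$species,
         conserved = cons,
         conserved_after_masking = cons_masked,
         te_related = cons & !cons_masked,
         orf_conserved = tx$id %in% conserved_ids(orf_clusters),
         paralog = tx$id %in% paralog_ids(paralog_clusters))
}

#' Translated-ORF similarity edges
#'
#' Translates each transcript's longest qualifying ORF and runs the
#' protein-level local search all-vs-all across species (BLOSUM62,
#' gap 11/1). Transcripts without a qualifying ORF are skipped and counted
#' in a message.
#'
#' @param tx Transcript tibble.
#' @param orfs ORF table from [orf_calls()] (computed if NULL).
#' @param params Protein [protein_align_params()].
#' @param min_aa Minimum peptide length when `orfs` is computed here.
#' @return Protein-level edge tibble.
#' @export
orf_similarity <- function(tx, orfs = NULL, params = protein_align_params(),
                           min_aa = 25) {
  if (is.null(orfs)) orfs <- orf_calls(tx, min_aa = min_aa)
  orfs <- filter(orfs, !is.na(orf_aa))
  skipped <- nrow(tx) - nrow(orfs)
  if (skipped > 0) inform(sprintf("%d transcript(s) without qualifying ORF skipped", skipped))
  if (nrow(orfs) < 2) return(empty_edges())
  peps <- vapply(orfs$orf_seq, translate_cds, character(1), USE.NAMES = FALSE)
  ptx <- tibble(id = orfs$id, species = tx$species[match(orfs$id, tx$id)],
                seq = peps)
  enc <- lapply(ptx$seq, encode_protein, residues = params$residues)
  cand <- .word_pairs_cpp(enc, params$word_size, params$alpha)
  if (nrow(cand) == 0) return(empty_edges())
  keep <- ptx$species[cand[, 1]] != ptx$species[cand[, 2]]
  cand <- cand[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(r) {
    i <- cand[r, 1]; j <- cand[r, 2]
    local_search(ptx$seq[i], ptx$seq[j], params,
                 query_id = ptx$id[i], subject_id = ptx$id[j])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_edges())
  out <- purrr::list_rbind(rows)
  out$query_species <- ptx$species[match(out$query_id, ptx$id)]
  out$subject_species <- ptx$species[match(out$subject_id, ptx$id)]
  out$masked_mode <- FALSE
  out
}

# Translate a CDS (starting in frame 0) to amino acids, stop codon dropped.
translate_cds <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3
  if (n < 3) return("")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(cds, 1, n)),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Screen transcripts for similarity to known proteins
#'
#' Translates each transcript in six frames and searches against a
#' reference protein set; any hit below the e-value threshold flags the
#' transcript as likely coding contamination (pseudogene remnant or
#' unannotated coding exon). The threshold is configurable: 1e-6 at the
#' assembly-filter stage, 1e-5 at the screening stage.
#'
#' @param tx Transcript tibble.
#' @param reference_proteins Named character vector of amino-acid
#'   sequences.
#' @param threshold E-value threshold (default 1e-6).
#' @param params Protein [protein_align_params()].
#' @return Tibble: `id`, `best_evalue`, `flagged`.
#' @export
coding_contamination_screen <- function(tx, reference_proteins,
                                        threshold = 1e-6,
                                        params = protein_align_params()) {
  if (length(reference_proteins) == 0) abort("empty reference protein set")
  if (nrow(tx) == 0) {
    return(tibble(id = character(0), best_evalue = numeric(0), flagged = logical(0)))
  }
  frames6 <- function(s) {
    rc <- revcomp(s)
    unlist(lapply(0:2, function(f) {
      c(translate_cds(substr(s, f + 1, nchar(s))),
        translate_cds(substr(rc, f + 1, nchar(rc))))
    }))
  }
  rows <- lapply(seq_len(nrow(tx)), function(r) {
    peps <- frames6(tx$seq[r])
    best <- Inf
    for (pep in peps) {
      if (nchar(pep) < params$word_size) next
      for (ref in reference_proteins) {
        hit <- local_search(pep, ref, params, keep_all = TRUE)
        if (!is.null(hit)) best <- min(best, hit$best_evalue)
      }
    }
    tibble(id = tx$id[r], best_evalue = best, flagged = best < threshold)
  })
  purrr::list_rbind(rows)
}
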