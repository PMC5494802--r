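withr_tempdir <- function() {
  d <- tempfile("lincuniv")
  dir.create(d)
  d
}

# Adjusted Rand index between recovered clusters and planted families,
# over the whole transcript set (unclustered transcripts are their own
# singleton in both labelings).
family_ari <- function(universe, clusters) {
  fam <- universe$truth$family_assignments
  lab_true <- ifelse(is.na(fam$family), paste0("s", seq_len(nrow(fam))),
                     paste0("f", fam$family))
  pred <- clusters$cluster_id[match(fam$id, clusters$id)]
  lab_pred <- ifelse(is.na(pred), paste0("s", seq_len(nrow(fam))),
                     paste0("c", pred))
  adjusted_rand_index(lab_true, lab_pred)
}

# Independent ARI implementation (pair-counting formula).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sum_ij <- comb2(tab)
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# A pair of transcripts in two species whose only similarity is a shared
# planted TE copy (same library consensus, low divergence).
make_te_pair <- function(te_seq, flank = 250, seed = NULL) {
  linctools:::with_seed(seed, {
    mk <- function(sp, i) {
      copy <- linctools:::mutate_sites(te_seq, 0.02)
      s <- paste0(random_dna(flank), copy, random_dna(flank))
      tibble::tibble(
        id = sprintf("%s_te%03d", sp, i), species = sp, chrom = paste0(sp, "_chr1"),
        strand = "+", biotype = "lincRNA",
        exons = list(tibble::tibble(start = 0, end = nchar(s))), seq = s,
        te_start = flank, te_end = flank + nchar(te_seq))
    }
    dplyr::bind_rows(mk("spA", 1), mk("spB", 1))
  })
}
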