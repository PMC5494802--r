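# Local similarity search, e-value statistics, masking, MCL clustering,
# conservation labels, protein-level search.

test_that("Karlin-Altschul parameters reproduce the published ungapped constants", {
  p <- align_params()
  expect_equal(p$lambda, 1.33, tolerance = 0.005)
  expect_equal(p$K, 0.621, tolerance = 0.01)
  pp <- protein_align_params()
  expect_equal(pp$lambda, 0.3176, tolerance = 0.002)
  expect_equal(pp$K, 0.134, tolerance = 0.01)
})

test_that("identical sequences give a full-length identity-1 retained edge", {
  set.seed(71)
  s <- random_dna(150)
  e <- local_search(s, s, query_id = "a", subject_id = "b")
  expect_identical(e$max_patch_length, 150L)
  expect_equal(e$identity, 1)
  expect_true(e$retained)
  expect_lt(e$best_evalue, 1e-50)
})

test_that("an 80-nt shared block in random background is rejected by the patch rule", {
  set.seed(72)
  block <- random_dna(80)
  q <- paste0(random_dna(200), block, random_dna(200))
  s <- paste0(random_dna(150), block, random_dna(250))
  expect_null(local_search(q, s))
  e <- local_search(q, s, keep_all = TRUE)
  expect_false(is.null(e))
  expect_false(e$retained)
  expect_lte(e$max_patch_length, 100)
})

test_that("planted family pairs at 5% divergence align near 95% identity", {
  set.seed(73)
  for (rep in 1:10) {
    a <- random_dna(600)
    b <- linctools:::mutate_sites(a, 0.05)
    e <- local_search(a, b)
    expect_true(e$retained)
    expect_lt(abs(e$identity - 0.95), 0.03)
    expect_gt(e$max_patch_length, 500)
  }
})

test_that("gapped patch score equals full Smith-Waterman (Biostrings oracle)", {
  skip_if_not_installed("Biostrings")
  set.seed(74)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  for (rep in 1:30) {
    len <- sample(60:120, 1)
    core <- random_dna(len)
    a <- sample.int(len - 25, 1)
    # a clean 25-nt window guarantees a seed that reaches the gap trigger;
    # past that point the gapped stage is exact Smith-Waterman
    mut <- paste0(
      linctools:::mutate_sites(substr(core, 1, a), runif(1, 0, 0.12)),
      substr(core, a + 1, a + 25),
      linctools:::mutate_sites(substr(core, a + 26, len), runif(1, 0, 0.12)))
    q <- paste0(random_dna(sample(20:90, 1)), mut, random_dna(sample(20:90, 1)))
    s <- paste0(random_dna(sample(20:90, 1)), core, random_dna(sample(20:90, 1)))
    e <- local_search(q, s, keep_all = TRUE)
    pa <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    expect_false(is.null(e))
    expect_equal(e$best_score, Biostrings::score(pa))
  }
})

test_that("all-vs-all modes route pairs correctly", {
  set.seed(75)
  base <- random_dna(400)
  tx <- tibble::tibble(
    id = c("a1", "a2", "b1"), species = c("spA", "spA", "spB"),
    chrom = "c", strand = "+", biotype = "lincRNA",
    exons = list(tibble::tibble(start = 0, end = 400)),
    seq = c(base, base, base))
  within <- all_vs_all(tx, "within_species")
  expect_identical(nrow(within), 1L)
  expect_setequal(c(within$query_id, within$subject_id), c("a1", "a2"))
  crossed <- all_vs_all(tx, "cross_species")
  expect_identical(nrow(crossed), 2L)
  # single species in cross-species mode: empty
  solo <- all_vs_all(tx[1:2, ], "cross_species")
  expect_identical(nrow(solo), 0L)
})

test_that("TE-driven similarity disappears under masking (monotonic edge sets)", {
  lib <- te_library()
  pair <- make_te_pair(lib$seq[lib$class == "LTR"], seed = 76)
  repeats <- tibble::tibble(
    chrom = pair$chrom, species = pair$species,
    start = pair$te_start, end = pair$te_end,
    class = "LTR", name = "LTR-1_synth", divergence_pct = 2)
  unmasked <- all_vs_all(pair, "cross_species")
  masked <- all_vs_all(pair, "cross_species", masked = TRUE, repeats = repeats)
  expect_identical(nrow(unmasked), 1L)
  expect_identical(nrow(masked), 0L)
  # masked edges are a subset of unmasked edges
  expect_true(all(paste(masked$query_id, masked$subject_id) %in%
                    paste(unmasked$query_id, unmasked$subject_id)))
})

test_that("MCL behaves canonically on toy graphs", {
  ed <- function(a, b) tibble::tibble(query_id = a, subject_id = b,
                                      best_evalue = 1e-30)
  # two disconnected triangles are never merged
  tri2 <- dplyr::bind_rows(ed("a", "b"), ed("b", "c"), ed("a", "c"),
                           ed("x", "y"), ed("y", "z"), ed("x", "z"))
  cl <- mcl_cluster(tri2)
  expect_identical(dplyr::n_distinct(cl$cluster_id), 2L)
  expect_identical(dplyr::n_distinct(cl$cluster_id[cl$id %in% c("a", "b", "c")]), 1L)
  # single edge -> one cluster of two
  cl1 <- mcl_cluster(ed("A", "B"))
  expect_identical(cl1$cluster_id, c(1, 1))
  # empty edge list -> empty clustering
  expect_identical(nrow(mcl_cluster(tri2[0, ])), 0L)
  # a weakly-bridged pair of triangles: moderate inflation separates them,
  # inflation 1 (pure expansion) keeps one connected component
  bridged <- dplyr::bind_rows(tri2, tibble::tibble(query_id = "c",
                                                   subject_id = "x",
                                                   best_evalue = 1e-4))
  expect_identical(dplyr::n_distinct(mcl_cluster(bridged, inflation = 4)$cluster_id), 2L)
  expect_identical(dplyr::n_distinct(mcl_cluster(bridged, inflation = 1)$cluster_id), 1L)
})

test_that("conservation labels distinguish genuine from TE-driven similarity", {
  set.seed(77)
  lib <- te_library()
  te_pair <- make_te_pair(lib$seq[lib$class == "LINE"], seed = 78)
  real <- random_dna(400)
  real_pair <- tibble::tibble(
    id = c("spA_real", "spB_real"), species = c("spA", "spB"),
    chrom = c("spA_chr1", "spB_chr1"), strand = "+", biotype = "lincRNA",
    exons = list(tibble::tibble(start = 0, end = 400)),
    seq = c(real, linctools:::mutate_sites(real, 0.02)),
    te_start = NA_real_, te_end = NA_real_)
  tx <- dplyr::bind_rows(te_pair, real_pair)
  repeats <- tibble::tibble(
    chrom = te_pair$chrom, species = te_pair$species,
    start = te_pair$te_start, end = te_pair$te_end,
    class = "LINE", name = "LINE-1_synth", divergence_pct = 2)
  cl <- mcl_cluster(all_vs_all(tx, "cross_species"))
  clm <- mcl_cluster(all_vs_all(tx, "cross_species", masked = TRUE,
                                repeats = repeats))
  lab <- classify_conservation(tx, cl, clm)
  te_lab <- dplyr::filter(lab, id == "spA_te001")
  expect_true(te_lab$conserved)
  expect_false(te_lab$conserved_after_masking)
  expect_true(te_lab$te_related)
  real_lab <- dplyr::filter(lab, id == "spA_real")
  expect_true(real_lab$conserved)
  expect_true(real_lab$conserved_after_masking)
  expect_false(real_lab$te_related)
  # singleton: no labels
  singleton <- tibble::tibble(
    id = "spC_alone", species = "spC", chrom = "c", strand = "+",
    biotype = "lincRNA", exons = list(tibble::tibble(start = 0, end = 300)),
    seq = random_dna(300))
  lab2 <- classify_conservation(dplyr::bind_rows(tx[, names(singleton)], singleton),
                                cl, clm)
  expect_false(any(unlist(lab2[lab2$id == "spC_alone",
                               c("conserved", "te_related", "paralog")])))
  # universe mismatch is an error
  expect_error(classify_conservation(real_pair, cl, clm), "universe")
})

test_that("protein-level search keeps synonymously diverged ORFs connected", {
  set.seed(79)
  codon_table <- list(
    A = c("GCT", "GCC", "GCA", "GCG"), G = c("GGT", "GGC", "GGA", "GGG"),
    L = c("CTT", "CTC", "CTA", "CTG"), P = c("CCT", "CCC", "CCA", "CCG"),
    T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"))
  aas <- sample(names(codon_table), 60, TRUE)
  pick <- function() paste0("ATG", paste(vapply(aas, function(a)
    sample(codon_table[[a]], 1), character(1)), collapse = ""), "TAA")
  cds1 <- pick(); cds2 <- pick() # same peptide, different codons
  nuc_ident <- mean(strsplit(cds1, "")[[1]] == strsplit(cds2, "")[[1]])
  expect_lt(nuc_ident, 0.9) # nucleotide-level similarity degraded
  tx <- tibble::tibble(
    id = c("x1", "y1"), species = c("spX", "spY"), chrom = "c", strand = "+",
    biotype = "lincRNA",
    exons = list(tibble::tibble(start = 0, end = nchar(cds1))),
    seq = c(cds1, cds2))
  edges <- suppressMessages(orf_similarity(tx, min_aa = 25))
  expect_identical(nrow(edges), 1L)
  expect_true(edges$retained)
  # transcripts without a qualifying ORF are skipped with a message
  tx2 <- dplyr::bind_rows(tx, tibble::tibble(
    id = "noorf", species = "spZ", chrom = "c", strand = "+",
    biotype = "lincRNA", exons = list(tibble::tibble(start = 0, end = 210)),
    seq = paste(rep("TAA", 70), collapse = "")))
  expect_message(orf_similarity(tx2, min_aa = 25), "skipped")
})

test_that("coding contamination screen flags embedded reference CDS only", {
  set.seed(80)
  ref_cds <- linctools:::make_coding_sequence(450)
  ref_prot <- linctools:::translate_cds(ref_cds)
  hot <- paste0(random_dna(100), ref_cds, random_dna(100))
  cold <- random_dna(650)
  tx <- tibble::tibble(
    id = c("hot", "cold"), species = "sp", chrom = "c", strand = "+",
    biotype = "lincRNA",
    exons = list(tibble::tibble(start = 0, end = 650)),
    seq = c(hot, cold))
  out <- coding_contamination_screen(tx, c(ref = ref_prot), threshold = 1e-6)
  expect_true(out$flagged[out$id == "hot"])
  expect_false(out$flagged[out$id == "cold"])
  expect_error(coding_contamination_screen(tx, character(0)), "empty")
  empty <- coding_contamination_screen(tx[0, ], c(ref = ref_prot))
  expect_identical(nrow(empty), 0L)
})
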