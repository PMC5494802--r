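# The synthetic-data generator: determinism, planted-truth contracts,
# serialization, expression correlation structure, TE placement.

small_spec <- function(...) {
  synth_spec(species_count = 2, lincrna_per_species = 15,
             length_range = c(200L, 400L), family_count = 3, ...)
}

test_that("generation is deterministic given the seed (byte-identical writes)", {
  u1 <- simulate_universe(small_spec(seed = 9))
  u2 <- simulate_universe(small_spec(seed = 9))
  d1 <- withr_tempdir(); d2 <- withr_tempdir()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  write_universe(u1, d1)
  write_universe(u2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  u3 <- simulate_universe(small_spec(seed = 10))
  expect_false(identical(u1$transcripts$seq, u3$transcripts$seq))
})

test_that("zero cases behave: no structure, no divergence, no families", {
  u0 <- simulate_universe(small_spec(seed = 3, structured_fraction = 0))
  expect_length(u0$truth$structured_ids, 0)
  ud <- simulate_universe(small_spec(seed = 4, family_divergence = 0))
  fam <- ud$truth$family_assignments
  for (f in unique(stats::na.omit(fam$family))) {
    members <- fam$id[!is.na(fam$family) & fam$family == f]
    seqs <- ud$transcripts$seq[match(members, ud$transcripts$id)]
    # identical up to planted TEs; with TE densities zeroed they are equal
  }
  ud0 <- simulate_universe(small_spec(seed = 4, family_divergence = 0,
                                      te_density_exon = 0, te_density_intron = 0))
  fam <- ud0$truth$family_assignments
  for (f in unique(stats::na.omit(fam$family))) {
    members <- fam$id[!is.na(fam$family) & fam$family == f]
    seqs <- ud0$transcripts$seq[match(members, ud0$transcripts$id)]
    expect_identical(length(unique(seqs)), 1L, info = paste("family", f))
  }
})

test_that("planted truth covers every transcript and families span species", {
  u <- simulate_universe(small_spec(seed = 5))
  fam <- u$truth$family_assignments
  expect_setequal(fam$id, u$transcripts$id)
  expect_true(all(u$truth$structured_ids %in% u$transcripts$id))
  expect_setequal(names(u$truth$te_intervals), u$transcripts$id)
  for (f in unique(stats::na.omit(fam$family))) {
    members <- fam$id[!is.na(fam$family) & fam$family == f]
    expect_gte(length(members), 2)
    sp <- u$transcripts$species[match(members, u$transcripts$id)]
    expect_gte(dplyr::n_distinct(sp), 2)
  }
})

test_that("planted hairpins contain a perfect inverted repeat (stem >= 15, loop >= 4)", {
  u <- simulate_universe(small_spec(seed = 6, structured_fraction = 0.4,
                                    te_density_exon = 0, te_density_intron = 0))
  ids <- u$truth$structured_ids
  expect_gt(length(ids), 0)
  has_inverted_repeat <- function(s, stem_min = 15, loop_range = 4:8) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    for (i in seq_len(n - 2 * stem_min - min(loop_range))) {
      for (loop in loop_range) {
        j <- i + stem_min + loop # start of reverse arm
        if (j + stem_min - 1 > n) next
        arm <- substr(s, i, i + stem_min - 1)
        rcarm <- revcomp(arm)
        if (substr(s, j, j + stem_min - 1) == rcarm) return(TRUE)
      }
    }
    FALSE
  }
  for (id in ids[seq_len(min(5, length(ids)))]) {
    s <- u$transcripts$seq[u$transcripts$id == id]
    expect_true(has_inverted_repeat(s), info = id)
  }
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(synth_spec(length_range = c(100L, 500L)), "length_range")
  expect_error(synth_spec(gc_range = c(0.6, 0.2)), "gc_range")
  expect_error(synth_spec(structured_fraction = 1.5), "structured_fraction")
  expect_error(synth_spec(te_density_exon = 0.5, te_density_intron = 0.1),
               "te_density_exon")
  expect_error(synth_spec(expression_tissues = 2), "expression_tissues")
})

test_that("expression recovers the planted distance-bin correlation", {
  # ~200 gene-lincRNA pairs, 10 tissues, nearest-bin correlation 0.8
  spec <- synth_spec(species_count = 2, lincrna_per_species = 100,
                     length_range = c(200L, 300L), family_count = 0,
                     te_density_exon = 0, te_density_intron = 0,
                     expression_tissues = 10,
                     expression_profile = c(`0` = 0.8, `1000` = 0.8,
                                            `5000` = 0.8, `20000` = 0.8,
                                            `100000` = 0.8),
                     seed = 77)
  u <- simulate_universe(spec)
  em <- u$expression
  tcols <- grep("^tissue", names(em), value = TRUE)
  cors <- vapply(seq_len(nrow(u$transcripts)), function(r) {
    a <- as.numeric(em[em$feature_id == u$transcripts$id[r], tcols])
    g <- as.numeric(em[em$feature_id == u$transcripts$nearest_gene_truth[r], tcols])
    cor(a, g)
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.8), 0.1)
  expect_true(all(as.matrix(em[tcols]) >= 0))
})

test_that("all-zero expression profile gives near-zero mean pair correlation", {
  spec <- synth_spec(species_count = 2, lincrna_per_species = 75,
                     length_range = c(200L, 300L), family_count = 0,
                     te_density_exon = 0, te_density_intron = 0,
                     expression_profile = c(`0` = 0, `1000` = 0, `5000` = 0,
                                            `20000` = 0, `100000` = 0),
                     seed = 78)
  u <- simulate_universe(spec)
  em <- u$expression
  tcols <- grep("^tissue", names(em), value = TRUE)
  cors <- vapply(seq_len(nrow(u$transcripts)), function(r) {
    a <- as.numeric(em[em$feature_id == u$transcripts$id[r], tcols])
    g <- as.numeric(em[em$feature_id == u$transcripts$nearest_gene_truth[r], tcols])
    cor(a, g)
  }, numeric(1))
  # mean of ~150 null correlations over 10 tissues: SE ~ 1/sqrt(9*150) ~ 0.03
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("minimal expression case: 1 lincRNA, 3 tissues, finite values", {
  spec <- synth_spec(species_count = 2, lincrna_per_species = 1,
                     family_count = 0, expression_tissues = 3, seed = 79)
  u <- simulate_universe(spec)
  em <- dplyr::filter(u$expression, type == "lincRNA")
  expect_identical(nrow(em), 2L) # one per species
  expect_true(all(is.finite(as.matrix(em[grep("^tissue", names(em))]))))
  expect_error(generate_expression(u, tissues = 2), "tissues")
})

test_that("TE planting respects densities, budgets and saturation", {
  set.seed(55)
  lib <- te_library()
  host <- random_dna(1000)
  # zero density: untouched
  p0 <- plant_te_insertions(host, 0, lib)
  expect_identical(p0$seq, host)
  expect_identical(nrow(p0$features), 0L)
  # 30% target on 1 kb: coverage close to 300 bp
  p30 <- plant_te_insertions(host, 0.30, lib, seed = 1)
  cov <- sum(p30$features$end - p30$features$start)
  expect_lt(abs(cov - 300), 30)
  expect_identical(nchar(p30$seq), 1000L)
  # features are disjoint and within bounds
  f <- p30$features[order(p30$features$start), ]
  expect_true(all(f$start >= 0 & f$end <= 1000))
  if (nrow(f) > 1) expect_true(all(f$start[-1] >= f$end[-nrow(f)]))
  # density 1.0 with a 100 bp library tiles the host exactly
  lib100 <- tibble::tibble(name = "TE100", class = "DNA", seq = random_dna(100))
  pf <- plant_te_insertions(random_dna(1000), 1.0, lib100, seed = 2)
  expect_identical(sum(pf$features$end - pf$features$start), 1000)
  expect_identical(nrow(pf$features), 10L)
  # empty library with nonzero density errors
  expect_error(plant_te_insertions(host, 0.2, lib[0, ]), "library")
})

test_that("exon TE coverage is planted below intron coverage", {
  u <- simulate_universe(synth_spec(species_count = 2, lincrna_per_species = 40,
                                    length_range = c(900L, 1400L),
                                    family_count = 0, structured_fraction = 0,
                                    te_density_exon = 0.05,
                                    te_density_intron = 0.30, seed = 91))
  cov <- repeat_overlap(u$transcripts, u$repeats)
  tot <- dplyr::filter(cov, class == "total")
  ex <- dplyr::filter(tot, compartment == "exon")$fraction
  intr <- dplyr::filter(tot, compartment == "intron")$fraction
  expect_gt(length(intr), 10)
  expect_lt(mean(ex), mean(intr))
})

test_that("repeatmasker .out round-trip preserves intervals and classes", {
  u <- simulate_universe(small_spec(seed = 12))
  d <- withr_tempdir()
  on.exit(unlink(d, recursive = TRUE))
  sp <- "species01"
  write_repeatmasker_out(dplyr::filter(u$repeats, species == sp),
                         file.path(d, "r.out"))
  back <- read_repeatmasker_out(file.path(d, "r.out"))
  orig <- dplyr::filter(u$repeats, species == sp)
  expect_identical(nrow(back), nrow(orig))
  expect_identical(back$start, orig$start)
  expect_identical(back$end, orig$end)
  expect_identical(back$class, orig$class)
  # class collapsing handles full family strings
  expect_identical(
    suppressMessages(collapse_repeat_class(c("LTR/Gypsy", "DNA/hAT", "Weird"))),
    c("LTR", "DNA", "other"))
})
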