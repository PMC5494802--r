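# Interval analyses: intergenic filtering, repeat coverage, closest genes,
# GO enrichment, expression-distance profiles, chromosomal density.

test_that("intergenic filter removes genic-span overlaps only", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(1000, 5000), end = c(3000, 6000))
  mk <- function(id, start, end) tibble::tibble(
    id = id, species = "sp", chrom = "chr1", strand = "+", biotype = "lincRNA",
    exons = list(tibble::tibble(start = start, end = end)),
    seq = strrep("A", sum(end - start)))
  # transcript inside the gene's intron region (within its span): removed
  inside <- mk("inside", 1500, 1800)
  # 1 bp downstream of the gene end: retained
  downstream <- mk("downstream", 3001, 3400)
  out <- intergenic_filter(dplyr::bind_rows(inside, downstream), genes)
  expect_identical(out$retained$id, "downstream")
  expect_identical(out$removed$id, "inside")
  expect_identical(out$removed$overlapping_gene, "g1")
  d <- closest_gene(out$retained, genes)
  expect_identical(d$distance_bp, 1)
})

test_that("planted genic overlaps are filtered at the exact truth rate", {
  set.seed(81)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                          start = seq(0, 19) * 10000,
                          end = seq(0, 19) * 10000 + 2000)
  overlap_truth <- runif(100) < 0.2
  tx <- purrr::list_rbind(lapply(1:100, function(i) {
    if (overlap_truth[i]) {
      g <- sample(20, 1)
      start <- genes$start[g] + sample(0:1500, 1)
    } else {
      g <- sample(20, 1)
      start <- genes$end[g] + sample(1000:6000, 1)
    }
    tibble::tibble(id = paste0("t", i), species = "sp", chrom = "chr1",
                   strand = "+", biotype = "lincRNA",
                   exons = list(tibble::tibble(start = start, end = start + 400)),
                   seq = strrep("A", 400))
  }))
  out <- intergenic_filter(tx, genes)
  expect_identical(nrow(out$retained), sum(!overlap_truth))
})

test_that("repeat coverage merges overlaps and never double-counts", {
  tx <- tibble::tibble(id = "t", species = "sp", chrom = "chr1", strand = "+",
                       biotype = "lincRNA",
                       exons = list(tibble::tibble(start = 100, end = 200)),
                       seq = strrep("A", 100))
  # one repeat half-overlapping the exon
  r1 <- tibble::tibble(chrom = "chr1", species = "sp", start = 150, end = 250,
                       class = "LINE", name = "L", divergence_pct = 1)
  cov <- repeat_overlap(tx, r1)
  expect_equal(dplyr::filter(cov, class == "LINE")$fraction, 0.5)
  # two overlapping repeats tiling the exon: merged coverage 1.0
  r2 <- tibble::tibble(chrom = "chr1", species = "sp",
                       start = c(100, 140), end = c(160, 200),
                       class = "DNA", name = "D", divergence_pct = 1)
  cov2 <- repeat_overlap(tx, r2)
  expect_equal(dplyr::filter(cov2, class == "DNA")$fraction, 1)
  expect_equal(dplyr::filter(cov2, class == "total")$fraction, 1)
  # idempotence: merging the repeat track first changes nothing
  r2m <- tibble::tibble(chrom = "chr1", species = "sp", start = 100, end = 200,
                        class = "DNA", name = "D", divergence_pct = 1)
  expect_equal(dplyr::filter(repeat_overlap(tx, r2m), class == "DNA")$fraction,
               dplyr::filter(cov2, class == "DNA")$fraction)
})

test_that("TE content comparison finds planted class-specific enrichment", {
  set.seed(82)
  # two groups of transcripts; group A has 3x LTR coverage, equal SINE
  mkcov <- function(ids, ltr, sine) {
    purrr::list_rbind(lapply(ids, function(id) tibble::tibble(
      id = id, species = "sp", compartment = "exon",
      class = c("LTR", "SINE"),
      covered = NA_real_, length = 1000,
      fraction = c(max(0, rnorm(1, ltr, 0.01)), max(0, rnorm(1, sine, 0.01))))))
  }
  cov <- dplyr::bind_rows(mkcov(sprintf("a%02d", 1:30), 0.06, 0.02),
                          mkcov(sprintf("b%02d", 1:30), 0.02, 0.02))
  res <- compare_te_content(cov, set_a = sprintf("a%02d", 1:30))
  ltr <- dplyr::filter(res, class == "LTR")
  sine <- dplyr::filter(res, class == "SINE")
  expect_lt(ltr$t_q, 0.05)
  expect_gt(sine$t_q, 0.05)
  # identical sets: p ~ 1, effect ~ 0
  same <- compare_te_content(dplyr::bind_rows(mkcov(sprintf("c%02d", 1:20), 0.03, 0.02),
                                              mkcov(sprintf("d%02d", 1:20), 0.03, 0.02)),
                             set_a = sprintf("c%02d", 1:20))
  expect_gt(min(same$t_p, na.rm = TRUE), 0.01)
  # all-zero coverage: degenerate flag, no test
  zero <- dplyr::bind_rows(mkcov(sprintf("e%02d", 1:10), 0, 0),
                           mkcov(sprintf("f%02d", 1:10), 0, 0))
  zero$fraction <- 0
  zres <- compare_te_content(zero, set_a = sprintf("e%02d", 1:10))
  expect_true(all(zres$degenerate))
  expect_error(compare_te_content(cov, set_a = "a01"), ">= 3")
})

test_that("closest gene matches the brute-force all-pairs scan", {
  # worked example: gene [0,100), lincRNA [150,300), gene [400,500)
  genes <- tibble::tibble(gene_id = c("gL", "gR"), chrom = "c",
                          start = c(0, 400), end = c(100, 500))
  tx <- tibble::tibble(id = "t", species = "sp", chrom = "c", strand = "+",
                       biotype = "lincRNA",
                       exons = list(tibble::tibble(start = 150, end = 300)),
                       seq = strrep("A", 150))
  got <- closest_gene(tx, genes)
  expect_identical(got$nearest_gene_id, "gL")
  expect_identical(got$distance_bp, 50)
  # equidistant genes: deterministic tie-break by smaller start
  genes_tie <- tibble::tibble(gene_id = c("gB", "gA"), chrom = "c",
                              start = c(400, 0), end = c(500, 100))
  tx_mid <- tibble::tibble(id = "m", species = "sp", chrom = "c", strand = "+",
                           biotype = "lincRNA",
                           exons = list(tibble::tibble(start = 200, end = 300)),
                           seq = strrep("A", 100))
  expect_identical(closest_gene(tx_mid, genes_tie)$nearest_gene_id, "gA")
  # randomized layout vs exhaustive oracle
  set.seed(83)
  genes_r <- tibble::tibble(gene_id = sprintf("g%03d", 1:40),
                            chrom = sample(c("c1", "c2"), 40, TRUE),
                            start = sample.int(1e6, 40))
  genes_r$end <- genes_r$start + sample(500:3000, 40, TRUE)
  tx_r <- purrr::list_rbind(lapply(1:30, function(i) {
    st <- sample.int(1e6, 1)
    tibble::tibble(id = paste0("t", i), species = "sp",
                   chrom = sample(c("c1", "c2"), 1), strand = "+",
                   biotype = "lincRNA",
                   exons = list(tibble::tibble(start = st, end = st + 300)),
                   seq = strrep("A", 300))
  }))
  got <- closest_gene(tx_r, genes_r)
  for (i in seq_len(nrow(tx_r))) {
    g <- genes_r[genes_r$chrom == tx_r$chrom[i], ]
    span <- linctools:::tx_span(tx_r[i, ])
    dists <- vapply(seq_len(nrow(g)), function(k) {
      max(0, g$start[k] - span$end, span$start - g$end[k])
    }, numeric(1))
    expect_equal(got$distance_bp[i], min(dists))
    # distance measured from the gene side agrees
    gi <- match(got$nearest_gene_id[i], genes_r$gene_id)
    expect_equal(got$distance_bp[i],
                 max(0, genes_r$start[gi] - span$end, span$start - genes_r$end[gi]))
  }
  # transcript alone on a chromosome
  lonely <- tx_r[1, ]; lonely$chrom <- "c9"
  expect_true(closest_gene(lonely, genes_r)$no_neighbor)
})

test_that("Fisher enrichment equals exhaustive hypergeometric tail sums", {
  # worked 2x2: 10 FG-with, 40 FG-without, 50 BG-with total, 900 BG-without
  ann <- tibble::tibble(
    gene_id = c(sprintf("fg%02d", 1:10), sprintf("bg%03d", 1:40)),
    term = "GO:X")
  fg <- c(sprintf("fg%02d", 1:10), sprintf("oth%02d", 1:40))
  bg <- c(ann$gene_id, sprintf("oth%02d", 1:40), sprintf("rest%03d", 1:860))
  res <- go_enrichment(fg, bg, ann, ontology = NULL)
  # brute-force tail: sum over k >= 10 of choose(K,k) choose(N-K,n-k)/choose(N,n)
  N <- 950; K <- 50; n <- 50
  want <- sum(vapply(10:min(K, n), function(k)
    choose(K, k) * choose(N - K, n - k), numeric(1))) / choose(N, n)
  expect_equal(res$p_value, want, tolerance = 1e-12)
  # random tables vs brute force
  set.seed(84)
  for (rep in 1:25) {
    N <- sample(50:1000, 1)
    K <- sample(5:(N / 2), 1)
    n <- sample(5:(N / 2), 1)
    k <- sample(0:min(K, n), 1)
    got <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    want <- sum(vapply(k:min(K, n), function(kk)
      choose(K, kk) * choose(N - K, n - kk), numeric(1))) / choose(N, n)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("GO enrichment handles closure, planted signal and the fg = bg null", {
  onto <- go_mini_ontology()
  set.seed(85)
  genes <- sprintf("g%03d", 1:200)
  ann <- purrr::list_rbind(lapply(genes, function(g)
    tibble::tibble(gene_id = g, term = sample(onto$leaves, 2))))
  # fg = bg -> all p = 1
  res0 <- go_enrichment(genes, genes, ann, onto)
  expect_true(all(res0$p_value == 1))
  # planted: term painted on the foreground genes ranks first
  fg <- sprintf("g%03d", 1:25)
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(gene_id = fg, term = "GO:0000166"))
  res <- go_enrichment(fg, genes, ann2, onto)
  expect_identical(res$term[1], "GO:0000166")
  # ancestor closure: parents of the planted term are enriched too
  expect_true("GO:0043167" %in% res$term)
  expect_error(go_enrichment(character(0), genes, ann), "empty")
  expect_error(go_enrichment("zzz", genes, ann), "subset")
})

test_that("expression-distance profile recovers planted decay and nulls", {
  set.seed(86)
  n_pairs <- 120
  dists <- c(runif(40, 0, 900), runif(40, 1500, 4500), runif(40, 6000, 19000))
  rho_of <- function(d) c(0.8, 0.3, 0)[findInterval(d, c(0, 1000, 5000))]
  tiss <- sprintf("tissue%02d", 1:10)
  feats <- list(); ctx_rows <- list()
  for (i in seq_len(n_pairs)) {
    g <- rnorm(10); e <- rnorm(10)
    rho <- rho_of(dists[i])
    l <- rho * g + sqrt(1 - rho^2) * e
    feats[[length(feats) + 1]] <- tibble::tibble(feature_id = paste0("g", i),
                                                 !!!setNames(as.list(10 + 2 * g), tiss))
    feats[[length(feats) + 1]] <- tibble::tibble(feature_id = paste0("l", i),
                                                 !!!setNames(as.list(10 + 2 * l), tiss))
    ctx_rows[[i]] <- tibble::tibble(id = paste0("l", i),
                                    nearest_gene_id = paste0("g", i),
                                    distance_bp = dists[i])
  }
  em <- purrr::list_rbind(feats)
  ctx <- purrr::list_rbind(ctx_rows)
  prof <- expression_distance_profile(ctx, em, seed = 1)
  expect_identical(nrow(prof), 3L)
  expect_true(all(diff(prof$mean_cor) < 0))
  expect_lt(abs(prof$mean_cor[1] - 0.8), 0.12)
  # shuffled pairing: flat near-zero profile
  ctx_shuf <- ctx
  ctx_shuf$nearest_gene_id <- sample(ctx$nearest_gene_id)
  prof0 <- expression_distance_profile(ctx_shuf, em, seed = 2)
  expect_true(all(abs(prof0$mean_cor) < 0.25))
  # single pair: degenerate CI
  p1 <- expression_distance_profile(ctx[1, ], em, seed = 3)
  expect_true(p1$degenerate)
  # zero-variance features are excluded and counted
  em0 <- em; em0[em0$feature_id == "g1", tiss] <- 5
  pz <- expression_distance_profile(ctx, em0, seed = 4)
  expect_identical(attr(pz, "n_excluded"), 1L)
})

test_that("chromosomal density flags planted hotspots but not uniform layouts", {
  set.seed(87)
  lens <- c(chrA = 2e6, chrB = 2e6, chrC = 2e6)
  mk_tx <- function(chrom, pos) {
    purrr::list_rbind(purrr::map2(chrom, pos, function(ch, p) tibble::tibble(
      id = paste0(ch, "_", p), species = "sp", chrom = ch, strand = "+",
      biotype = "lincRNA",
      exons = list(tibble::tibble(start = p, end = p + 500)),
      seq = strrep("A", 500))))
  }
  # uniform placement: flagged windows within FDR expectation
  uni <- mk_tx(sample(names(lens), 120, TRUE),
               sample.int(1.9e6, 120))
  du <- chromosomal_density(uni, lens)
  expect_lte(sum(du$windows$flag), ceiling(0.1 * nrow(du$windows)))
  expect_gt(du$chisq_p, 1e-3)
  # everything on one arm: that region flagged, chi-square rejects
  hot <- mk_tx(rep("chrA", 80), sample.int(4e5, 80))
  dh <- chromosomal_density(hot, lens)
  expect_true(any(dh$windows$flag[dh$windows$chrom == "chrA"]))
  expect_lt(dh$chisq_p, 1e-6)
  # empty set
  de <- chromosomal_density(uni[0, ], lens)
  expect_identical(nrow(de$windows), 0L)
  # window larger than chromosome: single window
  tiny <- chromosomal_density(uni, c(chrA = 2e6, chrB = 2e6, chrC = 2e6),
                              window = 1e7)
  expect_identical(nrow(tiny$windows), 3L)
})
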