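# Genomic-context analyses: intergenic filtering, repeat overlap by
# compartment and class, closest-gene distances, GO enrichment of nearby
# genes, expression-distance profiles, and chromosomal density.

#' Default gene-lincRNA distance bins (bp lower edges)
#' @return Numeric vector of bin lower edges.
#' @export
default_distance_bins <- function() c(0, 1000, 5000, 20000, 100000)

#' Keep only fully intergenic transcripts
#'
#' Removes every transcript whose genomic span shares any base with an
#' annotated protein-coding gene span (either strand, introns included) —
#' the span-overlap semantics of the assembler's intergenic class code.
#'
#' @param tx Transcript tibble.
#' @param genes Gene tibble: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return List: `retained` (transcript tibble), `removed` (tibble `id`,
#'   `overlapping_gene`).
#' @export
intergenic_filter <- function(tx, genes) {
  if (nrow(tx) == 0) return(list(retained = tx, removed = tibble(id = character(0), overlapping_gene = character(0))))
  if (nrow(genes) > 0 &&
      length(intersect(unique(tx$chrom), unique(genes$chrom))) == 0) {
    warn("no chromosome names shared between transcripts and gene annotation")
  }
  span <- tx_span(tx)
  removed <- list()
  keep <- rep(TRUE, nrow(tx))
  for (r in seq_len(nrow(tx))) {
    g <- genes[genes$chrom == tx$chrom[r] &
                 genes$start < span$end[r] & genes$end > span$start[r], ]
    if (nrow(g) > 0) {
      keep[r] <- FALSE
      removed[[length(removed) + 1]] <- tibble(id = tx$id[r],
                                               overlapping_gene = g$gene_id[1])
    }
  }
  list(retained = tx[keep, ],
       removed = if (length(removed)) purrr::list_rbind(removed) else
         tibble(id = character(0), overlapping_gene = character(0)))
}

merged_overlap_width <- function(a_start, a_end, b_start, b_end) {
  # total bases of [a] covered by union of [b] intervals
  if (length(b_start) == 0) return(0)
  ir_a <- IRanges::IRanges(start = a_start + 1, end = a_end)
  ir_b <- IRanges::reduce(IRanges::IRanges(start = b_start + 1, end = b_end))
  sum(IRanges::width(IRanges::intersect(ir_a, ir_b)))
}

#' Repeat coverage per transcript, class and compartment
#'
#' Coverage is merged-overlap base count divided by compartment length
#' (overlapping repeat copies are never double-counted). Exons and introns
#' are disjoint compartments; per-class rows are reported alongside a
#' `total` row per compartment.
#'
#' @param tx Transcript tibble.
#' @param repeats Repeat tibble: `chrom`, `start`, `end`, `class`
#'   (optionally `species`, matched against `tx$species` when present).
#' @return Tibble: `id`, `species`, `compartment` (exon/intron), `class`
#'   (repeat class or "total"), `covered`, `length`, `fraction`.
#' @export
repeat_overlap <- function(tx, repeats) {
  classes <- c("DNA", "LINE", "SINE", "LTR", "simple_repeat", "low_complexity", "other")
  rows <- list()
  for (r in seq_len(nrow(tx))) {
    rp <- repeats[repeats$chrom == tx$chrom[r], ]
    if ("species" %in% names(repeats) && "species" %in% names(tx)) {
      rp <- rp[rp$species == tx$species[r], ]
    }
    ex <- tx$exons[[r]]
    intr <- tx_introns(ex)
    for (comp in c("exon", "intron")) {
      iv <- if (comp == "exon") ex else intr
      L <- sum(iv$end - iv$start)
      if (L == 0) next
      for (cls in c(classes, "total")) {
        sel <- if (cls == "total") rp else rp[rp$class == cls, ]
        cov <- sum(vapply(seq_len(nrow(iv)), function(k) {
          merged_overlap_width(iv$start[k], iv$end[k], sel$start, sel$end)
        }, numeric(1)))
        rows[[length(rows) + 1]] <- tibble(
          id = tx$id[r],
          species = if ("species" %in% names(tx)) tx$species[r] else NA_character_,
          compartment = comp, class = cls,
          covered = cov, length = L, fraction = cov / L)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(id = character(0), species = character(0),
                  compartment = character(0), class = character(0),
                  covered = numeric(0), length = numeric(0), fraction = numeric(0)))
  }
  purrr::list_rbind(rows)
}

#' Compare repeat content between two transcript sets
#'
#' Per repeat class, a two-sample location test on per-transcript exonic
#' coverage fractions between set A and set B (defaulting to A vs not-A).
#' Both Welch's t and the Wilcoxon rank-sum statistic are emitted, with
#' Benjamini-Hochberg adjustment across classes.
#'
#' @param coverage Output of [repeat_overlap()] (exon compartment is used).
#' @param set_a Ids of the first set (e.g. structured lincRNAs).
#' @param set_b Ids of the second set; defaults to all other ids.
#' @param compartment Compartment to compare (default "exon").
#' @return Tibble per class: means, `t_p`, `wilcox_p`, BH-adjusted
#'   columns, `degenerate` flag (all-zero coverage in both sets).
#' @export
compare_te_content <- function(coverage, set_a, set_b = NULL,
                               compartment = "exon") {
  cov <- filter(coverage, compartment == !!compartment, class != "total")
  if (is.null(set_b)) set_b <- setdiff(unique(cov$id), set_a)
  if (length(set_a) < 3 || length(set_b) < 3) abort("each set needs >= 3 members")
  rows <- cov |>
    group_by(class) |>
    group_map(function(d, key) {
      a <- d$fraction[d$id %in% set_a]
      b <- d$fraction[d$id %in% set_b]
      if (length(a) < 3 || length(b) < 3 || (all(a == 0) && all(b == 0)) ||
          (sd(a) == 0 && sd(b) == 0)) {
        return(tibble(class = key$class, mean_a = mean(a), mean_b = mean(b),
                      t_p = NA_real_, wilcox_p = NA_real_, degenerate = TRUE))
      }
      tibble(class = key$class, mean_a = mean(a), mean_b = mean(b),
             t_p = tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_),
             wilcox_p = suppressWarnings(wilcox.test(a, b)$p.value),
             degenerate = FALSE)
    }) |> purrr::list_rbind()
  rows$t_q <- p.adjust(rows$t_p, "BH")
  rows$wilcox_q <- p.adjust(rows$wilcox_p, "BH")
  rows
}

#' Closest gene per transcript
#'
#' Nearest protein-coding gene by genomic gap on the same chromosome,
#' strand-agnostic; distance 0 when the spans overlap. Equidistant genes
#' are broken deterministically by smaller gene start, then gene id.
#' Transcripts alone on their chromosome get `nearest_gene_id = NA` and
#' `no_neighbor = TRUE`.
#'
#' @param tx Transcript tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @return Tibble: `id`, `nearest_gene_id`, `distance_bp`, `no_neighbor`.
#' @export
closest_gene <- function(tx, genes) {
  span <- tx_span(tx)
  rows <- lapply(seq_len(nrow(tx)), function(r) {
    g <- genes[genes$chrom == tx$chrom[r], ]
    if ("species" %in% names(genes) && "species" %in% names(tx)) {
      g <- g[g$species == tx$species[r], ]
    }
    if (nrow(g) == 0) {
      return(tibble(id = tx$id[r], nearest_gene_id = NA_character_,
                    distance_bp = NA_real_, no_neighbor = TRUE))
    }
    d <- pmax(0, pmax(g$start - span$end[r], span$start[r] - g$end))
    ord <- order(d, g$start, g$gene_id)
    tibble(id = tx$id[r], nearest_gene_id = g$gene_id[ord[1]],
           distance_bp = d[ord[1]], no_neighbor = FALSE)
  })
  purrr::list_rbind(rows)
}

# Ancestor closure over a parent-pointer term table.
go_ancestor_closure <- function(terms, ontology) {
  parents <- setNames(ontology$terms$parent, ontology$terms$term)
  out <- unique(terms)
  repeat {
    up <- stats::na.omit(unname(parents[out]))
    new <- setdiff(up, out)
    if (length(new) == 0) break
    out <- c(out, new)
  }
  out
}

#' GO term enrichment by Fisher's exact test
#'
#' One-sided (over-representation) Fisher's exact test per term — the
#' hypergeometric upper tail — comparing a foreground gene set against a
#' background, after ancestor closure of the annotation. Terms absent from
#' the foreground are omitted; p-values are BH-adjusted.
#'
#' @param foreground,background Gene id vectors (foreground must be a
#'   subset of background).
#' @param annotation Tibble `gene_id`, `term` (direct annotations).
#' @param ontology Ontology as from [go_mini_ontology()] (list with
#'   `terms` tibble `term`, `parent`); NULL skips ancestor closure.
#' @return Tibble: `term`, `fg_with`, `fg_size`, `bg_with`, `bg_size`,
#'   `fold_enrichment`, `p_value`, `q_value`.
#' @export
go_enrichment <- function(foreground, background, annotation,
                          ontology = go_mini_ontology()) {
  if (length(foreground) == 0) abort("empty foreground")
  if (!all(foreground %in% background)) abort("foreground must be a subset of background")
  ann <- annotation |> filter(gene_id %in% background) |> distinct()
  if (!is.null(ontology)) {
    ann <- ann |> group_by(gene_id) |>
      reframe(term = go_ancestor_closure(term, ontology))
  }
  N <- length(unique(background))
  n_fg <- length(unique(foreground))
  rows <- ann |> group_by(term) |>
    summarise(bg_with = n_distinct(gene_id),
              fg_with = n_distinct(intersect(gene_id, foreground)),
              .groups = "drop") |>
    filter(fg_with > 0)
  rows |>
    mutate(fg_size = n_fg, bg_size = N,
           fold_enrichment = (fg_with / n_fg) / (bg_with / N),
           p_value = phyper(fg_with - 1, bg_with, N - bg_with, n_fg,
                            lower.tail = FALSE),
           q_value = p.adjust(p_value, "BH")) |>
    arrange(p_value)
}

#' Expression correlation of gene-lincRNA pairs by distance bin
#'
#' For every transcript with a neighboring gene, the Pearson correlation
#' of their expression across tissues is computed, pairs are binned by
#' genomic distance, and the per-bin mean with a bootstrap confidence
#' interval is returned. Pairs with zero-variance expression are excluded
#' and counted.
#'
#' @param context Output of [closest_gene()] (or any tibble with `id`,
#'   `nearest_gene_id`, `distance_bp`).
#' @param expression Expression tibble (`feature_id` + tissue columns).
#' @param bins Distance bin lower edges (default
#'   [default_distance_bins()]).
#' @param n_boot Bootstrap replicates for the CI (default 200).
#' @param seed Optional seed for the bootstrap.
#' @return Tibble per bin: `bin`, `n_pairs`, `mean_cor`, `ci_lo`, `ci_hi`
#'   (`degenerate` TRUE when a single pair), plus attribute
#'   `n_excluded` (zero-variance pairs).
#' @export
expression_distance_profile <- function(context, expression,
                                        bins = default_distance_bins(),
                                        n_boot = 200, seed = NULL) {
  tcols <- grep("^tissue", names(expression), value = TRUE)
  if (length(tcols) < 3) abort("need >= 3 tissues")
  em <- as.matrix(expression[, tcols])
  rownames(em) <- expression$feature_id
  ctx <- filter(context, !is.na(nearest_gene_id),
                id %in% rownames(em), nearest_gene_id %in% rownames(em))
  n_excluded <- 0L
  cors <- numeric(0); dists <- numeric(0)
  for (r in seq_len(nrow(ctx))) {
    a <- em[ctx$id[r], ]; b <- em[ctx$nearest_gene_id[r], ]
    if (sd(a) == 0 || sd(b) == 0) { n_excluded <- n_excluded + 1L; next }
    cors <- c(cors, cor(a, b))
    dists <- c(dists, ctx$distance_bp[r])
  }
  bin_idx <- findInterval(dists, bins)
  out <- with_seed(seed, purrr::list_rbind(lapply(sort(unique(bin_idx)), function(bi) {
    v <- cors[bin_idx == bi]
    if (length(v) == 1) {
      return(tibble(bin = bins[bi], n_pairs = 1L, mean_cor = v,
                    ci_lo = NA_real_, ci_hi = NA_real_, degenerate = TRUE))
    }
    boots <- vapply(seq_len(n_boot), function(i) mean(sample(v, replace = TRUE)),
                    numeric(1))
    tibble(bin = bins[bi], n_pairs = length(v), mean_cor = mean(v),
           ci_lo = unname(quantile(boots, 0.025)),
           ci_hi = unname(quantile(boots, 0.975)), degenerate = FALSE)
  })))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Chromosomal density of transcripts
#'
#' Counts transcripts per fixed window, tests the per-chromosome totals
#' against a length-proportional expectation (chi-square goodness of fit),
#' and flags windows whose counts deviate from the uniform rate (binomial
#' test, BH-adjusted at 0.05).
#'
#' @param tx Transcript tibble.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window Window size in bp (default 1e6); chromosomes shorter than
#'   one window form a single window.
#' @return List: `windows` (tibble `chrom`, `win_start`, `count`,
#'   `p_value`, `q_value`, `flag`), `chromosomes` (per-chromosome counts
#'   and expected), `chisq_p` (overall uniformity).
#' @export
chromosomal_density <- function(tx, chrom_lengths, window = 1e6) {
  if (nrow(tx) == 0) {
    return(list(windows = tibble(chrom = character(0), win_start = numeric(0),
                                 count = integer(0), p_value = numeric(0),
                                 q_value = numeric(0), flag = logical(0)),
                chromosomes = tibble(chrom = names(chrom_lengths),
                                     length = unname(chrom_lengths), count = 0L),
                chisq_p = NA_real_))
  }
  span <- tx_span(tx)
  mid <- (span$start + span$end) / 2
  wins <- purrr::list_rbind(lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, L - 1), by = window)
    tibble(chrom = ch, win_start = starts,
           win_end = pmin(starts + window, L))
  }))
  wins$count <- vapply(seq_len(nrow(wins)), function(w) {
    sum(tx$chrom == wins$chrom[w] & mid >= wins$win_start[w] & mid < wins$win_end[w])
  }, integer(1))
  n <- nrow(tx)
  wins$expected <- (wins$win_end - wins$win_start) / sum(chrom_lengths) * n
  wins$p_value <- vapply(seq_len(nrow(wins)), function(w) {
    binom.test(wins$count[w], n, wins$expected[w] / n)$p.value
  }, numeric(1))
  wins$q_value <- p.adjust(wins$p_value, "BH")
  wins$flag <- wins$q_value < 0.05
  chroms <- tibble(chrom = names(chrom_lengths),
                   length = unname(chrom_lengths)) |>
    mutate(count = vapply(chrom, function(ch) sum(tx$chrom == ch), integer(1)),
           expected = length / sum(length) * n)
  chisq_p <- suppressWarnings(
    chisq.test(chroms$count, p = chroms$length / sum(chroms$length))$p.value)
  list(windows = select(wins, chrom, win_start, count, expected, p_value,
                        q_value, flag),
       chromosomes = chroms, chisq_p = chisq_p)
}

#' Boxplot-style GC comparison across compartments
#' @param gc_table Output of [compartment_gc()].
#' @return A ggplot object.
#' @export
plot_gc_compartments <- function(gc_table) {
  ggplot2::ggplot(gc_table, ggplot2::aes(x = compartment, y = gc)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(y = "GC fraction", x = NULL)
}

#' Repeat coverage comparison by compartment
#' @param coverage Output of [repeat_overlap()].
#' @return A ggplot object.
#' @export
plot_te_content <- function(coverage) {
  df <- filter(coverage, class == "total")
  ggplot2::ggplot(df, ggplot2::aes(x = compartment, y = fraction)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(y = "TE-covered fraction", x = NULL)
}

#' Expression-distance profile plot
#' @param profile Output of [expression_distance_profile()].
#' @return A ggplot object.
#' @export
plot_expression_distance <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = factor(bin), y = mean_cor)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_lo, ymax = ci_hi), width = 0.2) +
    ggplot2::labs(x = "distance bin lower edge (bp)",
                  y = "mean gene-lincRNA expression correlation")
}
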