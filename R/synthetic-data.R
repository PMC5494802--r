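# Synthetic multi-species universes with planted, known signal.
#
# The generator emits genomes, gene and lincRNA annotations, repeat tracks
# and tissue expression whose statistical structure matches what every
# downstream stage assumes: per-transcript GC drawn from a configured range,
# a fraction of lincRNAs carrying a planted stable hairpin, homolog families
# at controlled divergence spanning species, transposable-element insertions
# with exon-vs-intron density asymmetry, gene neighborhoods with GO labels,
# and expression whose gene-lincRNA correlation decays with distance.
# Everything is deterministic given the spec seed, and the "planted truth"
# is returned alongside so recovery can be scored exactly.

#' Specification for a synthetic universe
#'
#' Defaults describe a small comparative study: three species, one hundred
#' lincRNAs each, lincRNA lengths 200-1500 nt (medians in real insect sets
#' fall between ~550 and ~1000 nt), intergenic-like GC 0.30-0.45, 10% of
#' lincRNAs structured, ten homolog families at 5% divergence, and a
#' depletion of transposable elements in exons (5%) relative to introns
#' (30%).
#'
#' @param species_count Number of species (>= 1).
#' @param lincrna_per_species lincRNAs per species.
#' @param gc_range Two fractions in \[0,1\]: per-transcript GC is uniform in
#'   this range.
#' @param length_range Two integers, min >= 200 (lincRNAs are defined as
#'   transcripts longer than 200 nt).
#' @param structured_fraction Fraction of lincRNAs with a planted hairpin
#'   (perfect inverted repeat, stem 15-40 bp, loop 4-8 nt).
#' @param family_count Planted homolog families (each >= 2 members spanning
#'   >= 2 species).
#' @param family_divergence Per-site substitution probability within a
#'   family in \[0,1\]; 1-2 short indels are added above 0.1.
#' @param te_density_exon,te_density_intron Expected fraction of bases
#'   covered by TE insertions per compartment; exon density must not exceed
#'   intron density (the generator plants depletion, not enrichment).
#' @param expression_tissues Number of tissues (>= 3).
#' @param expression_profile Named numeric vector of target gene-lincRNA
#'   expression correlations per distance bin (names are bin lower edges in
#'   bp, matching [default_distance_bins()]).
#' @param seed Integer RNG seed.
#' @return A validated `synth_spec` list.
#' @export
synth_spec <- function(species_count = 3, lincrna_per_species = 100,
                       gc_range = c(0.30, 0.45), length_range = c(200L, 1500L),
                       structured_fraction = 0.1, family_count = 10,
                       family_divergence = 0.05,
                       te_density_exon = 0.05, te_density_intron = 0.30,
                       expression_tissues = 10,
                       expression_profile = c(`0` = 0.5, `1000` = 0.3,
                                              `5000` = 0.1, `20000` = 0, `100000` = 0),
                       seed = 1L) {
  species_count <- assert_count(species_count, "species_count", 1L)
  lincrna_per_species <- assert_count(lincrna_per_species, "lincrna_per_species", 1L)
  assert_fraction(gc_range, "gc_range")
  if (length(gc_range) != 2 || gc_range[1] > gc_range[2]) abort("`gc_range` must be (lo, hi)")
  if (length(length_range) != 2 || length_range[1] < 200)
    abort("`length_range` minimum must be >= 200 (lincRNA length definition)")
  assert_fraction(structured_fraction, "structured_fraction")
  family_count <- assert_count(family_count, "family_count", 0L)
  assert_fraction(family_divergence, "family_divergence")
  assert_fraction(te_density_exon, "te_density_exon")
  assert_fraction(te_density_intron, "te_density_intron")
  if (te_density_exon > te_density_intron)
    abort("`te_density_exon` must be <= `te_density_intron` (planted depletion)")
  expression_tissues <- assert_count(expression_tissues, "expression_tissues", 3L)
  assert_fraction(abs(expression_profile), "expression_profile")
  structure(list(
    species_count = species_count, lincrna_per_species = lincrna_per_species,
    gc_range = gc_range, length_range = as.integer(length_range),
    structured_fraction = structured_fraction, family_count = family_count,
    family_divergence = family_divergence,
    te_density_exon = te_density_exon, te_density_intron = te_density_intron,
    expression_tissues = expression_tissues,
    expression_profile = expression_profile,
    seed = as.integer(seed)), class = "synth_spec")
}

random_dna_gc <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Synthetic transposable-element consensus library
#'
#' Five canonical consensus sequences, one per repeat class (DNA, LINE,
#' LTR, SINE, simple_repeat), 80-500 bp. The library is deterministic; TE
#' copies placed by the generator are mutated at 5% per site.
#'
#' @return Tibble: `name`, `class`, `seq`.
#' @export
te_library <- function() {
  with_seed(990331, {
    tibble(
      name = c("DNA-1_synth", "LINE-1_synth", "LTR-1_synth", "SINE-1_synth",
               "SR-1_synth"),
      class = c("DNA", "LINE", "LTR", "SINE", "simple_repeat"),
      seq = c(random_dna_gc(300, 0.40), random_dna_gc(500, 0.42),
              random_dna_gc(400, 0.48), random_dna_gc(150, 0.45),
              strrep("ACGGT", 16)))
  })
}

# Mutate a sequence at `rate` per site (substitutions to a different base).
mutate_sites <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  ch <- seq_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

# Apply 1-2 short indels (<= 10 bp) to a sequence, keeping length >= 200.
apply_indels <- function(seq, n_indels) {
  for (k in seq_len(n_indels)) {
    len <- sample(1:10, 1)
    if (runif(1) < 0.5 && nchar(seq) - len >= 200) {
      pos <- sample.int(nchar(seq) - len, 1)
      seq <- paste0(substr(seq, 1, pos), substr(seq, pos + len + 1, nchar(seq)))
    } else {
      pos <- sample.int(nchar(seq), 1)
      seq <- paste0(substr(seq, 1, pos), random_dna_gc(len, 0.5),
                    substr(seq, pos + 1, nchar(seq)))
    }
  }
  seq
}

# Plant one perfect inverted repeat (stem 15-40 bp, loop 4-8 nt) at a
# uniform random position, overwriting background (length preserved).
plant_hairpin <- function(seq) {
  stem <- sample(15:40, 1)
  loop <- sample(4:8, 1)
  hp_len <- 2 * stem + loop
  if (nchar(seq) < hp_len + 2) {
    stem <- max(15L, (nchar(seq) - 8L) %/% 2L - 1L)
    loop <- 4L
    hp_len <- 2 * stem + loop
  }
  arm <- random_dna_gc(stem, 0.6)
  hp <- paste0(arm, random_dna_gc(loop, 0.4), revcomp(arm))
  pos <- sample.int(nchar(seq) - hp_len + 1, 1) - 1
  paste0(substr(seq, 1, pos), hp, substr(seq, pos + hp_len + 1, nchar(seq)))
}

#' Plant TE insertions into one sequence at a target coverage
#'
#' Selects library copies until the target covered-base budget is met
#' (the final copy is truncated to land on the budget when the remaining
#' allowance is at least 30 bp), mutates each copy at 5% per site, and
#' places the copies without overlap by drawing a random integer
#' composition of the free space (equal-probability multinomial gaps). Density 1.0 therefore tiles the sequence
#' exactly. Insertions are realized as same-length replacements of the
#' background sequence so coordinates of the host feature never shift.
#'
#' @param sequence Host sequence.
#' @param density Target covered fraction in \[0,1\].
#' @param library TE consensus library, see [te_library()].
#' @param seed Optional seed.
#' @return List: `seq` (mutated host), `features` (tibble `start`, `end`
#'   0-based half-open on the host, `class`, `name`, `divergence_pct`).
#' @export
plant_te_insertions <- function(sequence, density, library = te_library(),
                                seed = NULL) {
  assert_fraction(density, "density")
  empty <- tibble(start = numeric(0), end = numeric(0), class = character(0),
                  name = character(0), divergence_pct = numeric(0))
  if (density == 0 || nchar(sequence) == 0) {
    return(list(seq = sequence, features = empty))
  }
  if (nrow(library) == 0) abort("empty repeat library with nonzero density")
  with_seed(seed, {
    len <- nchar(sequence)
    budget <- round(density * len)
    picks <- integer(0)
    lens <- integer(0)
    total <- 0
    while (total < budget) {
      i <- sample.int(nrow(library), 1)
      l <- nchar(library$seq[i])
      if (total + l > budget) {
        l <- budget - total
        if (l < 30) break
      }
      picks <- c(picks, i)
      lens <- c(lens, l)
      total <- total + l
    }
    if (length(picks) == 0) return(list(seq = sequence, features = empty))
    free <- len - total
    gaps <- as.vector(stats::rmultinom(1, free, rep(1, length(picks) + 1)))
    pos <- 0
    feats <- vector("list", length(picks))
    out <- sequence
    for (k in seq_along(picks)) {
      pos <- pos + gaps[k]
      copy <- substr(library$seq[picks[k]], 1, lens[k])
      copy <- mutate_sites(copy, 0.05)
      out <- paste0(substr(out, 1, pos), copy,
                    substr(out, pos + lens[k] + 1, len))
      feats[[k]] <- tibble(start = pos, end = pos + lens[k],
                           class = library$class[picks[k]],
                           name = library$name[picks[k]],
                           divergence_pct = 5)
      pos <- pos + lens[k]
    }
    list(seq = out, features = purrr::list_rbind(feats))
  })
}

# Split total length L into k parts each >= minimum (uniform composition).
random_partition <- function(L, k, minimum) {
  if (k == 1) return(L)
  free <- L - k * minimum
  if (free < 0) abort("partition infeasible")
  minimum + as.vector(stats::rmultinom(1, free, rep(1, k)))
}

# Miniature GO ontology (three roots, two levels) for annotation tests.
#' Miniature ontology used for synthetic GO annotation
#' @return List: `terms` (tibble `term`, `parent`), leaf term ids.
#' @export
go_mini_ontology <- function() {
  terms <- tibble(
    term = c("GO:0008150", "GO:0003674", "GO:0005575",
              "GO:0065007", "GO:0009987", "GO:0005488", "GO:0003824",
              "GO:0043167", "GO:0000166", "GO:0046872",
              "GO:0050789", "GO:0007154", "GO:0016301", "GO:0016787"),
    parent = c(NA, NA, NA,
               "GO:0008150", "GO:0008150", "GO:0003674", "GO:0003674",
               "GO:0005488", "GO:0043167", "GO:0043167",
               "GO:0065007", "GO:0009987", "GO:0003824", "GO:0003824"))
  list(terms = terms,
       leaves = setdiff(terms$term, terms$parent[!is.na(terms$parent)]))
}

#' Generate a synthetic multi-species universe
#'
#' Builds genomes, protein-coding gene annotations with GO labels, lincRNA
#' transcripts (with planted hairpins, homolog families and TE insertions),
#' repeat tracks, and a tissue expression matrix. Returns everything
#' in-memory together with the planted truth; [write_universe()] serializes
#' to the standard formats.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `linc_universe`: `transcripts` (lincRNAs),
#'   `genes`, `genomes` (species -> chrom -> sequence), `chrom_lengths`,
#'   `repeats`, `expression`, `go_annotation`, `truth`, `spec`.
#' @export
simulate_universe <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, simulate_universe_impl(spec))
}

simulate_universe_impl <- function(spec) {
  sp_names <- sprintf("species%02d", seq_len(spec$species_count))
  n_total <- spec$species_count * spec$lincrna_per_species
  lib <- te_library()

  # --- global slot plan: which (species, index) hold family members -------
  slots <- tibble(species = rep(sp_names, each = spec$lincrna_per_species),
                  idx = rep(seq_len(spec$lincrna_per_species), spec$species_count),
                  id = sprintf("%s_linc%04d",
                               rep(sp_names, each = spec$lincrna_per_species),
                               rep(seq_len(spec$lincrna_per_species), spec$species_count)))
  family_of <- setNames(rep(NA_integer_, n_total), slots$id)
  if (spec$family_count > 0) {
    if (spec$species_count < 2)
      abort("family planting needs species_count >= 2 (families span species)")
    free <- seq_len(n_total)
    for (f in seq_len(spec$family_count)) {
      m <- sample(2:3, 1)
      # ensure >= 2 distinct species among members
      repeat {
        pick <- sample(free, m)
        if (length(unique(slots$species[pick])) >= 2) break
      }
      family_of[pick] <- f
      free <- setdiff(free, pick)
      if (length(free) < 3) break
    }
  }

  # --- founder sequences per family ---------------------------------------
  founder_len <- setNames(integer(0), character(0))
  founders <- list()
  for (f in unique(stats::na.omit(family_of))) {
    L <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
    founders[[as.character(f)]] <-
      random_dna_gc(L, runif(1, spec$gc_range[1], spec$gc_range[2]))
  }

  # hairpins are planted only into non-family transcripts so the two
  # planted signals (structure, homology) stay orthogonal: a hairpin
  # overwrite inside a short family member could fragment its similarity
  # patch below the retention rule. Exactly round(fraction * N) transcripts
  # are drawn (the parameter is a fraction, not a per-transcript rate).
  eligible <- which(is.na(family_of))
  k_struct <- min(round(spec$structured_fraction * n_total), length(eligible))
  structured <- rep(FALSE, n_total)
  if (k_struct > 0) structured[sample(eligible, k_struct)] <- TRUE
  structured_ids <- slots$id[structured]

  # --- per-transcript spliced sequences ------------------------------------
  spliced <- character(n_total)
  for (t in seq_len(n_total)) {
    f <- family_of[t]
    if (!is.na(f)) {
      s <- mutate_sites(founders[[as.character(f)]], spec$family_divergence)
      if (spec$family_divergence > 0.1) s <- apply_indels(s, sample(1:2, 1))
    } else {
      L <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
      s <- random_dna_gc(L, runif(1, spec$gc_range[1], spec$gc_range[2]))
    }
    if (structured[t]) s <- plant_hairpin(s)
    spliced[t] <- s
  }

  # --- exon structure, TE planting, genome layout --------------------------
  n_chrom <- 4L
  tx_rows <- vector("list", n_total)
  gene_rows <- list()
  repeat_rows <- list()
  te_truth <- vector("list", n_total)
  genomes <- list()
  gene_counter <- 0L
  t_global <- 0L

  for (sp in sp_names) {
    chrom_parts <- replicate(n_chrom, character(0), simplify = FALSE)
    chrom_pos <- rep(0, n_chrom)
    names(chrom_pos) <- sprintf("%s_chr%d", sp, seq_len(n_chrom))
    chrom_names <- names(chrom_pos)
    append_seq <- function(ci, s) {
      chrom_parts[[ci]] <<- c(chrom_parts[[ci]], s)
      start <- unname(chrom_pos[ci])
      chrom_pos[ci] <<- start + nchar(s)
      start
    }
    sp_slots <- which(slots$species == sp)
    for (k in seq_along(sp_slots)) {
      t_global <- sp_slots[k]
      tid <- slots$id[t_global]
      s <- spliced[t_global]
      ci <- sample.int(n_chrom, 1)
      chrom <- chrom_names[ci]
      strand <- sample(c("+", "-"), 1)

      # upstream spacer then a protein-coding gene neighbor
      append_seq(ci, random_dna_gc(sample(300:1500, 1), 0.35))
      gene_counter <- gene_counter + 1L
      gid <- sprintf("%s_gene%04d", sp, gene_counter)
      gene_len <- 3L * sample(200:500, 1)
      gene_seq <- make_coding_sequence(gene_len)
      gstart <- append_seq(ci, gene_seq)
      gene_rows[[length(gene_rows) + 1]] <-
        tibble(gene_id = gid, species = sp, chrom = chrom, start = gstart,
               end = gstart + gene_len, strand = sample(c("+", "-"), 1),
               seq = gene_seq)
      # spacer between gene and lincRNA (the gene-lincRNA distance)
      append_seq(ci, random_dna_gc(sample(100:4000, 1), 0.35))

      # exon structure
      L <- nchar(s)
      n_ex <- if (runif(1) < 0.4 || L < 120) 1L else sample(2:5, 1)
      if (L < n_ex * 60) n_ex <- max(1L, L %/% 60L)
      ex_lens <- random_partition(L, n_ex, 60L)
      # exon TE planting on the spliced sequence, exon-wise
      offs <- cumsum(c(0, ex_lens))[seq_len(n_ex)]
      te_feats_tx <- list()
      if (spec$te_density_exon > 0) {
        for (e in seq_len(n_ex)) {
          seg <- substr(s, offs[e] + 1, offs[e] + ex_lens[e])
          pl <- plant_te_insertions(seg, spec$te_density_exon, lib)
          s <- paste0(substr(s, 1, offs[e]), pl$seq,
                      substr(s, offs[e] + ex_lens[e] + 1, L))
          if (nrow(pl$features)) {
            pl$features$start <- pl$features$start + offs[e]
            pl$features$end <- pl$features$end + offs[e]
            pl$features$compartment <- "exon"
            te_feats_tx[[length(te_feats_tx) + 1]] <- pl$features
          }
        }
      }
      # genome layout: exons in genomic order with TE-bearing introns
      ex_genomic <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      exon_tbl <- tibble(start = numeric(n_ex), end = numeric(n_ex))
      intron_feats <- list()
      for (pos_k in seq_along(ex_genomic)) {
        e <- ex_genomic[pos_k]
        seg <- substr(s, offs[e] + 1, offs[e] + ex_lens[e])
        gseg <- if (strand == "+") seg else revcomp(seg)
        gstart_e <- append_seq(ci, gseg)
        exon_tbl$start[e] <- gstart_e
        exon_tbl$end[e] <- gstart_e + ex_lens[e]
        if (pos_k < n_ex) {
          ilen <- sample(200:800, 1)
          iseq <- random_dna_gc(ilen, 0.30)
          ipl <- plant_te_insertions(iseq, spec$te_density_intron, lib)
          istart <- append_seq(ci, ipl$seq)
          if (nrow(ipl$features)) {
            ipl$features$start <- ipl$features$start + istart
            ipl$features$end <- ipl$features$end + istart
            ipl$features$compartment <- "intron"
            intron_feats[[length(intron_feats) + 1]] <- ipl$features
          }
        }
      }
      # map exon-space TE features to genomic coordinates while exon_tbl is
      # still indexed in transcript order
      geno_te <- list()
      if (length(te_feats_tx)) {
        for (ft in te_feats_tx) {
          for (rr in seq_len(nrow(ft))) {
            e <- max(which(offs < ft$end[rr]))
            within <- c(ft$start[rr], ft$end[rr]) - offs[e]
            if (strand == "+") {
              a <- exon_tbl$start[e] + within[1]
              b <- exon_tbl$start[e] + within[2]
            } else {
              a <- exon_tbl$end[e] - within[2]
              b <- exon_tbl$end[e] - within[1]
            }
            geno_te[[length(geno_te) + 1]] <-
              tibble(start = a, end = b, class = ft$class[rr],
                     name = ft$name[rr], divergence_pct = ft$divergence_pct[rr],
                     compartment = "exon")
          }
        }
      }
      exon_tbl <- exon_tbl[order(exon_tbl$start), ]
      all_te <- purrr::list_rbind(c(geno_te, intron_feats))
      if (nrow(all_te)) {
        all_te$chrom <- chrom
        all_te$species <- sp
        repeat_rows[[length(repeat_rows) + 1]] <- all_te
      }
      te_truth[[t_global]] <- bind_rows(
        if (length(te_feats_tx)) purrr::list_rbind(te_feats_tx) else
          tibble(start = numeric(0), end = numeric(0), class = character(0),
                 name = character(0), divergence_pct = numeric(0),
                 compartment = character(0)))
      append_seq(ci, random_dna_gc(sample(300:1500, 1), 0.35))

      tx_rows[[t_global]] <- tibble(
        id = tid, species = sp, chrom = chrom, strand = strand,
        biotype = "lincRNA", exons = list(exon_tbl), seq = s,
        nearest_gene_truth = gid)
    }
    chroms <- vapply(chrom_parts, paste, character(1), collapse = "")
    # pad every chromosome with a tail so lengths exceed feature ends
    chroms <- paste0(chroms, vapply(seq_len(n_chrom),
                                    function(i) random_dna_gc(500, 0.35), character(1)))
    names(chroms) <- chrom_names
    genomes[[sp]] <- chroms
  }

  transcripts <- purrr::list_rbind(tx_rows)
  # exon-space coordinates were computed against pre-TE exon layout; the
  # spliced sequence in `transcripts` is the post-TE one, same lengths
  validate_transcripts(transcripts)
  genes <- purrr::list_rbind(gene_rows)
  repeats <- if (length(repeat_rows)) purrr::list_rbind(repeat_rows) else
    tibble(start = numeric(0), end = numeric(0), class = character(0),
           name = character(0), divergence_pct = numeric(0),
           compartment = character(0), chrom = character(0), species = character(0))

  # --- GO annotation --------------------------------------------------------
  onto <- go_mini_ontology()
  go_annotation <- purrr::list_rbind(lapply(genes$gene_id, function(g) {
    tibble(gene_id = g, term = sample(onto$leaves, sample(1:3, 1)))
  }))

  truth <- list(
    family_assignments = tibble(id = slots$id, family = unname(family_of)),
    structured_ids = structured_ids,
    te_intervals = setNames(te_truth, slots$id),
    expression_profile = spec$expression_profile)

  universe <- list(transcripts = transcripts, genes = genes, genomes = genomes,
                   chrom_lengths = unlist(unname(lapply(genomes, nchar))),
                   repeats = repeats, go_annotation = go_annotation,
                   truth = truth, spec = spec)
  class(universe) <- "linc_universe"

  universe$expression <- generate_expression(universe, spec$expression_tissues,
                                             seed = NULL)
  universe
}

# A coding-like sequence: ATG + random non-stop codons + stop.
make_coding_sequence <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(codons, len / 3 - 2, TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' @export
print.linc_universe <- function(x, ...) {
  cat("<linc_universe>", x$spec$species_count, "species,",
      nrow(x$transcripts), "lincRNAs,", nrow(x$genes), "genes,",
      nrow(x$repeats), "repeat copies\n")
  invisible(x)
}

#' Generate tissue expression with distance-dependent correlation
#'
#' Emits non-negative, unit-free expression values for every gene and
#' lincRNA across `tissues` tissues. Each lincRNA's profile is correlated
#' with its flanking gene's profile at the target Pearson correlation for
#' the pair's distance bin (shared-latent construction); genes without a
#' lincRNA partner are independent.
#'
#' @param universe A `linc_universe` (or any list with `transcripts`,
#'   `genes`, `truth$expression_profile`).
#' @param tissues Number of tissues (>= 3).
#' @param seed Optional seed.
#' @return Tibble: `feature_id`, `type` (gene/lincRNA), then one column per
#'   tissue (`tissue01`...).
#' @export
generate_expression <- function(universe, tissues = 10, seed = NULL) {
  tissues <- assert_count(tissues, "tissues", 3L)
  profile <- universe$truth$expression_profile
  bins <- as.numeric(names(profile))
  with_seed(seed, {
    tx <- universe$transcripts
    genes <- universe$genes
    tn <- sprintf("tissue%02d", seq_len(tissues))
    glat <- matrix(rnorm(nrow(genes) * tissues), nrow(genes), tissues,
                   dimnames = list(genes$gene_id, tn))
    tlat <- matrix(NA_real_, nrow(tx), tissues, dimnames = list(tx$id, tn))
    span <- tx_span(tx)
    for (r in seq_len(nrow(tx))) {
      gid <- tx$nearest_gene_truth[r]
      eps <- rnorm(tissues)
      if (is.null(gid) || is.na(gid) || !(gid %in% genes$gene_id)) {
        tlat[r, ] <- eps
        next
      }
      gi <- match(gid, genes$gene_id)
      d <- interval_gap(span$start[r], span$end[r], genes$start[gi], genes$end[gi])
      rho <- profile[[findInterval(d, bins)]]
      tlat[r, ] <- rho * glat[gi, ] + sqrt(1 - rho^2) * eps
    }
    to_expr <- function(z) { z[] <- pmax(0, 10 + 2 * z); z } # keep matrix shape
    bind_rows(
      bind_cols(tibble(feature_id = genes$gene_id, type = "gene"),
                as_tibble(to_expr(glat))),
      bind_cols(tibble(feature_id = tx$id, type = "lincRNA"),
                as_tibble(to_expr(tlat))))
  })
}

# gap between two 0-based half-open intervals on one chromosome (0 if overlap)
interval_gap <- function(a1, b1, a2, b2) {
  max(0, a2 - b1, a1 - b2)
}

#' Serialize a universe to standard formats
#'
#' Writes, per species: spliced lincRNA FASTA, lincRNA GFF3, gene GFF3,
#' genome FASTA, RepeatMasker-style `.out` table; plus `expression.tsv`,
#' `go_annotation.tsv` and `truth.json` at the top level.
#'
#' @param universe A `linc_universe`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (sp in names(universe$genomes)) {
    tx <- filter(universe$transcripts, species == sp)
    pre <- file.path(dir, sp)
    write_transcript_fasta(tx, paste0(pre, "_lincrna.fa"))
    write_transcript_gff3(tx, paste0(pre, "_lincrna.gff3"))
    g <- universe$genomes[[sp]]
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(g),
                                paste0(pre, "_genome.fa"), width = 60L)
    genes <- filter(universe$genes, species == sp)
    gene_lines <- c("##gff-version 3",
      sprintf("%s\tlinctools\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              genes$chrom, genes$start + 1, genes$end, genes$strand, genes$gene_id))
    writeLines(gene_lines, paste0(pre, "_genes.gff3"))
    write_repeatmasker_out(filter(universe$repeats, species == sp),
                           paste0(pre, "_repeats.out"))
    paths[[sp]] <- paste0(pre, c("_lincrna.fa", "_lincrna.gff3", "_genome.fa",
                                 "_genes.gff3", "_repeats.out"))
  }
  readr::write_tsv(universe$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(universe$go_annotation, file.path(dir, "go_annotation.tsv"))
  truth <- universe$truth
  truth$te_intervals <- lapply(truth$te_intervals, function(x) as.list(x))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  paths$expression <- file.path(dir, "expression.tsv")
  paths$truth <- file.path(dir, "truth.json")
  invisible(paths)
}

#' Write a RepeatMasker-style .out table
#'
#' @param repeats Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `class`, `name`, `divergence_pct`.
#' @param path Output file.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  if (nrow(repeats) == 0) { writeLines(hdr, path); return(invisible(path)) }
  rows <- sprintf("%5d %5.1f  0.0  0.0  %-10s %7d %7d (0) + %-14s %-18s 1 %d (0) %d",
                  1000L, repeats$divergence_pct, repeats$chrom,
                  repeats$start + 1, repeats$end, repeats$name,
                  rm_class_string(repeats$class), repeats$end - repeats$start,
                  seq_len(nrow(repeats)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

rm_class_string <- function(class) {
  c(DNA = "DNA/synth", LINE = "LINE/synth", SINE = "SINE/synth",
    LTR = "LTR/synth", simple_repeat = "Simple_repeat",
    low_complexity = "Low_complexity", other = "Unknown")[class]
}

#' Read a RepeatMasker .out table
#'
#' Parses the standard whitespace-delimited `.out` format (3 header lines)
#' into the package's repeat tibble; repeat class/family strings are
#' collapsed to the 7-class vocabulary by prefix matching (unknowns to
#' `other`, with a message counting them).
#'
#' @param path `.out` file.
#' @return Tibble: `chrom`, `start`, `end` (0-based half-open), `class`,
#'   `name`, `divergence_pct`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3, length(lines)))]
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (length(lines) == 0) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  class = character(0), name = character(0),
                  divergence_pct = numeric(0)))
  }
  f <- strsplit(lines, "\\s+")
  tibble(chrom = vapply(f, `[`, "", 5),
         start = as.numeric(vapply(f, `[`, "", 6)) - 1,
         end = as.numeric(vapply(f, `[`, "", 7)),
         class = collapse_repeat_class(vapply(f, `[`, "", 11)),
         name = vapply(f, `[`, "", 10),
         divergence_pct = as.numeric(vapply(f, `[`, "", 2)))
}

#' Collapse RepeatMasker class/family strings to the 7-class vocabulary
#' @param x Character vector like "LTR/Gypsy", "Simple_repeat".
#' @return Factor-like character vector over DNA, LINE, SINE, LTR,
#'   simple_repeat, low_complexity, other.
#' @export
collapse_repeat_class <- function(x) {
  out <- dplyr::case_when(
    grepl("^DNA", x) ~ "DNA",
    grepl("^LINE", x) ~ "LINE",
    grepl("^SINE", x) ~ "SINE",
    grepl("^LTR", x) ~ "LTR",
    grepl("^Simple_repeat", x, ignore.case = TRUE) ~ "simple_repeat",
    grepl("^Low_complexity", x, ignore.case = TRUE) ~ "low_complexity",
    TRUE ~ "other")
  n_other <- sum(out == "other" & !is.na(x))
  if (n_other > 0) inform(sprintf("%d repeat(s) mapped to class 'other'", n_other))
  out
}
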