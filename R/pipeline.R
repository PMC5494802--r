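# End-to-end orchestration: intergenic filter -> coding screen ->
# properties -> shuffle/fold/stability -> structured selection ->
# homology (unmasked, masked, ORF, paralog) -> genomic context -> report.
# Every stage's output is written before the next starts; the whole run is
# a pure function of (inputs, config, seed).

#' Pipeline configuration
#'
#' Thresholds default to the values used throughout the comparative
#' analysis: minimum lincRNA length 200 nt, ORF threshold 25 aa,
#' conservation e-value 1e-5, coding-screen e-value 1e-6, patch length
#' rule >100 nt, 100 shuffle controls, folding-strength quantiles
#' 90/95/97/99, MCL inflation 2.
#'
#' @param min_length,min_orf_aa,evalue_conserved,evalue_coding,patch_min
#'   Analysis thresholds.
#' @param n_controls Shuffle controls per sequence.
#' @param quantiles Structured-set quantiles.
#' @param mcl_inflation MCL inflation.
#' @param expression_threshold Detection threshold for expression breadth.
#' @param seed Integer seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_length = 200, min_orf_aa = 25,
                            evalue_conserved = 1e-5, evalue_coding = 1e-6,
                            patch_min = 100, n_controls = 100,
                            quantiles = c(90, 95, 97, 99),
                            mcl_inflation = 2.0,
                            expression_threshold = 1.0, seed = 1L) {
  vals <- c(min_length, min_orf_aa, evalue_conserved, evalue_coding,
            patch_min, n_controls, mcl_inflation, expression_threshold)
  if (any(vals <= 0)) abort("all thresholds must be positive")
  structure(list(min_length = min_length, min_orf_aa = min_orf_aa,
                 evalue_conserved = evalue_conserved,
                 evalue_coding = evalue_coding, patch_min = patch_min,
                 n_controls = n_controls, quantiles = quantiles,
                 mcl_inflation = mcl_inflation,
                 expression_threshold = expression_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stage <- function(out_dir, name, obj) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, paste0(name, ".tsv"))
  df <- as_tibble(obj)
  df <- df[!vapply(df, is.list, logical(1))] # list columns stay in memory
  readr::write_tsv(df, path)
  invisible(path)
}

#' Run the full comparative lincRNA pipeline
#'
#' Executes every stage on an in-memory universe (such as from
#' [simulate_universe()], or assembled from files by the reader
#' functions): intergenic filtering against the gene annotation, coding
#' contamination screening (when reference proteins are given), sequence
#' properties, shuffle-null stability with structured-set selection,
#' homology in three modes (unmasked and masked cross-species, paralog
#' within-species, translated ORF), conservation labeling, repeat overlap
#' and genomic-context analyses, and a summary report.
#'
#' @param universe A `linc_universe`-like list (`transcripts`, `genes`,
#'   `genomes`, `repeats`, `expression`, `go_annotation`,
#'   `chrom_lengths`).
#' @param config A [pipeline_config()].
#' @param out_dir Directory for per-stage TSV outputs (NULL keeps
#'   everything in memory only).
#' @param reference_proteins Optional named character vector for the
#'   coding screen.
#' @param log Emit per-stage progress messages.
#' @return A list of class `linc_pipeline` with every stage output and a
#'   `report` (see [make_report()]).
#' @export
run_pipeline <- function(universe, config = pipeline_config(), out_dir = NULL,
                         reference_proteins = NULL, log = TRUE) {
  t_all <- Sys.time()
  say <- function(stage, ...) {
    if (log) inform(sprintf("[%s] %s", stage, sprintf(...)))
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)

  # -- stage 1: intergenic filter -----------------------------------------
  filt <- intergenic_filter(universe$transcripts, universe$genes)
  say("filter", "%d retained, %d removed (genic overlap)",
      nrow(filt$retained), nrow(filt$removed))
  tx <- filt$retained
  tx <- tx[tx_length(tx) >= config$min_length, ]
  res$filtered <- filt
  write_stage(out_dir, "01_filtered", tibble(id = tx$id))

  # -- stage 2: coding contamination screen -------------------------------
  if (!is.null(reference_proteins)) {
    screen <- coding_contamination_screen(tx, reference_proteins,
                                          threshold = config$evalue_coding)
    tx <- tx[!tx$id %in% screen$id[screen$flagged], ]
    say("coding-screen", "%d flagged, %d retained", sum(screen$flagged), nrow(tx))
    res$coding_screen <- screen
    write_stage(out_dir, "02_coding_screen", screen)
  }

  # -- stage 3: sequence properties ---------------------------------------
  genome_of <- function(sp) universe$genomes[[sp]]
  props <- purrr::list_rbind(lapply(split(tx, tx$species), function(d) {
    transcript_properties(d, genome_of(d$species[1]), min_aa = config$min_orf_aa)
  }))
  gc_comp <- purrr::list_rbind(lapply(split(tx, tx$species), function(d) {
    compartment_gc(d, genome_of(d$species[1]))
  }))
  exonic <- classify_exonic_structure(tx)
  say("props", "%d property rows", nrow(props))
  res$properties <- props
  res$gc_compartments <- gc_comp
  res$exonic_structure <- exonic
  write_stage(out_dir, "03_properties", props)

  # -- stage 4: stability -------------------------------------------------
  stab <- stability_table(tx, n_controls = config$n_controls,
                          seed = config$seed)
  structured <- purrr::list_rbind(lapply(config$quantiles, function(q) {
    select_structured(stab, q)
  }))
  say("stability", "mean z_fs %.3f, mean z_mfe %.3f",
      mean(stab$z_fs, na.rm = TRUE), mean(stab$z_mfe, na.rm = TRUE))
  res$stability <- stab
  res$structured <- structured
  write_stage(out_dir, "04_stability", stab)
  write_stage(out_dir, "04_structured", structured)

  # -- stage 5: homology --------------------------------------------------
  params <- align_params(evalue_max = config$evalue_conserved,
                         patch_min = config$patch_min)
  edges <- all_vs_all(tx, "cross_species", params = params)
  edges_masked <- all_vs_all(tx, "cross_species", masked = TRUE,
                             repeats = universe$repeats, params = params)
  edges_paralog <- all_vs_all(tx, "within_species", params = params)
  orfs <- orf_calls(tx, min_aa = config$min_orf_aa)
  edges_orf <- orf_similarity(tx, orfs)
  cl <- mcl_cluster(edges, config$mcl_inflation)
  cl_masked <- mcl_cluster(edges_masked, config$mcl_inflation)
  cl_paralog <- mcl_cluster(edges_paralog, config$mcl_inflation)
  cl_orf <- mcl_cluster(edges_orf, config$mcl_inflation)
  labels <- classify_conservation(tx, cl, cl_masked, cl_orf, cl_paralog)
  say("homology", "%d/%d/%d/%d edges (unmasked/masked/paralog/orf)",
      nrow(edges), nrow(edges_masked), nrow(edges_paralog), nrow(edges_orf))
  res$edges <- list(unmasked = edges, masked = edges_masked,
                    paralog = edges_paralog, orf = edges_orf)
  res$clusters <- list(unmasked = cl, masked = cl_masked,
                       paralog = cl_paralog, orf = cl_orf)
  res$conservation <- labels
  write_stage(out_dir, "05_edges", edges)
  write_stage(out_dir, "05_conservation", labels)

  # -- stage 6: genomic context -------------------------------------------
  coverage <- repeat_overlap(tx, universe$repeats)
  ctx <- purrr::list_rbind(lapply(split(tx, tx$species), function(d) {
    closest_gene(d, filter(universe$genes, species == d$species[1]))
  }))
  q90 <- filter(structured, quantile == 90)$sequence_id
  te_cmp <- tryCatch(
    compare_te_content(coverage, q90),
    error = function(e) NULL)
  profile <- if (!is.null(universe$expression)) {
    expression_distance_profile(ctx, universe$expression, seed = config$seed)
  }
  density <- chromosomal_density(tx, universe$chrom_lengths)
  go <- if (!is.null(universe$go_annotation)) {
    near_structured <- unique(ctx$nearest_gene_id[ctx$id %in% q90])
    if (length(near_structured) > 0) {
      go_enrichment(near_structured, unique(universe$genes$gene_id),
                    universe$go_annotation)
    }
  }
  say("context", "%d coverage rows, %d context rows", nrow(coverage), nrow(ctx))
  res$repeat_coverage <- coverage
  res$context <- ctx
  res$te_comparison <- te_cmp
  res$expression_profile <- profile
  res$density <- density
  res$go_enrichment <- go
  write_stage(out_dir, "06_coverage", coverage)
  write_stage(out_dir, "06_context", ctx)

  # -- report --------------------------------------------------------------
  res$report <- make_report(res)
  if (!is.null(out_dir)) {
    write_stage(out_dir, "07_report_species", res$report$species_summary)
    write_stage(out_dir, "07_report_conservation", res$report$conservation_summary)
  }
  say("done", "total %.1f s", as.numeric(Sys.time() - t_all, units = "secs"))
  class(res) <- "linc_pipeline"
  res
}

#' Summary report from pipeline stage outputs
#'
#' Builds the per-species count table (total/monoexonic/multiexonic,
#' conserved, conserved after masking, paralogs, TE-related, structured)
#' and the conservation-overlap counts (conserved both with and without
#' masking, only unmasked, ORF-conserved).
#'
#' @param res A partially or fully populated pipeline result list.
#' @return List of tibbles: `species_summary`, `conservation_summary`,
#'   `zscore_summary`.
#' @export
make_report <- function(res) {
  lab <- res$conservation
  exonic <- res$exonic_structure
  structured90 <- if (!is.null(res$structured)) {
    filter(res$structured, quantile == 90)$sequence_id
  } else character(0)
  species_summary <- exonic |>
    left_join(
      lab |> group_by(species) |>
        summarise(conserved = sum(conserved),
                  conserved_after_masking = sum(conserved_after_masking),
                  paralogs = sum(paralog), te_related = sum(te_related),
                  orf_conserved = sum(orf_conserved), .groups = "drop"),
      by = "species") |>
    mutate(structured = vapply(species, function(sp) {
      sum(lab$species == sp & lab$id %in% structured90)
    }, numeric(1), USE.NAMES = FALSE))
  conservation_summary <- tibble(
    conserved_unmasked = sum(lab$conserved),
    conserved_masked = sum(lab$conserved_after_masking),
    conserved_both = sum(lab$conserved & lab$conserved_after_masking),
    only_unmasked = sum(lab$te_related),
    orf_conserved = sum(lab$orf_conserved))
  zscore_summary <- if (!is.null(res$stability)) glance(res$stability)
  list(species_summary = species_summary,
       conservation_summary = conservation_summary,
       zscore_summary = zscore_summary)
}

#' @export
print.linc_pipeline <- function(x, ...) {
  cat("<linc_pipeline>\n")
  print(x$report$species_summary)
  invisible(x)
}

#' @export
tidy.linc_pipeline <- function(x, ...) x$report$species_summary

#' @export
glance.linc_pipeline <- function(x, ...) {
  bind_cols(x$report$conservation_summary, x$report$zscore_summary)
}
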