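# Shuffle-null stability statistics.
#
# For each native sequence, a batch of dinucleotide-preserving shuffles is
# folded and the native statistic x is standardized against the control
# distribution: Z = (x - mu) / sigma, where mu and sigma are the mean and
# standard deviation over the controls. Two statistics are tracked: the
# minimum free energy (z_mfe computed on raw, negative MFE, so
# thermodynamically stable sequences get negative z_mfe) and the folding
# strength (z_fs, where structured sequences get positive z_fs). Ratio
# variants (native MFE / mean control MFE; native FS / mean control FS) are
# emitted alongside.

#' Stability record for one sequence against its shuffle controls
#'
#' @param native A `folding_result` for the native sequence (or list with
#'   `mfe` and `folding_strength`).
#' @param controls List of `folding_result`s for the shuffled controls
#'   (>= 2).
#' @param sequence_id Id carried into the output.
#' @return One-row tibble: native statistics, control mean/sd, `z_fs`,
#'   `z_mfe`, `mfe_ratio`, `stem_ratio`, `n_controls`, `degenerate` (TRUE
#'   when a control sd is zero, e.g. for sequences invariant under
#'   shuffling — Z is NA then).
#' @export
stability_record <- function(native, controls, sequence_id = NA_character_) {
  if (length(controls) < 1) abort("empty control set")
  c_mfe <- vapply(controls, function(x) x$mfe, numeric(1))
  c_fs <- vapply(controls, function(x) x$folding_strength, numeric(1))
  mu_mfe <- mean(c_mfe); sigma_mfe <- sd(c_mfe)
  mu_fs <- mean(c_fs); sigma_fs <- sd(c_fs)
  degenerate <- isTRUE(sigma_mfe == 0) || isTRUE(sigma_fs == 0) ||
    is.na(sigma_mfe) || is.na(sigma_fs)
  tibble(
    sequence_id = sequence_id,
    x_fs = native$folding_strength, x_mfe = native$mfe,
    mu_fs = mu_fs, sigma_fs = sigma_fs,
    mu_mfe = mu_mfe, sigma_mfe = sigma_mfe,
    n_controls = length(controls),
    z_fs = if (isTRUE(sigma_fs > 0)) (native$folding_strength - mu_fs) / sigma_fs else NA_real_,
    z_mfe = if (isTRUE(sigma_mfe > 0)) (native$mfe - mu_mfe) / sigma_mfe else NA_real_,
    mfe_ratio = if (mu_mfe != 0) native$mfe / mu_mfe else NA_real_,
    stem_ratio = if (mu_fs != 0) native$folding_strength / mu_fs else NA_real_,
    degenerate = degenerate)
}

#' Shuffle-null stability statistics for a transcript table
#'
#' The core stability pipeline: per sequence, fold the native molecule,
#' generate `n_controls` composition-preserving shuffles, fold each, and
#' standardize. Returns a `linc_stability` tibble (one row per transcript)
#' that [select_structured()], [tidy()] and [autoplot()] understand.
#'
#' @param data Data frame with id and sequence columns (e.g. a transcript
#'   table).
#' @param n_controls Controls per sequence (default 100).
#' @param method Shuffle method, `"dinucleotide"` (default) or
#'   `"mononucleotide"`.
#' @param model [energy_model()] for folding.
#' @param seed Seed making the whole table reproducible.
#' @param seq_col,id_col Column names.
#' @return A `linc_stability` tibble; see [stability_record()] for columns
#'   (plus `species` if present in `data`).
#' @export
stability_table <- function(data, n_controls = 100,
                            method = c("dinucleotide", "mononucleotide"),
                            model = energy_model(), seed = NULL,
                            seq_col = "seq", id_col = "id") {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), seq_col %in% names(data), id_col %in% names(data))
  seeds <- derive_seeds(seed, nrow(data))
  rows <- lapply(seq_len(nrow(data)), function(r) {
    s <- data[[seq_col]][r]
    native <- fold_partition(s, model, return_matrix = FALSE)
    batch <- shuffle_controls(s, n = n_controls, method = method,
                              seed = seeds[[r]], source_id = data[[id_col]][r])
    ctl <- lapply(batch$sequence, fold_partition, model = model,
                  return_matrix = FALSE)
    stability_record(native, ctl, sequence_id = data[[id_col]][r])
  })
  out <- purrr::list_rbind(rows)
  if ("species" %in% names(data)) out$species <- data$species
  class(out) <- c("linc_stability", class(out))
  attr(out, "n_controls") <- n_controls
  attr(out, "method") <- method
  out
}

#' Select structured transcripts by folding-strength quantile
#'
#' Members are the records at or above the chosen folding-strength
#' quantile (the top (100-q)% by native folding strength), with
#' deterministic tie-breaks by `z_fs` then id. By default selection is
#' performed within each species; `pool = TRUE` selects over the pooled
#' set.
#'
#' @param records A `linc_stability` tibble (or any data frame with
#'   `sequence_id`, `x_fs`, `z_fs`, optionally `species`).
#' @param quantile One of 90, 95, 97, 99.
#' @param pool Select on the pooled set rather than per species.
#' @return Tibble `sequence_id`, `species`, `quantile` — the structured set
#'   membership list.
#' @export
select_structured <- function(records, quantile = 90, pool = FALSE) {
  if (!quantile %in% c(90, 95, 97, 99)) abort("`quantile` must be 90, 95, 97 or 99")
  if (nrow(records) == 0) abort("`records` is empty")
  grp <- if (!pool && "species" %in% names(records)) records$species
         else rep("all", nrow(records))
  picked <- lapply(split(seq_len(nrow(records)), grp), function(idx) {
    k <- ceiling((100 - quantile) * length(idx) / 100 - 1e-9)
    ord <- idx[order(-records$x_fs[idx], -xtfrm(records$z_fs[idx]),
                     records$sequence_id[idx])]
    ord[seq_len(k)]
  })
  idx <- sort(unlist(picked, use.names = FALSE))
  tibble(sequence_id = records$sequence_id[idx],
         species = if ("species" %in% names(records)) records$species[idx]
                   else NA_character_,
         quantile = quantile)
}

#' Correlation with p-value
#'
#' Thin wrapper around the standard correlation test, with explicit
#' handling of degenerate (constant) inputs.
#'
#' @param xs,ys Numeric vectors, equal length >= 3, finite.
#' @param method `"spearman"` or `"pearson"`.
#' @return One-row tibble: `estimate`, `p_value`, `n`, `method`.
#' @export
correlate <- function(xs, ys, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(xs) != length(ys) || length(xs) < 3) abort("need equal-length vectors, n >= 3")
  if (!all(is.finite(xs)) || !all(is.finite(ys))) abort("inputs must be finite")
  if (sd(xs) == 0 || sd(ys) == 0) abort("correlation undefined for constant input")
  ct <- suppressWarnings(cor.test(xs, ys, method = method, exact = FALSE))
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
         n = length(xs), method = method)
}

#' Join stability statistics with expression summaries
#'
#' Expression breadth is the fraction of tissues in which the feature is
#' detected above `detection_threshold` (default 1 on the unit-free
#' synthetic scale).
#'
#' @param records `linc_stability` tibble.
#' @param expression Expression tibble: `feature_id` + one column per
#'   tissue (as emitted by [generate_expression()]).
#' @param detection_threshold Detection threshold for breadth.
#' @param properties Optional per-transcript property table (joined by id;
#'   brings in GC).
#' @return Tibble: id, mean_expression, expression_breadth, x_fs, z_fs,
#'   z_mfe (+ gc_exon if `properties` given). Ids missing from the
#'   expression matrix raise an error (no silent drops).
#' @export
expression_stability_table <- function(records, expression,
                                       detection_threshold = 1,
                                       properties = NULL) {
  tcols <- grep("^tissue", names(expression), value = TRUE)
  if (length(tcols) == 0) abort("expression matrix has no tissue columns")
  missing_ids <- setdiff(records$sequence_id, expression$feature_id)
  if (length(missing_ids)) {
    abort(sprintf("%d record id(s) missing from expression matrix (first: %s)",
                  length(missing_ids), missing_ids[1]))
  }
  em <- as.matrix(expression[match(records$sequence_id, expression$feature_id), tcols])
  out <- tibble(
    id = records$sequence_id,
    mean_expression = rowMeans(em),
    expression_breadth = rowMeans(em > detection_threshold),
    x_fs = records$x_fs, z_fs = records$z_fs, z_mfe = records$z_mfe)
  if (!is.null(properties)) {
    out <- left_join(out, select(properties, id, gc_exon), by = "id")
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.linc_stability <- function(x, ...) {
  as_tibble(x)[c("sequence_id",
                 intersect("species", names(x)),
                 "x_fs", "x_mfe", "z_fs", "z_mfe", "mfe_ratio", "stem_ratio",
                 "degenerate")]
}

#' @export
glance.linc_stability <- function(x, ...) {
  tibble(n = nrow(x),
         n_controls = attr(x, "n_controls") %||% unique(x$n_controls)[1],
         mean_z_fs = mean(x$z_fs, na.rm = TRUE),
         mean_z_mfe = mean(x$z_mfe, na.rm = TRUE),
         median_mfe_ratio = stats::median(x$mfe_ratio, na.rm = TRUE),
         prop_degenerate = mean(x$degenerate))
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.linc_stability <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy.linc_stability(object),
                            cols = c("z_fs", "z_mfe"),
                            names_to = "statistic", values_to = "z")
  ggplot2::ggplot(df, ggplot2::aes(x = z)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "Z-score vs dinucleotide-shuffled controls",
                  y = "transcripts")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
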