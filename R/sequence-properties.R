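# Per-transcript sequence properties: GC content by genomic compartment,
# lengths and exonic structure, and getorf-style longest-ORF calls with the
# 25-amino-acid threshold used to screen for residual coding potential.

#' GC content of a sequence
#'
#' (G+C)/(A+C+G+T); N bases are excluded from numerator and denominator.
#' A sequence consisting only of N (or empty) has undefined GC content and
#' returns NA with a warning.
#'
#' @param sequence Character vector of nucleotide strings.
#' @return Numeric vector of fractions in \[0, 1\] (NA where undefined).
#' @export
#' @examples
#' gc_content(c("GCGC", "ATATAT", "ACGTN"))
gc_content <- function(sequence) {
  sequence <- normalize_sequence(sequence)
  gc <- nchar(gsub("[^GC]", "", sequence))
  acgt <- nchar(gsub("[^ACGT]", "", sequence))
  undef <- acgt == 0
  if (any(undef)) warn("GC content undefined for sequence(s) with no A/C/G/T")
  ifelse(undef, NA_real_, gc / acgt)
}

at_content <- function(sequence) {
  sequence <- normalize_sequence(sequence)
  at <- nchar(gsub("[^AT]", "", sequence))
  acgt <- nchar(gsub("[^ACGT]", "", sequence))
  ifelse(acgt == 0, NA_real_, at / acgt)
}

#' GC content by genomic compartment
#'
#' One row per transcript per compartment: lincRNA exons (spliced sequence),
#' lincRNA introns (intronic sequence from the genome), and coding sequences
#' (spliced sequence of `biotype == "coding"` transcripts). Monoexonic
#' transcripts contribute no intron row.
#'
#' @param tx Transcript tibble (lincRNA and/or coding biotypes).
#' @param genome Named list or character vector, chromosome -> sequence,
#'   for the species in `tx`. Needed only when intron rows are derivable.
#' @return Tibble: `id`, `species`, `compartment`
#'   (`lincrna_exon`/`lincrna_intron`/`coding`), `length`, `gc`.
#' @export
compartment_gc <- function(tx, genome = NULL) {
  rows <- lapply(seq_len(nrow(tx)), function(r) {
    if (tx$biotype[r] == "coding") {
      return(tibble(id = tx$id[r], species = tx$species[r],
                    compartment = "coding", length = nchar(tx$seq[r]),
                    gc = gc_content(tx$seq[r])))
    }
    out <- tibble(id = tx$id[r], species = tx$species[r],
                  compartment = "lincrna_exon", length = nchar(tx$seq[r]),
                  gc = gc_content(tx$seq[r]))
    intr <- tx_introns(tx$exons[[r]])
    if (nrow(intr) > 0) {
      if (is.null(genome)) abort("`genome` required to derive intron sequence")
      iseq <- extract_genomic(genome, tx$chrom[r], intr, tx$strand[r])
      out <- bind_rows(out, tibble(id = tx$id[r], species = tx$species[r],
                                   compartment = "lincrna_intron",
                                   length = nchar(iseq), gc = gc_content(iseq)))
    }
    out
  })
  purrr::list_rbind(rows)
}

#' Longest open reading frame of a spliced sequence
#'
#' Scans the three forward frames of the (stranded) spliced sequence for
#' ATG..stop open reading frames and returns the longest with a peptide of
#' at least `min_aa` amino acids (stop codon excluded from the length).
#' Transcripts are stranded molecules, so the reverse complement is not
#' searched unless `both_strands = TRUE`.
#'
#' @param sequence Single nucleotide string (length >= 3 for any call).
#' @param min_aa Minimum peptide length in amino acids (default 25).
#' @param both_strands Also scan the reverse complement (off by default).
#' @return One-row tibble `frame` (0/1/2), `start`, `end` (0-based half-open
#'   offsets on the spliced sequence, stop codon included in `end`),
#'   `peptide_length`, `strand` — or NULL when no qualifying ORF exists.
#' @export
#' @examples
#' find_longest_orf(paste0("ATG", strrep("GCA", 25), "TAA"), min_aa = 25)
find_longest_orf <- function(sequence, min_aa = 25, both_strands = FALSE) {
  sequence <- normalize_sequence(sequence)
  best <- NULL
  strands <- if (both_strands) c("+", "-") else "+"
  for (std in strands) {
    s <- if (std == "+") sequence else revcomp(sequence)
    n <- nchar(s)
    for (frame in 0:2) {
      codon_starts <- seq(frame + 1, n - 2, by = 3)
      if (length(codon_starts) == 0) next
      codons <- substring(s, codon_starts, codon_starts + 2)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      stop_idx <- which(is_stop)
      for (a in which(is_atg)) {
        nxt <- stop_idx[stop_idx > a]
        if (length(nxt) == 0) break_next <- NA else break_next <- nxt[1]
        if (is.na(break_next)) next
        pep <- break_next - a # codons between ATG and stop, inclusive of ATG
        if (pep < min_aa) next
        if (is.null(best) || pep > best$peptide_length) {
          best <- tibble(frame = frame,
                         start = codon_starts[a] - 1,
                         end = codon_starts[break_next] + 2,
                         peptide_length = pep,
                         strand = std)
        }
      }
    }
  }
  best
}

#' Longest-ORF calls for a transcript table
#'
#' @param tx Transcript tibble.
#' @inheritParams find_longest_orf
#' @return Tibble with one row per transcript holding an ORF call
#'   (`orf_aa` is NA where none qualifies).
#' @export
orf_calls <- function(tx, min_aa = 25, both_strands = FALSE) {
  rows <- lapply(seq_len(nrow(tx)), function(r) {
    o <- find_longest_orf(tx$seq[r], min_aa = min_aa, both_strands = both_strands)
    if (is.null(o)) {
      tibble(id = tx$id[r], frame = NA_integer_, start = NA_real_,
             end = NA_real_, orf_aa = NA_integer_, orf_seq = NA_character_)
    } else {
      oseq <- if (o$strand == "+") substr(tx$seq[r], o$start + 1, o$end)
              else substr(revcomp(tx$seq[r]), o$start + 1, o$end)
      tibble(id = tx$id[r], frame = as.integer(o$frame), start = o$start,
             end = o$end, orf_aa = as.integer(o$peptide_length), orf_seq = oseq)
    }
  })
  purrr::list_rbind(rows)
}

#' Monoexonic / multiexonic counts per species
#'
#' @param tx Transcript tibble.
#' @return Tibble: `species`, `monoexonic`, `multiexonic`, `total`.
#' @export
classify_exonic_structure <- function(tx) {
  if (nrow(tx) == 0) {
    return(tibble(species = character(0), monoexonic = integer(0),
                  multiexonic = integer(0), total = integer(0)))
  }
  tibble(species = tx$species, n_exons = tx_exon_count(tx)) |>
    group_by(species) |>
    summarise(monoexonic = sum(n_exons == 1L),
              multiexonic = sum(n_exons > 1L),
              total = n(), .groups = "drop")
}

#' Per-transcript property table
#'
#' The standard property sheet: length, exon count, exonic and intronic GC,
#' and longest-ORF length.
#'
#' @param tx Transcript tibble.
#' @param genome Genome for intron GC (optional; intron GC NA without it).
#' @param min_aa ORF threshold passed to [orf_calls()].
#' @return Tibble: `id`, `species`, `length`, `exon_count`, `gc_exon`,
#'   `gc_intron`, `orf_aa`.
#' @export
transcript_properties <- function(tx, genome = NULL, min_aa = 25) {
  gc_in <- rep(NA_real_, nrow(tx))
  if (!is.null(genome)) {
    for (r in seq_len(nrow(tx))) {
      intr <- tx_introns(tx$exons[[r]])
      if (nrow(intr) > 0) {
        gc_in[r] <- gc_content(extract_genomic(genome, tx$chrom[r], intr, tx$strand[r]))
      }
    }
  }
  tibble(id = tx$id, species = tx$species, length = tx_length(tx),
         exon_count = tx_exon_count(tx),
         gc_exon = gc_content(tx$seq), gc_intron = gc_in,
         orf_aa = orf_calls(tx, min_aa = min_aa)$orf_aa)
}
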