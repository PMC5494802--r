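# Transcript container and interchange with standard formats.
#
# A transcript set is an ordinary tibble, one row per transcript:
#   id, species, chrom, strand ("+"/"-"), biotype ("lincRNA"/"coding"),
#   exons (list column of tibbles with 0-based half-open genomic start/end,
#   sorted, non-overlapping), seq (spliced sequence, DNA alphabet).
# Coordinates are 0-based half-open everywhere inside the package and are
# converted to 1-based closed only at GFF3 boundaries.

#' Build a transcript table
#'
#' Validates and assembles the canonical transcript tibble used throughout
#' the package. lincRNA transcripts must be longer than 200 nt (the defining
#' length threshold for long noncoding RNAs).
#'
#' @param id,species,chrom,strand,biotype Character vectors (recycled where
#'   length 1).
#' @param exons List of data frames with `start`, `end` (0-based half-open
#'   genomic intervals, sorted, non-overlapping).
#' @param seq Spliced sequences; length must equal the summed exon widths.
#' @param min_lincrna_length Minimum spliced length enforced for
#'   `biotype == "lincRNA"` (default 200).
#' @return A tibble of class `linc_transcripts`.
#' @export
transcript_table <- function(id, species, chrom, strand, exons, seq,
                             biotype = "lincRNA", min_lincrna_length = 200L) {
  tx <- tibble(id = as.character(id), species = species, chrom = chrom,
               strand = strand, biotype = biotype,
               exons = lapply(exons, function(e) as_tibble(e[c("start", "end")])),
               seq = normalize_sequence(seq))
  validate_transcripts(tx, min_lincrna_length)
  tx
}

validate_transcripts <- function(tx, min_lincrna_length = 200L) {
  if (anyDuplicated(tx$id)) abort("transcript ids must be unique")
  if (!all(tx$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  for (r in seq_len(nrow(tx))) {
    e <- tx$exons[[r]]
    if (nrow(e) == 0) abort(sprintf("%s: transcript needs >= 1 exon", tx$id[r]))
    if (is.unsorted(e$start, strictly = TRUE) && nrow(e) > 1)
      abort(sprintf("%s: exons must be sorted by start", tx$id[r]))
    if (any(e$end <= e$start))
      abort(sprintf("%s: exon end must exceed start", tx$id[r]))
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      abort(sprintf("%s: exons overlap", tx$id[r]))
    if (sum(e$end - e$start) != nchar(tx$seq[r]))
      abort(sprintf("%s: spliced length %d != summed exon widths %d",
                    tx$id[r], nchar(tx$seq[r]), sum(e$end - e$start)))
    if (tx$biotype[r] == "lincRNA" && nchar(tx$seq[r]) < min_lincrna_length)
      abort(sprintf("%s: lincRNA shorter than %d nt", tx$id[r], min_lincrna_length))
  }
  invisible(tx)
}

tx_length <- function(tx) nchar(tx$seq)
tx_exon_count <- function(tx) vapply(tx$exons, nrow, integer(1))
tx_span <- function(tx) {
  tibble(start = vapply(tx$exons, function(e) min(e$start), numeric(1)),
         end = vapply(tx$exons, function(e) max(e$end), numeric(1)))
}

# Introns as 0-based half-open genomic intervals (possibly empty tibble).
tx_introns <- function(exons) {
  if (nrow(exons) < 2) return(tibble(start = numeric(0), end = numeric(0)))
  tibble(start = exons$end[-nrow(exons)], end = exons$start[-1])
}

# Extract a genomic sub-sequence set from a genome (named chrom -> sequence),
# on the given strand; intervals 0-based half-open, concatenated in genomic
# order then reverse-complemented for "-".
extract_genomic <- function(genome, chrom, intervals, strand = "+") {
  chrseq <- genome[[chrom]]
  if (is.null(chrseq)) abort(sprintf("chromosome '%s' not in genome", chrom))
  if (nrow(intervals) == 0) return("")
  if (any(intervals$end > nchar(chrseq)))
    abort(sprintf("interval exceeds chromosome '%s' length", chrom))
  parts <- substring(chrseq, intervals$start + 1, intervals$end)
  out <- paste(parts, collapse = "")
  if (strand == "-") revcomp(out) else out
}

#' Reverse complement
#' @param sequence DNA string(s).
#' @return Reverse-complemented string(s).
#' @export
revcomp <- function(sequence) {
  vapply(sequence, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write spliced transcript sequences as FASTA
#'
#' @param tx Transcript tibble.
#' @param path Output file; sequences wrapped at 60 columns.
#' @export
write_transcript_fasta <- function(tx, path) {
  xs <- Biostrings::DNAStringSet(setNames(tx$seq, tx$id))
  Biostrings::writeXStringSet(xs, path, width = 60L)
  invisible(path)
}

#' Write transcripts as GFF3
#'
#' Emits `transcript` rows with child `exon` rows (1-based closed
#' coordinates, `ID`/`Parent` attributes, species carried as an attribute).
#'
#' @param tx Transcript tibble.
#' @param path Output file.
#' @param source Value for the GFF source column.
#' @export
write_transcript_gff3 <- function(tx, path, source = "linctools") {
  span <- tx_span(tx)
  lines <- c("##gff-version 3")
  for (r in seq_len(nrow(tx))) {
    attrs <- sprintf("ID=%s;species=%s;biotype=%s", tx$id[r], tx$species[r], tx$biotype[r])
    lines <- c(lines, paste(tx$chrom[r], source, "transcript",
                            span$start[r] + 1, span$end[r], ".", tx$strand[r], ".",
                            attrs, sep = "\t"))
    e <- tx$exons[[r]]
    for (k in seq_len(nrow(e))) {
      lines <- c(lines, paste(tx$chrom[r], source, "exon",
                              e$start[k] + 1, e$end[k], ".", tx$strand[r], ".",
                              sprintf("ID=%s.exon%d;Parent=%s", tx$id[r], k, tx$id[r]),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcripts back from GFF3 + spliced FASTA
#'
#' Inverse of [write_transcript_gff3()] + [write_transcript_fasta()]: parses
#' the GFF3 with rtracklayer, regroups exons under their parent transcript,
#' converts to 0-based half-open coordinates and attaches the spliced
#' sequence by id.
#'
#' @param gff_path,fasta_path Paths written by the exporters.
#' @return Transcript tibble equal to the one written.
#' @export
read_transcripts <- function(gff_path, fasta_path) {
  g <- rtracklayer::import(gff_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  txr <- g[g$type == "transcript"]
  exr <- g[g$type == "exon"]
  parent <- vapply(exr$Parent, function(p) p[[1]], character(1))
  rows <- lapply(seq_along(txr), function(i) {
    tid <- txr$ID[i]
    ex <- exr[parent == tid]
    ex <- ex[order(GenomicRanges::start(ex))]
    tibble(
      id = tid,
      species = if (!is.null(txr$species)) txr$species[i] else NA_character_,
      chrom = as.character(GenomicRanges::seqnames(txr)[i]),
      strand = as.character(GenomicRanges::strand(txr)[i]),
      biotype = if (!is.null(txr$biotype)) txr$biotype[i] else "lincRNA",
      exons = list(tibble(start = GenomicRanges::start(ex) - 1,
                          end = as.numeric(GenomicRanges::end(ex)))),
      seq = as.character(seqs[[tid]])
    )
  })
  out <- purrr::list_rbind(rows)
  validate_transcripts(out)
  out
}

# Spliced sequence recomputed from genome + exons (strand-aware); used to
# check consistency between annotation and sequence.
spliced_from_genome <- function(tx, genome) {
  vapply(seq_len(nrow(tx)), function(r) {
    extract_genomic(genome, tx$chrom[r], tx$exons[[r]], tx$strand[r])
  }, character(1))
}
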