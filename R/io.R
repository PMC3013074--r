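# Readers and writers for the standard interchange formats of the pipeline:
# FASTA/FASTQ (Biostrings), BED (rtracklayer), the tab-separated annotation
# table (0-based half-open, explicit strand), GMT (fgsea) and the JSON
# truth record.

#' Write sequences to FASTA
#' @param x A named `DNAStringSet` or character vector.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (!inherits(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
}

#' Read a FASTA file
#' @param path Input path.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a read multiset to FASTQ (Phred+33, constant quality)
#'
#' Expands (sequence, count) multisets to one record per read.
#'
#' @param reads A data.frame with `sequence` and `count` columns (e.g. an
#'   element of [simulate_smallrna_reads()]), or a character vector of
#'   reads.
#' @param path Output path.
#' @param quality Constant per-base quality character (default `"I"`,
#'   Q40).
#' @export
write_fastq <- function(reads, path, quality = "I") {
  seqs <- if (is.data.frame(reads))
    rep(reads$sequence, reads$count) else reads
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("read_%07d", seq_along(x))
  q <- Biostrings::BStringSet(strrep(quality, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
}

#' Read a FASTQ file
#' @param path Input path.
#' @return A `DNAStringSet` (qualities dropped).
#' @export
read_fastq <- function(path)
  Biostrings::readDNAStringSet(path, format = "fastq")

#' Write the transcript annotation table
#'
#' Tab-separated columns `chrom`, `start`, `end`, `strand`, `gene_id`,
#' `transcript_id`; coordinates 0-based half-open.
#'
#' @param annotation The annotation data.frame.
#' @param path Output path.
#' @param header Optional comment lines (prefixed `#`) to prepend.
#' @export
write_annotation <- function(annotation, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(annotation, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a transcript annotation table
#' @param path Input path (as written by [write_annotation()]).
#' @return data.frame with 0-based half-open coordinates.
#' @export
read_annotation <- function(path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)

#' Write genomic loci to BED
#' @param gr A `GRanges`; the `mirna_id`/`id` metadata column becomes the
#'   BED name field.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  nm <- if ("mirna_id" %in% names(mc)) mc$mirna_id
        else if ("id" %in% names(mc)) mc$id else NULL
  if (!is.null(nm)) names(gr) <- nm
  rtracklayer::export.bed(gr, path)
}

#' Read genomic loci from BED
#' @param path Input path.
#' @return A `GRanges` with a `mirna_id` metadata column from the BED name.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  S4Vectors::mcols(gr)$mirna_id <- S4Vectors::mcols(gr)$name
  gr
}

#' Write the truth record to JSON
#'
#' Serializes planted effects and hairpin loci so downstream recovery
#' checks can run without the generator objects.
#'
#' @param truth A `dge_truth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  hp <- truth$novel_hairpin_loci
  obj <- list(
    de_genes = as.list(truth$de_genes[truth$de_genes != 0]),
    de_mirnas = as.list(truth$de_mirnas[truth$de_mirnas != 0]),
    novel_hairpin_loci = data.frame(
      chrom = as.character(GenomicRanges::seqnames(hp)),
      start = BiocGenerics::start(hp) - 1L,
      end = BiocGenerics::end(hp),
      strand = as.character(BiocGenerics::strand(hp)),
      id = S4Vectors::mcols(hp)$id, stringsAsFactors = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read a truth record written by [write_truth()]
#' @param path Input path.
#' @return A list with `de_genes`, `de_mirnas` (named numeric vectors) and
#'   `novel_hairpin_loci` (data.frame).
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(de_genes = unlist(obj$de_genes),
       de_mirnas = unlist(obj$de_mirnas),
       novel_hairpin_loci = obj$novel_hairpin_loci)
}

# write a data.frame as TSV with a provenance header
write_report_tsv <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
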