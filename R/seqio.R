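#' Genome records
#'
#' A `genome_record` holds one genome: an identifier, an ordered set of
#' contig sequences (uppercase, alphabet restricted to A/C/G/T/N), the total
#' length in bp, and a content checksum. Contig order is meaningful and
#' preserved; two records with identical ordered contig sequences have equal
#' checksums regardless of their identifiers, which is how duplicate
#' submissions to a code registry are detected.
#'
#' Normalization maps lowercase to uppercase, U to T, and every other IUPAC
#' ambiguity letter (R, Y, S, W, K, M, B, D, H, V) to N. N is treated as a
#' masked position throughout the package: it never counts as a match during
#' identity computation.
#'
#' @param sequences named character vector of contig sequences (names are
#'   contig ids), or an unnamed vector (contigs are then named
#'   `contig_1`, ...).
#' @param genome_id short unique identifier for the genome.
#' @return An object of class `genome_record` with fields `genome_id`,
#'   `contigs` (named character vector), `total_length` and `checksum`.
#' @examples
#' g <- genome_record(c(chr = "acgtACGT"), "toy")
#' g$total_length
#' @export
genome_record <- function(sequences, genome_id) {
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("contig_", seq_along(sequences))
  }
  contigs <- vapply(sequences, normalize_sequence, character(1))
  if (any(!nzchar(contigs))) {
    stop("genome '", genome_id, "' contains zero-length sequences")
  }
  rec <- structure(
    list(
      genome_id = genome_id,
      contigs = contigs,
      total_length = sum(nchar(contigs)),
      checksum = genome_checksum(contigs)
    ),
    class = "genome_record"
  )
  rec
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, ": ", length(x$contigs), " contig(s), ",
      x$total_length, " bp, checksum ", x$checksum, "\n", sep = "")
  invisible(x)
}

# Uppercase, U->T, non-ACGT IUPAC -> N; error when the content does not look
# like nucleotide sequence (majority of characters outside the IUPAC set).
normalize_sequence <- function(seq) {
  s <- toupper(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  iupac <- c("A", "C", "G", "T", "U", "N",
             "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  bad <- !(chars %in% iupac)
  if (length(chars) > 0 && mean(bad) > 0.5) {
    stop("sequence does not look like nucleotide data (",
         round(100 * mean(bad)), "% of characters outside the IUPAC ",
         "nucleotide alphabet)")
  }
  chars[chars == "U"] <- "T"
  chars[!(chars %in% c("A", "C", "G", "T"))] <- "N"
  paste(chars, collapse = "")
}

# Content digest of the ordered contig sequences (ids excluded, so the same
# assembly under different naming hashes identically).
genome_checksum <- function(contigs) {
  cpp_fnv1a(paste(contigs, collapse = "\x01"))
}

#' Read a genome from a FASTA file
#'
#' Reads all records of a FASTA file as the contigs of one genome, normalizes
#' the sequences (see [genome_record()]) and returns a `genome_record`.
#'
#' @param path path to a FASTA file (one file = one genome; multi-record
#'   files are read as multi-contig genomes).
#' @param genome_id identifier for the genome; defaults to the file name
#'   without extension.
#' @return A [genome_record()].
#' @export
read_genome <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA file '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    stop("FASTA file '", path, "' contains zero-length sequences")
  }
  # first whitespace-delimited token of the header is the contig id
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fna|fasta|txt)$", "", basename(path),
                     ignore.case = TRUE)
  }
  genome_record(seqs, genome_id)
}

#' Write a genome to a FASTA file
#'
#' Inverse of [read_genome()]: writing a record and reading it back yields an
#' identical record (same checksum, same contig order).
#'
#' @param genome a [genome_record()].
#' @param path output file path.
#' @param width line width for the sequence lines.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_record"))
  set <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
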