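#' Save a registry as JSON lines
#'
#' Writes one JSON record per line: a header carrying the threshold table
#' and the ANI configuration (with its digest, for provenance), followed by
#' one record per entry in assignment order. Genome sequences are embedded
#' by default so a reloaded registry can be extended without access to the
#' original FASTA files; with `sequences = FALSE` only checksums are kept
#' and the registry reloads for inspection but not extension.
#'
#' @param registry a [code_registry()].
#' @param path output path.
#' @param sequences embed contig sequences.
#' @return `path`, invisibly.
#' @export
save_registry <- function(registry, path, sequences = TRUE) {
  stopifnot(inherits(registry, "code_registry"))
  header <- list(
    record = "header",
    format = "anicode-registry-v1",
    labels = registry$thresholds$label,
    thresholds_pct = registry$thresholds$threshold_pct,
    config = unclass(registry$config),
    config_digest = config_digest(registry$config))
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA),
    vapply(registry$entries, function(e) {
      rec <- list(
        record = "entry",
        assignment_index = e$assignment_index,
        genome_id = e$genome$genome_id,
        checksum = e$genome$checksum,
        code = e$code,
        assigned_from = e$assigned_from,
        ani_at_assignment = e$ani_at_assignment,
        pct_aligned_at_assignment = e$pct_aligned_at_assignment,
        trusted = e$trusted)
      if (sequences) rec$contigs <- as.list(e$genome$contigs)
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Load a registry saved with [save_registry()]
#'
#' Checksums of embedded sequences are re-verified on load.
#'
#' @param path path to a JSON-lines registry file.
#' @return A [code_registry()].
#' @export
load_registry <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty registry file: ", path)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  if (!identical(header$record, "header") ||
      !identical(header$format, "anicode-registry-v1")) {
    stop("'", path, "' is not an anicode registry file")
  }
  cfg <- header$config
  cfg <- cfg[names(cfg) %in% names(formals(ani_config))]
  registry <- code_registry(
    thresholds = threshold_table(header$labels, header$thresholds_pct),
    config = do.call(ani_config, cfg))
  entries <- lapply(lines[-1], function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    if (!identical(rec$record, "entry")) stop("malformed registry line")
    genome <- NULL
    if (!is.null(rec$contigs)) {
      genome <- genome_record(unlist(rec$contigs), rec$genome_id)
      if (!identical(genome$checksum, rec$checksum)) {
        stop("checksum mismatch for genome '", rec$genome_id,
             "' in '", path, "'")
      }
    } else {
      genome <- structure(
        list(genome_id = rec$genome_id, contigs = NULL,
             total_length = NA_integer_, checksum = rec$checksum),
        class = "genome_record")
    }
    list(genome = genome,
         code = as.integer(rec$code),
         assigned_from = if (is.null(rec$assigned_from)) NA_character_
                         else rec$assigned_from,
         ani_at_assignment = if (is.null(rec$ani_at_assignment)) NA_real_
                             else rec$ani_at_assignment,
         pct_aligned_at_assignment =
           if (is.null(rec$pct_aligned_at_assignment)) NA_real_
           else rec$pct_aligned_at_assignment,
         trusted = if (is.null(rec$trusted)) NA else rec$trusted,
         assignment_index = rec$assignment_index)
  })
  registry$entries <- entries
  registry
}

#' Export registry codes as a display table
#'
#' Produces the kind of table used to report assigned codes: genome id,
#' formatted code (optionally projected onto a subset of positions, e.g.
#' only the deepest positions for a set of near-identical isolates),
#' assignment anchor, ANI and percentage of aligned fragments.
#'
#' @param registry a [code_registry()].
#' @param positions optional character vector of position labels to show.
#' @param path optional output path; when given, the table is also written
#'   as TSV.
#' @return A data frame.
#' @export
export_codes <- function(registry, positions = NULL, path = NULL) {
  stopifnot(inherits(registry, "code_registry"))
  tab <- do.call(rbind, lapply(registry$entries, function(e) data.frame(
    genome_id = e$genome$genome_id,
    code = format_code(genome_code(e$code, registry$thresholds), positions),
    assigned_from = e$assigned_from,
    ani_pct = e$ani_at_assignment,
    pct_aligned_fragments = e$pct_aligned_at_assignment,
    stringsAsFactors = FALSE)))
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}
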