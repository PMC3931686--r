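#' Tile a genome into consecutive fragments
#'
#' Cuts every contig, left to right, into consecutive non-overlapping windows
#' of `fragment_length` bp. A shorter trailing window is kept, so each contig
#' yields `ceiling(contig_length / fragment_length)` fragments and the
#' fragments cover the contig exactly. Contigs are tiled independently:
#' fragments never span a contig junction.
#'
#' @param genome a [genome_record()].
#' @param fragment_length window size in bp.
#' @return A data frame with one row per fragment and columns `contig`,
#'   `start`, `end` (1-based, inclusive) and `sequence`.
#' @export
tile_genome <- function(genome, fragment_length = 1020L) {
  stopifnot(inherits(genome, "genome_record"), fragment_length >= 1L)
  fragment_length <- as.integer(fragment_length)
  pieces <- lapply(seq_along(genome$contigs), function(i) {
    len <- nchar(genome$contigs[[i]])
    starts <- seq.int(1L, len, by = fragment_length)
    ends <- pmin(starts + fragment_length - 1L, len)
    data.frame(contig = names(genome$contigs)[i], start = starts, end = ends,
               sequence = substring(genome$contigs[[i]], starts, ends),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Align one fragment to a subject genome
#'
#' Finds the best local alignment of a fragment to either strand of any
#' subject contig and reports the aligned fraction of the fragment, the
#' percent identity of that single best alignment, and whether the fragment
#' passes the coverage and identity filters of `config`. Identity is
#' computed as identical aligned bases over alignment columns (matches,
#' mismatches and gap columns); N never counts as a match. Score ties are
#' resolved deterministically (lower subject contig index, lower subject
#' start, forward strand first).
#'
#' @param fragment a fragment sequence (character scalar).
#' @param subject a [genome_record()].
#' @param config an [ani_config()]; selects the backend and the filters.
#' @return A list with `aligned_fraction`, `identity_pct` and `passed`.
#' @export
align_fragment <- function(fragment, subject, config = ani_config()) {
  hits <- align_fragments(fragment, subject, config)
  list(aligned_fraction = hits$aligned_fraction[1],
       identity_pct = hits$identity_pct[1],
       passed = hits$aligned_fraction[1] >= config$coverage_min &&
         hits$identity_pct[1] >= config$identity_min)
}

# Batch alignment of many fragments against one subject genome.
# Returns a data.frame(aligned_fraction, identity_pct), one row per fragment.
align_fragments <- function(fragments, subject, config) {
  stopifnot(inherits(subject, "genome_record"))
  switch(config$backend,
         exact = align_fragments_exact(fragments, subject, config),
         seed = align_fragments_seed(fragments, subject, config),
         blast = align_fragments_blast(fragments, subject, config))
}

align_fragments_exact <- function(fragments, subject, config) {
  n <- length(fragments)
  frac <- numeric(n)
  ident <- numeric(n)
  for (i in seq_len(n)) {
    frag <- fragments[i]
    flen <- nchar(frag)
    rc <- revcomp(frag)
    best <- NULL
    # order encodes the tie-break: contigs in order, forward strand first
    for (ci in seq_along(subject$contigs)) {
      for (q in c(frag, rc)) {
        a <- cpp_sw_align(q, subject$contigs[[ci]],
                          config$match, config$mismatch, config$gap)
        if (a[1] > 0 && (is.null(best) || a[1] > best[1])) best <- a
      }
    }
    if (!is.null(best)) {
      frac[i] <- (best[3] - best[2] + 1L) / flen
      ident[i] <- 100 * best[6] / best[7]
    }
  }
  data.frame(aligned_fraction = frac, identity_pct = ident)
}

align_fragments_seed <- function(fragments, subject, config) {
  n <- length(fragments)
  best <- matrix(0L, nrow = n, ncol = 5)
  for (ci in seq_along(subject$contigs)) {
    m <- cpp_seed_align(fragments, subject$contigs[[ci]], config$seed_k,
                        config$match, config$mismatch)
    upd <- m[, "score"] > best[, 1]
    best[upd, ] <- m[upd, , drop = FALSE]
  }
  frac <- ifelse(best[, 1] > 0, best[, 4] / nchar(fragments), 0)
  ident <- ifelse(best[, 1] > 0, 100 * best[, 2] / pmax(best[, 3], 1L), 0)
  data.frame(aligned_fraction = frac, identity_pct = ident)
}

# External blastn backend using the classical ANIb parameterization
# (reward 1, mismatch -5, no dust filtering, e-value 1e-15). pident uses
# BLAST's own denominator (alignment length including gap columns), matching
# the package's definition; N handling is the aligner's own.
align_fragments_blast <- function(fragments, subject, config) {
  if (Sys.which("blastn") == "") {
    stop("the 'blast' backend requires blastn on the PATH")
  }
  n <- length(fragments)
  dir <- tempfile("anib")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  qf <- file.path(dir, "query.fasta")
  sf <- file.path(dir, "subject.fasta")
  writeLines(paste0(">f", seq_len(n), "\n", fragments), qf)
  writeLines(paste0(">", names(subject$contigs), "\n", subject$contigs), sf)
  out <- system2("blastn",
                 c("-task", "blastn", "-query", qf, "-subject", sf,
                   "-reward", "1", "-penalty", "-5",
                   "-gapopen", "3", "-gapextend", "3", "-dust", "no",
                   "-evalue", "1e-15", "-xdrop_gap_final", "150",
                   "-outfmt", shQuote("6 qseqid pident length qstart qend bitscore")),
                 stdout = TRUE)
  frac <- numeric(n)
  ident <- numeric(n)
  if (length(out)) {
    hits <- read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
                       col.names = c("qseqid", "pident", "length",
                                     "qstart", "qend", "bitscore"))
    hits$idx <- as.integer(sub("^f", "", hits$qseqid))
    hits <- hits[order(hits$idx, -hits$bitscore), ]
    hits <- hits[!duplicated(hits$idx), ]
    frac[hits$idx] <- (hits$qend - hits$qstart + 1) / nchar(fragments[hits$idx])
    ident[hits$idx] <- hits$pident
  }
  data.frame(aligned_fraction = frac, identity_pct = ident)
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE))
}

#' Core-genome identity filter
#'
#' Restricts a set of passed fragment identities to those within
#' `halfwidth` percentage points of their median (boundaries inclusive; the
#' median of an even-length set is the mean of the two central values). This
#' approximates the vertically inherited core genome: fragments from
#' horizontally transferred regions sit far from the bulk of the identity
#' distribution and are discarded before averaging.
#'
#' The result always contains every median-attaining element. In the
#' degenerate case where no identity lies within the window of the median
#' (possible for bimodal two-point inputs), the input is returned unfiltered
#' and the `"fallback"` attribute of the result is set to `TRUE`.
#'
#' @param identities numeric vector of percent identities (non-empty).
#' @param halfwidth window half-width in percentage points.
#' @return The filtered numeric vector, with attribute `fallback`.
#' @examples
#' core_filter(c(99.0, 99.05, 99.1, 98.0, 95.0), 0.1)
#' @export
core_filter <- function(identities, halfwidth = 0.1) {
  if (length(identities) == 0L) stop("'identities' must be non-empty")
  med <- median(identities)
  keep <- abs(identities - med) <= halfwidth
  if (!any(keep)) {
    return(structure(identities, fallback = TRUE))
  }
  structure(identities[keep], fallback = FALSE)
}

#' Fragment-based similarity of an ordered genome pair
#'
#' Tiles the query genome into fragments, aligns every fragment to the
#' subject, applies the coverage and identity filters, optionally applies
#' the core-genome median filter to the passed identities, and reports the
#' average nucleotide identity (ANI, the arithmetic mean of the retained
#' fragment identities) and the percentage of aligned fragments (passed
#' fragments over all query fragments, always computed before the core
#' filter).
#'
#' The measure is asymmetric by construction: `compute_similarity(a, b)`
#' tiles `a`, `compute_similarity(b, a)` tiles `b`, and the two need not
#' agree. When no fragment passes the filters the ANI is undefined and
#' reported as `NA`.
#'
#' @param query,subject [genome_record()]s.
#' @param config an [ani_config()].
#' @return A list of class `pairwise_similarity` with fields `query_id`,
#'   `subject_id`, `ani_pct`, `pct_aligned_fragments`, `n_fragments`,
#'   `n_passed`, `passed_identities` (pre-core-filter), `core_filter_applied`
#'   and `core_filter_fallback`.
#' @export
compute_similarity <- function(query, subject, config = ani_config()) {
  stopifnot(inherits(query, "genome_record"), inherits(subject, "genome_record"))
  tiles <- tile_genome(query, config$fragment_length)
  if (is.null(tiles) || nrow(tiles) == 0L) {
    stop("query genome '", query$genome_id, "' yields no fragments")
  }
  hits <- align_fragments(tiles$sequence, subject, config)
  passed <- hits$aligned_fraction >= config$coverage_min &
    hits$identity_pct >= config$identity_min
  ids <- hits$identity_pct[passed]
  fallback <- FALSE
  ani_ids <- ids
  if (config$core_filter && length(ids) > 0L) {
    ani_ids <- core_filter(ids, config$core_filter_halfwidth)
    fallback <- isTRUE(attr(ani_ids, "fallback"))
  }
  structure(
    list(query_id = query$genome_id,
         subject_id = subject$genome_id,
         ani_pct = if (length(ani_ids)) mean(ani_ids) else NA_real_,
         pct_aligned_fragments = 100 * sum(passed) / nrow(tiles),
         n_fragments = nrow(tiles),
         n_passed = sum(passed),
         passed_identities = as.numeric(ids),
         core_filter_applied = config$core_filter,
         core_filter_fallback = fallback),
    class = "pairwise_similarity"
  )
}

#' @export
print.pairwise_similarity <- function(x, ...) {
  cat("<pairwise_similarity> ", x$query_id, " vs ", x$subject_id, ": ANI ",
      if (is.na(x$ani_pct)) "undefined" else sprintf("%.4f%%", x$ani_pct),
      ", ", sprintf("%.2f%%", x$pct_aligned_fragments), " of ",
      x$n_fragments, " fragments aligned\n", sep = "")
  invisible(x)
}

#' All-against-all similarity table
#'
#' Computes [compute_similarity()] for every ordered pair of genomes and
#' returns the results as one table with deterministic row order (query in
#' input order, then subject in input order).
#'
#' @param genomes list of [genome_record()]s with unique ids.
#' @param config an [ani_config()].
#' @param include_self also compute each genome against itself.
#' @param cache optional [similarity_cache()] to reuse across calls.
#' @return A data frame with columns `query_id`, `subject_id`, `ani_pct`,
#'   `pct_aligned_fragments`, `n_fragments`, `n_passed`.
#' @export
all_against_all <- function(genomes, config = ani_config(),
                            include_self = FALSE, cache = NULL) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- list()
  for (i in seq_along(genomes)) {
    for (j in seq_along(genomes)) {
      if (i == j && !include_self) next
      sim <- cached_similarity(genomes[[i]], genomes[[j]], config, cache)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = sim$query_id, subject_id = sim$subject_id,
        ani_pct = sim$ani_pct,
        pct_aligned_fragments = sim$pct_aligned_fragments,
        n_fragments = sim$n_fragments, n_passed = sim$n_passed,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a similarity table as TSV
#'
#' @param table result of [all_against_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Similarity cache
#'
#' A mutable cache of [compute_similarity()] results keyed by query
#' checksum, subject checksum and configuration digest. Sharing one cache
#' across registry builds (in particular across the random orders of
#' [permutation_study()]) ensures each ordered genome pair is aligned at
#' most once.
#'
#' @return An environment of class `similarity_cache`; `n_computed` counts
#'   cache misses.
#' @export
similarity_cache <- function() {
  env <- new.env(parent = emptyenv())
  env$store <- new.env(parent = emptyenv())
  env$n_computed <- 0L
  class(env) <- "similarity_cache"
  env
}

cached_similarity <- function(query, subject, config, cache = NULL) {
  if (is.null(cache)) return(compute_similarity(query, subject, config))
  key <- paste(query$checksum, subject$checksum, config_digest(config),
               sep = "|")
  hit <- cache$store[[key]]
  if (!is.null(hit)) return(hit)
  sim <- compute_similarity(query, subject, config)
  cache$store[[key]] <- sim
  cache$n_computed <- cache$n_computed + 1L
  sim
}
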