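#' ANI computation settings
#'
#' Bundles every tunable of the fragment-based ANI calculation. The defaults
#' reproduce the classical ANIb recipe: genomes are tiled into 1020 bp
#' consecutive fragments, and a fragment counts as aligned when its best
#' local alignment to the subject covers at least 70% of the fragment length
#' with at least 30% overall identity. Both filter comparisons are inclusive
#' (a fragment at exactly the boundary passes).
#'
#' @param fragment_length tile size in bp; trailing fragments of a contig may
#'   be shorter and are judged against their own length.
#' @param coverage_min minimum aligned fraction of the fragment length, in
#'   `(0, 1]`.
#' @param identity_min minimum percent identity of the best alignment.
#' @param trust_min_pct_aligned minimum percentage of aligned fragments for a
#'   subject to be a trusted anchor during code assignment.
#' @param core_filter if `TRUE`, passed fragment identities are additionally
#'   restricted to a window around their median before averaging
#'   (see [core_filter()]); approximates the vertically inherited core genome
#'   by discarding identity outliers such as horizontally transferred
#'   regions.
#' @param core_filter_halfwidth half-width, in percentage points, of the
#'   median window used by the core filter.
#' @param backend alignment backend: `"exact"` (Smith-Waterman local
#'   alignment; the default, exact but quadratic, intended for genomes up to
#'   a few tens of kb), `"seed"` (k-mer seed and ungapped extension; fast,
#'   for large substitution-divergent genomes without indels), or `"blast"`
#'   (external `blastn`, the aligner classically used for ANIb; requires
#'   BLAST+ on the PATH).
#' @param seed_k k-mer size of the `"seed"` backend.
#' @param match,mismatch,gap alignment scores (linear gap penalty), shared by
#'   the `"exact"` and `"seed"` backends.
#' @return A list of class `ani_config`.
#' @export
ani_config <- function(fragment_length = 1020L,
                       coverage_min = 0.70,
                       identity_min = 30,
                       trust_min_pct_aligned = 20,
                       core_filter = FALSE,
                       core_filter_halfwidth = 0.1,
                       backend = c("exact", "seed", "blast"),
                       seed_k = 13L,
                       match = 2L, mismatch = -3L, gap = 5L) {
  backend <- match.arg(backend)
  fragment_length <- as.integer(fragment_length)
  stopifnot(fragment_length >= 1L,
            coverage_min > 0, coverage_min <= 1,
            identity_min >= 0, identity_min <= 100,
            trust_min_pct_aligned >= 0, trust_min_pct_aligned <= 100,
            core_filter_halfwidth >= 0,
            seed_k >= 4L, seed_k <= 31L)
  structure(
    list(fragment_length = fragment_length,
         coverage_min = coverage_min,
         identity_min = identity_min,
         trust_min_pct_aligned = trust_min_pct_aligned,
         core_filter = isTRUE(core_filter),
         core_filter_halfwidth = core_filter_halfwidth,
         backend = backend,
         seed_k = as.integer(seed_k),
         match = as.integer(match),
         mismatch = as.integer(mismatch),
         gap = as.integer(gap)),
    class = "ani_config"
  )
}

#' @export
print.ani_config <- function(x, ...) {
  cat("<ani_config> fragment ", x$fragment_length, " bp; filters coverage >= ",
      x$coverage_min, ", identity >= ", x$identity_min, "%; trust >= ",
      x$trust_min_pct_aligned, "% aligned; core filter ",
      if (x$core_filter) paste0("on (median +/- ", x$core_filter_halfwidth,
                                " pp)") else "off",
      "; backend ", x$backend, "\n", sep = "")
  invisible(x)
}

# Stable digest of a config, recorded with similarity results and registry
# entries for provenance and used as part of the similarity cache key.
config_digest <- function(config) {
  stopifnot(inherits(config, "ani_config"))
  cpp_fnv1a(paste(names(config), vapply(config, format, character(1)),
                  sep = "=", collapse = ";"))
}

#' Read / write an `ani_config` as YAML
#'
#' @param path file path.
#' @return `read_ani_config()` returns an [ani_config()]; `write_ani_config()`
#'   returns `path` invisibly.
#' @export
read_ani_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ani_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  do.call(ani_config, vals)
}

#' @param config an [ani_config()].
#' @rdname read_ani_config
#' @export
write_ani_config <- function(config, path) {
  stopifnot(inherits(config, "ani_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Similarity threshold tables
#'
#' A threshold table defines the positions of a genome code: an ordered set
#' of labelled ANI thresholds, strictly increasing from left to right. Each
#' code position corresponds to one threshold; a genome shares a position
#' with its assignment anchor when its ANI strictly exceeds that position's
#' threshold.
#'
#' The default table has 24 positions labelled A through X, spanning 60% to
#' 99.9999% ANI, with intervals that shrink towards the right so that the
#' deepest positions resolve near-identical genomes:
#' A:60, B:70, C:80, D:85, E:90, F:95, G:98, H:99, I:99.5, J:99.6, K:99.7,
#' L:99.8, M:99.9, N:99.91, O:99.92, P:99.93, Q:99.94, R:99.95, S:99.96,
#' T:99.97, U:99.98, V:99.99, W:99.999, X:99.9999. The 95% threshold at
#' position F approximates the classical bacterial species boundary
#' (70% DNA-DNA hybridization).
#'
#' @param labels character vector of position labels.
#' @param thresholds numeric vector of ANI thresholds (percent), strictly
#'   increasing, all in (0, 100).
#' @return A data frame of class `threshold_table` with columns `label` and
#'   `threshold_pct`.
#' @export
threshold_table <- function(labels, thresholds) {
  stopifnot(is.character(labels), length(labels) >= 1L,
            length(labels) == length(thresholds),
            !anyDuplicated(labels))
  thresholds <- as.numeric(thresholds)
  if (any(thresholds <= 0) || any(thresholds >= 100)) {
    stop("thresholds must lie in (0, 100)")
  }
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing left to right")
  }
  structure(
    data.frame(label = labels, threshold_pct = thresholds,
               stringsAsFactors = FALSE),
    class = c("threshold_table", "data.frame")
  )
}

#' @rdname threshold_table
#' @export
default_threshold_table <- function() {
  threshold_table(
    c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
      "M", "N", "O", "P", "Q", "R", "S", "T", "U", "V", "W", "X"),
    c(60, 70, 80, 85, 90, 95, 98, 99, 99.5, 99.6, 99.7, 99.8,
      99.9, 99.91, 99.92, 99.93, 99.94, 99.95, 99.96, 99.97, 99.98,
      99.99, 99.999, 99.9999)
  )
}

table_digest <- function(table) {
  stopifnot(inherits(table, "threshold_table"))
  cpp_fnv1a(paste(table$label, format(table$threshold_pct, digits = 12),
                  sep = ":", collapse = ";"))
}

#' Read / write a threshold table as YAML
#'
#' The file holds a mapping of position label to ANI threshold, in position
#' order.
#'
#' @param path file path.
#' @return `read_threshold_table()` returns a [threshold_table()].
#' @export
read_threshold_table <- function(path) {
  vals <- yaml::read_yaml(path)
  threshold_table(names(vals), unlist(vals, use.names = FALSE))
}

#' @param table a [threshold_table()].
#' @rdname read_threshold_table
#' @export
write_threshold_table <- function(table, path) {
  stopifnot(inherits(table, "threshold_table"))
  yaml::write_yaml(setNames(as.list(table$threshold_pct), table$label), path)
  invisible(path)
}
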