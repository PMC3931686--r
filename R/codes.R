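#' Genome code registries
#'
#' A code registry is the growing database of coded genomes. Genomes are
#' registered strictly sequentially; each entry stores the genome, its code
#' (one non-negative integer per threshold position), the genome it was
#' assigned from, and the similarity values at assignment time. Codes are
#' immutable once assigned: registering further genomes never alters
#' existing entries, which is what makes the codes usable as permanent
#' names.
#'
#' @param thresholds a [threshold_table()]; defaults to the 24-position
#'   table of [default_threshold_table()].
#' @param config an [ani_config()].
#' @param cache a [similarity_cache()]; defaults to a fresh cache private to
#'   the registry. Pass a shared cache to reuse alignments across registries
#'   built from the same genomes.
#' @return An object of class `code_registry`.
#' @export
code_registry <- function(thresholds = default_threshold_table(),
                          config = ani_config(),
                          cache = similarity_cache()) {
  stopifnot(inherits(thresholds, "threshold_table"),
            inherits(config, "ani_config"))
  structure(
    list(entries = list(), thresholds = thresholds, config = config,
         cache = cache),
    class = "code_registry"
  )
}

#' @export
print.code_registry <- function(x, ...) {
  cat("<code_registry> ", length(x$entries), " genome(s), ",
      nrow(x$thresholds), " code positions (",
      x$thresholds$label[1], "..",
      x$thresholds$label[nrow(x$thresholds)], ")\n", sep = "")
  if (length(x$entries)) print(head(registry_table(x), 10))
  invisible(x)
}

registry_checksums <- function(registry) {
  vapply(registry$entries, function(e) e$genome$checksum, character(1))
}

registry_codes <- function(registry) {
  do.call(rbind, lapply(registry$entries, function(e) e$code))
}

#' Register the first genome of an empty registry
#'
#' The first genome is the reference point of the whole registry and is
#' assigned the value 0 at every code position.
#'
#' @param registry an empty [code_registry()].
#' @param genome a [genome_record()].
#' @return The updated registry (one entry, assignment index 0).
#' @export
register_first <- function(registry, genome) {
  stopifnot(inherits(registry, "code_registry"),
            inherits(genome, "genome_record"))
  if (length(registry$entries) > 0L) {
    stop("registry is not empty; use assign_code() or register_genome()")
  }
  entry <- list(genome = genome,
                code = integer(nrow(registry$thresholds)),
                assigned_from = NA_character_,
                ani_at_assignment = NA_real_,
                pct_aligned_at_assignment = NA_real_,
                trusted = NA,
                assignment_index = 0L)
  registry$entries <- list(entry)
  registry
}

#' Most similar registered genome
#'
#' Computes the similarity of a query against every registered genome. If
#' any subject attains at least `trust_min_pct_aligned` percent aligned
#' fragments, the candidate set is restricted to those subjects and the one
#' with the highest ANI is returned with `trusted = TRUE`. Otherwise the
#' globally highest-ANI subject is returned with `trusted = FALSE`
#' (a low alignable fraction means the ANI carries little phylogenetic
#' signal, so such a subject is not used as an assignment anchor). ANI ties
#' are broken towards the earlier-registered genome.
#'
#' @param registry a non-empty [code_registry()].
#' @param query a [genome_record()].
#' @return A list with `index` (position in the registry), `entry`,
#'   `similarity` (a `pairwise_similarity`) and `trusted`.
#' @export
find_most_similar <- function(registry, query) {
  stopifnot(inherits(registry, "code_registry"))
  if (length(registry$entries) == 0L) {
    stop("registry is empty; register the first genome with register_first()")
  }
  sims <- lapply(registry$entries, function(e)
    cached_similarity(query, e$genome, registry$config, registry$cache))
  ani <- vapply(sims, function(s) s$ani_pct, numeric(1))
  pct <- vapply(sims, function(s) s$pct_aligned_fragments, numeric(1))
  ani[is.na(ani)] <- -Inf
  candidates <- which(pct >= registry$config$trust_min_pct_aligned)
  trusted <- length(candidates) > 0L
  if (!trusted) candidates <- seq_along(sims)
  # which.max returns the first maximum: earlier-registered genome wins ties
  best <- candidates[which.max(ani[candidates])]
  if (trusted && !is.finite(ani[best])) trusted <- FALSE
  list(index = best, entry = registry$entries[[best]],
       similarity = sims[[best]], trusted = trusted)
}

# Threshold walk: copy the anchor's value while the ANI strictly exceeds the
# position threshold; at the first position not exceeded, leave NA (a fresh
# sibling value is filled in by the caller) and zero everything after. When
# every threshold is exceeded the anchor's code is copied in full, so two
# near-identical genomes may legitimately share a code.
walk_code <- function(anchor_values, ani_pct, thresholds_pct) {
  n <- length(thresholds_pct)
  values <- integer(n)
  n_shared <- sum(cumprod(ani_pct > thresholds_pct) > 0)
  if (n_shared == n) return(list(values = anchor_values, fresh_at = NA_integer_))
  if (n_shared > 0) values[seq_len(n_shared)] <- anchor_values[seq_len(n_shared)]
  values[n_shared + 1L] <- NA_integer_
  list(values = values, fresh_at = n_shared + 1L)
}

# Sibling-scoped fresh value at a position: one more than the largest value
# held at that position by registered entries whose codes match the new code
# at every position to the left; 0 when no such sibling exists.
fresh_value <- function(registry, values, position) {
  codes <- registry_codes(registry)
  if (is.null(codes)) return(0L)
  if (position > 1L) {
    prefix <- values[seq_len(position - 1L)]
    sib <- apply(codes[, seq_len(position - 1L), drop = FALSE], 1L,
                 function(v) all(v == prefix))
  } else {
    sib <- rep(TRUE, nrow(codes))
  }
  if (!any(sib)) return(0L)
  max(codes[sib, position]) + 1L
}

#' Assign a code to a new genome
#'
#' Implements the sequential assignment rule. The most similar registered
#' genome is located with [find_most_similar()]. If it is trusted (at least
#' `trust_min_pct_aligned` percent of the query fragments aligned), the code
#' positions are walked left to right: while the ANI strictly exceeds the
#' position's threshold the anchor's value is copied; at the first position
#' whose threshold is not exceeded the genome receives the next free value
#' among its code siblings (entries sharing its values at every position to
#' the left) and 0 at every later position. A genome whose ANI exceeds all
#' thresholds receives a full copy of the anchor's code. If no subject is
#' trusted (including the case of an undefined ANI), the genome founds a new
#' lineage: next free value at the first position, 0 elsewhere.
#'
#' Duplicate submissions (identical sequence content, by checksum) are
#' rejected with an error of class `anicode_duplicate_genome` carrying the
#' existing entry.
#'
#' @param registry a non-empty [code_registry()].
#' @param genome a [genome_record()] not yet registered.
#' @return The updated registry; the new entry is the last element of
#'   `registry$entries`.
#' @export
assign_code <- function(registry, genome) {
  stopifnot(inherits(registry, "code_registry"),
            inherits(genome, "genome_record"))
  if (length(registry$entries) == 0L) {
    stop("registry is empty; register the first genome with register_first()")
  }
  dup <- which(registry_checksums(registry) == genome$checksum)
  if (length(dup)) {
    existing <- registry$entries[[dup[1]]]
    stop(structure(
      class = c("anicode_duplicate_genome", "error", "condition"),
      list(message = paste0(
             "genome '", genome$genome_id, "' duplicates registered genome '",
             existing$genome$genome_id, "' (code ",
             format_code(genome_code(existing$code, registry$thresholds)), ")"),
           call = sys.call(-1), entry = existing)))
  }
  found <- find_most_similar(registry, genome)
  thr <- registry$thresholds$threshold_pct
  if (found$trusted) {
    walked <- walk_code(found$entry$code, found$similarity$ani_pct, thr)
    values <- walked$values
    if (!is.na(walked$fresh_at)) {
      values[walked$fresh_at] <- fresh_value(registry, values, walked$fresh_at)
    }
  } else {
    values <- integer(length(thr))
    values[1L] <- fresh_value(registry, values, 1L)
  }
  entry <- list(genome = genome,
                code = values,
                assigned_from = found$entry$genome$genome_id,
                ani_at_assignment =
                  if (is.finite(found$similarity$ani_pct))
                    found$similarity$ani_pct else NA_real_,
                pct_aligned_at_assignment = found$similarity$pct_aligned_fragments,
                trusted = found$trusted,
                assignment_index = length(registry$entries))
  registry$entries <- c(registry$entries, list(entry))
  registry
}

#' Register a genome (first or subsequent)
#'
#' Convenience dispatcher: [register_first()] on an empty registry,
#' [assign_code()] otherwise.
#'
#' @inheritParams assign_code
#' @return The updated registry.
#' @export
register_genome <- function(registry, genome) {
  if (length(registry$entries) == 0L) register_first(registry, genome)
  else assign_code(registry, genome)
}

#' Build a registry from an ordered set of genomes
#'
#' Registers the genomes strictly in the given order: the first founds the
#' registry with an all-zero code, every later genome is compared to all
#' genomes registered before it and coded from the most similar one.
#'
#' @param genomes ordered list of [genome_record()]s with unique ids.
#' @param thresholds a [threshold_table()].
#' @param config an [ani_config()].
#' @param cache optional shared [similarity_cache()].
#' @return The completed [code_registry()]; see [registry_table()] for the
#'   per-genome provenance table.
#' @export
build_registry <- function(genomes, thresholds = default_threshold_table(),
                           config = ani_config(), cache = similarity_cache()) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  registry <- code_registry(thresholds, config, cache)
  for (g in genomes) registry <- register_genome(registry, g)
  registry
}

#' Provenance table of a registry
#'
#' One row per registered genome: its formatted code, the genome it was
#' assigned from, and the ANI and percentage of aligned fragments measured
#' at assignment time.
#'
#' @param registry a [code_registry()].
#' @return A data frame ordered by assignment index.
#' @export
registry_table <- function(registry) {
  stopifnot(inherits(registry, "code_registry"))
  do.call(rbind, lapply(registry$entries, function(e) data.frame(
    assignment_index = e$assignment_index,
    genome_id = e$genome$genome_id,
    code = format_code(genome_code(e$code, registry$thresholds)),
    assigned_from = e$assigned_from,
    ani_pct = e$ani_at_assignment,
    pct_aligned_fragments = e$pct_aligned_at_assignment,
    trusted = e$trusted,
    stringsAsFactors = FALSE)))
}

#' Genome codes
#'
#' A `genome_code` couples a vector of non-negative position values with the
#' threshold table that defines the positions.
#'
#' @param values integer vector, one value per threshold position.
#' @param table the [threshold_table()] the code was assigned under.
#' @return An object of class `genome_code`.
#' @export
genome_code <- function(values, table = default_threshold_table()) {
  stopifnot(inherits(table, "threshold_table"),
            length(values) == nrow(table), all(values >= 0))
  structure(as.integer(values), labels = table$label,
            table_digest = table_digest(table), class = "genome_code")
}

#' @export
print.genome_code <- function(x, ...) {
  cat(format_code(x), "\n")
  invisible(x)
}

#' Last shared code position
#'
#' The rightmost position up to which two codes agree at every position: the
#' code system's measure of relatedness. The deeper the last shared
#' position, the more similar the genomes.
#'
#' @param code1,code2 [genome_code()]s assigned under the same threshold
#'   table.
#' @return The 1-based index of the last shared position, or 0 when the
#'   codes already differ at the first position.
#' @export
last_shared_position <- function(code1, code2) {
  stopifnot(inherits(code1, "genome_code"), inherits(code2, "genome_code"))
  if (!identical(attr(code1, "table_digest"), attr(code2, "table_digest"))) {
    stop("codes were assigned under different threshold tables")
  }
  sum(cumprod(unclass(code1) == unclass(code2)) > 0)
}

#' Format a genome code as text
#'
#' The canonical text form joins `<value>_<label>` tokens with underscores,
#' e.g. `"12_A_0_B_1_C"`. A subset of positions can be projected out for
#' display, e.g. only the deepest positions when comparing near-identical
#' genomes.
#'
#' @param code a [genome_code()].
#' @param positions optional character vector of position labels to show, in
#'   table order.
#' @return A character scalar.
#' @export
format_code <- function(code, positions = NULL) {
  stopifnot(inherits(code, "genome_code"))
  labels <- attr(code, "labels")
  idx <- seq_along(labels)
  if (!is.null(positions)) {
    if (!all(positions %in% labels)) {
      stop("unknown position label(s): ",
           paste(setdiff(positions, labels), collapse = ", "))
    }
    idx <- which(labels %in% positions)
  }
  paste(unclass(code)[idx], labels[idx], sep = "_", collapse = "_")
}

#' Parse a genome code from text
#'
#' Inverts [format_code()]. Full codes must cover every position of the
#' table in order. Projections (codes printed for a subset of positions) are
#' only accepted with `partial = TRUE`; unshown positions are filled with
#' `NA` and the result carries attribute `partial = TRUE`.
#'
#' @param text a code string such as `"12_A_0_B_1_C"`.
#' @param table the [threshold_table()] defining the positions.
#' @param partial allow a projection onto a subset of positions.
#' @return A [genome_code()] (with `NA` at unshown positions when partial).
#' @export
parse_code <- function(text, table = default_threshold_table(),
                       partial = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), "_+", fixed = FALSE)[[1]]
  if (length(tokens) == 0L || length(tokens) %% 2L != 0L) {
    stop("malformed code '", text, "': expected value/label token pairs")
  }
  vals <- tokens[seq(1L, length(tokens), by = 2L)]
  labs <- tokens[seq(2L, length(tokens), by = 2L)]
  if (any(!grepl("^[0-9]+$", vals))) {
    off <- which(!grepl("^[0-9]+$", vals))[1]
    stop("malformed code '", text, "': token ", 2L * off - 1L,
         " ('", vals[off], "') is not a non-negative integer")
  }
  pos <- match(labs, table$label)
  if (anyNA(pos)) {
    off <- which(is.na(pos))[1]
    stop("malformed code '", text, "': unknown position label '",
         labs[off], "' at token ", 2L * off)
  }
  if (any(diff(pos) <= 0)) {
    stop("malformed code '", text, "': position labels out of table order")
  }
  if (!partial && !identical(pos, seq_len(nrow(table)))) {
    stop("code '", text, "' does not cover all ", nrow(table),
         " positions; use partial = TRUE for projections")
  }
  values <- rep(NA_integer_, nrow(table))
  values[pos] <- as.integer(vals)
  out <- structure(values, labels = table$label,
                   table_digest = table_digest(table), class = "genome_code")
  attr(out, "partial") <- !identical(pos, seq_len(nrow(table)))
  out
}
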