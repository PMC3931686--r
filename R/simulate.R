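#' Specification of a simulated clade
#'
#' Describes a set of genomes to simulate by substitution along a rooted
#' tree. Branch lengths are per-site substitution probabilities: along each
#' branch every site mutates independently with that probability, and a
#' mutated base is drawn uniformly from the three alternatives (the simplest
#' symmetric substitution model). Optional horizontal transfer events splice
#' a divergent copy of a root segment into a recipient leaf, emulating
#' horizontally acquired regions that distort whole-genome similarity.
#' Optional short indels (1-10 bp) can be enabled; they default off so that
#' leaf coordinates remain directly comparable.
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths in
#'   substitutions per site, all in `[0, 1)`.
#' @param root_length root genome length in bp.
#' @param hgt optional data frame with columns `leaf`, `length` (bp) and
#'   `divergence` (per-site substitution probability of the donor copy
#'   relative to the root).
#' @param indel_rate per-site indel probability per branch.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return A list of class `clade_spec`.
#' @export
clade_spec <- function(tree, root_length, hgt = NULL, indel_rate = 0,
                       seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            root_length >= 1)
  if (any(tree$edge.length < 0) || any(tree$edge.length >= 1)) {
    stop("branch lengths must be per-site substitution probabilities in [0, 1)")
  }
  if (!is.null(hgt)) {
    stopifnot(is.data.frame(hgt),
              all(c("leaf", "length", "divergence") %in% names(hgt)),
              all(hgt$leaf %in% tree$tip.label),
              all(hgt$length >= 1), all(hgt$length <= root_length),
              all(hgt$divergence >= 0), all(hgt$divergence < 1))
  }
  stopifnot(indel_rate >= 0, indel_rate < 1)
  structure(list(tree = tree, root_length = as.integer(root_length),
                 hgt = hgt, indel_rate = indel_rate, seed = as.integer(seed)),
            class = "clade_spec")
}

# Run code with a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

BASES <- c("A", "C", "G", "T")

# substitute sites of a base-character vector with probability p; mutated
# bases drawn uniformly from the three alternatives
mutate_sites <- function(seq_vec, p) {
  if (p <= 0) return(list(seq = seq_vec,
                          events = data.frame(pos = integer(), from = character(),
                                              to = character())))
  idx <- which(runif(length(seq_vec)) < p)
  if (length(idx) == 0L) {
    return(list(seq = seq_vec,
                events = data.frame(pos = integer(), from = character(),
                                    to = character())))
  }
  from <- seq_vec[idx]
  shift <- sample.int(3L, length(idx), replace = TRUE)
  to <- BASES[((match(from, BASES) - 1L + shift) %% 4L) + 1L]
  seq_vec[idx] <- to
  list(seq = seq_vec, events = data.frame(pos = idx, from = from, to = to,
                                          stringsAsFactors = FALSE))
}

# short indels (1-10 bp); events are applied in decreasing position order so
# recorded coordinates stay valid on replay
apply_indels <- function(seq_vec, rate) {
  events <- data.frame(pos = integer(), type = character(), size = integer(),
                       inserted = character(), stringsAsFactors = FALSE)
  if (rate <= 0) return(list(seq = seq_vec, events = events))
  n_events <- rbinom(1L, length(seq_vec), rate)
  if (n_events == 0L) return(list(seq = seq_vec, events = events))
  pos <- sort(sample.int(length(seq_vec), n_events), decreasing = TRUE)
  type <- sample(c("ins", "del"), n_events, replace = TRUE)
  size <- sample.int(10L, n_events, replace = TRUE)
  inserted <- character(n_events)
  for (i in seq_len(n_events)) {
    if (type[i] == "ins") {
      ins <- sample(BASES, size[i], replace = TRUE)
      inserted[i] <- paste(ins, collapse = "")
      seq_vec <- append(seq_vec, ins, after = pos[i])
    } else {
      drop <- pos[i]:min(pos[i] + size[i] - 1L, length(seq_vec))
      seq_vec <- seq_vec[-drop]
    }
  }
  list(seq = seq_vec,
       events = data.frame(pos = pos, type = type, size = size,
                           inserted = inserted, stringsAsFactors = FALSE))
}

#' Simulate a clade of genomes with a mutation ledger
#'
#' Draws a root genome uniformly over A/C/G/T and evolves it along the tree
#' of the spec. Every event (substitution, indel, horizontal transfer) is
#' recorded in a ledger; replaying the ledger on the root sequence
#' reproduces each leaf exactly, which makes the ledger an aligner-free
#' oracle for the true per-fragment identity between leaves.
#'
#' @param spec a [clade_spec()].
#' @return A list of class `clade_sim`: `genomes` (named list of
#'   [genome_record()]s, one per leaf, in `tip.label` order), `ledger`, and
#'   `spec`.
#' @export
simulate_clade <- function(spec) {
  stopifnot(inherits(spec, "clade_spec"))
  tree <- ape::reorder.phylo(spec$tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  with_seed(spec$seed, {
    root_seq <- sample(BASES, spec$root_length, replace = TRUE)
    node_seqs <- list()
    node_seqs[[root_node]] <- root_seq
    edge_events <- vector("list", nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      mut <- mutate_sites(node_seqs[[parent]], tree$edge.length[e])
      ind <- apply_indels(mut$seq, spec$indel_rate)
      node_seqs[[child]] <- ind$seq
      edge_events[[e]] <- list(parent = parent, child = child,
                               substitutions = mut$events,
                               indels = ind$events)
    }
    hgt_events <- list()
    if (!is.null(spec$hgt)) {
      for (i in seq_len(nrow(spec$hgt))) {
        leaf <- match(spec$hgt$leaf[i], tree$tip.label)
        len <- as.integer(spec$hgt$length[i])
        leaf_len <- length(node_seqs[[leaf]])
        start <- sample.int(leaf_len - len + 1L, 1L)
        donor <- mutate_sites(root_seq[seq.int(start, start + len - 1L)],
                              spec$hgt$divergence[i])
        node_seqs[[leaf]][seq.int(start, start + len - 1L)] <- donor$seq
        hgt_events[[length(hgt_events) + 1L]] <-
          list(leaf = spec$hgt$leaf[i], start = start, end = start + len - 1L,
               divergence = spec$hgt$divergence[i],
               donor_substitutions = donor$events)
      }
    }
    genomes <- lapply(seq_len(n_tip), function(i)
      genome_record(setNames(paste(node_seqs[[i]], collapse = ""),
                             tree$tip.label[i]),
                    tree$tip.label[i]))
    names(genomes) <- tree$tip.label
    ledger <- structure(
      list(root_seq = paste(root_seq, collapse = ""),
           tree = tree, edges = edge_events, hgt = hgt_events),
      class = "mutation_ledger")
    structure(list(genomes = genomes, ledger = ledger, spec = spec),
              class = "clade_sim")
  })
}

# edges of the ledger tree on the path root -> leaf, in application order
edges_to_leaf <- function(ledger, leaf_index) {
  path <- integer()
  node <- leaf_index
  parents <- ledger$tree$edge[, 1]
  children <- ledger$tree$edge[, 2]
  repeat {
    e <- which(children == node)
    if (length(e) == 0L) break
    path <- c(e, path)
    node <- parents[e]
  }
  path
}

#' Replay the ledger for one leaf
#'
#' Applies the recorded events along the root-to-leaf path (then any
#' horizontal transfer into that leaf) to the root sequence. The result is
#' identical to the emitted leaf sequence.
#'
#' @param ledger the `ledger` component of a [simulate_clade()] result.
#' @param leaf a tip label.
#' @return The reconstructed leaf sequence (character scalar).
#' @export
replay_leaf <- function(ledger, leaf) {
  stopifnot(inherits(ledger, "mutation_ledger"))
  li <- match(leaf, ledger$tree$tip.label)
  if (is.na(li)) stop("unknown leaf: ", leaf)
  s <- strsplit(ledger$root_seq, "", fixed = TRUE)[[1]]
  for (e in edges_to_leaf(ledger, li)) {
    ev <- ledger$edges[[e]]
    if (nrow(ev$substitutions)) s[ev$substitutions$pos] <- ev$substitutions$to
    if (nrow(ev$indels)) {
      for (i in seq_len(nrow(ev$indels))) {
        if (ev$indels$type[i] == "ins") {
          s <- append(s, strsplit(ev$indels$inserted[i], "", fixed = TRUE)[[1]],
                      after = ev$indels$pos[i])
        } else {
          drop <- ev$indels$pos[i]:min(ev$indels$pos[i] + ev$indels$size[i] - 1L,
                                       length(s))
          s <- s[-drop]
        }
      }
    }
  }
  for (h in ledger$hgt) {
    if (h$leaf == leaf) {
      seg <- strsplit(ledger$root_seq, "", fixed = TRUE)[[1]][h$start:h$end]
      if (nrow(h$donor_substitutions)) {
        seg[h$donor_substitutions$pos] <- h$donor_substitutions$to
      }
      s[h$start:h$end] <- seg
    }
  }
  paste(s, collapse = "")
}

#' Expected per-site identity between two leaves
#'
#' Closed form under the symmetric substitution model: with per-branch
#' substitution probabilities \eqn{p_b} along the path connecting the two
#' leaves, the probability that a site is identical in both leaves is
#' \eqn{1/4 + 3/4 \prod_b (1 - 4 p_b / 3)}, since each branch scales the
#' non-uniform part of the base distribution by \eqn{1 - 4p/3}.
#'
#' @param spec a [clade_spec()].
#' @param leaf_a,leaf_b tip labels.
#' @return Expected identity as a percentage.
#' @export
expected_identity <- function(spec, leaf_a, leaf_b) {
  stopifnot(inherits(spec, "clade_spec"))
  tree <- spec$tree
  ia <- match(leaf_a, tree$tip.label)
  ib <- match(leaf_b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) {
    stop("unknown leaf: ", if (is.na(ia)) leaf_a else leaf_b)
  }
  if (ia == ib) return(100)
  nodes <- ape::nodepath(tree, ia, ib)
  lambda <- 1
  for (k in seq_len(length(nodes) - 1L)) {
    e <- which(tree$edge[, 1] == nodes[k] & tree$edge[, 2] == nodes[k + 1] |
               tree$edge[, 2] == nodes[k] & tree$edge[, 1] == nodes[k + 1])
    lambda <- lambda * (1 - 4 * tree$edge.length[e] / 3)
  }
  100 * (0.25 + 0.75 * lambda)
}

#' Ledger-derived per-fragment identity
#'
#' Computes, independently of any aligner, the true identity of each query
#' fragment against the homologous subject region by direct positional
#' comparison of the simulated sequences. Requires indels to be disabled in
#' the spec (otherwise leaf coordinates are not comparable). Fragments
#' overlapping a horizontal-transfer segment in either leaf are flagged.
#'
#' @param sim a [simulate_clade()] result.
#' @param query_leaf,subject_leaf tip labels.
#' @param fragment_length tile size in bp.
#' @return A data frame with one row per query fragment: `start`, `end`,
#'   `identity_pct`, `hgt` (logical).
#' @export
ledger_fragment_identity <- function(sim, query_leaf, subject_leaf,
                                     fragment_length = 1020L) {
  stopifnot(inherits(sim, "clade_sim"))
  if (sim$spec$indel_rate > 0) {
    stop("ledger fragment identities require indel_rate = 0")
  }
  qa <- sim$genomes[[query_leaf]]$contigs[[1]]
  qb <- sim$genomes[[subject_leaf]]$contigs[[1]]
  tiles <- tile_genome(sim$genomes[[query_leaf]], fragment_length)
  hgt_iv <- do.call(rbind, lapply(sim$ledger$hgt, function(h)
    if (h$leaf %in% c(query_leaf, subject_leaf))
      c(h$start, h$end) else NULL))
  ident <- numeric(nrow(tiles))
  in_hgt <- logical(nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    mc <- cpp_interval_matches(qa, qb, tiles$start[i], tiles$end[i])
    ident[i] <- 100 * mc[1] / mc[2]
    if (!is.null(hgt_iv)) {
      in_hgt[i] <- any(tiles$start[i] <= hgt_iv[, 2] &
                       tiles$end[i] >= hgt_iv[, 1])
    }
  }
  data.frame(start = tiles$start, end = tiles$end, identity_pct = ident,
             hgt = in_hgt)
}

#' Write a simulated clade to disk
#'
#' One FASTA per leaf, a TSV of all ledger events, and the spec (tree as
#' Newick plus parameters) as YAML, enough to archive and reproduce the
#' simulation.
#'
#' @param sim a [simulate_clade()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_clade <- function(sim, dir) {
  stopifnot(inherits(sim, "clade_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes) {
    write_genome(g, file.path(dir, paste0(g$genome_id, ".fasta")))
  }
  events <- list()
  for (ev in sim$ledger$edges) {
    if (nrow(ev$substitutions)) {
      events[[length(events) + 1L]] <- data.frame(
        type = "substitution",
        branch = paste0(ev$parent, "->", ev$child),
        pos = ev$substitutions$pos,
        detail = paste0(ev$substitutions$from, ">", ev$substitutions$to),
        stringsAsFactors = FALSE)
    }
    if (nrow(ev$indels)) {
      events[[length(events) + 1L]] <- data.frame(
        type = ev$indels$type, branch = paste0(ev$parent, "->", ev$child),
        pos = ev$indels$pos,
        detail = ifelse(ev$indels$type == "ins", ev$indels$inserted,
                        as.character(ev$indels$size)),
        stringsAsFactors = FALSE)
    }
  }
  for (h in sim$ledger$hgt) {
    events[[length(events) + 1L]] <- data.frame(
      type = "hgt", branch = h$leaf, pos = h$start,
      detail = paste0(h$start, "-", h$end, "@", h$divergence),
      stringsAsFactors = FALSE)
  }
  ev_tab <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), branch = character(), pos = integer(),
               detail = character())
  write.table(ev_tab, file.path(dir, "ledger.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(
    list(tree = ape::write.tree(sim$spec$tree),
         root_length = sim$spec$root_length,
         indel_rate = sim$spec$indel_rate,
         seed = sim$spec$seed,
         hgt = if (is.null(sim$spec$hgt)) NULL else as.list(sim$spec$hgt)),
    file.path(dir, "spec.yaml"))
  invisible(dir)
}
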