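# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute the bases at 1-based `positions` with a different base
# (deterministic: next base in A->C->G->T->A order)
substitute_bases <- function(seq, positions) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  chars[positions] <- bases[(match(chars[positions], bases) %% 4L) + 1L]
  paste(chars, collapse = "")
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  if (is.null(names(seqs))) names(seqs) <- paste0("ctg", seq_along(seqs))
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

# a pair of leaves at a given total path substitution rate
two_leaf_spec <- function(path_rate, root_length, seed = 1L) {
  p <- path_rate / 2
  tree <- ape::read.tree(text = sprintf("(a:%.10f,b:%.10f);", p, p))
  clade_spec(tree, root_length, seed = seed)
}

# branch length for one side of a two-leaf tree so that the expected
# pairwise identity equals `identity_pct`
branch_for_identity <- function(identity_pct) {
  lambda <- (identity_pct / 100 - 0.25) / 0.75
  (1 - sqrt(lambda)) * 3 / 4
}

# Independent local-alignment oracle built on Biostrings pairwiseAlignment
# with the package's scoring (match 2, mismatch -3, linear gap 5, N never a
# match). Returns identity over alignment columns, coverage of the fragment,
# and the raw score, taking the better strand.
bstr_align <- function(frag, subject, match = 2, mismatch = -3, gap = 5) {
  letters5 <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(mat) <- match
  mat["N", "N"] <- mismatch
  one <- function(q) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = gap)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    cols <- length(pa)
    matches <- sum(pa == sa & pa != "-" & pa != "N")
    qlen <- Biostrings::width(Biostrings::pattern(aln))
    list(score = Biostrings::score(aln),
         identity = if (cols) 100 * matches / cols else 0,
         coverage = qlen / nchar(q))
  }
  fwd <- one(frag)
  rev <- one(as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag))))
  if (rev$score > fwd$score) rev else fwd
}

# A clade whose genomes all hold identical codes: an identical shared core
# plus one private contig each (distinct checksums, ANI 100 both ways).
identical_core_clade <- function(n = 4L, core_bp = 10200L, seed = 11L) {
  set.seed(seed)
  core <- random_dna(core_bp)
  lapply(seq_len(n), function(i) {
    genome_record(c(core = core, private = random_dna(1020L)),
                  paste0("iso", i))
  })
}

# The tiered 12-genome clade used for clade-recovery and order-robustness
# checks: 3 clades x 2 subclades x 2 leaves, with expected identities of
# about 92% between clades, 99.65% within clades and 99.95% within
# subclades (tiers straddling the 95 / 99.5 / 99.9 thresholds).
tiered_clade_tree <- function() {
  a <- branch_for_identity(99.95) # tip branches
  within <- branch_for_identity(99.65)
  between <- branch_for_identity(92)
  b <- (1 - sqrt((1 - 4 * within / 3)^2 / (1 - 4 * a / 3)^2) ) * 3 / 4
  lam_c <- sqrt((1 - 4 * between / 3)^2 /
                ((1 - 4 * a / 3)^2 * (1 - 4 * b / 3)^2))
  cc <- (1 - lam_c) * 3 / 4
  sub <- function(cl, sb, t1, t2) {
    sprintf("(%s_%d:%.8f,%s_%d:%.8f):%.8f", cl, t1, a, cl, t2, a, b)
  }
  clade <- function(cl) {
    sprintf("(%s,%s):%.8f", sub(cl, 1, 1, 2), sub(cl, 2, 3, 4), cc)
  }
  ape::read.tree(text = paste0("(", clade("x"), ",", clade("y"), ",",
                               clade("z"), ");"))
}

tiered_clade_sim <- function(root_length = 100000L, seed = 2024L) {
  simulate_clade(clade_spec(tiered_clade_tree(), root_length, seed = seed))
}

# group labels by equality of the code prefix up to `position`
prefix_groups <- function(registry, position) {
  ids <- vapply(registry$entries, function(e) e$genome$genome_id, character(1))
  key <- vapply(registry$entries, function(e)
    paste(e$code[seq_len(position)], collapse = "."), character(1))
  setNames(match(key, unique(key)), ids)
}
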