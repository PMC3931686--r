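test_that("tiling cuts contigs into exact consecutive windows", {
  set.seed(10)
  g <- genome_record(c(c1 = random_dna(3060)), "t1")
  t1 <- tile_genome(g, 1020L)
  expect_equal(nrow(t1), 3L)
  expect_equal(nchar(t1$sequence), rep(1020L, 3))

  g2 <- genome_record(c(c1 = random_dna(2500)), "t2")
  t2 <- tile_genome(g2, 1020L)
  expect_equal(nchar(t2$sequence), c(1020L, 1020L, 460L))
  expect_equal(t2$start, c(1L, 1021L, 2041L))
  expect_equal(t2$end, c(1020L, 2040L, 2500L))
  # windows reassemble the contig exactly
  expect_equal(paste(t2$sequence, collapse = ""), g2$contigs[[1]])

  g3 <- genome_record(c(c1 = random_dna(1020), c2 = random_dna(460)), "t3")
  t3 <- tile_genome(g3, 1020L)
  expect_equal(nrow(t3), 2L)
  expect_equal(t3$contig, c("c1", "c2"))
  expect_equal(nchar(t3$sequence), c(1020L, 460L))
})

test_that("core filter keeps the median window and never empties", {
  out <- core_filter(c(99.0, 99.05, 99.1, 98.0, 95.0), 0.1)
  expect_equal(sort(as.numeric(out)), c(99.0, 99.05, 99.1))
  expect_false(attr(out, "fallback"))

  same <- core_filter(rep(97.3, 8), 0.1)
  expect_equal(as.numeric(same), rep(97.3, 8))

  # bimodal two-point input: nothing lies near the median; fall back to the
  # unfiltered input rather than returning an empty set
  fb <- core_filter(c(100, 90), 0.1)
  expect_equal(as.numeric(fb), c(100, 90))
  expect_true(attr(fb, "fallback"))

  expect_error(core_filter(numeric(0)), "non-empty")

  # property: subset of the input, median-attaining elements always survive
  set.seed(20)
  for (i in 1:25) {
    ids <- round(runif(sample(1:40, 1), 70, 100), 2)
    out <- core_filter(ids, 0.1)
    expect_true(all(out %in% ids))
    if (!attr(out, "fallback")) {
      expect_true(all(abs(out - median(ids)) <= 0.1))
      expect_true(any(abs(out - median(ids)) <= 1e-9) ||
                  all(abs(ids - median(ids)) > 0))
    }
  }
})

test_that("self-similarity is 100% ANI with all fragments aligned", {
  set.seed(30)
  g <- genome_record(c(c1 = random_dna(5100)), "self")
  for (backend in c("exact", "seed")) {
    s <- compute_similarity(g, g, ani_config(backend = backend))
    expect_equal(s$ani_pct, 100)
    expect_equal(s$pct_aligned_fragments, 100)
    expect_equal(s$n_fragments, 5L)
    expect_equal(s$n_passed, 5L)
  }
})

test_that("a half-matching query yields ANI 100 at 50% aligned fragments", {
  set.seed(31)
  subject <- genome_record(c(c1 = random_dna(10200)), "sub")
  # query: 5 exact subject tiles + 5 unrelated tiles, one contig each so
  # every fragment is a full 1020 bp window
  match_tiles <- tile_genome(subject, 1020L)$sequence[1:5]
  junk_tiles <- replicate(5, random_dna(1020))
  query <- genome_record(setNames(c(match_tiles, junk_tiles),
                                  paste0("f", 1:10)), "qry")
  s <- compute_similarity(query, subject, ani_config(backend = "exact"))
  expect_equal(s$ani_pct, 100)
  expect_equal(s$pct_aligned_fragments, 50)
  expect_equal(s$n_fragments, 10L)
  expect_equal(s$n_passed, 5L)
})

test_that("ANI on a simulated pair matches the mutation-ledger identity", {
  sim <- simulate_clade(two_leaf_spec(0.05, 30000L, seed = 5))
  led <- ledger_fragment_identity(sim, "a", "b")
  # seed backend: ungapped full-fragment alignment on substitution-only
  # divergence reproduces the positional identity exactly
  s <- compute_similarity(sim$genomes$a, sim$genomes$b,
                          ani_config(backend = "seed"))
  expect_equal(s$pct_aligned_fragments, 100)
  expect_equal(s$ani_pct, mean(led$identity_pct), tolerance = 1e-12)
  # exact backend may trim a few terminal mismatches but stays very close
  s2 <- compute_similarity(sim$genomes$a, sim$genomes$b,
                           ani_config(backend = "exact"))
  expect_lt(abs(s2$ani_pct - mean(led$identity_pct)), 0.1)
  # sanity on the invariants of the similarity object
  expect_true(s$ani_pct >= min(s$passed_identities) &&
              s$ani_pct <= max(s$passed_identities))
  expect_equal(s$pct_aligned_fragments, 100 * s$n_passed / s$n_fragments)
})

test_that("mean ANI recovers the simulator's expected identity per rate tier", {
  for (rate in c(0.01, 0.05, 0.10)) {
    sim <- simulate_clade(two_leaf_spec(rate, 40000L, seed = 100 + rate * 100))
    exp_id <- expected_identity(sim$spec, "a", "b")
    s <- compute_similarity(sim$genomes$a, sim$genomes$b,
                            ani_config(backend = "seed"))
    expect_lt(abs(s$ani_pct - exp_id), 1.0)
  }
})

test_that("raising the filters never increases the passed-fragment count", {
  sim <- simulate_clade(two_leaf_spec(0.15, 20000L, seed = 6))
  base <- ani_config(backend = "seed")
  n_passed <- function(cfg)
    compute_similarity(sim$genomes$a, sim$genomes$b, cfg)$n_passed
  n0 <- n_passed(base)
  for (cov in c(0.8, 0.9, 1.0)) {
    cfg <- base; cfg$coverage_min <- cov
    expect_lte(n_passed(cfg), n0)
  }
  prev <- n0
  for (idm in c(50, 80, 90, 99)) {
    cfg <- base; cfg$identity_min <- idm
    n <- n_passed(cfg)
    expect_lte(n, prev)
    prev <- n
  }
  # passed fragments all satisfy the identity floor, so ANI >= identity_min
  s <- compute_similarity(sim$genomes$a, sim$genomes$b, base)
  expect_true(all(s$passed_identities >= base$identity_min))
  expect_gte(s$ani_pct, base$identity_min)
})

test_that("all_against_all enumerates ordered pairs deterministically", {
  set.seed(40)
  tree <- ape::read.tree(text = "((a:0.01,b:0.01):0.02,c:0.03);")
  sim <- simulate_clade(clade_spec(tree, 6000L, seed = 41))
  cfg <- ani_config(backend = "seed")
  tab <- all_against_all(sim$genomes, cfg)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$query_id, rep(c("a", "b", "c"), each = 2))
  # matches direct per-pair calls
  direct <- compute_similarity(sim$genomes$a, sim$genomes$c, cfg)
  row <- tab[tab$query_id == "a" & tab$subject_id == "c", ]
  expect_equal(row$ani_pct, direct$ani_pct)
  expect_equal(row$pct_aligned_fragments, direct$pct_aligned_fragments)
  # byte-identical TSV on re-run
  f1 <- tempfile(); f2 <- tempfile()
  write_similarity_tsv(tab, f1)
  write_similarity_tsv(all_against_all(sim$genomes, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # self pairs on demand
  expect_equal(nrow(all_against_all(sim$genomes, cfg, include_self = TRUE)), 9L)
  # duplicate ids rejected up front
  expect_error(all_against_all(list(sim$genomes$a, sim$genomes$a), cfg),
               "duplicate")
})

test_that("similarity cache avoids recomputation and is config-keyed", {
  sim <- simulate_clade(two_leaf_spec(0.02, 5000L, seed = 8))
  cache <- similarity_cache()
  cfg <- ani_config(backend = "seed")
  s1 <- anicode:::cached_similarity(sim$genomes$a, sim$genomes$b, cfg, cache)
  expect_equal(cache$n_computed, 1L)
  s2 <- anicode:::cached_similarity(sim$genomes$a, sim$genomes$b, cfg, cache)
  expect_equal(cache$n_computed, 1L)
  expect_identical(s1, s2)
  # a different configuration is a different key
  cfg2 <- ani_config(backend = "seed", identity_min = 50)
  anicode:::cached_similarity(sim$genomes$a, sim$genomes$b, cfg2, cache)
  expect_equal(cache$n_computed, 2L)
})
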