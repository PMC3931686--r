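# small helper: a registry pre-populated with synthetic entries holding
# given codes (genome content irrelevant for walk/fresh-value unit tests)
stub_registry <- function(codes) {
  registry <- code_registry(config = ani_config(backend = "seed"))
  registry$entries <- lapply(seq_along(codes), function(i) {
    list(genome = genome_record(setNames(random_dna(400), "c"),
                                paste0("stub", i)),
         code = as.integer(codes[[i]]),
         assigned_from = NA_character_, ani_at_assignment = NA_real_,
         pct_aligned_at_assignment = NA_real_, trusted = NA,
         assignment_index = i - 1L)
  })
  registry
}

pad24 <- function(...) { v <- integer(24); x <- c(...); v[seq_along(x)] <- x; v }

test_that("the first genome receives 0 at all positions", {
  set.seed(60)
  g <- genome_record(c(c = random_dna(2040)), "first")
  registry <- register_first(code_registry(), g)
  expect_length(registry$entries, 1L)
  e <- registry$entries[[1]]
  expect_equal(e$code, integer(24))
  expect_equal(e$assignment_index, 0L)
  expect_true(is.na(e$assigned_from))
  expect_error(register_first(registry, g), "not empty")
  expect_error(assign_code(code_registry(), g), "empty")
  expect_error(find_most_similar(code_registry(), g), "empty")
})

test_that("the threshold walk copies shared positions and stops strictly", {
  thr <- default_threshold_table()$threshold_pct
  anchor <- pad24(3, 1, 4)
  # ANI 92: strictly exceeds 60,70,80,85,90; fails at 95 (position F)
  w <- anicode:::walk_code(anchor, 92, thr)
  expect_equal(w$fresh_at, 6L)
  expect_equal(w$values[1:5], anchor[1:5])
  expect_true(is.na(w$values[6]))
  expect_equal(w$values[7:24], integer(18))
  # a value exactly at a threshold does NOT share that position
  w95 <- anicode:::walk_code(anchor, 95, thr)
  expect_equal(w95$fresh_at, 6L)
  w95plus <- anicode:::walk_code(anchor, 95.0001, thr)
  expect_equal(w95plus$fresh_at, 7L)
  # ANI above the deepest threshold copies the full anchor code
  wall <- anicode:::walk_code(anchor, 99.99999, thr)
  expect_true(is.na(wall$fresh_at))
  expect_equal(wall$values, anchor)
})

test_that("fresh values are scoped to code siblings", {
  reg <- stub_registry(list(
    pad24(0, 0, 0), pad24(1, 0, 0), pad24(2, 0, 0), pad24(2, 0, 1),
    pad24(2, 0, 5), pad24(2, 1, 0), pad24(12, 0, 0)))
  # new lineage at position A: 1 + max over all entries
  expect_equal(anicode:::fresh_value(reg, integer(24), 1L), 13L)
  # within the 2_A_0_B sibling group the next C value follows the max (5)
  expect_equal(anicode:::fresh_value(reg, pad24(2, 0), 3L), 6L)
  # a prefix nobody holds founds its group at 0
  expect_equal(anicode:::fresh_value(reg, pad24(7, 3), 3L), 0L)
})

test_that("a second genome at ~92% ANI gets a fresh value at position F", {
  p <- branch_for_identity(92.5)
  tree <- ape::read.tree(text = sprintf("(a:%.8f,b:%.8f);", p, p))
  sim <- simulate_clade(clade_spec(tree, 20400L, seed = 61))
  registry <- build_registry(sim$genomes, config = ani_config(backend = "seed"))
  e <- registry$entries[[2]]
  expect_true(e$trusted)
  expect_gt(e$ani_at_assignment, 90)
  expect_lte(e$ani_at_assignment, 95)
  expect_equal(e$code, pad24(0, 0, 0, 0, 0, 1))
  expect_equal(e$assigned_from, "a")
})

test_that("an unalignable genome founds a new lineage at position A", {
  set.seed(62)
  g1 <- genome_record(c(c = random_dna(4080)), "g1")
  g2 <- genome_record(c(c = random_dna(4080)), "g2")
  registry <- register_first(code_registry(config = ani_config(backend = "exact")), g1)
  registry <- assign_code(registry, g2)
  e <- registry$entries[[2]]
  expect_false(e$trusted)
  expect_lt(e$pct_aligned_at_assignment, 20)
  expect_equal(e$code, pad24(1))
})

test_that("the >=20%-aligned candidate set takes precedence over raw ANI", {
  set.seed(63)
  # query: 10 fragments
  qseq <- random_dna(10200)
  query <- genome_record(c(c = qseq), "q")
  # subject "narrow": exact copy of 1 query tile -> 10% aligned, ANI 100
  narrow <- genome_record(c(c = paste0(substr(qseq, 1, 1020),
                                       random_dna(2000))), "narrow")
  # subject "broad": lightly mutated copy of 5 tiles -> 50% aligned, ANI ~98
  broad_seq <- substitute_bases(substr(qseq, 1, 5100),
                                seq(25L, 5100L, by = 50L))
  broad <- genome_record(c(c = broad_seq), "broad")
  cfg <- ani_config(backend = "seed")
  registry <- code_registry(config = cfg)
  registry <- register_first(registry, narrow)
  registry <- assign_code(registry, broad)
  found <- find_most_similar(registry, query)
  expect_true(found$trusted)
  expect_equal(found$entry$genome$genome_id, "broad")
  expect_lt(found$similarity$ani_pct, 100)
})

test_that("duplicate sequence content is rejected with the existing entry", {
  set.seed(64)
  s <- random_dna(3060)
  g1 <- genome_record(c(c = s), "orig")
  g2 <- genome_record(c(renamed = s), "resubmission")
  registry <- register_first(code_registry(config = ani_config(backend = "seed")), g1)
  err <- tryCatch(assign_code(registry, g2), condition = identity)
  expect_s3_class(err, "anicode_duplicate_genome")
  expect_equal(err$entry$genome$genome_id, "orig")
})

test_that("near-identical genomes may share a full code (collision tolerated)", {
  set.seed(65)
  core <- random_dna(10200)
  g1 <- genome_record(c(c = core), "g1")
  # same core plus a private contig: different checksum, ANI still 100
  g2 <- genome_record(c(c = core, extra = random_dna(1020)), "g2")
  registry <- build_registry(list(g1, g2), config = ani_config(backend = "seed"))
  expect_equal(registry$entries[[2]]$code, registry$entries[[1]]$code)
  expect_equal(registry$entries[[2]]$ani_at_assignment, 100)
})

test_that("genomes anchor to the most similar registered genome", {
  tree <- ape::read.tree(text = "((g1:0.01,g3:0.01):0.04,g2:0.05);")
  sim <- simulate_clade(clade_spec(tree, 15000L, seed = 66))
  registry <- build_registry(sim$genomes[c("g1", "g2", "g3")],
                             config = ani_config(backend = "seed"))
  expect_equal(registry$entries[[3]]$genome$genome_id, "g3")
  expect_equal(registry$entries[[3]]$assigned_from, "g1")
  # deterministic: rebuilding gives identical codes
  registry2 <- build_registry(sim$genomes[c("g1", "g2", "g3")],
                              config = ani_config(backend = "seed"))
  expect_identical(registry_table(registry2), registry_table(registry))
})

test_that("prefix depth equals the number of thresholds strictly exceeded", {
  tree <- tiered_clade_tree()
  keep <- c("x_1", "x_2", "x_3", "y_1", "y_2", "z_1")
  tree <- ape::keep.tip(tree, keep)
  sim <- simulate_clade(clade_spec(tree, 20400L, seed = 67))
  registry <- build_registry(sim$genomes, config = ani_config(backend = "seed"))
  thr <- registry$thresholds$threshold_pct
  ids <- vapply(registry$entries, function(e) e$genome$genome_id, character(1))
  for (e in registry$entries[-1]) {
    if (!isTRUE(e$trusted)) next
    anchor <- registry$entries[[match(e$assigned_from, ids)]]
    shared <- last_shared_position(
      genome_code(e$code, registry$thresholds),
      genome_code(anchor$code, registry$thresholds))
    expect_equal(shared, sum(e$ani_at_assignment > thr))
  }
})

test_that("registering another genome never alters existing codes", {
  tree <- ape::read.tree(text = "((a:0.002,b:0.002):0.02,(c:0.002,d:0.002):0.02);")
  sim <- simulate_clade(clade_spec(tree, 10200L, seed = 68))
  cfg <- ani_config(backend = "seed")
  registry <- build_registry(sim$genomes[c("a", "b", "c")], config = cfg)
  before <- lapply(registry$entries, `[[`, "code")
  registry <- assign_code(registry, sim$genomes$d)
  after <- lapply(registry$entries[1:3], `[[`, "code")
  expect_identical(after, before)
  expect_length(registry$entries, 4L)
})

test_that("codes format, project and parse round trip", {
  tt <- default_threshold_table()
  code <- genome_code(pad24(12, 0, 1), tt)
  txt <- format_code(code)
  expect_match(txt, "^12_A_0_B_1_C_0_D_")
  expect_equal(as.integer(parse_code(txt, tt)), as.integer(code))
  expect_false(attr(parse_code(txt, tt), "partial"))

  deep <- genome_code(c(rep(0, 21), 1, 1, 1), tt)
  expect_equal(format_code(deep, c("V", "W", "X")), "1_V_1_W_1_X")
  partial <- parse_code("1_V_1_W_1_X", tt, partial = TRUE)
  expect_true(attr(partial, "partial"))
  expect_equal(as.integer(partial)[22:24], c(1L, 1L, 1L))
  expect_true(all(is.na(as.integer(partial)[1:21])))

  expect_error(parse_code("1_V_1_W", tt), "cover all")
  expect_error(parse_code("x_A_0_B", tt), "not a non-negative integer")
  expect_error(parse_code("1_ZZ_0_B", tt), "unknown position label")
  expect_error(parse_code("1_B_0_A", tt), "out of table order")
  expect_error(format_code(code, c("A", "ZZ")), "unknown position label")
})

test_that("last shared position measures the common prefix", {
  tt <- default_threshold_table()
  a <- genome_code(pad24(1, 2, 3), tt)
  expect_equal(last_shared_position(a, a), 24)
  b <- genome_code(c(pad24(1, 2, 3)[1:23], 9), tt)
  expect_equal(last_shared_position(a, b), 23)
  c <- genome_code(pad24(2, 2, 3), tt)
  expect_equal(last_shared_position(a, c), 0)
  small <- threshold_table(c("A", "B"), c(60, 95))
  expect_error(
    last_shared_position(a, genome_code(c(1L, 2L), small)),
    "different threshold tables")
})

test_that("registries save, reload and extend bit-identically", {
  tree <- ape::read.tree(text = "((a:0.003,b:0.003):0.02,(c:0.003,d:0.003):0.02);")
  sim <- simulate_clade(clade_spec(tree, 10200L, seed = 69))
  cfg <- ani_config(backend = "seed")
  registry <- build_registry(sim$genomes[c("a", "b", "c")], config = cfg)
  path <- tempfile(fileext = ".jsonl")
  save_registry(registry, path)
  reloaded <- load_registry(path)
  expect_equal(registry_table(reloaded), registry_table(registry))
  expect_equal(config_digest(reloaded$config), config_digest(registry$config))
  # extending the reloaded registry matches extending the original
  r1 <- assign_code(registry, sim$genomes$d)
  r2 <- assign_code(reloaded, sim$genomes$d)
  expect_equal(registry_table(r2), registry_table(r1))
})
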