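cc_tier <- function(h) ccdbg:::cpp_cc_tier(h)
cc_pairs_key <- function(h) {
  p <- ccdbg:::cpp_cc_pairs(h)
  sort(paste(p$row, p$color))
}

test_that("word-tier containers hold one pair, then a bit matrix up to 62 cells", {
  h <- ccdbg:::cpp_cc_new(6, 10) # 60 cells <= 62: stays in one word
  ccdbg:::cpp_cc_add(h, 3, 4)
  expect_equal(cc_tier(h), "word")
  expect_true(ccdbg:::cpp_cc_has(h, 3, 4))
  ij <- expand.grid(i = 1:6, j = 1:10)
  ccdbg:::cpp_cc_add(h, ij$i, ij$j)
  expect_equal(cc_tier(h), "word")
  expect_true(all(ccdbg:::cpp_cc_has(h, ij$i, ij$j)))
  expect_equal(cc_pairs_key(h), sort(paste(ij$i, ij$j)))
})

test_that("a second pair on a large matrix upgrades word to medium, keeping content", {
  h <- ccdbg:::cpp_cc_new(100, 10) # 1000 cells > 62
  ccdbg:::cpp_cc_add(h, 5, 7)
  expect_equal(cc_tier(h), "word")
  ccdbg:::cpp_cc_add(h, 99, 2)
  expect_equal(cc_tier(h), "medium")
  expect_true(all(ccdbg:::cpp_cc_has(h, c(5, 99), c(7, 2))))
  expect_false(ccdbg:::cpp_cc_has(h, 1, 1))
})

test_that("medium upgrades to large on the serialized-size budget", {
  set.seed(601)
  h <- ccdbg:::cpp_cc_new(1000, 100) # bit matrix 12.5 KB > 8 KB budget
  ij <- expand.grid(i = 1:1000, j = 1:100)[sample(1e5, 2500), ]
  shadow <- character()
  for (q in seq_len(nrow(ij))) {
    ccdbg:::cpp_cc_add(h, ij$i[q], ij$j[q])
    shadow <- c(shadow, paste(ij$i[q], ij$j[q]))
  }
  # 4 bytes per pair: > 2048 pairs no longer fit the 8 KB pair list
  expect_equal(cc_tier(h), "large")
  expect_equal(cc_pairs_key(h), sort(unique(shadow)))
  expect_true(all(ccdbg:::cpp_cc_has(h, ij$i, ij$j)))
})

test_that("medium holds up to 65488 pairs when the bit matrix fits 8 KB", {
  set.seed(602)
  h <- ccdbg:::cpp_cc_new(4096, 16) # 65536 cells = exactly 8 KB as a bit matrix
  ij <- expand.grid(i = 1:4096, j = 1:16)
  ord <- sample(nrow(ij))
  ccdbg:::cpp_cc_add(h, ij$i[ord[1:65488]], ij$j[ord[1:65488]])
  expect_equal(cc_tier(h), "medium")
  ccdbg:::cpp_cc_add(h, ij$i[ord[65489]], ij$j[ord[65489]])
  expect_equal(cc_tier(h), "large")
  keep <- ord[1:65489]
  expect_true(all(ccdbg:::cpp_cc_has(h, ij$i[keep][1:200], ij$j[keep][1:200])))
  miss <- ord[65490:65536]
  expect_false(any(ccdbg:::cpp_cc_has(h, ij$i[miss], ij$j[miss])))
})

test_that("membership is tier-transparent under random insertion orders", {
  set.seed(603)
  for (dims in list(c(100, 10), c(6, 8), c(400, 30))) {
    h <- ccdbg:::cpp_cc_new(dims[1], dims[2])
    n <- dims[1] * dims[2]
    ij <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]))
    pick <- sample(n, min(n, 3000))
    ccdbg:::cpp_cc_add(h, ij$i[pick], ij$j[pick])
    expect_equal(cc_pairs_key(h), sort(paste(ij$i[pick], ij$j[pick])))
    other <- setdiff(seq_len(n), pick)
    if (length(other))
      expect_false(any(ccdbg:::cpp_cc_has(h, ij$i[other], ij$j[other])))
  }
})

make_pan <- function(seed, n_colors = 3, len = 2500, k = 21) {
  simulate_dataset(n_colors = n_colors, genome_len = len, mut_rate = 0.02,
                   coverage = 1, err_rate = 0, k = k, seed = seed)
}

test_that("per-k-mer color sets equal brute-force per-file sets", {
  sim <- make_pan(604, n_colors = 5)
  D <- build_cdbg(sim$genome_files, k = 21, mode = "reference", seed = 604,
                  colors = TRUE)
  expect_equal(color_names(D), basename(sim$genome_files))
  km <- sim$truth$union
  got <- colors_of(D, km)
  want <- lapply(km, function(x)
    which(vapply(sim$truth$per_color, function(s) x %in% s, TRUE)))
  expect_equal(lapply(got, as.integer), lapply(want, as.integer))
})

test_that("one input file: every k-mer single-colored, all unitigs single-set", {
  sim <- make_pan(605, n_colors = 1)
  D <- build_cdbg(sim$genome_files, k = 21, mode = "reference", seed = 605,
                  colors = TRUE)
  cs <- color_summary(D)
  expect_equal(cs$singleton, length(sim$truth$union))
  expect_equal(cs$core, 0)
  expect_equal(cs$uncolored, 0)
  expect_equal(cs$frac_single_set_unitigs, 1)
})

test_that("two identical files: every k-mer carries both colors", {
  set.seed(606)
  g <- random_dna(1500)
  f1 <- tmp_fasta(c(g = g)); f2 <- tmp_fasta(c(g = g))
  D <- build_cdbg(c(f1, f2), k = 21, mode = "reference", seed = 606,
                  colors = TRUE)
  cs <- color_summary(D)
  expect_equal(cs$core, length(unique(oracle_kmers(g, 21))))
  expect_equal(cs$singleton + cs$dispensable + cs$uncolored, 0)
})

test_that("singleton/core/dispensable partition matches the oracle", {
  sim <- make_pan(607, n_colors = 4)
  D <- build_cdbg(sim$genome_files, k = 21, mode = "reference", seed = 607,
                  colors = TRUE)
  counts <- table(vapply(sim$truth$union, function(x)
    sum(vapply(sim$truth$per_color, function(s) x %in% s, TRUE)), 0))
  cs <- color_summary(D)
  expect_equal(cs$singleton, unname(counts["1"]))
  expect_equal(cs$core, unname(counts["4"]) %||% 0)
  expect_equal(cs$dispensable, sum(counts[!names(counts) %in% c("1", "4")]))
})

test_that("slot resolution is bijective and stable under unrelated edits", {
  sim <- make_pan(608, n_colors = 2, len = 4000)
  D <- build_cdbg(sim$genome_files, k = 21, mode = "reference", seed = 608,
                  colors = TRUE)
  un <- unitigs(D)
  slots <- vapply(un$id, function(id) ccdbg:::cpp_slot_of(D$ptr, id), 0L)
  colored <- slots > 0
  expect_false(any(duplicated(slots[colored]))) # no two unitigs share a slot
  # record one unitig's slot and matrix, edit elsewhere, re-check
  target <- un$id[colored][1]
  slot0 <- slots[colored][1]
  mat0 <- unitig_colors(D, target)
  set.seed(608)
  u_new <- distinct_path(60, 21)
  if (!any(oracle_kmers(u_new, 21) %in% graph_kmer_set(D))) {
    id_new <- insert_unitig(D, u_new)
    ccdbg:::cpp_assign_slot(D$ptr, id_new)
    remove_unitig(D, id_new)
  }
  expect_equal(ccdbg:::cpp_slot_of(D$ptr, target), slot0)
  expect_equal(unitig_colors(D, target), mat0)
})

test_that("updating a colored graph preserves color sets and adds the new color", {
  sim <- make_pan(609, n_colors = 3, len = 3000)
  Da <- build_cdbg(sim$genome_files[1:2], k = 21, mode = "reference",
                   seed = 609, colors = TRUE)
  update_cdbg(Da, sim$genome_files[3])
  Db <- build_cdbg(sim$genome_files, k = 21, mode = "reference", seed = 609,
                   colors = TRUE)
  expect_identical(graph_unitig_multiset(Da), graph_unitig_multiset(Db))
  km <- sim$truth$union
  expect_equal(lapply(colors_of(Da, km), as.integer),
               lapply(colors_of(Db, km), as.integer))
})
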