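# fixtures here drive the extraction/build machinery with an exact filter
# (no false positives) or a real blocked Bloom filter, and compare against
# the brute-force compaction oracle

build_from <- function(reads, filter, k, g = NULL, seed = 1, t = 64) {
  if (is.null(g)) g <- max(k - 8, 1)
  D <- cdbg_new(k = k, g = g, t = t, seed = seed)
  cdbg_build_pass(D, reads, filter)
  D
}

test_that("an isolated k-mer extracts to a unitig of length k", {
  set.seed(501)
  x <- random_dna(21)
  f <- exact_filter(x)
  ex <- extract_unitig(f, x, g = 13)
  expect_equal(ex$seq, x)
})

test_that("a linear path extracts fully, 8 probes and 2 hits per advance", {
  set.seed(502)
  path <- distinct_path(200, 21)
  km <- oracle_kmers(path, 21, canonical = FALSE)
  f <- exact_filter(km)
  ex <- extract_unitig(f, km[80], g = 13, instrument = TRUE)
  expect_true(ex$seq == path || ex$seq == revcomp(path))
  expect_true(all(ex$step_probes == 8))
  expect_true(all(ex$step_hits == 2))
  eta <- length(km)
  expect_equal(length(ex$step_probes), eta - 1)
  expect_equal(ex$n_queries, 8 * (eta - 1) + 8) # + two terminal stops
  expect_equal(ex$n_hits, 2 * (eta - 1))
})

test_that("neighbour probing agrees with brute-force enumeration", {
  set.seed(503)
  km <- unique(vapply(1:50, function(i) random_dna(15), ""))
  f <- exact_filter(km)
  kset <- canonical_dna(km)
  for (x in km[1:10]) {
    fw <- ccdbg:::cpp_neighbors_present(f$ptr, x, 7L, 1, "forward")
    bw <- ccdbg:::cpp_neighbors_present(f$ptr, x, 7L, 1, "backward")
    expect_equal(fw, canonical_dna(paste0(substr(x, 2, 15), DNA)) %in% kset)
    expect_equal(bw, canonical_dna(paste0(DNA, substr(x, 1, 14))) %in% kset)
  }
})

test_that("extraction terminates on a cycle and spells each k-mer once", {
  set.seed(504)
  k <- 15
  repeat {
    core <- random_dna(120)
    circ <- paste0(core, substr(core, 1, k - 1))
    km <- oracle_kmers(circ, k, canonical = FALSE)
    if (!anyDuplicated(canonical_dna(km))) break
  }
  f <- exact_filter(km)
  ex <- extract_unitig(f, km[5], g = 7)
  expect_equal(nchar(ex$seq), 120 + k - 1)
  expect_setequal(oracle_kmers(ex$seq, k), canonical_dna(km))
})

test_that("two copies of one sequence build one unitig with saturated counters", {
  set.seed(505)
  s <- distinct_path(100, 31)
  f <- exact_filter(oracle_kmers(s, 31))
  D <- build_from(rep(s, 2), f, k = 31)
  un <- unitigs(D)
  expect_equal(nrow(un), 1L)
  expect_equal(nchar(un$seq), 100L)
  expect_true(all(kmer_counters(D, un$id) == 2L))
})

test_that("no k-mer spans a non-ACGT character", {
  set.seed(506)
  left <- distinct_path(60, 15)
  right <- distinct_path(60, 15)
  s <- paste0(left, "N", right)
  fa <- tmp_fasta(c(a = s, b = s))
  D <- build_cdbg(fa, k = 15, mode = "reads", seed = 1)
  expect_setequal(graph_kmer_set(D), oracle_kmers(s, 15))
})

test_that("a bridging false positive makes a false connection, removed by cleanup", {
  set.seed(507)
  for (trial in 1:5) {
    path <- distinct_path(120, 15)
    km <- oracle_kmers(path, 15, canonical = FALSE)
    mid <- 4 + trial
    truth <- km[-mid]                       # reads never cover km[mid]
    a <- substr(path, 1, mid - 1 + 14)      # segment before the gap
    b <- substr(path, mid + 1, 120)         # segment after
    f <- exact_filter(km)                   # ...but the filter contains it
    D <- build_from(rep(c(a, b), 2), f, k = 15)
    expect_setequal(graph_kmer_set(D), canonical_dna(km)) # bridged: one unitig
    expect_equal(nrow(unitigs(D)), 1L)
    cls <- classify_fp(D, km[mid])
    expect_equal(cls$kind, "false_connection")
    eliminate_false_positives(D, threshold = 2)
    expect_equal(nrow(unitigs(D)), 2L)      # deleting the k-mer splits in two
    expect_identical(graph_unitig_multiset(D), oracle_compact(canonical_dna(truth), 15))
  }
})

test_that("a branch false positive makes a false branching; cleanup re-joins", {
  set.seed(508)
  for (trial in 1:5) {
    repeat {
      path <- distinct_path(120, 15)
      km <- oracle_kmers(path, 15, canonical = FALSE)
      mid <- 40 + trial
      # x: alternative successor of km[mid], absent from the path
      nxt <- substr(path, mid + 15, mid + 15)
      x <- paste0(substr(km[mid], 2, 15), sample(setdiff(DNA, nxt), 1))
      allk <- canonical_dna(c(km, x))
      if (anyDuplicated(allk)) next
      # x must have no neighbours besides km[mid] (else it is no lone branch)
      nb <- canonical_dna(c(paste0(substr(x, 2, 15), DNA), paste0(DNA, substr(x, 1, 14))))
      if (sum(nb %in% allk) == 1) break
    }
    f <- exact_filter(c(km, x))
    # x occurs once in the reads: enough to be observed (and ghost-repaired),
    # not enough to survive the counter threshold
    D <- build_from(c(path, path, x), f, k = 15)
    expect_true(lookup_kmer(D, x)$found)
    expect_equal(nrow(unitigs(D)), 3L)      # three unitigs instead of one
    cls <- classify_fp(D, x)
    expect_equal(cls$kind, "false_branching")
    eliminate_false_positives(D, threshold = 2)
    expect_equal(nrow(unitigs(D)), 1L)      # deleting x joins them again
    expect_identical(graph_unitig_multiset(D), oracle_compact(canonical_dna(km), 15))
  }
})

test_that("cleanup is a no-op when every counter is at threshold", {
  set.seed(509)
  s <- distinct_path(150, 15)
  f <- exact_filter(oracle_kmers(s, 15))
  D <- build_from(rep(s, 2), f, k = 15)
  before <- graph_unitig_multiset(D)
  eliminate_false_positives(D, threshold = 2)
  expect_identical(graph_unitig_multiset(D), before)
  expect_equal(graph_stats(D)$n_fp_deleted, 0)
})

test_that("an unobserved ghost never enters the graph; repair restores real branches", {
  set.seed(510)
  repeat {
    path <- distinct_path(120, 15)
    km <- oracle_kmers(path, 15, canonical = FALSE)
    nxt <- substr(path, 65, 65)
    x <- paste0(substr(km[50], 2, 15), sample(setdiff(DNA, nxt), 1))
    allk <- canonical_dna(c(km, x))
    if (anyDuplicated(allk)) next
    nb <- canonical_dna(c(paste0(substr(x, 2, 15), DNA), paste0(DNA, substr(x, 1, 14))))
    if (sum(nb %in% allk) == 1) break
  }
  f <- exact_filter(c(km, x))
  # x never observed: treated as a Bloom false positive, extraction passes by
  D1 <- build_from(rep(path, 2), f, k = 15)
  expect_true(x %in% ghost_kmers(D1) || revcomp(x) %in% ghost_kmers(D1))
  eliminate_false_positives(D1, 2)
  expect_identical(graph_unitig_multiset(D1), oracle_compact(canonical_dna(km), 15))
  # x observed twice (after the path): ghost repair + counters keep it;
  # repeated observation is idempotent
  D2 <- build_from(c(path, path, x, x, x), f, k = 15)
  eliminate_false_positives(D2, 2)
  expect_identical(graph_unitig_multiset(D2),
                   oracle_compact(canonical_dna(c(km, x)), 15))
  expect_gte(graph_stats(D2)$n_ghost_repairs, 1)
})

test_that("ghost protection removes false-positive fragmentation", {
  set.seed(511)
  genome <- random_dna(20000)
  fa <- tmp_fasta(genome)
  fl <- filter_refs(fa, k = 31, g = 23, bits_per_kmer = 14, seed = 3)
  km <- oracle_kmers(genome, 31, canonical = FALSE)
  starts <- sample(km, 40)
  len_without <- vapply(starts, function(x)
    nchar(extract_unitig(fl$bbf2, x, g = 23, seed = 3, use_ghosts = FALSE)$seq), 0)
  len_with <- vapply(starts, function(x)
    nchar(extract_unitig(fl$bbf2, x, g = 23, seed = 3, use_ghosts = TRUE)$seq), 0)
  # the filter's own false positive rate (block-level correlations make it
  # a little higher than the analytic phi)
  set.seed(512)
  probes <- unique(vapply(1:20000, function(i) random_dna(31), ""))
  probes <- probes[!canonical_dna(probes) %in% canonical_dna(km)]
  p_emp <- mean(bbf_contains(fl$bbf2, probes, g = 23))
  # without ghosts a single false positive halts the walk: the extracted
  # length follows the two-sided geometric law ~ 2/(6p)
  mean_wo <- mean(len_without - 30)
  expect_lt(mean_wo, 2.5 * 2 / (6 * p_emp))
  expect_gt(mean_wo, 0.2 * 2 / (6 * p_emp))
  # ghost protection needs two adjacent false positives to halt: an
  # order-of-magnitude longer walk, approaching chromosome scale
  expect_gt(mean(len_with), 10 * mean_wo)
  expect_gt(mean(len_with), 1500)
})

test_that("extraction halt lengths follow the geometric law", {
  lens <- simulate_halt_lengths(2e4, p = 2e-3, probes = 6, seed = 12)
  q <- 1 - (1 - 2e-3)^6
  expect_lt(abs(mean(lens) - 1 / q) / (1 / q), 0.05)
})
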