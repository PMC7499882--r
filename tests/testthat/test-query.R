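test_that("edit-1 variants match an independent enumerator", {
  set.seed(701)
  for (i in 1:6) {
    x <- random_dna(5)
    expect_equal(edit1_variants(x), oracle_edit1(x))
  }
  x <- random_dna(9)
  v <- edit1_variants(x)
  expect_true(canonical_dna(x) %in% v)
  # substitution variants are within Hamming distance 1 of x or its
  # reverse complement; windowed indel variants within Levenshtein 2
  d <- pmin(utils::adist(v, x), utils::adist(v, revcomp(x)))
  expect_true(all(d <= 2))
})

make_query_graph <- function(seed, len = 3000, k = 21) {
  set.seed(seed)
  genome <- random_dna(len)
  fa <- tmp_fasta(c(genome = genome))
  D <- build_cdbg(fa, k = k, mode = "reference", seed = seed)
  list(D = D, genome = genome, kset = unique(oracle_kmers(genome, k)))
}

test_that("a stored unitig queries as fully present", {
  q <- make_query_graph(702)
  un <- unitigs(q$D)$seq
  res <- query_sequences(q$D, un[which.max(nchar(un))], theta = 1)
  expect_equal(res$ratio, 1)
  expect_true(res$present)
})

test_that("one central mismatch kills the exact query but not the inexact one", {
  q <- make_query_graph(703)
  k <- 21
  s <- substr(q$genome, 1001, 1080)
  pos <- 40
  bad <- s
  substr(bad, pos, pos) <- setdiff(DNA, substr(s, pos, pos))[1]
  # oracle ratio: k-mers overlapping the mismatch are destroyed unless the
  # mutated k-mer coincidentally exists elsewhere
  km <- oracle_kmers(bad, k)
  oracle_ratio <- mean(km %in% q$kset)
  exact <- query_sequences(q$D, bad, theta = 1)
  expect_equal(exact$ratio, oracle_ratio)
  expect_false(exact$present)
  inexact <- query_sequences(q$D, bad, theta = 1, inexact = TRUE)
  expect_equal(inexact$ratio, 1)
  expect_true(inexact$present)
})

test_that("verdicts equal the brute-force ratio oracle across thetas", {
  q <- make_query_graph(704)
  set.seed(704)
  k <- 21
  starts <- sample(nchar(q$genome) - 60, 60)
  reads <- substring(q$genome, starts, starts + 59)
  reads <- vapply(reads, function(r) { # 2% error
    p <- which(stats::runif(60) < 0.02)
    if (!length(p)) return(r)
    s <- strsplit(r, "")[[1]]
    for (q2 in p) s[q2] <- sample(setdiff(DNA, s[q2]), 1)
    paste(s, collapse = "")
  }, "", USE.NAMES = FALSE)
  decoys <- vapply(1:20, function(i) random_dna(60), "")
  queries <- c(reads, decoys)
  ratio_oracle <- vapply(queries, function(s)
    mean(oracle_kmers(s, k) %in% q$kset), 0, USE.NAMES = FALSE)
  prev <- NULL
  for (theta in c(0.5, 0.75, 0.9, 1.0)) {
    res <- query_sequences(q$D, queries, theta = theta)
    expect_equal(res$ratio, ratio_oracle)
    expect_equal(res$present, ratio_oracle >= theta)
    if (!is.null(prev)) expect_true(all(prev | !res$present)) # monotone in theta
    prev <- res$present
  }
  inx <- query_sequences(q$D, queries, theta = 1, inexact = TRUE)
  exa <- query_sequences(q$D, queries, theta = 1)
  expect_true(all(inx$n_found >= exa$n_found)) # inexact dominance
  # error-free queries drawn from the graph: equality
  clean <- substring(q$genome, starts[1:10], starts[1:10] + 59)
  expect_equal(query_sequences(q$D, clean, inexact = TRUE)$n_found,
               query_sequences(q$D, clean)$n_found)
})

test_that("queries shorter than k are flagged, never present", {
  q <- make_query_graph(705, len = 500)
  res <- query_sequences(q$D, c("ACGTA", substr(q$genome, 1, 50)))
  expect_true(res$too_short[1])
  expect_false(res$present[1])
  expect_equal(res$n_kmers[1], 0L)
  expect_false(res$too_short[2])
})

test_that("per-color found fractions are reported", {
  sim <- simulate_dataset(n_colors = 2, genome_len = 1500, mut_rate = 0.03,
                          coverage = 1, err_rate = 0, k = 21, seed = 706)
  D <- build_cdbg(sim$genome_files, k = 21, mode = "reference", seed = 706,
                  colors = TRUE)
  res <- query_sequences(D, substr(sim$genomes[1], 1, 200), theta = 0.5,
                         report_colors = TRUE)
  nm <- color_names(D)
  expect_true(all(nm %in% names(res)))
  expect_equal(res[[nm[1]]], 1) # the query is genome 1 verbatim
  expect_lte(res[[nm[2]]], 1)
})
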