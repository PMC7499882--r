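test_that("every k-mer of an inserted unitig is found at its exact offset", {
  set.seed(401)
  D <- cdbg_new(k = 15, g = 7, seed = 3)
  u <- distinct_path(90, 15)
  id <- insert_unitig(D, u)
  km <- oracle_kmers(u, 15, canonical = FALSE)
  hit <- lookup_kmer(D, km)
  expect_true(all(hit$found))
  expect_true(all(hit$id == id))
  expect_equal(hit$offset, seq_along(km))
  expect_true(all(hit$strand == "forward"))
  # reverse complements are found at the same offsets on the other strand
  rhit <- lookup_kmer(D, revcomp(km))
  expect_true(all(rhit$found))
  expect_equal(rhit$offset, seq_along(km))
  expect_true(all(rhit$strand == "reverse"))
})

test_that("a unitig of length k produces one k-mer and one minimizer entry", {
  D <- cdbg_new(k = 15, g = 7, seed = 3)
  insert_unitig(D, "ACGGATTTACCGGAT")
  mt <- minimizer_table(D)
  expect_equal(nrow(mt), 1L)
  expect_equal(unitigs(D)$n_kmers, 1L)
})

test_that("lookup of absent k-mers never false-positives", {
  set.seed(402)
  D <- cdbg_new(k = 15, g = 7, seed = 5)
  for (i in 1:5) {
    u <- distinct_path(60, 15)
    if (!any(lookup_kmer(D, oracle_kmers(u, 15))$found)) insert_unitig(D, u)
  }
  stored <- graph_kmer_set(D)
  probes <- unique(vapply(1:2000, function(i) random_dna(15), ""))
  absent <- probes[!canonical_dna(probes) %in% stored]
  expect_false(any(lookup_kmer(D, absent)$found))
})

test_that("remove_unitig is the inverse of insert_unitig", {
  set.seed(403)
  D <- cdbg_new(k = 15, g = 7, seed = 1)
  u1 <- distinct_path(60, 15)
  id1 <- insert_unitig(D, u1)
  km <- oracle_kmers(u1, 15)
  expect_true(all(lookup_kmer(D, km)$found))
  remove_unitig(D, id1)
  expect_false(any(lookup_kmer(D, km)$found))
  expect_equal(nrow(minimizer_table(D)), 0L)
  expect_error(remove_unitig(D, id1), "unknown or already removed")
})

test_that("random insert/remove interleavings keep M and U consistent", {
  set.seed(404)
  D <- cdbg_new(k = 15, g = 7, seed = 2)
  shadow <- list() # id -> unitig sequence
  for (step in 1:60) {
    if (length(shadow) == 0 || stats::runif(1) < 0.6) {
      u <- distinct_path(sample(30:80, 1), 15)
      if (any(oracle_kmers(u, 15) %in% unlist(lapply(shadow, oracle_kmers, k = 15))))
        next
      id <- insert_unitig(D, u)
      shadow[[as.character(id)]] <- u
    } else {
      id <- sample(names(shadow), 1)
      remove_unitig(D, as.integer(id))
      shadow[[id]] <- NULL
    }
    # the k-mers reachable through M equal the k-mers of the live unitigs
    want <- sort(unique(unlist(lapply(shadow, oracle_kmers, k = 15))))
    expect_identical(sort(graph_kmer_set(D)), want %||% character())
    if (length(want)) expect_true(all(lookup_kmer(D, want)$found))
  }
  # every minimizer tuple points at a live unitig and a real occurrence
  mt <- minimizer_table(D)
  un <- unitigs(D)
  expect_true(all(mt$id %in% un$id))
  for (r in seq_len(nrow(mt))) {
    useq <- un$seq[un$id == mt$id[r]]
    occ <- substr(useq, mt$pos[r], mt$pos[r] + nchar(mt$gmer[r]) - 1)
    expect_equal(canonical_dna(occ), mt$gmer[r])
  }
})

test_that("minimizer table matches brute-force occurrence enumeration", {
  set.seed(405)
  D <- cdbg_new(k = 9, g = 3, seed = 6)
  u <- distinct_path(40, 9)
  id <- insert_unitig(D, u)
  n <- nchar(u) - 9 + 1
  km <- substring(u, 1:n, 1:n + 8)
  want <- unique(do.call(rbind, lapply(seq_len(n), function(i) {
    m <- minimizer_of(km[i], g = 3, seed = 6)
    data.frame(gmer = m$gmer, id = id, pos = i + m$pos - 1)
  })))
  got <- as.data.frame(minimizer_table(D)[, c("gmer", "id", "pos")])
  o <- function(d) d[order(d$gmer, d$pos), , drop = FALSE]
  expect_equal(o(got), o(want), ignore_attr = TRUE)
})

test_that("recurrent minimizers fall back to the next non-recurrent g-mer", {
  set.seed(406)
  k <- 9; g <- 3
  # find x1 whose minimizer g-mer we can embed into a second k-mer x2
  # that selects the same g-mer as its own minimizer
  repeat {
    x1 <- random_dna(k)
    m1 <- minimizer_of(x1, g, seed = 8)
    x2 <- paste0(random_dna(1), m1$gmer, random_dna(5))
    if (x2 == x1 || grepl("[^ACGT]", x2)) next
    m2 <- minimizer_of(x2, g, seed = 8)
    if (m2$gmer == m1$gmer && canonical_dna(x2) != canonical_dna(x1)) break
  }
  D <- cdbg_new(k = k, g = g, t = 1, seed = 8) # every used minimizer recurs
  insert_unitig(D, x1)
  sel <- select_insert_minimizer(D, x2)
  expect_true(sel$fallback)
  expect_false(sel$gmer == m1$gmer)
  # insertion under the fallback minimizer still makes the k-mer findable
  insert_unitig(D, x2)
  expect_true(all(lookup_kmer(D, c(x1, x2))$found))
})

test_that("a homopolymer takes the overflow path and stays findable", {
  set.seed(407)
  k <- 9; g <- 3
  # make the A-homopolymer g-mer recurrent first
  repeat {
    x1 <- paste0(random_dna(2), "AAA", random_dna(4))
    if (grepl("AAAA", x1)) next
    if (minimizer_of(x1, g, seed = 4)$gmer == "AAA") break
  }
  D <- cdbg_new(k = k, g = g, t = 1, seed = 4)
  insert_unitig(D, x1)
  hp <- strrep("A", k)
  sel <- select_insert_minimizer(D, hp)
  expect_true(sel$overflow)
  expect_equal(sel$gmer, "AAA")
  insert_unitig(D, hp)
  expect_true(all(lookup_kmer(D, c(x1, hp))$found))
  # the overflowed list now exceeds t
  mt <- minimizer_table(D)
  expect_gt(sum(mt$gmer == "AAA"), 1)
  expect_true(all(mt$recurrent[mt$gmer == "AAA"]))
})
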