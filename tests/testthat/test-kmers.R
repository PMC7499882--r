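test_that("revcomp complements and reverses, and is an involution", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAAC"), "GTTT")
  set.seed(101)
  r <- vapply(1:25, function(i) random_dna(50), "")
  expect_equal(revcomp(r), oracle_revcomp(r))
  expect_equal(revcomp(revcomp(r)), r)
  expect_error(revcomp("ACGN"), "non-ACGT")
})

test_that("canonical form is the smaller strand, idempotent and symmetric", {
  expect_equal(canonical_dna("TTT"), "AAA")
  expect_equal(canonical_dna("ACG"), "ACG")
  set.seed(102)
  r <- vapply(1:50, function(i) random_dna(31), "")
  cn <- canonical_dna(r)
  expect_equal(cn, oracle_canonical(r))
  expect_equal(canonical_dna(cn), cn)
  expect_equal(canonical_dna(revcomp(r)), cn)
})

test_that("g-mer hash is deterministic, seed-dependent and strand-symmetric", {
  expect_equal(gmer_hash("ACGT", 7), gmer_hash("ACGT", 7))
  expect_false(gmer_hash("ACGT", 7) == gmer_hash("ACGT", 8))
  set.seed(103)
  y <- vapply(1:30, function(i) random_dna(11), "")
  expect_equal(gmer_hash(y, 5), gmer_hash(revcomp(y), 5))
})

test_that("rolling minimizer iteration equals per-k-mer recomputation", {
  set.seed(104)
  for (p in list(c(k = 31, g = 23, len = 200), c(k = 21, g = 11, len = 150),
                 c(k = 9, g = 3, len = 80), c(k = 7, g = 5, len = 4096))) {
    seq <- random_dna(p[["len"]])
    it <- iterate_minimizers(seq, p[["k"]], p[["g"]], seed = 9)
    n <- p[["len"]] - p[["k"]] + 1
    km <- substring(seq, 1:n, p[["k"]]:p[["len"]])
    mo <- minimizer_of(km, p[["g"]], seed = 9)
    expect_equal(it$gmer, mo$gmer)
    expect_equal(it$hash, mo$hash)
    expect_equal(it$pos, mo$pos)
  }
})

test_that("minimizer equals a brute-force argmin over interior g-mers", {
  set.seed(105)
  k <- 9; g <- 3
  for (i in 1:40) {
    x <- random_dna(k)
    pos <- 2:(k - g)                      # interior starts, 1-based
    gm <- substring(x, pos, pos + g - 1)
    h <- gmer_hash(gm, 3)                 # fixed-width hex: string order == numeric
    best <- which(h == min(h))[1]         # leftmost tie-break
    m <- minimizer_of(x, g, seed = 3)
    expect_equal(m$gmer, canonical_dna(gm[best]))
    expect_equal(m$pos, pos[best])
    expect_equal(m$hash, h[best])
  }
})

test_that("minimizer positions respect the interior window", {
  set.seed(106)
  seq <- random_dna(400)
  it <- iterate_minimizers(seq, 31, 23, seed = 5)
  expect_true(all(it$pos >= 2))
  expect_true(all(it$pos <= 31 - 23))     # 1-based: never 1, never k - g + 1
})

test_that("k = 3, g = 1 has a single interior candidate", {
  m <- minimizer_of(c("ACG", "TTT", "GAT"), g = 1, seed = 1)
  expect_equal(m$pos, c(2L, 2L, 2L))
  expect_equal(m$gmer, canonical_dna(c("C", "T", "A")))
})

test_that("all four forward neighbours of a k-mer share one minimizer", {
  set.seed(107)
  for (i in 1:20) {
    x <- random_dna(25)
    nb <- paste0(substr(x, 2, 25), DNA)
    m <- minimizer_of(nb, g = 11, seed = 2)
    expect_equal(length(unique(m$gmer)), 1L)
    expect_equal(length(unique(m$hash)), 1L)
  }
})

test_that("minimizer sequence of the reverse complement is the reverse", {
  set.seed(108)
  seq <- random_dna(150)
  a <- iterate_minimizers(seq, 21, 13, seed = 4)
  b <- iterate_minimizers(revcomp(seq), 21, 13, seed = 4)
  expect_equal(b$gmer, rev(a$gmer))
  expect_equal(b$hash, rev(a$hash))
})

test_that("sequences shorter than k yield an empty iteration", {
  expect_equal(nrow(iterate_minimizers("ACGTAC", 31, 23)), 0L)
  seq <- random_dna(31)
  it <- iterate_minimizers(seq, 31, 23, seed = 1)
  expect_equal(nrow(it), 1L)
  expect_equal(it$gmer, minimizer_of(seq, 23, seed = 1)$gmer)
})

test_that("invalid minimizer lengths are rejected", {
  expect_error(minimizer_of("ACGTACGTA", g = 8), "g must satisfy")
  expect_error(cdbg_new(k = 9, g = 8), "g must satisfy")
})
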