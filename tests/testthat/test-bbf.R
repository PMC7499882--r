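test_that("optimal hash count follows (m/n) ln 2", {
  n <- 1e5
  expect_equal(optimal_hash_count(n / log(2), n), 1L)
  expect_equal(optimal_hash_count(10 * n, n), 7L)   # round(6.93)
  expect_equal(optimal_hash_count(14 * n, n), 10L)  # round(9.70)
})

test_that("expected false positive rate matches the closed form", {
  out <- bloom_fpr(10, 1, f = 7)
  expect_equal(out$phi, (1 - exp(-0.7))^7)
  expect_equal(out$approx, 0.7^10)
  # the 0.7^(m/n) rule of thumb tracks the closed form at the optimum
  ratio <- bloom_fpr(10 * 64, 64)$phi / (0.7^10)
  expect_lt(abs(ratio - 1), 0.8)
  # phi -> 0 as the filter grows
  expect_lt(bloom_fpr(1e9, 10, f = 1)$phi, 1e-7)
})

test_that("inserted k-mers are always reported present, absent mostly not", {
  set.seed(201)
  km <- unique(vapply(1:500, function(i) random_dna(21), ""))
  b <- bbf(length(km), bits_per_kmer = 14, seed = 3)
  expect_false(any(bbf_contains(b, km, g = 13)))  # fresh filter is empty
  bbf_insert(b, km, g = 13)
  expect_true(all(bbf_contains(b, km, g = 13)))
  expect_true(all(bbf_contains(b, revcomp(km), g = 13)))  # canonical hashing
})

test_that("re-inserting a present k-mer writes nothing", {
  set.seed(202)
  km <- unique(vapply(1:300, function(i) random_dna(21), ""))
  b <- bbf(300, seed = 4)
  bbf_insert(b, km, g = 13)
  bits1 <- bbf_info(b)$total_set_bits
  bbf_insert(b, sample(km), g = 13)
  expect_equal(bbf_info(b)$total_set_bits, bits1)
})

test_that("identical seed and stream give identical filters", {
  set.seed(203)
  km <- vapply(1:400, function(i) random_dna(21), "")
  b1 <- bbf(400, seed = 9); bbf_insert(b1, km, g = 13)
  b2 <- bbf(400, seed = 9); bbf_insert(b2, km, g = 13)
  expect_identical(bbf_occupancy(b1), bbf_occupancy(b2))
})

test_that("no false negatives under random insert/query interleavings", {
  set.seed(204)
  b <- bbf(2000, bits_per_kmer = 10, seed = 5)
  inserted <- character()
  for (round in 1:20) {
    km <- vapply(1:80, function(i) random_dna(15), "")
    bbf_insert(b, km, g = 7)
    inserted <- c(inserted, km)
    probe <- sample(inserted, min(200, length(inserted)))
    expect_true(all(bbf_contains(b, probe, g = 7)))
  }
})

test_that("2-choice placement balances blocks better than single choice", {
  two <- bbf_calibration(1e4, 10, k = 21, g = 13, bits_per_kmer = 14,
                         seed = 77, two_choice = TRUE)
  one <- bbf_calibration(1e4, 10, k = 21, g = 13, bits_per_kmer = 14,
                         seed = 77, two_choice = FALSE)
  expect_lt(stats::var(two$occupancy), stats::var(one$occupancy))
  expect_lte(max(two$occupancy), max(one$occupancy))
})

test_that("empirical false positive rate tracks the 2-choice expectation", {
  for (bits in c(8, 14)) {
    cal <- bbf_calibration(2e4, 1e5, bits_per_kmer = bits, seed = 11)
    expect_equal(cal$false_negatives, 0)
    # reference: per-block Bloom rate corrected for the two-block query;
    # the in-block double-hash family costs a further ~25% at most
    ref <- bloom_fpr(bits, 1, f = cal$f)$two_choice
    expect_gt(cal$fpr / ref, 0.6)
    expect_lt(cal$fpr / ref, 1.6)
  }
})
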