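#' Optimal number of Bloom filter hash functions
#'
#' For a filter of m bits holding n elements the false positive rate is
#' minimised by f = (m/n) ln 2 probe bits per element; the result is rounded
#' and floored at 1.
#'
#' @param m Filter size in bits.
#' @param n Expected number of distinct elements.
#' @return Integer number of hash functions.
#' @examples
#' optimal_hash_count(14 * 1e5, 1e5)
#' @export
optimal_hash_count <- function(m, n) {
  as.integer(cpp_optimal_f(as.double(m), as.double(n)))
}

#' Expected Bloom filter false positive rate
#'
#' Evaluates the closed form \eqn{\varphi = (1 - e^{-fn/m})^f} together with
#' the coarser \eqn{0.7^{m/n}} approximation often used for sizing.
#'
#' For the blocked 2-choice filter of this package an absent element is
#' tested against both of its candidate blocks, so its expected false
#' positive rate is \code{1 - (1 - phi)^2}, about twice \code{phi}; that
#' value is returned as \code{two_choice}.
#'
#' @param m Filter size in bits.
#' @param n Number of inserted elements.
#' @param f Number of hash functions; default \code{optimal_hash_count(m, n)}.
#' @return A list with elements \code{phi}, \code{approx} and
#'   \code{two_choice}.
#' @export
bloom_fpr <- function(m, n, f = optimal_hash_count(m, n)) {
  cpp_expected_fpr(as.double(m), as.double(n), as.double(f))
}

#' Create a blocked Bloom filter
#'
#' A blocked Bloom filter is an array of 512-bit blocks (one cache line).
#' The candidate block pair of a k-mer is derived from its minimizer hash,
#' so neighbouring k-mers sharing a minimizer land in the same block; among
#' the two candidates the element goes to the block with fewer set bits
#' (2-choice balancing). Probe bits use double hashing of the canonical
#' k-mer. Inserted elements are always reported present (no false
#' negatives); absent elements are misreported at a rate controlled by
#' \code{bits_per_kmer}.
#'
#' @param n_expected Expected number of distinct k-mers.
#' @param bits_per_kmer Bits of filter per expected k-mer (default 14, for a
#'   false positive rate around 0.1 percent).
#' @param seed Integer seed; fixes all internal hash seeds.
#' @param two_choice Use 2-choice block placement (default) or a single
#'   block per minimizer (for comparison experiments).
#' @return An object of class \code{bbf}.
#' @export
bbf <- function(n_expected, bits_per_kmer = 14, seed = 1, two_choice = TRUE) {
  ptr <- cpp_bbf_new(as.double(n_expected), as.double(bits_per_kmer),
                     as.double(seed), isTRUE(two_choice))
  structure(list(ptr = ptr, seed = as.double(seed)), class = "bbf")
}

#' @export
print.bbf <- function(x, ...) {
  p <- cpp_bbf_params(x$ptr)
  cat(sprintf("Blocked Bloom filter: %d blocks x %d bits (m = %.0f), f = %d, %d bits set\n",
              as.integer(p$nb_blocks), p$block_bits, p$m, p$f,
              as.integer(p$total_set_bits)))
  invisible(x)
}

#' Insert k-mers into a blocked Bloom filter
#'
#' @param x A \code{\link{bbf}} object.
#' @param kmers Character vector of k-mers (one fixed length).
#' @param g Minimizer length used to pick the block.
#' @return Invisibly, the integer block each k-mer resides in. Re-inserting
#'   a k-mer already present in one of its candidate blocks writes nothing.
#' @export
bbf_insert <- function(x, kmers, g) {
  stopifnot(inherits(x, "bbf"))
  invisible(cpp_bbf_insert(x$ptr, as.character(kmers), as.integer(g), x$seed))
}

#' Query a blocked Bloom filter
#'
#' @inheritParams bbf_insert
#' @return Logical vector; \code{TRUE} for every inserted k-mer (never a
#'   false negative), occasionally \code{TRUE} for absent ones.
#' @export
bbf_contains <- function(x, kmers, g) {
  stopifnot(inherits(x, "bbf"))
  cpp_bbf_may_contain(x$ptr, as.character(kmers), as.integer(g), x$seed)
}

#' Blocked Bloom filter parameters and occupancy
#'
#' @param x A \code{\link{bbf}} object.
#' @return \code{bbf_info}: list with \code{nb_blocks}, \code{block_bits},
#'   \code{m}, \code{f} and \code{total_set_bits}. \code{bbf_occupancy}:
#'   integer vector of set bits per block.
#' @export
bbf_info <- function(x) {
  stopifnot(inherits(x, "bbf"))
  cpp_bbf_params(x$ptr)
}

#' @rdname bbf_info
#' @export
bbf_occupancy <- function(x) {
  stopifnot(inherits(x, "bbf"))
  cpp_bbf_occupancy(x$ptr)
}

#' Monte-Carlo calibration of the blocked Bloom filter
#'
#' Inserts \code{n_insert} random k-mers and queries \code{n_query} k-mers
#' known to be absent, reporting the empirical false positive rate, the
#' number of false negatives on the inserted set (always 0) and per-block
#' occupancy. Useful to compare the measured rate with
#' \code{\link{bloom_fpr}} and to contrast 2-choice with single-choice
#' placement.
#'
#' @param n_insert,n_query Numbers of inserted and of absent queried k-mers.
#' @param k,g K-mer and minimizer lengths.
#' @param bits_per_kmer Filter bits per inserted k-mer.
#' @param seed Integer seed (drives both the filter and the random k-mers).
#' @param two_choice Use 2-choice placement.
#' @return List with \code{fpr}, \code{false_negatives}, \code{f}, \code{m}
#'   and \code{occupancy}.
#' @export
bbf_calibration <- function(n_insert, n_query, k = 31, g = 23,
                            bits_per_kmer = 14, seed = 1, two_choice = TRUE) {
  cpp_bbf_fpr_experiment(as.double(n_insert), as.double(n_query),
                         as.integer(k), as.integer(g),
                         as.double(bits_per_kmer), as.double(seed),
                         isTRUE(two_choice))
}

#' Exact k-mer filter
#'
#' An exact membership set over canonical k-mers, usable wherever a blocked
#' Bloom filter is (unitig extraction, graph construction). Its answers have
#' no false positives, which makes it the reference filter in tests and
#' probe-accounting experiments.
#'
#' @param kmers Character vector of k-mers.
#' @return An object of class \code{exact_filter}.
#' @export
exact_filter <- function(kmers) {
  structure(list(ptr = cpp_exact_filter_new(as.character(kmers))),
            class = "exact_filter")
}

filter_ptr <- function(x) {
  if (inherits(x, "bbf") || inherits(x, "exact_filter")) return(x$ptr)
  if (inherits(x, "bbf_ptr") || inherits(x, "exact_ptr")) return(x)
  stop("expected a 'bbf' or 'exact_filter' object")
}
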