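#' Two-pass k-mer filtering through blocked Bloom filters
#'
#' First construction stage: every canonical k-mer of every maximal ACGT
#' run streams through two blocked Bloom filters. A k-mer already present
#' in the first filter is promoted to the second, so after the pass the
#' second filter holds (a superset of) all k-mers occurring at least twice
#' — single-occurrence k-mers, mostly sequencing errors, are left behind.
#' The first filter is then discarded. \code{filter_refs} is the
#' assembled-genome variant: every k-mer goes straight to the second filter
#' (single-copy k-mers are real in an assembly) and the downstream
#' elimination threshold drops to 1.
#'
#' A k-mer occurring once can enter the second filter only through a false
#' positive of the first; those contaminants are removed later by
#' counter-based elimination (\code{\link{eliminate_false_positives}}).
#'
#' @param files Character vector of FASTA/FASTQ paths, processed in order
#'   (determinism: fixed seed and input order give identical filters).
#' @param k,g K-mer and minimizer lengths.
#' @param bits_per_kmer Filter bits per expected element.
#' @param seed Integer seed.
#' @param expected_kmers Expected distinct k-mers (default: total k-mer
#'   count of the input, an upper bound).
#' @return List with \code{bbf2} (a \code{\link{bbf}} holding the surviving
#'   k-mers) and \code{stats} (sequences read, k-mers scanned, k-mers
#'   promoted).
#' @export
filter_reads <- function(files, k = 31, g = k - 8, bits_per_kmer = 14,
                         seed = 1, expected_kmers = NULL) {
  filter_impl(files, k, g, bits_per_kmer, seed, expected_kmers,
              reference_mode = FALSE)
}

#' @rdname filter_reads
#' @export
filter_refs <- function(files, k = 31, g = k - 8, bits_per_kmer = 14,
                        seed = 1, expected_kmers = NULL) {
  filter_impl(files, k, g, bits_per_kmer, seed, expected_kmers,
              reference_mode = TRUE)
}

filter_impl <- function(files, k, g, bits_per_kmer, seed, expected_kmers,
                        reference_mode) {
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("input file does not exist: ", missing[1])
  seqs <- unname(read_many(files))
  k <- as.integer(k); g <- as.integer(g)
  n_kmers <- sum(pmax(nchar(seqs) - k + 1, 0))
  if (is.null(expected_kmers)) expected_kmers <- max(n_kmers, 1)
  n2 <- if (reference_mode) expected_kmers else max(expected_kmers / 2, 1)
  fl <- cpp_filter_sequences(seqs, k, g, expected_kmers, n2,
                             as.double(bits_per_kmer), as.double(seed),
                             isTRUE(reference_mode))
  list(bbf2 = structure(list(ptr = fl$bbf2, seed = as.double(seed)),
                        class = "bbf"),
       stats = fl$stats)
}
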