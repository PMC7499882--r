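#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings over A/C/G/T.
#' @return Character vector of the same length with each string reversed and
#'   complemented (pairs A-T and C-G).
#' @examples
#' revcomp(c("AAAC", "ACGT"))
#' @export
revcomp <- function(x) {
  cpp_revcomp(as.character(x))
}

#' Canonical form of DNA strings
#'
#' The canonical form of a string is the lexicographically smaller of the
#' string and its reverse complement; it is the strand-independent
#' representative used throughout the package.
#'
#' @param x Character vector of DNA strings over A/C/G/T.
#' @return Character vector of canonical strings. Idempotent, and invariant
#'   under reverse complement of the input.
#' @examples
#' canonical_dna(c("TTT", "ACG"))
#' @export
canonical_dna <- function(x) {
  cpp_canonical(as.character(x))
}

#' Seeded hash of a canonical g-mer
#'
#' Hashes the canonical form of each g-mer with a seeded 64-bit mix, so a
#' g-mer and its reverse complement hash equal. This hash induces the random
#' minimizer order; one seed is fixed per index so results are reproducible.
#'
#' @param gmer Character vector of g-mers (length at most 31).
#' @param seed Integer seed of the hash (the index seed).
#' @return Character vector of 16-digit hexadecimal hash values.
#' @export
gmer_hash <- function(gmer, seed = 1) {
  cpp_gmer_hash(as.character(gmer), as.double(seed))
}

#' Minimizer of a k-mer
#'
#' Returns, for each k-mer, the interior g-mer with the smallest seeded hash
#' of its canonical form. The first and last g-mer of the k-mer are excluded
#' so that all forward (respectively backward) neighbours of a k-mer share
#' one minimizer; ties on equal hashes resolve to the leftmost position.
#'
#' @param kmer Character vector of k-mers (all of one length k).
#' @param g Minimizer length, with \code{1 <= g <= k - 2}.
#' @param seed Integer hash seed.
#' @return A tibble with columns \code{gmer} (canonical), \code{hash}
#'   (hexadecimal) and \code{pos} (1-based start of the occurrence in the
#'   k-mer; never 1 and never k - g + 1).
#' @examples
#' minimizer_of("ACGTACGTA", g = 3)
#' @export
minimizer_of <- function(kmer, g, seed = 1) {
  as_tibble(cpp_minimizer_of(as.character(kmer), as.integer(g), as.double(seed)))
}

#' Minimizers of every k-mer of a sequence
#'
#' Iterates over all k-mers of a sequence and reports each one's minimizer,
#' using an ascending-minima sliding window so total work is linear in the
#' sequence length. The output is identical to calling
#' \code{\link{minimizer_of}} on each k-mer independently.
#'
#' @param seq A single DNA string of length at least k (A/C/G/T only).
#' @param k K-mer length.
#' @param g Minimizer length, \code{1 <= g <= k - 2}.
#' @param seed Integer hash seed.
#' @return A tibble with one row per k-mer: \code{kmer_index} (1-based),
#'   \code{gmer}, \code{hash}, \code{pos} (within the k-mer) and
#'   \code{pos_abs} (within \code{seq}). Zero rows if \code{seq} is shorter
#'   than k.
#' @export
iterate_minimizers <- function(seq, k, g, seed = 1) {
  stopifnot(length(seq) == 1)
  if (nchar(seq) < k) {
    return(tibble(kmer_index = integer(), gmer = character(),
                  hash = character(), pos = integer(), pos_abs = integer()))
  }
  as_tibble(cpp_iterate_minimizers(seq, as.integer(k), as.integer(g),
                                   as.double(seed)))
}

#' K-mers of a sequence
#'
#' Utility enumerating the k-mers of each maximal A/C/G/T run of a sequence
#' (no k-mer spans a non-ACGT character).
#'
#' @param x Character vector of sequences.
#' @param k K-mer length.
#' @param canonical If \code{TRUE} (default), return canonical forms.
#' @return Character vector of k-mers, in order of occurrence.
#' @export
kmers_of <- function(x, k, canonical = TRUE) {
  out <- unlist(lapply(x, function(s) {
    runs <- strsplit(toupper(s), "[^ACGT]+")[[1]]
    runs <- runs[nchar(runs) >= k]
    unlist(lapply(runs, function(r) {
      n <- nchar(r)
      substring(r, 1:(n - k + 1), k:n)
    }))
  }), use.names = FALSE)
  if (is.null(out)) out <- character()
  if (canonical && length(out)) out <- cpp_canonical(out)
  out
}
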