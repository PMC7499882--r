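#' K-mer variants within one substitution or indel
#'
#' Enumerates the canonical k-mers reachable from a k-mer by at most one
#' edit: the k-mer itself, all 3k substitutions, and windowed indels — a
#' deletion restores length k by appending one base at either end of the
#' window, an insertion by trimming one base from either end. The set is
#' deduplicated over canonical forms.
#'
#' @param kmer One k-mer.
#' @return Character vector of canonical variants (sorted, unique,
#'   containing \code{canonical_dna(kmer)}).
#' @export
edit1_variants <- function(kmer) {
  stopifnot(length(kmer) == 1)
  cpp_edit1_variants(as.character(kmer))
}

#' Query sequences against a graph
#'
#' Counts, per query, how many of its k-mers are present in the graph and
#' declares the query present when the found fraction reaches the inclusion
#' rate \code{theta} (\code{theta = 1} requires every k-mer). In inexact
#' mode a k-mer also counts as found when any of its
#' \code{\link{edit1_variants}} (one substitution or indel) is in the
#' graph. K-mers never span non-ACGT characters; repeated k-mers within a
#' query are counted per position.
#'
#' @param x A \code{cdbg} object.
#' @param queries Character vector of query sequences (optionally named).
#' @param theta Inclusion rate in (0, 1].
#' @param inexact Allow one substitution or indel per k-mer.
#' @param report_colors Add one column per color with the fraction of query
#'   k-mers found carrying that color (colored graphs only).
#' @return Tibble with \code{id}, \code{n_kmers}, \code{n_found},
#'   \code{ratio}, \code{present} and \code{too_short} (query shorter than
#'   k: \code{n_kmers = 0}, never present). With \code{report_colors}, one
#'   extra column per color name.
#' @export
query_sequences <- function(x, queries, theta = 1, inexact = FALSE,
                            report_colors = FALSE) {
  stopifnot(inherits(x, "cdbg"))
  if (!is.numeric(theta) || theta <= 0 || theta > 1)
    stop("theta must be in (0, 1]")
  ids <- names(queries)
  if (is.null(ids)) ids <- paste0("query", seq_along(queries))
  res <- cpp_query_sequences(x$ptr, unname(as.character(queries)),
                             as.double(theta), isTRUE(inexact),
                             isTRUE(report_colors))
  out <- tibble(id = ids, n_kmers = res$n_kmers, n_found = res$n_found,
                ratio = res$ratio, present = res$present,
                too_short = res$too_short)
  if (report_colors) {
    nm <- cpp_color_names(x$ptr)
    if (length(nm)) {
      cm <- res$colors
      colnames(cm) <- nm
      out <- cbind(out, as.data.frame(cm, optional = TRUE))
      out <- as_tibble(out, .name_repair = "minimal")
    }
  }
  out
}

#' Query a FASTA/FASTQ file against a graph
#'
#' Reads queries from a file, runs \code{\link{query_sequences}} and
#' optionally writes the result as a TSV report (one row per query).
#'
#' @param x A \code{cdbg} object.
#' @param path Query FASTA/FASTQ file.
#' @param out Optional output TSV path.
#' @inheritParams query_sequences
#' @return The result tibble, invisibly when \code{out} is given.
#' @export
query_file <- function(x, path, out = NULL, theta = 1, inexact = FALSE,
                       report_colors = FALSE) {
  q <- read_sequences(path)
  res <- query_sequences(x, q, theta = theta, inexact = inexact,
                         report_colors = report_colors)
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}
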