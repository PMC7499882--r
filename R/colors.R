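#' Color a graph by input dataset
#'
#' Annotates every k-mer of a built graph with the subset of datasets
#' (colors) it occurs in. Each unitig of \eqn{\eta} k-mers is associated
#' with a binary \eqn{\eta \times |C|} matrix; a set bit at (i, j) means the
#' i-th k-mer of the unitig occurs in dataset j. Matrices live in tiered
#' containers chosen by sparsity: a single 64-bit word (one pair, or the
#' full matrix when \eqn{\eta |C| \le 62}), a bounded pair set (up to 65488
#' pairs within an 8 KB budget), or an unbounded set. Containers are linked
#' to unitigs through an array of hash seeds tried in order on the unitig's
#' head k-mer plus a fallback hash table, so graph edits elsewhere never
#' move a container.
#'
#' @param x A \code{cdbg} built from the union of \code{files}.
#' @param files One FASTA/FASTQ path per color, in color order; basenames
#'   become the color names.
#' @param strict Error if a k-mer of a color file is absent from the graph
#'   (reference mode expectation); by default absent k-mers are skipped
#'   (reads mode: they were filtered out).
#' @return \code{x}, invisibly (colored in place).
#' @export
add_colors <- function(x, files, strict = FALSE) {
  stopifnot(inherits(x, "cdbg"))
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("input file does not exist: ", missing[1])
  if (length(cpp_color_names(x$ptr)))
    stop("graph is already colored; use update_cdbg() to add datasets")
  cpp_init_colors(x$ptr, make.unique(basename(files)), 16L)
  for (i in seq_along(files)) {
    seqs <- unname(read_sequences(files[i]))
    cpp_add_color_file(x$ptr, seqs, i, isTRUE(strict))
  }
  invisible(x)
}

#' Color names of a graph
#'
#' @param x A \code{cdbg} object.
#' @return Character vector of color names (input file basenames), in
#'   color-id order; empty if the graph is uncolored.
#' @export
color_names <- function(x) {
  stopifnot(inherits(x, "cdbg"))
  cpp_color_names(x$ptr)
}

#' Color sets of k-mers
#'
#' @param x A colored \code{cdbg}.
#' @param kmers Character vector of k-mers.
#' @return A list, one element per k-mer: an integer vector of color ids
#'   (1-based, in file order), or \code{NULL} for k-mers absent from the
#'   graph.
#' @export
colors_of <- function(x, kmers) {
  stopifnot(inherits(x, "cdbg"))
  cpp_colors_of(x$ptr, as.character(kmers))
}

#' Pan-genome color summary
#'
#' Partitions the graph's k-mers by color multiplicity — singleton (exactly
#' one color), core (all colors), dispensable (more than one but not all) —
#' and reports the fraction of unitigs whose k-mers all share a single
#' color set.
#'
#' @param x A colored \code{cdbg}.
#' @return List with \code{n_colors}, \code{singleton}, \code{core},
#'   \code{dispensable}, \code{uncolored} k-mer counts and
#'   \code{frac_single_set_unitigs}.
#' @export
color_summary <- function(x) {
  stopifnot(inherits(x, "cdbg"))
  cpp_color_summary(x$ptr)
}

#' Color matrix of one unitig
#'
#' @param x A colored \code{cdbg}.
#' @param id Unitig id.
#' @return Tibble of set matrix cells: \code{row} (k-mer position, 1-based)
#'   and \code{color}.
#' @export
unitig_colors <- function(x, id) {
  stopifnot(inherits(x, "cdbg"))
  as_tibble(cpp_unitig_colors(x$ptr, as.integer(id)))
}
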