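new_cdbg <- function(ptr, mode = "reference") {
  p <- cpp_cdbg_params(ptr)
  structure(list(ptr = ptr, k = p$k, g = p$g, t = p$t, seed = p$seed,
                 mode = mode),
            class = "cdbg")
}

#' Create an empty compacted de Bruijn graph index
#'
#' The index D = (U, M) couples a unitig array U with a hash table M from
#' canonical minimizer g-mers to (unitig, position) tuples. It supports
#' exact k-mer lookup, dynamic insertion and removal of unitigs, and is the
#' object the construction pipeline (\code{\link{build_cdbg}}) fills.
#' Functions operating on it mutate it in place (reference semantics, like
#' an environment) and return it invisibly.
#'
#' @param k K-mer length: odd, between 3 and 31.
#' @param g Minimizer length, \code{1 <= g <= k - 2}; default \code{k - 8}.
#' @param t Recurrent-minimizer threshold: tuple lists in M longer than
#'   \code{t} make a minimizer recurrent, and insertion/lookup falls back to
#'   the k-mer's next minimizer in hash order.
#' @param seed Integer seed of the minimizer hash order, recorded in the
#'   index (and in GFA headers) for reproducibility.
#' @return An object of class \code{cdbg}.
#' @export
cdbg_new <- function(k = 31, g = k - 8, t = 64, seed = 1) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  g <- as.integer(g)
  if (g < 1L) g <- 1L
  new_cdbg(cpp_cdbg_new(k, g, as.integer(t), as.double(seed)))
}

#' Build a compacted de Bruijn graph from sequence files
#'
#' Runs the full construction pipeline:
#' \enumerate{
#'   \item Filtering: all canonical k-mers stream through two blocked Bloom
#'     filters; in \code{"reads"} mode only k-mers seen at least twice reach
#'     the second filter (single-occurrence k-mers are mostly sequencing
#'     errors), in \code{"reference"} mode every k-mer does.
#'   \item Unitig extraction: a second pass over the input extracts maximal
#'     non-branching paths directly from the filter. Candidate neighbours
#'     with no second neighbour in the filter are presumed false positives
#'     ("ghost" k-mers): they are recorded, ignored during extension, and
#'     repaired if a read later proves them real.
#'   \item Exactness: an occurrence counter per k-mer lets a cleanup pass
#'     delete filter false positives (counter below 2 in reads mode, below 1
#'     in reference mode), splitting and re-joining unitigs to a maximally
#'     compacted fixed point.
#' }
#' With \code{colors = TRUE} each input file becomes one color and every
#' k-mer is annotated with the subset of files it occurs in.
#'
#' @param files Character vector of FASTA/FASTQ paths (plain or gzip). In
#'   colored mode, one file per color.
#' @param k,g,t,seed See \code{\link{cdbg_new}}.
#' @param mode \code{"reads"} (k-mers must occur twice) or
#'   \code{"reference"} (assemblies; all k-mers kept).
#' @param bits_per_kmer Blocked-Bloom-filter bits per expected k-mer
#'   (default 14, about 0.1 percent false positives).
#' @param colors Color the graph with one color per input file.
#' @param expected_kmers Optional override of the filter sizing (expected
#'   distinct k-mers); by default estimated from the input volume.
#' @return A \code{cdbg} object (see \code{\link{unitigs}},
#'   \code{\link{lookup_kmer}}, \code{\link{query_sequences}},
#'   \code{\link{write_gfa}}).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g", paste(rep("ACGTTGCAGGTCAAC", 10), collapse = "")), fa)
#' D <- build_cdbg(fa, k = 15, mode = "reference")
#' D
#' @export
build_cdbg <- function(files, k = 31, g = k - 8, mode = c("reads", "reference"),
                       t = 64, seed = 1, bits_per_kmer = 14, colors = FALSE,
                       expected_kmers = NULL) {
  mode <- match.arg(mode)
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("input file does not exist: ", missing[1])
  seqs <- unname(read_many(files))
  D <- cdbg_new(k = k, g = g, t = t, seed = seed)
  D$mode <- mode
  k <- D$k; g <- D$g
  n_kmers <- sum(pmax(nchar(seqs) - k + 1, 0))
  if (is.null(expected_kmers)) expected_kmers <- max(n_kmers, 1)
  n2 <- if (mode == "reference") expected_kmers else max(expected_kmers / 2, 1)
  fl <- cpp_filter_sequences(seqs, k, g, expected_kmers, n2,
                             as.double(bits_per_kmer), D$seed,
                             mode == "reference")
  cpp_build_pass(D$ptr, seqs, fl$bbf2)
  cpp_eliminate_fp(D$ptr, if (mode == "reads") 2L else 1L)
  if (isTRUE(colors)) {
    nm <- make.unique(basename(files))
    cpp_init_colors(D$ptr, nm, 16L)
    for (i in seq_along(files)) {
      cseq <- unname(read_sequences(files[i]))
      cpp_add_color_file(D$ptr, cseq, i, FALSE)
    }
  }
  D
}

#' @export
print.cdbg <- function(x, ...) {
  s <- cpp_cdbg_stats(x$ptr)
  nm <- cpp_color_names(x$ptr)
  cat(sprintf("Compacted de Bruijn graph (k = %d, g = %d, %s mode)\n",
              x$k, x$g, x$mode))
  cat(sprintf("  %d unitigs, %d k-mers, %d minimizer keys\n",
              as.integer(s$n_unitigs), as.integer(s$n_kmers),
              as.integer(s$n_minimizer_keys)))
  if (length(nm))
    cat(sprintf("  colored: %d colors (%s%s)\n", length(nm),
                paste(utils::head(nm, 3), collapse = ", "),
                if (length(nm) > 3) ", ..." else ""))
  invisible(x)
}

#' @method summary cdbg
#' @export
summary.cdbg <- function(object, ...) {
  s <- cpp_cdbg_stats(object$ptr)
  un <- cpp_unitigs(object$ptr)
  out <- c(s, list(unitig_length_median = stats::median(nchar(un$seq)),
                   unitig_length_max = if (nrow(un)) max(nchar(un$seq)) else NA))
  class(out) <- "summary.cdbg"
  out
}

#' @export
print.summary.cdbg <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Unitigs of a graph
#'
#' @param x A \code{cdbg} object.
#' @return Tibble with \code{id} (stable integer identifier), \code{seq}
#'   (stored orientation: the lexicographically smaller of the sequence and
#'   its reverse complement) and \code{n_kmers}.
#' @export
unitigs <- function(x) {
  stopifnot(inherits(x, "cdbg"))
  as_tibble(cpp_unitigs(x$ptr))
}

#' Exact k-mer lookup
#'
#' Locates k-mers in the graph through the minimizer table: the k-mer's
#' minimizer selects candidate unitigs, the k-mer and its reverse
#' complement are anchored at the stored minimizer positions and compared.
#' Lookup is exact — no false positives or negatives — unlike the Bloom
#' filter stage of construction.
#'
#' @param x A \code{cdbg} object.
#' @param kmers Character vector of k-mers.
#' @return Tibble with \code{kmer}, \code{found}, \code{id}, \code{offset}
#'   (1-based start within the stored unitig) and \code{strand}
#'   (\code{"forward"}/\code{"reverse"}).
#' @export
lookup_kmer <- function(x, kmers) {
  stopifnot(inherits(x, "cdbg"))
  as_tibble(cpp_lookup_kmers(x$ptr, as.character(kmers)))
}

#' Insert or remove a unitig
#'
#' Low-level editing of the index: \code{insert_unitig} stores the sequence
#' (in canonical orientation) and registers every k-mer's minimizer in the
#' table; \code{remove_unitig} removes the unitig's tuples from the table
#' and tombstones its slot (identifiers of other unitigs never move).
#' Callers are responsible for not inserting k-mers already present.
#'
#' @param x A \code{cdbg} object.
#' @param seq DNA string of length at least k.
#' @param id Unitig identifier as in \code{\link{unitigs}}.
#' @return \code{insert_unitig} returns the new unitig's id;
#'   \code{remove_unitig} returns \code{x} invisibly. Removing an unknown
#'   id is an error.
#' @export
insert_unitig <- function(x, seq) {
  stopifnot(inherits(x, "cdbg"))
  cpp_insert_unitig(x$ptr, seq)
}

#' @rdname insert_unitig
#' @export
remove_unitig <- function(x, id) {
  stopifnot(inherits(x, "cdbg"))
  cpp_remove_unitig(x$ptr, as.integer(id))
  invisible(x)
}

#' Construction and index statistics
#'
#' @param x A \code{cdbg} object.
#' @return List of counters: unitigs, k-mers, minimizer keys, ghosts
#'   recorded and repaired, false-positive k-mers deleted, splits and joins.
#' @export
graph_stats <- function(x) {
  stopifnot(inherits(x, "cdbg"))
  cpp_cdbg_stats(x$ptr)
}

#' Counter-based false positive elimination
#'
#' Deletes every k-mer whose occurrence counter is below \code{threshold},
#' splitting unitigs at the deletion points and re-joining mergeable
#' neighbours to a maximally compacted fixed point. Called automatically by
#' \code{\link{build_cdbg}}; exposed for pipelines that drive
#' \code{\link{extract_unitig}} manually.
#'
#' @param x A \code{cdbg} with populated counters.
#' @param threshold Minimum counter to survive (2 in reads mode, 1 in
#'   reference mode).
#' @return \code{x}, invisibly; see \code{\link{graph_stats}} for counts.
#' @export
eliminate_false_positives <- function(x, threshold = 2) {
  stopifnot(inherits(x, "cdbg"))
  cpp_eliminate_fp(x$ptr, as.integer(threshold))
  invisible(x)
}

#' Classify a low-coverage k-mer's structural role
#'
#' A Bloom-filter false positive either glues two unitigs into one (a
#' "false connection": the k-mer sits in the interior, deleting it splits
#' the unitig) or hangs off a true path (a "false branching": the k-mer is
#' terminal or a whole unitig, deleting it lets the neighbours re-join).
#'
#' @param x A \code{cdbg} object.
#' @param kmer A k-mer present in the graph.
#' @return List with \code{kind} (\code{"false_connection"} or
#'   \code{"false_branching"}), \code{id} and \code{offset}.
#' @export
classify_fp <- function(x, kmer) {
  stopifnot(inherits(x, "cdbg"))
  cpp_classify_fp(x$ptr, kmer)
}

#' Extract one unitig from a filter
#'
#' Starting from a k-mer present in the filter, extends forward and
#' backward (backward extension is forward extension from the reverse
#' complement) while the next k-mer is the unique non-ghost successor and
#' the current one its unique non-ghost predecessor. A candidate neighbour
#' with no neighbour of its own besides the current k-mer is a ghost:
#' recorded and ignored, so a lone false positive does not halt the
#' extension. A per-extraction visited set guards against cycles.
#'
#' @param filter A \code{\link{bbf}} or \code{\link{exact_filter}}.
#' @param kmer Start k-mer (must be present in the filter).
#' @param g,seed Minimizer length and index seed (must match the filter's).
#' @param use_ghosts Disable to reproduce ghost-free extraction.
#' @param instrument Record per-advance filter probe and hit counts.
#' @return List with \code{seq}, total \code{n_queries}/\code{n_hits},
#'   per-advance \code{step_probes}/\code{step_hits} (if instrumented) and
#'   the \code{ghosts} recorded.
#' @export
extract_unitig <- function(filter, kmer, g, seed = 1, use_ghosts = TRUE,
                           instrument = FALSE) {
  cpp_extract_unitig(filter_ptr(filter), kmer, as.integer(g), as.double(seed),
                     isTRUE(use_ghosts), isTRUE(instrument))
}

#' Run the unitig-extraction pass over sequences
#'
#' Second construction stage, exposed for pipelines that manage their own
#' filter: iterates over the k-mers of \code{seqs}; k-mers absent from the
#' filter are skipped, k-mers already in the graph get their counter
#' incremented (saturating at 2), and unseen k-mers trigger
#' \code{\link{extract_unitig}} followed by insertion. K-mers found in the
#' ghost table are repaired (their neighbourhood is re-extracted). Finish
#' with \code{\link{eliminate_false_positives}}.
#'
#' @param x An empty or partially built \code{cdbg}.
#' @param seqs Character vector of sequences (reads or references).
#' @param filter A \code{\link{bbf}} or \code{\link{exact_filter}} holding
#'   the k-mers to keep.
#' @return \code{x}, invisibly.
#' @export
cdbg_build_pass <- function(x, seqs, filter) {
  stopifnot(inherits(x, "cdbg"))
  cpp_build_pass(x$ptr, unname(as.character(seqs)), filter_ptr(filter))
  invisible(x)
}

#' K-mer occurrence counters of a unitig
#'
#' Construction-phase counters, saturating at 2: the cleanup pass only
#' needs to distinguish 0/1 occurrences from 2 or more.
#'
#' @param x A \code{cdbg} object.
#' @param id Unitig id.
#' @return Integer vector of per-k-mer counters.
#' @export
kmer_counters <- function(x, id) {
  stopifnot(inherits(x, "cdbg"))
  cpp_counters(x$ptr, as.integer(id))
}

#' Ghost k-mers currently recorded
#'
#' @param x A \code{cdbg} object.
#' @return Character vector of canonical ghost k-mers.
#' @export
ghost_kmers <- function(x) {
  stopifnot(inherits(x, "cdbg"))
  cpp_ghosts(x$ptr)
}

#' Minimizer table contents
#'
#' @param x A \code{cdbg} object.
#' @return Tibble with one row per (minimizer g-mer, unitig id, position)
#'   tuple and the recurrence flag.
#' @export
minimizer_table <- function(x) {
  stopifnot(inherits(x, "cdbg"))
  as_tibble(cpp_minimizer_table(x$ptr))
}

#' Insertion-time minimizer selection with the recurrent fallback
#'
#' Returns the minimizer under which a k-mer would be registered: its true
#' minimizer if that g-mer's tuple list is below the recurrence threshold
#' t, otherwise the k-mer's next non-recurrent g-mer in hash order; if all
#' interior g-mers are recurrent the true minimizer is kept and the list
#' overflows.
#'
#' @param x A \code{cdbg} object.
#' @param kmer One k-mer.
#' @return List with \code{gmer}, \code{hash}, \code{pos}, \code{fallback}
#'   and \code{overflow}.
#' @export
select_insert_minimizer <- function(x, kmer) {
  stopifnot(inherits(x, "cdbg"))
  cpp_select_insert_minimizer(x$ptr, kmer)
}

#' Update a graph with additional sequence files
#'
#' Adds the k-mers of new files to an existing graph without rebuilding it:
#' new k-mers are inserted node-centrically, affected unitigs are split at
#' the new branch points and mergeable unitigs re-joined, so the result is
#' identical (k-mer set and unitig multiset) to a from-scratch build on the
#' union. On a colored graph each new file becomes a new color and k-mer
#' color sets are preserved across the splits and joins.
#'
#' @param x A \code{cdbg} object (reference-mode semantics: all new k-mers
#'   are kept).
#' @param files Character vector of FASTA/FASTQ paths.
#' @return \code{x}, invisibly (updated in place).
#' @export
update_cdbg <- function(x, files) {
  stopifnot(inherits(x, "cdbg"))
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("input file does not exist: ", missing[1])
  colored <- length(cpp_color_names(x$ptr)) > 0
  for (f in files) {
    seqs <- unname(read_sequences(f))
    cpp_update_kmers(x$ptr, seqs)
    if (colored) {
      idx <- cpp_register_color(x$ptr, basename(f))
      cpp_add_color_file(x$ptr, seqs, idx, FALSE)
    }
  }
  invisible(x)
}
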