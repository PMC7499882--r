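#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around \pkg{Biostrings} readers; the format is inferred from
#' the file extension (\code{.fq}/\code{.fastq}, optionally \code{.gz},
#' reads as FASTQ, anything else as FASTA). Sequences are returned as upper
#' case character strings; non-ACGT symbols are kept and later split on.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (file.size(path) == 0) return(stats::setNames(character(), character()))
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

read_many <- function(paths) {
  unlist(lapply(paths, read_sequences), use.names = TRUE)
}

write_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  lines <- character(2 * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", ids)
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
  invisible(path)
}

write_fastq <- function(seqs, path, qual_char = "I") {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  lines <- character(4 * length(seqs))
  lines[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", ids)
  lines[c(FALSE, TRUE, FALSE, FALSE)] <- unname(seqs)
  lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  lines[c(FALSE, FALSE, FALSE, TRUE)] <-
    vapply(seqs, function(s) strrep(qual_char, nchar(s)), "", USE.NAMES = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Write a graph as GFA 1.0
#'
#' One S-line per unitig (sequence verbatim, stable integer names) and one
#' L-line per adjacency with overlap CIGAR \code{(k-1)M}. The header records
#' k, g and the index seed as optional tags, so \code{\link{read_gfa}} can
#' rebuild an equivalent index.
#'
#' @param x A \code{\link{build_cdbg}} graph.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_gfa <- function(x, path) {
  stopifnot(inherits(x, "cdbg"))
  p <- cpp_cdbg_params(x$ptr)
  un <- cpp_unitigs(x$ptr)
  ad <- cpp_adjacency(x$ptr)
  h <- sprintf("H\tVN:Z:1.0\tKL:i:%d\tML:i:%d\tSD:i:%d", p$k, p$g, as.integer(p$seed))
  s <- if (nrow(un)) sprintf("S\t%d\t%s\tLN:i:%d", un$id, un$seq, nchar(un$seq)) else character()
  l <- if (nrow(ad)) sprintf("L\t%d\t%s\t%d\t%s\t%dM", ad$from, ad$from_orient,
                             ad$to, ad$to_orient, p$k - 1L) else character()
  writeLines(c(h, s, l), path)
  invisible(path)
}

#' Read a GFA 1.0 unitig graph
#'
#' Rebuilds a graph index from a GFA written by \code{\link{write_gfa}}:
#' S-line sequences are re-inserted as unitigs (adjacencies are implied by
#' the k-1 overlaps and are not read back). Round-tripping preserves the
#' k-mer set, the unitig multiset and the adjacency set.
#'
#' @param path GFA file.
#' @param k,g,seed Override the header tags (rarely needed).
#' @return A \code{cdbg} object.
#' @export
read_gfa <- function(path, k = NULL, g = NULL, seed = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty GFA file: ", path)
  rt <- substr(lines, 1, 1)
  hdr <- strsplit(lines[rt == "H"][1], "\t", fixed = TRUE)[[1]]
  tagval <- function(tag, default = NULL) {
    hit <- grep(paste0("^", tag, ":i:"), hdr, value = TRUE)
    if (length(hit)) as.integer(sub(".*:", "", hit[1])) else default
  }
  k <- if (is.null(k)) tagval("KL") else as.integer(k)
  g <- if (is.null(g)) tagval("ML") else as.integer(g)
  seed <- if (is.null(seed)) tagval("SD", 1L) else as.integer(seed)
  if (is.null(k) || is.null(g))
    stop("GFA header carries no KL/ML tags; supply k and g")
  D <- cdbg_new(k = k, g = g, seed = seed)
  for (i in which(rt == "S")) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed S-line at line ", i)
    insert_unitig(D, f[3])
  }
  bad <- which(!rt %in% c("H", "S", "L", "#") & nzchar(lines))
  if (length(bad)) stop("unrecognised GFA record at line ", bad[1])
  D
}

#' Export the color assignment as TSV
#'
#' Human-readable sidecar for a colored graph: one row per (unitig, k-mer
#' row, color name). Color names are the input file basenames.
#'
#' @param x A colored \code{cdbg}.
#' @param path Output TSV file.
#' @return Invisibly, \code{path}.
#' @export
write_colors_tsv <- function(x, path) {
  stopifnot(inherits(x, "cdbg"))
  nm <- cpp_color_names(x$ptr)
  un <- cpp_unitigs(x$ptr)
  rows <- lapply(un$id, function(id) {
    df <- cpp_unitig_colors(x$ptr, id)
    if (!nrow(df)) return(NULL)
    data.frame(id = id, row = df$row, color = nm[df$color],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(id = integer(), row = integer(),
                                      color = character())
  utils::write.table(out[order(out$id, out$row, out$color), ],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
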