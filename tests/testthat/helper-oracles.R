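# Independent oracles used across the suite. They deliberately avoid the
# package's compiled code paths: reverse complements come from Biostrings,
# k-mer enumeration and graph compaction are plain string manipulation.

DNA <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

oracle_canonical <- function(x) {
  r <- oracle_revcomp(x)
  ifelse(x <= r, x, r)
}

# all k-mers of each maximal ACGT run, canonical form
oracle_kmers <- function(seqs, k, canonical = TRUE) {
  out <- unlist(lapply(seqs, function(s) {
    runs <- strsplit(s, "[^ACGT]+")[[1]]
    runs <- runs[nchar(runs) >= k]
    unlist(lapply(runs, function(r) {
      n <- nchar(r)
      substring(r, 1:(n - k + 1), k:n)
    }))
  }), use.names = FALSE)
  if (is.null(out)) return(character())
  if (canonical) oracle_canonical(out) else out
}

oracle_kmer_counts <- function(seqs, k) table(oracle_kmers(seqs, k))

# brute-force compaction of a canonical k-mer set into maximal
# non-branching paths; unitigs are reported in canonical orientation,
# sorted, so multisets can be compared with identical()
oracle_compact <- function(kmer_set, k) {
  kk <- unique(kmer_set)
  rcs <- oracle_revcomp(kk)
  S <- new.env(hash = TRUE, parent = emptyenv())
  for (x in kk) assign(x, TRUE, envir = S)   # both orientations, so member
  for (x in rcs) assign(x, TRUE, envir = S)  # tests need no canonicalization
  in_set <- function(w) exists(w, envir = S, inherits = FALSE)

  succs <- function(w) {
    cand <- paste0(substr(w, 2, k), DNA)
    cand[vapply(cand, in_set, TRUE)]
  }
  preds <- function(w) {
    cand <- paste0(DNA, substr(w, 1, k - 1))
    cand[vapply(cand, in_set, TRUE)]
  }
  is_start <- function(w) {
    p <- preds(w)
    length(p) != 1 || length(succs(p[1])) != 1
  }

  rc_of <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(kk)) {
    assign(kk[i], rcs[i], envir = rc_of)
    assign(rcs[i], kk[i], envir = rc_of)
  }
  visited <- new.env(hash = TRUE, parent = emptyenv())
  mark <- function(w) {
    assign(w, TRUE, envir = visited)
    assign(get(w, envir = rc_of), TRUE, envir = visited)
  }
  unitigs <- character()
  walk <- function(w) {
    parts <- w
    mark(w)
    repeat {
      s <- succs(w)
      if (length(s) != 1) break
      if (length(preds(s[1])) != 1) break
      if (exists(s[1], envir = visited, inherits = FALSE)) break
      mark(s[1])
      parts <- c(parts, substr(s[1], k, k))
      w <- s[1]
    }
    paste(parts, collapse = "")
  }

  for (x in sort(kk)) {
    if (exists(x, envir = visited, inherits = FALSE)) next
    w <- if (is_start(x)) x else {
      r <- get(x, envir = rc_of)
      if (is_start(r)) r else NA_character_
    }
    if (!is.na(w)) unitigs <- c(unitigs, walk(w))
  }
  # leftovers are isolated cycles: walk them from an arbitrary phase
  for (x in sort(kk)) {
    if (exists(x, envir = visited, inherits = FALSE)) next
    unitigs <- c(unitigs, walk(x))
  }
  sort(oracle_canonical(unitigs))
}

# unitig multiset of a graph, canonical orientation, sorted
graph_unitig_multiset <- function(D) sort(oracle_canonical(unitigs(D)$seq))

graph_kmer_set <- function(D) oracle_kmers(unitigs(D)$seq, D$k)

# independent enumerator of the windowed edit-distance-1 variants
oracle_edit1 <- function(x) {
  k <- nchar(x)
  s <- strsplit(x, "")[[1]]
  out <- x
  for (p in seq_len(k)) for (b in DNA) {
    y <- s; y[p] <- b
    out <- c(out, paste(y, collapse = ""))
  }
  for (d in seq_len(k)) {
    core <- paste(s[-d], collapse = "")
    for (b in DNA) out <- c(out, paste0(b, core), paste0(core, b))
  }
  for (p in 0:k) for (b in DNA) {
    y <- paste0(substr(x, 1, p), b, substr(x, p + 1, k))
    out <- c(out, substr(y, 1, k), substr(y, 2, k + 1))
  }
  sort(unique(oracle_canonical(out)))
}

# write sequences to a temporary fasta and return the path
tmp_fasta <- function(seqs, dir = tempdir()) {
  f <- tempfile(tmpdir = dir, fileext = ".fasta")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  writeLines(rbind(paste0(">", ids), unname(seqs)), f)
  f
}

# a random sequence whose k-mers are all distinct (canonical), for clean
# linear-path fixtures
distinct_path <- function(len, k, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(len)
    km <- oracle_kmers(s, k)
    if (!anyDuplicated(km)) return(s)
  }
  stop("could not build a distinct-k-mer path")
}
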