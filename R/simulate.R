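rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

canon_chr <- function(x) {
  r <- rc_chr(x)
  ifelse(x <= r, x, r)
}

kmer_multiset <- function(seqs, k) {
  out <- unlist(lapply(seqs, function(s) {
    runs <- strsplit(s, "[^ACGT]+")[[1]]
    runs <- runs[nchar(runs) >= k]
    unlist(lapply(runs, function(r) {
      n <- nchar(r)
      substring(r, 1:(n - k + 1), k:n)
    }))
  }), use.names = FALSE)
  if (is.null(out) || !length(out)) return(character())
  canon_chr(out)
}

mutate_genome <- function(genome, mut_rate, indel_rate) {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(genome, "")[[1]]
  n <- length(s)
  sub_pos <- which(stats::runif(n) < mut_rate)
  for (p in sub_pos) s[p] <- sample(setdiff(bases, s[p]), 1)
  ev <- which(stats::runif(n) < indel_rate)
  if (length(ev)) {
    pieces <- list()
    last <- 1
    for (p in ev) {
      if (p < last) next
      if (stats::runif(1) < 0.5) { # deletion of 1-3 bases starting at p
        if (p > last) pieces[[length(pieces) + 1]] <- s[last:(p - 1)]
        last <- p + sample(3, 1)
      } else {                     # insertion of 1-3 bases after p
        pieces[[length(pieces) + 1]] <-
          c(s[last:p], sample(bases, sample(3, 1), TRUE))
        last <- p + 1
      }
    }
    if (last <= n) pieces[[length(pieces) + 1]] <- s[last:n]
    s <- unlist(pieces)
  }
  paste(s, collapse = "")
}

#' Simulate a pan-genome dataset with reads and truth tables
#'
#' Generates an ancestor genome, one mutated variant per color
#' (substitutions and short 1-3 bp indels), and error-bearing reads from
#' each variant, writing FASTA genomes and FASTQ reads to \code{dir}. The
#' returned truth tables — per-color canonical k-mer sets, the set of
#' k-mers covered at least twice by the reads, and the union — are computed
#' by exact counting with plain string operations, independently of the
#' graph machinery, so they can serve as oracles. Fully reproducible for a
#' fixed seed (byte-identical files).
#'
#' @param dir Output directory (created if needed).
#' @param n_colors Number of genome variants (colors).
#' @param genome_len Ancestor genome length in bp.
#' @param mut_rate Per-base substitution rate between ancestor and variant.
#' @param indel_rate Per-position probability of a short indel event.
#' @param coverage Mean read coverage per genome.
#' @param read_len Read length in bp.
#' @param err_rate Per-base sequencing substitution error rate.
#' @param k K-mer length used for the truth tables.
#' @param seed Integer seed.
#' @return List with \code{genome_files}, \code{read_files},
#'   \code{genomes} (sequences), \code{n_reads}, and \code{truth}: a list
#'   of \code{per_color} (k-mer sets per color), \code{union},
#'   \code{twice} (k-mers covered at least twice across all reads) and
#'   \code{read_kmer_counts}.
#' @export
simulate_dataset <- function(dir = tempfile("synthdata"), n_colors = 1,
                             genome_len = 10000, mut_rate = 0.01,
                             indel_rate = 0.001, coverage = 30,
                             read_len = 100, err_rate = 0.005, k = 31,
                             seed = 1) {
  if (genome_len < k) stop("genome_len must be at least k")
  stopifnot(mut_rate >= 0, mut_rate < 1, err_rate >= 0, err_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  ancestor <- paste(sample(c("A", "C", "G", "T"), genome_len, TRUE),
                    collapse = "")
  genomes <- character(n_colors)
  genome_files <- character(n_colors)
  read_files <- character(n_colors)
  all_reads <- list()
  for (ci in seq_len(n_colors)) {
    gseq <- if (mut_rate == 0 && indel_rate == 0) ancestor
            else mutate_genome(ancestor, mut_rate, indel_rate)
    genomes[ci] <- gseq
    genome_files[ci] <- file.path(dir, sprintf("genome_%02d.fasta", ci))
    gv <- stats::setNames(gseq, sprintf("genome_%02d", ci))
    write_fasta(gv, genome_files[ci])

    glen <- nchar(gseq)
    # one tiling pass per unit of coverage (random phase, ends anchored,
    # step read_len - k + 1), so every k-mer is contained in at least one
    # read per pass and coverage >= 2 covers every k-mer twice
    last <- glen - read_len + 1
    step <- max(read_len - k + 1, 1)
    starts <- unlist(lapply(seq_len(ceiling(coverage)), function(i) {
      unique(c(1, seq(sample(step, 1), last, by = step), last))
    }))
    n_reads <- length(starts)
    reads <- substring(gseq, starts, starts + read_len - 1)
    if (err_rate > 0) {
      reads <- vapply(reads, function(r) {
        pos <- which(stats::runif(read_len) < err_rate)
        if (!length(pos)) return(r)
        s <- strsplit(r, "")[[1]]
        for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
        paste(s, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    flip <- stats::runif(n_reads) < 0.5
    reads[flip] <- rc_chr(reads[flip])
    names(reads) <- sprintf("read_%02d_%06d", ci, seq_len(n_reads))
    read_files[ci] <- file.path(dir, sprintf("reads_%02d.fastq", ci))
    write_fastq(reads, read_files[ci])
    all_reads[[ci]] <- reads
  }

  per_color <- lapply(genomes, function(gs) unique(kmer_multiset(gs, k)))
  read_km <- kmer_multiset(unname(unlist(all_reads)), k)
  counts <- table(read_km)
  list(genome_files = genome_files, read_files = read_files,
       genomes = genomes,
       n_reads = vapply(all_reads, length, 0L),
       truth = list(per_color = per_color,
                    union = unique(unlist(per_color)),
                    twice = names(counts)[counts >= 2],
                    read_kmer_counts = counts),
       params = list(n_colors = n_colors, genome_len = genome_len,
                     mut_rate = mut_rate, indel_rate = indel_rate,
                     coverage = coverage, read_len = read_len,
                     err_rate = err_rate, k = k, seed = seed))
}

#' Simulate premature extraction halts from filter false positives
#'
#' Models unitig extraction without ghost protection: every advance to the
#' next k-mer makes \code{probes} filter queries that should return false,
#' and a single false positive (probability \code{p} each) halts the
#' extension. The number of k-mers extracted is geometric with halt
#' probability \eqn{1 - (1-p)^{probes} \approx probes \cdot p}, so the mean
#' extracted length is about \eqn{1/(probes \cdot p)} — about 167 k-mers at
#' p = 0.001 with 6 probes. Ghost protection removes this fragmentation.
#'
#' @param n_trials Number of independent extraction trials.
#' @param p Filter false positive rate.
#' @param probes False-capable probes per advance (6: the 8 neighbour
#'   probes minus the 2 true neighbours).
#' @param seed Integer seed.
#' @return Numeric vector of extracted lengths (in k-mers), one per trial.
#' @export
simulate_halt_lengths <- function(n_trials = 1e5, p = 1e-3, probes = 6,
                                  seed = 1) {
  cpp_simulate_halt_lengths(as.double(n_trials), as.double(p),
                            as.integer(probes), as.double(seed))
}
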