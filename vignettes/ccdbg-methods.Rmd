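---
title: "Constructing colored, compacted de Bruijn graphs with ccdbg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing colored, compacted de Bruijn graphs with ccdbg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdbg)
```

## The problem

A de Bruijn graph (dBG) over k-mers is the workhorse structure for
assembly-free analysis of sequencing data, but the uncompacted graph of a
real dataset is prohibitively large. Its compacted form (cdBG) merges every
maximal non-branching path of $\eta$ vertices into a single *unitig* of
length $k+\eta-1$, and is orders of magnitude smaller — yet most tools
build the uncompacted graph first. `ccdbg` constructs the compacted graph
*directly* from reads or assemblies, keeps it editable (insert, remove,
update with new samples), optionally colors every k-mer with the set of
input datasets it occurs in, and answers sequence-membership queries.

All sequences are handled strand-symmetrically through *canonical* k-mers
(the lexicographically smaller of a k-mer and its reverse complement).
Input is split at non-ACGT characters; no k-mer spans them.

## Pipeline overview

1. **Filtering.** Every canonical k-mer of the input streams through two
   blocked Bloom filters. In reads mode a k-mer reaches the second filter
   only at its second occurrence, discarding the bulk of sequencing-error
   k-mers; in reference (assembly) mode all k-mers pass directly. The
   second filter is an *approximation* of the dBG: complete, but with a
   tunable false positive rate.
2. **Unitig extraction.** A second pass over the input walks the filter:
   from each unseen k-mer the containing unitig is reconstructed by
   extending while the next k-mer is the unique successor and the current
   one its unique predecessor (backward extension is forward extension
   from the reverse complement; a per-extraction visited set guards
   against cycles). Extracted unitigs enter the index, and a saturating
   2-bit counter per k-mer records how often the reads support it.
3. **Exactness.** After the pass, k-mers with counter below the threshold
   (2 in reads mode, 1 in reference mode) are Bloom false positives or
   unfiltered errors: they are deleted, affected unitigs are split at the
   deletion points, and a join sweep re-merges mergeable neighbours until
   the graph is again maximally compacted. The result is *exact*: its
   k-mer set equals the exact-counter truth despite the approximate
   filter.

### Minimizers and the index

The index $D=(U,M)$ couples the unitig array $U$ with a hash table $M$
from minimizer g-mers to (unitig, position) tuples. The minimizer of a
k-mer is its interior g-mer (first and last g-mer excluded) with the
smallest seeded hash of its canonical form; hashing the canonical g-mer
makes the choice strand-symmetric, and excluding the window edges
guarantees that all forward (resp. backward) neighbours of a k-mer share
one minimizer, so neighbour probes during extraction stay within one
filter block. Iterating minimizers over a sequence uses an
ascending-minima sliding window, linear in the sequence length
(`iterate_minimizers()`); ties between equal hashes go to the leftmost
position. Lookup anchors the query k-mer and its reverse complement at
the stored minimizer positions and string-compares — the index is exact.

**Recurrent minimizers.** Low-complexity sequence makes some minimizers
occur in many unitigs. Tuple lists in $M$ are capped at $t$ (default 64):
once a list reaches $t$ the g-mer is flagged recurrent (the flag is
sticky, which keeps lookups correct when later removals shrink the list),
and insertion/lookup falls back to the k-mer's next non-recurrent g-mer in
ascending hash order. If every interior g-mer is recurrent the true
minimizer is kept and its list overflows.

### The blocked Bloom filter

The filter is an array of 512-bit blocks (one cache line). A k-mer's two
candidate blocks derive from its minimizer hash — overlapping k-mers
sharing a minimizer hit the same block — and it is inserted into the
candidate with fewer set bits (2-choice balancing) unless already present
in either. Probe bits come from enhanced (triangular) double hashing of
two hashes of the canonical k-mer, with distinct positions; plain
double-hash progressions correlate measurably inside a 512-bit block and
were avoided. Occupancy counters are maintained exactly per block. The
implementation is single-writer; per-block exclusive locking would be
required before any parallel mutation.

Because a query tests *both* candidate blocks, the expected false
positive rate of the whole filter is $1-(1-\varphi)^2 \approx 2\varphi$
where $\varphi=(1-e^{-fn/m})^f$ is the classical per-filter rate;
`bloom_fpr()` reports both values. Calibration experiments
(`bbf_calibration()`) confirm the filter sits at the 2-choice expectation
(within ~25%) with zero false negatives; the doubling is architectural —
it is the price of balanced insertion, which in exchange removes the
load-variance inflation that unbalanced blocked filters suffer.

### Ghost k-mers

A single false-positive neighbour would otherwise halt extraction: with 8
neighbour probes per internal k-mer (6 of which should answer false), a
false positive rate $p$ halts extension with probability $\approx 6p$ per
step, capping unitigs at a geometric mean length of $1/(6p)$ — about 167
k-mers at $p=10^{-3}$ (`simulate_halt_lengths()` reproduces this law).
Instead, a candidate neighbour with *no neighbour of its own* besides the
current k-mer is recorded as a **ghost** and ignored, so extraction walks
straight past lone false positives. Two safeguards matter in practice: a
k-mer already living in the graph, or belonging to the extension being
built, is never ghosted (it is demonstrably real). If a read later
contains a ghost, the surrounding unitigs are removed, re-extracted
through the now-trusted k-mer, and counters and colors are transferred by
k-mer — the graph ends up as if the k-mer had never been ghosted.

In measured practice the with-ghost halting rate is somewhat above the
independent-probe estimate $42p^2$ because false positives cluster within
blocks (neighbour probes deliberately share a block), but extraction
still reaches chromosome-scale unitigs, an order of magnitude past the
ghostless law.

### Dynamic updates

`update_cdbg()` adds datasets without rebuilding: new k-mers are inserted
node-centrically as length-k unitigs, every unitig is split at adjacency
points whose in/out-degree the new k-mers changed, and a worklist join
sweep restores maximal compaction. The same split/join machinery backs
false-positive elimination, so update-then-query equals build-from-union
exactly (k-mer set, unitig multiset, and color sets).

## Colors

A unitig of $\eta$ k-mers over $|C|$ datasets carries an $\eta \times
|C|$ binary presence matrix behind one of three containers chosen by
content: a single 64-bit word (one (row, color) pair, or the whole matrix
when $\eta|C| \le 62$, two bits being metadata); a bounded pair set
("medium", at most 65488 pairs within an 8 KB serialized budget — the
budget is the smaller of the bit-matrix and 4-bytes-per-pair encodings);
and an unbounded pair set ("large", playing the role a compressed Roaring
bitmap plays at scale — compression is an optimization, not a semantic,
so the reference implementation stores pairs plainly). Membership answers
are identical across tiers, and upgrades preserve content.

Containers are not addressed by unitig id: an array of hash seeds is
tried in order on the unitig's head k-mer to claim a free slot in the
container array (a fallback hash table catches total collision), and the
resolved slot index is stored on the unitig record. Graph edits elsewhere
therefore never move or re-resolve a container. Adding a color later
re-encodes only the word-tier bit matrices (their layout depends on
$|C|$).

The summary statistics follow pan-genome convention: a k-mer is
*singleton* with exactly one color, *core* with all colors, *dispensable*
otherwise; `color_summary()` also reports the fraction of unitigs whose
k-mers share a single color set.

## Queries

`query_sequences()` counts, per query, the fraction of its k-mers present
in the graph and declares the query present when the fraction reaches the
inclusion rate $\theta \in (0,1]$. Repeated k-mers count per position. In
inexact mode a k-mer is found if any of its variants within one
substitution or indel is in the graph; since an indel changes length, the
package uses windowed variants that restore length k — a deletion appends
one base at either window edge, an insertion trims one — verified only by
graph lookup. A k-mer found through a variant counts fully. This windowed
indel semantics is the one place the package's query definition is an
interpretation rather than a literal transcription, and it is what the
`edit1_variants()` enumerator implements and tests pin down.

## Synthetic data

`simulate_dataset()` generates the study conditions used throughout the
tests: a random ancestor genome (default 10 kb), one mutated variant per
color (1% substitutions, 0.1% short 1–3 bp indel events), and reads of
100 bp at 30-fold coverage with 0.5% substitution errors, written as
FASTA/FASTQ with exact-count truth tables computed independently of the
graph code. Reads are drawn as one tiling pass per unit of coverage with
random phase, anchored ends and step $\mathrm{read\_len}-k+1$, so
coverage $\ge 2$ guarantees every genomic k-mer is sequenced twice —
uniform-start sampling would systematically undercover the genome ends
and make exactness claims depend on sampling luck. The generator emulates
substitution-dominated short-read data with uniform error placement; it
does not model quality-score structure, indel sequencing errors, coverage
biases, or repeats beyond what a random genome contains, so passing tests
speak to algorithmic exactness, not to robustness against every artifact
of real libraries.

Defaults elsewhere: $k=31$, $g=k-8=23$ (both validated, $g \le k-2$),
filter sizing 14 bits per expected k-mer, recurrence threshold $t=64$, 16
slot-assignment seeds. One integer seed recorded in the index (and GFA
header) drives every hash; runs are bit-reproducible. $k$ is limited to
odd values up to 31 (two-bit packing in one 64-bit word; odd k also rules
out self-reverse-complementary k-mers, which would make strand handling
ambiguous).

Problem sizes in the test-suite (5–10 kb genomes, 20–40× coverage, up to
five colors, $10^4$ queries) were chosen so the whole suite, including
brute-force oracles, completes in minutes on one core while still
exercising every code path at realistic densities.

## Worked example

```{r example}
sim <- simulate_dataset(n_colors = 3, genome_len = 4000, mut_rate = 0.01,
                        coverage = 30, err_rate = 0.005, k = 31, seed = 7)
D <- build_cdbg(sim$read_files, k = 31, mode = "reads", seed = 7)
D
graph_stats(D)$n_fp_deleted   # Bloom false positives removed by cleanup
Dc <- build_cdbg(sim$genome_files, k = 31, mode = "reference", seed = 7,
                 colors = TRUE)
color_summary(Dc)
query_sequences(Dc, substr(sim$genomes[1], 1, 200), theta = 0.8,
                report_colors = TRUE)
```

## Known limitations

* Single-threaded by design; parallel construction requires per-block
  filter locking and is out of scope.
* $k \le 31$; larger k would need a two-word k-mer representation.
* The "large" color container is uncompressed; memory, not correctness,
  is the cost at very high color counts.
* Query semantics for indels are the windowed interpretation described
  above.
* The empirical filter false positive rate is $\approx 2\varphi$
  (two-block query); size with `bloom_fpr()$two_choice` in mind.
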