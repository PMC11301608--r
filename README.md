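# memtax

Taxonomic read classification with maximal exact matches (MEMs) over a
genome collection and over lossily compressed representations of it.

## The problem

Given a collection of reference genomes attached to the leaves of a
taxonomy, and a sequencing read, we want to report a small subtree likely
to contain the read's source genome. k-mer classifiers (Kraken-style)
fix one k at build time; MEM-based classification adapts the match length
to the data instead. The practical obstacle is index size: an augmented
FM-index over the raw concatenation is only feasible when the collection
is small. `memtax` builds that index over four texts:

* **full** — the genomes concatenated in left-to-right taxonomy order,
  each terminated by `$`;
* **kernel** — the order-`kmax` string kernel: only the characters lying
  in the *first or last* occurrence of each distinct `$`-free `kmax`-mer
  are kept, every maximal omitted run is replaced by one `#` (runs
  adjacent to a `$` are dropped outright). For every k ≤ kmax the kernel
  preserves the k-mer set *and* the genome of each k-mer's first and last
  occurrence;
* **digest** — the minimizer digest: with parameters (k, w) and a hash
  h, position j is selected iff it is the leftmost minimum of h over some
  window of w consecutive k-mer positions; the digest is the sequence of
  selected k-mers, re-encoded over a dense ≤ 4^k-letter alphabet. The
  default scheme is k = 3, w = 10, h(x) = (2544·x + 3937) mod 8863 on the
  base-4 value x of the k-mer;
* **digest-kernel** — the order-`kmax` kernel of the digest, combining
  both forms of compression.

## The index and the MEM table

The augmented FM-index stores the suffix array SA, the BWT with
rank/select support, the LCP array (with LCP[0] = −1) supporting
range-minimum and previous/next-smaller-value (PSV/NSV) queries, and a
rank structure over the `$` positions (the document-boundary bitvector
B). For a read P, matching statistics are computed right to left: each
character is one backward step; when the step fails, the current match is
contracted to its longest prefix preceded by that character anywhere in
the text — located through the nearest BWT occurrences of the character,
an LCP range-minimum, and the PSV/NSV enclosing interval — after which
the step succeeds. Every left-maximal match is a MEM; SA range-min/max
over its interval give the first and last occurrence positions, and
B-rank converts those to 0-based genome indices `[first, last]`.

Against the source genome `g`, a MEM range is a **TP** if it is exactly
`[g, g]`, **FP** if non-empty but excluding `g`, **VP** if it contains
`g` and at least one other genome, **FN** if empty (possible only in
digest modes, when the read's minimizers don't occur in the collection
digest). A read is a true positive when *all* its longest MEMs are TP.

## Worked example

```r
library(memtax)
col <- build_collection(c(g0 = "GACATG", g1 = "TATAG", g2 = "CACATC",
                          g3 = "GGTTGG", g4 = "TTATAC"))
idx <- fm_index(col)
mem_table(idx, "ACATA", read_id = "toy")
#>   read_id read_start length lo hi first_pos last_pos first_doc last_doc mode
#> 1     toy          0      4  6  7         1       14         0        2 full
#> 2     toy          2      3  9 10         8       29         1        4 full
```

The read `ACATA` has two MEMs: `ACAT` (read offset 0, length 4) occurring
first in genome 0 and last in genome 2, and `ATA` (offset 2, length 3)
spanning genomes 1–4. If the read came from genome 1, the longest MEM's
range [0, 2] contains genome 1 together with others, so the read counts
as a vague positive, not a true positive:

```r
classify_read(mem_table(idx, "ACATA"), source_doc = 1L)$aggregate_label
#> [1] "VP"
tree <- parse_taxonomy("((g0,(g1,g4)),(g2,g3));", "newick", col$names)
subtree_for_mem(tree, 1L, 4L)   # LCA of the ATA range's end genomes
#> [1] ".node3"
```

A small end-to-end evaluation (20 genomes of 500 bp, divergence 0.05,
10 reads/genome of 150 bp at 1% error):

```r
fx <- generate_fixture(20, 500, 0.05, seed = 1)
reads <- simulate_reads(fx$collection, 10, 150, 0.01, seed = 2)
evaluate_modes(fx$collection, reads,
               list(mode_spec("full"), mode_spec("kernel", kmax = 8),
                    mode_spec("digest", w = 10),
                    mode_spec("digest_kernel", kmax = 8, w = 5)))
#>            mode kmax  w text_length index_bytes tp_rate
#> 1          full   NA NA       10020      101709   1.000
#> 2        kernel    8 NA        9615       97608   0.965
#> 3        digest   NA 10        1877       19261   0.990
#> 4 digest_kernel    8  5        3412       34803   1.000
```

The digest-based indexes are several-fold smaller while the true-positive
rate stays close to the full index — the compression/accuracy trade-off
the four modes are designed to chart.

## Command line

A thin CLI over the same functions lives at `inst/cli/memtax.R`
(installed under `system.file("cli", "memtax.R", package = "memtax")`):

```sh
Rscript inst/cli/memtax.R build    --fasta refs.fa --mode digest-kernel --k 3 --w 5 --kmax 30 --out idx
Rscript inst/cli/memtax.R simulate --fasta refs.fa --reads-per-genome 500 --length 200 --error-rate 0.01 --seed 1 --out reads
Rscript inst/cli/memtax.R query    --index idx --reads reads.fa --provenance reads.prov.tsv --out out
Rscript inst/cli/memtax.R evaluate --fasta refs.fa --reads reads.fa --provenance reads.prov.tsv --out report
```

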