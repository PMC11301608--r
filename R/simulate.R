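# Synthetic phylogeny fixture and read simulator. The fixture emulates
# the shape of a large rRNA reference collection (many related sequences
# under a taxonomy) at reduced scale: a random binary tree, a random root
# sequence, and per-branch substitution at a fixed divergence rate. Reads
# follow the evaluation protocol: a uniform start inside one genome and
# exactly round(error_rate * length) substituted positions per read.

#' Generate a synthetic phylogeny fixture
#'
#' A random binary tree over `n_taxa` leaves; a uniform random root
#' sequence of `seq_length`; each branch substitutes each site of its
#' parent's sequence independently with probability `divergence` (to a
#' uniformly chosen different base). Leaf sequences become the genomes of
#' the collection, concatenated in the tree's left-to-right leaf order, so
#' adjacent genomes are phylogenetically close. Deterministic under
#' `seed`; the caller's RNG state is restored.
#'
#' @param n_taxa Number of leaf genomes (>= 2).
#' @param seq_length Genome length in bases.
#' @param divergence Per-branch per-site substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return `list(collection = , tree = , phylo = )`: a
#'   [build_collection()] result, the matching `taxonomy_tree`, and the
#'   underlying [ape] `phylo` object.
#' @export
generate_fixture <- function(n_taxa, seq_length, divergence, seed) {
  stopifnot(n_taxa >= 2, divergence >= 0, divergence < 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  phy <- ape::rtree(n_taxa)
  bases <- c("A", "C", "G", "T")
  root_seq <- sample(bases, seq_length, replace = TRUE)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + phy$Nnode)
  seqs[[root]] <- root_seq
  # edges of a phylo are in preorder, so parents are filled before children
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    s <- seqs[[par]]
    hit <- which(stats::runif(seq_length) < divergence)
    if (length(hit)) {
      s[hit] <- vapply(s[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
    }
    seqs[[child]] <- s
  }
  # left-to-right leaf order
  tip_order <- phy$edge[phy$edge[, 2] <= ntip, 2]
  labels <- sprintf("g%03d", seq_len(ntip) - 1L)
  phy$tip.label[tip_order] <- labels
  genomes <- stats::setNames(
    vapply(tip_order, function(t) paste(seqs[[t]], collapse = ""), character(1)),
    labels)
  collection <- build_collection(genomes)
  list(collection = collection,
       tree = taxonomy_from_phylo(phy, labels),
       phylo = phy)
}

#' Simulate error-bearing reads from a collection
#'
#' Each read takes a uniform random start within one genome (reads never
#' straddle a `$` boundary) and substitutes exactly
#' `round(error_rate * length)` distinct positions to a uniformly chosen
#' different base — a deterministic per-read mutation load. Genomes
#' shorter than the read length are skipped with a warning.
#'
#' @param collection A [build_collection()] result.
#' @param reads_per_doc Reads to draw from each genome.
#' @param length Read length in bases.
#' @param error_rate Substitution rate in `[0, 1)`.
#' @param seed Integer seed; the caller's RNG state is restored.
#' @return A data frame: `read_id`, `sequence`, `source_doc` (0-based),
#'   `start` (0-based offset within the genome), `mutated_positions`
#'   (comma-separated 0-based offsets within the read), `seed`.
#' @export
simulate_reads <- function(collection, reads_per_doc, length, error_rate, seed) {
  stopifnot(reads_per_doc >= 1, length >= 1, error_rate >= 0, error_rate < 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- collection_sequences(collection)
  n_mut <- round(error_rate * length)
  rows <- vector("list", collection$num_docs)
  for (d in seq_len(collection$num_docs)) {
    glen <- nchar(seqs[[d]])
    if (glen < length) {
      warning("genome '", collection$names[d], "' shorter than read length; skipped")
      next
    }
    gchars <- strsplit(seqs[[d]], "", fixed = TRUE)[[1]]
    starts <- sample.int(glen - length + 1L, reads_per_doc, replace = TRUE) - 1L
    reads <- character(reads_per_doc)
    muts <- character(reads_per_doc)
    for (j in seq_len(reads_per_doc)) {
      rc <- gchars[(starts[j] + 1L):(starts[j] + length)]
      mp <- if (n_mut > 0L) sort(sample.int(length, n_mut)) else integer()
      if (n_mut > 0L) {
        rc[mp] <- vapply(rc[mp], function(b)
          sample(setdiff(bases, b), 1L), character(1))
      }
      reads[j] <- paste(rc, collapse = "")
      muts[j] <- paste(mp - 1L, collapse = ",")
    }
    rows[[d]] <- data.frame(
      read_id = sprintf("r%03d_%04d", d - 1L, seq_len(reads_per_doc) - 1L),
      sequence = reads, source_doc = d - 1L, start = starts,
      mutated_positions = muts, seed = seed, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Write simulated reads as FASTA plus a provenance TSV
#'
#' @param reads Data frame from [simulate_reads()].
#' @param fasta_path,tsv_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_reads <- function(reads, fasta_path, tsv_path) {
  writeLines(paste0(">", reads$read_id, "\n", reads$sequence), fasta_path)
  utils::write.table(reads[, c("read_id", "source_doc", "start",
                               "mutated_positions")],
                     tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
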