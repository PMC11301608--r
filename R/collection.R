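#' Read sequences from a FASTA or FASTQ file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that uppercases the
#' sequences, validates that every record is non-empty, and optionally
#' replaces degenerate IUPAC codes by deterministically chosen concrete
#' bases (see [replace_degenerate_bases()]).
#'
#' @param path Path to a FASTA or FASTQ file (may be gzip-compressed).
#' @param format `"auto"` (by file extension), `"fasta"` or `"fastq"`.
#'   Qualities in FASTQ input are ignored.
#' @param resolve_degenerate If `TRUE` (default), non-ACGT IUPAC codes are
#'   replaced by a pseudo-random base from the code's allowed set, drawn
#'   from a fixed per-record seed so the result is reproducible.
#' @return A named character vector of uppercase sequences, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g0", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, format = c("auto", "fasta", "fastq"),
                       resolve_degenerate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      # locate the first offending line to give a usable parse error
      lines <- tryCatch(readLines(path, warn = FALSE), error = function(e2) character())
      bad <- which(!grepl("^[>@+;ACGTUNRYSWKMBDHVacgtunryswkmbdhv.*-]|^$", lines))[1]
      stop("malformed ", format, " file '", path, "'",
           if (!is.na(bad)) paste0(" near line ", bad) else "",
           ": ", conditionMessage(e), call. = FALSE)
    })
  if (length(set) == 0L) stop("no records in ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty record(s): ", paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "))
  }
  if (resolve_degenerate) seqs <- replace_degenerate_bases(seqs)
  seqs
}

#' Replace degenerate IUPAC codes by concrete bases, reproducibly
#'
#' Each non-ACGT code is replaced by a base drawn uniformly from the set of
#' bases the IUPAC code allows (e.g. `R` becomes `A` or `G`, `N` any base).
#' Draws use a fixed seed derived from the record's name and position, so
#' the replacement is deterministic and independent of the caller's RNG
#' state, which is saved and restored.
#'
#' @param seqs Named character vector of (uppercase) sequences.
#' @return The same vector with all characters in `{A,C,G,T}`.
#' @export
replace_degenerate_bases <- function(seqs) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  needs <- grepl("[^ACGT]", seqs)
  if (!any(needs)) return(seqs)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  nms <- names(seqs)
  if (is.null(nms)) nms <- as.character(seq_along(seqs))
  for (i in which(needs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% c("A", "C", "G", "T"))
    unknown <- setdiff(chars[bad], names(iupac))
    if (length(unknown)) {
      stop("record '", nms[i], "' contains non-IUPAC character(s): ",
           paste(unique(unknown), collapse = ", "))
    }
    set.seed((sum(utf8ToInt(nms[i])) * 131L + i) %% .Machine$integer.max)
    chars[bad] <- vapply(chars[bad], function(ch) {
      allowed <- strsplit(iupac[[ch]], "")[[1]]
      allowed[sample.int(length(allowed), 1L)]
    }, character(1))
    seqs[[i]] <- paste(chars, collapse = "")
  }
  seqs
}

#' Build a concatenated genome collection
#'
#' Concatenates the genomes in order, each terminated by a `$` separator,
#' recording the 0-based start offset of each genome. This is the text all
#' indexes and lossy representations are derived from.
#'
#' @param seqs Named character vector (or list of single strings) over
#'   `{A,C,G,T}`; names are the genome identifiers.
#' @return An object of class `genome_collection` with elements `text`
#'   (single string ending in `$`), `n` (total length, separators included),
#'   `doc_starts` (0-based), `names`, `num_docs`, `doc_lengths`.
#' @examples
#' build_collection(c(a = "AC", b = "GT"))
#' @export
build_collection <- function(seqs) {
  seqs <- unlist(seqs)
  if (length(seqs) == 0L) stop("no sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("g", seq_along(seqs) - 1L)
  if (any(nchar(seqs) == 0L)) stop("empty sequence(s) not allowed")
  if (any(grepl("[$#]", seqs)))
    stop("sequences must not contain the reserved separators '$' or '#'")
  if (any(grepl("[^ACGT]", seqs)))
    stop("sequences must be over {A,C,G,T}; resolve degenerate codes first")
  lens <- nchar(seqs)
  doc_starts <- c(0L, cumsum(lens + 1L))[seq_along(seqs)]
  obj <- structure(list(
    text = paste0(paste0(seqs, "$"), collapse = ""),
    n = sum(lens + 1L),
    doc_starts = as.integer(doc_starts),
    names = names(seqs),
    num_docs = length(seqs),
    doc_lengths = as.integer(lens)
  ), class = "genome_collection")
  obj
}

#' @export
print.genome_collection <- function(x, ...) {
  cat("genome_collection: ", x$num_docs, " genome(s), total length n = ",
      x$n, " (separators included)\n", sep = "")
  invisible(x)
}

#' Split a collection text back into its genomes
#' @param collection A `genome_collection`.
#' @return Named character vector of the genome sequences.
#' @export
collection_sequences <- function(collection) {
  out <- strsplit(collection$text, "$", fixed = TRUE)[[1]]
  names(out) <- collection$names
  out
}

# 0-based positions of the `$` separators in a collection text string
dollar_positions <- function(text) {
  which(strsplit(text, "", fixed = TRUE)[[1]] == "$") - 1L
}

#' Document (genome) index of a text position
#'
#' Returns the 0-based index of the genome containing a 0-based text
#' position, i.e. the number of `$` separators strictly before it — the
#' rank query on the document-boundary bitvector.
#'
#' @param x A `genome_collection`, `kernelized_text`, `digested_collection`,
#'   or `aug_fm_index`.
#' @param pos 0-based position(s) into the underlying text.
#' @return Integer vector of 0-based document indices.
#' @export
doc_of_position <- function(x, pos) {
  UseMethod("doc_of_position")
}

doc_rank_impl <- function(dollars0, n, pos) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 0L) || any(pos >= n))
    stop("position out of range [0, ", n - 1L, "]")
  findInterval(pos, dollars0 + 0.5)
}

#' @export
doc_of_position.genome_collection <- function(x, pos) {
  doc_rank_impl(dollar_positions(x$text), x$n, pos)
}

#' @export
doc_of_position.kernelized_text <- function(x, pos) {
  doc_rank_impl(x$dollar_positions, length(x$codes), pos)
}

#' @export
doc_of_position.digested_collection <- function(x, pos) {
  doc_rank_impl(which(x$codes == 0L) - 1L, length(x$codes), pos)
}

#' @export
doc_of_position.aug_fm_index <- function(x, pos) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 0L) || any(pos >= x$n))
    stop("position out of range [0, ", x$n - 1L, "]")
  x$dollar_cum[pos + 1L]
}
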