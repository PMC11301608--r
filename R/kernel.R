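# Order-kmax string kernels of the "first or last occurrence" kind:
# keep exactly the characters lying inside the first occurrence or the
# last occurrence of at least one distinct separator-free kmax-mer of the
# whole concatenation, keep every `$`, replace each maximal omitted run by
# a single `#` — unless the run touches a `$`, in which case it is dropped
# outright (reads never contain `$`, so no match can be lost there).
# This preserves the set of k-mers for every k <= kmax, and the documents
# of each k-mer's first and last occurrence.

#' Kept positions of an order-kmax kernel
#'
#' Computes the 0-based set of positions of a collection text that survive
#' kernelization: positions inside the first or last whole-collection
#' occurrence of some distinct separator-free kmax-mer, all `$` positions,
#' and every position of a genome shorter than kmax (kept verbatim so that
#' k-mer preservation holds for all k up to the genome length).
#'
#' @param text Collection text (string) or an integer code vector where
#'   `0` marks `$` and positive integers are ordinary symbols.
#' @param kmax Kernel order (positive integer).
#' @return Sorted integer vector of 0-based kept positions (including the
#'   `$` positions).
#' @export
mark_first_last <- function(text, kmax) {
  stopifnot(kmax >= 1)
  codes <- if (is.character(text)) {
    ch <- strsplit(text, "", fixed = TRUE)[[1]]
    ifelse(ch == "$", 0L, match(ch, c("$", "#", "A", "C", "G", "T")))
  } else as.integer(text)
  n <- length(codes)
  is_dollar <- codes == 0L
  keep <- is_dollar
  # genomes shorter than kmax are kept verbatim
  bnd <- c(-1L, which(is_dollar) - 1L)      # 0-based $ positions, with virtual -1
  doc_lo <- bnd[-length(bnd)] + 1L          # 0-based genome starts
  doc_hi <- bnd[-1] - 1L                    # 0-based last base of each genome
  short <- which(doc_hi - doc_lo + 1L < kmax)
  for (d in short) if (doc_hi[d] >= doc_lo[d]) keep[(doc_lo[d]:doc_hi[d]) + 1L] <- TRUE
  # window starts (1-based) whose kmax-mer is $-free and inside the text
  if (n >= kmax) {
    starts <- seq_len(n - kmax + 1L)
    nxt_dollar <- cummin(rev(ifelse(is_dollar, seq_len(n), n + 1L)))
    nxt_dollar <- rev(nxt_dollar)           # 1-based pos of next $ at or after i
    starts <- starts[nxt_dollar[starts] >= starts + kmax]
    if (length(starts)) {
      keys <- kmer_keys(codes, starts, kmax)
      sel <- starts[!duplicated(keys) | !duplicated(keys, fromLast = TRUE)]
      # paint covered intervals [s, s+kmax-1] with a difference array
      delta <- integer(n + 1L)
      tab_s <- tabulate(sel, nbins = n)
      tab_e <- tabulate(sel + kmax, nbins = n + 1L)
      delta[seq_len(n)] <- tab_s
      delta <- delta - tab_e
      keep <- keep | (cumsum(delta)[seq_len(n)] > 0L)
    }
  }
  which(keep) - 1L
}

# distinct-kmer keys for windows of width k starting at `starts` (1-based)
# over small integer codes; packs into integers when possible, else strings
kmer_keys <- function(codes, starts, k) {
  sigma <- max(codes) + 1L
  if (k * log2(sigma) <= 50) {
    key <- numeric(length(starts))
    for (j in 0:(k - 1L)) key <- key * sigma + codes[starts + j]
    key
  } else {
    mat <- vapply(0:(k - 1L), function(j) codes[starts + j], integer(length(starts)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(starts))
    do.call(paste, c(as.data.frame(mat), sep = ","))
  }
}

#' Build the order-kmax kernel of a collection or digested collection
#'
#' @param x A [genome_collection] or [digested_collection()] result.
#' @param kmax Kernel order.
#' @return A `kernelized_text` with elements `codes` (integer vector:
#'   `0` = `$`, `-1` = run-replacement symbol, positive = source symbols),
#'   `text` (character rendering for DNA sources, `#` for runs), `kmax`,
#'   `source_length`, `kept_positions_count`, `num_docs`,
#'   `dollar_positions` (0-based), `source_mode` (`"full"` or `"digest"`),
#'   and for digest sources the `scheme` and `alphabet_map` carried over.
#' @examples
#' col <- build_collection(c(a = "AAAAAA"))
#' katka_kernel(col, 2)$text   # "AA#AA$"
#' @export
katka_kernel <- function(x, kmax) {
  UseMethod("katka_kernel")
}

kernel_from_codes <- function(codes, kmax) {
  n <- length(codes)
  kept0 <- mark_first_last(codes, kmax)
  keep <- logical(n)
  keep[kept0 + 1L] <- TRUE
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- vector("list", length(r$lengths))
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) {
      out[[i]] <- codes[starts[i]:ends[i]]
    } else {
      prev_dollar <- starts[i] > 1L && codes[starts[i] - 1L] == 0L
      next_dollar <- ends[i] < n && codes[ends[i] + 1L] == 0L
      # runs at the very ends of the text also border no kept symbol worth
      # separating; the collection ends in $, so only the left text edge
      # can arise, and a run there is dropped like a $-adjacent run
      edge <- starts[i] == 1L || ends[i] == n
      out[[i]] <- if (prev_dollar || next_dollar || edge) integer() else -1L
    }
  }
  unlist(out)
}

#' @export
katka_kernel.genome_collection <- function(x, kmax) {
  ch <- strsplit(x$text, "", fixed = TRUE)[[1]]
  # same code space as the full-mode index: $=0 here, #=2, A..T = 3..6
  codes <- ifelse(ch == "$", 0L, match(ch, c("$", "#", "A", "C", "G", "T")))
  kc <- kernel_from_codes(codes, kmax)
  txt <- c("#", "$", "#", "#", "A", "C", "G", "T")[kc + 2L]
  structure(list(
    codes = kc, text = paste(txt, collapse = ""), kmax = as.integer(kmax),
    source_length = x$n,
    kept_positions_count = sum(kc > 0L),
    num_docs = x$num_docs, names = x$names,
    dollar_positions = which(kc == 0L) - 1L,
    source_mode = "full"
  ), class = "kernelized_text")
}

#' @export
katka_kernel.digested_collection <- function(x, kmax) {
  kc <- kernel_from_codes(x$codes, kmax)
  structure(list(
    codes = kc, text = NULL, kmax = as.integer(kmax),
    source_length = length(x$codes),
    kept_positions_count = sum(kc > 0L),
    num_docs = x$num_docs, names = x$names,
    dollar_positions = which(kc == 0L) - 1L,
    source_mode = "digest",
    scheme = x$scheme, alphabet_map = x$alphabet_map
  ), class = "kernelized_text")
}

#' @export
print.kernelized_text <- function(x, ...) {
  cat("kernelized_text (order ", x$kmax, ", source mode ", x$source_mode,
      "): ", length(x$codes), " symbols from a source of ", x$source_length,
      " (", sprintf("%.1f%%", 100 * length(x$codes) / x$source_length),
      "), ", x$num_docs, " document(s)\n", sep = "")
  invisible(x)
}

#' Document index of a kernel position
#'
#' Number of `$` symbols strictly before a 0-based kernel position; if a
#' k-mer's first kernel occurrence has i `$`s to its left, the k-mer's
#' first occurrence in the collection is in genome i (0-based), and
#' symmetrically for last occurrences.
#'
#' @param kernel A `kernelized_text`.
#' @param pos 0-based position(s).
#' @return 0-based document indices.
#' @export
kernel_doc_of_position <- function(kernel, pos) {
  doc_of_position(kernel, pos)
}
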