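# Augmented FM-index over any of the four text representations.
#
# Conventions (throughout the package): rows of SA/BWT/LCP and text
# positions are 0-based; intervals [lo, hi] are inclusive. The suffix
# array covers the n suffixes of the $-terminated text, with
# end-of-string comparing smaller than every symbol (the implicit
# end-of-file character); the BWT is cyclic, BWT[i] = text[(SA[i]-1) mod n],
# so e.g. the BWT of "ACAT$" is "T$CAA" and the whole-text interval of a
# 45-character collection is [0..44].
#
# Internal symbol coding: 1 = '$', 2 = '#'/run symbol, 3.. = pattern
# alphabet in ascending order (A<C<G<T, or dense digest codes ascending).
# This realizes the symbol order $ < # < pattern symbols.

PATTERN_BASE <- 2L   # pattern symbols have internal code > PATTERN_BASE

# ---- suffix array by prefix doubling (base order(), radix sort) ----
# codes: integer vector >= 1; end-of-string ranks 0 (smaller than all)
sa_prefix_doubling <- function(codes) {
  n <- length(codes)
  if (n == 1L) return(0L)
  rk <- match(codes, sort(unique(codes)))
  k <- 1L
  repeat {
    key2 <- c(rk[-seq_len(k)], integer(k))     # rank at i+k, 0 past the end
    o <- order(rk, key2, method = "radix")
    r1 <- rk[o]; r2 <- key2[o]
    changed <- c(TRUE, r1[-1] != r1[-n] | r2[-1] != r2[-n])
    newr <- cumsum(changed)
    rk[o] <- newr
    if (newr[n] == n) return(o - 1L)
    k <- k * 2L
  }
}

# LCP of adjacent sorted suffixes by chunked vectorized comparison;
# lcp[1] (row 0) = -1 sentinel so PSV is total
lcp_from_sa <- function(codes, sa0) {
  n <- length(codes)
  lcp <- integer(n)
  lcp[1] <- -1L
  if (n == 1L) return(lcp)
  chunk <- 64L
  for (r in 2:n) {
    a <- sa0[r - 1L]; b <- sa0[r]
    l <- 0L
    repeat {
      la <- min(chunk, n - a - l, n - b - l)
      if (la <= 0L) break
      ca <- codes[(a + l + 1L):(a + l + la)]
      cb <- codes[(b + l + 1L):(b + l + la)]
      neq <- which(ca != cb)
      if (length(neq)) { l <- l + neq[1] - 1L; break }
      l <- l + la
      if (la < chunk) break
    }
    lcp[r] <- l
  }
  lcp
}

# map an indexable object to internal codes + labels
as_internal_text <- function(x) {
  if (inherits(x, "genome_collection")) {
    ch <- strsplit(x$text, "", fixed = TRUE)[[1]]
    codes <- match(ch, c("$", "#", "A", "C", "G", "T"))
    list(codes = codes, labels = c("$", "#", "A", "C", "G", "T"),
         mode = "full", num_docs = x$num_docs, names = x$names,
         params = list(), extra = list())
  } else if (inherits(x, "kernelized_text")) {
    if (x$source_mode == "full") {
      codes <- ifelse(x$codes == 0L, 1L, ifelse(x$codes == -1L, 2L, x$codes))
      list(codes = codes, labels = c("$", "#", "A", "C", "G", "T"),
           mode = "kernel", num_docs = x$num_docs, names = x$names,
           params = list(kmax = x$kmax), extra = list())
    } else {
      nA <- length(x$alphabet_map)
      codes <- ifelse(x$codes == 0L, 1L, ifelse(x$codes == -1L, 2L, x$codes + PATTERN_BASE))
      list(codes = codes, labels = c("$", "#", paste0("m", seq_len(nA))),
           mode = "digest_kernel", num_docs = x$num_docs, names = x$names,
           params = list(kmax = x$kmax, k = x$scheme$k, w = x$scheme$w),
           extra = list(scheme = x$scheme, alphabet_map = x$alphabet_map))
    }
  } else if (inherits(x, "digested_collection")) {
    nA <- length(x$alphabet_map)
    codes <- ifelse(x$codes == 0L, 1L, x$codes + PATTERN_BASE)
    list(codes = codes, labels = c("$", "#", paste0("m", seq_len(nA))),
         mode = "digest", num_docs = x$num_docs, names = x$names,
         params = list(k = x$scheme$k, w = x$scheme$w),
         extra = list(scheme = x$scheme, alphabet_map = x$alphabet_map,
                      minimizer_positions = x$minimizer_positions))
  } else stop("cannot index object of class ", paste(class(x), collapse = "/"))
}

#' Build an augmented FM-index
#'
#' Constructs the suffix array, cyclic BWT with rank/select support
#' (cumulative-occurrence tables), LCP array with a row-0 sentinel of -1,
#' and the `$`-rank vector, over a genome collection or any of its lossy
#' representations. Symbol order is `$ < # < A < C < G < T` (digest modes:
#' `$` < run symbol < dense digest codes ascending), with end-of-string
#' smaller than everything.
#'
#' @param x A [build_collection()] result, a [katka_kernel()] result, or a
#'   [digest_collection()] result.
#' @return An `aug_fm_index` with 0-based `sa`, `bwt` (internal codes),
#'   `lcp`, `Ccum`, occurrence matrix `occ` (`occ[r+1, c]` = count of
#'   symbol `c` in BWT rows `0..r-1`), per-symbol select lists, `dollar_cum`,
#'   mode tag and build parameters.
#' @examples
#' idx <- fm_index(build_collection(c(g = "ACAT")))
#' index_bwt(idx)           # "T$CAA"
#' @export
fm_index <- function(x) {
  it <- as_internal_text(x)
  codes <- as.integer(it$codes)
  n <- length(codes)
  sigma <- length(it$labels)
  sa0 <- sa_prefix_doubling(codes)
  bwt <- codes[((sa0 - 1L) %% n) + 1L]
  lcp <- lcp_from_sa(codes, sa0)
  counts <- tabulate(codes, nbins = sigma)
  Ccum <- c(0L, cumsum(counts))[seq_len(sigma)]   # Ccum[c] = # symbols < c
  occ <- matrix(0L, nrow = n + 1L, ncol = sigma)
  for (c in which(counts > 0L)) occ[, c] <- c(0L, cumsum(bwt == c))
  sel <- lapply(seq_len(sigma), function(c) which(bwt == c) - 1L)
  dollar_cum <- c(0L, cumsum(codes == 1L))[seq_len(n)]  # strictly-before rank
  structure(c(list(codes = codes, n = n, sa = sa0, bwt = bwt, lcp = lcp,
                   Ccum = Ccum, occ = occ, sel = sel, counts = counts,
                   dollar_cum = dollar_cum, labels = it$labels,
                   sigma = sigma, mode = it$mode, num_docs = it$num_docs,
                   names = it$names, params = it$params),
              it$extra),
            class = "aug_fm_index")
}

#' @export
print.aug_fm_index <- function(x, ...) {
  p <- if (length(x$params))
    paste0(" (", paste(names(x$params), unlist(x$params), sep = "=",
                       collapse = ", "), ")") else ""
  cat("aug_fm_index [", x$mode, p, "]: n = ", x$n, ", alphabet ",
      x$sigma, ", ", x$num_docs, " document(s), ",
      format(serialized_size_bytes(x), big.mark = ","), " serialized bytes\n",
      sep = "")
  invisible(x)
}

#' BWT of an index as a string (DNA modes only)
#' @param index An `aug_fm_index` in `full` or `kernel` mode.
#' @return Single string rendering of the BWT.
#' @export
index_bwt <- function(index) {
  if (!index$mode %in% c("full", "kernel"))
    stop("string rendering only available for DNA-alphabet modes")
  paste(index$labels[index$bwt], collapse = "")
}

#' Whole-text suffix array interval
#' @param index An `aug_fm_index`.
#' @return `c(0, n - 1)`.
#' @export
whole_interval <- function(index) c(0L, index$n - 1L)

#' Map a pattern symbol to its internal code
#'
#' DNA modes accept `"A","C","G","T"`; digest modes accept dense digest
#' codes (integers >= 1). Symbols outside the pattern alphabet map to `NA`
#' and never match.
#' @param index An `aug_fm_index`.
#' @param sym Character vector (DNA modes) or integer vector (digest modes).
#' @return Internal codes (`NA` where unmatchable).
#' @export
encode_pattern <- function(index, sym) {
  if (index$mode %in% c("full", "kernel")) {
    if (!is.character(sym)) stop("DNA-mode patterns must be characters")
    ch <- if (length(sym) == 1L && nchar(sym[1]) > 1L)
      strsplit(sym, "", fixed = TRUE)[[1]] else sym
    match(toupper(ch), c("A", "C", "G", "T")) + PATTERN_BASE
  } else {
    out <- as.integer(sym) + PATTERN_BASE
    out[is.na(sym) | sym < 1L | sym > index$sigma - PATTERN_BASE] <- NA_integer_
    out
  }
}

#' One backward-search step
#'
#' Maps the interval of suffixes prefixed by `P` to the interval prefixed
#' by `cP`; an empty interval (`lo > hi`) results when `cP` does not occur.
#' Symbols outside the alphabet give an empty interval, not an error.
#'
#' @param index An `aug_fm_index`.
#' @param iv Inclusive 0-based interval `c(lo, hi)` (possibly empty).
#' @param sym One pattern symbol (see [encode_pattern()]), or an internal
#'   code via `code = TRUE`.
#' @param code If `TRUE`, `sym` is already an internal code.
#' @return The new interval `c(lo, hi)`.
#' @export
backward_step <- function(index, iv, sym, code = FALSE) {
  if (iv[1] > iv[2]) return(iv)
  c <- if (code) sym else encode_pattern(index, sym)
  if (length(c) != 1L || is.na(c) || c < 1L || c > index$sigma)
    return(c(1L, 0L))
  lo <- index$Ccum[c] + index$occ[iv[1] + 1L, c]
  hi <- index$Ccum[c] + index$occ[iv[2] + 2L, c] - 1L
  c(lo, hi)
}

#' Run a full backward search for a pattern
#' @param index An `aug_fm_index`.
#' @param pattern String (DNA modes) or integer code vector (digest modes).
#' @return Inclusive interval `c(lo, hi)`; empty (`lo > hi`) if absent.
#' @export
backward_search <- function(index, pattern) {
  cs <- encode_pattern(index, pattern)
  iv <- whole_interval(index)
  for (c in rev(cs)) {
    iv <- backward_step(index, iv, c, code = TRUE)
    if (iv[1] > iv[2]) return(iv)
  }
  iv
}

#' Smallest and largest text positions in a suffix-array interval
#'
#' Range-minimum and range-maximum over `SA[lo..hi]` — the first and last
#' occurrence positions of the pattern whose interval this is.
#'
#' @param index An `aug_fm_index`.
#' @param iv Non-empty inclusive interval.
#' @return `c(min, max)` of `SA[lo..hi]` (0-based text positions).
#' @export
sa_range_extrema <- function(index, iv) {
  if (iv[1] > iv[2]) stop("empty interval")
  if (iv[1] < 0L || iv[2] >= index$n) stop("interval out of range")
  s <- index$sa[(iv[1]:iv[2]) + 1L]
  c(min(s), max(s))
}

#' Leftmost minimum of an LCP range
#'
#' @param index An `aug_fm_index`.
#' @param i,j 0-based row bounds, `1 <= i <= j <= n - 1`.
#' @return `c(pos, value)`: leftmost row attaining the minimum, and the
#'   minimum LCP value.
#' @export
lcp_range_min <- function(index, i, j) {
  if (i < 1L || j < i || j > index$n - 1L) stop("bad LCP range [", i, ", ", j, "]")
  seg <- index$lcp[(i:j) + 1L]
  p <- which.min(seg)
  c(i + p - 1L, seg[p])
}

#' Previous / next smaller value on the LCP array
#'
#' `psv(t)` is the greatest row `j < t` with `LCP[j] < LCP[t]` (always
#' exists thanks to the row-0 sentinel of -1); `nsv(t)` is the least row
#' `j > t` with `LCP[j] < LCP[t]`, or `n` when none exists. The enclosing
#' interval of the prefix of depth `LCP[t]` is `[psv(t), nsv(t) - 1]`.
#'
#' @param index An `aug_fm_index`.
#' @param t 0-based row, `1 <= t <= n - 1`.
#' @return 0-based row index.
#' @export
psv <- function(index, t) {
  if (t < 1L || t > index$n - 1L) stop("row out of range")
  v <- index$lcp[t + 1L]
  cand <- which(index$lcp[seq_len(t)] < v)
  cand[length(cand)] - 1L
}

#' @rdname psv
#' @export
nsv <- function(index, t) {
  if (t < 1L || t > index$n - 1L) stop("row out of range")
  if (t == index$n - 1L) return(index$n)
  v <- index$lcp[t + 1L]
  after <- index$lcp[(t + 2L):(index$n)]
  hit <- which(after < v)
  if (length(hit) == 0L) index$n else t + hit[1]
}

#' Nearest BWT occurrences of a symbol around an interval
#'
#' The greatest row `p < lo` and least row `q > hi` with `BWT[row] == c`;
#' either may be absent (`NA`).
#'
#' @param index An `aug_fm_index`.
#' @param iv Inclusive interval.
#' @param sym Pattern symbol or internal code (`code = TRUE`).
#' @param code If `TRUE`, `sym` is an internal code.
#' @return `list(prev = , nxt = )`, 0-based rows or `NA`.
#' @export
bwt_nearest_occurrence <- function(index, iv, sym, code = FALSE) {
  c <- if (code) sym else encode_pattern(index, sym)
  if (length(c) != 1L || is.na(c) || c < 1L || c > index$sigma)
    return(list(prev = NA_integer_, nxt = NA_integer_))
  pos <- index$sel[[c]]
  before <- index$occ[iv[1] + 1L, c]
  through <- index$occ[iv[2] + 2L, c]
  list(prev = if (before > 0L) pos[before] else NA_integer_,
       nxt = if (through < length(pos)) pos[through + 1L] else NA_integer_)
}

#' Serialized size of an index, in bytes
#'
#' Size of the on-disk representation written by [write_index()]: one byte
#' per text and BWT symbol (alphabets here never exceed 256), four bytes
#' per suffix-array and LCP entry, one bit per document-boundary bitvector
#' position, plus a fixed metadata allowance. Deterministic and
#' non-decreasing in the text length, so relative comparisons between
#' modes are meaningful (absolute sizes depend on this plain-array layout,
#' not on succinct-structure engineering).
#'
#' @param index An `aug_fm_index`.
#' @return Integer number of bytes.
#' @export
serialized_size_bytes <- function(index) {
  n <- index$n
  meta <- 256L
  as.integer(n + n + 4L * n + 4L * n + ceiling(n / 8) + meta)
}
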