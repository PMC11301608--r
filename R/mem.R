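# MEM tables by right-to-left matching-statistics computation.
#
# Scanning the read right to left we maintain the interval and depth of
# the longest suffix-context currently matched. Prepending the next read
# character is one backward step; when it fails, the match is contracted
# to the longest prefix that IS preceded by that character somewhere in
# the text, located via the nearest BWT occurrences of the character and
# an LCP range-minimum, with PSV/NSV giving the enclosing interval at the
# contracted depth. A MEM starts at read position i when the match there
# cannot be extended left, i.e. MS[i-1] <= MS[i].

#' Contract a match to its longest prefix extendable by a symbol
#'
#' Given the interval `iv` of the current match (which contains no BWT
#' copy of `sym`), finds the longest prefix of the match that is preceded
#' by `sym` somewhere in the text: the nearest BWT occurrences of `sym`
#' before/after the interval bound the candidate depths
#' `min LCP(p+1 .. lo)` and `min LCP(hi+1 .. q)`; the larger wins (ties
#' prefer the earlier, smaller-SA side), and PSV/NSV around the leftmost
#' LCP minimum of the winning side give the enclosing interval. When `sym`
#' does not occur in the BWT at all, the whole-text interval at depth 0 is
#' returned.
#'
#' @param index An `aug_fm_index`.
#' @param iv Non-empty inclusive interval of the current match.
#' @param depth Current match depth (not used by the computation; the
#'   contracted depth is derived from the LCP array alone).
#' @param sym Pattern symbol, or internal code with `code = TRUE`.
#' @param code If `TRUE`, `sym` is an internal code.
#' @return `list(iv = c(lo, hi), depth = )` with
#'   `backward_step(index, iv, sym)` guaranteed non-empty whenever a
#'   candidate existed.
#' @export
contract_to_extendable <- function(index, iv, depth, sym, code = FALSE) {
  c <- if (code) sym else encode_pattern(index, sym)
  whole <- list(iv = whole_interval(index), depth = 0L)
  if (length(c) != 1L || is.na(c) || c < 1L || c > index$sigma) return(whole)
  occ <- bwt_nearest_occurrence(index, iv, c, code = TRUE)
  lp <- if (!is.na(occ$prev)) lcp_range_min(index, occ$prev + 1L, iv[1]) else NULL
  lq <- if (!is.na(occ$nxt))  lcp_range_min(index, iv[2] + 1L, occ$nxt) else NULL
  if (is.null(lp) && is.null(lq)) return(whole)
  use_p <- !is.null(lp) && (is.null(lq) || lp[2] >= lq[2])
  t <- if (use_p) lp[1] else lq[1]
  d <- if (use_p) lp[2] else lq[2]
  if (d <= 0L) return(whole)
  list(iv = c(psv(index, t), nsv(index, t) - 1L), depth = d)
}

#' Matching statistics of a read against an index
#'
#' `MS[i]` is the length of the longest prefix of `read[i..]` occurring in
#' the indexed text; computed right to left with one backward step per
#' character plus at most one contraction per failed step. Read symbols
#' outside the pattern alphabet (including digest k-mers foreign to the
#' collection) yield `MS[i] = 0` and reset the match.
#'
#' @param index An `aug_fm_index`.
#' @param read String over `{A,C,G,T}` (DNA modes) or integer digest codes
#'   (digest modes, see [digest_pattern()]).
#' @return `list(ms = , lo = , hi = )`, integer vectors with one entry per
#'   read position; `lo`/`hi` hold the SA interval of the match starting
#'   at each position (`NA` where `ms` is 0).
#' @export
matching_statistics <- function(index, read) {
  cs <- encode_pattern(index, read)
  m <- length(cs)
  ms <- integer(m); los <- rep(NA_integer_, m); his <- rep(NA_integer_, m)
  whole <- whole_interval(index)
  iv <- whole; d <- 0L
  for (i in rev(seq_len(m))) {
    c <- cs[i]
    if (is.na(c)) { iv <- whole; d <- 0L; next }
    step <- backward_step(index, iv, c, code = TRUE)
    if (step[1] > step[2] && d > 0L) {
      ctr <- contract_to_extendable(index, iv, d, c, code = TRUE)
      iv <- ctr$iv; d <- ctr$depth
      step <- backward_step(index, iv, c, code = TRUE)
    }
    if (step[1] > step[2]) {
      iv <- whole; d <- 0L
    } else {
      iv <- step; d <- d + 1L
      ms[i] <- d; los[i] <- iv[1]; his[i] <- iv[2]
    }
  }
  list(ms = ms, lo = los, hi = his)
}

#' MEM table of a read
#'
#' Computes matching statistics and emits the maximal exact matches: read
#' positions where the match cannot be extended left (`MS[i-1] <= MS[i]`)
#' and has length at least `min_mem_length`. Each MEM is mapped through
#' SA range-extrema to its first/last occurrence positions and through the
#' `$`-rank to its first/last documents. In digest modes positions and
#' lengths are in digest characters; when the index carries per-genome
#' minimizer positions, approximate source offsets of the first occurrence
#' are reported as well.
#'
#' @param index An `aug_fm_index`.
#' @param read String (DNA modes) or integer digest codes (digest modes).
#' @param min_mem_length Minimum MEM length to report (default 1; length-1
#'   MEMs are noise at scale but the definition admits them).
#' @param read_id Optional identifier copied into the table.
#' @return A data frame of class `mem_table`: `read_id`, `read_start`
#'   (0-based), `length`, `lo`, `hi` (SA interval), `first_pos`,
#'   `last_pos` (0-based text offsets), `first_doc`, `last_doc` (0-based),
#'   `mode`.
#' @examples
#' idx <- fm_index(build_collection(c(g = "ACAT")))
#' mem_table(idx, "CATT")
#' @export
mem_table <- function(index, read, min_mem_length = 1L, read_id = NA_character_) {
  st <- matching_statistics(index, read)
  ms <- st$ms
  starts <- which(ms >= max(1L, min_mem_length) &
                    (seq_along(ms) == 1L | c(0L, ms[-length(ms)]) <= ms))
  rows <- lapply(starts, function(i) {
    ext <- sa_range_extrema(index, c(st$lo[i], st$hi[i]))
    data.frame(read_id = read_id, read_start = i - 1L, length = ms[i],
               lo = st$lo[i], hi = st$hi[i],
               first_pos = ext[1], last_pos = ext[2],
               first_doc = doc_of_position(index, ext[1]),
               last_doc = doc_of_position(index, ext[2]),
               mode = index$mode, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(), read_start = integer(),
               length = integer(), lo = integer(), hi = integer(),
               first_pos = integer(), last_pos = integer(),
               first_doc = integer(), last_doc = integer(),
               mode = character(), stringsAsFactors = FALSE)
  if (!is.null(index$minimizer_positions) && nrow(out)) {
    out$source_first <- vapply(seq_len(nrow(out)), function(r) {
      digest_pos_to_source(index, out$first_pos[r], out$first_doc[r])
    }, integer(1))
  }
  class(out) <- c("mem_table", class(out))
  out
}

# approximate source offset of a digest-text position (digest mode only)
digest_pos_to_source <- function(index, pos, doc) {
  blocks <- index$minimizer_positions
  block_start <- sum(lengths(blocks[seq_len(doc)])) + doc  # + doc for the $s
  off <- pos - block_start + 1L
  mp <- blocks[[doc + 1L]]
  if (off >= 1L && off <= length(mp)) as.integer(mp[off]) else NA_integer_
}

#' Brute-force MEM table (reference semantics)
#'
#' Quadratic-time enumeration of all maximal exactly matching read
#' substrings against a plain text scan, with min/max occurrence
#' positions; the independent oracle for the FM-index MEM machinery.
#'
#' @param text Collection text string (with `$` separators), or an integer
#'   code vector (`0` = `$`, `-1` = run symbol, positive = symbols) for
#'   digest-mode texts.
#' @param read String over `{A,C,G,T}`, or integer digest codes (`NA`
#'   allowed, never matches).
#' @param min_mem_length Minimum MEM length to report.
#' @return A data frame with columns `read_start`, `length`, `first_pos`,
#'   `last_pos`, `first_doc`, `last_doc` (all 0-based).
#' @export
brute_force_mem_table <- function(text, read, min_mem_length = 1L) {
  if (is.character(text)) {
    ch <- strsplit(text, "", fixed = TRUE)[[1]]
    tcodes <- ifelse(ch == "$", 0L, ifelse(ch == "#", -1L,
                     match(ch, c("A", "C", "G", "T")) + 1L))
  } else tcodes <- as.integer(text)
  if (is.character(read)) {
    rcodes <- match(strsplit(toupper(read), "", fixed = TRUE)[[1]],
                    c("A", "C", "G", "T")) + 1L
  } else rcodes <- as.integer(read)
  n <- length(tcodes); m <- length(rcodes)
  dollars0 <- which(tcodes == 0L) - 1L
  ms <- integer(m); fp <- rep(NA_integer_, m); lp <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    if (is.na(rcodes[i])) next
    occ <- which(tcodes == rcodes[i])
    l <- 1L
    while (length(occ)) {
      ms[i] <- l; fp[i] <- occ[1] - 1L; lp[i] <- occ[length(occ)] - 1L
      if (i + l > m || is.na(rcodes[i + l])) break
      occ <- occ[occ + l <= n]
      occ <- occ[!is.na(tcodes[occ + l]) & tcodes[occ + l] == rcodes[i + l]]
      l <- l + 1L
    }
  }
  starts <- which(ms >= max(1L, min_mem_length) &
                    (seq_len(m) == 1L | c(0L, ms[-m]) <= ms))
  data.frame(read_start = starts - 1L, length = ms[starts],
             first_pos = fp[starts], last_pos = lp[starts],
             first_doc = if (length(starts))
               findInterval(fp[starts], dollars0 + 0.5) else integer(),
             last_doc = if (length(starts))
               findInterval(lp[starts], dollars0 + 0.5) else integer())
}
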