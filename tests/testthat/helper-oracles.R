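# Independent naive oracles: everything here works by sorting explicit
# suffix strings or scanning the text directly, never through the
# package's FM-index machinery.

# map internal codes (1..sigma) to bytes that sort in code order under
# C-locale radix sorting; end-of-string (shorter prefix first) is the
# radix sorter's native behaviour and realizes the implicit EOF symbol
codes_to_sortable <- function(codes) {
  vapply(seq_along(codes), function(i)
    intToUtf8(48L + codes[i:length(codes)]), character(1))
}

text_to_codes <- function(text) {
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  out <- match(ch, c("$", "#", "A", "C", "G", "T"))
  stopifnot(!anyNA(out))
  out
}

naive_sa <- function(codes) {
  order(codes_to_sortable(codes), method = "radix") - 1L
}

naive_bwt <- function(codes, sa0 = naive_sa(codes)) {
  codes[((sa0 - 1L) %% length(codes)) + 1L]
}

naive_lcp <- function(codes, sa0 = naive_sa(codes)) {
  n <- length(codes)
  lcp <- integer(n)
  lcp[1] <- -1L
  for (r in seq_len(n)[-1]) {
    a <- sa0[r - 1L]; b <- sa0[r]; l <- 0L
    while (a + l < n && b + l < n && codes[a + l + 1L] == codes[b + l + 1L])
      l <- l + 1L
    lcp[r] <- l
  }
  lcp
}

# 0-based start positions of a pattern (code vector; NA never matches)
naive_occurrences <- function(tcodes, pcodes) {
  n <- length(tcodes); m <- length(pcodes)
  if (m == 0L || anyNA(pcodes) || m > n) return(integer(0))
  hits <- integer(0)
  for (s in 0:(n - m)) {
    if (all(tcodes[(s + 1L):(s + m)] == pcodes)) hits <- c(hits, s)
  }
  hits
}

naive_psv <- function(lcp, t) {   # 0-based rows; lcp[1] = -1 sentinel
  j <- t - 1L
  while (lcp[j + 1L] >= lcp[t + 1L]) j <- j - 1L
  j
}

naive_nsv <- function(lcp, t) {
  n <- length(lcp)
  j <- t + 1L
  while (j <= n - 1L && lcp[j + 1L] >= lcp[t + 1L]) j <- j + 1L
  j
}

naive_doc_of <- function(text, pos) {   # count of $ strictly before pos
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  vapply(pos, function(p) sum(ch[seq_len(p)] == "$"), integer(1))
}

# definitional kernel kept-set: explicit occurrence scan per distinct kmer
naive_kernel_kept <- function(text, kmax) {
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(ch)
  keep <- ch == "$"
  bnd <- c(0L, which(ch == "$"))
  for (d in seq_len(length(bnd) - 1L)) {     # short genomes verbatim
    lo <- bnd[d] + 1L; hi <- bnd[d + 1L] - 1L
    if (hi >= lo && hi - lo + 1L < kmax) keep[lo:hi] <- TRUE
  }
  if (n >= kmax) {
    kmers <- vapply(seq_len(n - kmax + 1L), function(s)
      paste(ch[s:(s + kmax - 1L)], collapse = ""), character(1))
    ok <- !grepl("$", kmers, fixed = TRUE)
    for (km in unique(kmers[ok])) {
      occ <- which(kmers == km & ok)
      for (s in c(occ[1], occ[length(occ)]))
        keep[s:(s + kmax - 1L)] <- TRUE
    }
  }
  which(keep) - 1L
}

# $-free (and #-blocked) k-mer set of a text, with first/last 0-based
# occurrence positions
naive_kmer_sets <- function(text, k) {
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < k) return(data.frame(kmer = character(), first = integer(),
                               last = integer()))
  kmers <- vapply(seq_len(n - k + 1L), function(s)
    paste(ch[s:(s + k - 1L)], collapse = ""), character(1))
  ok <- !grepl("[$#]", kmers)
  kk <- kmers[ok]; pos <- which(ok) - 1L
  if (!length(kk)) return(data.frame(kmer = character(), first = integer(),
                                     last = integer()))
  first <- tapply(pos, kk, min)
  last <- tapply(pos, kk, max)
  data.frame(kmer = names(first), first = as.integer(first),
             last = as.integer(last), row.names = NULL)
}

# brute-force minimizer selection straight from the definition
naive_select_minimizers <- function(h, w) {
  nk <- length(h)
  if (nk == 0L) return(integer(0))
  sel <- logical(nk)
  if (nk <= w) {
    sel[which.min(h)] <- TRUE
  } else {
    for (i in seq_len(nk - w + 1L)) {
      sel[i - 1L + which.min(h[i:(i + w - 1L)])] <- TRUE
    }
  }
  which(sel) - 1L
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_collection <- function(max_docs = 4L, len_range = c(20L, 60L)) {
  nd <- sample.int(max_docs, 1L)
  seqs <- vapply(seq_len(nd), function(i)
    random_dna(sample(len_range[1]:len_range[2], 1L)), character(1))
  names(seqs) <- paste0("g", seq_len(nd) - 1L)
  build_collection(seqs)
}

# mutate a string at `k` random positions (substitutions only)
mutate_string <- function(s, k) {
  if (k == 0L) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- sample.int(length(ch), min(k, length(ch)))
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste(ch, collapse = "")
}

# ancestor chain of a node up to the root (inclusive)
ancestor_set <- function(tree, a) {
  out <- a
  while (tree$parent[[a]] != a) { a <- tree$parent[[a]]; out <- c(out, a) }
  out
}
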