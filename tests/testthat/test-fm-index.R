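test_that("index of ACAT$ matches the hand-checked suffix array and BWT", {
  idx <- fm_index(build_collection(c(g = "ACAT")))
  # suffixes sorted with end-of-string smallest: $, ACAT$, AT$, CAT$, T$
  expect_equal(idx$sa, c(4L, 0L, 2L, 1L, 3L))
  expect_equal(index_bwt(idx), "T$CAA")
  expect_equal(idx$lcp, c(-1L, 0L, 1L, 0L, 0L))
  expect_equal(whole_interval(idx), c(0L, 4L))
  # single-character genome
  idx1 <- fm_index(build_collection(c(g = "A")))
  expect_equal(idx1$sa, c(1L, 0L))
})

test_that("backward search walks match naive substring matching", {
  idx <- fm_index(build_collection(c(g = "ACAT")))
  iv <- backward_step(idx, whole_interval(idx), "T")
  iv <- backward_step(idx, iv, "A")
  expect_equal(iv, c(2L, 2L))          # the suffix AT$
  expect_equal(sa_range_extrema(idx, iv), c(2L, 2L))
  # absent symbol: empty interval, not an exception
  empty <- backward_step(idx, whole_interval(idx), "Z")
  expect_true(empty[1] > empty[2])
  expect_true(diff(backward_search(idx, "GT")) < 0)
})

test_that("SA/BWT/LCP and the query operations agree with naive oracles", {
  set.seed(41)
  for (rep in 1:60) {
    col <- random_collection(4L, c(5L, 50L))
    codes <- text_to_codes(col$text)
    idx <- fm_index(col)
    sa0 <- naive_sa(codes)
    expect_equal(idx$sa, sa0)
    expect_equal(idx$bwt, naive_bwt(codes, sa0))
    lcp <- naive_lcp(codes, sa0)
    expect_equal(idx$lcp, lcp)
    n <- length(codes)
    for (t in sample(seq_len(n - 1L), min(8, n - 1L))) {
      expect_equal(psv(idx, t), naive_psv(lcp, t))
      expect_equal(nsv(idx, t), naive_nsv(lcp, t))
    }
    i <- sample(seq_len(n - 1L), 1); j <- i + sample.int(n - i, 1) - 1L
    rm_ <- lcp_range_min(idx, i, j)
    seg <- lcp[(i:j) + 1L]
    expect_equal(rm_[2], min(seg))
    expect_equal(rm_[1], i + which.min(seg) - 1L)   # leftmost tie
    # backward search vs naive occurrence scan on sampled patterns
    for (p in 1:10) {
      plen <- sample.int(6, 1)
      pat <- if (p <= 7 && n - plen > 1) {
        s <- sample.int(n - plen, 1)
        substr(col$text, s, s + plen - 1L)
      } else random_dna(plen)
      if (grepl("[$#]", pat)) next
      iv <- backward_search(idx, pat)
      occ <- naive_occurrences(codes, text_to_codes(pat))
      expect_equal(max(0L, iv[2] - iv[1] + 1L), length(occ))
      if (length(occ)) {
        expect_setequal(idx$sa[(iv[1]:iv[2]) + 1L], occ)
        expect_equal(sa_range_extrema(idx, iv), range(occ))
      }
    }
  }
})

test_that("LF steps over whole sequences reproduce their occurrence sets", {
  set.seed(42)
  # single genome: stepping the entire text (trailing $ included) ends at
  # the unique rotation start
  for (rep in 1:10) {
    col <- random_collection(1L, c(10L, 30L))
    idx <- fm_index(col)
    codes <- text_to_codes(col$text)
    iv <- whole_interval(idx)
    for (c in rev(codes)) iv <- backward_step(idx, iv, c, code = TRUE)
    expect_equal(iv[1], iv[2])
    expect_equal(idx$sa[iv[1] + 1L], 0L)
  }
  # multiple genomes: stepping each genome character by character lands on
  # exactly its occurrence set ($ never occurs in query patterns)
  for (rep in 1:10) {
    col <- random_collection(3L, c(10L, 30L))
    idx <- fm_index(col)
    codes <- text_to_codes(col$text)
    for (g in collection_sequences(col)) {
      iv <- whole_interval(idx)
      for (c in rev(text_to_codes(g))) iv <- backward_step(idx, iv, c, code = TRUE)
      occ <- naive_occurrences(codes, text_to_codes(g))
      expect_setequal(idx$sa[(iv[1]:iv[2]) + 1L], occ)
    }
  }
})

test_that("bwt_nearest_occurrence finds flanking BWT copies", {
  idx <- fm_index(build_collection(c(g = "ACAT")))   # BWT T$CAA
  occ <- bwt_nearest_occurrence(idx, c(0L, 0L), "A")
  expect_true(is.na(occ$prev))
  expect_equal(occ$nxt, 3L)
  occ2 <- bwt_nearest_occurrence(idx, c(0L, 2L), "A")
  expect_true(is.na(occ2$prev))
  expect_equal(occ2$nxt, 3L)
  occ4 <- bwt_nearest_occurrence(idx, c(4L, 4L), "A")
  expect_equal(occ4$prev, 3L)
  expect_true(is.na(occ4$nxt))
  occ3 <- bwt_nearest_occurrence(idx, c(2L, 3L), "Z")
  expect_true(is.na(occ3$prev) && is.na(occ3$nxt))
})

test_that("psv/nsv recover the enclosing interval of a prefix depth", {
  idx <- fm_index(build_collection(c(g = "ACAT")))   # LCP -1 0 1 0 0
  expect_equal(psv(idx, 2L), 1L)
  expect_equal(nsv(idx, 2L), 3L)                     # interval [1,2]: suffixes A...
  expect_equal(lcp_range_min(idx, 2L, 2L), c(2L, 1L))
  expect_equal(psv(idx, 4L), 0L)                     # LCP 0 rows stop at sentinel
  expect_error(psv(idx, 0L), "range")
  expect_error(nsv(idx, 99L), "range")
})

test_that("serialized sizes are positive, monotone, and smaller in digest mode", {
  set.seed(43)
  seqs <- stats::setNames(vapply(1:6, function(i) random_dna(120), character(1)),
                          paste0("g", 0:5))
  idx_small <- fm_index(build_collection(seqs[1:3]))
  idx_big <- fm_index(build_collection(seqs))
  expect_gt(serialized_size_bytes(idx_small), 0L)
  expect_gte(serialized_size_bytes(idx_big), serialized_size_bytes(idx_small))
  col <- build_collection(seqs)
  for (w in c(5L, 10L)) {
    idx_dig <- fm_index(digest_collection(col, digest_scheme(w = w)))
    expect_lt(serialized_size_bytes(idx_dig), serialized_size_bytes(idx_big))
  }
})

test_that("indexes round-trip through the on-disk layout", {
  set.seed(44)
  col <- random_collection(3L, c(20L, 50L))
  dir <- withr::local_tempdir()
  for (rep_obj in list(col, katka_kernel(col, 3),
                       digest_collection(col, digest_scheme(k = 3, w = 3)))) {
    idx <- fm_index(rep_obj)
    d <- file.path(dir, idx$mode)
    write_index(idx, d)
    back <- read_index(d)
    for (f in c("codes", "sa", "lcp", "bwt", "n", "sigma", "mode", "num_docs"))
      expect_equal(back[[f]], idx[[f]], info = f)
    expect_equal(back$occ, idx$occ)
    r <- "ACGT"
    q <- if (idx$mode == "digest") as.integer(digest_pattern(r, idx)) else r
    expect_equal(mem_table(back, q), mem_table(idx, q))
  }
})

test_that("indexes over digest-mode texts order symbols $ < run < codes", {
  col <- build_collection(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT"))
  dig <- digest_collection(col, digest_scheme(k = 3, w = 2))
  idx <- fm_index(katka_kernel(dig, 1))
  expect_equal(idx$labels[1:2], c("$", "#"))
  expect_equal(idx$mode, "digest_kernel")
})
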