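test_that("matching statistics match per-position longest matches", {
  idx <- fm_index(build_collection(c(g = "ACAT")))
  expect_equal(matching_statistics(idx, "CATT")$ms, c(3L, 2L, 1L, 1L))
  # all symbols absent
  idx2 <- fm_index(build_collection(c(g = "AAAA")))
  expect_equal(matching_statistics(idx2, "CGT")$ms, c(0L, 0L, 0L))
})

test_that("MEM emission matches the hand example and the oracle", {
  idx <- fm_index(build_collection(c(g = "ACAT")))
  tab <- mem_table(idx, "CATT")
  expect_equal(tab$read_start, c(0L, 3L))
  expect_equal(tab$length, c(3L, 1L))
  expect_equal(tab$first_doc, c(0L, 0L))
  expect_equal(tab$last_doc, c(0L, 0L))
  oracle <- brute_force_mem_table("ACAT$", "CATT")
  expect_equal(tab$first_pos, oracle$first_pos)
  expect_equal(tab$last_pos, oracle$last_pos)
  # read with no matching symbol: empty table
  expect_equal(nrow(mem_table(idx, "GGG")), 0L)
  # min_mem_length filters short MEMs
  expect_equal(mem_table(idx, "CATT", min_mem_length = 2)$length, 3L)
})

test_that("contraction finds the longest extendable prefix", {
  # matching "CAT" in ACGCAT$ and prepending A fails (no ACAT); the longest
  # prefix of CAT preceded by A is "C" (the AC at position 0), so the match
  # contracts to depth 1 and the backward step then succeeds
  idx <- fm_index(build_collection(c(g = "ACGCAT")))
  iv <- backward_search(idx, "CAT")
  expect_true(diff(backward_step(idx, iv, "A")) < 0)   # direct step fails
  ctr <- contract_to_extendable(idx, iv, 3L, "A")
  expect_equal(ctr$depth, 1L)
  stepped <- backward_step(idx, ctr$iv, "A")
  expect_true(stepped[1] <= stepped[2])
  expect_equal(sa_range_extrema(idx, stepped), c(0L, 0L))  # AC only at 0
  # symbol absent from the whole BWT: whole interval at depth 0
  idx2 <- fm_index(build_collection(c(g = "ACAT")))
  iv2 <- backward_search(idx2, "AT")
  ctr0 <- contract_to_extendable(idx2, iv2, 2L, "G")
  expect_equal(ctr0$iv, whole_interval(idx2))
  expect_equal(ctr0$depth, 0L)
})

test_that("FM MEM tables equal brute force on random collections and reads", {
  set.seed(51)
  for (rep in 1:100) {
    col <- random_collection(4L, c(10L, 60L))
    idx <- fm_index(col)
    src <- collection_sequences(col)[[sample.int(col$num_docs, 1)]]
    rl <- min(nchar(src), sample(5:30, 1))
    s0 <- sample.int(nchar(src) - rl + 1L, 1)
    read <- mutate_string(substr(src, s0, s0 + rl - 1L), sample(0:3, 1))
    got <- mem_table(idx, read)
    want <- brute_force_mem_table(col$text, read)
    expect_equal(got$read_start, want$read_start)
    expect_equal(got$length, want$length)
    expect_equal(got$first_pos, want$first_pos)
    expect_equal(got$last_pos, want$last_pos)
    expect_equal(got$first_doc, want$first_doc)
    expect_equal(got$last_doc, want$last_doc)
  }
})

test_that("digest-mode MEM tables equal brute force on the digest text", {
  set.seed(52)
  sc <- digest_scheme(k = 3, w = 4)
  for (rep in 1:60) {
    col <- random_collection(4L, c(15L, 60L))
    dig <- digest_collection(col, sc)
    idx <- fm_index(dig)
    src <- collection_sequences(col)[[sample.int(col$num_docs, 1)]]
    rl <- min(nchar(src), sample(10:30, 1))
    s0 <- sample.int(nchar(src) - rl + 1L, 1)
    read <- mutate_string(substr(src, s0, s0 + rl - 1L), sample(0:3, 1))
    q <- as.integer(digest_pattern(read, dig))
    got <- mem_table(idx, q)
    want <- brute_force_mem_table(dig$codes, q)
    expect_equal(got$read_start, want$read_start)
    expect_equal(got$length, want$length)
    expect_equal(got$first_doc, want$first_doc)
    expect_equal(got$last_doc, want$last_doc)
  }
})

test_that("no emitted MEM is contained in another at the same alignment", {
  set.seed(53)
  for (rep in 1:30) {
    col <- random_collection()
    idx <- fm_index(col)
    read <- mutate_string(random_dna(25), 0L)
    tab <- mem_table(idx, read)
    if (nrow(tab) < 2) next
    s <- tab$read_start; e <- tab$read_start + tab$length - 1L
    for (a in seq_len(nrow(tab))) {
      inside <- s >= s[a] & e <= e[a] & seq_len(nrow(tab)) != a
      expect_false(any(inside))
    }
  }
})

test_that("kernel-mode first/last docs equal full-mode for short patterns", {
  set.seed(54)
  for (rep in 1:25) {
    col <- random_collection()
    kmax <- sample(3:5, 1)
    idx_full <- fm_index(col)
    idx_ker <- fm_index(katka_kernel(col, kmax))
    src <- collection_sequences(col)[[sample.int(col$num_docs, 1)]]
    for (p in 1:5) {
      plen <- sample.int(kmax, 1)
      if (nchar(src) < plen) next
      s0 <- sample.int(nchar(src) - plen + 1L, 1)
      pat <- substr(src, s0, s0 + plen - 1L)
      ivf <- backward_search(idx_full, pat)
      ivk <- backward_search(idx_ker, pat)
      expect_true(ivf[1] <= ivf[2] && ivk[1] <= ivk[2])
      exf <- sa_range_extrema(idx_full, ivf)
      exk <- sa_range_extrema(idx_ker, ivk)
      expect_equal(doc_of_position(idx_ker, exk),
                   doc_of_position(idx_full, exf))
    }
  }
})

test_that("digest-mode tables report approximate source offsets", {
  sc <- digest_scheme(k = 3, w = 3)
  col <- build_collection(c(a = "ACGTACGTACGTACGT", b = "TTGCATTGCATTGCAT"))
  dig <- digest_collection(col, sc)
  idx <- fm_index(dig)
  q <- as.integer(digest_pattern("ACGTACGTACGT", dig))
  tab <- mem_table(idx, q)
  expect_true("source_first" %in% names(tab))
  expect_true(all(tab$source_first[tab$first_doc == 0L] <
                    nchar("ACGTACGTACGTACGT")))
})

test_that("duplicate read substrings give one MEM per position", {
  idx <- fm_index(build_collection(c(g = "ACGT")))
  tab <- mem_table(idx, "ACGACG")
  expect_equal(sum(tab$length == 3L), 2L)
  expect_equal(anyDuplicated(tab[, c("read_start", "length")]), 0L)
})
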