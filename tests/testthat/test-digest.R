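test_that("the affine hash evaluates the printed formula", {
  sc <- digest_scheme()
  expect_equal(hash_kmer("AAA", sc), 3937)          # x = 0
  expect_equal(hash_kmer("ACG", sc), 1475)          # x = 6
  expect_equal(hash_kmer("TTT", sc), 4675)          # x = 63
  expect_error(hash_kmer("ACN", sc), "A,C,G,T")
  expect_error(hash_kmer("AC", sc), "length")
})

test_that("the default hash is injective on 3-mers and the scheme validates", {
  sc <- digest_scheme()
  kmers <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                             c("A","C","G","T")), 1, paste, collapse = "")
  expect_equal(length(unique(hash_kmer(kmers, sc))), 64L)
  expect_error(digest_scheme(hash_a = 4, hash_m = 64), "injective")
})

test_that("select_minimizers applies the leftmost-window-minimum rule", {
  expect_equal(select_minimizers("ACGTACGT", digest_scheme(k = 3, w = 2)),
               c(0L, 2L, 4L))
  # exactly one k-mer: single window, single candidate
  expect_equal(select_minimizers("ACG", digest_scheme(k = 3, w = 10)), 0L)
  # equal hashes: only the leftmost min of the single full window
  expect_equal(select_minimizers("AAAA", digest_scheme(k = 3, w = 2)), 0L)
  expect_equal(select_minimizers("AC", digest_scheme(k = 3, w = 2)), integer(0))
})

test_that("selection matches the brute-force window scan on random strings", {
  set.seed(31)
  sc <- digest_scheme()
  for (rep in 1:100) {
    s <- random_dna(sample(3:120, 1))
    h <- (sc$hash_a * memtax:::kmer_values(s, sc$k) + sc$hash_b) %% sc$hash_m
    expect_equal(select_minimizers(s, sc), naive_select_minimizers(h, sc$w))
  }
})

test_that("every window of w k-mer positions contains a selected position", {
  set.seed(32)
  sc <- digest_scheme()
  for (rep in 1:500) {
    s <- random_dna(100)
    pos <- select_minimizers(s, sc)
    expect_gte(length(pos), 1L)
    expect_true(all(diff(pos) <= sc$w))
    expect_lte(pos[1], sc$w - 1L)                       # first window covered
    nk <- 100 - sc$k + 1L
    expect_gte(pos[length(pos)], nk - sc$w)             # last window covered
  }
})

test_that("digests are deterministic and collection digests concatenate per genome", {
  sc <- digest_scheme(k = 3, w = 2)
  col <- build_collection(c(a = "ACGTACGT", b = "ACGTACGT"))
  dig1 <- digest_collection(col, sc)
  dig2 <- digest_collection(col, sc)
  expect_identical(dig1$codes, dig2$codes)
  # two identical genomes: D $ D $ with D of length 3
  expect_equal(sum(dig1$codes == 0L), 2L)
  blocks <- split(dig1$codes, cumsum(c(1, head(dig1$codes, -1) == 0L)))
  expect_equal(unname(lengths(blocks)), c(4L, 4L))      # 3 codes + $
  expect_identical(blocks[[1]], blocks[[2]])
  d <- digest_sequence("ACGTACGT", sc)
  expect_equal(length(d), 3L)
  expect_equal(d[1], d[3])                              # ACG ... ACG
  expect_lte(length(dig1$alphabet_map), 64L)
})

test_that("genomes shorter than k contribute an empty digest block", {
  sc <- digest_scheme()
  col <- build_collection(c(tiny = "AC"))
  dig <- digest_collection(col, sc)
  expect_equal(dig$codes, 0L)                           # just the $
  expect_equal(length(digest_pattern("AC", dig)), 0L)
})

test_that("a full-genome pattern digests to exactly its genome's block", {
  set.seed(33)
  sc <- digest_scheme(k = 3, w = 5)
  for (rep in 1:20) {
    col <- random_collection(3L, c(20L, 60L))
    dig <- digest_collection(col, sc)
    seqs <- collection_sequences(col)
    blocks <- split(dig$codes, cumsum(c(1, head(dig$codes, -1) == 0L)))
    for (d in seq_along(seqs)) {
      pat <- digest_pattern(seqs[[d]], dig)
      blk <- blocks[[d]]
      expect_identical(as.integer(pat), blk[blk != 0L])
      expect_false(anyNA(pat))
    }
  }
})

test_that("digest characters decode to k-mers present at their recorded offsets", {
  set.seed(34)
  sc <- digest_scheme()
  col <- random_collection(3L, c(30L, 80L))
  dig <- digest_collection(col, sc)
  seqs <- collection_sequences(col)
  for (d in seq_along(seqs)) {
    mp <- dig$minimizer_positions[[d]]
    x <- memtax:::kmer_values(seqs[[d]], sc$k)
    blocks <- split(dig$codes, cumsum(c(1, head(dig$codes, -1) == 0L)))
    codes <- blocks[[d]][blocks[[d]] != 0L]
    expect_equal(dig$alphabet_map[codes], unname(x[mp + 1L]))
  }
})

test_that("printable rendering round-trips and stays within ASCII 37..100", {
  codes <- c(1L, 25L, 64L)
  txt <- render_digest(codes)
  expect_equal(decode_digest_rendering(txt), codes)
  expect_true(all(utf8ToInt(txt) >= 37 & utf8ToInt(txt) <= 100))
})
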