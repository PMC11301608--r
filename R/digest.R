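# Minimizer digests (winnowing): slide a window of w consecutive k-mers
# over a sequence, select the position of the leftmost minimum hash in
# each window, and keep the selected k-mers in position order. The default
# hash is the affine map h(x) = (2544 x + 3937) mod 8863 on the base-4
# value x of the k-mer, with k = 3 and w = 10.

#' Construct a minimizer digest scheme
#'
#' @param k Minimizer width (k-mer length).
#' @param w Window size, in number of consecutive k-mer positions.
#' @param hash_a,hash_b,hash_m Parameters of the affine hash
#'   `h(x) = (hash_a * x + hash_b) mod hash_m` applied to the base-4 value
#'   `x` of a k-mer (A=0, C=1, G=2, T=3).
#' @param display_base Smallest ASCII value used by the printable rendering
#'   of digest symbols (see [render_digest()]).
#' @return A `digest_scheme` object. Construction checks that the hash is
#'   injective on k-mers whenever `4^k <= hash_m` (which requires
#'   `gcd(hash_a, hash_m) == 1`), so the hash order is a permutation of the
#'   k-mer space and selection is collision-free.
#' @examples
#' sc <- digest_scheme()            # k = 3, w = 10, h(x) = (2544x+3937) mod 8863
#' hash_kmer("AAA", sc)             # 3937
#' @export
digest_scheme <- function(k = 3L, w = 10L, hash_a = 2544L, hash_b = 3937L,
                          hash_m = 8863L, display_base = 37L) {
  stopifnot(k >= 1, w >= 1, hash_m > 0, hash_a >= 0, hash_b >= 0)
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  if (4^k <= hash_m) {
    if (gcd(hash_a %% hash_m, hash_m) != 1)
      stop("hash is not injective on ", k, "-mers: gcd(hash_a, hash_m) != 1")
  }
  if (4^k * hash_a + hash_b >= 2^53)
    stop("hash parameters overflow double precision for k = ", k)
  structure(list(k = as.integer(k), w = as.integer(w),
                 hash_a = hash_a, hash_b = hash_b, hash_m = hash_m,
                 display_base = as.integer(display_base)),
            class = "digest_scheme")
}

#' @export
print.digest_scheme <- function(x, ...) {
  cat("digest_scheme: k = ", x$k, ", w = ", x$w, ", h(x) = (", x$hash_a,
      " x + ", x$hash_b, ") mod ", x$hash_m, "\n", sep = "")
  invisible(x)
}

# base-4 values of all k-mers of an ACGT sequence; NA where any base unknown
kmer_values <- function(seq, k) {
  b <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T")) - 1
  n <- length(b)
  if (n < k) return(numeric(0))
  x <- numeric(n - k + 1L)
  for (j in 0:(k - 1L)) x <- x * 4 + b[seq_len(n - k + 1L) + j]
  x
}

#' Hash a k-mer under a digest scheme
#'
#' @param kmer Length-k string over `{A,C,G,T}` (or a vector of them).
#' @param scheme A [digest_scheme()].
#' @return Integer hash value(s) `(a x + b) mod m`.
#' @export
hash_kmer <- function(kmer, scheme) {
  vapply(kmer, function(km) {
    if (nchar(km) != scheme$k) stop("k-mer must have length ", scheme$k)
    x <- kmer_values(km, scheme$k)
    if (anyNA(x)) stop("k-mer contains characters outside {A,C,G,T}: ", km)
    (scheme$hash_a * x + scheme$hash_b) %% scheme$hash_m
  }, numeric(1), USE.NAMES = FALSE)
}

#' Select minimizer positions of a sequence
#'
#' Position j (0-based k-mer start) is selected iff there is a window of w
#' consecutive k-mer positions containing j in which `h` at j is the
#' leftmost occurrence of the window minimum. Sequences with fewer than w
#' k-mers use a single window covering all their k-mers, so every sequence
#' of length >= k digests deterministically.
#'
#' @param seq String over `{A,C,G,T}`.
#' @param scheme A [digest_scheme()].
#' @return Sorted integer vector of selected 0-based k-mer start offsets
#'   (empty when `nchar(seq) < k`).
#' @examples
#' select_minimizers("ACGTACGT", digest_scheme(k = 3, w = 2))  # 0 2 4
#' @export
select_minimizers <- function(seq, scheme) {
  x <- kmer_values(seq, scheme$k)
  if (length(x) == 0L) return(integer(0))
  if (anyNA(x)) stop("sequence contains characters outside {A,C,G,T}")
  h <- (scheme$hash_a * x + scheme$hash_b) %% scheme$hash_m
  select_minimizers_hashes(h, scheme$w)
}

# core window scan on a hash vector; returns 0-based selected positions
select_minimizers_hashes <- function(h, w) {
  nk <- length(h)
  if (nk <= w) return(which.min(h) - 1L)
  sel <- logical(nk)
  j <- which.min(h[1:w])             # leftmost min of the first window
  sel[j] <- TRUE
  for (i in 2:(nk - w + 1L)) {       # window covers i .. i+w-1 (1-based)
    hi <- i + w - 1L
    if (j < i) {                     # previous argmin slid out: rescan
      j <- i - 1L + which.min(h[i:hi])
      sel[j] <- TRUE
    } else if (h[hi] < h[j]) {       # strictly smaller new entrant wins
      j <- hi
      sel[j] <- TRUE
    }                                # ties keep the leftmost minimum
  }
  which(sel) - 1L
}

#' Digest a sequence into its selected k-mers
#'
#' @param seq String over `{A,C,G,T}`.
#' @param scheme A [digest_scheme()].
#' @return Numeric vector of the selected k-mers' base-4 values, in
#'   position order, with the 0-based selected offsets as attribute
#'   `"positions"`. Encoding into the dense digest alphabet happens at the
#'   collection level ([digest_collection()]), where the alphabet map is
#'   defined.
#' @export
digest_sequence <- function(seq, scheme) {
  pos <- select_minimizers(seq, scheme)
  x <- kmer_values(seq, scheme$k)
  structure(x[pos + 1L], positions = pos)
}

#' Digest every genome of a collection
#'
#' Per-genome digests are concatenated with `$` separators: the digest of
#' the collection. Digest characters are dense ranks of the underlying
#' k-mer value among the k-mers actually selected somewhere in the
#' collection, so identity of digest characters is collision-free
#' regardless of the hash (the hash only drives selection).
#'
#' @param collection A [build_collection()] result.
#' @param scheme A [digest_scheme()].
#' @return A `digested_collection`: `codes` (integer vector, `0` = `$`,
#'   dense codes from 1), `alphabet_map` (sorted k-mer values; code i is
#'   `alphabet_map[i]`), `minimizer_positions` (per genome, 0-based source
#'   offsets of the selected k-mers), `scheme`, `num_docs`, `names`,
#'   `source_length`.
#' @export
digest_collection <- function(collection, scheme) {
  seqs <- collection_sequences(collection)
  digs <- lapply(seqs, digest_sequence, scheme = scheme)
  alphabet_map <- sort(unique(unlist(digs)))
  if (length(alphabet_map) > scheme$hash_m)
    stop("digest alphabet larger than hash modulus")  # cannot happen for k-mers
  blocks <- lapply(digs, function(d) c(match(d, alphabet_map), 0L))
  structure(list(
    codes = as.integer(unlist(blocks, use.names = FALSE)),
    alphabet_map = alphabet_map,
    minimizer_positions = lapply(digs, function(d) attr(d, "positions")),
    scheme = scheme,
    num_docs = collection$num_docs,
    names = collection$names,
    source_length = collection$n
  ), class = "digested_collection")
}

#' @export
print.digested_collection <- function(x, ...) {
  cat("digested_collection: ", x$num_docs, " genome(s), ",
      sum(x$codes > 0L), " digest symbols over an alphabet of ",
      length(x$alphabet_map), " (source length ", x$source_length, ")\n",
      sep = "")
  invisible(x)
}

#' Digest a read pattern against a digested collection's alphabet
#'
#' Applies the identical minimizer selection to the read and maps the
#' selected k-mers through the collection's dense alphabet; selected
#' k-mers never seen in the collection's digest map to `NA` and therefore
#' can never match during backward search.
#'
#' @param read String over `{A,C,G,T}`.
#' @param digested A `digested_collection` (or a `kernelized_text` built
#'   from one, which carries the same scheme and alphabet).
#' @return Integer vector of dense digest codes (`NA` for foreign k-mers),
#'   with attribute `"positions"` (0-based source offsets); empty when the
#'   read is shorter than k.
#' @export
digest_pattern <- function(read, digested) {
  d <- digest_sequence(read, digested$scheme)
  structure(match(d, digested$alphabet_map),
            positions = attr(d, "positions"))
}

#' Printable rendering of digest codes
#'
#' Maps dense digest codes to consecutive ASCII characters starting at the
#' scheme's `display_base` (37 by default, so an alphabet of up to 64
#' symbols stays within printable ASCII 37..100); the inverse is
#' [decode_digest_rendering()]. The rendering is presentation only.
#'
#' @param codes Integer digest codes (>= 1), e.g. a block of
#'   `digested_collection$codes`.
#' @param display_base Smallest ASCII value to use.
#' @return A single string.
#' @export
render_digest <- function(codes, display_base = 37L) {
  stopifnot(all(codes >= 1L))
  intToUtf8(display_base + codes - 1L)
}

#' @rdname render_digest
#' @param text Rendered digest string.
#' @return `decode_digest_rendering`: integer codes (>= 1).
#' @export
decode_digest_rendering <- function(text, display_base = 37L) {
  utf8ToInt(text) - display_base + 1L
}
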