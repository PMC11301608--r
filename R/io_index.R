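# On-disk index layout: a directory holding meta.json (mode, parameters,
# alphabet, integer widths, format version), little-endian binary arrays
# text.bin / sa.bin / lcp.bin / bwt.bin / b.bin (byte-per-bit document
# bitvector), and names.tsv. Rank/occurrence tables are rebuilt on load.

INDEX_FORMAT_VERSION <- 1L

#' Write an augmented FM-index to a directory
#'
#' @param index An `aug_fm_index`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_index <- function(index, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = INDEX_FORMAT_VERSION,
               mode = index$mode, n = index$n, sigma = index$sigma,
               num_docs = index$num_docs, labels = index$labels,
               params = index$params,
               text_width = 1L, int_width = 4L, endian = "little")
  if (!is.null(index$alphabet_map)) meta$alphabet_map <- index$alphabet_map
  if (!is.null(index$scheme)) meta$scheme <- unclass(index$scheme)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wr <- function(x, f, size) {
    con <- file(file.path(dir, f), "wb")
    on.exit(close(con))
    writeBin(as.integer(x), con, size = size, endian = "little")
  }
  wr(index$codes, "text.bin", 1L)
  wr(index$sa, "sa.bin", 4L)
  wr(index$lcp, "lcp.bin", 4L)
  wr(index$bwt, "bwt.bin", 1L)
  wr(as.integer(index$codes == 1L), "b.bin", 1L)
  utils::write.table(data.frame(doc = seq_len(index$num_docs) - 1L,
                                name = index$names),
                     file.path(dir, "names.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(index$minimizer_positions)) {
    jsonlite::write_json(index$minimizer_positions,
                         file.path(dir, "minimizer_positions.json"))
  }
  invisible(dir)
}

#' Read an augmented FM-index from a directory
#'
#' Loads the serialized arrays and rebuilds the in-memory rank structures;
#' the result round-trips with [write_index()].
#'
#' @param dir Directory written by [write_index()].
#' @return An `aug_fm_index`.
#' @export
read_index <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (meta$format_version != INDEX_FORMAT_VERSION)
    stop("unsupported index format version ", meta$format_version)
  n <- meta$n
  rd <- function(f, size, m = n) {
    con <- file(file.path(dir, f), "rb")
    on.exit(close(con))
    readBin(con, "integer", n = m, size = size, endian = "little")
  }
  codes <- rd("text.bin", 1L)
  sa0 <- rd("sa.bin", 4L)
  lcp <- rd("lcp.bin", 4L)
  bwt <- rd("bwt.bin", 1L)
  sigma <- meta$sigma
  counts <- tabulate(codes, nbins = sigma)
  occ <- matrix(0L, nrow = n + 1L, ncol = sigma)
  for (c in which(counts > 0L)) occ[, c] <- c(0L, cumsum(bwt == c))
  nm <- utils::read.table(file.path(dir, "names.tsv"), sep = "\t",
                          header = TRUE, colClasses = c("integer", "character"))
  extra <- list()
  if (!is.null(meta$alphabet_map)) extra$alphabet_map <- meta$alphabet_map
  if (!is.null(meta$scheme)) extra$scheme <- do.call(digest_scheme, as.list(meta$scheme))
  mpf <- file.path(dir, "minimizer_positions.json")
  if (file.exists(mpf))
    extra$minimizer_positions <- jsonlite::read_json(mpf, simplifyVector = TRUE)
  structure(c(list(codes = codes, n = n, sa = sa0, bwt = bwt, lcp = lcp,
                   Ccum = c(0L, cumsum(counts))[seq_len(sigma)],
                   occ = occ,
                   sel = lapply(seq_len(sigma), function(c) which(bwt == c) - 1L),
                   counts = counts,
                   dollar_cum = c(0L, cumsum(codes == 1L))[seq_len(n)],
                   labels = meta$labels, sigma = sigma, mode = meta$mode,
                   num_docs = meta$num_docs, names = nm$name,
                   params = as.list(meta$params)),
              extra),
            class = "aug_fm_index")
}
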