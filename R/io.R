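#' Read and write dense feature-by-sample matrices
#'
#' Plain TSV/CSV with feature ids in the first column and sample ids in the
#' header row. Values are written with 9 significant digits, enough for the
#' reference metrics to round-trip.
#'
#' @param path File path; `.csv` extension selects comma separation,
#'   anything else tab.
#' @return [read_dense_matrix()]: a numeric matrix with dimnames.
#' @export
read_dense_matrix <- function(path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  as_dense_matrix(as.data.frame(df))
}

#' @rdname read_dense_matrix
#' @param x Numeric matrix with dimnames.
#' @export
write_dense_matrix <- function(x, path) {
  x <- as_dense_matrix(x)
  df <- data.frame(feature_id = rownames(x),
                   signif(x, 9), check.names = FALSE)
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection as packed signatures
#'
#' Each GMT line is a set name, a description, then tab-separated member
#' features. Sets become signature columns over the sorted union of all
#' members.
#'
#' @param path GMT file path.
#' @return A `sig_matrix` with one column per set (set names as signature
#'   ids) over the union universe.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names_))
    abort(sprintf("duplicate set name(s): %s",
                  paste(unique(names_[duplicated(names_)]), collapse = ", ")))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- names_
  empty <- names_[lengths(sets) == 0]
  if (length(empty) > 0)
    warn(sprintf("empty set(s), stored as all-zero columns: %s",
                 paste(empty, collapse = ", ")))
  universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0) abort("no members in any set.")
  mat <- vapply(sets, function(s) as.integer(universe %in% s),
                integer(length(universe)))
  mat <- matrix(mat, nrow = length(universe),
                dimnames = list(universe, names_))
  pack_signatures(mat)
}

# Binary signature container: magic "SIGPACK1", five little-endian int32
# (version, K, N, W, reserved), 8*W*N bytes of little-endian words, then the
# two id tables as int32 byte length + newline-joined UTF-8.
sig_magic <- charToRaw("SIGPACK1")

#' Read and write the binary signature container
#'
#' A compact, portable on-disk form of a `sig_matrix`: a magic header with
#' K, N and W, the column-major little-endian 64-bit words, then the
#' feature and signature id tables. The padding invariant (zero bits beyond
#' K in each column's last word) is re-checked on load.
#'
#' @param sig A `sig_matrix`.
#' @param path File path.
#' @export
write_signatures <- function(sig, path) {
  validate_sig_matrix(sig)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(sig_magic, con)
  writeBin(as.integer(c(1L, sig$K, sig$N, sig$W, 0L)), con,
           size = 4, endian = "little")
  writeBin(sig$words, con)
  for (ids in list(sig$feature_ids, sig$signature_ids)) {
    bytes <- charToRaw(paste(ids, collapse = "\n"))
    writeBin(length(bytes), con, size = 4, endian = "little")
    writeBin(bytes, con)
  }
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", length(sig_magic))
  if (!identical(magic, sig_magic)) abort("not a signature container (bad magic).")
  hdr <- readBin(con, "integer", 5, size = 4, endian = "little")
  if (hdr[1] != 1L) abort(sprintf("unsupported container version %d.", hdr[1]))
  K <- hdr[2]; N <- hdr[3]; W <- hdr[4]
  if (W != (K + 63L) %/% 64L) abort("corrupted header: W != ceiling(K/64).")
  words <- readBin(con, "raw", 8 * W * N)
  ids <- lapply(1:2, function(i) {
    nb <- readBin(con, "integer", 1, size = 4, endian = "little")
    strsplit(rawToChar(readBin(con, "raw", nb)), "\n", fixed = TRUE)[[1]]
  })
  if (length(ids[[1]]) != K || length(ids[[2]]) != N)
    abort("corrupted id tables.")
  sig <- new_sig_matrix(words, ids[[1]], ids[[2]])
  validate_sig_matrix(sig)  # rejects nonzero padding bits
  sig
}

#' Read and write edge tables
#'
#' Edge lists are TSV with columns `node_i`, `node_j`, `weight`;
#' [write_graphml()] exports the same graph for external viewers.
#'
#' @param graph A `sig_edges` table.
#' @param path File path.
#' @export
write_edges <- function(graph, path) {
  readr::write_tsv(as_tibble(graph)[, c("node_i", "node_j", "weight")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          node_i = readr::col_character(),
                          node_j = readr::col_character(),
                          weight = readr::col_double()))
  new_sig_edges(df)
}

#' @rdname write_edges
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Stream comparison chunks to TSV files
#'
#' Returns a sink for [sig_compare_chunked()] that writes each block as a
#' long-form TSV (`query_id`, `library_id`, `count`) named by its block
#' coordinates, plus a `manifest.json` describing the run.
#'
#' @param dir Output directory (created if needed).
#' @param meta Named list merged into the manifest (operator, K, ...).
#' @return A function usable as the `sink` argument of
#'   [sig_compare_chunked()].
#' @export
tsv_chunk_sink <- function(dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chunks <- character(0)
  function(block, counts) {
    name <- sprintf("chunk_r%d-%d_c%d-%d.tsv",
                    block$row_start, block$row_end,
                    block$col_start, block$col_end)
    df <- tibble(query_id = rep(rownames(counts), times = ncol(counts)),
                 library_id = rep(colnames(counts), each = nrow(counts)),
                 count = as.vector(counts))
    readr::write_tsv(df, file.path(dir, name), progress = FALSE)
    chunks <<- c(chunks, name)
    jsonlite::write_json(
      c(meta, list(chunks = chunks,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    invisible(NULL)
  }
}

#' Read a taxonomy label table
#'
#' TSV with columns `genome`, `domain`, `group`, `genus`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_taxonomy <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
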