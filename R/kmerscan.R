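# Per-position k-mer indexing of the vector and read scanning: the "counts"
# track. Each vector position contributes its canonical k-mer (lexicographic
# minimum of the k-mer and its reverse complement), so read strand never
# matters; circular vectors contribute wrap-around k-mers.

#' Build the per-position canonical k-mer index of a vector
#'
#' Position `i` of a circular vector of length `L` is represented by the
#' canonical form of the k-mer starting at `i` (wrapping through the origin
#' for `i > L - k + 1`); a linear sequence indexes positions
#' `1 .. L - k + 1`. Windows containing non-ACGT characters are skipped and
#' their positions marked absent. Duplicate k-mers are allowed: every
#' position sharing a k-mer receives the same hit count when scanned.
#'
#' @param vector a `vector_map`, or a plain character DNA string.
#' @param k k-mer size, `4 <= k <= 63` and `k <=` vector length.
#' @param topology overrides the vector's topology ("circular" or "linear").
#' @return a `position_index`: list with `k`, `topology`, `vector_length`,
#'   `positions` (indexed positions), `kmers` (canonical k-mer per indexed
#'   position), `keys` (unique canonical k-mers) and `key_id`
#'   (`keys[key_id[j]] == kmers[j]`).
#' @examples
#' idx <- build_index("ACGTAC", k = 4, topology = "linear")
#' idx$kmers
#' @export
build_index <- function(vector, k, topology = NULL) {
  if (is.character(vector)) {
    vector <- list(sequence = vector,
                   topology = if (is.null(topology)) "linear" else topology,
                   name = "vector")
  }
  if (is.null(topology)) topology <- vector$topology
  topology <- match.arg(topology, c("circular", "linear"))
  seqn <- toupper(vector$sequence)
  L <- nchar(seqn)
  k <- as.integer(k)
  if (k < 4L || k > 63L) stop("k must lie in 4..63", call. = FALSE)
  if (k > L) stop("k exceeds the vector length", call. = FALSE)
  if (topology == "circular") {
    ext <- paste0(seqn, substr(seqn, 1L, k - 1L))
    pos <- seq_len(L)
  } else {
    ext <- seqn
    pos <- seq_len(L - k + 1L)
  }
  raw <- substring(ext, pos, pos + k - 1L)
  can <- cpp_canonical_kmers(raw)
  keep <- !is.na(can)
  pos <- pos[keep]
  can <- can[keep]
  keys <- unique(can)
  structure(
    list(k = k, topology = topology, vector_length = L,
         positions = pos, kmers = can,
         keys = keys, key_id = match(can, keys)),
    class = "position_index"
  )
}

#' @export
print.position_index <- function(x, ...) {
  cat("<position_index> k=", x$k, ", ", x$topology, " vector of ",
      x$vector_length, " bp, ", length(x$positions), " positions / ",
      length(x$keys), " distinct k-mers\n", sep = "")
  invisible(x)
}

#' Map from canonical k-mer to vector positions
#' @param index a `position_index`.
#' @return named list: canonical k-mer -> integer positions.
#' @export
kmer_to_positions <- function(index) {
  split(index$positions, index$kmers)[index$keys]
}

#' Count reads carrying each vector position's k-mer
#'
#' For every indexed position, counts the number of reads whose canonical
#' k-mer set contains that position's k-mer. A read increments a position at
#' most once (presence, not occurrence), so counts are bounded by the
#' library size and form valid margins for the per-position 2x2 test. Reads
#' shorter than `k` contribute no hits but still count toward
#' `library_size`, which is a sequencing-effort margin.
#'
#' @param reads a `read_set` (or plain character vector of read sequences).
#' @param index a `position_index` from [build_index()].
#' @param sample_name identifier stored in the profile.
#' @return a `kmer_profile`: list with `counts` (aligned with
#'   `index$positions`), `positions`, `library_size`, `k`, `topology`,
#'   `vector_length`, `sample_name`.
#' @export
scan_reads <- function(reads, index, sample_name = NULL) {
  if (is.character(reads)) {
    reads <- list(reads = reads, source_name = "reads")
  }
  if (is.null(sample_name)) sample_name <- reads$source_name
  stopifnot(inherits(index, "position_index"))
  n <- length(reads$reads)
  if (n == 0L) {
    warning("empty read set: returning an all-zero profile", call. = FALSE)
    key_counts <- integer(length(index$keys))
  } else {
    key_counts <- cpp_scan_reads(toupper(reads$reads), index$keys, index$k)
  }
  structure(
    list(counts = key_counts[index$key_id],
         positions = index$positions,
         library_size = n,
         k = index$k,
         topology = index$topology,
         vector_length = index$vector_length,
         sample_name = sample_name),
    class = "kmer_profile"
  )
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("<kmer_profile> ", x$sample_name, ": k=", x$k, ", ",
      length(x$positions), " positions, library_size=", x$library_size,
      ", max count=", if (length(x$counts)) max(x$counts) else 0, "\n", sep = "")
  invisible(x)
}

#' Write a hit profile as TSV plus JSON sidecar
#'
#' The TSV has columns `position` and `count`; the sidecar
#' (`<path>.json`) records `k`, `library_size`, `topology`,
#' `vector_length` and `sample_name`.
#'
#' @param profile a `kmer_profile`.
#' @param path TSV output file.
#' @export
write_profile <- function(profile, path) {
  write.table(
    data.frame(position = profile$positions, count = profile$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    list(k = profile$k, library_size = profile$library_size,
         topology = profile$topology, vector_length = profile$vector_length,
         sample_name = profile$sample_name),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a hit profile written by [write_profile()]
#' @param path TSV file (its `<path>.json` sidecar must exist).
#' @return a `kmer_profile`.
#' @export
read_profile <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(counts = as.integer(tab$count),
         positions = as.integer(tab$position),
         library_size = as.integer(meta$library_size),
         k = as.integer(meta$k),
         topology = meta$topology,
         vector_length = as.integer(meta$vector_length),
         sample_name = meta$sample_name),
    class = "kmer_profile"
  )
}
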