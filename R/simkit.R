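# Synthetic data generator: host genomes, annotated binary vectors,
# integration events and shotgun reads with recorded ground truth, so the
# whole verification pipeline can be exercised at desk scale.
#
# Coordinates are 1-based inclusive throughout; circular sequences index
# positions modulo their length.

#' Generate a random host genome
#'
#' Bases are drawn i.i.d. with the requested GC content. Stands in for the
#' genomic DNA of a regenerated plant line; copies of a polyploid genome are
#' treated as identical unless an edit is applied downstream.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc target GC fraction, strictly between 0 and 1.
#' @param seed integer seed; identical arguments give identical genomes.
#' @param name identifier for the genome.
#' @return a `host_genome` object: list with `sequence`, `name`, `ploidy_note`.
#' @examples
#' g <- make_host_genome(2000, gc = 0.36, seed = 1)
#' nchar(g$sequence)
#' @export
make_host_genome <- function(length, gc, seed, name = "host") {
  if (!is.numeric(length) || length < 1000) {
    stop("length must be >= 1000 bp", call. = FALSE)
  }
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    stop("gc must lie strictly between 0 and 1", call. = FALSE)
  }
  sequence <- with_seed(seed, random_dna(as.integer(length), gc))
  structure(
    list(sequence = sequence, name = name,
         ploidy_note = "copies identical unless an edit is applied"),
    class = "host_genome"
  )
}

#' @export
print.host_genome <- function(x, ...) {
  cat("<host_genome> ", x$name, ": ", nchar(x$sequence), " bp\n", sep = "")
  invisible(x)
}

#' Generate an annotated circular binary vector
#'
#' Models an Agrobacterium binary transformation vector: a circular sequence
#' partitioned into a T-DNA region (`[1, tdna_len]`) and a backbone
#' (`[tdna_len + 1, total]`), with a probe feature of `probe_len` bp placed
#' inside the T-DNA (the hybridization-probe analog). Optional homology tract
#' templates are cut from the backbone for later embedding into a host genome,
#' emulating plant-derived vector elements that share sequence with the host.
#'
#' @param tdna_len,backbone_len lengths in bp, each >= 500.
#' @param seed integer seed.
#' @param homology optional integer vector of tract lengths to excise as
#'   homology templates.
#' @param probe_len probe feature length in bp (default 500).
#' @param gc GC fraction of the random sequence.
#' @param name vector identifier.
#' @return a `vector_map`: list with `sequence`, `topology`, `features`
#'   (data.frame label/start/end/strand), `homology_templates`
#'   (data.frame vec_start/vec_end/length), `name`.
#' @examples
#' v <- make_vector(2000, 3000, seed = 2)
#' v$features
#' @export
make_vector <- function(tdna_len, backbone_len, seed, homology = NULL,
                        probe_len = 500, gc = 0.5, name = "vector") {
  if (tdna_len < 500 || backbone_len < 500) {
    stop("tdna_len and backbone_len must each be >= 500 bp", call. = FALSE)
  }
  if (probe_len >= tdna_len) stop("probe_len must be smaller than tdna_len", call. = FALSE)
  total <- as.integer(tdna_len + backbone_len)
  sequence <- with_seed(seed, random_dna(total, gc))
  probe_start <- as.integer(floor((tdna_len - probe_len) / 2) + 1)
  features <- data.frame(
    label  = c("tdna", "backbone", "probe"),
    start  = c(1L, as.integer(tdna_len + 1L), probe_start),
    end    = c(as.integer(tdna_len), total, as.integer(probe_start + probe_len - 1L)),
    strand = c("+", "+", "+"),
    stringsAsFactors = FALSE
  )
  tracts <- data.frame(vec_start = integer(0), vec_end = integer(0),
                       length = integer(0))
  if (!is.null(homology) && length(homology) > 0) {
    if (sum(homology) > backbone_len) {
      stop("homology tracts do not fit in the backbone", call. = FALSE)
    }
    # non-overlapping templates packed from the start of the backbone
    at <- as.integer(tdna_len + 1L)
    for (len in as.integer(homology)) {
      tracts <- rbind(tracts, data.frame(vec_start = at, vec_end = at + len - 1L,
                                         length = len))
      at <- at + len
    }
  }
  structure(
    list(sequence = sequence, topology = "circular", features = features,
         homology_templates = tracts, name = name),
    class = "vector_map"
  )
}

#' @export
print.vector_map <- function(x, ...) {
  cat("<vector_map> ", x$name, ": ", nchar(x$sequence), " bp, ",
      x$topology, ", ", nrow(x$features), " features\n", sep = "")
  invisible(x)
}

#' Feature interval lookup on a vector map
#' @param vector a `vector_map`.
#' @param label feature label, e.g. "tdna", "backbone", "probe".
#' @return integer vector `c(start, end)` (first matching feature).
#' @export
vector_feature <- function(vector, label) {
  f <- vector$features[vector$features$label == label, , drop = FALSE]
  if (nrow(f) == 0) stop("no feature labelled '", label, "'", call. = FALSE)
  c(start = f$start[1], end = f$end[1])
}

#' Copy homology tracts from a vector into a host genome
#'
#' Overwrites host segments at generator-chosen loci with the vector's
#' homology template sequences, so the host shares exact tracts with the
#' vector without any integration event. Host length is unchanged.
#'
#' @param host a `host_genome`.
#' @param vector a `vector_map` built with `homology` templates.
#' @param seed integer seed choosing the host loci.
#' @return list with `host` (modified genome) and `tracts` (data.frame
#'   host_start/host_end/vec_start/vec_end).
#' @export
embed_homology <- function(host, vector, seed) {
  tmpl <- vector$homology_templates
  if (nrow(tmpl) == 0) {
    return(list(host = host,
                tracts = data.frame(host_start = integer(0), host_end = integer(0),
                                    vec_start = integer(0), vec_end = integer(0))))
  }
  hlen <- nchar(host$sequence)
  seqs <- seq_substr(vector$sequence, tmpl$vec_start, tmpl$vec_end)
  loci <- with_seed(seed, {
    # rejection-sample non-overlapping placements
    placed <- integer(0)
    out <- integer(nrow(tmpl))
    for (i in seq_len(nrow(tmpl))) {
      repeat {
        s <- sample.int(hlen - tmpl$length[i] + 1L, 1L)
        iv <- s:(s + tmpl$length[i] - 1L)
        if (!any(iv %in% placed)) { placed <- c(placed, iv); out[i] <- s; break }
      }
    }
    out
  })
  seqchars <- host$sequence
  for (i in seq_len(nrow(tmpl))) {
    substr(seqchars, loci[i], loci[i] + tmpl$length[i] - 1L) <- seqs[i]
  }
  host$sequence <- seqchars
  list(host = host,
       tracts = data.frame(host_start = loci,
                           host_end = loci + tmpl$length - 1L,
                           vec_start = tmpl$vec_start, vec_end = tmpl$vec_end))
}

#' Integrate a vector segment into a host genome
#'
#' Inserts the vector sub-sequence `vector_interval` (1-based inclusive; a
#' start greater than the end wraps through the circular origin) immediately
#' after host position `host_locus`, and records exact ground-truth
#' coordinates. With `vector_interval = NULL` the genome is returned
#' unchanged and the truth record states no integration.
#'
#' @param host a `host_genome`.
#' @param vector a `vector_map`.
#' @param vector_interval `c(start, end)` on the vector, or `NULL`.
#' @param host_locus insertion point on the host (segment occupies
#'   `host_locus + 1 ...` in the returned genome), required when integrating.
#' @param homology_tracts optional tract data.frame from [embed_homology()].
#' @param seed integer recorded in the truth record.
#' @return list with `genome` (`host_genome`) and `truth` (`truth_record`).
#' @examples
#' h <- make_host_genome(10000, 0.4, seed = 1)
#' v <- make_vector(2000, 3000, seed = 2)
#' res <- integrate_vector(h, v, c(1, 2000), host_locus = 5000)
#' nchar(res$genome$sequence)  # 12000
#' @export
integrate_vector <- function(host, vector, vector_interval = NULL,
                             host_locus = NULL, homology_tracts = NULL,
                             seed = NA_integer_) {
  hlen <- nchar(host$sequence)
  vlen <- nchar(vector$sequence)
  if (is.null(homology_tracts)) {
    homology_tracts <- data.frame(host_start = integer(0), host_end = integer(0),
                                  vec_start = integer(0), vec_end = integer(0))
  }
  if (is.null(vector_interval)) {
    truth <- structure(
      list(integrated = FALSE, vector_interval = NULL, host_locus = NULL,
           homology_tracts = homology_tracts, seed = seed),
      class = "truth_record"
    )
    return(list(genome = host, truth = truth))
  }
  vs <- as.integer(vector_interval[1]); ve <- as.integer(vector_interval[2])
  if (vs < 1 || vs > vlen || ve < 1 || ve > vlen) {
    stop("vector_interval outside [1, vector length]", call. = FALSE)
  }
  if (is.null(host_locus) || host_locus < 0 || host_locus > hlen) {
    stop("host_locus outside the host genome", call. = FALSE)
  }
  segment <- if (vs <= ve) {
    seq_substr(vector$sequence, vs, ve)
  } else {
    if (vector$topology != "circular") {
      stop("wrapped vector_interval requires a circular vector", call. = FALSE)
    }
    paste0(seq_substr(vector$sequence, vs, vlen), seq_substr(vector$sequence, 1, ve))
  }
  host$sequence <- paste0(
    seq_substr(host$sequence, 1, host_locus),
    segment,
    if (host_locus < hlen) seq_substr(host$sequence, host_locus + 1, hlen) else ""
  )
  host$name <- paste0(host$name, "+", vector$name, "[", vs, "-", ve, "]")
  truth <- structure(
    list(integrated = TRUE, vector_interval = c(start = vs, end = ve),
         host_locus = as.integer(host_locus), homology_tracts = homology_tracts,
         seed = seed),
    class = "truth_record"
  )
  list(genome = host, truth = truth)
}

#' Simulate single-end shotgun reads
#'
#' Uniform start positions, both strands equiprobable, i.i.d. per-base
#' substitution errors at `error_rate`. The number of reads is
#' `round(genome_length * depth / read_length)`. Quality strings are constant
#' placeholders; the downstream analysis uses only k-mer content.
#'
#' @param genome a `host_genome` (or any list with a `sequence` string).
#' @param depth fold-coverage, > 0.
#' @param read_length read length in bp, <= genome length.
#' @param error_rate per-base substitution probability in `[0, 0.1)`.
#' @param seed integer seed.
#' @param source_name identifier for the read set.
#' @return a `read_set`: list with `reads` (character vector), `ids`,
#'   `read_length`, `source_name`, `quality_char`.
#' @examples
#' g <- make_host_genome(10000, 0.5, seed = 1)
#' rs <- simulate_reads(g, depth = 30, read_length = 100, seed = 3)
#' length(rs$reads)  # 3000
#' @export
simulate_reads <- function(genome, depth, read_length, error_rate = 0,
                           seed, source_name = genome$name) {
  glen <- nchar(genome$sequence)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (read_length > glen) stop("read_length exceeds genome length", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.1) {
    stop("error_rate must lie in [0, 0.1)", call. = FALSE)
  }
  n <- as.integer(round(glen * depth / read_length))
  reads <- with_seed(seed, {
    starts <- sample.int(glen - read_length + 1L, n, replace = TRUE)
    minus <- runif(n) < 0.5
    out <- seq_substr(genome$sequence, starts, starts + read_length - 1L)
    if (any(minus)) out[minus] <- revcomp(out[minus])
    if (error_rate > 0) {
      n_err <- rbinom(1L, n * read_length, error_rate)
      if (n_err > 0) {
        at <- sample.int(n * read_length, n_err)           # flat base index
        ri <- ((at - 1L) %/% read_length) + 1L
        pj <- ((at - 1L) %% read_length) + 1L
        for (e in seq_len(n_err)) {
          cur <- substr(out[ri[e]], pj[e], pj[e])
          alt <- sample(setdiff(DNA_BASES, cur), 1L)
          substr(out[ri[e]], pj[e], pj[e]) <- alt
        }
      }
    }
    out
  })
  structure(
    list(reads = reads,
         ids = paste0(source_name, "_r", seq_len(n)),
         read_length = as.integer(read_length),
         source_name = source_name,
         quality_char = "I"),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", x$source_name, ": ", length(x$reads), " reads x ",
      x$read_length, " bp\n", sep = "")
  invisible(x)
}

# ---- plain-text IO --------------------------------------------------------

#' Write a genome or vector sequence to FASTA
#' @param x a `host_genome` or `vector_map`.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(x$sequence)
  names(ss) <- x$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a read set to FASTQ
#' @param reads a `read_set`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep(reads$quality_char, nchar(reads$reads))
  ss <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$reads),
    Biostrings::PhredQuality(qual)
  )
  names(ss) <- reads$ids
  Biostrings::writeQualityScaledXStringSet(ss, path)
  invisible(path)
}

#' Read sequencing reads from FASTQ or FASTA
#' @param path input file; format inferred from the extension
#'   (`.fastq`/`.fq` vs `.fasta`/`.fa`/`.fna`).
#' @param source_name identifier; defaults to the file name.
#' @return a `read_set`.
#' @export
read_reads <- function(path, source_name = basename(path)) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  reads <- as.character(ss)
  structure(
    list(reads = unname(reads),
         ids = names(ss),
         read_length = if (length(reads)) as.integer(max(nchar(reads))) else 0L,
         source_name = source_name,
         quality_char = "I"),
    class = "read_set"
  )
}

#' Write a vector feature table (label, start, end, strand) as TSV
#' @param vector a `vector_map`.
#' @param path output file.
#' @export
write_feature_table <- function(vector, path) {
  write.table(vector$features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation truth record as JSON
#' @param truth a `truth_record`.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(integrated = truth$integrated,
         vector_interval = as.list(truth$vector_interval),
         host_locus = truth$host_locus,
         homology_tracts = truth$homology_tracts,
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a vector map from FASTA plus feature table
#' @param fasta FASTA file with one sequence.
#' @param feature_table TSV with columns label, start, end, strand.
#' @param topology "circular" (default) or "linear".
#' @return a `vector_map`.
#' @export
read_vector_map <- function(fasta, feature_table, topology = "circular") {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L) stop("expected exactly one vector sequence", call. = FALSE)
  features <- read.table(feature_table, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  structure(
    list(sequence = as.character(ss[[1]]), topology = topology,
         features = features,
         homology_templates = data.frame(vec_start = integer(0),
                                         vec_end = integer(0),
                                         length = integer(0)),
         name = names(ss)[1]),
    class = "vector_map"
  )
}
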