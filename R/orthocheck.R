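# Orthogonal verification computations: tiled in-silico PCR over a primer
# panel, restriction-digest/probe fragment prediction (the hybridization
# expectation), and target-site allele classification with off-target
# screening and editing-efficiency arithmetic.

#' Built-in restriction enzyme table
#'
#' Recognition motifs and cut offsets (bases 5' of the cut on the motif's
#' plus strand) for the enzymes used in fragment prediction. Overridable by
#' passing explicit motifs to [digest_and_probe()]. Incomplete digestion is
#' not modeled.
#'
#' @return data.frame with `name`, `motif`, `cut_offset`.
#' @export
restriction_enzymes <- function() {
  data.frame(
    name = c("BamHI", "HindIII", "EcoRI"),
    motif = c("GGATCC", "AAGCTT", "GAATTC"),
    cut_offset = c(1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Read a primer panel from TSV
#'
#' Expects columns `set_id`, `forward`, `reverse` (additional columns are
#' kept). Primer sequences must be A/C/G/T and set ids unique.
#'
#' @param path TSV file.
#' @return data.frame primer panel.
#' @export
read_primer_panel <- function(path) {
  panel <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("set_id", "forward", "reverse") %in% names(panel))) {
    stop("primer panel needs columns set_id, forward, reverse", call. = FALSE)
  }
  validate_panel(panel)
}

#' @noRd
validate_panel <- function(panel) {
  if (anyDuplicated(panel$set_id)) stop("duplicate set_id in panel", call. = FALSE)
  for (p in c(panel$forward, panel$reverse)) assert_dna(toupper(p), "primer")
  bad <- nchar(panel$forward) < 15 | nchar(panel$forward) > 35 |
    nchar(panel$reverse) < 15 | nchar(panel$reverse) > 35
  if (any(bad)) {
    warning("primer length outside 15-35 nt for set(s): ",
            paste(panel$set_id[bad], collapse = ", "), call. = FALSE)
  }
  panel$forward <- toupper(panel$forward)
  panel$reverse <- toupper(panel$reverse)
  panel
}

# Match sites of a primer annealing to the plus strand (fwd = TRUE: the
# primer sequence itself occurs; its 3' end is the rightmost base) or to the
# minus strand (the primer's reverse complement occurs on the plus strand;
# its 3' end corresponds to the leftmost base). Returns start positions of
# the occurrence on the (possibly extended) plus strand.
#' @noRd
primer_sites <- function(templ, primer, plus_strand, max_mismatch, three_prime_exact) {
  patt <- if (plus_strand) primer else revcomp(primer)
  m <- Biostrings::matchPattern(patt, Biostrings::DNAString(templ),
                                max.mismatch = max_mismatch)
  starts <- BiocGenerics::start(m)
  if (length(starts) == 0L || three_prime_exact == 0L) return(starts)
  len <- nchar(patt)
  tpe <- min(three_prime_exact, len)
  if (plus_strand) {
    want <- substr(patt, len - tpe + 1L, len)
    got <- substring(templ, starts + len - tpe, starts + len - 1L)
  } else {
    want <- substr(patt, 1L, tpe)
    got <- substring(templ, starts, starts + tpe - 1L)
  }
  starts[got == want]
}

#' In-silico PCR of one primer pair against a template
#'
#' Reports every template interval where one primer matches one strand and
#' the other primer matches the opposite strand downstream, each with at
#' most `max_mismatch` mismatches and an exact match over the 3'-terminal
#' `three_prime_exact` bases, and a product no longer than
#' `max_amplicon_length`. Circular templates allow origin-spanning
#' products (reported with `end > template length`).
#'
#' @param template DNA string (or `host_genome`/`vector_map`).
#' @param pair list or one-row data.frame with `set_id`, `forward`,
#'   `reverse`.
#' @param topology "linear" or "circular" (taken from the template object
#'   when available).
#' @param max_mismatch mismatches tolerated per primer (default 2).
#' @param three_prime_exact 3'-terminal bases that must match exactly
#'   (default 3).
#' @param max_amplicon_length longest reportable product (default 5000).
#' @return data.frame of amplicon hits: `template_name`, `set_id`, `start`,
#'   `end`, `length`, `orientation` (`"F+/R-"` when the forward primer sits
#'   on the plus strand).
#' @export
insilico_pcr <- function(template, pair, topology = NULL, max_mismatch = 2,
                         three_prime_exact = 3, max_amplicon_length = 5000) {
  tname <- "template"
  if (is.list(template)) {
    tname <- template$name %||% tname
    if (is.null(topology)) topology <- template$topology
    template <- template$sequence
  }
  if (is.null(topology)) topology <- "linear"
  topology <- match.arg(topology, c("linear", "circular"))
  template <- toupper(template)
  L <- nchar(template)
  if (L == 0L) stop("empty template", call. = FALSE)
  fwd <- toupper(pair$forward); rev <- toupper(pair$reverse)
  if (max_amplicon_length < max(nchar(fwd), nchar(rev))) {
    stop("max_amplicon_length shorter than a primer", call. = FALSE)
  }
  templ <- if (topology == "circular" && L > 1) {
    paste0(template, substr(template, 1L, min(max_amplicon_length - 1L, L - 1L)))
  } else {
    template
  }

  one_orientation <- function(p5, p3, tag) {
    s5 <- primer_sites(templ, p5, TRUE, max_mismatch, three_prime_exact)
    s3 <- primer_sites(templ, p3, FALSE, max_mismatch, three_prime_exact)
    if (topology == "circular") s5 <- s5[s5 <= L]   # dedupe modulo origin
    if (length(s5) == 0L || length(s3) == 0L) return(NULL)
    grid <- expand.grid(sf = s5, sr = s3)
    grid$end <- grid$sr + nchar(p3) - 1L
    grid$len <- grid$end - grid$sf + 1L
    ok <- grid$sr >= grid$sf & grid$len >= nchar(p5) + nchar(p3) &
      grid$len <= max_amplicon_length
    grid <- grid[ok, , drop = FALSE]
    if (nrow(grid) == 0L) return(NULL)
    data.frame(template_name = tname, set_id = pair$set_id %||% NA_character_,
               start = grid$sf, end = grid$end, length = grid$len,
               orientation = tag, stringsAsFactors = FALSE)
  }
  hits <- rbind(one_orientation(fwd, rev, "F+/R-"),
                one_orientation(rev, fwd, "R+/F-"))
  if (is.null(hits)) {
    return(data.frame(template_name = character(0), set_id = character(0),
                      start = integer(0), end = integer(0), length = integer(0),
                      orientation = character(0)))
  }
  hits <- unique(hits)
  rownames(hits) <- NULL
  hits[order(hits$start, hits$end), , drop = FALSE]
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Presence/absence (band) matrix of a primer panel across templates
#'
#' Rows are primer sets, columns templates; each cell lists the predicted
#' product sizes (empty string = no band). A genome is "vector-free by PCR"
#' when every vector-panel cell on it is empty while the genomic control
#' set amplifies.
#'
#' @param templates named list; each element a DNA string, `host_genome`,
#'   `vector_map`, or `list(sequence=, topology=)`.
#' @param panel data.frame with `set_id`, `forward`, `reverse`.
#' @param ... passed to [insilico_pcr()].
#' @return character matrix of ";"-joined product sizes with attribute
#'   `"band"`: the logical any-product matrix.
#' @export
presence_matrix <- function(templates, panel, ...) {
  if (nrow(panel) == 0L) stop("empty primer panel", call. = FALSE)
  if (is.null(names(templates)) || any(names(templates) == "")) {
    stop("templates must be named", call. = FALSE)
  }
  sizes <- matrix("", nrow = nrow(panel), ncol = length(templates),
                  dimnames = list(panel$set_id, names(templates)))
  band <- matrix(FALSE, nrow = nrow(panel), ncol = length(templates),
                 dimnames = dimnames(sizes))
  for (i in seq_len(nrow(panel))) {
    for (j in seq_along(templates)) {
      hits <- insilico_pcr(templates[[j]], panel[i, , drop = FALSE], ...)
      if (nrow(hits)) {
        sizes[i, j] <- paste(sort(hits$length), collapse = ";")
        band[i, j] <- TRUE
      }
    }
  }
  attr(sizes, "band") <- band
  sizes
}

#' @noRd
motif_cut_positions <- function(seqn, motif, cut_offset) {
  find <- function(p, off) {
    s <- BiocGenerics::start(
      Biostrings::matchPattern(p, Biostrings::DNAString(seqn)))
    s + off - 1L   # cut falls between this position and the next
  }
  cuts <- find(motif, cut_offset)
  rc <- revcomp(motif)
  if (rc != motif) {
    # cut on the complementary occurrence mirrors the offset
    cuts <- c(cuts, find(rc, nchar(motif) - cut_offset))
  }
  cuts
}

#' Predict restriction fragments and which ones a probe detects
#'
#' Cuts the genome at every occurrence of each recognition motif (both
#' strands for non-palindromic motifs), partitions it into fragments, and
#' reports the fragments sharing at least `min_overlap` bp with an
#' integrated copy of the probe sequence. An integration-free genome gives
#' an empty probe-hit list. Digestion is complete by construction.
#'
#' @param genome DNA string or `host_genome`.
#' @param enzymes named character vector `c(name = motif)`, or a character
#'   vector of names from [restriction_enzymes()].
#' @param probe probe DNA string, or a `vector_map` (probe feature sequence
#'   is extracted).
#' @param integration optional `truth_record`; if it claims integration and
#'   the probe sequence is absent from the genome, an error is raised.
#' @param topology "linear" or "circular".
#' @param min_overlap minimum probe/fragment overlap in bp (default 50).
#' @param cut_offsets named integer vector of cut offsets (default 1, or
#'   the built-in table's value for known enzyme names).
#' @return a `fragment_prediction`: list with `fragment_sizes_all`,
#'   `fragments_hit_by_probe`, `enzymes`, `cut_positions`,
#'   `probe_occurrences` (data.frame start/end).
#' @export
digest_and_probe <- function(genome, enzymes, probe, integration = NULL,
                             topology = "linear", min_overlap = 50,
                             cut_offsets = NULL) {
  if (is.list(genome)) {
    topology <- genome$topology %||% topology
    genome <- genome$sequence
  }
  topology <- match.arg(topology, c("linear", "circular"))
  seqn <- toupper(genome)
  L <- nchar(seqn)
  builtin <- restriction_enzymes()
  if (is.null(names(enzymes))) {
    idx <- match(enzymes, builtin$name)
    if (anyNA(idx)) stop("unknown enzyme name(s): ",
                         paste(enzymes[is.na(idx)], collapse = ", "), call. = FALSE)
    motifs <- stats::setNames(builtin$motif[idx], builtin$name[idx])
    offs <- stats::setNames(builtin$cut_offset[idx], builtin$name[idx])
  } else {
    motifs <- toupper(enzymes)
    offs <- stats::setNames(rep(1L, length(motifs)), names(motifs))
    known <- match(names(motifs), builtin$name)
    offs[!is.na(known)] <- builtin$cut_offset[known[!is.na(known)]]
  }
  if (!is.null(cut_offsets)) offs[names(cut_offsets)] <- cut_offsets
  for (m in motifs) assert_dna(m, "recognition motif")

  cuts <- sort(unique(unlist(
    lapply(names(motifs), function(nm) motif_cut_positions(seqn, motifs[[nm]], offs[[nm]]))
  )))
  cuts <- cuts[cuts >= 1 & cuts <= L - 1]   # a cut after position p, p in 1..L-1

  if (topology == "linear") {
    bounds <- c(0L, cuts, L)
    frag_start <- bounds[-length(bounds)] + 1L
    frag_end <- bounds[-1]
  } else if (length(cuts) == 0L) {
    frag_start <- 1L; frag_end <- L
  } else {
    # fragment i runs from cut i (exclusive) to the next cut, wrapping
    frag_start <- cuts + 1L
    frag_end <- c(cuts[-1], cuts[1] + L)
  }
  frag_len <- frag_end - frag_start + 1L

  if (is.list(probe)) {
    iv <- vector_feature(probe, "probe")
    probe <- seq_substr(probe$sequence, iv["start"], iv["end"])
  }
  probe <- toupper(probe)
  occ_one <- function(p) {
    m <- Biostrings::matchPattern(p, Biostrings::DNAString(seqn))
    data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
  }
  occs <- occ_one(probe)
  rcp <- revcomp(probe)
  if (rcp != probe) occs <- rbind(occs, occ_one(rcp))
  if (!is.null(integration) && isTRUE(integration$integrated) && nrow(occs) == 0L) {
    stop("integration claimed but probe sequence absent from the genome",
         call. = FALSE)
  }

  overlap_len <- function(fs, fe, os, oe) {
    # fragment may wrap past L (circular); split into plain intervals
    segs <- if (fe <= L) list(c(fs, fe)) else list(c(fs, L), c(1L, fe - L))
    sum(vapply(segs, function(sg) {
      max(0L, min(sg[2], oe) - max(sg[1], os) + 1L)
    }, numeric(1)))
  }
  hit <- rep(FALSE, length(frag_start))
  if (nrow(occs)) {
    for (i in seq_along(frag_start)) {
      for (j in seq_len(nrow(occs))) {
        if (overlap_len(frag_start[i], frag_end[i], occs$start[j], occs$end[j]) >=
            min(min_overlap, occs$end[j] - occs$start[j] + 1L)) {
          hit[i] <- TRUE
          break
        }
      }
    }
  }
  structure(
    list(fragment_sizes_all = frag_len,
         fragments_hit_by_probe = frag_len[hit],
         enzymes = names(motifs),
         cut_positions = cuts,
         probe_occurrences = occs),
    class = "fragment_prediction"
  )
}

#' @export
print.fragment_prediction <- function(x, ...) {
  cat("<fragment_prediction> ", length(x$fragment_sizes_all), " fragments (",
      paste(x$enzymes, collapse = "+"), "); probe detects: ",
      if (length(x$fragments_hit_by_probe))
        paste(x$fragments_hit_by_probe, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

# ---- allele classification ------------------------------------------------

#' @noRd
alignment_events <- function(pat_gapped, sub_gapped) {
  p <- strsplit(pat_gapped, "")[[1]]
  s <- strsplit(sub_gapped, "")[[1]]
  n <- length(p)
  events <- data.frame(position = integer(0), length = integer(0),
                       kind = character(0), stringsAsFactors = FALSE)
  refpos <- 0L
  i <- 1L
  matches <- 0L
  while (i <= n) {
    if (p[i] == "-" && s[i] != "-") {          # deletion from the reference
      j <- i
      while (j <= n && p[j] == "-" && s[j] != "-") j <- j + 1L
      events <- rbind(events, data.frame(position = refpos + 1L,
                                         length = j - i, kind = "deletion"))
      refpos <- refpos + (j - i)
      i <- j
    } else if (s[i] == "-" && p[i] != "-") {   # insertion relative to it
      j <- i
      while (j <= n && s[j] == "-" && p[j] != "-") j <- j + 1L
      events <- rbind(events, data.frame(position = refpos + 1L,
                                         length = j - i, kind = "insertion"))
      i <- j
    } else {
      refpos <- refpos + 1L
      if (p[i] == s[i]) {
        matches <- matches + 1L
      } else {
        events <- rbind(events, data.frame(position = refpos, length = 1L,
                                           kind = "substitution"))
      }
      i <- i + 1L
    }
  }
  list(events = events, identity = matches / n)
}

#' @noRd
event_overlaps <- function(ev, s, e) {
  if (ev$kind == "insertion") {
    # inserted bases sit immediately before reference position ev$position
    ev$position >= s && ev$position <= e + 1L
  } else {
    ev$position <= e && (ev$position + ev$length - 1L) >= s
  }
}

#' Classify target-site alleles from cloned amplicon sequences
#'
#' Each clone is globally aligned to the amplicon reference (affine gap
#' penalties) and indel/substitution events overlapping the nuclease target
#' interval are recorded. A clone is intact when no event overlaps the
#' target interval. The net indel over the target interval determines the
#' frame consequence: a non-zero multiple of 3 is `in_frame`, any other
#' non-zero net is `frameshift` (a substitution-only allele keeps
#' `frame = "intact"` while losing the intact flag). Clones aligning below
#' `min_identity` are flagged unalignable and excluded with a warning.
#'
#' @param clone_seqs character vector of clone sequences (names used as
#'   clone ids).
#' @param reference amplicon reference DNA string.
#' @param target_interval `c(start, end)` of the nuclease target on the
#'   reference.
#' @param min_identity alignment identity floor (default 0.7).
#' @param match,mismatch,gap_open,gap_extend alignment scoring
#'   (defaults 2, -3, 5, 2; gap penalties positive).
#' @return an `allele_calls` list; each element has `clone_id`,
#'   `indel_events` (data.frame position/length/kind, reference
#'   coordinates), `net_indel`, `frame`, `intact`, `identity`,
#'   `unalignable`. Use [as.data.frame()] for a summary table.
#' @export
classify_alleles <- function(clone_seqs, reference, target_interval,
                             min_identity = 0.7, match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2) {
  if (length(clone_seqs) == 0L) stop("no clone sequences", call. = FALSE)
  reference <- toupper(reference)
  s <- as.integer(target_interval[1]); e <- as.integer(target_interval[2])
  if (s < 1 || e > nchar(reference) || s > e) {
    stop("target_interval outside the reference", call. = FALSE)
  }
  ids <- names(clone_seqs)
  if (is.null(ids)) ids <- paste0("clone", seq_along(clone_seqs))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  calls <- vector("list", length(clone_seqs))
  for (i in seq_along(clone_seqs)) {
    aln <- Biostrings::pairwiseAlignment(
      toupper(clone_seqs[[i]]), reference, type = "global",
      substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend
    )
    walked <- alignment_events(
      as.character(Biostrings::alignedPattern(aln)),
      as.character(Biostrings::alignedSubject(aln))
    )
    ev <- walked$events
    if (walked$identity < min_identity) {
      warning("clone ", ids[i], " aligns at ",
              round(100 * walked$identity, 1), "% identity; excluded",
              call. = FALSE)
      calls[[i]] <- structure(
        list(clone_id = ids[i], indel_events = ev, net_indel = NA_integer_,
             frame = NA_character_, intact = NA, identity = walked$identity,
             unalignable = TRUE),
        class = "allele_call")
      next
    }
    in_target <- if (nrow(ev)) {
      vapply(seq_len(nrow(ev)), function(r) event_overlaps(ev[r, ], s, e), logical(1))
    } else {
      logical(0)
    }
    evt <- ev[in_target, , drop = FALSE]
    net <- sum(ifelse(evt$kind == "insertion", evt$length,
                      ifelse(evt$kind == "deletion", -evt$length, 0L)))
    frame <- if (net != 0 && net %% 3 == 0) "in_frame"
             else if (net %% 3 != 0) "frameshift"
             else "intact"
    calls[[i]] <- structure(
      list(clone_id = ids[i], indel_events = ev, net_indel = as.integer(net),
           frame = frame, intact = nrow(evt) == 0L,
           identity = walked$identity, unalignable = FALSE),
      class = "allele_call")
  }
  structure(calls, class = "allele_calls")
}

#' @export
as.data.frame.allele_calls <- function(x, ...) {
  do.call(rbind, lapply(x, function(cl) {
    data.frame(clone_id = cl$clone_id, n_events = nrow(cl$indel_events),
               net_indel = cl$net_indel, frame = cl$frame, intact = cl$intact,
               identity = cl$identity, unalignable = cl$unalignable,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.allele_calls <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' Summarize a line's editing status from its allele calls
#'
#' A line is a complete disruptant when no intact allele is observed among
#' its sequenced clones and at least one mutated clone is present. Clone
#' sampling cannot distinguish identical mutations on homologous
#' chromosomes, so only distinct observed alleles are counted, never copy
#' numbers.
#'
#' @param calls an `allele_calls` object.
#' @param line_id identifier.
#' @return a `line_status`: list with `line_id`, `n_clones`, `n_intact`,
#'   `status` in `{"complete_disruptant", "partial", "unedited"}`.
#' @export
line_status <- function(calls, line_id = "line") {
  if (length(calls) == 0L) stop("no allele calls", call. = FALSE)
  usable <- Filter(function(cl) !isTRUE(cl$unalignable), calls)
  if (length(usable) == 0L) stop("no alignable clones", call. = FALSE)
  n <- length(usable)
  n_intact <- sum(vapply(usable, function(cl) isTRUE(cl$intact), logical(1)))
  status <- if (n_intact == 0L) "complete_disruptant"
            else if (n_intact == n) "unedited"
            else "partial"
  structure(list(line_id = line_id, n_clones = n, n_intact = n_intact,
                 status = status),
            class = "line_status")
}

#' @export
print.line_status <- function(x, ...) {
  cat("<line_status> ", x$line_id, ": ", x$status, " (", x$n_intact, "/",
      x$n_clones, " intact)\n", sep = "")
  invisible(x)
}

#' Off-target check against a homologous locus
#'
#' Classifies the same clones against the homolog's reference; by default
#' the whole homolog reference is the interval of interest. An unedited
#' off-target locus gives all-intact calls.
#'
#' @param clone_seqs character vector of clone sequences.
#' @param homolog_reference homolog amplicon reference.
#' @param target_interval optional interval on the homolog (default: the
#'   whole reference).
#' @param ... passed to [classify_alleles()].
#' @return an `allele_calls` object.
#' @export
offtarget_check <- function(clone_seqs, homolog_reference,
                            target_interval = NULL, ...) {
  if (is.null(target_interval)) {
    target_interval <- c(1L, nchar(homolog_reference))
  }
  classify_alleles(clone_seqs, homolog_reference, target_interval, ...)
}

#' Editing efficiency per regenerated shoot
#'
#' `100 * n_candidates / n_regenerated`, rounded to one decimal —
#' candidates being the target-site-positive, transgene-free lines among
#' the regenerated shoots.
#'
#' @param n_candidates candidate line count (0 <= n <= n_regenerated).
#' @param n_regenerated regenerated shoot count (> 0).
#' @return percentage rounded to one decimal.
#' @examples
#' editing_efficiency(5, 195)  # 2.6
#' editing_efficiency(2, 224)  # 0.9
#' @export
editing_efficiency <- function(n_candidates, n_regenerated) {
  if (any(n_regenerated <= 0)) stop("n_regenerated must be positive", call. = FALSE)
  if (any(n_candidates < 0 | n_candidates > n_regenerated)) {
    stop("n_candidates must lie in [0, n_regenerated]", call. = FALSE)
  }
  round(100 * n_candidates / n_regenerated, 1)
}
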