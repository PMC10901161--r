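# Canned simulation scenarios used for calibration of the statistic.

#' Null-calibration G track
#'
#' Type-I calibration of the per-position G-test requires every vector
#' position to carry hits in both read sets; a genome sharing no sequence
#' with the vector yields all-zero tables (G = 0) and is uninformative
#' about the statistic. This scenario therefore builds a genome carrying a
#' full-length homologous copy of the vector (the circular sequence plus
#' its first k-1 bases, so wrap-around positions are represented) between
#' random flanks, draws two independent read sets from it — equivalent to
#' randomly splitting one sequencing run — and tests them against each
#' other. The null of equal hit proportions holds at every position, so
#' the fraction of significant positions among covered positions estimates
#' the realized type-I error.
#'
#' Reads are `k` bp long so that each read carries exactly one k-mer and
#' per-position significance indicators are independent, which makes the
#' binomial reference distribution for the significant fraction exact. At
#' the default depth each arm holds roughly `depth / k` hits per position,
#' comfortably inside chi-square territory.
#'
#' @param vector a `vector_map`.
#' @param k k-mer size (also the simulated read length).
#' @param depth fold-coverage per arm (default 1000).
#' @param flank random flank length on each side (default 1000 bp).
#' @param gc flank GC fraction.
#' @param seed integer seed (the control arm derives its own stream).
#' @param alpha significance level.
#' @return a `g_track` over the vector's circular position set.
#' @export
calibration_track <- function(vector, k, depth = 1000, flank = 1000,
                              gc = 0.36, seed = 1, alpha = 0.01) {
  vseq <- vector$sequence
  flanks <- with_seed(seed + 900007, random_dna(2L * flank, gc))
  genome <- structure(
    list(sequence = paste0(substr(flanks, 1L, flank),
                           vseq, substr(vseq, 1L, k - 1L),
                           substr(flanks, flank + 1L, 2L * flank)),
         name = "calibration"),
    class = "host_genome"
  )
  arm1 <- simulate_reads(genome, depth, k, seed = seed, source_name = "half1")
  arm2 <- simulate_reads(genome, depth, k, seed = seed + 500009L,
                         source_name = "half2")
  idx <- build_index(vector, k)
  per_position_g(scan_reads(arm1, idx), scan_reads(arm2, idx), alpha = alpha)
}

#' Fraction of significant positions among testable positions
#'
#' Positions with no hit in either read set are untestable (their table is
#' degenerate in the hit column) and are excluded from the denominator.
#'
#' @param track a `g_track`.
#' @return proportion of testable positions flagged significant.
#' @export
significant_fraction <- function(track) {
  testable <- (track$counts_sample + track$counts_control) > 0
  if (!any(testable)) return(NA_real_)
  mean(track$significant[testable])
}
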