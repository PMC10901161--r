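# Per-position G-test of an edited line against the wild-type control.
#
# At each vector position the 2x2 table is
#     (hits_sample, library_sample - hits_sample)
#     (hits_control, library_control - hits_control)
# which normalizes for unequal sequencing depth through the margins. Under
# the null of equal hit proportions the G-statistic is chi-square with 1 df,
# so the 1% significance threshold is qchisq(0.99, 1) = 6.634...; calls
# exceeding the threshold ("peaks") only count as evidence of integration
# when they replicate across independent sequencing runs.

#' G-statistic (log-likelihood ratio) for 2x2 tables
#'
#' `G = 2 * sum(O * ln(O / E))` over the four cells, with expected values
#' from the margins and the convention `0 * ln(0) = 0`. Vectorized over
#' tables. A table with a zero row sum is untestable and yields `NA`
#' (treated downstream as non-significant).
#'
#' @param a,b,c,d cell counts: `a` hits in the sample, `b` its library size
#'   minus `a`, `c` hits in the control, `d` its library size minus `c`.
#' @return numeric vector of G values (>= 0, or `NA` for untestable tables).
#' @examples
#' g_statistic(10, 990, 10, 990)   # 0: observed equals expected
#' g_statistic(10, 990, 0, 1000)   # ~13.91
#' @export
g_statistic <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  # double precision: margin products overflow 32-bit integers at NGS scale
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n  <- a + b + c + d
  r1 <- a + b; r2 <- c + d
  c1 <- a + c; c2 <- b + d
  O <- cbind(a, b, c, d)
  E <- cbind(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  term <- ifelse(O == 0, 0, O * log(O / E))
  g <- 2 * rowSums(term)
  g[r1 == 0 | r2 == 0] <- NA_real_
  # guard tiny negative round-off when observed ~ expected
  g[!is.na(g) & g < 0 & g > -1e-9] <- 0
  unname(g)
}

#' Chi-square critical value for the G-test
#'
#' Upper `alpha`-quantile of the chi-square distribution with `df` degrees
#' of freedom; with the defaults this is the 1% threshold 6.634... for a
#' 2x2 table.
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1); 1 for a 2x2 table.
#' @return the critical G value.
#' @examples
#' critical_value(0.01, 1)  # 6.6349
#' @export
critical_value <- function(alpha = 0.01, df = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  qchisq(1 - alpha, df = df)
}

#' Per-position G track of a sample profile against a control
#'
#' Builds the depth-normalizing 2x2 table at every vector position and
#' flags positions whose G value strictly exceeds the critical value
#' (ties at the threshold are non-significant). Positions where the sample
#' hit proportion exceeds the control's are additionally flagged
#' `sample_excess`; only those count toward integration verdicts, since the
#' question is presence of vector sequence in the edited line.
#'
#' @param sample,control `kmer_profile` objects over the same index
#'   (same k, topology and position set).
#' @param alpha significance level (default 0.01).
#' @return a `g_track`: list with `positions`, `g_values`, `alpha`,
#'   `critical_value`, `significant`, `sample_excess`, counts and library
#'   sizes for both profiles, `k`, `vector_length`, `topology`,
#'   `sample_name`, `control_name`.
#' @export
per_position_g <- function(sample, control, alpha = 0.01) {
  stopifnot(inherits(sample, "kmer_profile"), inherits(control, "kmer_profile"))
  if (sample$k != control$k) stop("profiles built with different k", call. = FALSE)
  if (!identical(sample$positions, control$positions)) {
    stop("profiles cover different position sets", call. = FALSE)
  }
  a <- sample$counts;  n1 <- sample$library_size
  c <- control$counts; n2 <- control$library_size
  g <- g_statistic(a, n1 - a, c, n2 - c)
  crit <- critical_value(alpha, df = 1)
  sig <- !is.na(g) & g > crit
  p1 <- if (n1 > 0) a / n1 else rep(0, length(a))
  p2 <- if (n2 > 0) c / n2 else rep(0, length(c))
  structure(
    list(positions = sample$positions, g_values = g, alpha = alpha,
         critical_value = crit, significant = sig,
         sample_excess = p1 > p2,
         counts_sample = a, counts_control = c,
         library_sample = n1, library_control = n2,
         k = sample$k, vector_length = sample$vector_length,
         topology = sample$topology,
         sample_name = sample$sample_name, control_name = control$sample_name),
    class = "g_track"
  )
}

#' @export
print.g_track <- function(x, ...) {
  cat("<g_track> ", x$sample_name, " vs ", x$control_name, ": k=", x$k,
      ", ", sum(x$significant), "/", length(x$positions),
      " positions above G=", round(x$critical_value, 3),
      " (alpha=", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Call candidate integration segments from a G track
#'
#' Maximal runs of significant positions, merging runs separated by at most
#' `max_gap` non-significant positions; each call's end is extended by
#' `k - 1` because a hit at a starting position implies vector sequence
#' through `start + k - 1`. Isolated single significant positions are
#' reported as calls. By default only sample-excess positions are used.
#'
#' On a circular vector, runs touching both sides of the origin are merged
#' when the gap across it is within `max_gap`; such origin-spanning calls
#' are reported on the unrolled axis with `vector_end` greater than the
#' vector length (the same convention origin-spanning PCR products use).
#'
#' @param track a `g_track`.
#' @param max_gap maximum gap merged into one call (default `k - 1`).
#' @param sample_excess_only restrict to positions where the sample hit
#'   proportion exceeds the control's (default TRUE).
#' @return data.frame with columns `vector_start`, `vector_end`,
#'   `n_significant`, `max_g`, `replicated` (initialized FALSE), carrying
#'   the vector length and topology as attributes.
#' @export
call_segments <- function(track, max_gap = NULL, sample_excess_only = TRUE) {
  stopifnot(inherits(track, "g_track"))
  k <- track$k
  L <- track$vector_length
  if (is.null(max_gap)) max_gap <- k - 1L
  if (max_gap < 0) stop("max_gap must be >= 0", call. = FALSE)
  use <- track$significant
  if (sample_excess_only) use <- use & track$sample_excess
  pos <- sort(track$positions[use])
  out_attrs <- function(calls) {
    attr(calls, "vector_length") <- L
    attr(calls, "topology") <- track$topology
    calls
  }
  empty <- data.frame(vector_start = integer(0), vector_end = integer(0),
                      n_significant = integer(0), max_g = numeric(0),
                      replicated = logical(0))
  if (length(pos) == 0L) return(out_attrs(empty))
  brk <- which(diff(pos) - 1L > max_gap)
  run_start <- pos[c(1L, brk + 1L)]
  run_end <- pos[c(brk, length(pos))]
  nruns <- length(run_start)
  wrap <- track$topology == "circular" && nruns >= 2L &&
    (run_start[1L] + L) - run_end[nruns] - 1L <= max_gap
  gmap <- track$g_values
  names(gmap) <- track$positions
  one_call <- function(s, e) {
    # e may exceed L for an origin-spanning run (unrolled coordinates)
    in_run <- if (e <= L) pos[pos >= s & pos <= e] else {
      pos[pos >= s | pos <= e - L]
    }
    end <- e + k - 1L
    end <- if (track$topology == "linear") min(end, L) else min(end, s + L - 1L)
    data.frame(vector_start = s, vector_end = end,
               n_significant = length(in_run),
               max_g = max(gmap[as.character(in_run)]),
               replicated = FALSE)
  }
  if (wrap) {
    merged <- one_call(run_start[nruns], run_end[1L] + L)
    keep <- seq_len(nruns)[-c(1L, nruns)]
    calls <- c(list(merged),
               lapply(keep, function(i) one_call(run_start[i], run_end[i])))
  } else {
    calls <- lapply(seq_len(nruns), function(i) one_call(run_start[i], run_end[i]))
  }
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$vector_start), , drop = FALSE]
  rownames(calls) <- NULL
  out_attrs(calls)
}

#' Intersect peak calls from two independent sequencing runs
#'
#' Returns the calls from run 1 whose span overlaps any call in run 2,
#' marked `replicated = TRUE`. The transgene-free verdict requires this
#' list to be empty: replicate intersection is the false-positive control,
#' in place of any per-position multiplicity correction.
#'
#' @param calls_run1,calls_run2 data.frames from [call_segments()].
#' @return the replicated subset of `calls_run1`.
#' @export
intersect_replicates <- function(calls_run1, calls_run2) {
  if (nrow(calls_run1) == 0L || nrow(calls_run2) == 0L) {
    return(calls_run1[integer(0), , drop = FALSE])
  }
  L <- attr(calls_run1, "vector_length")
  if (is.null(L)) L <- attr(calls_run2, "vector_length")
  # origin-spanning calls (end beyond L) are unrolled into two segments
  segs <- function(s, e) {
    if (!is.null(L) && e > L) list(c(s, L), c(1L, e - L)) else list(c(s, e))
  }
  ov <- vapply(seq_len(nrow(calls_run1)), function(i) {
    s1 <- segs(calls_run1$vector_start[i], calls_run1$vector_end[i])
    any(vapply(seq_len(nrow(calls_run2)), function(j) {
      s2 <- segs(calls_run2$vector_start[j], calls_run2$vector_end[j])
      any(vapply(s1, function(a) {
        any(vapply(s2, function(b) a[1] <= b[2] && a[2] >= b[1], logical(1)))
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  out <- calls_run1[ov, , drop = FALSE]
  if (nrow(out)) out$replicated <- TRUE
  rownames(out) <- NULL
  out
}

#' Write a per-position G track as TSV
#'
#' Columns: `position`, `count_sample`, `count_control`, `G`,
#' `significant`.
#'
#' @param track a `g_track`.
#' @param path output file.
#' @export
write_gtrack <- function(track, path) {
  write.table(
    data.frame(position = track$positions,
               count_sample = track$counts_sample,
               count_control = track$counts_control,
               G = track$g_values,
               significant = track$significant),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Plot counts and G tracks for a sample/control comparison
#'
#' Two stacked panels: per-position hit counts for both read sets, and the
#' per-position G values with the significance threshold drawn as a
#' horizontal line; positions above the line are drawn in red.
#'
#' @param track a `g_track`.
#' @param main title.
#' @importFrom graphics abline legend lines par points
#' @export
plot_gtrack <- function(track, main = NULL) {
  if (is.null(main)) {
    main <- paste0(track$sample_name, " vs ", track$control_name,
                   " (k=", track$k, ")")
  }
  op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(par(op), add = TRUE)
  plot(track$positions, track$counts_sample, type = "h", col = "grey40",
       xlab = "", ylab = "count", main = main)
  lines(track$positions, track$counts_control, type = "h", col = "steelblue")
  legend("topright", legend = c(track$sample_name, track$control_name),
         col = c("grey40", "steelblue"), lty = 1, bty = "n", cex = 0.8)
  gv <- ifelse(is.na(track$g_values), 0, track$g_values)
  cols <- ifelse(track$significant, "red", "grey40")
  plot(track$positions, gv, type = "h", col = cols,
       xlab = "vector position", ylab = "G")
  abline(h = track$critical_value, col = "red")
  invisible(track)
}
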