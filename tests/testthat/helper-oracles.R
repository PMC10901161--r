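# Independent brute-force oracles, deliberately sharing no code with the
# package internals (string reverse + chartr instead of Biostrings, plain
# loops instead of the compiled scanner).

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

naive_position_kmers <- function(seqn, k, topology = "linear") {
  L <- nchar(seqn)
  if (topology == "circular") {
    ext <- paste0(seqn, substr(seqn, 1, k - 1))
    pos <- seq_len(L)
  } else {
    ext <- seqn
    pos <- seq_len(L - k + 1)
  }
  vapply(pos, function(p) substr(ext, p, p + k - 1), character(1))
}

# read-level presence counts by exhaustive substring comparison
naive_scan <- function(reads, seqn, k, topology = "linear") {
  kmers <- naive_position_kmers(seqn, k, topology)
  vapply(kmers, function(km) {
    rckm <- rc_chr(km)
    sum(vapply(reads, function(r) {
      grepl(km, r, fixed = TRUE) || grepl(rckm, r, fixed = TRUE)
    }, logical(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

# scalar direct evaluation of 2 * sum(O * ln(O/E))
direct_g <- function(a, b, c, d) {
  O <- c(a, b, c, d)
  n <- sum(O)
  E <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  tot <- 0
  for (i in 1:4) if (O[i] > 0) tot <- tot + O[i] * log(O[i] / E[i])
  2 * tot
}

random_tables <- function(n, seed) {
  set.seed(seed)
  data.frame(a = rpois(n, 20) + 1L, b = rpois(n, 2000) + 1L,
             c = rpois(n, 20) + 1L, d = rpois(n, 2000) + 1L)
}

random_dna_chr <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force run enumeration for segment calling
naive_segments <- function(sig_positions, k, max_gap, vector_length) {
  sp <- sort(sig_positions)
  if (length(sp) == 0) return(NULL)
  runs <- list(c(sp[1], sp[1]))
  for (p in sp[-1]) {
    last <- runs[[length(runs)]]
    if (p - last[2] - 1 <= max_gap) {
      runs[[length(runs)]][2] <- p
    } else {
      runs[[length(runs) + 1]] <- c(p, p)
    }
  }
  data.frame(vector_start = vapply(runs, `[`, numeric(1), 1),
             vector_end = pmin(vapply(runs, `[`, numeric(1), 2) + k - 1,
                               vector_length))
}

# distance between two positions on a circle of length L
circ_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  min(d, L - d)
}
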