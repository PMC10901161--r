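make_pair <- function(f, r, id = "PCR1") {
  data.frame(set_id = id, forward = f, reverse = r, stringsAsFactors = FALSE)
}

test_that("in-silico PCR finds a constructed amplicon and nothing elsewhere", {
  set.seed(1)
  f <- random_dna_chr(20, 101)
  r <- random_dna_chr(20, 102)
  insert <- random_dna_chr(100, 103)
  template <- paste0(random_dna_chr(150, 104), f, insert, rc_chr(r),
                     random_dna_chr(150, 105))
  hits <- insilico_pcr(template, make_pair(f, r))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$length, 20 + 100 + 20)
  expect_equal(hits$start, 151)
  expect_equal(hits$end, 151 + 139)

  none <- insilico_pcr(random_dna_chr(500, 106), make_pair(f, r))
  expect_equal(nrow(none), 0)
})

test_that("a duplicated forward site yields the products enumerated by brute force", {
  f <- random_dna_chr(20, 111)
  r <- random_dna_chr(20, 112)
  spacer1 <- random_dna_chr(60, 113)
  spacer2 <- random_dna_chr(200, 114)
  template <- paste0("ACGT", f, spacer1, f, spacer2, rc_chr(r), "ACGT")
  hits <- insilico_pcr(template, make_pair(f, r))
  # both forward sites pair with the single reverse site: two product sizes
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$length,
                  c(20 + 60 + 20 + 200 + 20, 20 + 200 + 20))
})

test_that("PCR hits survive reverse-complementing the template", {
  f <- random_dna_chr(22, 121)
  r <- random_dna_chr(18, 122)
  template <- paste0(random_dna_chr(80, 123), f, random_dna_chr(120, 124),
                     rc_chr(r), random_dna_chr(80, 125))
  fwd <- insilico_pcr(template, make_pair(f, r))
  revd <- insilico_pcr(rc_chr(template), make_pair(f, r))
  expect_equal(sort(revd$length), sort(fwd$length))
  expect_setequal(revd$orientation, "R+/F-")
})

test_that("3'-exact and mismatch constraints gate primer matching", {
  f <- random_dna_chr(20, 131)
  r <- random_dna_chr(20, 132)
  template <- paste0("AAAA", f, random_dna_chr(100, 133), rc_chr(r), "AAAA")
  # corrupt the 3'-terminal base of the forward primer: no product
  f_bad3 <- paste0(substr(f, 1, 19), chartr("ACGT", "TGCA", substr(f, 20, 20)))
  expect_equal(nrow(insilico_pcr(template, make_pair(f_bad3, r))), 0)
  # two internal mismatches are tolerated, three are not
  mutate_at <- function(p, at) {
    for (i in at) substr(p, i, i) <- chartr("ACGT", "TGCA", substr(p, i, i))
    p
  }
  expect_equal(nrow(insilico_pcr(template, make_pair(mutate_at(f, c(3, 7)), r))), 1)
  expect_equal(nrow(insilico_pcr(template,
                                 make_pair(mutate_at(f, c(3, 7, 11)), r))), 0)
})

test_that("circular templates amplify across the origin", {
  f <- random_dna_chr(20, 141)
  r <- random_dna_chr(20, 142)
  # product spans the origin: forward sits near the end, reverse near the start
  template <- paste0(random_dna_chr(30, 143), rc_chr(r),
                     random_dna_chr(400, 144), f, random_dna_chr(30, 145))
  expect_equal(nrow(insilico_pcr(template, make_pair(f, r), topology = "linear")), 0)
  hits <- insilico_pcr(template, make_pair(f, r), topology = "circular")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$length, 20 + 60 + 20)   # through the origin
})

test_that("the presence matrix reproduces the truth of a known integration", {
  v <- make_vector(2000, 3000, seed = 151)
  h <- make_host_genome(20000, 0.36, seed = 152)
  res <- integrate_vector(h, v, c(1, 2000), host_locus = 12000)

  # tiled vector panel: 200 bp amplicons every 500 bp around the circle
  starts <- seq(1, 4501, by = 500)
  panel <- do.call(rbind, lapply(seq_along(starts), function(i) {
    s <- starts[i]
    make_pair(substr(v$sequence, s, s + 19),
              rc_chr(substr(v$sequence, s + 180, s + 199)),
              id = sprintf("PCR%d", i))
  }))
  # genomic control primers target a host locus far from the insertion
  control <- make_pair(substr(h$sequence, 3000, 3019),
                       rc_chr(substr(h$sequence, 3180, 3199)), id = "PCR0")
  panel <- rbind(control, panel)

  templates <- list(vector = v, naive_host = h, edited = res$genome)
  mat <- presence_matrix(templates, panel)
  band <- attr(mat, "band")

  # vector panel amplifies on the vector, never on the naive host
  expect_true(all(band[paste0("PCR", seq_along(starts)), "vector"]))
  expect_false(any(band[paste0("PCR", seq_along(starts)), "naive_host"]))
  # on the edited genome exactly the sets fully inside the integrated interval band
  inside <- starts + 199 <= 2000
  expect_identical(unname(band[paste0("PCR", seq_along(starts)), "edited"]),
                   inside)
  # the control set amplifies on every host-derived template
  expect_true(all(band["PCR0", c("naive_host", "edited")]))
  expect_false(band["PCR0", "vector"])
})

test_that("primer panels round-trip through TSV with validation", {
  dir <- withr::local_tempdir()
  panel <- rbind(make_pair(random_dna_chr(20, 161), random_dna_chr(20, 162), "A"),
                 make_pair(random_dna_chr(20, 163), random_dna_chr(20, 164), "B"))
  path <- file.path(dir, "panel.tsv")
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_primer_panel(path)
  expect_equal(got$set_id, c("A", "B"))
  panel$set_id <- c("A", "A")
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_primer_panel(path), "duplicate")
})

test_that("restriction digestion partitions linear and circular genomes exactly", {
  # cuts fall after positions 20 and 60 (motif GGATCC cut after its first base)
  base <- strrep("A", 100)
  substr(base, 20, 25) <- "GGATCC"
  substr(base, 60, 65) <- "GGATCC"
  pred <- digest_and_probe(base, c(BamHI = "GGATCC"), probe = strrep("C", 60))
  expect_equal(pred$fragment_sizes_all, c(20, 40, 40))
  expect_equal(sum(pred$fragment_sizes_all), 100)
  expect_equal(length(pred$fragments_hit_by_probe), 0)

  circ <- digest_and_probe(base, c(BamHI = "GGATCC"), probe = strrep("C", 60),
                           topology = "circular")
  expect_equal(sort(circ$fragment_sizes_all), c(40, 60))
  expect_equal(sum(circ$fragment_sizes_all), 100)

  uncut <- digest_and_probe(base, c(X = "GGGGGGGG"), probe = strrep("C", 60),
                            topology = "circular")
  expect_equal(uncut$fragment_sizes_all, 100)
})

test_that("non-palindromic motifs are cut on both strands", {
  base <- strrep("T", 80)
  substr(base, 30, 35) <- "GACGTC"    # palindromic: one cut
  p1 <- digest_and_probe(base, c(AatII = "GACGTC"), probe = strrep("C", 60))
  expect_equal(length(p1$cut_positions), 1)

  base2 <- strrep("T", 80)
  substr(base2, 30, 34) <- "GGTCA"    # non-palindromic motif
  substr(base2, 60, 64) <- rc_chr("GGTCA")
  p2 <- digest_and_probe(base2, c(Z = "GGTCA"), probe = strrep("C", 60))
  expect_equal(length(p2$cut_positions), 2)
})

test_that("probe fragment prediction matches hand-computed flanking-cut distances", {
  v <- make_vector(2000, 3000, seed = 171, gc = 0.5)
  h <- make_host_genome(20000, 0.36, seed = 172)
  res <- integrate_vector(h, v, c(1, 2000), host_locus = 10000)
  probe_iv <- vector_feature(v, "probe")
  probe_seq <- substr(v$sequence, probe_iv["start"], probe_iv["end"])

  pred <- digest_and_probe(res$genome, c("BamHI", "HindIII"), probe = v,
                           integration = res$truth)
  # independent expectation from hand-computed cut-site arithmetic: the
  # fragments overlapping the integrated probe copy by >= 50 bp
  ps <- 10000 + probe_iv[["start"]]
  pe <- 10000 + probe_iv[["end"]]
  bounds <- sort(unique(c(0, pred$cut_positions, nchar(res$genome$sequence))))
  fs <- head(bounds, -1) + 1
  fe <- bounds[-1]
  ov <- pmin(fe, pe) - pmax(fs, ps) + 1
  expected_hits <- (fe - fs + 1)[ov >= 50]
  expect_gt(length(expected_hits), 0)
  expect_setequal(pred$fragments_hit_by_probe, expected_hits)

  # an integration-free genome detects nothing
  clean <- digest_and_probe(h, c("BamHI", "HindIII"), probe = v)
  expect_equal(length(clean$fragments_hit_by_probe), 0)
  expect_error(digest_and_probe(h, c("BamHI", "HindIII"), probe = v,
                                integration = res$truth), "probe sequence absent")
})

test_that("allele classification recovers constructed indels and frames", {
  ref <- random_dna_chr(400, 181)
  target <- c(180, 220)

  same <- classify_alleles(c(clean = ref), ref, target)
  expect_true(same[[1]]$intact)
  expect_equal(nrow(same[[1]]$indel_events), 0)
  expect_identical(same[[1]]$frame, "intact")

  del6 <- paste0(substr(ref, 1, 194), substr(ref, 201, 400))
  d <- classify_alleles(c(d6 = del6), ref, target)[[1]]
  expect_false(d$intact)
  expect_equal(d$net_indel, -6)
  expect_identical(d$frame, "in_frame")
  expect_equal(sum(d$indel_events$kind == "deletion"), 1)
  expect_equal(d$indel_events$length[d$indel_events$kind == "deletion"], 6)

  ins1 <- paste0(substr(ref, 1, 200), "A", substr(ref, 201, 400))
  i <- classify_alleles(c(i1 = ins1), ref, target)[[1]]
  expect_false(i$intact)
  expect_equal(i$net_indel, 1)
  expect_identical(i$frame, "frameshift")

  # a substitution inside the target breaks intactness but not the frame
  subst <- ref
  substr(subst, 200, 200) <- chartr("ACGT", "TGCA", substr(ref, 200, 200))
  s <- classify_alleles(c(s1 = subst), ref, target)[[1]]
  expect_false(s$intact)
  expect_equal(s$net_indel, 0)
  expect_identical(s$frame, "intact")

  # events outside the target interval do not affect the intact flag
  outside <- paste0(substr(ref, 1, 47), substr(ref, 51, 400))
  o <- classify_alleles(c(far = outside), ref, target)[[1]]
  expect_true(o$intact)
  expect_equal(nrow(o$indel_events), 1)
})

test_that("clones aligning below the identity floor are excluded with a warning", {
  ref <- random_dna_chr(300, 191)
  junk <- random_dna_chr(300, 192)
  expect_warning(calls <- classify_alleles(c(bad = junk, ok = ref), ref,
                                           c(100, 150)),
                 "excluded")
  expect_true(calls[[1]]$unalignable)
  expect_false(calls[[2]]$unalignable)
  st <- line_status(calls)
  expect_equal(st$n_clones, 1)   # only the alignable clone counts
})

test_that("line status distinguishes complete disruptants, partials and unedited lines", {
  ref <- random_dna_chr(400, 201)
  target <- c(180, 220)
  del6 <- paste0(substr(ref, 1, 194), substr(ref, 201, 400))
  ins1 <- paste0(substr(ref, 1, 200), "A", substr(ref, 201, 400))

  all_mut <- classify_alleles(c(a = del6, b = ins1), ref, target)
  expect_identical(line_status(all_mut, "L1")$status, "complete_disruptant")

  mix <- classify_alleles(c(a = del6, b = ref), ref, target)
  expect_identical(line_status(mix, "L2")$status, "partial")

  none <- classify_alleles(c(a = ref, b = ref), ref, target)
  expect_identical(line_status(none, "L3")$status, "unedited")
  expect_error(line_status(list()), "no allele calls")
})

test_that("off-target screening reports homolog mutations and clean loci", {
  homolog <- random_dna_chr(350, 211)
  clean <- offtarget_check(c(c1 = homolog, c2 = homolog), homolog)
  expect_true(all(vapply(clean, function(x) x$intact, logical(1))))

  del3 <- paste0(substr(homolog, 1, 150), substr(homolog, 154, 350))
  mut <- offtarget_check(c(c1 = del3), homolog)
  expect_false(mut[[1]]$intact)
  expect_equal(mut[[1]]$net_indel, -3)
})

test_that("editing efficiency reproduces the per-shoot percentage arithmetic", {
  expect_equal(editing_efficiency(1, 95), 1.1)
  expect_equal(editing_efficiency(1, 98), 1.0)
  expect_equal(editing_efficiency(0, 100), 0.0)
  expect_error(editing_efficiency(5, 0), "positive")
  expect_error(editing_efficiency(6, 5), "n_candidates")
})
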