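# transfree

Transgene-freedom verification for genome-edited plant lines.

When a crop is edited by transient nuclease expression — for example a
vegetatively propagated potato cultivar, where no null segregant can ever
be bred out — regulatory certification requires sequence-level evidence
that no fragment of the transformation vector (T-DNA *or* backbone)
persists in the genome. `transfree` implements the computational evidence
channels for that certification:

* **Per-position k-mer screen.** Every position *i* of the circular
  binary vector is represented by its canonical k-mer (lexicographic
  minimum of the k-mer and its reverse complement, with wrap-around
  windows at the origin). Whole-genome reads from the edited line and a
  wild-type control are scanned, counting for each position the number of
  reads carrying its k-mer.
* **Per-position G-test.** At each position the 2×2 table
  (hits, library − hits) for sample vs. control is tested with the
  log-likelihood-ratio statistic *G* = 2 Σ *O* ln(*O*/*E*) (0 ln 0 = 0),
  chi-square with 1 df; the 1% threshold is qchisq(0.99, 1) = 6.6349.
  Runs of significant sample-excess positions become candidate
  integration segments (ends extended by k − 1).
* **Replicate intersection.** No per-position multiplicity correction;
  instead, only peaks recurring at overlapping positions in an
  independent re-sequencing run count. The transgene-free verdict
  requires an empty replicated peak list at every configured k (20 and
  25 by default).
* **Orthogonal checks.** Tiled in-silico PCR over a primer panel
  (band/no-band matrix with a genomic control set), restriction-digest +
  probe fragment prediction (the hybridization expectation), target-site
  allele classification (indels, reading frame, complete-disruptant
  status) and off-target screening, plus the per-shoot editing-efficiency
  arithmetic.
* **Synthetic data with ground truth.** Host genomes, annotated vectors,
  integration events, homology tracts and error-bearing shotgun reads, so
  the whole pipeline is testable at desk scale.

## Worked example

Simulate a 50 kb host, a 5 kb vector (2 kb T-DNA + 3 kb backbone), insert
the T-DNA at host position 25,000, sequence edited line and wild type
twice at 30× and verify:

```r
library(transfree)

host   <- make_host_genome(50000, gc = 0.36, seed = 2)
vec    <- make_vector(2000, 3000, seed = 20)
edited <- integrate_vector(host, vec, c(1, 2000), host_locus = 25000)

verdict <- run_verification(list(
  vector         = vec,
  reads_sample   = simulate_reads(edited$genome, 30, 100, seed = 3),
  reads_control  = simulate_reads(host, 30, 100, seed = 4),
  reads_sample2  = simulate_reads(edited$genome, 30, 100, seed = 5),
  reads_control2 = simulate_reads(host, 30, 100, seed = 6)
))
verdict
#> <verdict> transgene_free = FALSE
#>   k=20: 1 peak(s) run1, 1 replicated
#>   k=25: 1 peak(s) run1, 1 replicated

verdict$per_k[["20"]]$replicated
#>   vector_start vector_end n_significant    max_g replicated
#> 1            1       2000          1981 49.89902       TRUE
```

The replicated call recovers the integrated interval [1, 2000] exactly:
1981 significant positions (positions 1982–2000 have their k-mers
truncated by the junction) extended by k − 1 = 19. Re-running with reads
drawn from the unedited host instead returns

```r
#> <verdict> transgene_free = TRUE
#>   k=20: 0 peak(s) run1, 0 replicated
#>   k=25: 0 peak(s) run1, 0 replicated
```

Lower-level entry points (`build_index()`, `scan_reads()`,
`per_position_g()`, `call_segments()`, `intersect_replicates()`,
`insilico_pcr()`, `digest_and_probe()`, `classify_alleles()`, …) expose
each stage separately; `plot_gtrack()` draws the counts and G tracks with
the significance line. A thin command-line wrapper with subcommands
(`simulate`, `scan`, `gtest`, `pcr`, `digest`, `alleles`, `verify`) is
installed at `inst/cli/transfree.R`; `verify` is driven by a YAML config
(see `?read_run_config`).

See the vignette in `vignettes/transgene-freedom-verification.Rmd` for
the model, its assumptions, calibration design and limitations.

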