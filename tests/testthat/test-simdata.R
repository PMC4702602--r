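test_that("genome generation is seeded, GC-accurate, and validated", {
  g1 <- generate_genome(1000, 0.5, seed = 1)
  g2 <- generate_genome(1000, 0.5, seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_genome(1000, 0.5, seed = 2)))
  expect_equal(nchar(g1[[1]]), 1000)

  g <- generate_genome(1e6, 0.42, seed = 7)
  gc <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C")) / 1e6
  expect_lt(abs(gc - 0.42), 0.005)

  expect_error(generate_genome(0, 0.5), "positive")
  expect_error(generate_genome(100, 1.2), "gc_fraction")
})

test_that("embedded composite sites read TG[Ns]WGATAA on the motif strand", {
  sim <- sim_sites(n = 40, classes = "cobound", seed = 5)
  tr <- sim$truth
  expect_equal(nrow(tr), 40)
  for (i in seq_len(nrow(tr))) {
    s <- tr$spacer_length[i]
    expect_true(s %in% c(7, 8))
    # element spans TG + spacer + WGATAA upstream of/at the motif
    if (tr$motif_strand[i] == "+") {
      elem <- substr(sim$genome[[tr$chrom[i]]],
                     tr$motif_start[i] + 1 - s - 2,
                     tr$motif_start[i] + 6)
    } else {
      raw <- substr(sim$genome[[tr$chrom[i]]],
                    tr$motif_start[i] + 1,
                    tr$motif_start[i] + 8 + s)
      elem <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(raw)))
    }
    expect_match(elem, paste0("^TG[ACGT]{", s, "}[AT]GATAA$"))
  }
})

test_that("empty site spec leaves the genome unchanged", {
  g <- generate_genome(5000, 0.5, seed = 2)
  es <- embed_sites(g, site_spec(n_cobound = 0), seed = 3)
  expect_identical(es$genome, g)
  expect_equal(nrow(es$truth), 0)
})

test_that("GATA-only sites carry no TG at 5-10 bp upstream", {
  sim <- sim_sites(n = 50, classes = "gata_only", seed = 9)
  tr <- sim$truth
  hist <- tg_distance_histogram(tr, sim$genome, scan_range = 1:12)
  counts <- hist$histogram
  expect_equal(sum(counts$count[counts$distance %in% 5:10]), 0)
})

test_that("TAL1-only sites carry an E-box and no WGATAA within 40 bp", {
  sim <- sim_sites(n = 30, classes = "tal_only", seed = 11)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    raw <- substr(sim$genome[[tr$chrom[i]]], tr$motif_start[i] + 1,
                  tr$motif_start[i] + 6)
    elem <- if (tr$motif_strand[i] == "+") raw
      else as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(raw)))
    expect_match(elem, "^CAG[AC]TG$")
    win <- substr(sim$genome[[tr$chrom[i]]],
                  max(1, tr$motif_start[i] - 39), tr$motif_start[i] + 46)
    expect_false(grepl("[AT]GATAA", win) || grepl("TTATC[AT]", win))
  }
})

test_that("insufficient genome space is rejected with the constraint named", {
  g <- generate_genome(3000, 0.5, seed = 1)
  expect_error(embed_sites(g, site_spec(n_cobound = 50,
                                        min_site_separation = 1000)),
               "separation")
})

test_that("exo tags sit exo_stop_offset bp either side of the cross-link", {
  sim <- sim_sites(n = 4, classes = "gata_only", genome_len = 30000,
                   seed = 13, sep = 5000)
  m <- crosslink_model("GATA1", 0, exo_stop_offset = 6, jitter_sd = 0)
  tk <- simulate_exo_tags(sim$truth, m, sim$seqlengths, 40, seed = 14)
  for (i in seq_len(nrow(sim$truth))) {
    cl <- sim$truth$reference_point[i]
    near <- tk$tags[abs(tk$tags$pos - cl) < 50, ]
    expect_true(all(near$pos[near$strand == "+"] == cl - 6))
    expect_true(all(near$pos[near$strand == "-"] == cl + 6))
  }
})

test_that("empty truth with zero background yields an empty exo track", {
  sim <- sim_sites(n = 0, seed = 1, genome_len = 2000)
  m <- crosslink_model("GATA1", 0, background_rate = 0)
  tk <- simulate_exo_tags(sim$truth, m, c(chr1 = 2000L), 10, seed = 1)
  expect_equal(total_tags(tk), 0)
})

test_that("background-only exo totals obey the Poisson bound", {
  L <- 1e6
  lam <- 0.01
  sim <- sim_sites(n = 0, seed = 1, genome_len = 2000)
  m <- crosslink_model("GATA1", 0, background_rate = lam)
  tk <- simulate_exo_tags(sim$truth, m, c(chr1 = as.integer(L)), 10,
                          seed = 21)
  expect_lt(abs(total_tags(tk) - 2 * lam * L), 3 * sqrt(2 * lam * L))
})

test_that("plus/minus 5'-end modes are 2*stop_offset apart without jitter", {
  for (stop_off in c(4, 6, 9)) {
    sim <- sim_sites(n = 10, classes = "gata_only", genome_len = 40000,
                     seed = 17 + stop_off, sep = 3000)
    m <- crosslink_model("GATA1", 0, exo_stop_offset = stop_off,
                         jitter_sd = 0)
    tk <- simulate_exo_tags(sim$truth, m, sim$seqlengths, 50,
                            seed = stop_off)
    for (i in seq_len(nrow(sim$truth))) {
      cl <- sim$truth$reference_point[i]
      near <- tk$tags[abs(tk$tags$pos - cl) < 50, ]
      pmode <- near$pos[near$strand == "+"][
        which.max(near$count[near$strand == "+"])]
      mmode <- near$pos[near$strand == "-"][
        which.max(near$count[near$strand == "-"])]
      expect_equal(mmode - pmode, 2 * stop_off)
    }
  }
})

test_that("seq tags are broad, site-covering, and exo tags are sharp", {
  sim <- sim_sites(n = 1, classes = "gata_only", genome_len = 20000,
                   seed = 23, sep = 5000)
  fm <- 200
  tk <- simulate_seq_tags(sim$truth, sim$seqlengths, fragment_mean = fm,
                          fragment_sd = 50, mean_tags_per_site = 10000,
                          factor_name = "GATA1", seed = 24)
  p <- sim$truth$reference_point[1]
  d <- abs(tk$tags$pos - p)
  for (std in c("+", "-")) {
    spread <- stats::sd(rep(tk$tags$pos[tk$tags$strand == std],
                            tk$tags$count[tk$tags$strand == std]))
    expect_gt(spread, fm / 2 / 2)  # sd of a uniform over ~fm bp
  }
  md <- sum(d * tk$tags$count) / sum(tk$tags$count)
  expect_gt(md, fm / 4)
  expect_lt(md, fm)

  empty <- simulate_seq_tags(sim$truth[0, ], sim$seqlengths,
                             background_rate = 0, seed = 1)
  expect_equal(total_tags(empty), 0)
})

test_that("input track is seeded, uniform-Poisson, and empty at rate 0", {
  sl <- c(chr1 = 1000000L)
  expect_equal(total_tags(simulate_input_track(sl, 0, seed = 1)), 0)
  t1 <- simulate_input_track(sl, 0.01, seed = 5)
  t2 <- simulate_input_track(sl, 0.01, seed = 5)
  expect_identical(t1$tags, t2$tags)
  expect_lt(abs(total_tags(t1) - 2e4), 3 * sqrt(2e4))
})

test_that("annotation links cobound sites to elevated expression", {
  sim <- sim_sites(n = 30, classes = "cobound", seed = 27)
  ann <- simulate_annotation(sim$truth, sim$seqlengths, n_genes = 300,
                             effect_log2fc_cobound = 2, noise_sd = 0.1,
                             seed = 28)
  targ <- ann$expression$log2fc[ann$expression$nearest_cobound]
  expect_gt(length(targ), 5)
  expect_lt(abs(mean(targ) - 2), 0.1)
  rest <- ann$expression$log2fc[!ann$expression$nearest_cobound]
  expect_lt(abs(mean(rest)), 0.1)
  ann2 <- simulate_annotation(sim$truth, sim$seqlengths, n_genes = 300,
                              effect_log2fc_cobound = 2, noise_sd = 0.1,
                              seed = 28)
  expect_identical(ann, ann2)
})

test_that("truth coordinates always retrieve the embedded motif", {
  sim <- sim_sites(n = 60, classes = c("cobound", "gata_only"),
                   genome_len = 150000, seed = 31)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    raw <- substr(sim$genome[[tr$chrom[i]]], tr$motif_start[i] + 1,
                  tr$motif_end[i])
    s <- if (tr$motif_strand[i] == "+") raw
      else as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(raw)))
    expect_match(s, "^[AT]GATAA$")
  }
})
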