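test_that("co-occupancy classification applies the 40-bp midpoint rule", {
  g <- data.frame(chrom = "chr1", midpoint = 100L)
  res <- classify_cooccupancy(g, data.frame(chrom = "chr1",
                                            midpoint = 135L))
  expect_equal(res$venn[["cobound"]], 1)

  res2 <- classify_cooccupancy(g, data.frame(chrom = "chr1",
                                             midpoint = 141L))
  expect_equal(res2$venn[["cobound"]], 0)
  expect_equal(res2$venn[["gata_only"]], 1)
  expect_equal(res2$venn[["tal_only"]], 1)

  res3 <- classify_cooccupancy(g, data.frame(chrom = character(),
                                             midpoint = integer()))
  expect_equal(res3$venn[["gata_only"]], 1)
})

test_that("co-occupancy matching is one-to-one and nearest-first", {
  g <- data.frame(chrom = "chr1", midpoint = c(100L, 120L))
  t <- data.frame(chrom = "chr1", midpoint = 110L)
  res <- classify_cooccupancy(g, t)
  expect_equal(nrow(res$cobound), 1)
  expect_equal(res$cobound$i_gata, 1)   # distance 10 < 10 vs 20: site 1 wins
})

test_that("composite profiles place tags at strand-correct offsets", {
  tr <- make_track(plus = 986, len = 2000L)
  anch <- data.frame(chrom = "chr1", reference_point = 1000L,
                     strand = "+")
  prof <- composite_profile(tr, anch, flank = 50, smooth = 1)
  expect_equal(prof$plus_density[prof$offsets == -14], 1)
  expect_equal(sum(prof$plus_density), 1)
  expect_equal(sum(prof$minus_density), 0)

  anch_m <- data.frame(chrom = "chr1", reference_point = 1000L,
                       strand = "-")
  prof_m <- composite_profile(tr, anch_m, flank = 50, smooth = 1)
  expect_equal(prof_m$minus_density[prof_m$offsets == 14], 1)
  expect_equal(sum(prof_m$plus_density), 0)

  empty <- composite_profile(make_track(len = 2000L), anch, flank = 50)
  expect_true(all(empty$plus_density == 0) && all(empty$minus_density == 0))
})

test_that("composite profiles are equivariant under genome mirroring", {
  sim <- sim_sites(n = 40, classes = "gata_only", seed = 81)
  tk <- simulate_exo_tags(sim$truth, gata1_model(), sim$seqlengths, 50,
                          seed = 82)
  anch <- truth_anchors(sim$truth)
  prof <- composite_profile(tk, anch, flank = 40, smooth = 1)

  L <- sim$seqlengths[[1]]
  mirrored <- tk$tags
  mirrored$pos <- L - 1L - mirrored$pos
  mirrored$strand <- ifelse(mirrored$strand == "+", "-", "+")
  tk_m <- tag_track(mirrored, sim$seqlengths)
  anch_m <- anch
  anch_m$reference_point <- L - 1L - anch$reference_point
  anch_m$strand <- ifelse(anch$strand == "+", "-", "+")
  prof_m <- composite_profile(tk_m, anch_m, flank = 40, smooth = 1)
  expect_equal(prof_m$plus_density, prof$plus_density)
  expect_equal(prof_m$minus_density, prof$minus_density)
})

test_that("cross-link estimation pairs profile maxima by the 12-bp rule", {
  toy <- function(plus_at, minus_at, h = 1) {
    off <- -40:40
    p <- numeric(81); m <- numeric(81)
    p[match(plus_at, off)] <- h
    m[match(minus_at, off)] <- h
    structure(list(offsets = off, plus_density = p, minus_density = m,
                   n_anchors = 1, smoothing_window = 5),
              class = "CompositeProfile")
  }
  one <- estimate_crosslinks(toy(-14, -2))
  expect_equal(one$crosslink_offset, -8)
  expect_equal(one$separation, 12)

  sym <- estimate_crosslinks(toy(-6, 6))
  expect_equal(sym$crosslink_offset, 0)

  two <- estimate_crosslinks(toy(c(-14, 2), c(-2, 14), h = c(2, 1)))
  expect_equal(sort(two$crosslink_offset), c(-8, 8))
  expect_equal(diff(sort(two$crosslink_offset)), 16)
  expect_equal(two$crosslink_offset[which.max(two$intensity)], -8)

  expect_warning(res <- estimate_crosslinks(toy(integer(), integer())),
                 "no pairable")
  expect_equal(nrow(res), 0)
})

test_that("cross-link recovery from simulation is within 1 bp of truth", {
  sim <- sim_sites(n = 220, classes = "cobound", seed = 85)
  anch <- truth_anchors(sim$truth)
  gt <- simulate_exo_tags(sim$truth, gata1_model(), sim$seqlengths, 50,
                          seed = 86)
  cg <- estimate_crosslinks(composite_profile(gt, anch, flank = 60))
  expect_equal(sort(cg$crosslink_offset), c(-8, 8), tolerance = 1)

  tt <- simulate_exo_tags(sim$truth, tal1_model(), sim$seqlengths, 50,
                          seed = 87)
  ct <- estimate_crosslinks(composite_profile(tt, anch, flank = 60))
  expect_equal(sort(ct$crosslink_offset), c(-21, -13), tolerance = 1)
})

test_that("occupancy windows are factor-specific and strand-oriented", {
  anch <- data.frame(chrom = "chr1", reference_point = 1000L,
                     strand = "+")
  tr_in <- make_track(plus = 980, len = 2000L)    # offset -20
  tr_out <- make_track(plus = 970, len = 2000L)   # offset -30
  tr_tal <- make_track(plus = 965, len = 2000L)   # offset -35
  occ <- occupancy_table(list(GATA1 = tr_in), anch)
  expect_equal(occ$GATA1, 1)
  occ2 <- occupancy_table(list(GATA1 = tr_out), anch)
  expect_equal(occ2$GATA1, 0)
  occ3 <- occupancy_table(list(TAL1 = tr_tal), anch)
  expect_equal(occ3$TAL1, 1)
  # minus-strand anchor: upstream is the higher-coordinate side
  anch_m <- data.frame(chrom = "chr1", reference_point = 1000L,
                       strand = "-")
  occ4 <- occupancy_table(list(TAL1 = make_track(plus = 1035, len = 2000L)),
                          anch_m)
  expect_equal(occ4$TAL1, 1)
  occ5 <- occupancy_table(list(TAL1 = make_track(plus = 1045, len = 2000L)),
                          anch_m)
  expect_equal(occ5$TAL1, 0)
  expect_equal(occupancy_table(list(GATA1 = make_track(len = 2000L)),
                               anch)$GATA1, 0)
})

test_that("heatmap rows sort by the requested key with stable ties", {
  anchors <- data.frame(chrom = "chr1",
                        reference_point = c(1000L, 3000L, 5000L),
                        strand = "+")
  tr <- make_track(plus = c(rep(1000, 5), rep(3000, 9), 5000),
                   len = 10000L)
  hm <- heatmap_matrix(tr, anchors, flank = 50)
  expect_equal(hm$key, c(9, 5, 1))
  expect_equal(hm$order, c(2, 1, 3))

  # sense1 counts only plus-strand tags in [-25, 0]
  tr2 <- make_track(plus = c(990, 990), minus = c(990, 990, 990),
                    len = 10000L)
  hm2 <- heatmap_matrix(tr2, anchors, flank = 50, sort_key = "sense1")
  expect_equal(hm2$key[1], 2)

  # ties keep coordinate order
  tr3 <- make_track(plus = c(1000, 3000, 5000), len = 10000L)
  hm3 <- heatmap_matrix(tr3, anchors, flank = 50)
  expect_equal(hm3$order, 1:3)

  expect_error(heatmap_matrix(tr, anchors, sort_key = "nope"), "sort key")
})

test_that("sequence composition is exact on consensus anchors", {
  sim <- sim_sites(n = 50, classes = "gata_only", seed = 91)
  anch <- truth_anchors(sim$truth)
  comp <- sequence_composition(anch, sim$genome)
  # reference point (offset 0) is the second A of WGATAA's GATAA tail
  expect_equal(comp$frequency["0", "A"], 1)
  expect_equal(comp$frequency["-1", "T"], 1)   # ..GAT(A)A: offset -1 is T
  expect_true(all(abs(rowSums(comp$frequency) - 1) < 1e-9))

  # random anchors: all bases near 0.29/0.21 for gc = 0.42
  g <- generate_genome(60000, 0.42, seed = 93)
  ranch <- data.frame(chrom = "chr1",
                      reference_point = seq(100L, 59000L, by = 600L),
                      strand = "+")
  rcomp <- sequence_composition(ranch, g)
  expect_true(all(abs(rcomp$frequency[, "A"] - 0.29) < 0.2))
})

test_that("homotypic clustering follows the 500-bp adjacency rule", {
  locs <- data.frame(chrom = "chr1", midpoint = c(1000L, 1400L, 5000L))
  cs <- find_clusters(locs)
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$location, 1200)
  expect_equal(cs$nonclusters, 3)

  chain <- find_clusters(data.frame(chrom = "chr1",
                                    midpoint = c(0L, 400L, 800L)))
  expect_equal(nrow(chain$clusters), 1)
  expect_equal(chain$clusters$location, 400)
  expect_equal(chain$clusters$n_members, 3)

  apart <- find_clusters(data.frame(chrom = "chr1",
                                    midpoint = c(0L, 500L, 1000L)))
  expect_equal(nrow(apart$clusters), 0)
  expect_equal(length(apart$nonclusters), 3)
})

test_that("clustering equals the pairwise connected-components oracle", {
  set.seed(95)
  for (rep in 1:5) {
    mids <- sort(sample(0:200000, 300))
    locs <- data.frame(chrom = "chr1", midpoint = mids)
    cs <- find_clusters(locs)
    comp <- oracle_clusters(mids)
    sizes <- table(comp)
    expect_equal(nrow(cs$clusters), sum(sizes >= 2))
    expect_equal(length(cs$nonclusters), sum(sizes == 1))
    # membership partitions agree
    got <- ifelse(is.na(cs$members), -seq_along(cs$members), cs$members)
    expect_equal(length(unique(paste(got, comp))),
                 length(unique(got)))
  }
})

test_that("cluster-linked genes show the simulated expression effect", {
  locs <- data.frame(chrom = "chr1",
                     midpoint = c(1000L, 1300L, 9000L, 20000L))
  cs <- find_clusters(locs)
  tss <- data.frame(gene = c("g1", "g2", "g3"), chrom = "chr1",
                    tss = c(800L, 9100L, 20500L))
  # nearest TSS: cluster at 1150 -> g1; nonclusters -> g2, g3
  expr <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(3, 0.1, -0.2))
  res <- expression_by_cluster(cs, locs, tss, expr)
  expect_equal(res$cluster_genes, "g1")
  expect_setequal(res$noncluster_genes, c("g2", "g3"))
  expect_equal(res$cluster_median, 3)

  # identical groups: p near 1
  expr2 <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(1, 1, 1))
  res2 <- expression_by_cluster(cs, locs, tss, expr2)
  expect_gt(res2$p_value, 0.9)
})

test_that("clustered cobound sites separate expression groups by rank test", {
  hits <- 0L
  for (seed in 1:5) {
    sim <- sim_sites(n = 25, classes = "cobound", genome_len = 50000,
                     seed = 100 + seed, sep = 2000)
    ref <- sim$truth$reference_point
    # pairs of locations flanking each cobound site form 2-member
    # clusters; isolated locations midway between sites are nonclusters
    locs <- data.frame(
      chrom = "chr1",
      midpoint = as.integer(c(ref - 100, ref + 100, ref + 1000)))
    locs <- locs[order(locs$midpoint), , drop = FALSE]
    cs <- find_clusters(locs)
    ann <- simulate_annotation(sim$truth, sim$seqlengths, n_genes = 150,
                               effect_log2fc_cobound = 2, noise_sd = 0.5,
                               seed = seed)
    res <- expression_by_cluster(cs, locs, ann$tss, ann$expression)
    if (!is.na(res$p_value) && res$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 4)
})
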