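# small programmatic fixtures shared across tests

# a TagTrack from explicit positions
make_track <- function(plus = integer(), minus = integer(), len = 10000L,
                       chrom = "chr1", name = "test") {
  tags <- rbind(
    if (length(plus)) data.frame(chrom = chrom, pos = as.integer(plus),
                                 strand = "+", count = 1L),
    if (length(minus)) data.frame(chrom = chrom, pos = as.integer(minus),
                                  strand = "-", count = 1L))
  tag_track(tags, stats::setNames(len, chrom), name = name)
}

# a small default simulation used by several recovery tests
sim_sites <- function(n = 250, classes = "gata_only", genome_len = n * 1000,
                      seed = 42, spacer = c(7, 8), sep = 1000) {
  g <- generate_genome(genome_len, 0.42, seed = seed)
  spec <- site_spec(
    n_cobound = if ("cobound" %in% classes) n else 0,
    n_gata_only = if ("gata_only" %in% classes) n else 0,
    n_tal_only = if ("tal_only" %in% classes) n else 0,
    spacer_lengths = spacer, min_site_separation = sep)
  es <- embed_sites(g, spec, seed = seed + 1)
  list(genome = es$genome, truth = es$truth,
       seqlengths = c(chr1 = nchar(es$genome[[1]])))
}

truth_anchors <- function(truth) {
  data.frame(chrom = truth$chrom,
             reference_point = truth$reference_point,
             strand = truth$motif_strand)
}

# independent single-linkage clustering oracle: connected components of the
# "distance < max_gap" relation, computed by pairwise expansion rather than
# a linear sweep over sorted adjacent gaps
oracle_clusters <- function(midpoints, max_gap = 500) {
  n <- length(midpoints)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      near <- which(abs(midpoints - midpoints[i]) < max_gap)
      target <- min(comp[near], comp[i])
      if (any(comp[near] != target) || comp[i] != target) {
        comp[near] <- target
        comp[i] <- target
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}
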