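#!/usr/bin/env Rscript
# Build the synthetic study data set: a random genome carrying composite
# (TG[N7-8]WGATAA), GATA-only and E-box-only sites; ChIP-exo tracks for
# GATA1 (three activation time points) and TAL1; a matched-depth input
# control; a ChIP-seq track; and TSS/expression tables. Everything is
# written under results/sim/ in plain-text formats (FASTA, BED, TSV).

suppressPackageStartupMessages(library(exoorg))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026

# 350-kb genome at mouse-like 42% GC. Sites sit on a 480-bp grid: close
# enough that adjacent occupied slots fall under the 500-bp homotypic
# clustering distance, so the cluster analysis has both clusters and
# nonclusters to work with.
genome <- generate_genome(350000, gc_fraction = 0.42, seed = seed)
spec <- site_spec(n_cobound = 120, n_gata_only = 80, n_tal_only = 60,
                  min_site_separation = 480)
es <- embed_sites(genome, spec, seed = seed + 1)
truth <- es$truth
sl <- c(chr1 = nchar(es$genome[[1]]))
write_fasta(es$genome, file.path(out, "genome.fa"))
write.table(truth, file.path(out, "truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

# GATA1 occupancy kinetics: a fifth of GATA1 sites double by 24 h, a
# fifth halve; the rest stay flat. Per-time-point truth tables only
# rescale occupancy.
set.seed(seed + 2)
is_gata <- truth$occ_gata1 > 0
kin <- rep("flat", nrow(truth))
kin[is_gata] <- sample(c("up", "down", "flat"), sum(is_gata),
                       replace = TRUE, prob = c(0.2, 0.2, 0.6))
scale_at <- function(tp) ifelse(kin == "up", c(t0 = 1, t3 = 1.4, t24 = 2)[tp],
                         ifelse(kin == "down", c(t0 = 1, t3 = 0.7, t24 = 0.5)[tp], 1))
gata_tracks <- list()
for (tp in c("t0", "t3", "t24")) {
  tr_tp <- truth
  tr_tp$occ_gata1 <- tr_tp$occ_gata1 * scale_at(tp)
  tk <- simulate_exo_tags(tr_tp, gata1_model(background_rate = 1e-4), sl,
                          mean_tags_per_site = 60,
                          seed = seed + match(tp, c("t0", "t3", "t24")) + 10)
  write_tags(tk, file.path(out, paste0("gata1_exo_", tp, ".bed")))
  gata_tracks[[tp]] <- tk
}

tal_tk <- simulate_exo_tags(truth, tal1_model(background_rate = 1e-4), sl,
                            mean_tags_per_site = 60, seed = seed + 20)
write_tags(tal_tk, file.path(out, "tal1_exo.bed"))

merged_depth <- sum(vapply(gata_tracks, total_tags, numeric(1)))
input_tk <- simulate_input_track(sl, merged_depth / 3 / (2 * sl[[1]]),
                                 seed = seed + 21)
write_tags(input_tk, file.path(out, "input.bed"))

seq_tk <- simulate_seq_tags(truth, sl, fragment_mean = 200,
                            fragment_sd = 50, mean_tags_per_site = 60,
                            background_rate = 5e-4, seed = seed + 22)
write_tags(seq_tk, file.path(out, "gata1_seq.bed"))

ann <- simulate_annotation(truth, sl, n_genes = 600,
                           effect_log2fc_cobound = 2, noise_sd = 0.5,
                           seed = seed + 23)
write.table(ann$tss, file.path(out, "tss.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(ann$expression, file.path(out, "expression.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(site_id = truth$site_id, kinetics = kin),
            file.path(out, "kinetics_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

# a small blacklist region free of sites, to exercise the filter
write.table(data.frame(chrom = "chr1", start = 0L, end = 150L),
            file.path(out, "blacklist.bed"), sep = "\t",
            row.names = FALSE, col.names = FALSE, quote = FALSE)

write_run_config(list(seed = seed, genome_bp = sl[[1]],
                      n_cobound = spec$n_cobound,
                      n_gata_only = spec$n_gata_only,
                      n_tal_only = spec$n_tal_only,
                      mean_tags_per_site = 60),
                 file.path(out, "config.yaml"))

cat("Simulated", nrow(truth), "sites on a", sl[[1]], "bp genome\n")
cat("GATA1 exo tags per time point:",
    paste(vapply(gata_tracks, total_tags, numeric(1)), collapse = ", "),
    "\n")
cat("TAL1 exo:", total_tags(tal_tk), " input:", total_tags(input_tk),
    " ChIP-seq:", total_tags(seq_tk), "\n")
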