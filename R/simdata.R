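#' Cross-link geometry model for a transcription factor
#'
#' ChIP-exo tag 5' ends mark where the lambda exonuclease stalls, about 6 bp
#' 5' of a formaldehyde protein-DNA cross-link, on each strand. A
#' `CrossLinkModel` states, for one factor, where its cross-links sit
#' relative to the motif reference point and how tags scatter around the
#' stall points.
#'
#' Defaults encode the geometries this package is built around: GATA1
#' cross-links at the two edges of the WGATAA element (-8 and +8 from the
#' reference point, with the upstream contact the stronger of the two), and
#' TAL1 cross-links at -21 and -13, flanking the TG half E-box of the
#' composite TG[N7-8]WGATAA element.
#'
#' @param factor_name factor label; must match an occupancy column of the
#'   truth table (`occ_<factor>` after lowercasing).
#' @param crosslink_offsets numeric vector of cross-link offsets (bp,
#'   relative to the motif reference point; negative = upstream on the motif
#'   strand).
#' @param weights per-offset sampling weights; normalized to sum to 1.
#' @param exo_stop_offset bp between a cross-link and the exonuclease stop
#'   on each strand (default 6).
#' @param jitter_sd standard deviation (bp) of the rounded-Gaussian scatter
#'   of stop positions.
#' @param background_rate expected background tags per bp per strand.
#' @return an object of class `CrossLinkModel`.
#' @export
crosslink_model <- function(factor_name, crosslink_offsets, weights = NULL,
                            exo_stop_offset = 6, jitter_sd = 1.0,
                            background_rate = 0) {
  if (is.null(weights)) weights <- rep(1, length(crosslink_offsets))
  stopifnot(length(weights) == length(crosslink_offsets),
            all(weights >= 0), sum(weights) > 0,
            exo_stop_offset >= 0, jitter_sd >= 0, background_rate >= 0)
  structure(list(factor_name = factor_name,
                 crosslink_offsets = crosslink_offsets,
                 weights = weights / sum(weights),
                 exo_stop_offset = exo_stop_offset,
                 jitter_sd = jitter_sd,
                 background_rate = background_rate),
            class = "CrossLinkModel")
}

#' @rdname crosslink_model
#' @param major_weight weight of the upstream (-8) GATA1 cross-link; the
#'   downstream (+8) contact gets the remainder.
#' @export
gata1_model <- function(major_weight = 0.75, exo_stop_offset = 6,
                        jitter_sd = 1.0, background_rate = 0) {
  crosslink_model("GATA1", c(-8, 8), c(major_weight, 1 - major_weight),
                  exo_stop_offset, jitter_sd, background_rate)
}

#' @rdname crosslink_model
#' @param distal_weight optional weight of a third, downstream cross-link
#'   (off by default); the two upstream contacts share the rest equally.
#' @param distal_offset offset of the optional downstream cross-link.
#' @export
tal1_model <- function(distal_weight = 0, distal_offset = 15,
                       exo_stop_offset = 6, jitter_sd = 1.0,
                       background_rate = 0) {
  offs <- c(-21, -13)
  w <- c(1, 1) / 2 * (1 - distal_weight)
  if (distal_weight > 0) {
    offs <- c(offs, distal_offset)
    w <- c(w, distal_weight)
  }
  crosslink_model("TAL1", offs, w, exo_stop_offset, jitter_sd,
                  background_rate)
}

#' Site layout specification for the simulator
#'
#' @param n_cobound number of composite TG[N7-8]WGATAA sites bound by both
#'   factors.
#' @param n_gata_only number of WGATAA sites with no TG 5-10 bp upstream.
#' @param n_tal_only number of CAGMTG E-box sites with no WGATAA within
#'   40 bp.
#' @param spacer_lengths allowed N-spacer lengths between TG and WGATAA.
#' @param occupancy_log_mean,occupancy_log_sd lognormal occupancy
#'   parameters (meanlog/sdlog).
#' @param min_site_separation minimum bp between embedded sites.
#' @param shared_strength if TRUE (default) cobound GATA1/TAL1 occupancies
#'   share a per-site strength factor, making them positively correlated; if
#'   FALSE they are drawn independently.
#' @return an object of class `SiteSpec`.
#' @export
site_spec <- function(n_cobound = 200, n_gata_only = 0, n_tal_only = 0,
                      spacer_lengths = c(7, 8),
                      occupancy_log_mean = 3, occupancy_log_sd = 1,
                      min_site_separation = 1000, shared_strength = TRUE) {
  stopifnot(n_cobound >= 0, n_gata_only >= 0, n_tal_only >= 0,
            all(spacer_lengths >= 0), min_site_separation > 0)
  structure(list(n_cobound = n_cobound, n_gata_only = n_gata_only,
                 n_tal_only = n_tal_only, spacer_lengths = spacer_lengths,
                 occupancy_log_mean = occupancy_log_mean,
                 occupancy_log_sd = occupancy_log_sd,
                 min_site_separation = min_site_separation,
                 shared_strength = shared_strength),
            class = "SiteSpec")
}

#' Generate a random genome
#'
#' I.i.d. bases at the requested GC fraction; bit-reproducible for a fixed
#' seed.
#'
#' @param length chromosome length in bp (vector for several chromosomes,
#'   named `chr1`, `chr2`, ...).
#' @param gc_fraction expected fraction of G+C, strictly between 0 and 1.
#' @param seed RNG seed.
#' @return named character vector of uppercase sequences.
#' @export
generate_genome <- function(length, gc_fraction = 0.42, seed = 1) {
  if (any(length <= 0)) stop("chromosome length must be positive")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must lie strictly between 0 and 1")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- vapply(length, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  stats::setNames(seqs, paste0("chr", seq_along(length)))
}

.rand_bases <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

# motif reference point: 5th base (0-based index 4) of WGATAA, the A next to
# the motif midpoint. motif_start is the 0-based genomic start of the 6-mer.
.reference_point <- function(motif_start, motif_strand) {
  ifelse(motif_strand == "+", motif_start + 4L, motif_start + 1L)
}

#' Embed binding sites into a genome
#'
#' Writes composite (TG[Ns]WGATAA), GATA-only (WGATAA with no TG at 5-10 bp
#' upstream) and TAL1-only (CAGMTG with no WGATAA within 40 bp) elements at
#' well-separated positions, on either strand with equal probability, and
#' returns the modified genome together with a ground-truth table.
#'
#' The truth table records, per site: coordinates and strand of the motif,
#' site class, spacer length, the motif reference point (5th base of
#' WGATAA; for TAL1-only sites the 5th base of the E-box) and lognormal
#' occupancies per factor.
#'
#' @param genome named character vector (from [generate_genome()] or
#'   [read_fasta()]).
#' @param spec a [site_spec()].
#' @param seed RNG seed.
#' @return list with `genome` (modified) and `truth` (data.frame).
#' @export
embed_sites <- function(genome, spec, seed = 1) {
  stopifnot(inherits(spec, "SiteSpec"))
  set.seed(seed)
  n_total <- spec$n_cobound + spec$n_gata_only + spec$n_tal_only
  if (n_total == 0)
    return(list(genome = genome,
                truth = data.frame(site_id = character(),
                                   chrom = character(),
                                   motif_start = integer(),
                                   motif_end = integer(),
                                   motif_strand = character(),
                                   site_class = character(),
                                   spacer_length = integer(),
                                   reference_point = integer(),
                                   occ_gata1 = numeric(),
                                   occ_tal1 = numeric())))
  pad <- 200L
  step <- spec$min_site_separation
  slots <- do.call(rbind, lapply(names(genome), function(ch) {
    L <- nchar(genome[[ch]])
    s <- seq.int(pad, L - pad, by = step)
    if (length(s) == 0) return(NULL)
    data.frame(chrom = ch, pos = s)
  }))
  if (is.null(slots) || nrow(slots) < n_total)
    stop("genome too short to host ", n_total, " sites at ",
         step, " bp minimum separation")
  slots <- slots[sample(nrow(slots), n_total), , drop = FALSE]
  classes <- c(rep("cobound", spec$n_cobound),
               rep("gata_only", spec$n_gata_only),
               rep("tal_only", spec$n_tal_only))
  strands <- sample(c("+", "-"), n_total, replace = TRUE)

  # occupancies
  occ_g <- numeric(n_total)
  occ_t <- numeric(n_total)
  base <- stats::rnorm(n_total, spec$occupancy_log_mean, spec$occupancy_log_sd)
  if (spec$shared_strength) {
    occ_g <- exp(base + stats::rnorm(n_total, 0, 0.3))
    occ_t <- exp(base + stats::rnorm(n_total, 0, 0.3))
  } else {
    occ_g <- exp(base)
    occ_t <- exp(stats::rnorm(n_total, spec$occupancy_log_mean,
                              spec$occupancy_log_sd))
  }
  occ_g[classes == "tal_only"] <- 0
  occ_t[classes == "gata_only"] <- 0

  truth <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    ch <- slots$chrom[i]
    at <- slots$pos[i]           # 0-based genomic start of the element
    cls <- classes[i]
    std <- strands[i]
    spacer <- NA_integer_
    if (cls == "cobound") {
      spacer <- sample(rep(spec$spacer_lengths, 2), 1)
      w <- sample(c("A", "T"), 1)
      elem <- paste0("TG", .rand_bases(spacer), w, "GATAA")
      written <- if (std == "+") elem else .revcomp(elem)
      substr(genome[[ch]], at + 1, at + nchar(elem)) <- written
      # WGATAA genomic start within the element
      motif_start <- if (std == "+") at + 2L + spacer else at
    } else if (cls == "gata_only") {
      w <- sample(c("A", "T"), 1)
      elem <- paste0(w, "GATAA")
      written <- if (std == "+") elem else .revcomp(elem)
      substr(genome[[ch]], at + 1, at + 6) <- written
      motif_start <- at
      # scrub TG at 5-10 bp upstream (motif strand): rewrite upstream bases
      # until the forbidden distances are clean
      for (try in 1:50) {
        up <- .upstream_seq(genome[[ch]], motif_start, std, 12L)
        d <- .tg_distances(up)
        if (!any(d >= 5 & d <= 10)) break
        .upstream_seq(genome[[ch]], motif_start, std, 12L) <- .rand_bases(12)
      }
    } else {  # tal_only: E-box, no WGATAA nearby
      m <- sample(c("A", "C"), 1)
      elem <- paste0("CAG", m, "TG")
      for (try in 1:50) {
        written <- if (std == "+") elem else .revcomp(elem)
        substr(genome[[ch]], at + 1, at + 6) <- written
        win <- substr(genome[[ch]], max(1, at - 39), at + 46)
        if (!grepl("[AT]GATAA", win) && !grepl("TTATC[AT]", win)) break
        # resample flanks, keep the E-box
        substr(genome[[ch]], max(1, at - 39), at) <-
          .rand_bases(at - max(1, at - 39) + 1)
        substr(genome[[ch]], at + 7, at + 46) <- .rand_bases(40)
      }
      motif_start <- at
    }
    truth[[i]] <- data.frame(
      site_id = sprintf("site%05d", i), chrom = ch,
      motif_start = motif_start, motif_end = motif_start + 6L,
      motif_strand = std, site_class = cls, spacer_length = spacer,
      reference_point = .reference_point(motif_start, std),
      occ_gata1 = occ_g[i], occ_tal1 = occ_t[i])
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$chrom, truth$motif_start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

# sequence immediately 5' of a motif, read on the motif strand
.upstream_seq <- function(seq, motif_start, strand, n) {
  if (strand == "+") {
    substr(seq, motif_start - n + 1, motif_start)
  } else {
    .revcomp(substr(seq, motif_start + 7, motif_start + 6 + n))
  }
}

`.upstream_seq<-` <- function(seq, motif_start, strand, n, value) {
  if (strand == "+") {
    substr(seq, motif_start - n + 1, motif_start) <- value
  } else {
    substr(seq, motif_start + 7, motif_start + 6 + n) <- .revcomp(value)
  }
  seq
}

# distances of TG occurrences from the end of an upstream sequence:
# distance d = number of bases between the G of TG and the motif start, so
# TG at the last two characters has d = 0.
.tg_distances <- function(upstream) {
  n <- nchar(upstream)
  if (n < 2) return(integer())
  hits <- gregexpr("TG", upstream)[[1]]
  if (hits[1] == -1) return(integer())
  n - (as.integer(hits) + 1L)
}

#' Simulate ChIP-exo tags from a truth table
#'
#' Per bound molecule, one cross-link offset is drawn according to the model
#' weights; the cross-link sits at `reference_point + offset` on plus-strand
#' motifs and mirrored (`reference_point - offset`) on minus-strand motifs.
#' The exonuclease stop produces a plus-strand 5' end `exo_stop_offset` bp
#' below the cross-link and a minus-strand 5' end the same distance above
#' it, each with independent rounded-Gaussian jitter. Per-site molecule
#' counts are Poisson with mean proportional to truth occupancy; uniform
#' Poisson background is added per strand at `model$background_rate`.
#'
#' @param truth truth table from [embed_sites()].
#' @param model a [crosslink_model()].
#' @param seqlengths named integer chromosome lengths.
#' @param mean_tags_per_site expected bound molecules per site (each
#'   molecule yields one plus- and one minus-strand tag).
#' @param seed RNG seed.
#' @return a [tag_track()]; attribute `n_dropped` counts tags falling
#'   outside the chromosome.
#' @export
simulate_exo_tags <- function(truth, model, seqlengths,
                              mean_tags_per_site = 50, seed = 1) {
  stopifnot(inherits(model, "CrossLinkModel"), mean_tags_per_site > 0)
  set.seed(seed)
  occ_col <- paste0("occ_", tolower(model$factor_name))
  if (!occ_col %in% names(truth))
    stop("truth table has no occupancy column '", occ_col, "'")
  sites <- truth[truth[[occ_col]] > 0, , drop = FALSE]
  tags <- list()
  n_dropped <- 0L
  if (nrow(sites)) {
    occ <- sites[[occ_col]]
    n_mol <- stats::rpois(nrow(sites), mean_tags_per_site * occ / mean(occ))
    for (i in seq_len(nrow(sites))) {
      if (n_mol[i] == 0) next
      off <- sample(rep(model$crosslink_offsets, 2), n_mol[i],
                    replace = TRUE, prob = rep(model$weights, 2))
      sgn <- if (sites$motif_strand[i] == "+") 1L else -1L
      cl <- sites$reference_point[i] + sgn * off
      jp <- round(stats::rnorm(n_mol[i], 0, model$jitter_sd))
      jm <- round(stats::rnorm(n_mol[i], 0, model$jitter_sd))
      ppos <- cl - model$exo_stop_offset + jp
      mpos <- cl + model$exo_stop_offset + jm
      L <- seqlengths[[sites$chrom[i]]]
      okp <- ppos >= 0 & ppos < L
      okm <- mpos >= 0 & mpos < L
      n_dropped <- n_dropped + sum(!okp) + sum(!okm)
      tags[[length(tags) + 1L]] <- data.frame(
        chrom = sites$chrom[i],
        pos = as.integer(c(ppos[okp], mpos[okm])),
        strand = rep(c("+", "-"), c(sum(okp), sum(okm))),
        count = 1L)
    }
  }
  if (model$background_rate > 0)
    tags[[length(tags) + 1L]] <-
      .uniform_tags(seqlengths, model$background_rate)
  tags <- if (length(tags)) do.call(rbind, tags) else NULL
  track <- tag_track(tags, seqlengths,
                     name = paste0(model$factor_name, "_exo"),
                     factor = model$factor_name)
  attr(track, "n_dropped") <- n_dropped
  track
}

.uniform_tags <- function(seqlengths, rate) {
  out <- lapply(names(seqlengths), function(ch) {
    L <- seqlengths[[ch]]
    n <- stats::rpois(1, 2 * rate * L)   # both strands
    if (n == 0) return(NULL)
    data.frame(chrom = ch, pos = sample.int(L, n, replace = TRUE) - 1L,
               strand = sample(c("+", "-"), n, replace = TRUE), count = 1L)
  })
  do.call(rbind, out)
}

#' Simulate ChIP-seq tags (sonication breakpoint model)
#'
#' Each tag derives from a random fragment overlapping the bound site: the
#' fragment length is Gaussian, its placement uniform among positions
#' covering the site, and the 5' end is the fragment start (plus strand) or
#' end (minus strand). The resulting strand-separated densities are broad
#' and unimodal, in contrast to the sharp exonuclease-stop peaks.
#'
#' @inheritParams simulate_exo_tags
#' @param fragment_mean,fragment_sd sonication fragment length (bp).
#' @param factor_name occupancy column to use (`occ_<factor>`).
#' @param background_rate uniform background tags per bp per strand.
#' @return a [tag_track()].
#' @export
simulate_seq_tags <- function(truth, seqlengths, fragment_mean = 200,
                              fragment_sd = 50, mean_tags_per_site = 50,
                              background_rate = 0, factor_name = "GATA1",
                              seed = 1) {
  stopifnot(fragment_mean > 0)
  set.seed(seed)
  occ_col <- paste0("occ_", tolower(factor_name))
  sites <- truth[truth[[occ_col]] > 0, , drop = FALSE]
  tags <- list()
  if (nrow(sites)) {
    occ <- sites[[occ_col]]
    n_tag <- stats::rpois(nrow(sites), mean_tags_per_site * occ / mean(occ))
    for (i in seq_len(nrow(sites))) {
      if (n_tag[i] == 0) next
      p <- sites$reference_point[i]
      fl <- pmax(20L, round(stats::rnorm(n_tag[i], fragment_mean,
                                         fragment_sd)))
      fstart <- p - vapply(fl, function(l) sample.int(l, 1) - 1L, integer(1))
      std <- sample(c("+", "-"), n_tag[i], replace = TRUE)
      pos <- ifelse(std == "+", fstart, fstart + fl - 1L)
      L <- seqlengths[[sites$chrom[i]]]
      ok <- pos >= 0 & pos < L
      tags[[length(tags) + 1L]] <- data.frame(
        chrom = sites$chrom[i], pos = as.integer(pos[ok]),
        strand = std[ok], count = 1L)
    }
  }
  if (background_rate > 0)
    tags[[length(tags) + 1L]] <- .uniform_tags(seqlengths, background_rate)
  tags <- if (length(tags)) do.call(rbind, tags) else NULL
  tag_track(tags, seqlengths, name = paste0(factor_name, "_seq"),
            factor = factor_name)
}

#' Simulate a uniform input control track
#'
#' Strand-independent uniform Poisson tags, the null model against which
#' peak-pair enrichment is tested.
#'
#' @param seqlengths named integer chromosome lengths.
#' @param rate expected tags per bp per strand.
#' @param seed RNG seed.
#' @return a [tag_track()].
#' @export
simulate_input_track <- function(seqlengths, rate, seed = 1) {
  set.seed(seed)
  tags <- if (rate > 0) .uniform_tags(seqlengths, rate) else NULL
  tag_track(tags, seqlengths, name = "input")
}

#' Simulate TSS and expression tables
#'
#' Places gene TSSs uniformly over the genome; genes that are the nearest
#' TSS to a cobound site receive expression log2 fold changes centred on
#' `effect_log2fc_cobound`, all other genes on 0.
#'
#' @param truth truth table from [embed_sites()].
#' @param seqlengths named integer chromosome lengths.
#' @param n_genes number of genes.
#' @param effect_log2fc_cobound mean log2FC of genes nearest cobound sites.
#' @param noise_sd Gaussian sd of log2FC.
#' @param seed RNG seed.
#' @return list with `tss` (gene, chrom, tss, strand) and `expression`
#'   (gene, log2fc).
#' @export
simulate_annotation <- function(truth, seqlengths, n_genes = 500,
                                effect_log2fc_cobound = 2, noise_sd = 0.5,
                                seed = 1) {
  stopifnot(n_genes > 0)
  set.seed(seed)
  chrom <- sample(names(seqlengths), n_genes, replace = TRUE,
                  prob = seqlengths / sum(seqlengths))
  tss <- vapply(chrom, function(ch) sample.int(seqlengths[[ch]], 1) - 1L,
                integer(1))
  genes <- data.frame(gene = sprintf("gene%04d", seq_len(n_genes)),
                      chrom = chrom, tss = tss,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE))
  target <- rep(FALSE, n_genes)
  cb <- truth[truth$site_class == "cobound", , drop = FALSE]
  for (i in seq_len(nrow(cb))) {
    same <- which(genes$chrom == cb$chrom[i])
    if (!length(same)) next
    j <- same[which.min(abs(genes$tss[same] - cb$reference_point[i]))]
    target[j] <- TRUE
  }
  lfc <- stats::rnorm(n_genes, ifelse(target, effect_log2fc_cobound, 0),
                      noise_sd)
  list(tss = genes,
       expression = data.frame(gene = genes$gene, log2fc = lfc,
                               nearest_cobound = target))
}
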