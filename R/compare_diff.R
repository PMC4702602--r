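#' Overlap between ChIP-exo and ChIP-seq binding locations
#'
#' Locations from the two assays overlap when their midpoints lie within
#' `midpoint_dist` bp (equivalently, an 80-bp window for the default).
#' Counting is asymmetric, as in Venn reporting: the number of seq
#' locations with at least one exo location in range, and vice versa. Per
#' category, the fraction of locations with a motif hit within
#' `motif_dist` bp is reported when hits are supplied.
#'
#' @param exo_locs,seq_locs data.frames with `chrom`, `midpoint`.
#' @param midpoint_dist overlap distance (bp, inclusive; default 40).
#' @param motif_hits optional hits from [scan_iupac()] / [scan_pwm()].
#' @param motif_dist motif annotation distance (bp; default 40).
#' @return list of class `OverlapSummary`: counts `n_exo`, `n_seq`,
#'   `n_exo_shared`, `n_seq_shared`, `n_exo_only`, `n_seq_only`; logical
#'   index vectors `exo_shared`, `seq_shared`; and `motif_fraction` (named
#'   vector per category) when hits are given.
#' @export
overlap_locations <- function(exo_locs, seq_locs, midpoint_dist = 40,
                              motif_hits = NULL, motif_dist = 40) {
  near <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      any(b$chrom == a$chrom[i] &
            abs(b$midpoint - a$midpoint[i]) <= midpoint_dist)
    }, logical(1))
  }
  exo_shared <- if (nrow(exo_locs)) near(exo_locs, seq_locs) else logical()
  seq_shared <- if (nrow(seq_locs)) near(seq_locs, exo_locs) else logical()
  out <- list(n_exo = nrow(exo_locs), n_seq = nrow(seq_locs),
              n_exo_shared = sum(exo_shared),
              n_seq_shared = sum(seq_shared),
              n_exo_only = sum(!exo_shared),
              n_seq_only = sum(!seq_shared),
              exo_shared = exo_shared, seq_shared = seq_shared)
  if (!is.null(motif_hits)) {
    has_motif <- function(locs) {
      if (!nrow(locs)) return(logical())
      vapply(seq_len(nrow(locs)), function(i) {
        any(motif_hits$chrom == locs$chrom[i] &
              abs(motif_hits$reference_point - locs$midpoint[i]) <
                motif_dist)
      }, logical(1))
    }
    me <- has_motif(exo_locs)
    ms <- has_motif(seq_locs)
    out$motif_fraction <- c(
      exo_shared = mean(me[exo_shared]),
      exo_only = mean(me[!exo_shared]),
      seq_shared = mean(ms[seq_shared]),
      seq_only = mean(ms[!seq_shared]))
  }
  class(out) <- "OverlapSummary"
  out
}

#' @export
print.OverlapSummary <- function(x, ...) {
  cat(sprintf(paste0("OverlapSummary: %d exo (%d shared), ",
                     "%d seq (%d shared)\n"),
              x$n_exo, x$n_exo_shared, x$n_seq, x$n_seq_shared))
  invisible(x)
}

#' Spearman correlation of occupancy between two libraries
#'
#' Per anchor, tag counts of both libraries within a `window`-bp window
#' centred on the midpoint are log10-transformed with pseudocount 1 and
#' rank-correlated. A binned 2-D density table of the transformed counts
#' is returned for heat-scatter plotting.
#'
#' @param track_a,track_b `TagTrack`s.
#' @param anchors data.frame with `chrom`, `midpoint` (typically the union
#'   of both assays' locations).
#' @param window full window width in bp (default 400).
#' @param n_bins bins per axis of the density table.
#' @return list with `spearman_r`, `log10_a`, `log10_b`, `density` (binned
#'   counts matrix).
#' @export
correlate_occupancy <- function(track_a, track_b, anchors, window = 400,
                                n_bins = 25) {
  if (nrow(anchors) < 3) stop("need at least 3 anchors")
  hw <- floor(window / 2)
  a <- window_counts(track_a, anchors$chrom, anchors$midpoint, -hw, hw)
  b <- window_counts(track_b, anchors$chrom, anchors$midpoint, -hw, hw)
  la <- log10(a + 1)
  lb <- log10(b + 1)
  r <- stats::cor(la, lb, method = "spearman")
  brks_a <- seq(min(la), max(la) + 1e-9, length.out = n_bins + 1)
  brks_b <- seq(min(lb), max(lb) + 1e-9, length.out = n_bins + 1)
  dens <- table(cut(la, brks_a, include.lowest = TRUE),
                cut(lb, brks_b, include.lowest = TRUE))
  list(spearman_r = r, log10_a = la, log10_b = lb, density = dens)
}

#' Composite exo profile around seq-only midpoints
#'
#' Builds the ChIP-exo composite around locations detected only by
#' ChIP-seq (20-bp smoothing) and reports whether the combined profile
#' mode lies within `center_tol` bp of the midpoints, i.e. whether exo
#' signal is present but subthreshold at those locations.
#'
#' @param exo_track a [tag_track()].
#' @param seq_only_midpoints data.frame with `chrom`, `midpoint` (strand
#'   taken as "+" when absent).
#' @param flank profile half-width (default 200).
#' @param smooth moving-average width (default 20).
#' @param center_tol centering tolerance in bp (default 10).
#' @return list with `profile` (a `CompositeProfile`), `mode_offset`,
#'   `centered` (logical).
#' @export
seq_only_profile <- function(exo_track, seq_only_midpoints, flank = 200,
                             smooth = 20, center_tol = 10) {
  anchors <- data.frame(chrom = seq_only_midpoints$chrom,
                        reference_point = seq_only_midpoints$midpoint,
                        strand = if ("strand" %in%
                                       names(seq_only_midpoints))
                          seq_only_midpoints$strand else "+")
  prof <- composite_profile(exo_track, anchors, flank = flank,
                            smooth = smooth)
  combined <- prof$plus_density + prof$minus_density
  mode_offset <- prof$offsets[which.max(combined)]
  list(profile = prof, mode_offset = mode_offset,
       centered = abs(mode_offset) <= center_tol)
}

#' Total-count-normalized differential occupancy across time points
#'
#' Per-location occupancy counts at each time point are scaled so the
#' per-time-point totals are equal (to the mean library size), then log2
#' fold changes with pseudocount 1 are computed for each requested ratio.
#'
#' @param tracks named list of `TagTrack`s, one per time point (e.g.
#'   `t0`, `t3`, `t24`).
#' @param locations data.frame with `chrom`, `midpoint`, and optionally
#'   `strand` for window orientation.
#' @param window c(upstream, downstream) occupancy window (default GATA1's
#'   c(25, 25)).
#' @param ratios list of 2-element character vectors
#'   c(numerator, denominator); defaults to all successive-and-overall
#'   contrasts of three time points named `t0`, `t3`, `t24`.
#' @param pseudocount added to both counts (default 1).
#' @return data.frame of per-location log2FC columns named
#'   `log2fc_<num>_<den>`, preceded by the normalized counts per time
#'   point.
#' @export
differential_occupancy <- function(tracks, locations,
                                   window = c(25, 25),
                                   ratios = list(c("t3", "t0"),
                                                 c("t24", "t3"),
                                                 c("t24", "t0")),
                                   pseudocount = 1) {
  stopifnot(length(tracks) >= 2)
  totals <- vapply(tracks, total_tags, numeric(1))
  if (any(totals == 0)) stop("time-point track with zero total tags")
  target <- mean(totals)
  std <- if ("strand" %in% names(locations)) locations$strand
    else rep("+", nrow(locations))
  from <- ifelse(std == "+", -window[1], -window[2])
  to <- ifelse(std == "+", window[2], window[1])
  counts <- sapply(names(tracks), function(nm) {
    cc <- numeric(nrow(locations))
    for (i in seq_len(nrow(locations))) {
      cc[i] <- window_counts(tracks[[nm]], locations$chrom[i],
                             locations$midpoint[i], from[i], to[i])
    }
    cc * target / totals[[nm]]
  })
  counts <- matrix(counts, nrow = nrow(locations),
                   dimnames = list(NULL, names(tracks)))
  out <- data.frame(chrom = locations$chrom,
                    midpoint = locations$midpoint)
  for (nm in names(tracks)) out[[paste0("norm_", nm)]] <- counts[, nm]
  for (r in ratios) {
    out[[paste0("log2fc_", r[1], "_", r[2])]] <-
      log2((counts[, r[1]] + pseudocount) / (counts[, r[2]] + pseudocount))
  }
  out
}

#' Kinetic classification of binding locations by k-means
#'
#' k-means (default k = 6, 10 restarts, seeded) on the per-location log2FC
#' vectors; clusters are ranked by their mean fold change on the
#' `order_by` contrast and grouped: top two = increased, middle two =
#' unchanged, bottom two = decreased.
#'
#' @param log2fc data.frame or matrix of log2FC columns (rows =
#'   locations).
#' @param k number of clusters (default 6).
#' @param seed RNG seed.
#' @param order_by column used to rank clusters (default the last column,
#'   conventionally the overall 24h/0h contrast).
#' @return list of class `KineticClassAssignment`: `cluster` (1..k, ranked
#'   so cluster 1 has the highest mean `order_by`), `group` (factor
#'   increased/unchanged/decreased), `centers`, `cluster_means`.
#' @export
kinetic_classes <- function(log2fc, k = 6, seed = 1, order_by = NULL) {
  x <- as.matrix(log2fc)
  stopifnot(all(is.finite(x)))
  if (nrow(x) < k)
    stop("fewer locations (", nrow(x), ") than clusters (", k, ")")
  if (is.null(order_by)) order_by <- ncol(x)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)
  mean_fc <- km$centers[, order_by]
  rank_of <- rank(-mean_fc, ties.method = "first")
  cluster <- rank_of[km$cluster]
  n_inc <- min(2, k)
  n_dec <- min(2, k - n_inc)
  group <- cut(cluster, breaks = c(0, n_inc, k - n_dec, k),
               labels = c("increased", "unchanged", "decreased"))
  centers <- km$centers[order(rank_of), , drop = FALSE]
  rownames(centers) <- seq_len(k)
  structure(list(cluster = as.integer(cluster), group = group,
                 centers = centers,
                 cluster_means = sort(mean_fc, decreasing = TRUE)),
            class = "KineticClassAssignment")
}

#' @export
print.KineticClassAssignment <- function(x, ...) {
  cat("KineticClassAssignment:", length(x$cluster), "locations in",
      nrow(x$centers), "clusters\n")
  print(table(x$group))
  invisible(x)
}
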