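#' Classify co-occupancy of two factors' binding locations
#'
#' Each location of factor A is matched one-to-one to the nearest location
#' of factor B with midpoints at most `max_dist` bp apart (nearest pairs
#' matched first); unmatched locations become factor-only sets.
#'
#' @param gata_locs,tal_locs data.frames with `chrom`, `midpoint`.
#' @param max_dist co-occupancy distance (bp, inclusive; default 40).
#' @return list with `cobound` (data.frame of index pairs `i_gata`,
#'   `i_tal`, `distance`), `gata_only`, `tal_only` (row indices), and
#'   `venn` (named counts).
#' @export
classify_cooccupancy <- function(gata_locs, tal_locs, max_dist = 40) {
  ng <- nrow(gata_locs)
  nt <- nrow(tal_locs)
  cand <- list()
  for (i in seq_len(ng)) {
    d <- abs(tal_locs$midpoint - gata_locs$midpoint[i])
    j <- which(tal_locs$chrom == gata_locs$chrom[i] & d <= max_dist)
    if (length(j))
      cand[[length(cand) + 1L]] <- data.frame(i_gata = i, i_tal = j,
                                              distance = d[j])
  }
  cand <- do.call(rbind, cand)
  pairs <- data.frame(i_gata = integer(), i_tal = integer(),
                      distance = integer())
  if (!is.null(cand)) {
    cand <- cand[order(cand$distance, cand$i_gata, cand$i_tal), ,
                 drop = FALSE]
    gused <- rep(FALSE, ng)
    tused <- rep(FALSE, nt)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!gused[cand$i_gata[k]] && !tused[cand$i_tal[k]]) {
        keep[k] <- TRUE
        gused[cand$i_gata[k]] <- TRUE
        tused[cand$i_tal[k]] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  list(cobound = pairs,
       gata_only = setdiff(seq_len(ng), pairs$i_gata),
       tal_only = setdiff(seq_len(nt), pairs$i_tal),
       venn = c(cobound = nrow(pairs),
                gata_only = ng - nrow(pairs),
                tal_only = nt - nrow(pairs)))
}

#' Motif-anchored composite tag profile
#'
#' Accumulates tag 5'-end counts at offsets relative to each anchor's
#' reference point. For minus-strand anchors, offsets are negated and
#' strands swapped before accumulation, so the profile is always in the
#' motif frame (negative offsets = upstream on the motif strand). Densities
#' are per anchor per bp; a centered moving average of width `smooth` is
#' applied per strand.
#'
#' @param track a [tag_track()].
#' @param anchors data.frame with `chrom`, `reference_point` and `strand`
#'   (anchor orientation; `motif_strand` is also accepted).
#' @param flank half-width of the offset window (profile covers -flank to
#'   +flank).
#' @param smooth moving-average width in bp (1 = none; default 5).
#' @return object of class `CompositeProfile`: list with `offsets`,
#'   `plus_density`, `minus_density`, `n_anchors`, `smoothing_window`.
#' @export
composite_profile <- function(track, anchors, flank = 100, smooth = 5) {
  stopifnot(flank > 0, smooth >= 1)
  std <- if ("strand" %in% names(anchors)) anchors$strand
    else anchors$motif_strand
  stopifnot(!is.null(std))
  offsets <- -flank:flank
  w <- length(offsets)
  plus <- numeric(w)
  minus <- numeric(w)
  tg <- track$tags
  for (ch in unique(anchors$chrom)) {
    sel <- tg$chrom == ch
    if (!any(sel)) next
    pos <- tg$pos[sel]; cnt <- tg$count[sel]; tstd <- tg$strand[sel]
    aidx <- which(anchors$chrom == ch)
    for (i in aidx) {
      a <- anchors$reference_point[i]
      off <- pos - a
      inw <- abs(off) <= flank
      if (!any(inw)) next
      o <- off[inw]; cn <- cnt[inw]; ts <- tstd[inw]
      if (std[i] == "-") {
        o <- -o
        ts <- ifelse(ts == "+", "-", "+")
      }
      ip <- ts == "+"
      if (any(ip))
        plus <- plus + .accumulate(o[ip] + flank + 1L, cn[ip], w)
      if (any(!ip))
        minus <- minus + .accumulate(o[!ip] + flank + 1L, cn[!ip], w)
    }
  }
  n <- nrow(anchors)
  plus <- plus / max(n, 1)
  minus <- minus / max(n, 1)
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    ma <- function(v) {
      out <- stats::filter(v, k, sides = 2)
      out[is.na(out)] <- 0
      as.numeric(out)
    }
    plus <- ma(plus)
    minus <- ma(minus)
  }
  structure(list(offsets = offsets, plus_density = plus,
                 minus_density = minus, n_anchors = n,
                 smoothing_window = smooth),
            class = "CompositeProfile")
}

.accumulate <- function(idx, counts, width) {
  v <- numeric(width)
  tab <- rowsum(counts, idx)
  v[as.integer(rownames(tab))] <- tab[, 1]
  v
}

#' @export
print.CompositeProfile <- function(x, ...) {
  cat("CompositeProfile over", length(x$offsets), "offsets,",
      x$n_anchors, "anchors, smoothing", x$smoothing_window, "bp\n")
  invisible(x)
}

#' Estimate cross-link points from a composite profile
#'
#' Finds local maxima independently on the plus and minus densities, pairs
#' them with the same separation rule as genomic peak pairing (minus minus
#' plus within `[d_min, d_max]`, partner ranked by closeness to
#' `target_sep`), and reports each pair's midpoint as an inferred
#' cross-link offset. Pairs are returned by descending intensity (mean of
#' the two maxima), up to `max_pairs`.
#'
#' @param profile a [composite_profile()] (smoothing window >= 3).
#' @param max_pairs maximum number of cross-link points to report.
#' @param d_min,d_max,target_sep pairing rule, as in [pair_peaks()].
#' @param min_height discard maxima below this fraction of the strand's
#'   maximum (default 0.1, suppressing baseline ripple).
#' @return data.frame with `crosslink_offset` (bp, may be half-integral),
#'   `separation`, `intensity`, `plus_offset`, `minus_offset`.
#' @export
estimate_crosslinks <- function(profile, max_pairs = 2, d_min = -5,
                                d_max = 25, target_sep = 12,
                                min_height = 0.1) {
  if (profile$smoothing_window < 3)
    warning("profile smoothing window < 3; cross-link estimates may be ",
            "dominated by single-base noise")
  find_maxima <- function(v) {
    n <- length(v)
    if (n < 3 || max(v) <= 0) return(integer())
    left <- c(Inf, v[-n])
    right <- c(v[-1], Inf)
    idx <- which(v > left & v >= right & v >= min_height * max(v))
    idx
  }
  pidx <- find_maxima(profile$plus_density)
  midx <- find_maxima(profile$minus_density)
  if (!length(pidx) || !length(midx)) {
    warning("no pairable maxima in composite profile")
    return(data.frame(crosslink_offset = numeric(), separation = numeric(),
                      intensity = numeric(), plus_offset = numeric(),
                      minus_offset = numeric()))
  }
  poff <- profile$offsets[pidx]
  moff <- profile$offsets[midx]
  ph <- profile$plus_density[pidx]
  mh <- profile$minus_density[midx]
  taken <- rep(FALSE, length(moff))
  out <- list()
  for (i in order(poff)) {
    d <- moff - poff[i]
    elig <- which(!taken & d >= d_min & d <= d_max)
    if (!length(elig)) next
    best <- elig[order(abs(d[elig] - target_sep), -mh[elig])][1]
    taken[best] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      crosslink_offset = (poff[i] + moff[best]) / 2,
      separation = moff[best] - poff[i],
      intensity = (ph[i] + mh[best]) / 2,
      plus_offset = poff[i], minus_offset = moff[best])
  }
  if (!length(out)) {
    warning("no pairable maxima in composite profile")
    return(data.frame(crosslink_offset = numeric(), separation = numeric(),
                      intensity = numeric(), plus_offset = numeric(),
                      minus_offset = numeric()))
  }
  out <- do.call(rbind, out)
  out <- out[order(-out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_pairs)
}

#' Per-location occupancy in factor-specific windows
#'
#' Occupancy is the tag count (both strands) within a strand-oriented
#' window around each anchor's reference point: `upstream` bp 5' to
#' `downstream` bp 3' on the motif strand. Defaults follow the
#' factor-specific conventions used throughout this package: GATA1
#' (-25, +25) and TAL1 (-40, +30).
#'
#' @param tracks named list of `TagTrack`s, one per factor.
#' @param anchors data.frame with `chrom`, `reference_point`, `strand` (or
#'   `motif_strand`).
#' @param windows named list factor -> c(upstream, downstream), both
#'   positive bp.
#' @return data.frame with one occupancy column per factor.
#' @export
occupancy_table <- function(tracks, anchors,
                            windows = list(GATA1 = c(25, 25),
                                           TAL1 = c(40, 30))) {
  std <- if ("strand" %in% names(anchors)) anchors$strand
    else anchors$motif_strand
  out <- data.frame(chrom = anchors$chrom,
                    reference_point = anchors$reference_point)
  for (f in names(tracks)) {
    w <- windows[[f]]
    if (is.null(w)) stop("no occupancy window for factor ", f)
    up <- w[1]; down <- w[2]
    from <- ifelse(std == "+", -up, -down)
    to <- ifelse(std == "+", down, up)
    cc <- numeric(nrow(anchors))
    for (i in seq_len(nrow(anchors))) {
      cc[i] <- window_counts(tracks[[f]], anchors$chrom[i],
                             anchors$reference_point[i], from[i], to[i])
    }
    out[[f]] <- cc
  }
  out
}

#' Anchor-by-offset tag matrix for heatmaps
#'
#' One row per anchor (motif frame, as in [composite_profile()]), one
#' column per offset, strand-separated; rows are sorted descending by the
#' requested key. Keys are either total occupancy in a window or one of
#' the four named peak windows: `sense1` = plus-strand [-25, 0], `sense2` =
#' plus-strand [0, +25], `antisense1` = minus-strand [-25, +5],
#' `antisense2` = minus-strand [+5, +25].
#'
#' @param track a [tag_track()].
#' @param anchors data.frame with `chrom`, `reference_point`, `strand` (or
#'   `motif_strand`).
#' @param flank half-width of the offset window.
#' @param sort_key `"occupancy"` or one of `"sense1"`, `"sense2"`,
#'   `"antisense1"`, `"antisense2"`; or a numeric vector (external key,
#'   e.g. another factor's occupancy).
#' @param occupancy_window c(upstream, downstream) used when `sort_key` is
#'   `"occupancy"`.
#' @return list with `plus`, `minus` (matrices, rows ordered), `order`
#'   (anchor indices), `key` (sorted key values), `offsets`.
#' @export
heatmap_matrix <- function(track, anchors, flank = 100,
                           sort_key = "occupancy",
                           occupancy_window = c(25, 25)) {
  std <- if ("strand" %in% names(anchors)) anchors$strand
    else anchors$motif_strand
  offsets <- -flank:flank
  w <- length(offsets)
  n <- nrow(anchors)
  P <- matrix(0, n, w)
  M <- matrix(0, n, w)
  tg <- track$tags
  for (i in seq_len(n)) {
    sel <- tg$chrom == anchors$chrom[i] &
      abs(tg$pos - anchors$reference_point[i]) <= flank
    if (!any(sel)) next
    o <- tg$pos[sel] - anchors$reference_point[i]
    cn <- tg$count[sel]
    ts <- tg$strand[sel]
    if (std[i] == "-") {
      o <- -o
      ts <- ifelse(ts == "+", "-", "+")
    }
    ip <- ts == "+"
    if (any(ip)) P[i, ] <- .accumulate(o[ip] + flank + 1L, cn[ip], w)
    if (any(!ip)) M[i, ] <- .accumulate(o[!ip] + flank + 1L, cn[!ip], w)
  }
  key <- if (is.numeric(sort_key)) {
    stopifnot(length(sort_key) == n)
    sort_key
  } else {
    win <- switch(sort_key,
                  occupancy = NULL,
                  sense1 = list(mat = "P", from = -25, to = 0),
                  sense2 = list(mat = "P", from = 0, to = 25),
                  antisense1 = list(mat = "M", from = -25, to = 5),
                  antisense2 = list(mat = "M", from = 5, to = 25),
                  stop("unknown sort key '", sort_key, "'; use 'occupancy',",
                       " 'sense1', 'sense2', 'antisense1', 'antisense2' or ",
                       "a numeric vector"))
    if (is.null(win)) {
      cols <- which(offsets >= -occupancy_window[1] &
                      offsets <= occupancy_window[2])
      rowSums(P[, cols, drop = FALSE]) + rowSums(M[, cols, drop = FALSE])
    } else {
      mat <- if (win$mat == "P") P else M
      cols <- which(offsets >= win$from & offsets <= win$to)
      rowSums(mat[, cols, drop = FALSE])
    }
  }
  ord <- order(-key, anchors$reference_point)
  list(plus = P[ord, , drop = FALSE], minus = M[ord, , drop = FALSE],
       order = ord, key = key[ord], offsets = offsets)
}

#' Per-offset base composition around anchors
#'
#' Base frequencies on the motif strand at each offset of the window,
#' optionally stratified by a numeric key (e.g. cross-link level or
#' occupancy) cut into bins. Per-offset frequencies sum to 1 over A/C/G/T.
#'
#' @param anchors data.frame with `chrom`, `reference_point`, `strand` (or
#'   `motif_strand`).
#' @param genome named character vector.
#' @param window c(from, to) offsets, inclusive (default c(-18, 3)).
#' @param strata optional numeric per-anchor key; `n_bins` quantile bins.
#' @param n_bins number of strata bins.
#' @return list with `frequency` (offset x base matrix; or a list of such
#'   per stratum), `letters` (anchor x offset character matrix, the
#'   four-colour panel), `n_skipped`.
#' @export
sequence_composition <- function(anchors, genome, window = c(-18, 3),
                                 strata = NULL, n_bins = 4) {
  std <- if ("strand" %in% names(anchors)) anchors$strand
    else anchors$motif_strand
  offs <- window[1]:window[2]
  w <- length(offs)
  n <- nrow(anchors)
  letters <- matrix(NA_character_, n, w,
                    dimnames = list(NULL, as.character(offs)))
  n_skipped <- 0L
  for (i in seq_len(n)) {
    ch <- anchors$chrom[i]
    a <- anchors$reference_point[i]
    L <- nchar(genome[[ch]])
    if (a + window[1] < 0 || a + window[2] >= L ||
        a - window[2] < 0 || a - window[1] >= L) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (std[i] == "+") {
      s <- substr(genome[[ch]], a + window[1] + 1, a + window[2] + 1)
    } else {
      s <- .revcomp(substr(genome[[ch]], a - window[2] + 1,
                           a - window[1] + 1))
    }
    letters[i, ] <- strsplit(s, "")[[1]]
  }
  freq_of <- function(rows) {
    sub <- letters[rows, , drop = FALSE]
    f <- vapply(seq_len(w), function(j) {
      col <- sub[, j]
      col <- col[!is.na(col)]
      if (!length(col)) return(rep(NA_real_, 4))
      tab <- table(factor(col, levels = .BASES))
      as.numeric(tab) / length(col)
    }, numeric(4))
    dimnames(f) <- list(.BASES, as.character(offs))
    t(f)
  }
  if (is.null(strata)) {
    freq <- freq_of(seq_len(n))
  } else {
    stopifnot(length(strata) == n)
    bins <- cut(rank(strata, ties.method = "first"), n_bins,
                labels = paste0("bin", seq_len(n_bins)))
    freq <- lapply(split(seq_len(n), bins), freq_of)
  }
  list(frequency = freq, letters = letters, n_skipped = n_skipped)
}

#' Homotypic clustering of binding locations
#'
#' Single-linkage chaining: adjacent midpoints (per chromosome, sorted)
#' closer than `max_gap` bp join one cluster. Clusters have at least two
#' members and are located at the median member coordinate (even sizes:
#' rounded mean of the two central coordinates); isolated locations are
#' nonclusters.
#'
#' @param locations data.frame with `chrom`, `midpoint`.
#' @param max_gap clustering distance in bp (strict: gaps must be
#'   < max_gap; default 500).
#' @return object of class `HomotypicClusterSet`: list with `clusters`
#'   (data.frame `cluster_id`, `chrom`, `location`, `n_members`),
#'   `members` (location index -> cluster_id, NA for nonclusters),
#'   `nonclusters` (location indices), and `summary`.
#' @export
find_clusters <- function(locations, max_gap = 500) {
  n <- nrow(locations)
  members <- rep(NA_integer_, n)
  clusters <- list()
  ord <- order(locations$chrom, locations$midpoint)
  cid <- 0L
  run <- integer()
  flush <- function(run, cid, members, clusters) {
    if (length(run) >= 2) {
      cid <- cid + 1L
      members[run] <- cid
      mids <- sort(locations$midpoint[run])
      k <- length(mids)
      loc <- if (k %% 2 == 1) mids[(k + 1) / 2]
        else as.integer(round((mids[k / 2] + mids[k / 2 + 1]) / 2))
      clusters[[cid]] <- data.frame(cluster_id = cid,
                                    chrom = locations$chrom[run[1]],
                                    location = loc, n_members = k)
    }
    list(cid = cid, members = members, clusters = clusters)
  }
  prev_ch <- NULL
  prev_mid <- NULL
  for (i in ord) {
    ch <- locations$chrom[i]
    mid <- locations$midpoint[i]
    if (!is.null(prev_ch) && ch == prev_ch && (mid - prev_mid) < max_gap) {
      run <- c(run, i)
    } else {
      st <- flush(run, cid, members, clusters)
      cid <- st$cid; members <- st$members; clusters <- st$clusters
      run <- i
    }
    prev_ch <- ch
    prev_mid <- mid
  }
  st <- flush(run, cid, members, clusters)
  cid <- st$cid; members <- st$members; clusters <- st$clusters
  clusters <- if (length(clusters)) do.call(rbind, clusters)
    else data.frame(cluster_id = integer(), chrom = character(),
                    location = integer(), n_members = integer())
  structure(list(clusters = clusters, members = members,
                 nonclusters = which(is.na(members)),
                 summary = c(n_locations = n,
                             n_clustered = sum(!is.na(members)),
                             n_clusters = nrow(clusters),
                             fraction_clustered =
                               if (n) sum(!is.na(members)) / n else NA,
                             mean_per_cluster =
                               if (nrow(clusters))
                                 mean(clusters$n_members) else NA)),
            class = "HomotypicClusterSet")
}

#' @export
print.HomotypicClusterSet <- function(x, ...) {
  s <- x$summary
  cat(sprintf("HomotypicClusterSet: %d/%d locations in %d clusters (%.1f%%)\n",
              s[["n_clustered"]], s[["n_locations"]], s[["n_clusters"]],
              100 * s[["fraction_clustered"]]))
  invisible(x)
}

#' Expression change of genes nearest clusters vs nonclusters
#'
#' Assigns each cluster location and each noncluster location the gene
#' with the nearest TSS (ties: lower TSS coordinate) and compares the two
#' groups' expression log2 fold changes with a two-sided Mann-Whitney test.
#'
#' @param cluster_set a [find_clusters()] result.
#' @param locations the location data.frame the clusters were built from.
#' @param tss_table data.frame with `gene`, `chrom`, `tss`.
#' @param expression_table data.frame with `gene`, `log2fc`.
#' @return list with `statistic` (U), `p_value`, `cluster_genes`,
#'   `noncluster_genes`, and group medians/means.
#' @export
expression_by_cluster <- function(cluster_set, locations, tss_table,
                                  expression_table) {
  nearest_gene <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      same <- which(tss_table$chrom == chrom[i])
      if (!length(same)) return(NA_character_)
      d <- abs(tss_table$tss[same] - pos[i])
      j <- same[order(d, tss_table$tss[same])][1]
      tss_table$gene[j]
    }, character(1))
  }
  cl <- cluster_set$clusters
  cl_genes <- if (nrow(cl)) nearest_gene(cl$chrom, cl$location)
    else character()
  nc <- cluster_set$nonclusters
  nc_genes <- if (length(nc))
    nearest_gene(locations$chrom[nc], locations$midpoint[nc])
    else character()
  lfc <- stats::setNames(expression_table$log2fc, expression_table$gene)
  a <- lfc[cl_genes[!is.na(cl_genes)]]
  b <- lfc[nc_genes[!is.na(nc_genes)]]
  if (!length(a) || !length(b)) {
    warning("empty cluster or noncluster group; comparison skipped")
    return(list(statistic = NA_real_, p_value = NA_real_,
                cluster_genes = cl_genes, noncluster_genes = nc_genes,
                cluster_median = stats::median(a),
                noncluster_median = stats::median(b),
                cluster_mean = mean(a), noncluster_mean = mean(b)))
  }
  if (length(unique(c(a, b))) == 1) {
    # fully tied samples: no evidence of a shift
    wt <- list(statistic = length(a) * length(b) / 2, p.value = 1)
  } else {
    wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
  }
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       cluster_genes = cl_genes, noncluster_genes = nc_genes,
       cluster_median = stats::median(a),
       noncluster_median = stats::median(b),
       cluster_mean = mean(a), noncluster_mean = mean(b))
}
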