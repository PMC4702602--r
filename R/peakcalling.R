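#' Gaussian smoothing of a strand-separated tag track
#'
#' Convolves each strand's 5'-end count vector independently with a
#' Gaussian kernel (sd `sigma`, truncated at 4 sigma and renormalized to
#' unit mass), so total tag mass is preserved up to the truncation
#' tolerance. This is the smoothing step of the strand-separated peak
#' caller.
#'
#' @param track a [tag_track()].
#' @param chrom chromosome to smooth.
#' @param sigma Gaussian sd in bp (default 5).
#' @return list with numeric vectors `plus` and `minus` (length =
#'   chromosome length; element i is position i-1) and the raw count
#'   vectors `plus_raw`, `minus_raw`.
#' @export
smooth_track <- function(track, chrom, sigma = 5) {
  if (sigma <= 0) stop("sigma must be positive")
  half <- ceiling(4 * sigma)
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  sm <- function(v) {
    out <- stats::filter(v, kern, sides = 2)
    out[is.na(out)] <- 0
    as.numeric(out)
  }
  praw <- strand_counts(track, chrom, "+")
  mraw <- strand_counts(track, chrom, "-")
  list(plus = sm(praw), minus = sm(mraw), plus_raw = praw, minus_raw = mraw)
}

#' Call peaks on a smoothed strand with an exclusion zone
#'
#' Candidate peaks are local maxima of the smoothed density (plateaus
#' contribute their first position). Candidates are accepted greedily from
#' the highest smoothed height downward; a candidate closer than
#' `exclusion` bp (center-to-center) to an already accepted peak is
#' discarded. Each accepted peak is assigned the raw tag count within
#' `floor(exclusion/2)` bp of its center and is dropped if that count is
#' below `min_raw`.
#'
#' @param smoothed numeric vector of smoothed density (position i-1 at
#'   element i).
#' @param raw numeric vector of raw per-base counts, same length.
#' @param exclusion minimum center-to-center distance of accepted peaks
#'   (default 10).
#' @param min_raw minimum raw tag count per peak (default 3).
#' @return data.frame with `position` (0-based), `smoothed_height`,
#'   `raw_count`, sorted by position.
#' @export
call_peaks <- function(smoothed, raw, exclusion = 10, min_raw = 3) {
  stopifnot(exclusion >= 1, length(smoothed) == length(raw))
  n <- length(smoothed)
  empty <- data.frame(position = integer(), smoothed_height = numeric(),
                      raw_count = numeric())
  if (n < 3) return(empty)
  x <- smoothed
  left <- c(Inf, x[-n])
  right <- c(x[-1], Inf)
  # strict rise from the left, non-rise to the right: plateau keeps its
  # first position
  cand <- which(x > 0 & x > left & x >= right)
  if (!length(cand)) return(empty)
  o <- order(-x[cand], cand)
  cand <- cand[o]
  accepted <- integer()
  for (p in cand) {
    if (!length(accepted) || all(abs(accepted - p) >= exclusion))
      accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)
  hw <- floor(exclusion / 2)
  rc <- vapply(accepted, function(p) {
    sum(raw[max(1, p - hw):min(n, p + hw)])
  }, numeric(1))
  keep <- rc >= min_raw
  data.frame(position = accepted[keep] - 1L,
             smoothed_height = smoothed[accepted[keep]],
             raw_count = rc[keep])
}

#' Pair plus- and minus-strand peaks
#'
#' A plus peak at p and a minus peak at m are pairable iff the separation
#' d = m - p lies in `[d_min, d_max]`; the default window (-5, +25) brackets
#' the ~12 bp separation expected when both exonuclease stops flank a
#' single cross-link. Matching is one-to-one: plus peaks are processed in
#' coordinate order and each takes the eligible minus peak minimizing
#' |d - target_sep| (ties broken by larger raw count, then smaller
#' coordinate); matched minus peaks are removed from further pairing.
#'
#' @param plus_peaks,minus_peaks data.frames from [call_peaks()].
#' @param d_min,d_max pairing window on the separation (bp).
#' @param target_sep ideal separation used to rank eligible partners
#'   (default 12, i.e. 2 x the exonuclease stop offset).
#' @return data.frame with one row per pair: `plus_pos`, `minus_pos`,
#'   `midpoint`, `separation`, `plus_height`, `minus_height`, `raw_count`
#'   (sum of both peaks).
#' @export
pair_peaks <- function(plus_peaks, minus_peaks, d_min = -5, d_max = 25,
                       target_sep = 12) {
  empty <- data.frame(plus_pos = integer(), minus_pos = integer(),
                      midpoint = integer(), separation = integer(),
                      plus_height = numeric(), minus_height = numeric(),
                      raw_count = numeric())
  if (!nrow(plus_peaks) || !nrow(minus_peaks)) return(empty)
  plus_peaks <- plus_peaks[order(plus_peaks$position), , drop = FALSE]
  minus_peaks <- minus_peaks[order(minus_peaks$position), , drop = FALSE]
  taken <- rep(FALSE, nrow(minus_peaks))
  out <- vector("list", nrow(plus_peaks))
  for (i in seq_len(nrow(plus_peaks))) {
    p <- plus_peaks$position[i]
    d <- minus_peaks$position - p
    elig <- which(!taken & d >= d_min & d <= d_max)
    if (!length(elig)) next
    score <- abs(d[elig] - target_sep)
    best <- elig[order(score, -minus_peaks$raw_count[elig],
                       minus_peaks$position[elig])][1]
    taken[best] <- TRUE
    m <- minus_peaks$position[best]
    out[[i]] <- data.frame(
      plus_pos = p, minus_pos = m,
      midpoint = as.integer(round((p + m) / 2)),
      separation = m - p,
      plus_height = plus_peaks$smoothed_height[i],
      minus_height = minus_peaks$smoothed_height[best],
      raw_count = plus_peaks$raw_count[i] + minus_peaks$raw_count[best])
  }
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Call peak pairs on a whole track
#'
#' Runs [smooth_track()], [call_peaks()] and [pair_peaks()] per chromosome.
#'
#' @param track a [tag_track()].
#' @param sigma,exclusion,min_raw see [call_peaks()].
#' @param d_min,d_max see [pair_peaks()].
#' @return data.frame of pairs with a `chrom` column.
#' @export
call_peak_pairs <- function(track, sigma = 5, exclusion = 10, min_raw = 3,
                            d_min = -5, d_max = 25) {
  out <- lapply(names(track$seqlengths), function(ch) {
    sm <- smooth_track(track, ch, sigma)
    pp <- call_peaks(sm$plus, sm$plus_raw, exclusion, min_raw)
    mp <- call_peaks(sm$minus, sm$minus_raw, exclusion, min_raw)
    pairs <- pair_peaks(pp, mp, d_min, d_max)
    if (nrow(pairs)) cbind(chrom = ch, pairs) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), plus_pos = integer(),
                      minus_pos = integer(), midpoint = integer(),
                      separation = integer(), plus_height = numeric(),
                      minus_height = numeric(), raw_count = numeric())
  out
}

#' Remove peak pairs falling in blacklist regions
#'
#' @param pairs data.frame with `chrom` and `midpoint`.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based,
#'   half-open), as from [read_intervals()].
#' @return the filtered pairs.
#' @export
filter_blacklist <- function(pairs, intervals) {
  if (!nrow(pairs) || is.null(intervals) || !nrow(intervals)) return(pairs)
  drop <- rep(FALSE, nrow(pairs))
  for (i in seq_len(nrow(intervals))) {
    drop <- drop | (pairs$chrom == intervals$chrom[i] &
                      pairs$midpoint >= intervals$start[i] &
                      pairs$midpoint < intervals$end[i])
  }
  pairs[!drop, , drop = FALSE]
}

#' Binomial enrichment test of peak pairs against an input control
#'
#' For each pair, ChIP and input tags (both strands) are counted within
#' `count_halfwidth` bp of the midpoint. The fold enrichment is the ChIP
#' count over the library-size-scaled input count plus a pseudocount of 1;
#' the p value is the upper tail of the exact binomial for the ChIP count
#' out of (ChIP + input) tags with success probability equal to the ChIP
#' share of the two library totals. q values are Benjamini-Hochberg across
#' all tested pairs; pairs with fold > `min_fold` and q < `q_max` are
#' retained.
#'
#' @param pairs data.frame from [call_peak_pairs()].
#' @param chip,input `TagTrack`s.
#' @param count_halfwidth counting half-window around the midpoint (bp).
#' @param min_fold,q_max selection thresholds.
#' @param keep_all if TRUE, return all pairs annotated (with a `selected`
#'   column) instead of only the selected ones.
#' @return annotated (and by default filtered) pairs with `chip_count`,
#'   `input_count`, `fold`, `p_value`, `q_value`.
#' @export
test_enrichment <- function(pairs, chip, input, count_halfwidth = 40,
                            min_fold = 2, q_max = 0.05, keep_all = FALSE) {
  if (!nrow(pairs)) {
    pairs$chip_count <- pairs$input_count <- pairs$fold <- numeric()
    pairs$p_value <- pairs$q_value <- numeric()
    if (keep_all) pairs$selected <- logical()
    return(pairs)
  }
  tc <- total_tags(chip)
  ti <- total_tags(input)
  if (ti == 0)
    stop("input track has zero tags; simulate a uniform pseudo-control ",
         "(see simulate_input_track) instead")
  if (tc == 0) stop("ChIP track has zero tags")
  cc <- window_counts(chip, pairs$chrom, pairs$midpoint,
                      -count_halfwidth, count_halfwidth)
  ic <- window_counts(input, pairs$chrom, pairs$midpoint,
                      -count_halfwidth, count_halfwidth)
  s <- tc / ti
  fold <- cc / (s * ic + 1)
  pr <- tc / (tc + ti)
  p <- stats::pbinom(cc - 1, size = cc + ic, prob = pr, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  pairs$chip_count <- cc
  pairs$input_count <- ic
  pairs$fold <- fold
  pairs$p_value <- p
  pairs$q_value <- q
  sel <- fold > min_fold & q < q_max
  if (keep_all) {
    pairs$selected <- sel
    pairs
  } else {
    pairs[sel, , drop = FALSE]
  }
}

#' Consolidate binding locations across conditions
#'
#' Single-linkage chaining of location midpoints from any number of
#' conditions: successive gaps of at most `merge_dist` bp join locations
#' into one union location whose representative midpoint is the
#' occupancy-weighted mean (rounded). Locations further apart remain
#' condition-specific. Per-condition occupancies are retained as columns
#' `occ_<condition>`.
#'
#' @param location_lists named list of data.frames, one per condition, each
#'   with `chrom`, `midpoint` and optionally `occupancy` (defaults to the
#'   pair `chip_count` or 1).
#' @param merge_dist maximum gap joining locations (bp, inclusive;
#'   default 40).
#' @return data.frame of union locations: `chrom`, `midpoint`,
#'   `n_supporting_pairs`, one `occ_*` and one `bound_*` column per
#'   condition.
#' @export
merge_conditions <- function(location_lists, merge_dist = 40) {
  stopifnot(length(location_lists) >= 1)
  if (is.null(names(location_lists)))
    names(location_lists) <- paste0("cond", seq_along(location_lists))
  all <- do.call(rbind, lapply(names(location_lists), function(nm) {
    df <- location_lists[[nm]]
    if (!nrow(df))
      return(NULL)
    occ <- if ("occupancy" %in% names(df)) df$occupancy
      else if ("chip_count" %in% names(df)) df$chip_count
      else rep(1, nrow(df))
    data.frame(chrom = df$chrom, midpoint = df$midpoint,
               occupancy = occ, condition = nm)
  }))
  conds <- names(location_lists)
  if (is.null(all)) {
    out <- data.frame(chrom = character(), midpoint = integer(),
                      n_supporting_pairs = integer())
    for (nm in conds) {
      out[[paste0("occ_", nm)]] <- numeric()
      out[[paste0("bound_", nm)]] <- logical()
    }
    return(out)
  }
  all <- all[order(all$chrom, all$midpoint), , drop = FALSE]
  gap_new <- c(TRUE, diff(all$midpoint) > merge_dist |
                 all$chrom[-1] != all$chrom[-nrow(all)])
  grp <- cumsum(gap_new)
  out <- lapply(split(seq_len(nrow(all)), grp), function(idx) {
    sub <- all[idx, , drop = FALSE]
    mid <- as.integer(round(sum(sub$midpoint * sub$occupancy) /
                              sum(sub$occupancy)))
    row <- data.frame(chrom = sub$chrom[1], midpoint = mid,
                      n_supporting_pairs = nrow(sub))
    for (nm in conds) {
      occ <- sum(sub$occupancy[sub$condition == nm])
      row[[paste0("occ_", nm)]] <- occ
      row[[paste0("bound_", nm)]] <- any(sub$condition == nm)
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$midpoint), , drop = FALSE]
}

#' Intersect union locations with an external event list
#'
#' Final binding locations are the external (e.g. MultiGPS) locations
#' having at least one union peak-pair location within `window` bp; the
#' final coordinate is the external coordinate. Locations supported by only
#' one method are returned as outersects for reporting.
#'
#' @param union_locs data.frame with `chrom`, `midpoint` (peak-pair union).
#' @param external_locs data.frame with `chrom`, `midpoint`.
#' @param window maximum distance (bp, inclusive; default 100).
#' @return list with `final` (external rows + `n_supporting_pairs`),
#'   `external_only`, `union_only`.
#' @export
intersect_locations <- function(union_locs, external_locs, window = 100) {
  if (!nrow(external_locs)) {
    final <- external_locs
    final$n_supporting_pairs <- integer(0)
    return(list(final = final, external_only = external_locs,
                union_only = union_locs))
  }
  nsupp <- integer(nrow(external_locs))
  union_used <- rep(FALSE, nrow(union_locs))
  for (i in seq_len(nrow(external_locs))) {
    near <- union_locs$chrom == external_locs$chrom[i] &
      abs(union_locs$midpoint - external_locs$midpoint[i]) <= window
    nsupp[i] <- sum(near)
    union_used <- union_used | near
  }
  final <- external_locs[nsupp > 0, , drop = FALSE]
  final$n_supporting_pairs <- nsupp[nsupp > 0]
  list(final = final,
       external_only = external_locs[nsupp == 0, , drop = FALSE],
       union_only = union_locs[!union_used, , drop = FALSE])
}

#' Full location-calling chain for one condition
#'
#' Convenience wrapper: peak-pair calling, blacklist filtering and
#' enrichment testing against the input control, returning the selected
#' pairs as a location table (`chrom`, `midpoint`, `occupancy` =
#' ChIP count).
#'
#' @param chip,input `TagTrack`s.
#' @param blacklist optional intervals data.frame.
#' @param sigma,exclusion,min_raw,d_min,d_max,count_halfwidth,min_fold,q_max
#'   chain parameters; see [call_peaks()], [pair_peaks()] and
#'   [test_enrichment()].
#' @return data.frame of selected locations with the pair annotation
#'   columns.
#' @export
call_locations <- function(chip, input, blacklist = NULL, sigma = 5,
                           exclusion = 10, min_raw = 3, d_min = -5,
                           d_max = 25, count_halfwidth = 40, min_fold = 2,
                           q_max = 0.05) {
  pairs <- call_peak_pairs(chip, sigma, exclusion, min_raw, d_min, d_max)
  if (!is.null(blacklist)) pairs <- filter_blacklist(pairs, blacklist)
  sel <- test_enrichment(pairs, chip, input, count_halfwidth, min_fold,
                         q_max)
  sel$occupancy <- sel$chip_count
  sel
}
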