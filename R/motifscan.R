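.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"), N = .BASES)

.check_iupac <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters, names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC letter(s): ", paste(unique(bad), collapse = ", "))
  letters
}

#' Scan a genome for exact matches to an IUPAC consensus
#'
#' Both strands are scanned; minus-strand hits are matches of the reverse
#' complement. Every hit carries the match p value under a uniform
#' background, `prod(allowed letters per position) / 4^L`, and the motif
#' reference point (see [motif_reference_point()]).
#'
#' @param genome named character vector of sequences.
#' @param consensus IUPAC consensus string (e.g. `"WGATAA"`).
#' @param ref_index 0-based index of the reference base within the motif
#'   (default 4, the 5th base: for WGATAA, the A adjacent to the motif
#'   midpoint).
#' @return data.frame of hits: `chrom`, `start`, `end` (0-based,
#'   half-open), `strand`, `score` (= motif length), `p_value`,
#'   `reference_point`.
#' @export
scan_iupac <- function(genome, consensus, ref_index = 4) {
  letters <- .check_iupac(consensus)
  L <- length(letters)
  pval <- prod(vapply(letters, function(l) length(.IUPAC[[l]]), numeric(1))) /
    4^L
  pat <- Biostrings::DNAString(toupper(consensus))
  out <- lapply(names(genome), function(ch) {
    subj <- Biostrings::DNAString(genome[[ch]])
    fwd <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    subj, fixed = FALSE)
    start <- c(BiocGenerics::start(fwd), BiocGenerics::start(rev)) - 1L
    strand <- rep(c("+", "-"), c(length(fwd), length(rev)))
    if (!length(start)) return(NULL)
    data.frame(chrom = ch, start = start, end = start + L, strand = strand,
               score = L, p_value = pval)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), p_value = numeric())
  out$reference_point <- motif_reference_point(out$start, out$end,
                                               out$strand, ref_index)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Reference point of a motif hit
#'
#' The anchor coordinate from which all offsets (cross-link positions,
#' occupancy windows, composite profiles) are measured. For a motif of
#' length L with 0-based reference index r, the reference point of a
#' plus-strand hit is `start + r`, of a minus-strand hit `end - 1 - r`.
#'
#' @param start,end 0-based half-open hit coordinates.
#' @param strand `"+"` or `"-"`.
#' @param ref_index 0-based index of the reference base within the motif.
#' @return integer genomic coordinates.
#' @export
motif_reference_point <- function(start, end, strand, ref_index = 4) {
  as.integer(ifelse(strand == "+", start + ref_index,
                    end - 1L - ref_index))
}

#' Build a position weight matrix from an IUPAC consensus
#'
#' Uniform probability over the allowed letters at each position, with a
#' pseudocount spread over the disallowed ones.
#'
#' @param consensus IUPAC string.
#' @param pseudocount probability mass given to each disallowed base.
#' @param background background base probabilities (A, C, G, T).
#' @return object of class `Pwm`: list with `matrix` (L x 4 probabilities),
#'   `background`, `log_odds` (natural log), `motif_id`.
#' @export
pwm_from_iupac <- function(consensus, pseudocount = 1e-3,
                           background = rep(0.25, 4)) {
  letters <- .check_iupac(consensus)
  L <- length(letters)
  if (L < 2) stop("motif length must be at least 2")
  mat <- t(vapply(letters, function(l) {
    allowed <- .BASES %in% .IUPAC[[l]]
    p <- ifelse(allowed, 1 / sum(allowed), pseudocount)
    p / sum(p)
  }, numeric(4)))
  colnames(mat) <- .BASES
  rownames(mat) <- NULL
  names(background) <- .BASES
  structure(list(motif_id = toupper(consensus), matrix = mat,
                 background = background,
                 log_odds = log(sweep(mat, 2, background, "/"))),
            class = "Pwm")
}

# discretized per-position score bins and the exact null distribution of
# the total binned score under the background model
.pwm_score_distribution <- function(pwm, bin = 0.005) {
  L <- nrow(pwm$matrix)
  bins <- round(pwm$log_odds / bin)        # integer bins per position/base
  # DP: start with a point mass at 0, shift per position
  dist <- 1
  offset <- 0L   # bin value of dist[1]
  for (i in seq_len(L)) {
    bmin <- min(bins[i, ])
    new_len <- length(dist) + max(bins[i, ]) - bmin
    new <- numeric(new_len)
    for (b in seq_along(.BASES)) {
      sh <- bins[i, b] - bmin
      new[(1 + sh):(length(dist) + sh)] <-
        new[(1 + sh):(length(dist) + sh)] + dist * pwm$background[b]
    }
    dist <- new
    offset <- offset + bmin
  }
  list(dist = dist, offset = offset, bins = bins, bin = bin)
}

#' Exact p value of a PWM score
#'
#' P(score' >= score) for a random sequence under the background model,
#' computed by dynamic programming over the discretized per-position score
#' distribution (bin width 0.005 log-odds units). Scores are binned the
#' same way on both sides of the comparison, so the p value is exact for
#' the binned score.
#'
#' @param pwm a [pwm_from_iupac()] or compatible `Pwm`.
#' @param score log-odds score (natural log).
#' @return p value in (0, 1].
#' @export
pwm_pvalue <- function(pwm, score) {
  sd <- .pwm_score_distribution(pwm)
  vals <- (sd$offset + seq_along(sd$dist) - 1) * sd$bin
  # binned totals drift from raw sums by at most L/2 bins; tolerate that
  # much so attainable raw scores map onto their own bin
  eps <- (nrow(pwm$matrix) / 2 + 0.5) * sd$bin
  sum(sd$dist[vals >= score - eps])
}

#' Scan a genome with a PWM
#'
#' Scores every window on both strands with the log-odds matrix and
#' reports hits with exact p value below `p_max`. For short motifs this is
#' equivalent to full enumeration of matching windows.
#'
#' @param genome named character vector.
#' @param pwm a `Pwm`.
#' @param p_max p-value threshold (default 1e-3).
#' @param ref_index 0-based reference index (see
#'   [motif_reference_point()]).
#' @return data.frame of hits as in [scan_iupac()], with log-odds `score`.
#' @export
scan_pwm <- function(genome, pwm, p_max = 1e-3, ref_index = 4) {
  stopifnot(p_max > 0, p_max <= 1)
  L <- nrow(pwm$matrix)
  sd <- .pwm_score_distribution(pwm)
  tail <- rev(cumsum(rev(sd$dist)))
  # per-binned-score p value lookup
  pv_of_bin <- function(q) {
    idx <- pmin(pmax(q - sd$offset + 1L, 1L), length(sd$dist))
    out <- tail[idx]
    out[q - sd$offset + 1L > length(sd$dist)] <- 0
    out[q - sd$offset + 1L < 1L] <- 1
    out
  }
  out <- lapply(names(genome), function(ch) {
    seq <- genome[[ch]]
    n <- nchar(seq)
    if (n < L) return(NULL)
    code <- match(strsplit(seq, "")[[1]], .BASES)   # NA for ambiguity codes
    nw <- n - L + 1L
    fwd_bins <- integer(nw)
    rev_bins <- integer(nw)
    ok <- rep(TRUE, nw)
    for (i in seq_len(L)) {
      b <- code[i:(i + nw - 1L)]
      ok <- ok & !is.na(b)
      bi <- ifelse(is.na(b), 1L, b)
      fwd_bins <- fwd_bins + sd$bins[i, bi]
      # reverse strand: position i of the motif reads the complement of
      # genome base at window_start + L - i
      br <- code[(L - i + 1L):(L - i + nw)]
      bc <- c(4L, 3L, 2L, 1L)[ifelse(is.na(br), 1L, br)]
      rev_bins <- rev_bins + sd$bins[i, bc]
    }
    res <- list()
    for (std in c("+", "-")) {
      q <- if (std == "+") fwd_bins else rev_bins
      pv <- pv_of_bin(q)
      hit <- which(ok & pv < p_max)
      if (!length(hit)) next
      res[[std]] <- data.frame(chrom = ch, start = hit - 1L,
                               end = hit - 1L + L, strand = std,
                               score = q[hit] * sd$bin, p_value = pv[hit])
    }
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), p_value = numeric())
  out$reference_point <- motif_reference_point(out$start, out$end,
                                               out$strand, ref_index)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Center binding locations on their most significant motif
#'
#' Each location's midpoint moves to the reference point of the hit with
#' the smallest p value within `max_dist` bp (ties: nearest hit, then lower
#' coordinate). Locations without an eligible hit are flagged motif-less
#' and left unmoved.
#'
#' @param locations data.frame with `chrom`, `midpoint`.
#' @param hits motif hits from [scan_iupac()] / [scan_pwm()].
#' @param max_dist maximum midpoint-to-reference distance (bp, inclusive;
#'   default 40).
#' @return locations with `midpoint` updated and columns `has_motif`,
#'   `motif_strand`, `motif_start`, `motif_p`.
#' @export
center_on_motif <- function(locations, hits, max_dist = 40) {
  n <- nrow(locations)
  locations$has_motif <- rep(FALSE, n)
  locations$motif_strand <- rep(NA_character_, n)
  locations$motif_start <- rep(NA_integer_, n)
  locations$motif_p <- rep(NA_real_, n)
  if (!n || !nrow(hits)) return(locations)
  for (i in seq_len(n)) {
    d <- abs(hits$reference_point - locations$midpoint[i])
    elig <- which(hits$chrom == locations$chrom[i] & d <= max_dist)
    if (!length(elig)) next
    best <- elig[order(hits$p_value[elig], d[elig],
                       hits$reference_point[elig])][1]
    locations$midpoint[i] <- hits$reference_point[best]
    locations$has_motif[i] <- TRUE
    locations$motif_strand[i] <- hits$strand[best]
    locations$motif_start[i] <- hits$start[best]
    locations$motif_p[i] <- hits$p_value[best]
  }
  locations
}

#' Histogram of TG distances upstream of motif sites
#'
#' For each motif-annotated site, the sequence 5' of the motif on the motif
#' strand is scanned for the dinucleotide TG. The distance of an occurrence
#' is the number of bases between the G of TG and the first base of the
#' motif (so TGN7WGATAA records distance 7). All occurrences within
#' `scan_range` are tallied.
#'
#' @param sites data.frame with `chrom`, `motif_start`, `motif_strand`
#'   (e.g. truth table rows or centered locations).
#' @param genome named character vector.
#' @param scan_range integer distances to scan (default 1:20).
#' @param flag_range distances for the per-site presence flag (default
#'   7:9).
#' @return list with `histogram` (data.frame distance/count), `per_site`
#'   (data.frame site index, has_tg_in_flag_range, closest distance), and
#'   `n_skipped` (sites too close to the chromosome edge).
#' @export
tg_distance_histogram <- function(sites, genome, scan_range = 1:20,
                                  flag_range = 7:9) {
  max_d <- max(scan_range)
  need <- max_d + 2L
  counts <- stats::setNames(integer(length(scan_range)),
                            as.character(scan_range))
  per_site <- data.frame(site = seq_len(nrow(sites)),
                         has_tg = rep(FALSE, nrow(sites)),
                         closest = rep(NA_integer_, nrow(sites)))
  n_skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]
    m <- sites$motif_start[i]
    std <- sites$motif_strand[i]
    L <- nchar(genome[[ch]])
    enough <- if (std == "+") m >= need else m + 6L + need <= L
    if (!enough) { n_skipped <- n_skipped + 1L; next }
    up <- .upstream_seq(genome[[ch]], m, std, need)
    d <- .tg_distances(up)
    d <- d[d %in% scan_range]
    if (length(d)) {
      tab <- table(d)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
      per_site$has_tg[i] <- any(d %in% flag_range)
      if (any(d %in% flag_range))
        per_site$closest[i] <- .pick_tg(d[d %in% flag_range])
    }
  }
  list(histogram = data.frame(distance = scan_range,
                              count = as.integer(counts)),
       per_site = per_site, n_skipped = n_skipped)
}

# preferred TG occurrence: the one closest to the 7-8 bp band; ties to the
# smaller distance
.pick_tg <- function(d) {
  band <- pmin(abs(d - 7), abs(d - 8))
  d[order(band, d)][1]
}

#' Classify E-box composition upstream of the TG half-site
#'
#' Writing the E-box as ZZNNTG, reads the 4 bases 5' of each site's chosen
#' TG on the motif strand and tabulates (i) the ZZ dinucleotide, (ii) the
#' NN dinucleotide within the ZZ = CA class, the fraction matching the full
#' E-box CANNTG, and the degenerate MA / BG classes at positions 1-2.
#'
#' @param sites data.frame with `chrom`, `motif_start`, `motif_strand` and
#'   `tg_distance` (the chosen TG occurrence, e.g. `closest` from
#'   [tg_distance_histogram()]).
#' @param genome named character vector.
#' @return list with `zz_counts`, `nn_counts_within_ca`,
#'   `fraction_canntg`, `fraction_ma`, `fraction_bg`, `n_excluded`.
#' @export
classify_ebox <- function(sites, genome) {
  stopifnot("tg_distance" %in% names(sites))
  zz <- character()
  nn <- character()
  n_excluded <- 0L
  for (i in seq_len(nrow(sites))) {
    d <- sites$tg_distance[i]
    if (is.na(d)) { n_excluded <- n_excluded + 1L; next }
    ch <- sites$chrom[i]
    m <- sites$motif_start[i]
    std <- sites$motif_strand[i]
    need <- d + 6L     # ZZNNTG then d spacer bases before the motif
    L <- nchar(genome[[ch]])
    enough <- if (std == "+") m >= need else m + 6L + need <= L
    if (!enough) { n_excluded <- n_excluded + 1L; next }
    up <- .upstream_seq(genome[[ch]], m, std, need)
    ebox <- substr(up, 1, 6)     # ZZNNTG
    zz <- c(zz, substr(ebox, 1, 2))
    nn <- c(nn, substr(ebox, 3, 4))
  }
  zz_counts <- sort(table(zz), decreasing = TRUE)
  nn_ca <- sort(table(nn[zz == "CA"]), decreasing = TRUE)
  z1 <- substr(zz, 1, 1)
  z2 <- substr(zz, 2, 2)
  list(zz_counts = zz_counts,
       nn_counts_within_ca = nn_ca,
       fraction_canntg = if (length(zz)) mean(zz == "CA") else NA_real_,
       fraction_ma = if (length(zz))
         mean(z1 %in% c("A", "C") & z2 == "A") else NA_real_,
       fraction_bg = if (length(zz))
         mean(z1 %in% c("C", "G", "T") & z2 == "G") else NA_real_,
       n_excluded = n_excluded)
}
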