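#' Tag tracks: sparse strand-separated 5'-end counts
#'
#' A `TagTrack` stores, per chromosome and strand, a sparse mapping from
#' 0-based position to the number of tag 5' ends observed there. It is the
#' atomic signal container for ChIP-exo, ChIP-seq and input libraries: every
#' downstream computation (smoothing, peak calling, occupancy counting,
#' composite profiles) consumes 5'-end counts only.
#'
#' @param tags data.frame with columns `chrom` (character), `pos` (integer,
#'   0-based), `strand` (`"+"` or `"-"`), `count` (positive integer).
#'   Duplicate (chrom, pos, strand) rows are aggregated.
#' @param seqlengths named integer vector of chromosome lengths (bp).
#' @param name library name.
#' @param factor factor (antibody target) label.
#' @param condition condition/time-point label.
#' @return An object of class `TagTrack`.
#' @export
tag_track <- function(tags = NULL, seqlengths, name = "library",
                      factor = NA_character_, condition = NA_character_) {
  if (is.null(tags)) {
    tags <- data.frame(chrom = character(), pos = integer(),
                       strand = character(), count = integer())
  }
  stopifnot(all(c("chrom", "pos", "strand", "count") %in% names(tags)))
  if (nrow(tags)) {
    if (!all(tags$strand %in% c("+", "-")))
      stop("tag strand must be '+' or '-'")
    if (any(tags$count <= 0))
      stop("tag counts must be positive integers")
    key <- paste(tags$chrom, tags$pos, tags$strand)
    if (anyDuplicated(key)) {
      agg <- rowsum(tags$count, key)
      parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
      tags <- data.frame(chrom = parts[, 1],
                         pos = as.integer(parts[, 2]),
                         strand = parts[, 3],
                         count = as.integer(agg[, 1]))
    }
    tags <- tags[order(tags$chrom, tags$strand, tags$pos), , drop = FALSE]
    rownames(tags) <- NULL
    bad <- !(tags$chrom %in% names(seqlengths)) |
      tags$pos < 0 | tags$pos >= seqlengths[tags$chrom]
    if (any(bad))
      stop(sum(bad), " tag(s) fall outside the declared chromosomes")
  }
  structure(list(tags = tags,
                 seqlengths = stats::setNames(as.integer(seqlengths),
                                              names(seqlengths)),
                 meta = list(name = name, factor = factor,
                             condition = condition)),
            class = "TagTrack")
}

#' @export
print.TagTrack <- function(x, ...) {
  cat("TagTrack '", x$meta$name, "': ", total_tags(x), " tags on ",
      length(x$seqlengths), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Total tag count of a track
#' @param track a `TagTrack`.
#' @return integer total over all positions and strands.
#' @export
total_tags <- function(track) {
  sum(track$tags$count)
}

#' Dense per-strand count vector for one chromosome
#'
#' Expands the sparse representation to a numeric vector of length
#' `seqlengths[chrom]`, where element `i` holds the tag count at 0-based
#' position `i - 1`.
#'
#' @param track a `TagTrack`.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @return numeric vector of per-base 5'-end counts.
#' @export
strand_counts <- function(track, chrom, strand) {
  len <- track$seqlengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  v <- numeric(len)
  sel <- track$tags$chrom == chrom & track$tags$strand == strand
  if (any(sel)) v[track$tags$pos[sel] + 1L] <- track$tags$count[sel]
  v
}

#' Tag counts in windows around positions
#'
#' Sums tags with 5' ends in `[center + from, center + to]` (0-based,
#' inclusive) for each center. Used for enrichment counting, occupancy
#' windows and correlation windows.
#'
#' @param track a `TagTrack`.
#' @param chrom chromosome of the centers (recycled if length 1).
#' @param centers integer vector of 0-based center positions.
#' @param from,to window bounds relative to the center, inclusive.
#' @param strand optional: restrict to one strand (`"+"` or `"-"`).
#' @return numeric vector of counts, one per center.
#' @export
window_counts <- function(track, chrom, centers, from, to, strand = NULL) {
  chrom <- rep_len(chrom, length(centers))
  out <- numeric(length(centers))
  tg <- track$tags
  if (!is.null(strand)) tg <- tg[tg$strand == strand, , drop = FALSE]
  for (ch in unique(chrom)) {
    sel <- tg$chrom == ch
    if (!any(sel)) next
    pos <- tg$pos[sel]
    cnt <- tg$count[sel]
    o <- order(pos)
    pos <- pos[o]
    cs <- cumsum(cnt[o])
    idx <- which(chrom == ch)
    lo <- findInterval(centers[idx] + from - 1L, pos)
    hi <- findInterval(centers[idx] + to, pos)
    out[idx] <- cs[pmax(hi, 1L)] * (hi > 0) - cs[pmax(lo, 1L)] * (lo > 0)
  }
  out
}

#' Merge tag tracks
#'
#' Pools the tags of several libraries (e.g. time points of one factor) into
#' one track, as done when computing merged-data occupancy.
#'
#' @param ... `TagTrack` objects sharing chromosome lengths.
#' @param name name of the merged library.
#' @return a `TagTrack`.
#' @export
merge_tracks <- function(..., name = "merged") {
  tracks <- list(...)
  stopifnot(length(tracks) >= 1)
  sl <- tracks[[1]]$seqlengths
  tags <- do.call(rbind, lapply(tracks, function(t) t$tags))
  tag_track(tags, sl, name = name, factor = tracks[[1]]$meta$factor)
}
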