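#' Read tag 5' ends from a BED file
#'
#' Each BED record contributes exactly one tag at its 5' end: `start` for
#' plus-strand records, `end - 1` for minus-strand records (0-based,
#' half-open coordinates). Fragment 3' ends are discarded: all analyses in
#' this package operate on 5'-end counts only.
#'
#' @param path BED file (at least 6 columns; strand required).
#' @param seqlengths optional named integer vector of chromosome lengths; if
#'   missing, lengths are taken as the maximum observed end per chromosome.
#' @param name,factor,condition library metadata.
#' @return a [tag_track()].
#' @export
read_tags <- function(path, seqlengths = NULL, name = basename(path),
                      factor = NA_character_, condition = NA_character_) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to parse BED '", path,
                                          "': ", conditionMessage(e)))
  if (length(gr) == 0) {
    if (is.null(seqlengths)) seqlengths <- c(chr1 = 1L)
    return(tag_track(NULL, seqlengths, name, factor, condition))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("BED records without strand cannot define a tag 5' end (record ",
         which(strand == "*")[1], ")")
  # rtracklayer is 1-based inclusive; convert to 0-based 5' ends
  pos <- ifelse(strand == "+",
                BiocGenerics::start(gr) - 1L,
                BiocGenerics::end(gr) - 1L)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (is.null(seqlengths)) {
    seqlengths <- tapply(BiocGenerics::end(gr), chrom, max)
    seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  }
  tag_track(data.frame(chrom = chrom, pos = as.integer(pos),
                       strand = strand, count = 1L),
            seqlengths, name, factor, condition)
}

#' Write a tag track as BED
#'
#' One record per tag (count > 1 expands to repeated records), 0-based
#' half-open, 1-bp intervals at the 5'-end position.
#'
#' @param track a `TagTrack`.
#' @param path output BED path.
#' @export
write_tags <- function(track, path) {
  tg <- track$tags
  tg <- tg[rep(seq_len(nrow(tg)), tg$count), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = tg$chrom,
    ranges = IRanges::IRanges(start = tg$pos + 1L, width = 1L),
    strand = tg$strand)
  S4Vectors::mcols(gr)$name <- rep(track$meta$name, length(gr))
  S4Vectors::mcols(gr)$score <- rep(0L, length(gr))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read genomic intervals from BED (e.g. a blacklist)
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (0-based, half-open) and
#'   `strand` (`"."` when absent).
#' @export
read_intervals <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to parse BED '", path,
                                          "': ", conditionMessage(e)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = sub("\\*", ".", as.character(BiocGenerics::strand(gr))))
}

#' Read / write binding-location tables
#'
#' Binding locations travel as headered tab-separated tables; `chrom` and
#' `midpoint` are mandatory, all other columns (per-condition occupancy,
#' motif annotation, q values, ...) are carried through unchanged, so
#' `write_locations()` followed by `read_locations()` is the identity.
#'
#' @param locations data.frame with at least `chrom` and `midpoint`.
#' @param path TSV path.
#' @return `read_locations` returns the data.frame.
#' @export
write_locations <- function(locations, path) {
  .check_location_columns(locations)
  utils::write.table(locations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_locations
#' @export
read_locations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check_location_columns(df)
  df
}

.check_location_columns <- function(df) {
  required <- c("chrom", "midpoint")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("location table is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read / write genome FASTA
#'
#' Sequences are returned as a named character vector in canonical
#' uppercase; lowercase (soft-masked) input is accepted.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate sequence name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  stats::setNames(toupper(as.character(set)), nm)
}

#' @rdname read_fasta
#' @param genome named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(toupper(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Snapshot run parameters as YAML
#'
#' @param params named list of parameters.
#' @param path output path.
#' @export
write_run_config <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}
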