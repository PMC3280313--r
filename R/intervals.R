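#' @importFrom GenomicRanges GRanges findOverlaps reduce seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All coordinates inside the package are 0-based half-open (UCSC table
# convention).  The helpers below are the only place the +/-1 arithmetic to
# and from the 1-based closed GRanges representation occurs.

#' Construct a genomic interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' `strand`, using 0-based half-open coordinates throughout.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive.
#' @param end Integer vector, 0-based exclusive (`end > start`).
#' @param strand Character vector in `+`, `-`, `*` (recycled).
#' @return A validated data frame of intervals.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), strand = "*") {
  iv <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv, what = "interval") {
  stopifnot(is.data.frame(iv),
            all(c("chrom", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0) return(invisible(iv))
  if (any(is.na(iv$chrom)) || any(!nzchar(iv$chrom)))
    stop(what, ": chrom must be non-empty")
  bad <- which(!(iv$start >= 0 & iv$end > iv$start))
  if (length(bad))
    stop(what, " ", bad[1], ": need 0 <= start < end (got start=",
         iv$start[bad[1]], ", end=", iv$end[bad[1]], ")")
  invisible(iv)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

# GRanges conversions over a shared seqlevel universe so findOverlaps never
# complains about disjoint seqinfo.
gr_intervals <- function(iv, levels) {
  GenomicRanges::GRanges(factor(iv$chrom, levels = levels),
                         IRanges::IRanges(start = iv$start + 1, end = iv$end))
}

gr_points <- function(chrom, pos, levels) {
  GenomicRanges::GRanges(factor(chrom, levels = levels),
                         IRanges::IRanges(start = pos + 1, width = 1))
}

#' Merge (union) a set of intervals per chromosome
#'
#' @param iv Interval data frame.
#' @return Interval data frame of the merged union, strand dropped, sorted
#'   by (chrom, start).
#' @export
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(empty_intervals())
  validate_intervals(iv)
  lv <- sort(unique(iv$chrom))
  r <- GenomicRanges::reduce(gr_intervals(iv, lv))
  data.frame(chrom = as.character(GenomicRanges::seqnames(r)),
             start = GenomicRanges::start(r) - 1,
             end = as.numeric(GenomicRanges::end(r)),
             strand = "*", stringsAsFactors = FALSE)
}

#' Total base-pair area of the merged union of intervals
#'
#' @param iv Interval data frame.
#' @return Numeric scalar, sum of merged interval widths in bp.
#' @export
interval_area <- function(iv) {
  m <- merge_intervals(iv)
  sum(m$end - m$start)
}

# (point, interval) overlap pairs; returns data.frame(point, region) of
# indices.  Point i overlaps region j iff start_j <= pos_i < end_j.
point_overlap_pairs <- function(chrom, pos, iv) {
  if (length(pos) == 0 || nrow(iv) == 0)
    return(data.frame(point = integer(), region = integer()))
  lv <- sort(unique(c(chrom, iv$chrom)))
  h <- GenomicRanges::findOverlaps(gr_points(chrom, pos, lv),
                                   gr_intervals(iv, lv))
  data.frame(point = S4Vectors::queryHits(h),
             region = S4Vectors::subjectHits(h))
}

#' Build a point-in-interval query index
#'
#' Wraps a set of intervals for repeated point queries.  Two query modes are
#' supported downstream: membership in the merged union (used for density
#' denominators) and per-region-instance hits (used for profiles, where a
#' summit near two anchors counts twice).
#'
#' @param iv Interval data frame.
#' @return An object of class `interval_index`.
#' @export
build_index <- function(iv) {
  validate_intervals(iv)
  structure(list(intervals = iv, merged = merge_intervals(iv)),
            class = "interval_index")
}

#' Count summits falling in an indexed interval set
#'
#' @param index An `interval_index` from [build_index()], or a plain interval
#'   data frame.
#' @param summits Summit data frame (`chrom`, `pos`).
#' @param mode `"unique"` counts each summit at most once (membership in the
#'   merged union); `"per_region"` counts one hit per (summit, region
#'   instance) pair.
#' @return Integer count.
#' @export
count_points_in <- function(index, summits, mode = c("unique", "per_region")) {
  mode <- match.arg(mode)
  if (!inherits(index, "interval_index")) index <- build_index(index)
  if (is.null(summits) || nrow(summits) == 0) return(0L)
  iv <- if (mode == "unique") index$merged else index$intervals
  nrow(point_overlap_pairs(summits$chrom, summits$pos, iv))
}

# Logical: is each point inside the merged union of iv?
points_in_union <- function(chrom, pos, iv) {
  out <- logical(length(pos))
  if (length(pos) == 0) return(out)
  m <- merge_intervals(iv)
  if (nrow(m) == 0) return(out)
  hits <- point_overlap_pairs(chrom, pos, m)
  out[unique(hits$point)] <- TRUE
  out
}

# Intersect iv with a single window [start, end) on one chromosome.
clip_intervals <- function(iv, chrom, start, end) {
  if (nrow(iv) == 0) return(empty_intervals())
  keep <- iv$chrom == chrom & iv$start < end & iv$end > start
  out <- iv[keep, , drop = FALSE]
  out$start <- pmax(out$start, start)
  out$end <- pmin(out$end, end)
  rownames(out) <- NULL
  out
}

# Set difference a \ b per chromosome, both interval data frames.
setdiff_intervals <- function(a, b) {
  if (nrow(a) == 0) return(empty_intervals())
  if (is.null(b) || nrow(b) == 0) return(merge_intervals(a))
  lv <- sort(unique(c(a$chrom, b$chrom)))
  ga <- GenomicRanges::reduce(gr_intervals(a, lv))
  gb <- GenomicRanges::reduce(gr_intervals(b, lv))
  d <- GenomicRanges::setdiff(ga, gb)
  if (length(d) == 0) return(empty_intervals())
  data.frame(chrom = as.character(GenomicRanges::seqnames(d)),
             start = GenomicRanges::start(d) - 1,
             end = as.numeric(GenomicRanges::end(d)),
             strand = "*", stringsAsFactors = FALSE)
}
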