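# CpG-island methylation classification, validation, size binning and
# genomic-location assignment.

#' Classify CpG islands as methylated or unmethylated
#'
#' An island is methylated iff at least one methylation peak summit falls
#' inside it (`[start, end)`, half-open: a summit exactly at `end` does not
#' count).
#'
#' @param islands Island data frame from [read_cgi_track()].
#' @param summits Summit data frame.
#' @return The island data frame with added `summit_count` and `status`
#'   (`"methylated"` / `"unmethylated"`) columns.
#' @export
classify_islands <- function(islands, summits) {
  counts <- integer(nrow(islands))
  if (nrow(islands) && nrow(summits)) {
    hits <- point_overlap_pairs(summits$chrom, summits$pos, islands)
    tab <- table(hits$region)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  islands$summit_count <- counts
  islands$status <- ifelse(counts >= 1, "methylated", "unmethylated")
  islands
}

#' Validate CpG-island criteria
#'
#' An island is a valid CGI iff (a) length strictly greater than 200 bp,
#' (b) GC content > 50%, and (c) CpG observed/expected > 0.6.  With a
#' nucleotide sequence the statistics are recomputed from scratch:
#' `GC = (#G + #C) / len` and `obs/exp = (#CG dinucleotides * len) /
#' (#C * #G)`; otherwise the track's fields are used.
#'
#' @param islands Island data frame.
#' @param sequences Optional character vector of island sequences (one per
#'   island, each of the island's length).
#' @return Data frame: `valid` (logical) and `reasons` (comma-separated
#'   failed criteria, empty when valid).
#' @export
validate_cgi <- function(islands, sequences = NULL) {
  len <- islands$end - islands$start
  gc <- islands$gc_fraction
  oe <- islands$obs_exp
  if (!is.null(sequences)) {
    if (length(sequences) != nrow(islands))
      stop("validate_cgi: one sequence per island required")
    sl <- nchar(sequences)
    if (any(sl != len))
      stop("validate_cgi: sequence length differs from island length (island ",
           which(sl != len)[1], ")")
    up <- toupper(sequences)
    nC <- nchar(up) - nchar(gsub("C", "", up, fixed = TRUE))
    nG <- nchar(up) - nchar(gsub("G", "", up, fixed = TRUE))
    nCG <- vapply(up, function(s) {
      m <- gregexpr("(?=CG)", s, perl = TRUE)[[1]]
      if (m[1] == -1) 0 else length(m)
    }, numeric(1), USE.NAMES = FALSE)
    gc <- (nC + nG) / len
    oe <- ifelse(nC * nG > 0, nCG * len / (nC * nG), 0)
  }
  fail_len <- !(len > 200)
  fail_gc <- !(gc > 0.5)
  fail_oe <- !(oe > 0.6)
  reasons <- mapply(function(a, b, c)
    paste(c(if (a) "length<=200", if (b) "gc<=0.5",
            if (c) "obs_exp<=0.6"), collapse = ","),
    fail_len, fail_gc, fail_oe)
  data.frame(valid = !(fail_len | fail_gc | fail_oe), reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Bin islands by size
#'
#' Assigns each island a half-open size bin `[lo, hi)` from the given edges,
#' with a terminal open-ended bin (default: 100 bp steps from 200 bp up to a
#' `>=1000` bin).  Islands shorter than the first edge go to an explicit
#' `<min` bin with a warning.
#'
#' @param calls Island data frame (optionally from [classify_islands()]).
#' @param edges Strictly increasing numeric bin edges.
#' @return The input with an added `size_bin` factor column.
#' @export
bin_by_size <- function(calls, edges = seq(200, 1000, by = 100)) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("bin_by_size: edges must be strictly increasing")
  len <- calls$end - calls$start
  labs <- c(paste0("<", edges[1]),
            paste0(edges[-length(edges)], "-", edges[-1]),
            paste0(">=", edges[length(edges)]))
  idx <- findInterval(len, edges) + 1L
  if (any(idx == 1L))
    warning("bin_by_size: ", sum(idx == 1L), " island(s) shorter than ",
            edges[1], " bp assigned to bin '", labs[1], "'")
  calls$size_bin <- factor(labs[idx], levels = labs)
  calls
}

#' Per-status island counts per size bin
#'
#' @param calls Output of [classify_islands()] + [bin_by_size()].
#' @return Data frame: `size_bin`, `methylated`, `unmethylated`, `total`.
#' @export
size_bin_table <- function(calls) {
  tab <- table(calls$size_bin, factor(calls$status,
                                      levels = c("methylated",
                                                 "unmethylated")))
  data.frame(size_bin = rownames(tab),
             methylated = as.integer(tab[, "methylated"]),
             unmethylated = as.integer(tab[, "unmethylated"]),
             total = as.integer(rowSums(tab)), stringsAsFactors = FALSE)
}

#' Assign each island a genomic location
#'
#' Islands are placed into one of `exon`, `promoter`, `intron` or `others`
#' by largest base-pair overlap with the merged feature classes (5 kb
#' promoters by default); ties break by the precedence exon > promoter >
#' intron, and islands overlapping none of the three are `others`.
#'
#' @param calls Island data frame.
#' @param fs A `feature_set` from [derive_features()].
#' @return The input with an added `location` column.
#' @export
locate_islands <- function(calls, fs) {
  classes <- c(exon = "exon", promoter = "promoter_5kb", intron = "intron")
  ov <- matrix(0, nrow = nrow(calls), ncol = length(classes),
               dimnames = list(NULL, names(classes)))
  for (j in seq_along(classes)) {
    iv <- merge_intervals(fs$features[[classes[j]]])
    if (nrow(iv) == 0) next
    lv <- sort(unique(c(calls$chrom, iv$chrom)))
    h <- GenomicRanges::findOverlaps(gr_intervals(calls, lv),
                                     gr_intervals(iv, lv))
    if (length(h) == 0) next
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    w <- pmin(calls$end[qi], iv$end[si]) - pmax(calls$start[qi], iv$start[si])
    agg <- tapply(w, qi, sum)
    ov[as.integer(names(agg)), j] <- as.numeric(agg)
  }
  best <- apply(ov, 1, function(r)
    if (all(r == 0)) "others" else names(classes)[which.max(r)])
  calls$location <- best
  calls
}

#' Per-size-bin normalized island location distribution
#'
#' Within each size bin, counts islands per location and divides by the
#' total number of islands in that bin, so each bin's fractions sum to 1.
#'
#' @param calls Output of [bin_by_size()] + [locate_islands()]; may be
#'   pre-filtered to one methylation status.
#' @return Data frame: `size_bin`, `location`, `count`, `fraction`.
#' @export
island_location_table <- function(calls) {
  locs <- c("exon", "promoter", "intron", "others")
  tab <- table(calls$size_bin, factor(calls$location, levels = locs))
  totals <- rowSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("size_bin", "location", "count")
  out$fraction <- ifelse(totals[out$size_bin] > 0,
                         out$count / totals[out$size_bin], 0)
  out[order(match(out$size_bin, rownames(tab))), , drop = FALSE]
}
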