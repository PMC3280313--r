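# Binned, anchor-normalized, smoothed summit-density metaprofiles around
# TSSs, exon junctions and CpG-island starts.

#' Centered moving average with edge-shrunk windows
#'
#' Smooths a numeric vector with a centered window of `k` values.  Near the
#' edges the window is truncated to the available values (for `k = 5` the
#' first output averages values 1..3), so the output has the input's length
#' and no padding zeros bias the ends.
#'
#' @param values Numeric vector.
#' @param k Odd window size; `k = 1` is the identity.
#' @return Numeric vector of `length(values)`.
#' @export
moving_average <- function(values, k = 5) {
  if (length(k) != 1 || k < 1 || k %% 2 != 1)
    stop("moving_average: k must be a positive odd integer")
  n <- length(values)
  if (n == 0 || k == 1) return(values)
  h <- (k - 1) / 2
  vapply(seq_len(n), function(i) {
    w <- max(1, i - h):min(n, i + h)
    mean(values[w])
  }, numeric(1))
}

#' Metaprofile of summit density around a set of anchors
#'
#' For every (summit, anchor) pair whose strand-oriented offset lies in
#' `[-flank, flank)`, the pair contributes one count to the bin
#' `[k * bin_width, (k + 1) * bin_width)` containing the offset.  Offsets
#' are oriented by the anchor's strand: on `-` anchors the offset is
#' mirrored so that negative is always upstream in transcript direction.
#' Per-bin counts are normalized by the number of anchors (anchors near a
#' chromosome edge keep their truncated windows but still count in the
#' denominator) and smoothed with [moving_average()].
#'
#' @param summits Summit data frame.
#' @param anchors Data frame with `chrom`, `pos` (0-based anchor base) and
#'   optional `strand` (`*` is treated as `+`).
#' @param flank Half window in bp; must be a multiple of `bin_width`.
#' @param bin_width Bin width in bp.
#' @param smooth_k Moving-average window (odd), default 5.
#' @param anchor_kind Label stored in the profile.
#' @return Object of class `medip_profile`: list with `offsets` (bin left
#'   edges relative to the anchor), `raw_counts`, `n_anchors`, `normalized`,
#'   `smoothed`, and the parameters.
#' @export
anchored_profile <- function(summits, anchors, flank = 5000, bin_width = 100,
                             smooth_k = 5, anchor_kind = "anchor") {
  if (nrow(anchors) == 0) stop("anchored_profile: no anchors supplied")
  if (flank <= 0 || bin_width <= 0 || flank %% bin_width != 0)
    stop("anchored_profile: flank must be a positive multiple of bin_width")
  strand <- if ("strand" %in% names(anchors)) anchors$strand else "*"
  strand <- rep_len(strand, nrow(anchors))
  n_bins <- as.integer(2 * flank / bin_width)
  offsets <- seq(-flank, flank - bin_width, by = bin_width)
  raw <- integer(n_bins)
  if (nrow(summits) > 0) {
    # fetch one bp extra on each side, then filter on the oriented offset
    win <- data.frame(chrom = anchors$chrom,
                      start = pmax(0, anchors$pos - flank),
                      end = anchors$pos + flank + 1,
                      stringsAsFactors = FALSE)
    hits <- point_overlap_pairs(summits$chrom, summits$pos, win)
    if (nrow(hits) > 0) {
      off <- summits$pos[hits$point] - anchors$pos[hits$region]
      minus <- strand[hits$region] == "-"
      off[minus] <- -off[minus]
      keep <- off >= -flank & off < flank
      if (any(keep)) {
        bin <- floor(off[keep] / bin_width) + flank / bin_width + 1
        raw <- tabulate(bin, nbins = n_bins)
      }
    }
  }
  normalized <- raw / nrow(anchors)
  structure(list(anchor_kind = anchor_kind, bin_width = bin_width,
                 flank = flank, smooth_k = smooth_k, offsets = offsets,
                 raw_counts = raw, n_anchors = nrow(anchors),
                 normalized = normalized,
                 smoothed = moving_average(normalized, smooth_k)),
            class = "medip_profile")
}

#' @export
print.medip_profile <- function(x, ...) {
  cat(sprintf("medip_profile '%s': %d anchors, %d bins of %d bp (flank %d bp)\n",
              x$anchor_kind, x$n_anchors, length(x$offsets), x$bin_width,
              x$flank))
  cat(sprintf("  total summit hits %d; normalized range [%.4g, %.4g]\n",
              sum(x$raw_counts), min(x$normalized), max(x$normalized)))
  invisible(x)
}

#' @export
as.data.frame.medip_profile <- function(x, ...) {
  data.frame(offset = x$offsets, raw = x$raw_counts,
             normalized = x$normalized, smoothed = x$smoothed)
}

#' Stratify genes by expression level
#'
#' Per gene, replicate intensities are averaged first and the mean converted
#' to log2.  Genes more than one sample standard deviation above (below) the
#' mean of that log2 score are the high (low) stratum.
#'
#' @param expr Expression data frame from [read_expression()]: `gene_id`
#'   plus one positive numeric column per replicate.
#' @return List with `high` and `low` gene-id vectors, `mu`, `sigma`, and
#'   the per-gene scores `x`.
#' @export
stratify_expression <- function(expr) {
  reps <- setdiff(names(expr), "gene_id")
  vals <- as.matrix(expr[, reps, drop = FALSE])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("stratify_expression: intensities must be positive and finite")
  if (nrow(expr) < 2)
    stop("stratify_expression: need at least 2 genes")
  x <- log2(rowMeans(vals))
  mu <- mean(x)
  sigma <- stats::sd(x)
  list(high = expr$gene_id[x > mu + sigma],
       low = expr$gene_id[x < mu - sigma],
       mu = mu, sigma = sigma,
       x = stats::setNames(x, expr$gene_id))
}

tss_anchors <- function(genes) {
  plus <- genes$strand != "-"
  data.frame(chrom = genes$chrom,
             pos = ifelse(plus, genes$tx_start, genes$tx_end - 1),
             strand = genes$strand, gene = genes$name,
             stringsAsFactors = FALSE)
}

#' TSS metaprofiles, optionally stratified by expression
#'
#' Anchors are transcription start sites (the first transcribed base:
#' `txStart` on `+`, the base before `txEnd` on `-`).  With `strata`
#' (from [stratify_expression()]) separate profiles are computed for all
#' genes and for the high/low strata; stratum gene ids are resolved against
#' the transcript name and gene symbol, unresolved ids are dropped with a
#' message, and an empty stratum after resolution is an error.
#'
#' @param summits Summit data frame.
#' @param genes Gene-model data frame.
#' @param strata Optional list with `high`/`low` gene-id vectors.
#' @param flank,bin_width,smooth_k Profile parameters (defaults 5000 / 100 /
#'   5).
#' @return A single `medip_profile` when `strata` is `NULL`, else a named
#'   list of profiles (`all`, `high`, `low`).
#' @export
tss_profile <- function(summits, genes, strata = NULL, flank = 5000,
                        bin_width = 100, smooth_k = 5) {
  anchors <- tss_anchors(genes)
  if (is.null(strata))
    return(anchored_profile(summits, anchors, flank, bin_width, smooth_k,
                            anchor_kind = "tss"))
  out <- list(all = anchored_profile(summits, anchors, flank, bin_width,
                                     smooth_k, anchor_kind = "tss"))
  for (s in c("high", "low")) {
    ids <- strata[[s]]
    hit <- genes$name %in% ids |
      (!is.na(genes$gene_symbol) & genes$gene_symbol %in% ids)
    n_unresolved <- length(setdiff(ids, c(genes$name, genes$gene_symbol)))
    if (n_unresolved > 0)
      message("tss_profile: ", n_unresolved, " unresolved gene id(s) in '",
              s, "' stratum skipped")
    if (!any(hit))
      stop("tss_profile: stratum '", s, "' is empty after id resolution")
    out[[s]] <- anchored_profile(summits, anchors[hit, , drop = FALSE],
                                 flank, bin_width, smooth_k,
                                 anchor_kind = paste0("tss_", s))
  }
  out
}

#' Exon-junction metaprofiles
#'
#' Anchors are exon starts (acceptor side) or exon ends (donor side) in
#' transcript orientation: on `+` the start anchor is the exon's first base
#' and the end anchor its last; on `-` the roles mirror.  Exon subsets for
#' the figure-level contrasts (first/last/internal/second exons, coding vs
#' non-coding) are selected with [select_exons()].
#'
#' @param summits Summit data frame.
#' @param exons Exon interval data frame (`chrom`, `start`, `end`,
#'   `strand`), e.g. from [select_exons()].
#' @param anchor `"exon_start"` or `"exon_end"`, in transcript orientation.
#' @param flank,bin_width,smooth_k Profile parameters (defaults 200 / 10 /
#'   5).
#' @return A `medip_profile`.
#' @export
junction_profile <- function(summits, exons,
                             anchor = c("exon_start", "exon_end"),
                             flank = 200, bin_width = 10, smooth_k = 5) {
  anchor <- match.arg(anchor)
  if (nrow(exons) == 0)
    stop("junction_profile: empty exon selection")
  plus <- exons$strand != "-"
  pos <- if (anchor == "exon_start")
    ifelse(plus, exons$start, exons$end - 1)
  else
    ifelse(plus, exons$end - 1, exons$start)
  anchors <- data.frame(chrom = exons$chrom, pos = pos,
                        strand = exons$strand, stringsAsFactors = FALSE)
  anchored_profile(summits, anchors, flank, bin_width, smooth_k,
                   anchor_kind = anchor)
}

#' CpG-island start metaprofile
#'
#' Anchors are island start coordinates; the CGI track is unstranded, so no
#' orientation is applied.  Useful for contrasting methylated vs
#' unmethylated islands (pre-filter `islands` by the [classify_islands()]
#' status).
#'
#' @param summits Summit data frame.
#' @param islands Island data frame.
#' @param flank,bin_width,smooth_k Profile parameters (defaults 5000 / 100 /
#'   5).
#' @return A `medip_profile`.
#' @export
cgi_start_profile <- function(summits, islands, flank = 5000,
                              bin_width = 100, smooth_k = 5) {
  if (nrow(islands) == 0) stop("cgi_start_profile: no islands supplied")
  anchors <- data.frame(chrom = islands$chrom, pos = islands$start,
                        strand = "*", stringsAsFactors = FALSE)
  anchored_profile(summits, anchors, flank, bin_width, smooth_k,
                   anchor_kind = "cgi_start")
}
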