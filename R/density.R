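# Bar-plot methylation densities: summit count per bp of region area.

#' Methylation density of a region set
#'
#' Density is the number of peak summits falling in the merged union of the
#' regions divided by the union's area in bp, so a summit inside two
#' overlapping regions counts once and the numerator matches the merged
#' denominator.
#'
#' @param summits Summit data frame.
#' @param regions Interval data frame.
#' @param label Row label for the output.
#' @return One-row data frame: `label`, `summit_count`, `area_bp`,
#'   `density`.
#' @export
region_density <- function(summits, regions, label = "region") {
  area <- interval_area(regions)
  if (area <= 0)
    stop("region_density: merged area of '", label, "' is zero")
  count <- count_points_in(regions, summits, mode = "unique")
  data.frame(label = label, summit_count = count, area_bp = area,
             density = count / area, stringsAsFactors = FALSE)
}

#' Per-feature-class methylation density table
#'
#' One density record per gene-model feature class (promoters, exon,
#' intron, exonic UTRs) and, when a repeat track is given, per repeat
#' class.  Classes with zero merged area are omitted.  Alongside the raw
#' densities a `share` column gives each class's relative share
#' (`density / sum(densities)`).
#'
#' @param summits Summit data frame.
#' @param fs A `feature_set` from [derive_features()].
#' @param repeats Optional repeat data frame from [read_rmsk()].
#' @param classes Feature classes to report; defaults to the promoter,
#'   exon, intron and UTR-exonic classes.
#' @return Data frame: `label`, `summit_count`, `area_bp`, `density`,
#'   `share`.
#' @export
class_density_table <- function(summits, fs, repeats = NULL,
                                classes = c("promoter_5kb",
                                            "promoter_proximal_2kb", "exon",
                                            "intron", "utr5_exonic",
                                            "utr3_exonic")) {
  rows <- list()
  for (cl in classes) {
    iv <- fs$features[[cl]]
    if (is.null(iv) || interval_area(iv) == 0) next
    rows[[cl]] <- region_density(summits, iv, cl)
  }
  if (!is.null(repeats) && nrow(repeats) > 0) {
    for (rc in unique(repeats$rep_class)) {
      iv <- repeats[repeats$rep_class == rc, , drop = FALSE]
      rows[[rc]] <- region_density(summits, iv, rc)
    }
  }
  if (!length(rows)) stop("class_density_table: no class with positive area")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$share <- out$density / sum(out$density)
  out
}

#' Exclusive summit-class fractions
#'
#' Classifies every summit into exactly one class by precedence (see
#' [classify_points()]) and reports the fraction of summits per class,
#' including the `others` remainder, so the fractions always sum to 1.
#' When any precedence label is a repeat class, the attribute
#' `repeats_overall` carries the summed fraction across repeat classes.
#'
#' @inheritParams classify_points
#' @return Data frame: `label`, `count`, `fraction`; attribute
#'   `repeats_overall`.
#' @export
summit_class_fractions <- function(summits, fs, repeats = NULL,
                                   precedence = default_precedence(repeats)) {
  if (nrow(summits) == 0)
    stop("summit_class_fractions: fractions are undefined for an empty summit set")
  labels <- classify_points(summits, fs, repeats, precedence)
  lvls <- c(precedence, "others")
  counts <- table(factor(labels, levels = lvls))
  out <- data.frame(label = lvls, count = as.integer(counts),
                    fraction = as.integer(counts) / nrow(summits),
                    stringsAsFactors = FALSE)
  rep_labels <- if (!is.null(repeats))
    intersect(precedence, c(unique(repeats$rep_class), "repeat"))
  else character()
  attr(out, "repeats_overall") <-
    sum(out$fraction[out$label %in% rep_labels])
  out
}

# Three bins around an event: 200 bp upstream of the start, the event body,
# and 200 bp downstream of the end (genomic orientation; bins clipped at the
# chromosome start).
event_bins <- function(events, flank_bp = 200) {
  list(upstream_200 = data.frame(chrom = events$chrom,
                                 start = pmax(0, events$start - flank_bp),
                                 end = events$start, stringsAsFactors = FALSE),
       body = data.frame(chrom = events$chrom, start = events$start,
                         end = events$end, stringsAsFactors = FALSE),
       downstream_200 = data.frame(chrom = events$chrom, start = events$end,
                                   end = events$end + flank_bp,
                                   stringsAsFactors = FALSE))
}

#' Three-bin methylation density per splice-event type
#'
#' For each event type present, pools three bins over all events of that
#' type — 200 bp upstream of the event start, the event body, and 200 bp
#' downstream of the event end — and computes summit count / area per bin.
#' Counts and areas are pooled per event instance (a summit falling in two
#' events' bins contributes to both), mirroring the per-anchor counting of
#' the metaprofiles.  Upstream bins truncated by the chromosome start keep
#' their clipped area.
#'
#' @param summits Summit data frame.
#' @param events Splice-event data frame from [read_splice_events()].
#' @param flank_bp Upstream/downstream bin width, default 200 bp.
#' @return Named list (one per event type) of three-row data frames with
#'   columns `bin`, `summit_count`, `area_bp`, `density`.
#' @export
splice_event_density <- function(summits, events, flank_bp = 200) {
  if (nrow(events) == 0) stop("splice_event_density: no events supplied")
  out <- list()
  for (ty in unique(events$event_type)) {
    ev <- events[events$event_type == ty, , drop = FALSE]
    bins <- event_bins(ev, flank_bp)
    rows <- lapply(names(bins), function(bn) {
      iv <- bins[[bn]]
      iv <- iv[iv$end > iv$start, , drop = FALSE]
      area <- sum(iv$end - iv$start)
      if (area <= 0)
        stop("splice_event_density: zero pooled area for bin '", bn,
             "' of event type '", ty, "'")
      count <- if (nrow(iv)) nrow(point_overlap_pairs(summits$chrom,
                                                      summits$pos, iv)) else 0L
      data.frame(bin = bn, summit_count = count, area_bp = area,
                 density = count / area, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    out[[ty]] <- tab
  }
  out
}
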