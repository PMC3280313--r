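# Alternative-splicing methylation comparisons: retained vs constitutive
# introns (and cassette vs constitutive exons) via the three-bin density
# layout, plus per-intron methylation calls for RT-PCR candidate nomination.

#' Compare methylation between two splice-event classes
#'
#' Computes the three-bin density layout ([splice_event_density()]) for a
#' test and a control event type and summarizes the contrast as
#' `body_ratio` = test body density / control body density.
#'
#' @param summits Summit data frame.
#' @param events Splice-event data frame containing both types.
#' @param test_type,control_type Event types to contrast, e.g.
#'   `"intron_retention"` vs `"constitutive_intron"`.
#' @param flank_bp Upstream/downstream bin width, default 200 bp.
#' @return Object of class `event_comparison`: list with `test`, `control`
#'   (three-bin density tables), the type labels and `body_ratio`.
#' @export
compare_event_classes <- function(summits, events, test_type, control_type,
                                  flank_bp = 200) {
  for (ty in c(test_type, control_type))
    if (!any(events$event_type == ty))
      stop("compare_event_classes: no events of type '", ty, "'")
  dens <- splice_event_density(
    summits, events[events$event_type %in% c(test_type, control_type), ,
                    drop = FALSE], flank_bp)
  test <- dens[[test_type]]
  control <- dens[[control_type]]
  ctrl_body <- control$density[control$bin == "body"]
  if (ctrl_body == 0)
    stop("compare_event_classes: control body density is zero; ratio undefined")
  structure(list(test_type = test_type, control_type = control_type,
                 test = test, control = control,
                 body_ratio = test$density[test$bin == "body"] / ctrl_body),
            class = "event_comparison")
}

#' @export
print.event_comparison <- function(x, ...) {
  cat(sprintf("event_comparison: %s vs %s, body density ratio %.3f\n",
              x$test_type, x$control_type, x$body_ratio))
  invisible(x)
}

#' Flag methylated introns as retention candidates
#'
#' Counts summits per intron body and flags introns with at least
#' `min_summits` hits as methylated, i.e. predicted-retention candidates for
#' targeted RT-PCR follow-up.
#'
#' @param summits Summit data frame.
#' @param introns Interval data frame of intron bodies (e.g. splice events
#'   of one type, or [derive_features()]'s `intron` class).
#' @param min_summits Minimum summit count to flag, default 1.
#' @return Data frame of the introns with `summit_count` and `methylated`
#'   columns, sorted by count descending.
#' @export
call_retained_candidates <- function(summits, introns, min_summits = 1) {
  validate_intervals(introns, "intron")
  counts <- integer(nrow(introns))
  if (nrow(introns) && nrow(summits)) {
    hits <- point_overlap_pairs(summits$chrom, summits$pos, introns)
    tab <- table(hits$region)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  introns$summit_count <- counts
  introns$methylated <- counts >= min_summits
  out <- introns[order(-introns$summit_count), , drop = FALSE]
  rownames(out) <- NULL
  out
}
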