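# MeDIP quality metrics: qPCR fold enrichment, replicate concordance, and
# summit saturation by data reduction.

#' qPCR fold enrichment from delta-delta-Ct
#'
#' Per region, the MeDIP-fraction Ct is normalized to the input Ct
#' (`dCt = ct_input - ct_medip`, so stronger pull-down gives larger dCt);
#' the target's dCt is then normalized to the dCt of an unmethylated
#' control region (`ddCt = dCt_target - dCt_control`) and the fold
#' enrichment is `E = 2 ^ ddCt`.  A methylated target enriched by MeDIP
#' therefore yields `E > 1`, and `E = 1` when target and control behave
#' identically.
#'
#' @param target One-row data frame or list with `target`, `ct_medip`,
#'   `ct_input`.
#' @param control Same fields for the unmethylated control region; its
#'   `is_control` flag must be `TRUE`.
#' @return One-row data frame: `target_name`, `delta_ct`, `delta_delta_ct`,
#'   `E`.
#' @export
enrichment <- function(target, control) {
  if (!isTRUE(as.logical(control$is_control[1])))
    stop("enrichment: control measurement must have is_control = TRUE")
  d_t <- target$ct_input - target$ct_medip
  d_c <- control$ct_input - control$ct_medip
  ddct <- d_t - d_c
  data.frame(target_name = as.character(target$target),
             delta_ct = d_t, delta_delta_ct = ddct, E = 2^ddct,
             stringsAsFactors = FALSE)
}

#' Fold enrichment for every target in a Ct table
#'
#' Applies [enrichment()] to each non-control row against the control row
#' (the mean control dCt when several control regions are present).
#'
#' @param ct Ct data frame from [read_ct_table()].
#' @return Data frame, one row per non-control target.
#' @export
enrichment_table <- function(ct) {
  ctl <- ct[ct$is_control, , drop = FALSE]
  if (nrow(ctl) == 0) stop("enrichment_table: no control row (is_control)")
  d_c <- mean(ctl$ct_input - ctl$ct_medip)
  tgt <- ct[!ct$is_control, , drop = FALSE]
  if (nrow(tgt) == 0) stop("enrichment_table: no target rows")
  d_t <- tgt$ct_input - tgt$ct_medip
  data.frame(target_name = tgt$target, delta_ct = d_t,
             delta_delta_ct = d_t - d_c, E = 2^(d_t - d_c),
             stringsAsFactors = FALSE)
}

summit_bin_counts <- function(summits, bin_bp, spans) {
  counts <- numeric(0)
  for (chrom in names(spans)) {
    n_bins <- ceiling(spans[[chrom]] / bin_bp)
    pos <- summits$pos[summits$chrom == chrom]
    counts <- c(counts, tabulate(pos %/% bin_bp + 1, nbins = n_bins))
  }
  counts
}

#' Replicate concordance by binned-coverage correlation
#'
#' Counts summit events per `bin_bp` window over the union of the two
#' replicates' chromosome spans and reports Pearson's correlation between
#' the two per-bin count vectors (all bins of the spans, including shared
#' zeros, are used).
#'
#' @param summits_a,summits_b Summit data frames for the two replicates.
#' @param bin_bp Bin width in bp, default 1 (per-base coverage).
#' @param chrom_sizes Optional named vector of chromosome lengths; by
#'   default spans are taken as `max(pos) + 1` per chromosome over both
#'   replicates.
#' @return Pearson correlation coefficient.
#' @export
replicate_concordance <- function(summits_a, summits_b, bin_bp = 1,
                                  chrom_sizes = NULL) {
  if (nrow(summits_a) == 0 || nrow(summits_b) == 0)
    stop("replicate_concordance: both replicates must be non-empty")
  if (is.null(chrom_sizes)) {
    both <- rbind(summits_a[, c("chrom", "pos")], summits_b[, c("chrom", "pos")])
    chrom_sizes <- tapply(both$pos, both$chrom, max) + 1
  }
  spans <- as.list(chrom_sizes)
  a <- summit_bin_counts(summits_a, bin_bp, spans)
  b <- summit_bin_counts(summits_b, bin_bp, spans)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("replicate_concordance: zero variance in binned counts; correlation undefined")
  stats::cor(a, b)
}

# Seed-scoped RNG: run fn under a given seed, restoring the caller's RNG.
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn()
}

#' Summit saturation curve by data reduction
#'
#' For each fraction `f`, subsamples `floor(f * n)` summits without
#' replacement and measures recovery: the share of full-set summits having a
#' subsampled summit on the same chromosome within `match_bp`.  At `f = 1`
#' recovery is 1 by construction; a curve that plateaus well before `f = 1`
#' indicates saturating coverage.
#'
#' @param summits Summit data frame.
#' @param fractions Subsampling fractions in (0, 1].
#' @param seed Integer seed for the subsampling draws (required).
#' @param match_bp Proximity tolerance for recovery matching, default 100.
#' @return Data frame: `fraction`, `n_subsampled`, `recovery`.
#' @export
saturation_curve <- function(summits, fractions = seq(0.1, 1, by = 0.1),
                             seed, match_bp = 100) {
  if (missing(seed)) stop("saturation_curve: seed is required")
  if (any(fractions <= 0 | fractions > 1))
    stop("saturation_curve: fractions must lie in (0, 1]")
  n <- nrow(summits)
  ord <- order(summits$chrom, summits$pos)
  full <- summits[ord, , drop = FALSE]
  with_seed(seed, function() {
    rows <- lapply(fractions, function(f) {
      k <- floor(f * n)
      if (k == 0) {
        warning("saturation_curve: fraction ", f,
                " yields an empty subsample; skipped")
        return(NULL)
      }
      sub <- summits[sample.int(n, k), , drop = FALSE]
      matched <- 0
      for (ch in unique(full$chrom)) {
        fp <- full$pos[full$chrom == ch]
        sp <- sort(sub$pos[sub$chrom == ch])
        if (length(sp) == 0) next
        i <- findInterval(fp, sp)
        d_lo <- ifelse(i >= 1, fp - sp[pmax(i, 1)], Inf)
        d_hi <- ifelse(i < length(sp), sp[pmin(i + 1, length(sp))] - fp, Inf)
        matched <- matched + sum(pmin(d_lo, d_hi) <= match_bp)
      }
      data.frame(fraction = f, n_subsampled = k, recovery = matched / n)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
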