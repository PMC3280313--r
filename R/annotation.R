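# Derivation of the classified feature universe (promoters, exons, introns,
# UTR-exonic regions, terminal exons) from transcript models, plus the point
# classification used for exclusive summit fractions.

gene_exons <- function(genes) {
  n <- lengths(genes$exon_starts)
  data.frame(chrom = rep(genes$chrom, n),
             start = unlist(genes$exon_starts, use.names = FALSE),
             end = unlist(genes$exon_ends, use.names = FALSE),
             strand = rep(genes$strand, n),
             gene = rep(genes$name, n),
             exon_rank = unlist(lapply(n, seq_len), use.names = FALSE),
             stringsAsFactors = FALSE)
}

gene_introns <- function(genes) {
  multi <- genes[lengths(genes$exon_starts) >= 2, , drop = FALSE]
  if (nrow(multi) == 0) return(empty_intervals())
  n <- lengths(multi$exon_starts) - 1L
  data.frame(chrom = rep(multi$chrom, n),
             start = unlist(lapply(multi$exon_ends, function(v)
               v[-length(v)]), use.names = FALSE),
             end = unlist(lapply(multi$exon_starts, `[`, -1),
                          use.names = FALSE),
             strand = rep(multi$strand, n),
             gene = rep(multi$name, n),
             stringsAsFactors = FALSE)
}

# Strand-aware upstream promoter windows, clipped at position 0.  On the +
# strand the window is [TSS - bp, TSS); on the - strand the TSS is the last
# transcribed base and the window is [txEnd, txEnd + bp).
promoter_windows <- function(genes, bp) {
  plus <- genes$strand != "-"
  start <- ifelse(plus, pmax(0, genes$tx_start - bp), genes$tx_end)
  end <- ifelse(plus, genes$tx_start, genes$tx_end + bp)
  keep <- end > start
  data.frame(chrom = genes$chrom[keep], start = start[keep], end = end[keep],
             strand = genes$strand[keep], gene = genes$name[keep],
             stringsAsFactors = FALSE)
}

is_coding <- function(genes) genes$cds_start < genes$cds_end

# Exonic UTR pieces of coding transcripts.  In transcript orientation the
# 5' UTR lies before cds_start (+) / after cds_end (-).
utr_exonic <- function(genes, side = c("utr5", "utr3")) {
  side <- match.arg(side)
  out <- vector("list", nrow(genes))
  for (i in which(is_coding(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    left <- c(genes$tx_start[i], genes$cds_start[i])   # [txStart, cdsStart)
    right <- c(genes$cds_end[i], genes$tx_end[i])      # [cdsEnd, txEnd)
    plus <- genes$strand[i] != "-"
    win <- if ((side == "utr5") == plus) left else right
    if (win[2] <= win[1]) next
    s <- pmax(es, win[1]); e <- pmin(ee, win[2])
    keep <- e > s
    if (!any(keep)) next
    out[[i]] <- data.frame(chrom = genes$chrom[i], start = s[keep],
                           end = e[keep], strand = genes$strand[i],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty_intervals())
  do.call(rbind, out)
}

terminal_exon_rows <- function(genes, which = c("first", "last")) {
  which <- match.arg(which)
  keep <- lengths(genes$exon_starts) >= 1
  g <- genes[keep, , drop = FALSE]
  if (nrow(g) == 0) return(empty_intervals())
  n <- lengths(g$exon_starts)
  plus <- g$strand != "-"
  # transcript orientation: on - strand the genomically last exon is "first"
  idx <- if (which == "first") ifelse(plus, 1L, n) else ifelse(plus, n, 1L)
  data.frame(chrom = g$chrom,
             start = mapply(function(v, i) v[i], g$exon_starts, idx),
             end = mapply(function(v, i) v[i], g$exon_ends, idx),
             strand = g$strand, gene = g$name, exon_rank = idx,
             stringsAsFactors = FALSE)
}

FEATURE_CLASSES <- c("promoter_5kb", "promoter_proximal_2kb", "exon",
                     "intron", "utr5_exonic", "utr3_exonic", "first_exon",
                     "last_exon", "internal_exon")

#' Derive the classified feature universe from gene models
#'
#' Builds, per feature class, the interval lists used by every density and
#' classification call: strand-aware upstream promoter windows (a distal
#' `promoter_bp` window and a proximal `proximal_bp` window, both clipped at
#' the chromosome start), exons, per-transcript introns, exonic 5'/3' UTR
#' pieces of coding transcripts, and first/last/internal exons resolved in
#' transcript orientation.  Per-class areas are computed on the merged union
#' of each class, so overlapping isoforms are not double counted.
#'
#' @param genes Gene-model data frame from [read_genepred()].
#' @param promoter_bp Size of the (distal) promoter window upstream of the
#'   TSS, default 5000 bp.
#' @param proximal_bp Size of the proximal promoter window, default 2000 bp.
#' @param provenance Optional identifier of the gene-model source, stored
#'   in the result.
#' @return An object of class `feature_set`: list with `features` (named
#'   list of interval data frames), `area` (named numeric, merged bp per
#'   class), `params` and `provenance`.
#' @export
derive_features <- function(genes, promoter_bp = 5000, proximal_bp = 2000,
                            provenance = NA_character_) {
  if (promoter_bp < 0 || proximal_bp < 0)
    stop("promoter window sizes must be non-negative")
  if (nrow(genes) == 0) {
    feats <- stats::setNames(rep(list(empty_intervals()),
                                 length(FEATURE_CLASSES)), FEATURE_CLASSES)
  } else {
    exons <- gene_exons(genes)
    n_ex <- lengths(genes$exon_starts)
    internal <- exons[exons$exon_rank > 1 &
                        exons$exon_rank < rep(n_ex, n_ex), , drop = FALSE]
    feats <- list(
      promoter_5kb = promoter_windows(genes, promoter_bp),
      promoter_proximal_2kb = promoter_windows(genes, proximal_bp),
      exon = exons,
      intron = gene_introns(genes),
      utr5_exonic = utr_exonic(genes, "utr5"),
      utr3_exonic = utr_exonic(genes, "utr3"),
      first_exon = terminal_exon_rows(genes, "first"),
      last_exon = terminal_exon_rows(genes, "last"),
      internal_exon = internal)
  }
  area <- vapply(feats, interval_area, numeric(1))
  structure(list(features = feats, area = area,
                 params = list(promoter_bp = promoter_bp,
                               proximal_bp = proximal_bp),
                 provenance = provenance),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set:", length(x$features), "classes\n")
  for (cl in names(x$features))
    cat(sprintf("  %-22s %6d intervals, %10.0f bp merged\n", cl,
                nrow(x$features[[cl]]), x$area[[cl]]))
  invisible(x)
}

# Resolve a precedence label to an interval set.  Labels may be feature
# classes, individual repeat classes, or "repeat" (all repeats).
resolve_class_intervals <- function(label, fs, repeats = NULL) {
  if (label %in% names(fs$features)) return(fs$features[[label]])
  if (!is.null(repeats)) {
    if (label == "repeat") return(repeats)
    if (label %in% repeats$rep_class)
      return(repeats[repeats$rep_class == label, , drop = FALSE])
  }
  empty_intervals()
}

#' Exclusively classify summit points by feature class
#'
#' Each summit is assigned the first class in `precedence` whose merged
#' intervals contain it; points contained in no listed class are labelled
#' `"others"`.  Precedence labels may be feature-set classes (e.g. `"exon"`,
#' `"promoter_5kb"`), individual repeat classes (e.g. `"SINE"`), or
#' `"repeat"` for all repeat elements.
#'
#' @param summits Summit data frame (`chrom`, `pos`).
#' @param fs A `feature_set` from [derive_features()].
#' @param repeats Optional repeat data frame from [read_rmsk()].
#' @param precedence Ordered character vector of class labels; default
#'   `exon > promoter_5kb > intron` followed by `repeat` when repeats are
#'   supplied.
#' @return Character vector of class labels, one per summit.
#' @export
classify_points <- function(summits, fs, repeats = NULL,
                            precedence = default_precedence(repeats)) {
  labels <- rep("others", nrow(summits))
  unassigned <- rep(TRUE, nrow(summits))
  for (cl in precedence) {
    if (!any(unassigned)) break
    iv <- resolve_class_intervals(cl, fs, repeats)
    if (nrow(iv) == 0) next
    idx <- which(unassigned)
    hit <- points_in_union(summits$chrom[idx], summits$pos[idx], iv)
    labels[idx[hit]] <- cl
    unassigned[idx[hit]] <- FALSE
  }
  labels
}

#' Default classification precedence
#'
#' Exon beats promoter beats intron; repeats, when supplied, rank after the
#' gene-model classes (one label per repeat class, in the track's order of
#' appearance).  Anything else is `others`.
#'
#' @param repeats Optional repeat data frame.
#' @return Character vector of class labels.
#' @export
default_precedence <- function(repeats = NULL) {
  p <- c("exon", "promoter_5kb", "intron")
  if (!is.null(repeats) && nrow(repeats) > 0)
    p <- c(p, unique(repeats$rep_class))
  p
}

#' Classify a terminal exon as coding or non-coding
#'
#' A transcript's first (or last, in transcript orientation) exon is
#' `coding` iff it intersects the CDS interval `[cds_start, cds_end)`;
#' terminal exons lying entirely in UTR are `non_coding`.  Non-coding
#' transcripts have no CDS, so the call is not applicable and `NA` is
#' returned for them.
#'
#' @param genes Gene-model data frame.
#' @param which `"first"` or `"last"` exon, in transcript orientation.
#' @return Character vector (`"coding"`, `"non_coding"`, or `NA` for
#'   non-coding transcripts), one per transcript.
#' @export
classify_terminal_exons <- function(genes, which = c("first", "last")) {
  which <- match.arg(which)
  te <- terminal_exon_rows(genes, which)
  out <- rep(NA_character_, nrow(genes))
  coding_tx <- is_coding(genes)
  # half-open intersection test
  hit <- te$start < genes$cds_end & genes$cds_start < te$end
  out[coding_tx] <- ifelse(hit[coding_tx], "coding", "non_coding")
  out
}

#' Select exons by position and coding status
#'
#' The selector behind the junction metaprofiles: picks all / first / last /
#' internal / second exons (in transcript orientation), optionally filtered
#' by whether the exon intersects the transcript's CDS.  Exons of non-coding
#' transcripts count as `non_coding`.
#'
#' @param genes Gene-model data frame.
#' @param which One of `"all"`, `"first"`, `"last"`, `"internal"`,
#'   `"second"`.
#' @param coding_status `"any"`, `"coding"`, or `"non_coding"`.
#' @return Interval data frame (`chrom`, `start`, `end`, `strand`, `gene`,
#'   `exon_rank`).
#' @export
select_exons <- function(genes, which = c("all", "first", "last", "internal",
                                          "second"),
                         coding_status = c("any", "coding", "non_coding")) {
  which <- match.arg(which)
  coding_status <- match.arg(coding_status)
  ex <- gene_exons(genes)
  n_ex <- lengths(genes$exon_starts)
  # rank in transcript orientation
  tx_rank <- ifelse(rep(genes$strand, n_ex) == "-",
                    rep(n_ex, n_ex) - ex$exon_rank + 1L, ex$exon_rank)
  sel <- switch(which,
                all = rep(TRUE, nrow(ex)),
                first = tx_rank == 1L,
                last = tx_rank == rep(n_ex, n_ex),
                internal = tx_rank > 1L & tx_rank < rep(n_ex, n_ex),
                second = tx_rank == 2L)
  if (coding_status != "any") {
    cs <- rep(genes$cds_start, n_ex)
    ce <- rep(genes$cds_end, n_ex)
    exon_coding <- cs < ce & ex$start < ce & cs < ex$end
    sel <- sel & (exon_coding == (coding_status == "coding"))
  }
  out <- ex[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
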