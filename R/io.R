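# Readers and writers for the external formats the pipeline touches.  All
# parsed coordinates are normalized to 0-based half-open on the way in; the
# formats here (BED, genePred/refFlat, cpgIslandExt, rmsk, bedGraph) already
# use that convention, so no shifting is needed beyond validation.

read_data_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

parse_int <- function(x, lineno, what, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad))
    stop(sprintf("%s: line %d: %s '%s' is not an integer",
                 basename(path), lineno[bad[1]], what, x[bad[1]]))
  v
}

#' Read MACS-style peak summits from a BED file
#'
#' Each data line yields one single-base summit.  For 1 bp rows (`end ==
#' start + 1`, the usual MACS summit output) the summit is the start
#' coordinate; wider rows are treated as peak intervals and collapsed to
#' their midpoint `floor((start + end) / 2)`.  Column 5, when present, is
#' kept as the score.
#'
#' @param path BED3/BED5 file, 0-based half-open; `track`/`browser`/comment
#'   lines are skipped.
#' @return Data frame (`chrom`, `pos`, `score`) sorted by (chrom, pos).
#'   An empty file yields an empty data frame.
#' @export
read_summits <- function(path) {
  d <- read_data_lines(path)
  if (length(d$lines) == 0)
    return(data.frame(chrom = character(), pos = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  f <- split_fields(d$lines)
  ncols <- lengths(f)
  if (any(ncols < 3))
    stop(sprintf("%s: line %d: expected >= 3 tab-separated columns, got %d",
                 basename(path), d$lineno[which(ncols < 3)[1]],
                 min(ncols)))
  chrom <- vapply(f, `[[`, "", 1)
  start <- parse_int(vapply(f, `[[`, "", 2), d$lineno, "start", path)
  end <- parse_int(vapply(f, `[[`, "", 3), d$lineno, "end", path)
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop(sprintf("%s: line %d: need 0 <= start < end", basename(path),
                 d$lineno[bad[1]]))
  pos <- ifelse(end == start + 1, start, floor((start + end) / 2))
  score <- rep(NA_real_, length(pos))
  has5 <- ncols >= 5
  score[has5] <- suppressWarnings(
    as.numeric(vapply(f[has5], `[[`, "", 5)))
  out <- data.frame(chrom = chrom, pos = pos, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write peak summits as BED5
#'
#' Inverse of [read_summits()]: each summit becomes a 1 bp interval
#' `[pos, pos + 1)`.
#'
#' @param summits Summit data frame (`chrom`, `pos`, optional `score`).
#' @param path Output file.
#' @export
write_summits <- function(summits, path) {
  score <- if ("score" %in% names(summits)) summits$score else NA_real_
  score <- ifelse(is.na(score), 0, score)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", summits$chrom,
                   as.integer(summits$pos), as.integer(summits$pos) + 1L,
                   paste0("summit_", seq_len(nrow(summits))),
                   format(score, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

parse_block_list <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE),
         function(v) as.numeric(v[nzchar(v)]))
}

#' Read UCSC genePred / refFlat gene models
#'
#' The two dialects are auto-detected by column count: 10 columns is
#' genePred (`name chrom strand txStart txEnd cdsStart cdsEnd exonCount
#' exonStarts exonEnds`); 11 columns is refFlat, which prepends a
#' `geneName` symbol column.  Exon block lists may carry UCSC's trailing
#' comma.  `cdsStart == cdsEnd` marks a non-coding transcript.
#'
#' @param path genePred or refFlat text file.
#' @return Data frame with one row per transcript: `name`, `gene_symbol`,
#'   `chrom`, `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`,
#'   `exon_count`, and list-columns `exon_starts` / `exon_ends` (0-based
#'   half-open, genomic order).
#' @export
read_genepred <- function(path) {
  d <- read_data_lines(path)
  if (length(d$lines) == 0) return(empty_gene_models())
  f <- split_fields(d$lines)
  ncols <- lengths(f)
  if (!all(ncols %in% c(10L, 11L)))
    stop(sprintf("%s: line %d: expected 10 (genePred) or 11 (refFlat) columns, got %d",
                 basename(path), d$lineno[which(!ncols %in% c(10L, 11L))[1]],
                 ncols[which(!ncols %in% c(10L, 11L))[1]]))
  off <- ncols - 10L  # 1 for refFlat rows
  col <- function(i) mapply(function(v, o) v[[i + o]], f, off)
  gene_symbol <- ifelse(off == 1L, vapply(f, `[[`, "", 1), NA_character_)
  tx_start <- parse_int(col(4), d$lineno, "txStart", path)
  tx_end <- parse_int(col(5), d$lineno, "txEnd", path)
  cds_start <- parse_int(col(6), d$lineno, "cdsStart", path)
  cds_end <- parse_int(col(7), d$lineno, "cdsEnd", path)
  exon_count <- parse_int(col(8), d$lineno, "exonCount", path)
  exon_starts <- parse_block_list(col(9))
  exon_ends <- parse_block_list(col(10))
  strand <- col(3)
  if (any(!strand %in% c("+", "-")))
    stop(sprintf("%s: line %d: strand must be '+' or '-'", basename(path),
                 d$lineno[which(!strand %in% c("+", "-"))[1]]))
  genes <- data.frame(name = col(1), gene_symbol = gene_symbol,
                      chrom = col(2), strand = strand,
                      tx_start = tx_start, tx_end = tx_end,
                      cds_start = cds_start, cds_end = cds_end,
                      exon_count = exon_count, stringsAsFactors = FALSE)
  genes$exon_starts <- exon_starts
  genes$exon_ends <- exon_ends
  validate_gene_models(genes, d$lineno, path)
  genes
}

empty_gene_models <- function() {
  g <- data.frame(name = character(), gene_symbol = character(),
                  chrom = character(), strand = character(),
                  tx_start = numeric(), tx_end = numeric(),
                  cds_start = numeric(), cds_end = numeric(),
                  exon_count = numeric(), stringsAsFactors = FALSE)
  g$exon_starts <- list()
  g$exon_ends <- list()
  g
}

validate_gene_models <- function(genes, lineno = seq_len(nrow(genes)),
                                 path = "gene models") {
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    where <- sprintf("%s: line %d (%s)", basename(path), lineno[i],
                     genes$name[i])
    if (length(es) != genes$exon_count[i] || length(ee) != genes$exon_count[i])
      stop(where, ": exonCount disagrees with exon block list length")
    if (any(ee <= es) || is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)]))
      stop(where, ": exons must be sorted, non-overlapping, non-empty")
    if (es[1] < genes$tx_start[i] || ee[length(ee)] > genes$tx_end[i])
      stop(where, ": exons extend outside transcript bounds")
    if (genes$cds_start[i] > genes$cds_end[i])
      stop(where, ": cdsStart > cdsEnd")
    if (genes$cds_start[i] < genes$cds_end[i] &&
        (genes$cds_start[i] < genes$tx_start[i] ||
         genes$cds_end[i] > genes$tx_end[i]))
      stop(where, ": CDS bounds outside transcript bounds")
  }
  invisible(genes)
}

#' Write gene models as genePred or refFlat text
#'
#' @param genes Gene-model data frame as returned by [read_genepred()].
#' @param path Output file.
#' @param dialect `"refflat"` (leading geneName column) or `"genepred"`.
#' @export
write_genepred <- function(genes, path, dialect = c("refflat", "genepred")) {
  dialect <- match.arg(dialect)
  starts <- vapply(genes$exon_starts, function(v)
    paste0(paste(as.integer(v), collapse = ","), ","), "")
  ends <- vapply(genes$exon_ends, function(v)
    paste0(paste(as.integer(v), collapse = ","), ","), "")
  core <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                  genes$name, genes$chrom, genes$strand,
                  as.integer(genes$tx_start), as.integer(genes$tx_end),
                  as.integer(genes$cds_start), as.integer(genes$cds_end),
                  as.integer(genes$exon_count), starts, ends)
  if (dialect == "refflat") {
    sym <- ifelse(is.na(genes$gene_symbol), genes$name, genes$gene_symbol)
    core <- paste(sym, core, sep = "\t")
  }
  writeLines(core, path)
  invisible(path)
}

#' Read a UCSC cpgIslandExt CpG-island track
#'
#' Accepts the 10-column table (`chrom start end name length cpgNum gcNum
#' perCpg perGc obsExp`) with or without UCSC's leading `bin` column; a
#' `#`-prefixed header line is skipped.  `perGc` (a percentage) is converted
#' to a `gc_fraction` in \[0, 1\].
#'
#' @param path cpgIslandExt-format file.
#' @return Data frame: `chrom`, `start`, `end`, `name`, `length`,
#'   `cpg_count`, `gc_fraction`, `obs_exp`.
#' @export
read_cgi_track <- function(path) {
  d <- read_data_lines(path)
  if (length(d$lines) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), length = numeric(),
                      cpg_count = numeric(), gc_fraction = numeric(),
                      obs_exp = numeric(), stringsAsFactors = FALSE))
  f <- split_fields(d$lines)
  ncols <- lengths(f)
  if (any(!ncols %in% c(10L, 11L)))
    stop(sprintf("%s: line %d: expected 10 or 11 (leading bin) columns",
                 basename(path), d$lineno[which(!ncols %in% c(10L, 11L))[1]]))
  off <- ncols - 10L
  col <- function(i) mapply(function(v, o) v[[i + o]], f, off)
  out <- data.frame(chrom = col(1),
                    start = parse_int(col(2), d$lineno, "chromStart", path),
                    end = parse_int(col(3), d$lineno, "chromEnd", path),
                    name = col(4),
                    length = parse_int(col(5), d$lineno, "length", path),
                    cpg_count = parse_int(col(6), d$lineno, "cpgNum", path),
                    gc_fraction = as.numeric(col(9)) / 100,
                    obs_exp = as.numeric(col(10)),
                    stringsAsFactors = FALSE)
  validate_intervals(out, "CpG island")
  out
}

#' Write CpG islands in cpgIslandExt format
#' @param islands Island data frame as from [read_cgi_track()].
#' @param path Output file.
#' @export
write_cgi_track <- function(islands, path) {
  len <- islands$end - islands$start
  gcnum <- round(islands$gc_fraction * len)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%d\t%s\t%s\t%s",
                   islands$chrom, as.integer(islands$start),
                   as.integer(islands$end), islands$name, as.integer(len),
                   as.integer(islands$cpg_count), as.integer(gcnum),
                   format(200 * islands$cpg_count / len, trim = TRUE),
                   format(100 * islands$gc_fraction, trim = TRUE),
                   format(islands$obs_exp, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

REPEAT_CLASSES <- c("SINE", "LINE", "LTR", "DNA", "Simple_repeat",
                    "Low_complexity", "Satellite", "RNA", "rRNA", "Other",
                    "Unknown")

#' Read a RepeatMasker (rmsk) annotation table
#'
#' Requires a header line (optionally `#`-prefixed) naming at least
#' `genoName`, `genoStart`, `genoEnd` and `repClass`; any other rmsk columns
#' are ignored, so both full UCSC dumps and slimmed extracts parse.  Repeat
#' classes outside the known vocabulary are binned to `Other` with a
#' warning.
#'
#' @param path rmsk-format file with header.
#' @return Data frame: `chrom`, `start`, `end`, `rep_class`.
#' @export
read_rmsk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      rep_class = character(), stringsAsFactors = FALSE))
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  need <- c("genoName", "genoStart", "genoEnd", "repClass")
  miss <- setdiff(need, header)
  if (length(miss))
    stop(sprintf("%s: missing required column '%s' in header",
                 basename(path), miss[1]))
  idx <- match(need, header)
  body <- lines[-1]
  if (length(body) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      rep_class = character(), stringsAsFactors = FALSE))
  f <- split_fields(body)
  col <- function(i) vapply(f, `[[`, "", i)
  rep_class <- col(idx[4])
  # rmsk uses e.g. "SINE?"; strip the uncertainty marker before matching
  rep_class <- sub("\\?$", "", rep_class)
  unknown <- !(rep_class %in% REPEAT_CLASSES)
  if (any(unknown)) {
    warning(sprintf("%s: %d repeat element(s) with unknown repClass (%s) binned to Other",
                    basename(path), sum(unknown),
                    paste(unique(rep_class[unknown]), collapse = ", ")))
    rep_class[unknown] <- "Other"
  }
  out <- data.frame(chrom = col(idx[1]),
                    start = parse_int(col(idx[2]), seq_along(body) + 1,
                                      "genoStart", path),
                    end = parse_int(col(idx[3]), seq_along(body) + 1,
                                    "genoEnd", path),
                    rep_class = rep_class, stringsAsFactors = FALSE)
  validate_intervals(out, "repeat element")
  out
}

#' Write repeat elements as a headered rmsk extract
#' @param repeats Repeat data frame as from [read_rmsk()].
#' @param path Output file.
#' @export
write_rmsk <- function(repeats, path) {
  lines <- c("#genoName\tgenoStart\tgenoEnd\trepClass",
             sprintf("%s\t%d\t%d\t%s", repeats$chrom,
                     as.integer(repeats$start), as.integer(repeats$end),
                     repeats$rep_class))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-expression intensity table
#'
#' Headered TSV: a `gene_id` column followed by one positive numeric column
#' per replicate.
#'
#' @param path TSV file.
#' @return Data frame with `gene_id` plus the replicate intensity columns.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab))
    stop(sprintf("%s: missing required column 'gene_id'", basename(path)))
  reps <- setdiff(names(tab), "gene_id")
  if (length(reps) < 1)
    stop(sprintf("%s: need at least one replicate intensity column",
                 basename(path)))
  for (r in reps) {
    tab[[r]] <- as.numeric(tab[[r]])
    if (any(is.na(tab[[r]])) || any(tab[[r]] <= 0))
      stop(sprintf("%s: column '%s' must be positive numeric intensities",
                   basename(path), r))
  }
  tab
}

#' Write a gene-expression intensity table
#' @param expr Expression data frame as from [read_expression()].
#' @param path Output file.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SPLICE_EVENT_TYPES <- c("intron_retention", "cassette_exon",
                        "constitutive_intron", "constitutive_exon")

#' Read a splice-event table
#'
#' Headered TSV with columns `event_type`, `chrom`, `start`, `end`,
#' `host_gene` (a headerless file in that column order is also accepted).
#' `event_type` must come from the closed vocabulary `intron_retention`,
#' `cassette_exon`, `constitutive_intron`, `constitutive_exon`.
#'
#' @param path TSV file.
#' @return Data frame: `event_type`, `chrom`, `start`, `end`, `host_gene`.
#' @export
read_splice_events <- function(path) {
  d <- read_data_lines(path)
  cols <- c("event_type", "chrom", "start", "end", "host_gene")
  if (length(d$lines) == 0)
    return(data.frame(event_type = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      host_gene = character(), stringsAsFactors = FALSE))
  f <- split_fields(d$lines)
  if (any(lengths(f) != 5))
    stop(sprintf("%s: line %d: expected 5 columns", basename(path),
                 d$lineno[which(lengths(f) != 5)[1]]))
  if (identical(f[[1]][1], "event_type")) {
    if (!identical(f[[1]], cols))
      stop(sprintf("%s: header must be: %s", basename(path),
                   paste(cols, collapse = ", ")))
    f <- f[-1]
    d$lineno <- d$lineno[-1]
  }
  col <- function(i) vapply(f, `[[`, "", i)
  type <- col(1)
  bad <- which(!type %in% SPLICE_EVENT_TYPES)
  if (length(bad))
    stop(sprintf("%s: line %d: unknown event_type '%s'", basename(path),
                 d$lineno[bad[1]], type[bad[1]]))
  out <- data.frame(event_type = type, chrom = col(2),
                    start = parse_int(col(3), d$lineno, "start", path),
                    end = parse_int(col(4), d$lineno, "end", path),
                    host_gene = col(5), stringsAsFactors = FALSE)
  validate_intervals(out, "splice event")
  out
}

#' Write a splice-event table
#' @param events Splice-event data frame as from [read_splice_events()].
#' @param path Output file.
#' @export
write_splice_events <- function(events, path) {
  utils::write.table(events[, c("event_type", "chrom", "start", "end",
                                "host_gene")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Headered TSV with columns `target`, `ct_medip`, `ct_input`, `is_control`
#' (0/1 or TRUE/FALSE; TRUE marks the unmethylated control region).
#'
#' @param path TSV file.
#' @return Data frame: `target`, `ct_medip`, `ct_input`, `is_control`.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target", "ct_medip", "ct_input", "is_control")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("%s: missing required column '%s'", basename(path), miss[1]))
  tab$ct_medip <- as.numeric(tab$ct_medip)
  tab$ct_input <- as.numeric(tab$ct_input)
  if (any(!is.finite(tab$ct_medip)) || any(!is.finite(tab$ct_input)) ||
      any(tab$ct_medip <= 0) || any(tab$ct_input <= 0))
    stop(sprintf("%s: Ct values must be finite and positive", basename(path)))
  tab$is_control <- as.logical(tab$is_control)
  tab[, need]
}

#' Write a qPCR Ct table
#' @param ct Ct data frame as from [read_ct_table()].
#' @param path Output file.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param iv Interval data frame; must be sorted by (chrom, start) and
#'   non-overlapping within each chromosome.
#' @param values Numeric vector, one value per interval.
#' @param path Output file.
#' @export
write_bedgraph <- function(iv, values, path) {
  validate_intervals(iv, "bedGraph interval")
  if (length(values) != nrow(iv))
    stop("bedGraph: one value per interval required")
  if (nrow(iv) > 1) {
    o <- order(iv$chrom, iv$start)
    if (!identical(o, seq_len(nrow(iv))))
      stop("bedGraph: intervals must be sorted by (chrom, start)")
    same <- iv$chrom[-1] == iv$chrom[-nrow(iv)]
    if (any(same & iv$start[-1] < iv$end[-nrow(iv)]))
      stop("bedGraph: intervals overlap within a chromosome")
  }
  writeLines(sprintf("%s\t%d\t%d\t%s", iv$chrom, as.integer(iv$start),
                     as.integer(iv$end),
                     format(values, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Write a generic report table as TSV
#' @param tab Data frame.
#' @param path Output file.
#' @export
write_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
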