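# Seeded synthetic-data generator: toy genomes with gene models, CpG
# islands, repeats, splice events, expression and Ct tables, and summit
# sets drawn with known per-class enrichment weights, so every pipeline
# stage can be tested against ground truth.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic genome.  Summit placement is a
#' two-stage mixture: a feature class is drawn with probability
#' proportional to `weight * merged class area`, then a position uniform
#' within that class, giving closed-form expected densities
#' (`n * weight_c / sum_k(weight_k * area_k)`).  Weight names may include
#' `ir_intron` (retained-intron bodies, carved out of the intron class),
#' `cassette_exon`, `coding_exon` / `noncoding_exon` (CDS-split exon
#' classes), individual repeat classes, and `others` for the remaining
#' genome.
#'
#' @param seed Integer RNG seed (required; every generator call is
#'   deterministic given the config).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_genes Number of transcripts to lay out (non-overlapping, with
#'   intergenic gaps).
#' @param exon_count_range Min/max exons per transcript.
#' @param exon_len_log,intron_len_log,island_len_log,repeat_len_log
#'   `c(meanlog, sdlog)` of the log-normal length draws.
#' @param noncoding_prob Probability a transcript is non-coding (no CDS).
#' @param utr_first_prob,utr_last_prob Probability the first/last exon is
#'   entirely UTR (CDS starts/ends in a neighbouring exon).
#' @param expressed_fraction Fraction of genes planted as expressed: their
#'   TSSs get the methylation dip and they form the high-expression
#'   stratum.
#' @param tss_dip `list(depth, halfwidth)`: summits landing within
#'   `halfwidth` bp of an expressed TSS are kept with probability
#'   `1 - depth`.
#' @param n_islands,island_placement,island_methylated_prob CpG-island
#'   count, placement mix over promoter/exon/intron/intergenic, and the
#'   probability an island is planted methylated (unmethylated islands
#'   receive no summits; methylated ones at least one).
#' @param n_repeats,repeat_class_probs Repeat element count and class mix
#'   (placed in intergenic space).
#' @param ir_fraction,cassette_fraction Fraction of introns (exons) emitted
#'   as retained-intron (cassette-exon) events; equally many constitutive
#'   controls are drawn from the remainder, so control lengths follow the
#'   same distribution.
#' @param weights Named relative summit intensities per feature class.  The
#'   classes are made disjoint in the order given (earlier names win
#'   overlaps), so carve-out classes like `ir_intron` must precede their
#'   parent class (`intron`).
#' @param n_summits Number of summits to draw.
#' @param expression `list(n_replicates, mu_log2, sigma_log2, separation,
#'   rep_sd)`: baseline log2 intensities are normal(mu, sigma); planted
#'   high/low genes sit at `mu +/- separation * sigma`, with per-replicate
#'   log2 noise `rep_sd`.
#' @param planted_E Named vector of qPCR fold enrichments to encode in the
#'   Ct table.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed,
                              chrom_lengths = c(chr1 = 6e6, chr2 = 3e6),
                              n_genes = 250,
                              exon_count_range = c(2, 8),
                              exon_len_log = c(log(250), 0.5),
                              intron_len_log = c(log(1500), 0.6),
                              noncoding_prob = 0.1,
                              utr_first_prob = 0.25,
                              utr_last_prob = 0.25,
                              expressed_fraction = 0.15,
                              tss_dip = list(depth = 0.8, halfwidth = 500),
                              n_islands = 300,
                              island_len_log = c(log(400), 0.35),
                              island_placement = c(promoter = 0.3,
                                                   exon = 0.2,
                                                   intron = 0.2,
                                                   intergenic = 0.3),
                              island_methylated_prob = 0.5,
                              n_repeats = 600,
                              repeat_class_probs = c(SINE = 0.35,
                                                     LINE = 0.30,
                                                     LTR = 0.12, DNA = 0.08,
                                                     Simple_repeat = 0.06,
                                                     Low_complexity = 0.04,
                                                     Satellite = 0.05),
                              repeat_len_log = c(log(300), 0.5),
                              ir_fraction = 0.15,
                              cassette_fraction = 0.15,
                              weights = c(ir_intron = 3, exon = 5,
                                          promoter_5kb = 2, intron = 1,
                                          SINE = 3, LINE = 2, LTR = 2,
                                          DNA = 1, Simple_repeat = 1,
                                          Low_complexity = 1, Satellite = 4,
                                          others = 1),
                              n_summits = 100000,
                              expression = list(n_replicates = 3,
                                                mu_log2 = 6, sigma_log2 = 1,
                                                separation = 2,
                                                rep_sd = 0.3),
                              planted_E = c(imprinted_a = 8,
                                            imprinted_b = 32)) {
  if (missing(seed)) stop("simulation_config: seed is required")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (any(weights < 0) || !any(weights > 0))
    stop("weights must be non-negative with at least one positive")
  structure(as.list(environment()), class = "sim_config")
}

# Carve a placement of given width out of a free-interval table; returns
# list(placed interval row or NULL, updated free table).  Guarantees placed
# intervals never overlap.
carve_slot <- function(free, width, min_width = width) {
  free <- free[, c("chrom", "start", "end"), drop = FALSE]
  ok <- which(free$end - free$start >= min_width)
  if (!length(ok)) return(list(slot = NULL, free = free))
  w <- (free$end - free$start)[ok]
  i <- ok[sample.int(length(ok), 1, prob = w)]
  avail <- free$end[i] - free$start[i]
  width <- min(width, avail)
  s <- free$start[i] + floor(stats::runif(1) * (avail - width + 1))
  slot <- data.frame(chrom = free$chrom[i], start = s, end = s + width,
                     stringsAsFactors = FALSE)
  pieces <- data.frame(chrom = free$chrom[i],
                       start = c(free$start[i], slot$end),
                       end = c(slot$start, free$end[i]),
                       stringsAsFactors = FALSE)
  pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]
  list(slot = slot, free = rbind(free[-i, , drop = FALSE], pieces))
}

sim_gene_models <- function(cfg) {
  margin <- 25000
  cursor <- stats::setNames(rep(margin, length(cfg$chrom_lengths)),
                            names(cfg$chrom_lengths))
  rows <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    k <- sample(seq(cfg$exon_count_range[1], cfg$exon_count_range[2]), 1)
    elens <- pmin(pmax(round(stats::rlnorm(k, cfg$exon_len_log[1],
                                           cfg$exon_len_log[2])), 60), 2000)
    ilens <- if (k > 1)
      pmin(pmax(round(stats::rlnorm(k - 1, cfg$intron_len_log[1],
                                    cfg$intron_len_log[2])), 200), 15000)
    else numeric(0)
    gap <- round(stats::runif(1, 12000, 20000))
    glen <- sum(elens) + sum(ilens)
    # place on the chromosome with the most remaining room
    room <- cfg$chrom_lengths - cursor - margin
    ch <- names(which.max(room))
    if (room[[ch]] < gap + glen)
      stop("sim_gene_models: genome too small for ", cfg$n_genes, " genes")
    tx_start <- cursor[[ch]] + gap
    starts <- tx_start + cumsum(c(0, elens[-k] + ilens))
    ends <- starts + elens
    cursor[[ch]] <- ends[k]
    strand <- sample(c("+", "-"), 1)
    noncoding <- stats::runif(1) < cfg$noncoding_prob
    if (noncoding) {
      cds_start <- cds_end <- tx_start
    } else {
      utr_first <- k >= 2 && stats::runif(1) < cfg$utr_first_prob
      utr_last <- k >= 2 && stats::runif(1) < cfg$utr_last_prob
      # indices in transcript orientation, then mapped to genomic order
      i1 <- if (utr_first) 2L else 1L
      i2 <- if (utr_last) k - 1L else k
      if (i1 > i2) { i1 <- 1L; i2 <- k }
      if (strand == "-") { tmp <- i1; i1 <- k - i2 + 1L; i2 <- k - tmp + 1L }
      cds_start <- starts[i1] + floor(0.3 * elens[i1])
      cds_end <- ends[i2] - floor(0.3 * elens[i2])
      if (cds_end <= cds_start) cds_end <- cds_start + 1
    }
    rows[[g]] <- data.frame(name = sprintf("TX%04d", g),
                            gene_symbol = sprintf("G%04d", g), chrom = ch,
                            strand = strand, tx_start = tx_start,
                            tx_end = ends[k], cds_start = cds_start,
                            cds_end = cds_end, exon_count = k,
                            stringsAsFactors = FALSE)
    rows[[g]]$exon_starts <- list(starts)
    rows[[g]]$exon_ends <- list(ends)
  }
  genes <- do.call(rbind, rows)
  validate_gene_models(genes, path = "simulated gene models")
  genes
}

empty_island_table <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), length = numeric(), cpg_count = numeric(),
             gc_fraction = numeric(), obs_exp = numeric(),
             placement = character(), stringsAsFactors = FALSE)
}

sim_islands <- function(cfg, fs, free_intergenic) {
  if (cfg$n_islands == 0) return(empty_island_table())
  cats <- sample(names(cfg$island_placement), cfg$n_islands, replace = TRUE,
                 prob = cfg$island_placement)
  lens <- pmax(round(stats::rlnorm(cfg$n_islands, cfg$island_len_log[1],
                                   cfg$island_len_log[2])), 201)
  free <- list(promoter = fs$features$promoter_5kb[, c("chrom", "start", "end")],
               exon = fs$features$exon[, c("chrom", "start", "end")],
               intron = fs$features$intron[, c("chrom", "start", "end")],
               intergenic = free_intergenic)
  placed <- vector("list", cfg$n_islands)
  placed_cat <- character(cfg$n_islands)
  for (i in seq_len(cfg$n_islands)) {
    cat_i <- cats[i]
    res <- carve_slot(free[[cat_i]], lens[i], min_width = 202)
    if (is.null(res$slot)) {  # category full; fall back to intergenic space
      cat_i <- "intergenic"
      res <- carve_slot(free[["intergenic"]], lens[i], min_width = 202)
      if (is.null(res$slot)) stop("sim_islands: no room left for islands")
    }
    free[[cat_i]] <- res$free
    placed[[i]] <- res$slot
    placed_cat[i] <- cat_i
  }
  islands <- do.call(rbind, placed)
  len <- islands$end - islands$start
  gc <- stats::runif(cfg$n_islands, 0.55, 0.75)
  oe <- stats::runif(cfg$n_islands, 0.65, 1.1)
  out <- data.frame(chrom = islands$chrom, start = islands$start,
                    end = islands$end,
                    name = sprintf("CpG_%03d", seq_len(cfg$n_islands)),
                    length = len,
                    cpg_count = pmax(1, round(oe * (gc / 2)^2 * len)),
                    gc_fraction = gc, obs_exp = oe,
                    placement = placed_cat, stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

sim_repeats <- function(cfg, free_intergenic) {
  if (cfg$n_repeats == 0) {
    out <- empty_intervals()[, c("chrom", "start", "end")]
    out$rep_class <- character(0)
    return(list(repeats = out, free = free_intergenic))
  }
  classes <- sample(names(cfg$repeat_class_probs), cfg$n_repeats,
                    replace = TRUE, prob = cfg$repeat_class_probs)
  lens <- pmax(round(stats::rlnorm(cfg$n_repeats, cfg$repeat_len_log[1],
                                   cfg$repeat_len_log[2])), 50)
  free <- free_intergenic
  placed <- vector("list", cfg$n_repeats)
  for (i in seq_len(cfg$n_repeats)) {
    res <- carve_slot(free, lens[i], min_width = 50)
    if (is.null(res$slot)) stop("sim_repeats: no intergenic room for repeats")
    free <- res$free
    placed[[i]] <- res$slot
  }
  out <- do.call(rbind, placed)
  out$rep_class <- classes
  list(repeats = out, free = free)
}

sim_splice_events <- function(cfg, genes) {
  introns <- gene_introns(genes)
  exons <- select_exons(genes, "internal")
  pick <- function(iv, frac) {
    n <- max(1L, round(frac * nrow(iv)))
    idx <- sample.int(nrow(iv), min(2L * n, nrow(iv)))
    list(test = idx[seq_len(n)], control = idx[n + seq_len(min(n, length(idx) - n))])
  }
  ev <- list()
  if (nrow(introns) >= 2) {
    p <- pick(introns, cfg$ir_fraction)
    ev$ir <- data.frame(event_type = "intron_retention",
                        introns[p$test, c("chrom", "start", "end")],
                        host_gene = introns$gene[p$test],
                        stringsAsFactors = FALSE)
    ev$ci <- data.frame(event_type = "constitutive_intron",
                        introns[p$control, c("chrom", "start", "end")],
                        host_gene = introns$gene[p$control],
                        stringsAsFactors = FALSE)
  }
  if (nrow(exons) >= 2) {
    p <- pick(exons, cfg$cassette_fraction)
    ev$ce <- data.frame(event_type = "cassette_exon",
                        exons[p$test, c("chrom", "start", "end")],
                        host_gene = exons$gene[p$test],
                        stringsAsFactors = FALSE)
    ev$cx <- data.frame(event_type = "constitutive_exon",
                        exons[p$control, c("chrom", "start", "end")],
                        host_gene = exons$gene[p$control],
                        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Generate the synthetic annotation universe
#'
#' Lays out non-overlapping gene models with intergenic gaps, places CpG
#' islands in promoter/exon/intron/intergenic space and repeat elements in
#' intergenic space (none of the placed elements overlap each other), and
#' derives splice events (retained and constitutive introns, cassette and
#' constitutive exons) from the gene structures.  Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A `sim_config` from [simulation_config()].
#' @return List: `genes`, `islands` (with a `placement` column), `repeats`,
#'   `events`, `features` (the derived `feature_set`), `expressed_genes`.
#' @export
generate_annotation <- function(cfg) {
  with_seed(cfg$seed, function() {
    genes <- sim_gene_models(cfg)
    fs <- derive_features(genes, provenance = "simulated")
    genome <- data.frame(chrom = names(cfg$chrom_lengths), start = 0,
                         end = as.numeric(cfg$chrom_lengths),
                         stringsAsFactors = FALSE)
    genic <- rbind(fs$features$promoter_5kb[, c("chrom", "start", "end")],
                   data.frame(chrom = genes$chrom, start = genes$tx_start,
                              end = genes$tx_end, stringsAsFactors = FALSE))
    intergenic <- setdiff_intervals(genome, genic)
    rep_res <- sim_repeats(cfg, intergenic)
    islands <- sim_islands(cfg, fs, rep_res$free)
    events <- sim_splice_events(cfg, genes)
    expressed <- sort(sample(genes$name,
                             max(1L, round(cfg$expressed_fraction *
                                             nrow(genes)))))
    list(genes = genes, islands = islands, repeats = rep_res$repeats,
         events = events, features = fs, expressed_genes = expressed)
  })
}

# Disjoint partition of the genome into the weighted classes, in the order
# the weights are named (earlier classes win overlaps); "others" is the
# remainder.
sim_class_partition <- function(cfg, ann) {
  fs <- ann$features
  genes <- ann$genes
  raw <- list()
  for (cl in names(cfg$weights)) {
    raw[[cl]] <- switch(cl,
      others = NULL,
      ir_intron = {
        ev <- ann$events[ann$events$event_type == "intron_retention", ,
                         drop = FALSE]
        ev[, c("chrom", "start", "end")]
      },
      cassette_exon = {
        ev <- ann$events[ann$events$event_type == "cassette_exon", ,
                         drop = FALSE]
        ev[, c("chrom", "start", "end")]
      },
      coding_exon = ,
      noncoding_exon = {
        ex <- gene_exons(genes)
        n_ex <- lengths(genes$exon_starts)
        cs <- rep(genes$cds_start, n_ex); ce <- rep(genes$cds_end, n_ex)
        coding <- cs < ce & ex$start < ce & cs < ex$end
        ex[if (cl == "coding_exon") coding else !coding,
           c("chrom", "start", "end"), drop = FALSE]
      },
      if (cl %in% names(fs$features)) fs$features[[cl]]
      else if (cl %in% REPEAT_CLASSES)
        ann$repeats[ann$repeats$rep_class == cl, c("chrom", "start", "end"),
                    drop = FALSE]
      else stop("sim_class_partition: weight class '", cl,
                "' matches no feature"))
  }
  genome <- data.frame(chrom = names(cfg$chrom_lengths), start = 0,
                       end = as.numeric(cfg$chrom_lengths),
                       stringsAsFactors = FALSE)
  part <- list()
  taken <- empty_intervals()
  for (cl in setdiff(names(cfg$weights), "others")) {
    m <- setdiff_intervals(raw[[cl]], taken)
    part[[cl]] <- m
    taken <- merge_intervals(rbind(taken[, c("chrom", "start", "end",
                                             "strand")],
                                   m[, c("chrom", "start", "end", "strand")]))
  }
  if ("others" %in% names(cfg$weights))
    part$others <- setdiff_intervals(genome, taken)
  part
}

#' Generate summits with known per-class enrichment
#'
#' Two-stage draw: a feature class with probability proportional to
#' `weight * area` over a disjoint class partition of the genome, then a
#' uniform position within that class.  Planted structure: summits within
#' `tss_dip$halfwidth` of an expressed gene's TSS are thinned by
#' `tss_dip$depth`; islands planted unmethylated are excluded from
#' placement entirely, and each island planted methylated is guaranteed at
#' least one summit (drawn uniformly inside it, replacing an `others`
#' summit so the total count stays `n_summits`).
#'
#' @param cfg A `sim_config`.
#' @param ann Annotation list from [generate_annotation()].
#' @return List: `summits` (data frame sorted by chrom, pos) and `truth`
#'   (class areas, expected counts and densities, island status, expressed
#'   genes, the planted retained/constitutive intron body ratio).
#' @export
generate_summits <- function(cfg, ann) {
  with_seed(cfg$seed + 1L, function() {
    part <- sim_class_partition(cfg, ann)
    island_status <- ifelse(stats::runif(nrow(ann$islands)) <
                              cfg$island_methylated_prob,
                            "methylated", "unmethylated")
    unmeth <- ann$islands[island_status == "unmethylated", , drop = FALSE]
    # placement universe excludes planted-unmethylated islands
    part_eff <- lapply(part, function(iv) setdiff_intervals(iv, unmeth))
    areas <- vapply(part, interval_area, numeric(1))
    areas_eff <- vapply(part_eff, interval_area, numeric(1))
    w <- cfg$weights[names(part)] * areas_eff
    if (sum(w) <= 0) stop("generate_summits: all effective class weights zero")
    if (cfg$n_summits == 0) {
      summits <- data.frame(chrom = character(), pos = numeric(),
                            score = numeric(), stringsAsFactors = FALSE)
    } else {
      n_c <- as.vector(stats::rmultinom(1, cfg$n_summits, w / sum(w)))
      names(n_c) <- names(part)
      tss <- tss_anchors(ann$genes)
      tss <- tss[tss$gene %in% ann$expressed_genes, , drop = FALSE]
      dip_pos <- split(tss$pos, tss$chrom)
      draw_class <- function(cl, n) {
        iv <- part_eff[[cl]]
        widths <- iv$end - iv$start
        out_chrom <- character(n); out_pos <- numeric(n)
        filled <- 0L
        while (filled < n) {
          m <- n - filled
          i <- sample.int(nrow(iv), m, replace = TRUE, prob = widths)
          pos <- iv$start[i] + floor(stats::runif(m) * widths[i])
          chrom <- iv$chrom[i]
          # TSS dip thinning near expressed genes
          keep <- rep(TRUE, m)
          for (ch in names(dip_pos)) {
            sel <- which(chrom == ch)
            if (!length(sel)) next
            tp <- sort(dip_pos[[ch]])
            j <- findInterval(pos[sel], tp)
            d1 <- ifelse(j >= 1, pos[sel] - tp[pmax(j, 1)], Inf)
            d2 <- ifelse(j < length(tp), tp[pmin(j + 1, length(tp))] -
                           pos[sel], Inf)
            near <- pmin(d1, d2) <= cfg$tss_dip$halfwidth
            keep[sel][near] <- stats::runif(sum(near)) >= cfg$tss_dip$depth
          }
          kn <- sum(keep)
          if (kn > 0) {
            out_chrom[filled + seq_len(kn)] <- chrom[keep]
            out_pos[filled + seq_len(kn)] <- pos[keep]
            filled <- filled + kn
          }
        }
        data.frame(chrom = out_chrom, pos = out_pos,
                   stringsAsFactors = FALSE)
      }
      parts <- lapply(names(part), function(cl)
        if (n_c[[cl]] > 0) draw_class(cl, n_c[[cl]]) else NULL)
      summits <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
      # guarantee every planted-methylated island holds >= 1 summit
      meth <- ann$islands[island_status == "methylated", , drop = FALSE]
      if (nrow(meth) > 0) {
        hits <- point_overlap_pairs(summits$chrom, summits$pos, meth)
        missing <- setdiff(seq_len(nrow(meth)), unique(hits$region))
        if (length(missing)) {
          in_island <- points_in_union(summits$chrom, summits$pos,
                                       ann$islands)
          donors <- utils::tail(which(!in_island), length(missing))
          for (j in seq_along(missing)) {
            k <- missing[j]
            summits$chrom[donors[j]] <- meth$chrom[k]
            summits$pos[donors[j]] <- meth$start[k] +
              floor(stats::runif(1) * (meth$end[k] - meth$start[k]))
          }
        }
      }
      summits$score <- round(stats::runif(nrow(summits), 10, 300), 1)
      summits <- summits[order(summits$chrom, summits$pos), , drop = FALSE]
      rownames(summits) <- NULL
    }
    truth <- list(class_areas = areas, weights = cfg$weights[names(part)],
                  expected_counts = if (cfg$n_summits > 0)
                    cfg$n_summits * w / sum(w) else 0 * w,
                  expected_density = if (cfg$n_summits > 0)
                    cfg$n_summits * (cfg$weights[names(part)] / sum(w))
                  else 0 * w,
                  island_status = stats::setNames(island_status,
                                                  ann$islands$name),
                  expressed_genes = ann$expressed_genes,
                  planted_ir_body_ratio =
                    unname(cfg$weights["ir_intron"] / cfg$weights["intron"]))
    list(summits = summits, truth = truth)
  })
}

#' Generate a replicate expression table with planted strata
#'
#' Planted high genes are the annotation's expressed genes (so the
#' high-expression stratum is the one whose TSSs carry the methylation
#' dip); an equal number of planted low genes is drawn from the rest.  Per
#' gene, the log2 intensity is `mu +/- separation * sigma` for planted
#' genes and normal(mu, sigma) otherwise; replicates add normal log2 noise.
#'
#' @param cfg A `sim_config`.
#' @param ann Annotation list from [generate_annotation()].
#' @return List: `expression` (data frame `gene_id` + replicate columns)
#'   and `truth` (`high`, `low` gene-id vectors).
#' @export
generate_expression <- function(cfg, ann) {
  with_seed(cfg$seed + 2L, function() {
    e <- cfg$expression
    ids <- ann$genes$name
    high <- ann$expressed_genes
    low <- sort(sample(setdiff(ids, high), length(high)))
    x <- stats::rnorm(length(ids), e$mu_log2, e$sigma_log2)
    names(x) <- ids
    x[high] <- e$mu_log2 + e$separation * e$sigma_log2
    x[low] <- e$mu_log2 - e$separation * e$sigma_log2
    reps <- vapply(seq_len(e$n_replicates), function(r)
      2^(x + stats::rnorm(length(x), 0, e$rep_sd)), numeric(length(x)))
    expr <- data.frame(gene_id = ids, reps, stringsAsFactors = FALSE)
    names(expr) <- c("gene_id", paste0("rep", seq_len(e$n_replicates)))
    list(expression = expr, truth = list(high = sort(high), low = low))
  })
}

#' Generate a qPCR Ct table encoding known fold enrichments
#'
#' Constructed so that [enrichment()] against the control row recovers each
#' planted `E` exactly: the control's dCt is fixed and each target's dCt is
#' `control dCt + log2(E)`.
#'
#' @param cfg A `sim_config`.
#' @return List: `ct` (Ct data frame) and `truth` (named planted E).
#' @export
generate_ct_table <- function(cfg) {
  dct_control <- 2
  ct_input <- 26
  targets <- names(cfg$planted_E)
  ct <- data.frame(target = c(targets, "unmethylated_control"),
                   ct_medip = c(ct_input - (dct_control +
                                              log2(cfg$planted_E)),
                                ct_input - dct_control),
                   ct_input = ct_input,
                   is_control = c(rep(FALSE, length(targets)), TRUE),
                   stringsAsFactors = FALSE)
  rownames(ct) <- NULL
  list(ct = ct, truth = cfg$planted_E)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_annotation()],
#' [generate_summits()], [generate_expression()] and
#' [generate_ct_table()].
#'
#' @param cfg A `sim_config`.
#' @return List: `genes`, `islands`, `repeats`, `events`, `features`,
#'   `summits`, `expression`, `ct`, `truth`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  ann <- generate_annotation(cfg)
  sm <- generate_summits(cfg, ann)
  ex <- generate_expression(cfg, ann)
  qt <- generate_ct_table(cfg)
  truth <- sm$truth
  truth$strata <- ex$truth
  truth$planted_E <- qt$truth
  list(genes = ann$genes, islands = ann$islands, repeats = ann$repeats,
       events = ann$events, features = ann$features, summits = sm$summits,
       expression = ex$expression, ct = qt$ct, truth = truth, cfg = cfg)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits exactly the formats the readers consume: `summits.bed`,
#' `genes.refflat`, `cgi.txt` (cpgIslandExt), `rmsk.txt`,
#' `splice_events.tsv`, `expression.tsv`, `ct.tsv`, plus `truth.json`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param outdir Output directory (created if missing).
#' @return The output directory, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_summits(sim$summits, p("summits.bed"))
  write_genepred(sim$genes, p("genes.refflat"), dialect = "refflat")
  write_cgi_track(sim$islands, p("cgi.txt"))
  write_rmsk(sim$repeats, p("rmsk.txt"))
  write_splice_events(sim$events, p("splice_events.tsv"))
  write_expression(sim$expression, p("expression.tsv"))
  write_ct_table(sim$ct, p("ct.tsv"))
  truth <- sim$truth
  truth$island_status <- as.list(truth$island_status)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
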