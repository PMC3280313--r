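test_that("moving average uses symmetric edge-shrunk windows", {
  expect_equal(moving_average(c(0, 0, 10, 0, 0), k = 5),
               c(10 / 3, 2.5, 2, 2.5, 10 / 3))
  expect_equal(moving_average(rep(7, 9), k = 5), rep(7, 9))
  x <- rnorm(10)
  expect_equal(moving_average(x, k = 1), x)
  expect_error(moving_average(x, k = 4), "odd")
})

test_that("anchored profiles bin strand-oriented offsets half-open", {
  a_plus <- data.frame(chrom = "chr1", pos = 10000, strand = "+")
  s <- summit_df("chr1", 9950)
  p <- anchored_profile(s, a_plus, flank = 5000, bin_width = 100)
  expect_equal(p$raw_counts[p$offsets == -100], 1)   # bin [-100, 0)
  expect_equal(sum(p$raw_counts), 1)
  a_minus <- a_plus; a_minus$strand <- "-"
  pm <- anchored_profile(s, a_minus, flank = 5000, bin_width = 100)
  expect_equal(pm$raw_counts[pm$offsets == 0], 1)    # mirrored to [0, 100)
  # summit exactly at the anchor lands in [0, bin_width)
  p0 <- anchored_profile(summit_df("chr1", 10000), a_plus, flank = 200,
                         bin_width = 10)
  expect_equal(p0$raw_counts[p0$offsets == 0], 1)
  expect_error(anchored_profile(s, a_plus[0, ]), "anchors")
  expect_error(anchored_profile(s, a_plus, flank = 5000, bin_width = 300),
               "multiple")
})

test_that("profile counts are conserved against the brute-force pair count", {
  withr::local_seed(41)
  anchors <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                        pos = floor(runif(40, 6000, 90000)),
                        strand = sample(c("+", "-"), 40, TRUE))
  summits <- random_points(800, span = 1e5)
  flank <- 1000
  p <- anchored_profile(summits, anchors, flank = flank, bin_width = 50)
  brute <- 0L
  for (i in seq_len(nrow(anchors))) {
    off <- summits$pos[summits$chrom == anchors$chrom[i]] - anchors$pos[i]
    if (anchors$strand[i] == "-") off <- -off
    brute <- brute + sum(off >= -flank & off < flank)
  }
  expect_equal(sum(p$raw_counts), brute)
  expect_equal(p$normalized, p$raw_counts / nrow(anchors))
})

test_that("profiles are translation invariant and mirror under strand flip", {
  withr::local_seed(43)
  anchors <- data.frame(chrom = "chr1", pos = floor(runif(20, 6000, 5e4)),
                        strand = sample(c("+", "-"), 20, TRUE))
  summits <- random_points(500, chroms = "chr1", span = 6e4)
  p <- anchored_profile(summits, anchors, flank = 2000, bin_width = 100)
  shift <- 12345
  p_shift <- anchored_profile(transform(summits, pos = pos + shift),
                              transform(anchors, pos = pos + shift),
                              flank = 2000, bin_width = 100)
  expect_equal(p_shift$raw_counts, p$raw_counts)
  M <- 2e5
  sm <- summit_df(summits$chrom, M - 1 - summits$pos)
  am <- data.frame(chrom = anchors$chrom, pos = M - 1 - anchors$pos,
                   strand = chartr("+-", "-+", anchors$strand))
  p_mirror <- anchored_profile(sm, am, flank = 2000, bin_width = 100)
  expect_equal(p_mirror$raw_counts, p$raw_counts)
})

test_that("expression stratification is mean-then-log2 with sample-SD cutoffs", {
  # planted scores x = (0,0,0,0,10): mu = 2, sd = sqrt(20)
  expr <- data.frame(gene_id = paste0("g", 1:5), rep1 = 2^c(0, 0, 0, 0, 10))
  st <- stratify_expression(expr)
  expect_equal(st$mu, 2)
  expect_equal(st$sigma, sqrt(20))
  expect_equal(st$high, "g5")
  expect_equal(st$low, character(0))
  # replicates are averaged before the log: (2,8) -> log2(5), not 2
  expr2 <- data.frame(gene_id = c("a", "b"), rep1 = c(2, 4), rep2 = c(8, 4))
  st2 <- stratify_expression(expr2)
  expect_equal(unname(st2$x["a"]), log2(5))
  # all genes equal: both strata empty
  expr3 <- data.frame(gene_id = c("a", "b", "c"), rep1 = c(4, 4, 4))
  st3 <- stratify_expression(expr3)
  expect_equal(length(st3$high) + length(st3$low), 0)
  expect_error(stratify_expression(data.frame(gene_id = "a", rep1 = -1)),
               "positive")
})

test_that("TSS profiles recover the planted expression-linked dip", {
  sim <- simulate_dataset(simulation_config(seed = 7, n_summits = 50000))
  strata <- stratify_expression(sim$expression)
  profs <- tss_profile(sim$summits, sim$genes, strata)
  high <- profs$high
  # argmin of the smoothed profile sits inside the planted +/-500 bp dip
  expect_lte(abs(high$offsets[which.min(high$smoothed)] +
                   high$bin_width / 2), 500)
  # unexpressed stratum shows no central depletion
  low <- profs$low
  center <- abs(low$offsets + low$bin_width / 2) <= 500
  expect_gte(mean(low$normalized[center]), mean(low$normalized[!center]))
  # identical gene sets give identical profiles
  profs2 <- tss_profile(sim$summits, sim$genes,
                        list(high = strata$high, low = strata$high))
  expect_equal(as.data.frame(profs2$high), as.data.frame(profs2$low))
  expect_error(tss_profile(sim$summits, sim$genes,
                           list(high = "absent", low = strata$low)),
               "high")
})

test_that("junction profiles separate coding from non-coding terminal exons", {
  cfg <- simulation_config(seed = 11, n_summits = 30000,
                           weights = c(coding_exon = 6, noncoding_exon = 0,
                                       promoter_5kb = 1, intron = 1,
                                       others = 1))
  ann <- generate_annotation(cfg)
  sm <- generate_summits(cfg, ann)
  coding <- junction_profile(sm$summits,
                             select_exons(ann$genes, "first", "coding"),
                             anchor = "exon_start")
  noncod <- junction_profile(sm$summits,
                             select_exons(ann$genes, "first", "non_coding"),
                             anchor = "exon_start")
  post <- coding$offsets >= 0
  expect_gt(mean(coding$normalized[post]), 2 * mean(coding$normalized[!post]))
  expect_lt(mean(noncod$normalized[post]), 0.2 * mean(coding$normalized[post]))
  expect_error(junction_profile(sm$summits,
                                select_exons(ann$genes[0, ], "first")),
               "empty")
})

test_that("all-distal summits give an all-zero profile; CGI anchors are unstranded", {
  g <- tiny_genes()
  p <- tss_profile(summit_df("chr1", 5e5), g, flank = 5000)
  expect_true(all(p$raw_counts == 0))
  isl <- data.frame(chrom = "chr1", start = 1000, end = 1400, name = "i")
  pc <- cgi_start_profile(summit_df("chr1", 950), isl, flank = 1000,
                          bin_width = 100)
  expect_equal(pc$raw_counts[pc$offsets == -100], 1)
})
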