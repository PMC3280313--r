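ct_row <- function(target, dct, control = FALSE, ct_input = 26) {
  data.frame(target = target, ct_medip = ct_input - dct,
             ct_input = ct_input, is_control = control,
             stringsAsFactors = FALSE)
}

test_that("delta-delta-Ct enrichment follows E = 2^ddCt with the MeDIP sign", {
  e <- enrichment(ct_row("t", 3), ct_row("c", 1, control = TRUE))
  expect_equal(e$delta_delta_ct, 2)
  expect_equal(e$E, 4)
  # identical measurements give E = 1
  same <- enrichment(ct_row("x", 1.7), ct_row("x", 1.7, control = TRUE))
  expect_equal(same$E, 1)
  # inverse consistency at a reported enrichment magnitude
  e493 <- enrichment(ct_row("t", 1 + log2(4.93)),
                     ct_row("c", 1, control = TRUE))
  expect_equal(e493$E, 4.93)
  expect_error(enrichment(ct_row("t", 3), ct_row("c", 1, control = FALSE)),
               "is_control")
  # antisymmetry: swapping target and control inverts E
  a <- ct_row("a", 3, control = TRUE)
  b <- ct_row("b", 1, control = TRUE)
  expect_equal(enrichment(a, b)$E * enrichment(b, a)$E, 1)
})

test_that("enrichment_table recovers planted fold enrichments exactly", {
  cfg <- simulation_config(seed = 2, planted_E = c(r1 = 8, r2 = 4.93))
  gen <- generate_ct_table(cfg)
  tab <- enrichment_table(gen$ct)
  expect_equal(stats::setNames(tab$E, tab$target_name), gen$truth)
  expect_error(enrichment_table(gen$ct[!gen$ct$is_control, ]), "control")
})

test_that("replicate concordance is 1 for identical sets and symmetric", {
  withr::local_seed(71)
  a <- random_points(500, span = 1e5)
  expect_equal(replicate_concordance(a, a, bin_bp = 1000), 1)
  b <- random_points(500, span = 1e5)
  expect_equal(replicate_concordance(a, b, bin_bp = 1000),
               replicate_concordance(b, a, bin_bp = 1000))
  # perfectly complementary placement on a two-bin toy
  x <- summit_df("chr1", c(10, 20, 150))
  y <- summit_df("chr1", c(110, 120, 30))
  expect_equal(replicate_concordance(x, y, bin_bp = 100,
                                     chrom_sizes = c(chr1 = 200)), -1)
  flat <- summit_df("chr1", c(50, 150))
  expect_error(replicate_concordance(flat, flat, bin_bp = 100,
                                     chrom_sizes = c(chr1 = 200)),
               "variance")
})

test_that("independent draws from one planted intensity correlate strongly", {
  # peaked intensity field (MeDIP coverage is strongly clustered): with
  # per-1kb-bin expected count mu_b = n * lambda_b / sum(lambda), Pearson r
  # between two independent Poisson-like draws is var(mu)/(var(mu) + mean(mu));
  # these weights at n = 30k give var/mean >> 4, i.e. expected r > 0.8
  cfg_a <- simulation_config(seed = 37, n_summits = 30000,
                             weights = c(exon = 20, promoter_5kb = 5,
                                         intron = 2, others = 0.2))
  ann <- generate_annotation(cfg_a)
  rep_a <- generate_summits(cfg_a, ann)$summits
  cfg_b <- cfg_a
  cfg_b$seed <- 38
  rep_b <- generate_summits(cfg_b, ann)$summits
  r <- replicate_concordance(rep_a, rep_b, bin_bp = 1000,
                             chrom_sizes = cfg_a$chrom_lengths)
  expect_gt(r, 0.8)
  # unrelated intensities correlate far less
  cfg_c <- simulation_config(seed = 99, n_summits = 30000,
                             weights = c(exon = 20, promoter_5kb = 5,
                                         intron = 2, others = 0.2))
  rep_c <- generate_summits(cfg_c, generate_annotation(cfg_c))$summits
  expect_lt(replicate_concordance(rep_a, rep_c, bin_bp = 1000,
                                  chrom_sizes = cfg_a$chrom_lengths), r)
})

test_that("saturation recovery is exact at full data and high for clustered summits", {
  withr::local_seed(83)
  s <- random_points(500, span = 1e6)
  curve <- saturation_curve(s, fractions = c(0.2, 0.6, 1), seed = 9)
  expect_equal(curve$recovery[curve$fraction == 1], 1)
  expect_equal(curve$n_subsampled, c(100, 300, 500))
  expect_true(all(diff(curve$recovery) >= -0.1))  # noisy but near-monotone
  expect_error(saturation_curve(s, fractions = c(0, 0.5), seed = 1), "0, 1")
  expect_error(saturation_curve(s, fractions = 0.5), "seed")
  # clusters of 10 summits within 50 bp: f = 0.3 recovers > 0.9
  centers <- floor(runif(200, 1000, 1e6))
  clustered <- summit_df("chr1", as.vector(vapply(centers, function(cc)
    sort(cc + sample.int(50, 10)), numeric(10))))
  cl <- saturation_curve(clustered, fractions = 0.3, seed = 4,
                         match_bp = 100)
  expect_gt(cl$recovery, 0.9)
  # duplicate positions: half the data still matches everything
  dup <- summit_df("chr1", c(100, 100))
  expect_equal(saturation_curve(dup, fractions = 0.5, seed = 1)$recovery, 1)
})
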