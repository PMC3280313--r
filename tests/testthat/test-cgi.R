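test_that("island methylation calls are half-open at both boundaries", {
  isl <- data.frame(chrom = "chr1", start = 100, end = 400, name = "i1",
                    length = 300, cpg_count = 20, gc_fraction = 0.6,
                    obs_exp = 0.8, strand = "*")
  expect_equal(classify_islands(isl, summit_df("chr1", 100))$status,
               "methylated")    # start is inclusive
  expect_equal(classify_islands(isl, summit_df("chr1", 400))$status,
               "unmethylated")  # end is exclusive
  expect_equal(classify_islands(isl, summit_df("chr1", 399))$summit_count, 1)
})

test_that("island calls equal the exhaustive scan and conserve totals", {
  withr::local_seed(23)
  islands <- random_intervals(1000, max_len = 1500)
  islands$name <- paste0("i", seq_len(nrow(islands)))
  summits <- random_points(1000)
  calls <- classify_islands(islands, summits)
  per_island <- vapply(seq_len(nrow(islands)), function(i)
    sum(summits$chrom == islands$chrom[i] &
          summits$pos >= islands$start[i] &
          summits$pos < islands$end[i]), numeric(1))
  expect_equal(calls$summit_count, as.integer(per_island))
  expect_equal(calls$status == "methylated", per_island >= 1)
  expect_equal(sum(calls$status == "methylated") +
                 sum(calls$status == "unmethylated"), nrow(islands))
  # no summits -> none methylated; one summit per island -> all methylated
  expect_true(all(classify_islands(islands, summits[0, ])$status ==
                    "unmethylated"))
  inside <- summit_df(islands$chrom, islands$start)
  expect_true(all(classify_islands(islands, inside)$status == "methylated"))
})

test_that("CGI criteria: length strictly > 200, GC > 0.5, obs/exp > 0.6", {
  isl <- data.frame(chrom = "chr1", start = c(100, 0, 0, 0),
                    end = c(450, 200, 350, 350),
                    gc_fraction = c(0.625, 0.7, 0.45, 0.625),
                    obs_exp = c(0.81, 0.8, 0.8, 0.5))
  v <- validate_cgi(isl)
  expect_equal(v$valid, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(v$reasons[2], "length")
  expect_match(v$reasons[3], "gc")
  expect_match(v$reasons[4], "obs_exp")
})

test_that("CGI statistics recomputed from sequence match hand counts", {
  seq_cg <- strrep("CG", 150)  # len 300: 150 C, 150 G, 150 CG dinucleotides
  isl <- data.frame(chrom = "chr1", start = 0, end = 300,
                    gc_fraction = 0, obs_exp = 0)  # track fields ignored
  v <- validate_cgi(isl, sequences = seq_cg)
  expect_true(v$valid)
  # obs/exp = (150 * 300) / (150 * 150) = 2; GC = 1
  seq_at <- paste0(strrep("AT", 100), strrep("CG", 50))  # len 300
  isl2 <- data.frame(chrom = "chr1", start = 0, end = 300,
                     gc_fraction = 0, obs_exp = 0)
  v2 <- validate_cgi(isl2, sequences = seq_at)
  # GC = 100/400 = 0.25 -> fails the GC criterion
  expect_false(v2$valid)
  expect_match(v2$reasons, "gc")
  expect_error(validate_cgi(isl, sequences = "ACGT"), "length")
})

test_that("size bins are half-open with explicit under/overflow bins", {
  calls <- data.frame(chrom = "chr1", start = 0,
                      end = c(250, 299, 300, 1000, 2000, 150))
  expect_warning(b <- bin_by_size(calls), "shorter")
  expect_equal(as.character(b$size_bin),
               c("200-300", "200-300", "300-400", ">=1000", ">=1000",
                 "<200"))
  expect_error(bin_by_size(calls, edges = c(300, 200)), "increasing")
  # conservation per status
  calls$status <- rep(c("methylated", "unmethylated"), 3)
  suppressWarnings(tab <- size_bin_table(bin_by_size(calls)))
  expect_equal(sum(tab$methylated), 3)
  expect_equal(sum(tab$total), 6)
})

test_that("island location is majority-overlap with exon > promoter > intron ties", {
  fs <- derive_features(tiny_genes())
  # fully inside TXP exon 1
  isl <- data.frame(chrom = "chr1", start = c(1100, 1700, 990),
                    end = c(1500, 2300, 1010), name = c("a", "b", "c"))
  loc <- locate_islands(isl, fs)$location
  expect_equal(loc[1], "exon")
  # island b: [1700,2300) = 300 bp exon + 300 bp intron -> tie -> exon
  expect_equal(loc[2], "exon")
  # island c: [990,1010) = 10 bp promoter + 20 bp exon -> exon majority
  expect_equal(loc[3], "exon")
  isl2 <- data.frame(chrom = "chr1", start = 2100, end = 2800, name = "d")
  expect_equal(locate_islands(isl2, fs)$location, "intron")
  isl3 <- data.frame(chrom = "chr1", start = 7e5, end = 7e5 + 400,
                     name = "e")
  expect_equal(locate_islands(isl3, fs)$location, "others")
})

test_that("per-bin location fractions sum to one on random fixtures", {
  withr::local_seed(29)
  sim <- simulate_dataset(simulation_config(seed = 23, n_genes = 40,
                                            n_islands = 120, n_repeats = 40,
                                            n_summits = 3000))
  calls <- locate_islands(bin_by_size(classify_islands(sim$islands,
                                                       sim$summits)),
                          sim$features)
  tab <- island_location_table(calls)
  sums <- tapply(tab$fraction, tab$size_bin, sum)
  occupied <- tapply(tab$count, tab$size_bin, sum) > 0
  expect_true(all(abs(sums[occupied] - 1) < 1e-12))
})
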