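test_that("promoter windows are strand-aware, clipped at zero", {
  g <- tiny_genes()
  g$tx_start[1] <- 6000; g$tx_end[1] <- 9000
  g$exon_starts[[1]] <- 6000; g$exon_ends[[1]] <- 9000
  g$cds_start[1] <- 6100; g$cds_end[1] <- 8900; g$exon_count[1] <- 1
  fs <- derive_features(g, promoter_bp = 5000)
  prom <- fs$features$promoter_5kb
  expect_equal(prom$start[prom$gene == "TXP"], 1000)  # [TSS-5kb, TSS)
  expect_equal(prom$end[prom$gene == "TXP"], 6000)
  # minus strand: TSS at txEnd, window downstream in genome coordinates
  expect_equal(prom$start[prom$gene == "TXM"], 14000)
  expect_equal(prom$end[prom$gene == "TXM"], 19000)

  g$tx_start[1] <- 2000  # clipping at chromosome start
  g$exon_starts[[1]] <- 2000
  fs2 <- derive_features(g, promoter_bp = 5000)
  expect_equal(fs2$features$promoter_5kb$start[1], 0)
  expect_error(derive_features(g, promoter_bp = -1), "non-negative")
})

test_that("introns are per-transcript exon gaps with merged-union areas", {
  fs <- derive_features(tiny_genes())
  introns <- fs$features$intron
  expect_equal(introns$start, c(2000, 11000))
  expect_equal(introns$end, c(4000, 13000))
  expect_equal(unname(fs$area["intron"]), 4000)
  expect_equal(unname(fs$area["exon"]), 4000)
  # empty gene list is a valid, empty feature set
  fs0 <- derive_features(tiny_genes()[0, ])
  expect_true(all(fs0$area == 0))
})

test_that("terminal exons resolve in transcript orientation with half-open CDS overlap", {
  g <- tiny_genes()
  # TXP first exon [1000,2000) vs cds 1200 -> coding
  expect_equal(classify_terminal_exons(g, "first"),
               c("coding", "coding"))
  g$cds_start[1] <- 4100  # first exon entirely UTR
  expect_equal(classify_terminal_exons(g, "first")[1], "non_coding")
  g$cds_start[1] <- 2000  # cds_start == exon1 end: half-open, no overlap
  expect_equal(classify_terminal_exons(g, "first")[1], "non_coding")
  # on the minus strand the genomically last exon is "first"
  g$cds_end[2] <- 12000   # genomic last exon [13000,14000) now UTR
  expect_equal(classify_terminal_exons(g, "first")[2], "non_coding")
  expect_equal(classify_terminal_exons(g, "last")[2], "coding")
  # non-coding transcript: not applicable
  g$cds_start[1] <- g$cds_end[1] <- g$tx_start[1]
  expect_true(is.na(classify_terminal_exons(g, "first")[1]))
})

test_that("UTR-exonic classes capture exon pieces outside the CDS", {
  fs <- derive_features(tiny_genes())
  u5 <- fs$features$utr5_exonic
  # TXP: [1000,1200); TXM (minus): 5' UTR after cds_end -> [13500,14000)
  expect_equal(u5$start, c(1000, 13500))
  expect_equal(u5$end, c(1200, 14000))
  u3 <- fs$features$utr3_exonic
  expect_equal(u3$start, c(4800, 10000))
  expect_equal(u3$end, c(5000, 10500))
})

test_that("point classification honours precedence and falls back to others", {
  g <- tiny_genes()
  # overlapping second gene whose promoter covers TXP's first exon
  g2 <- g[1, ]; g2$name <- "TXQ"; g2$strand <- "-"
  g2$tx_start <- 0; g2$tx_end <- 900
  g2$exon_starts <- list(0); g2$exon_ends <- list(900)
  g2$cds_start <- 100; g2$cds_end <- 800; g2$exon_count <- 1
  gg <- rbind(g, g2)
  fs <- derive_features(gg)
  p <- summit_df("chr1", 1500)  # in TXP exon AND TXQ promoter [900,5900)
  expect_equal(classify_points(p, fs, precedence = c("exon", "promoter_5kb",
                                                     "intron")), "exon")
  expect_equal(classify_points(p, fs, precedence = c("promoter_5kb", "exon",
                                                     "intron")),
               "promoter_5kb")
  expect_equal(classify_points(summit_df("chr1", 500000), fs), "others")
})

test_that("classification agrees with the exhaustive-scan oracle on random fixtures", {
  withr::local_seed(101)
  sim <- simulate_dataset(simulation_config(seed = 3, n_genes = 40,
                                            n_islands = 20, n_repeats = 80,
                                            n_summits = 3000))
  fs <- sim$features
  prec <- default_precedence(sim$repeats)
  got <- classify_points(sim$summits, fs, sim$repeats, prec)
  class_list <- c(list(exon = fs$features$exon,
                       promoter_5kb = fs$features$promoter_5kb,
                       intron = fs$features$intron),
                  split(sim$repeats, sim$repeats$rep_class)[
                    unique(sim$repeats$rep_class)])
  names(class_list) <- prec
  want <- oracle_classify(sim$summits$chrom, sim$summits$pos, class_list)
  expect_identical(got, want)
})

test_that("count_points_in matches direct counting in both query modes", {
  iv <- data.frame(chrom = "chr1", start = c(0, 20), end = c(10, 30),
                   strand = "*")
  s <- summit_df("chr1", c(5, 15, 25))
  expect_equal(count_points_in(iv, s), 2)
  expect_equal(count_points_in(iv, s[0, ]), 0)

  withr::local_seed(77)
  iv <- random_intervals(1000)
  pts <- random_points(5000)
  idx <- build_index(iv)
  expect_equal(count_points_in(idx, pts, "unique"),
               sum(oracle_contains(pts$chrom, pts$pos, iv)))
  expect_equal(count_points_in(idx, pts, "per_region"),
               oracle_pair_count(pts$chrom, pts$pos, iv))
})

test_that("class areas are invariant under strand flip + coordinate mirror", {
  g <- tiny_genes()
  # keep promoters clear of position 0 so no window is clipped
  shift <- 50000
  g$tx_start <- g$tx_start + shift; g$tx_end <- g$tx_end + shift
  g$cds_start <- g$cds_start + shift; g$cds_end <- g$cds_end + shift
  g$exon_starts <- lapply(g$exon_starts, `+`, shift)
  g$exon_ends <- lapply(g$exon_ends, `+`, shift)
  fs <- derive_features(g)
  M <- 1e6
  gm <- g
  gm$strand <- chartr("+-", "-+", g$strand)
  gm$tx_start <- M - g$tx_end
  gm$tx_end <- M - g$tx_start
  gm$cds_start <- M - g$cds_end
  gm$cds_end <- M - g$cds_start
  gm$exon_starts <- lapply(g$exon_ends, function(v) rev(M - v))
  gm$exon_ends <- lapply(g$exon_starts, function(v) rev(M - v))
  fsm <- derive_features(gm)
  expect_equal(fsm$area, fs$area)
})

test_that("exon selectors pick transcript-oriented subsets", {
  g <- tiny_genes()
  first <- select_exons(g, "first")
  # TXM is minus: its first exon is the genomically last one
  expect_equal(first$start[first$gene == "TXM"], 13000)
  expect_equal(select_exons(g, "second")$exon_rank, c(2, 1))
  expect_equal(nrow(select_exons(g, "internal")), 0)
  g$cds_start[1] <- 4100  # TXP exon1 now fully UTR
  nc <- select_exons(g, "first", coding_status = "non_coding")
  expect_equal(nc$gene, "TXP")
})
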