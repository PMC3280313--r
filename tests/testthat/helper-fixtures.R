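# Shared fixtures and exhaustive-scan oracles.  The oracles deliberately
# avoid the package's interval machinery: containment is checked by direct
# coordinate comparison against every interval.

# Vectorized exhaustive scan: is point i inside any interval (half-open)?
oracle_contains <- function(chrom, pos, iv) {
  out <- logical(length(pos))
  if (length(pos) == 0 || nrow(iv) == 0) return(out)
  for (ch in unique(chrom)) {
    pi <- which(chrom == ch)
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    m <- outer(pos[pi], sub$start, ">=") & outer(pos[pi], sub$end, "<")
    out[pi] <- rowSums(m) > 0
  }
  out
}

# Exhaustive per-point classification under a precedence order of interval
# sets (named list); unmatched points get "others".
oracle_classify <- function(chrom, pos, class_list) {
  labels <- rep("others", length(pos))
  open <- rep(TRUE, length(pos))
  for (cl in names(class_list)) {
    hit <- open & oracle_contains(chrom, pos, class_list[[cl]])
    labels[hit] <- cl
    open[hit] <- FALSE
  }
  labels
}

# Brute-force (summit, region instance) pair count.
oracle_pair_count <- function(chrom, pos, iv) {
  n <- 0L
  for (i in seq_along(pos))
    n <- n + sum(iv$chrom == chrom[i] & iv$start <= pos[i] & pos[i] < iv$end)
  n
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 1e6,
                             max_len = 2000) {
  start <- floor(runif(n, 0, span - max_len))
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + ceiling(runif(n, 1, max_len)), strand = "*",
             stringsAsFactors = FALSE)
}

random_points <- function(n, chroms = c("chr1", "chr2"), span = 1e6) {
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             pos = floor(runif(n, 0, span)), stringsAsFactors = FALSE)
}

# A small hand-built two-gene model set used across modules:
#   TXP: + strand, chr1, exons [1000,2000) [4000,5000), CDS [1200,4800)
#   TXM: - strand, chr1, exons [10000,11000) [13000,14000), CDS [10500,13500)
tiny_genes <- function() {
  g <- data.frame(name = c("TXP", "TXM"), gene_symbol = c("GP", "GM"),
                  chrom = "chr1", strand = c("+", "-"),
                  tx_start = c(1000, 10000), tx_end = c(5000, 14000),
                  cds_start = c(1200, 10500), cds_end = c(4800, 13500),
                  exon_count = 2, stringsAsFactors = FALSE)
  g$exon_starts <- list(c(1000, 4000), c(10000, 13000))
  g$exon_ends <- list(c(2000, 5000), c(11000, 14000))
  g
}

summit_df <- function(chrom, pos) {
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

# Mirror all coordinates around a fixed point M (base-level mirror for
# 0-based coordinates) and flip strands.
mirror_intervals <- function(iv, M) {
  out <- iv
  out$start <- M - iv$end
  out$end <- M - iv$start
  if ("strand" %in% names(iv))
    out$strand <- chartr("+-", "-+", iv$strand)
  out
}
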