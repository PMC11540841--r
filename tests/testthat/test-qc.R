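test_that("locus and individual QC enforces the documented thresholds", {
  # 10 individuals x 5 loci: L1 30% missing, L2 fixed everywhere,
  # L3-L5 clean and polymorphic
  d <- matrix(1L, 10, 5)
  d[1:3, 1] <- NA
  d[, 2] <- 0L
  d[, 3] <- rep(c(0L, 1L), 5)
  d[, 4] <- rep(c(1L, 2L), 5)
  d[, 5] <- rep(c(0L, 2L), 5)
  gm <- gm_from(d)
  res <- apply_locus_and_individual_qc(gm)
  expect_equal(loci(res$genotypes), c("L3", "L4", "L5"))
  expect_equal(res$report$loci_dropped_missing, "L1")
  expect_equal(res$report$loci_dropped_fixed, "L2")
  expect_equal(res$report$n_loci_before - length(res$report$loci_dropped_missing) -
                 length(res$report$loci_dropped_fixed),
               res$report$n_loci_after)
})

test_that("individuals above (strictly) 25% missing are dropped", {
  # 50 loci: 13/50 = 26% missing -> dropped; 12/50 = 24% retained;
  # boundary markers at exactly 25% remain
  d <- matrix(rep(c(0L, 1L, 2L), length.out = 50 * 4), 4, 50, byrow = TRUE)
  d[1, 1:13] <- NA
  d[2, 1:12] <- NA
  gm <- gm_from(d)
  res <- apply_locus_and_individual_qc(gm, max_locus_missing = 0.6)
  expect_equal(res$report$individuals_dropped, "i1")
  expect_true("i2" %in% individuals(res$genotypes))
})

test_that("QC is idempotent", {
  sim <- simulate_dataset(small_inversion_config(seed = 3,
                                                 missing_rate = 0.15))
  r1 <- apply_locus_and_individual_qc(sim$genotypes)
  r2 <- apply_locus_and_individual_qc(r1$genotypes)
  expect_identical(dosage(r2$genotypes), dosage(r1$genotypes))
  expect_length(r2$report$loci_dropped_missing, 0)
  expect_length(r2$report$individuals_dropped, 0)
})

# independent brute-force re-implementation of the candidate-SNP filter
brute_filter <- function(rec, qual_min = 600, cov_min = 10, cov_max = 50,
                         spacing = 200, one_per_contig = TRUE) {
  dp <- as.matrix(rec[, grep("^DP", colnames(rec)), drop = FALSE])
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (rec$TYPE[i] != "SNP") next
    if (!(rec$QUAL[i] > qual_min)) next
    if (any(dp[i, ] < cov_min | dp[i, ] > cov_max)) next
    crowded <- FALSE
    for (j in seq_len(nrow(rec))) {
      if (i == j) next
      if (rec$CHROM[j] == rec$CHROM[i] &&
          abs(rec$POS[j] - rec$POS[i]) < spacing) crowded <- TRUE
    }
    keep[i] <- !crowded
  }
  out <- rec[keep, ]
  if (one_per_contig) {
    picked <- lapply(split(out, out$CHROM), function(x)
      x[order(-x$QUAL, x$POS), ][1, ])
    out <- do.call(rbind, picked)
  }
  out[order(out$CHROM, out$POS), ]
}

test_that("candidate-SNP filtering matches a brute-force oracle", {
  set.seed(42)
  n <- 200
  rec <- data.frame(
    CHROM = sample(sprintf("ctg%02d", 1:25), n, replace = TRUE),
    POS = sample.int(5000, n, replace = TRUE),
    QUAL = round(runif(n, 400, 900)),
    TYPE = sample(c("SNP", "indel"), n, replace = TRUE, prob = c(0.8, 0.2)),
    DP1 = rpois(n, 25), DP2 = rpois(n, 25), DP3 = rpois(n, 30),
    DP4 = rpois(n, 30), stringsAsFactors = FALSE)
  rec <- rec[!duplicated(rec[, c("CHROM", "POS")]), ]
  got <- filter_candidate_snps(rec)
  want <- brute_filter(rec)
  key <- function(x) paste(x$CHROM, x$POS)
  expect_setequal(key(got), key(want))
  # never two retained records on one contig
  expect_false(anyDuplicated(got$CHROM) > 0)
})

test_that("candidate-SNP boundary rules: strict QUAL, spacing removes both", {
  rec <- data.frame(CHROM = c("c1", "c1", "c2"),
                    POS = c(1000, 1150, 500),
                    QUAL = c(800, 800, 600), TYPE = "SNP",
                    DP1 = 30, stringsAsFactors = FALSE)
  got <- filter_candidate_snps(rec)
  # the two 150-bp-apart SNPs both removed; QUAL == 600 exactly removed
  expect_equal(nrow(got), 0L)
  rec$POS[2] <- 1200   # exactly 200 bp: allowed
  got <- filter_candidate_snps(rec, one_per_contig = FALSE)
  expect_equal(got$POS, c(1000, 1200))
})
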