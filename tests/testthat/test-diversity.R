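test_that("per-locus diversity matches hand computations", {
  # 2 individuals, both heterozygous at L1: Ho = 1, He = 0.5,
  # uHe = 0.5 * 4/3; L2 monomorphic: Ho = uHe = 0, no FIS contribution
  gm <- gm_from(rbind(c(1L, 0L), c(1L, 0L)))
  md <- sample_metadata(individuals(gm), "s1", "g")
  div <- per_sample_diversity(gm, md)
  expect_equal(div$ho_mean, mean(c(1, 0)))
  expect_equal(div$uhe_mean, mean(c(0.5 * 4 / 3, 0)))
  expect_equal(div$polymorphic_pct, 50)
  # FIS averages only over polymorphic loci: (He - Ho)/He = -1
  expect_equal(div$fis_mean, -1)
})

test_that("uHe strictly exceeds He for finite polymorphic samples", {
  sim <- simulate_dataset(small_inversion_config(seed = 7))
  d <- dosage(sim$genotypes)
  md <- align_ok <- sim$metadata
  for (s in unique(md$site)[1:2]) {
    x <- d[md$site == s, , drop = FALSE]
    p <- colMeans(x, na.rm = TRUE) / 2
    n <- colSums(!is.na(x))
    he <- 2 * p * (1 - p)
    uhe <- 2 * n / (2 * n - 1) * he
    poly <- p > 0 & p < 1 & n > 1
    expect_true(all(uhe[poly] > he[poly]))
  }
})

test_that("HWE exact test matches full enumeration", {
  # one AA + one BB, n = 2: configurations nAB in {0, 2} with
  # probabilities 1/3 and 2/3 -> two-sided p = 1/3
  r <- hwe_exact_test(1, 0, 1)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$direction, "deficit")
  # all-heterozygote samples deviate toward excess
  expect_equal(hwe_exact_test(0, 7, 0)$direction, "excess")
  # monomorphic: p = 1, direction undefined
  expect_equal(hwe_exact_test(5, 0, 0)$p, 1)
  expect_true(is.na(hwe_exact_test(5, 0, 0)$direction))
  # random counts vs the brute-force oracle
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:50, 1)
    cnt <- as.vector(rmultinom(1, n, runif(3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3])$p,
                 hwe_brute(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("HWE exact p is invariant to allele relabelling", {
  set.seed(5)
  for (rep in 1:20) {
    cnt <- as.vector(rmultinom(1, 30, runif(3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3])$p,
                 hwe_exact_test(cnt[3], cnt[2], cnt[1])$p,
                 tolerance = 1e-12)
  }
})

test_that("genotype accumulation curve has the expected limits", {
  # clones: always exactly one multilocus genotype
  gm <- gm_from(matrix(1L, 6, 10))
  curve <- genotype_accumulation_curve(gm, reps = 5, seed = 1)
  expect_true(all(curve == 1))
  # all-distinct individuals plateau at n individuals
  d <- diag(6); d[d == 1] <- 2
  gm2 <- gm_from(cbind(d, d))
  curve2 <- genotype_accumulation_curve(gm2, reps = 10, seed = 1)
  expect_true(all(curve2[, ncol(curve2)] == 6))
  # mean curve is non-decreasing in subset size
  sim <- simulate_dataset(small_inversion_config(seed = 9))
  c3 <- genotype_accumulation_curve(sim$genotypes, max_loci = 20,
                                    reps = 25, seed = 2)
  m <- colMeans(c3)
  expect_true(all(diff(m) > -0.5))      # non-decreasing up to resampling noise
  expect_gt(m[20], m[1])
})

test_that("Kruskal-Wallis comparisons behave at the reference points", {
  expect_equal(kruskal_wallis_groups(rep(1, 9), rep(c("a", "b", "c"), 3)),
               list(H = 0, df = 2, p = 1))
  # tieless two-group case has the closed-form H = 3.857
  r <- kruskal_wallis_groups(c(1, 2, 3, 10, 11, 12),
                             rep(c("a", "b"), each = 3))
  expect_equal(r$H, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7,
               tolerance = 1e-12)
  expect_error(kruskal_wallis_groups(1:5, rep("a", 5)), "two groups")
})

test_that("preset diversity contrast: Mediterranean uHe under half of Ocean", {
  sim <- simulate_dataset(preset_three_habitats(seed = 4, n_scale = 0.2))
  div <- per_sample_diversity(sim$genotypes, sim$metadata)
  uhe <- tapply(div$uhe_mean, div$group, mean)
  expect_lt(uhe[["Mediterranean"]], uhe[["Ocean"]] / 2)
  expect_lt(uhe[["Mediterranean"]], uhe[["Fjords"]] / 2)
  # the panel identifies unique individuals with under a quarter of loci
  quarter <- floor(ncol(dosage(sim$genotypes)) / 4)
  acc <- genotype_accumulation_curve(sim$genotypes, max_loci = quarter,
                                     reps = 10, seed = 3)
  expect_gte(mean(acc[, quarter]), 0.99 * nrow(dosage(sim$genotypes)))
})
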