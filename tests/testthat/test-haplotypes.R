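test_that("two-locus EM matches an independent EM fixed point", {
  set.seed(51)
  # genotypes from haplotype pool with LD
  hf <- c(0.55, 0.05, 0.1, 0.3)     # AA, BA, AB, BB
  hap <- sample(0:3, 400, replace = TRUE, prob = hf)
  h1 <- hap[1:200]; h2 <- hap[201:400]
  d <- cbind(bitwAnd(h1, 1) + bitwAnd(h2, 1),
             bitwAnd(h1, 2) / 2 + bitwAnd(h2, 2) / 2)
  gm <- gm_from(d)
  hs <- em_phase_haplotypes(gm, restarts = 3, seed = 1, prune_rare = FALSE)
  want <- em2_brute(d)
  got <- setNames(rep(0, 4), c("AA", "BA", "AB", "BB"))
  got[names(hs$frequencies)] <- hs$frequencies
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
})

test_that("fully homozygous data reduces EM to direct counting", {
  d <- rbind(c(0L, 0L, 2L), c(2L, 2L, 0L), c(0L, 0L, 2L), c(2L, 0L, 0L))
  hs <- em_phase_haplotypes(gm_from(d), restarts = 2, seed = 1,
                            prune_rare = FALSE)
  counts <- c(AAB = 4, BBA = 2, BAA = 2) / 8
  expect_equal(sort(unname(hs$frequencies), decreasing = TRUE),
               sort(unname(counts), decreasing = TRUE), tolerance = 1e-9)
  # homozygous phases are unambiguous
  expect_equal(hs$phases$posterior, rep(1, 4))
  expect_equal(hs$phases$hap1[1], "AAB")
})

test_that("haplotype frequencies are recovered from simulated pools", {
  set.seed(60)
  hf <- c(0.5, 0.45, 0.05)
  haps <- c(0L, 7L, 5L)      # AAA, BBB, BAB over 3 loci
  recov <- replicate(10, {
    pool <- sample(haps, 1000, replace = TRUE, prob = hf)
    h1 <- pool[1:500]; h2 <- pool[501:1000]
    d <- vapply(0:2, function(b)
      (bitwAnd(h1, 2^b) > 0) + (bitwAnd(h2, 2^b) > 0), numeric(500))
    hs <- em_phase_haplotypes(gm_from(d), restarts = 2, seed = 1)
    unname(hs$frequencies["BBB"])
  })
  expect_lt(abs(mean(recov) - 0.45),
            3 * sqrt(0.45 * 0.55 / 1000) / sqrt(10) + 0.01)
})

test_that("missing diagnostic calls get posterior-weighted phases", {
  d <- rbind(c(0L, 0L), c(2L, 2L), c(0L, 0L), c(2L, 2L), c(NA, 0L))
  hs <- em_phase_haplotypes(gm_from(d), restarts = 2, seed = 2,
                            prune_rare = FALSE)
  ph <- hs$phases[5, ]
  # the missing allele is most probably A given the estimated pool
  expect_equal(ph$hap1, "AA")
  expect_lt(ph$posterior, 1)
})

test_that("haplotype-level differentiation hits its boundary values", {
  sim_meta <- sample_metadata(sprintf("i%d", 1:20),
                              site = rep(c("s1", "s2"), each = 10),
                              group = rep(c("g1", "g2"), each = 10))
  # two samples fixed for different haplotypes -> FST = 1
  d <- rbind(matrix(0L, 10, 3), matrix(2L, 10, 3))
  rownames(d) <- sim_meta$individual
  hs <- em_phase_haplotypes(genotype_matrix(d), restarts = 2, seed = 1)
  hd <- haplotype_differentiation(hs, sim_meta, hierarchical = FALSE,
                                  n_perm = 49, seed = 1)
  expect_equal(hd$fst$fst["s1", "s2"], 1, tolerance = 1e-9)
  expect_gt(hd$amova_flat$pct[["among_samples"]], 99)
  # identical haplotype distributions -> FST about 0
  set.seed(71)
  pool <- sample(c(0L, 7L), 80, replace = TRUE)
  h1 <- pool[1:40]; h2 <- pool[41:80]
  d2 <- vapply(0:2, function(b)
    (bitwAnd(h1, 2^b) > 0) + (bitwAnd(h2, 2^b) > 0), numeric(40))
  rownames(d2) <- sprintf("j%d", 1:40)
  md2 <- sample_metadata(rownames(d2), rep(c("s1", "s2"), each = 20),
                         rep("g", 40))
  hs2 <- em_phase_haplotypes(genotype_matrix(d2), restarts = 2, seed = 1)
  hd2 <- haplotype_differentiation(hs2, md2, hierarchical = FALSE,
                                   n_perm = 49, seed = 1)
  expect_lt(abs(hd2$fst$fst["s1", "s2"]), 0.06)
})

test_that("preset diagnostic loci yield two dominant haplotypes", {
  sim <- simulate_dataset(preset_three_habitats(seed = 41, n_scale = 0.25))
  diag_loci <- names(sim$truth$locus_class)[
    sim$truth$locus_class == "inversion-diagnostic"]
  hs <- em_phase_haplotypes(sim$genotypes, diag_loci, restarts = 3,
                            seed = 2)
  top2 <- sort(hs$frequencies, decreasing = TRUE)[1:2]
  expect_gt(sum(top2), 0.95)
  # the two dominant haplotypes are the opposite arrangements
  expect_setequal(names(top2), c("AAAAA", "BBBBB"))
})
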