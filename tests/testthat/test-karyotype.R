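test_that("karyotype classification recovers the simulated truth exactly on clean data", {
  sim <- simulate_dataset(small_inversion_config(seed = 25,
                                                 n_per_site = 50,
                                                 missing_rate = 0))
  gm <- sim$genotypes
  drivers <- names(sim$truth$locus_class)[
    sim$truth$locus_class != "background"]
  calls <- classify_karyotypes(gm, drivers, metadata = sim$metadata,
                               mode = "driver")
  expect_identical(unname(calls$karyotype),
                   unname(sim$truth$karyotype[calls$individual]))
  # labels invariant to a PC sign flip: flipping dosage polarity relabels
  # alleles but heterozygosity/Ocean-frequency anchoring keeps calls stable
  pca <- pca_genotypes(gm[, drivers])
  pca$scores[, 1] <- -pca$scores[, 1]
  calls2 <- classify_karyotypes(gm, drivers, pca = pca,
                                metadata = sim$metadata)
  expect_identical(calls2$karyotype, calls$karyotype)
})

test_that("Mediterranean individuals are all BB under the preset", {
  sim <- simulate_dataset(preset_three_habitats(seed = 6, n_scale = 0.2))
  pca <- pca_genotypes(sim$genotypes)
  dr <- driver_loci_from_loadings(pca)
  calls <- classify_karyotypes(sim$genotypes, dr$locus, pca = pca,
                               metadata = sim$metadata)
  med <- sim$metadata$group == "Mediterranean"
  kk <- calls$karyotype[med]
  expect_true(all(kk[kk != "unassigned"] == "BB"))
})

test_that("classification is rejected when no heterokaryotype cluster exists", {
  sim <- simulate_dataset(two_group_config(seed = 26, n_per_site = 40,
                                           n_loci = 30))
  gm <- sim$genotypes
  expect_error(
    classify_karyotypes(gm, loci(gm)[1:5], metadata = sim$metadata),
    "rejected")
})

test_that("frequency table shows the 1-0.5-0 signature and recovers partial frequencies", {
  sim <- simulate_dataset(small_inversion_config(seed = 28,
                                                 n_per_site = 400,
                                                 missing_rate = 0))
  gm <- sim$genotypes
  drivers <- names(sim$truth$locus_class)[
    sim$truth$locus_class != "background"]
  calls <- classify_karyotypes(gm, drivers, metadata = sim$metadata,
                               mode = "driver")
  ft <- karyotype_frequency_table(gm, calls,
                                  loci_sel = c(drivers, "bg001"),
                                  metadata = sim$metadata)
  tot <- ft[ft$scope == "Total", ]
  diag_loci <- names(sim$truth$locus_class)[
    sim$truth$locus_class == "inversion-diagnostic"]
  dd <- tot[tot$locus %in% diag_loci, ]
  expect_equal(dd$f_AA, rep(1, nrow(dd)))
  expect_equal(dd$f_AB, rep(0.5, nrow(dd)))
  expect_equal(dd$f_BB, rep(0, nrow(dd)))
  expect_true(all(dd$diagnostic))
  # partial locus with arrangement frequencies (0.7, 0): expect about
  # (0.7, 0.35, 0) within 3 binomial SE
  part <- tot[tot$locus == "inv05", ]   # first partial locus
  n_aa <- sum(calls$karyotype == "AA")
  expect_lt(abs(part$f_AA - 0.7), 3 * sqrt(0.7 * 0.3 / (2 * n_aa)))
  n_ab <- sum(calls$karyotype == "AB")
  expect_lt(abs(part$f_AB - 0.35), 3 * sqrt(0.35 * 0.65 / (2 * n_ab)))
  expect_false(part$diagnostic)
  # background locus: similar frequency across karyotypes
  bg <- tot[tot$locus == "bg001", ]
  expect_lt(max(abs(c(bg$f_AA - bg$f_AB, bg$f_AB - bg$f_BB))), 0.25)
})

test_that("per-sample haplogroup proportions track configured group frequencies", {
  cfg <- small_inversion_config(seed = 30, n_per_site = 600,
                                missing_rate = 0)
  sim <- simulate_dataset(cfg)
  drivers <- names(sim$truth$locus_class)[
    sim$truth$locus_class != "background"]
  calls <- classify_karyotypes(sim$genotypes, drivers,
                               metadata = sim$metadata, mode = "driver")
  hb <- haplogroup_frequencies_by_sample(calls, sim$metadata)
  fj <- hb[hb$site == "fj1", ]
  se <- function(p) 3 * sqrt(p * (1 - p) / 600)
  expect_lt(abs(fj$f_AB - 0.537), se(0.537) + 0.01)
  expect_lt(abs(fj$f_AA - 0.185), se(0.185) + 0.01)
  oc <- hb[hb$site == "oc1", ]
  expect_lt(abs(oc$f_AA - 0.567), se(0.567) + 0.01)
  expect_equal(hb$f_AA + hb$f_AB + hb$f_BB, rep(1, nrow(hb)))
  # single individual: one-hot proportions
  one <- calls[1, , drop = FALSE]
  md1 <- sim$metadata[sim$metadata$individual == one$individual, ]
  hb1 <- haplogroup_frequencies_by_sample(one, md1)
  expect_equal(sort(unname(unlist(hb1[, c("f_AA", "f_AB", "f_BB")])),
                    decreasing = TRUE)[1], 1)
})

test_that("migrant detection flags exactly the planted individuals", {
  cfg <- two_group_config(seed = 31, n_per_site = 40, n_loci = 80,
                          fst_between = 0.25)
  cfg$migrants <- data.frame(to_site = "s1", from_group = "G2", n = 3,
                             stringsAsFactors = FALSE)
  sim <- simulate_dataset(cfg)
  memb <- habitat_memberships(sim$genotypes, sim$metadata)
  flags <- detect_migrants(memb, sim$metadata, q_threshold = 0.7)
  expect_setequal(flags$individual, sim$truth$migrant_ids)
  expect_true(all(flags$assigned_cluster == "G2"))
  # no-migrant data: no flags
  cfg0 <- two_group_config(seed = 32, n_per_site = 40, n_loci = 80,
                           fst_between = 0.25)
  sim0 <- simulate_dataset(cfg0)
  memb0 <- habitat_memberships(sim0$genotypes, sim0$metadata)
  expect_equal(nrow(detect_migrants(memb0, sim0$metadata, 0.7)), 0L)
  # memberships behave like posteriors: rows on the simplex
  expect_equal(unname(rowSums(memb)), rep(1, nrow(memb)), tolerance = 1e-9)
})

test_that("stripe counting distinguishes striated from diffuse score vectors", {
  set.seed(2)
  striped <- c(rnorm(80, -3, 0.4), rnorm(100, 0, 0.4), rnorm(70, 3, 0.4))
  expect_equal(stripe_count(striped), 3L)
  expect_equal(stripe_count(rnorm(250)), 1L)
})
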