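test_that("simulation is deterministic for a given seed", {
  cfg <- small_inversion_config(seed = 5, missing_rate = 0.03)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(dosage(s1$genotypes), dosage(s2$genotypes))
  expect_identical(s1$truth$karyotype, s2$truth$karyotype)
})

test_that("perfect diagnostic loci are a deterministic function of karyotype", {
  sim <- simulate_dataset(small_inversion_config(seed = 2,
                                                 missing_rate = 0))
  diag_loci <- names(sim$truth$locus_class)[
    sim$truth$locus_class == "inversion-diagnostic"]
  d <- dosage(sim$genotypes)[, diag_loci, drop = FALSE]
  k <- sim$truth$karyotype
  expect_true(all(d[k == "AA", ] == 0))
  expect_true(all(d[k == "AB", ] == 1))
  expect_true(all(d[k == "BB", ] == 2))
})

test_that("karyotype counts converge to configured frequencies (3 SE)", {
  cfg <- simulation_config(
    seed = 8,
    groups = data.frame(group = "Fjords", site = "f", n = 10000),
    n_background_loci = 2, n_inversion_loci = 2, n_diagnostic = 2,
    karyotype_freqs = matrix(c(0.185, 0.537, 0.278) / 1,
                             1, 3, dimnames = list("Fjords", NULL)))
  sim <- simulate_dataset(cfg)
  tab <- table(sim$truth$karyotype) / 10000
  expect_lt(abs(tab[["AB"]] - 0.537), 3 * sqrt(0.537 * 0.463 / 10000))
  expect_lt(abs(tab[["AA"]] - 0.185), 3 * sqrt(0.185 * 0.815 / 10000))
})

test_that("background heterozygosity matches the Balding-Nichols expectation", {
  # E[2 p_site q_site] = 2 p q (1 - F_total) with F layered across levels:
  # var(p_site) = pq (Fb + Fw (1 - Fb))
  fb <- 0.1; fw <- 0.02; p <- 0.3
  cfg <- simulation_config(
    seed = 13,
    groups = data.frame(group = "g", site = "s", n = 4000),
    n_background_loci = 400, n_inversion_loci = 0,
    fst_between = fb, fst_within = fw, maf_range = c(p, p))
  sim <- simulate_dataset(cfg)
  he <- colMeans(dosage(sim$genotypes) == 1)
  f_tot <- fb + fw * (1 - fb)
  expected <- 2 * p * (1 - p) * (1 - f_tot)
  expect_lt(abs(mean(he) - expected),
            3 * sd(he) / sqrt(length(he)))
})

test_that("two-group background FST is recovered by Weir-Cockerham", {
  ths <- vapply(1:20, function(s) {
    sim <- simulate_dataset(two_group_config(seed = s, n_per_site = 50,
                                             n_loci = 50,
                                             fst_between = 0.15,
                                             fst_within = 0))
    grp <- sim$metadata$group
    weir_cockerham_fst(sim$genotypes, grp, pairwise = FALSE)
  }, numeric(1))
  # per-group drift F from the ancestral pool gives among-group FST = F
  expect_lt(abs(mean(ths) - 0.15), 3 * sd(ths) / sqrt(length(ths)) + 0.01)
})

test_that("the three-habitat preset encodes the study design", {
  cfg <- preset_three_habitats()
  expect_equal(nrow(cfg$groups), 16L)
  expect_equal(length(unique(cfg$groups$group)), 3L)
  expect_equal(cfg$n_background_loci + cfg$n_inversion_loci, 121)
  expect_equal(cfg$n_inversion_loci, 12)
  expect_equal(cfg$n_diagnostic, 5)
  expect_equal(unname(cfg$karyotype_freqs["Mediterranean", ]), c(0, 0, 1))
  expect_equal(unname(cfg$karyotype_freqs["Fjords", ]),
               c(0.185, 0.537, 0.279) / sum(c(0.185, 0.537, 0.279)))
  # config <-> YAML round trip
  path <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  back <- read_simulation_config(path)
  expect_equal(back$karyotype_freqs, cfg$karyotype_freqs, tolerance = 1e-6)
  expect_identical(dosage(simulate_dataset(back)$genotypes)[1:5, 1:5],
                   dosage(simulate_dataset(cfg)$genotypes)[1:5, 1:5])
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(
    seed = 1, groups = data.frame(group = "g", site = "s", n = 5),
    n_inversion_loci = 2, n_diagnostic = 2,
    karyotype_freqs = matrix(c(0.5, 0.4, 0.2), 1, 3,
                             dimnames = list("g", NULL))),
    "sum to 1")
  expect_error(simulation_config(
    seed = 1, groups = data.frame(group = "g", site = "s", n = 5),
    missing_rate = 1.5), "missing_rate")
})

test_that("planted migrants carry their origin-group genotype profile", {
  cfg <- two_group_config(seed = 21, n_per_site = 40, n_loci = 60,
                          fst_between = 0.2)
  cfg$migrants <- data.frame(to_site = "s1", from_group = "G2", n = 3,
                             stringsAsFactors = FALSE)
  sim <- simulate_dataset(cfg)
  expect_length(sim$truth$migrant_ids, 3)
  md <- sim$metadata
  expect_true(all(md$site[md$individual %in% sim$truth$migrant_ids] == "s1"))
  # migrants sit closer to their origin group in dosage space
  d <- imp <- dosage(sim$genotypes)
  cent <- function(rows) colMeans(d[rows, , drop = FALSE], na.rm = TRUE)
  c1 <- cent(md$group == "G1" & !(md$individual %in% sim$truth$migrant_ids))
  c2 <- cent(md$group == "G2")
  for (id in sim$truth$migrant_ids) {
    x <- d[id, ]
    expect_lt(sum((x - c2)^2, na.rm = TRUE), sum((x - c1)^2, na.rm = TRUE))
  }
})
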