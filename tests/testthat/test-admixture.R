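test_that("K = 1 likelihood approaches the pooled closed form and Q is degenerate", {
  set.seed(81)
  d <- matrix(rbinom(40 * 30, 2, 0.5), 40, 30)
  gm <- gm_from(d)
  r <- run_admixture(gm, 1, burn_in = 200, n_iter = 600, seed = 1)
  expect_equal(unname(r$Q[, 1]), rep(1, 40))
  p_hat <- colMeans(d) / 2
  closed <- sum(dbinom(t(d), 2, p_hat, log = TRUE))
  # posterior-averaged log-likelihood sits slightly below the plug-in
  # maximum (about half a unit per locus parameter)
  expect_lt(abs(r$L_mean - closed), ncol(d))
  expect_gt(closed, r$L_mean)
})

test_that("two fixed opposite populations are perfectly resolved at K = 2", {
  d <- rbind(matrix(0L, 15, 25), matrix(2L, 15, 25))
  gm <- gm_from(d)
  r <- run_admixture(gm, 2, burn_in = 200, n_iter = 600, seed = 3)
  assignment <- max.col(r$Q)
  expect_equal(length(unique(assignment[1:15])), 1L)
  expect_equal(length(unique(assignment[16:30])), 1L)
  expect_true(assignment[1] != assignment[16])
  expect_true(all(apply(r$Q, 1, max) > 0.9))
  # simplex invariant
  expect_equal(unname(rowSums(r$Q)), rep(1, 30), tolerance = 1e-9)
  expect_error(run_admixture(gm, 40), "exceeds")
})

test_that("Evanno table implements the stated second-difference formula", {
  fake <- function(K, L) structure(list(K = K, L = L),
                                   class = "admixture_run")
  runs <- list(fake(1, -100.5), fake(1, -99.5),
               fake(2, -50.5), fake(2, -49.5),
               fake(3, -45.5), fake(3, -44.5),
               fake(4, -44.6), fake(4, -43.4))
  ev <- evanno_delta_k(runs)
  sds <- apply(matrix(c(-100.5, -99.5, -50.5, -49.5, -45.5, -44.5,
                        -44.6, -43.4), 2), 2, sd)
  expect_equal(ev$delta_k[2], abs(-45 - 2 * (-50) + (-100)) / sds[2])
  expect_equal(ev$delta_k[3], abs(-44 - 2 * (-45) + (-50)) / sds[3])
  expect_equal(attr(ev, "best_k"), 2)
  expect_true(is.na(ev$delta_k[1]) && is.na(ev$delta_k[4]))
  # equal means across K: delta-K all zero
  runs0 <- list(fake(1, -10), fake(1, -12), fake(2, -10), fake(2, -12),
                fake(3, -10), fake(3, -12))
  expect_equal(evanno_delta_k(runs0)$delta_k[2], 0)
})

test_that("Evanno recovers K = 2 from two well-separated simulated groups", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_dataset(two_group_config(seed = s, n_per_site = 20,
                                             n_loci = 40,
                                             fst_between = 0.2))
    runs <- admixture_scan(sim$genotypes, 1:4, n_runs = 2, burn_in = 150,
                           n_iter = 400, seed = s)
    attr(evanno_delta_k(runs), "best_k") == 2
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("Puechmaille statistics count well-supported clusters", {
  q_sep <- rbind(matrix(c(1, 0, 0), 30, 3, byrow = TRUE),
                 matrix(c(0, 1, 0), 30, 3, byrow = TRUE),
                 matrix(c(0, 0, 1), 30, 3, byrow = TRUE))
  rownames(q_sep) <- sprintf("i%d", 1:90)
  run <- structure(list(Q = q_sep, K = 3, L = -1), class = "admixture_run")
  sites <- rep(c("s1", "s2", "s3"), each = 30)
  pu <- puechmaille_statistics(list(run, run), sites)
  expect_equal(c(pu$MedMedK, pu$MedMeanK, pu$MaxMedK, pu$MaxMeanK),
               rep(3L, 4))
  # single panmictic sample: only one cluster reaches the threshold
  q_flat <- cbind(rep(0.5, 60), 0.25, 0.25)
  rownames(q_flat) <- sprintf("i%d", 1:60)
  run0 <- structure(list(Q = q_flat, K = 3, L = -1),
                    class = "admixture_run")
  pu0 <- puechmaille_statistics(list(run0, run0), rep("s1", 60))
  expect_equal(pu0$MaxMeanK, 1L)
  expect_error(puechmaille_statistics(list(run0), rep("s1", 60), 1.2),
               "threshold")
})

test_that("run alignment undoes label switching and averages correctly", {
  set.seed(91)
  q <- matrix(rgamma(40 * 3, 1), 40, 3)
  q <- q / rowSums(q)
  rownames(q) <- sprintf("i%d", 1:40)
  mk <- function(Q, L) structure(list(Q = Q, K = 3, L = L),
                                 class = "admixture_run")
  perm <- c(3, 1, 2)
  r1 <- mk(q, -10)
  r2 <- mk(q[, order(perm)], -11)
  al <- align_and_average_runs(list(r1, r2))
  expect_equal(al$G_mean, 1, tolerance = 1e-12)
  expect_equal(unname(al$Q_mean), unname(q), tolerance = 1e-12)
  # noise on top of a label swap: average stays within noise of the source
  eps <- matrix(runif(40 * 3, 0, 0.02), 40, 3)
  q2 <- (q + eps) / rowSums(q + eps)
  r3 <- mk(q2[, order(perm)], -12)
  al2 <- align_and_average_runs(list(r1, r3))
  expect_lt(max(abs(al2$Q_mean - q)), 0.02)
  # full K-selection invariance to relabelling of an input run
  runs <- list(r1, r2, mk(q, -10.5), r1, r2, mk(q, -10.2))
  for (i in seq_along(runs)) runs[[i]]$K <- c(2, 2, 3, 3, 4, 4)[i]
  ev1 <- evanno_delta_k(runs)
  runs2 <- runs
  runs2[[3]]$Q <- runs2[[3]]$Q[, c(2, 3, 1)]
  ev2 <- evanno_delta_k(runs2)
  expect_equal(ev1$delta_k, ev2$delta_k)
})

test_that("admixture handles missing genotypes and stays on the simplex", {
  sim <- simulate_dataset(small_inversion_config(seed = 33,
                                                 missing_rate = 0.15))
  r <- run_admixture(sim$genotypes, 3, burn_in = 100, n_iter = 300,
                     seed = 4)
  expect_equal(unname(rowSums(r$Q)), rep(1, nrow(r$Q)), tolerance = 1e-9)
  expect_true(all(r$P >= 0 & r$P <= 1))
  expect_true(is.finite(r$L))
  # determinism under a fixed seed
  r2 <- run_admixture(sim$genotypes, 3, burn_in = 100, n_iter = 300,
                      seed = 4)
  expect_identical(r$Q, r2$Q)
})
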