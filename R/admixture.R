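#' Admixture-model clustering by Gibbs sampling
#'
#' Fits the admixture model: each individual has an ancestry vector Q over
#' K clusters, each cluster has per-locus allele frequencies P with
#' independent Beta(1, 1) priors, and every allele copy draws its cluster
#' of origin from Q. The sampler alternates conditional updates of P, Q,
#' the copy origins, and the Dirichlet concentration alpha (Metropolis
#' step). The reported model likelihood `L` is the mean of the
#' log-likelihood trace minus half its variance, the usual "estimated ln
#' probability of data"; the plain posterior-mean trace average is also
#' returned.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of clusters (>= 1).
#' @param burn_in,n_iter burn-in and retained sweeps.
#' @param alpha_init initial Dirichlet concentration.
#' @param seed RNG seed.
#' @return list of class `admixture_run`: `Q` (N x K posterior means, rows
#'   on the simplex), `P` (K x L), `L`, `L_mean`, `loglik_trace`,
#'   `alpha_mean`, `K`, `seed`, `burn_in`, `n_iter`.
#' @export
run_admixture <- function(gm, K, burn_in = 1000, n_iter = 3000,
                          alpha_init = 1, seed = 1) {
  d <- gm$dosage
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(d)) stop("K exceeds the number of individuals")
  stopifnot(n_iter > 0, burn_in >= 0)
  g <- d; g[is.na(g)] <- -1L
  res <- with_seed(derive_seed(seed, paste0("admix", K)), {
    admixture_gibbs_cpp(g, as.integer(K), as.integer(burn_in),
                        as.integer(n_iter), alpha_init)
  })
  Q <- res$Q
  rownames(Q) <- rownames(d)
  colnames(Q) <- paste0("Cluster", seq_len(K))
  tr <- res$loglik_trace
  structure(list(Q = Q, P = res$P, loglik_trace = tr,
                 L = mean(tr) - var(tr) / 2, L_mean = mean(tr),
                 alpha_mean = res$alpha_mean, K = K, seed = seed,
                 burn_in = burn_in, n_iter = n_iter),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat(sprintf("admixture_run: K = %d, %d individuals, L = %.1f (alpha %.2f)\n",
              x$K, nrow(x$Q), x$L, x$alpha_mean))
  invisible(x)
}

#' Evanno delta-K table
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / SD(L(K))`,
#' computed over replicate runs per K; the suggested K is the interior
#' argmax.
#'
#' @param runs list of `admixture_run` objects spanning at least three
#'   consecutive K values with >= 2 runs each.
#' @return data.frame of class `evanno_table` with per-K mean/SD of L,
#'   first and second differences and deltaK; attribute `best_k`.
#' @export
evanno_delta_k <- function(runs) {
  Ks <- vapply(runs, `[[`, numeric(1), "K")
  Ls <- vapply(runs, `[[`, numeric(1), "L")
  ks <- sort(unique(Ks))
  if (length(ks) < 3) stop("need at least three consecutive K values")
  if (any(diff(ks) != 1)) stop("K values must be consecutive")
  if (any(table(Ks) < 2)) stop("need at least two runs per K")
  ml <- tapply(Ls, Ks, mean)[as.character(ks)]
  sl <- tapply(Ls, Ks, sd)[as.character(ks)]
  n <- length(ks)
  lp <- c(NA, diff(ml))
  lpp <- c(NA, abs(ml[-(1:2)] - 2 * ml[-c(1, n)] + ml[-c(n - 1, n)]), NA)
  dk <- lpp / sl
  dk[sl == 0] <- NA
  out <- data.frame(K = ks, L_mean = as.numeric(ml), L_sd = as.numeric(sl),
                    L_prime = as.numeric(lp), L_second = as.numeric(lpp),
                    delta_k = as.numeric(dk))
  attr(out, "best_k") <- if (all(is.na(dk))) NA_integer_ else
    ks[which.max(dk)]
  class(out) <- c("evanno_table", "data.frame")
  out
}

#' Puechmaille K-selection statistics
#'
#' For each run and predefined sample, computes the mean and median
#' membership to every cluster; a cluster counts for a run if at least one
#' sample's mean (respectively median) membership reaches `threshold`.
#' MaxMeanK/MaxMedK are the maxima of the per-run counts, MedMeanK/MedMedK
#' the medians (rounded to the nearest integer).
#'
#' @param runs list of `admixture_run` objects (any K, typically one K).
#' @param sites per-individual sample labels aligned with the Q rows.
#' @param threshold membership threshold in (0, 1).
#' @return list of class `puechmaille_result` with the four statistics and
#'   the per-run counts.
#' @export
puechmaille_statistics <- function(runs, sites, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  counts <- vapply(runs, function(run) {
    Q <- run$Q
    stopifnot(length(sites) == nrow(Q))
    mn <- vapply(seq_len(ncol(Q)), function(k)
      max(tapply(Q[, k], sites, mean)), numeric(1))
    md <- vapply(seq_len(ncol(Q)), function(k)
      max(tapply(Q[, k], sites, median)), numeric(1))
    c(mean_count = sum(mn >= threshold),
      median_count = sum(md >= threshold))
  }, numeric(2))
  structure(list(threshold = threshold,
                 per_run = counts,
                 MedMedK = as.integer(round(median(counts["median_count", ]))),
                 MedMeanK = as.integer(round(median(counts["mean_count", ]))),
                 MaxMedK = as.integer(max(counts["median_count", ])),
                 MaxMeanK = as.integer(max(counts["mean_count", ]))),
            class = "puechmaille_result")
}

# similarity between two aligned Q matrices (1 = identical)
q_similarity <- function(q1, q2) {
  1 - sqrt(sum((q1 - q2)^2) / (2 * nrow(q1)))
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1)) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1)
  }
  out
}

#' Align replicate runs and average their ancestry matrices
#'
#' Cluster labels are arbitrary across runs. Each run is aligned to the
#' reference (the run with highest L) by the cluster permutation that
#' maximises the pairwise similarity G' = 1 - ||Q1 - Q2||_F / sqrt(2N);
#' the search is exhaustive for K <= 8 and greedy column matching above.
#' Aligned Q matrices are averaged.
#'
#' @param runs list of >= 2 `admixture_run` objects with equal K over the
#'   same individuals.
#' @return list with `Q_mean`, `permutations` (list per run), `G_mean`
#'   (mean similarity of aligned runs to the reference) and `reference`.
#' @export
align_and_average_runs <- function(runs) {
  if (length(runs) < 2) stop("need at least two runs")
  Ks <- vapply(runs, `[[`, numeric(1), "K")
  if (length(unique(Ks)) != 1) stop("runs must share one K")
  ids <- lapply(runs, function(r) rownames(r$Q))
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("runs cover different individual sets")
  K <- Ks[1]
  ref <- which.max(vapply(runs, `[[`, numeric(1), "L"))
  qref <- runs[[ref]]$Q
  perms <- vector("list", length(runs))
  gs <- numeric(length(runs))
  aligned <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    q <- runs[[r]]$Q
    if (r == ref) {
      perms[[r]] <- seq_len(K); gs[r] <- 1; aligned[[r]] <- q
      next
    }
    if (K <= 8) {
      best <- NULL; bestg <- -Inf
      for (p in all_permutations(K)) {
        g <- q_similarity(qref, q[, p, drop = FALSE])
        if (g > bestg) { bestg <- g; best <- p }
      }
    } else {
      # greedy column matching on squared-error cost
      cost <- matrix(0, K, K)
      for (a in seq_len(K)) for (b in seq_len(K))
        cost[a, b] <- sum((qref[, a] - q[, b])^2)
      best <- integer(K)
      freeb <- seq_len(K)
      for (a in order(apply(cost, 1, min))) {
        b <- freeb[which.min(cost[a, freeb])]
        best[a] <- b
        freeb <- setdiff(freeb, b)
      }
      bestg <- q_similarity(qref, q[, best, drop = FALSE])
    }
    perms[[r]] <- best
    gs[r] <- bestg
    aligned[[r]] <- q[, best, drop = FALSE]
  }
  qm <- Reduce(`+`, aligned) / length(aligned)
  colnames(qm) <- colnames(qref)
  list(Q_mean = qm, permutations = perms, G_mean = mean(gs[-ref]),
       reference = ref)
}

#' Run replicate admixture fits over a K range
#'
#' @param gm a [genotype_matrix()].
#' @param k_range integer vector of K values.
#' @param n_runs replicates per K.
#' @param burn_in,n_iter sampler settings per run.
#' @param seed global seed (one derived seed per run).
#' @return list of `admixture_run` objects.
#' @export
admixture_scan <- function(gm, k_range = 1:6, n_runs = 5, burn_in = 1000,
                           n_iter = 3000, seed = 1) {
  runs <- list()
  for (K in k_range) for (r in seq_len(n_runs)) {
    runs[[length(runs) + 1L]] <-
      run_admixture(gm, K, burn_in, n_iter,
                    seed = derive_seed(seed, sprintf("scan_K%d_r%d", K, r)))
  }
  runs
}
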