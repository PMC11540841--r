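# Enumerate the haplotype pairs compatible with one multilocus genotype.
# Haplotypes are bitmask integers (bit j set = B allele at locus j).
# Heterozygous loci split alleles between the two haplotypes; missing loci
# leave both haplotypes free at that position.
compatible_pairs <- function(geno) {
  L <- length(geno)
  het <- which(!is.na(geno) & geno == 1)
  mis <- which(is.na(geno))
  base <- 0L
  for (j in which(!is.na(geno) & geno == 2)) base <- bitwOr(base, bitwShiftL(1L, j - 1L))
  free <- c(het, mis)
  h1s <- h2s <- integer(0)
  n_amb <- length(het) + 2 * length(mis)
  for (m in 0:(2^n_amb - 1)) {
    h1 <- h2 <- base
    bit <- m
    for (j in het) {
      if (bit %% 2 == 1) h1 <- bitwOr(h1, bitwShiftL(1L, j - 1L))
      else h2 <- bitwOr(h2, bitwShiftL(1L, j - 1L))
      bit <- bit %/% 2
    }
    for (j in mis) {
      if (bit %% 2 == 1) h1 <- bitwOr(h1, bitwShiftL(1L, j - 1L))
      bit <- bit %/% 2
      if (bit %% 2 == 1) h2 <- bitwOr(h2, bitwShiftL(1L, j - 1L))
      bit <- bit %/% 2
    }
    h1s <- c(h1s, h1); h2s <- c(h2s, h2)
  }
  keep <- !duplicated(paste(pmin(h1s, h2s), pmax(h1s, h2s)))
  cbind(h1 = pmin(h1s, h2s)[keep], h2 = pmax(h1s, h2s)[keep])
}

hap_string <- function(h, L) {
  paste(ifelse(bitwAnd(h, bitwShiftL(1L, seq_len(L) - 1L)) > 0, "B", "A"),
        collapse = "")
}

#' EM haplotype frequency estimation from unphased genotypes
#'
#' Maximum-likelihood multinomial haplotype frequencies under
#' Hardy-Weinberg random pairing, with genotypes observed as unordered
#' pairs summed over all compatible phases (missing calls are summed over
#' both alleles). Standard EM with random restarts; the best run by
#' log-likelihood is kept. Haplotypes with estimated frequency below
#' `1/(4n)` are pruned and the EM re-run once to stabilise the set of
#' observed haplotypes.
#'
#' @param gm a [genotype_matrix()] restricted to the phased loci (at most
#'   ~12 loci).
#' @param loci_sel optional locus subset.
#' @param tol convergence threshold on the largest frequency change.
#' @param restarts random restarts.
#' @param max_iter iteration cap per run.
#' @param seed RNG seed.
#' @param prune_rare apply the rare-haplotype floor?
#' @return list of class `haplotype_set`: `haplotypes` (strings over A/B),
#'   `frequencies`, `phases` (per-individual best pair with posterior
#'   probability), `loglik`, `n_iter`.
#' @export
em_phase_haplotypes <- function(gm, loci_sel = NULL, tol = 1e-8,
                                restarts = 10, max_iter = 2000, seed = 1,
                                prune_rare = TRUE) {
  if (!is.null(loci_sel)) gm <- gm[, loci_sel]
  d <- gm$dosage
  L <- ncol(d)
  if (L > 14) stop("haplotype space too large: at most 14 loci supported")
  if (nrow(d) < 2) stop("need at least two individuals")
  poly <- apply(d, 2, function(x) length(unique(x[!is.na(x)])) > 1)
  if (!any(poly)) stop("no polymorphic locus to phase")

  pairs <- lapply(seq_len(nrow(d)), function(i) compatible_pairs(d[i, ]))
  haps <- sort(unique(unlist(lapply(pairs, as.vector))))
  H <- length(haps)
  pair_idx <- lapply(pairs, function(pp)
    cbind(match(pp[, 1], haps), match(pp[, 2], haps)))

  run_em <- function(f0) {
    f <- f0
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      # E step: posterior over compatible pairs; M step: expected counts
      cnt <- numeric(H)
      ll <- 0
      for (i in seq_along(pair_idx)) {
        pi <- pair_idx[[i]]
        w <- f[pi[, 1]] * f[pi[, 2]] * ifelse(pi[, 1] == pi[, 2], 1, 2)
        sw <- sum(w)
        if (sw <= 0) next
        ll <- ll + log(sw)
        w <- w / sw
        for (r in seq_len(nrow(pi))) {
          cnt[pi[r, 1]] <- cnt[pi[r, 1]] + w[r]
          cnt[pi[r, 2]] <- cnt[pi[r, 2]] + w[r]
        }
      }
      f_new <- cnt / sum(cnt)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (ll < ll_old - 1e-9)
        stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
      ll_old <- ll
      if (delta < tol) break
    }
    list(f = f, loglik = ll_old, n_iter = it)
  }

  best <- with_seed(derive_seed(seed, "em"), {
    best <- run_em(rep(1 / H, H))
    for (r in seq_len(restarts - 1)) {
      f0 <- rgamma(H, 1); f0 <- f0 / sum(f0)
      cand <- run_em(f0)
      if (cand$loglik > best$loglik + 1e-9) best <- cand
    }
    best
  })

  if (prune_rare) {
    floor_f <- 1 / (4 * nrow(d))
    keep <- best$f >= floor_f
    if (any(!keep) && any(keep)) {
      haps2 <- haps[keep]
      ok_pairs <- vapply(pair_idx, function(pi)
        any(haps[pi[, 1]] %in% haps2 & haps[pi[, 2]] %in% haps2), logical(1))
      if (all(ok_pairs)) {
        haps <- haps2
        # rebuild indices against the pruned haplotype list
        pair_idx <- lapply(pairs, function(pp) {
          sel <- pp[, 1] %in% haps2 & pp[, 2] %in% haps2
          pp <- pp[sel, , drop = FALSE]
          cbind(match(pp[, 1], haps2), match(pp[, 2], haps2))
        })
        H <- length(haps)
        best <- run_em(rep(1 / H, H))
      }
    }
  }

  # per-individual best phase
  phases <- do.call(rbind, lapply(seq_along(pair_idx), function(i) {
    pi <- pair_idx[[i]]
    f <- best$f
    w <- f[pi[, 1]] * f[pi[, 2]] * ifelse(pi[, 1] == pi[, 2], 1, 2)
    r <- which.max(w)
    data.frame(individual = individuals(gm)[i],
               hap1 = hap_string(haps[pi[r, 1]], L),
               hap2 = hap_string(haps[pi[r, 2]], L),
               posterior = w[r] / sum(w), stringsAsFactors = FALSE)
  }))
  structure(list(
    haplotypes = vapply(haps, hap_string, "", L = L),
    frequencies = setNames(best$f, vapply(haps, hap_string, "", L = L)),
    phases = phases, loglik = best$loglik, n_iter = best$n_iter,
    loci = loci(gm)), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$haplotypes), "haplotypes over",
      length(x$loci), "loci; logL =", round(x$loglik, 2), "\n")
  print(round(sort(x$frequencies, decreasing = TRUE), 4))
  invisible(x)
}

#' Haplotype-level differentiation
#'
#' Treats each individual's best haplotype pair as a genotype at one
#' multi-allelic super-locus and runs pairwise FST (Weir-Cockerham summed
#' over haplotype alleles) and AMOVA with allele-identity distances.
#'
#' @param hapset a `haplotype_set` from [em_phase_haplotypes()].
#' @param metadata a [sample_metadata()] covering the phased individuals.
#' @param hierarchical also fit the group hierarchy?
#' @param n_perm permutations for AMOVA / pairwise tests.
#' @param seed RNG seed.
#' @return list with `fst` (an `fst_matrix`), `amova_flat` and (optionally)
#'   `amova_hier`.
#' @export
haplotype_differentiation <- function(hapset, metadata, hierarchical = TRUE,
                                      n_perm = 1000, seed = 1) {
  ph <- hapset$phases
  idx <- match(ph$individual, metadata$individual)
  if (anyNA(idx)) stop("metadata missing for phased individuals")
  sites <- metadata$site[idx]
  groups <- metadata$group[idx]
  alleles <- sort(unique(c(ph$hap1, ph$hap2)))
  # super-locus as one dosage column per haplotype allele
  dos <- vapply(alleles, function(a)
    (ph$hap1 == a) + (ph$hap2 == a), numeric(nrow(ph)))
  rownames(dos) <- ph$individual

  theta_pair <- function(dd, lab) {
    comp <- vapply(seq_len(ncol(dd)), function(j)
      wc_components(dd[, j, drop = FALSE] , lab)[, 1], numeric(3))
    sum(comp[1, ], na.rm = TRUE) / sum(comp, na.rm = TRUE)
  }
  sn <- unique(sites)
  S <- length(sn)
  fst <- p <- matrix(NA_real_, S, S, dimnames = list(sn, sn))
  with_seed(derive_seed(seed, "hapfst"), {
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      sel <- sites %in% c(sn[i], sn[j])
      th <- theta_pair(dos[sel, , drop = FALSE], sites[sel])
      fst[i, j] <- fst[j, i] <- th
      if (n_perm > 0) {
        cnt <- sum(vapply(seq_len(n_perm), function(b)
          theta_pair(dos[sel, , drop = FALSE], sample(sites[sel])) >= th,
          logical(1)))
        p[i, j] <- p[j, i] <- (cnt + 1) / (n_perm + 1)
      }
    }
  })
  fstm <- structure(list(samples = sn, fst = fst, p = p, q = p,
                         n_perm = n_perm), class = "fst_matrix")
  # allele-identity distance: copies not shared between the two pairs
  n <- nrow(ph)
  D2 <- matrix(0, n, n, dimnames = list(ph$individual, ph$individual))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- sum(pmin(dos[i, ], dos[j, ]))
    D2[i, j] <- D2[j, i] <- 2 - shared
  }
  out <- list(fst = fstm,
              amova_flat = amova_from_dist(D2, sites, NULL, n_perm, seed))
  if (hierarchical)
    out$amova_hier <- amova_from_dist(D2, sites, groups, n_perm, seed)
  out
}
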