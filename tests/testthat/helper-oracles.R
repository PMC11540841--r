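# Independent brute-force oracles shared by unit and acceptance tests.
# Each is a direct transcription of the defining formulas, kept separate
# from the package implementation paths it checks.

# independent textbook transcription of the per-locus variance components
wc_brute <- function(d, sites) {
  sites <- as.factor(sites)
  acc <- c(a = 0, b = 0, c = 0)
  for (l in seq_len(ncol(d))) {
    x <- split(d[, l], sites)
    x <- lapply(x, function(v) v[!is.na(v)])
    x <- x[lengths(x) > 0]
    r <- length(x)
    if (r < 2) next
    ni <- lengths(x)
    pi <- vapply(x, function(v) sum(v) / (2 * length(v)), numeric(1))
    hi <- vapply(x, function(v) mean(v == 1), numeric(1))
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    pbar <- sum(ni * pi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    acc <- acc + c(a = a, b = b, c = hbar / 2)
  }
  acc
}


# brute-force AMOVA from the full distance matrix, flat design
amova_brute_flat <- function(D2, sites) {
  N <- nrow(D2)
  ss_tot <- sum(D2[lower.tri(D2)]) / N
  ss_w <- 0
  for (s in unique(sites)) {
    idx <- which(sites == s)
    ss_w <- ss_w + sum(D2[idx, idx][lower.tri(diag(length(idx)))]) /
      length(idx)
  }
  S <- length(unique(sites))
  ms_a <- (ss_tot - ss_w) / (S - 1)
  ms_w <- ss_w / (N - S)
  n0 <- (N - sum(table(sites)^2) / N) / (S - 1)
  sig_a <- (ms_a - ms_w) / n0
  c(sig_a = sig_a, sig_w = ms_w, fst = sig_a / (sig_a + ms_w))
}


hwe_brute <- function(naa, nab, nbb) {
  # enumerate all genotype configurations with the observed allele counts
  n <- naa + nab + nbb
  na <- 2 * naa + nab
  hets <- seq(min(na, 2 * n - na) %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (na - h) / 2; bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(nab, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}


# direct transcription of the index-of-association definitions
ia_brute <- function(d) {
  n <- nrow(d); L <- ncol(d)
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  dl <- matrix(0, m, L)
  for (c in seq_len(m)) for (l in seq_len(L))
    dl[c, l] <- abs(d[pairs[1, c], l] - d[pairs[2, c], l])
  D <- rowSums(dl)
  pvar <- function(v) mean(v^2) - mean(v)^2
  vo <- pvar(D)
  vars <- apply(dl, 2, pvar)
  ve <- sum(vars)
  denom <- 0
  for (j in 1:(L - 1)) for (k in (j + 1):L)
    denom <- denom + sqrt(vars[j] * vars[k])
  c(ia = vo / ve - 1, rbard = (vo - ve) / (2 * denom))
}


# brute-force two-locus haplotype EM on a frequency grid + direct EM,
# written independently of the package implementation
em2_brute <- function(d) {
  # haplotypes over 2 loci: 00, 01, 10, 11 (B allele = 1)
  types <- expand.grid(h1 = 0:3, h2 = 0:3)
  types <- types[types$h1 <= types$h2, ]
  geno_of <- function(h) c(bitwAnd(h, 1), bitwAnd(h, 2) / 2)
  f <- rep(0.25, 4)
  for (it in 1:5000) {
    cnt <- rep(0, 4)
    for (i in seq_len(nrow(d))) {
      w <- numeric(nrow(types))
      for (t in seq_len(nrow(types))) {
        g <- geno_of(types$h1[t]) + geno_of(types$h2[t])
        if (all(g == d[i, ])) {
          w[t] <- f[types$h1[t] + 1] * f[types$h2[t] + 1] *
            ifelse(types$h1[t] == types$h2[t], 1, 2)
        }
      }
      if (sum(w) == 0) next
      w <- w / sum(w)
      for (t in which(w > 0)) {
        cnt[types$h1[t] + 1] <- cnt[types$h1[t] + 1] + w[t]
        cnt[types$h2[t] + 1] <- cnt[types$h2[t] + 1] + w[t]
      }
    }
    f_new <- cnt / sum(cnt)
    if (max(abs(f_new - f)) < 1e-12) break
    f <- f_new
  }
  setNames(f, c("AA", "BA", "AB", "BB"))
}

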