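#' Classify individuals into inversion karyotypes (AA / AB / BB)
#'
#' Runs 1-D k-means (k = 3) on PCA scores along one axis (by default PC1 of
#' the full panel), orders the clusters by centre, and verifies that the
#' middle cluster has the highest mean heterozygosity at the driver loci —
#' the defining property of heterokaryotypes. Individuals closer than
#' `unassigned_margin` times the local inter-centre spacing to a cluster
#' boundary are left unassigned. Flank labels follow the convention that
#' "A" is the arrangement whose homokaryotype cluster is most frequent
#' among `ocean_group` individuals when habitat metadata is available,
#' otherwise the flank whose driver-locus A-allele (first allele code)
#' frequency is higher is called AA.
#'
#' A fallback `mode = "driver"` classifies on the driver loci directly
#' (PC1 of the driver-locus submatrix), for datasets where background
#' structure dominates the full-panel PC1.
#'
#' @param gm a [genotype_matrix()].
#' @param driver_loci character vector of driver locus IDs.
#' @param pca optional precomputed full-panel `pca_result`.
#' @param axis score axis used for clustering.
#' @param metadata optional [sample_metadata()] used for the labelling
#'   convention.
#' @param mode `"pc1"` (full panel) or `"driver"` (driver-locus submatrix).
#' @param ocean_group name of the open-water group for the labelling
#'   convention.
#' @param unassigned_margin boundary margin as a fraction of inter-centre
#'   spacing.
#' @param n_restarts k-means restarts.
#' @param seed RNG seed.
#' @return data.frame of class `karyotype_calls`: `individual`,
#'   `karyotype` (AA/AB/BB/unassigned) and `quality` (score distance to the
#'   nearest cluster boundary, scaled by the spacing); attributes record the
#'   driver loci, mode and labelling convention.
#' @export
classify_karyotypes <- function(gm, driver_loci, pca = NULL, axis = 1,
                                metadata = NULL, mode = c("pc1", "driver"),
                                ocean_group = "Ocean",
                                unassigned_margin = 0.05, n_restarts = 50,
                                seed = 1) {
  mode <- match.arg(mode)
  stopifnot(all(driver_loci %in% loci(gm)), nrow(gm$dosage) >= 3)
  if (mode == "driver") {
    pca <- pca_genotypes(gm[, driver_loci])
    axis <- 1
  } else if (is.null(pca)) {
    pca <- pca_genotypes(gm)
  }
  sc <- pca$scores[, axis]

  km <- with_seed(derive_seed(seed, "karyo_kmeans"), {
    init <- matrix(c(min(sc), median(sc), max(sc)), ncol = 1)
    best <- tryCatch(kmeans(sc, centers = init),
                     error = function(e) NULL)
    for (r in seq_len(n_restarts)) {
      cand <- tryCatch(kmeans(sc, centers = matrix(sample(sc, 3), ncol = 1)),
                       error = function(e) NULL)
      if (!is.null(cand) &&
          (is.null(best) || cand$tot.withinss < best$tot.withinss))
        best <- cand
    }
    best
  })
  if (is.null(km) || length(unique(km$cluster)) < 3) {
    out <- data.frame(individual = individuals(gm),
                      karyotype = "unassigned", quality = NA_real_,
                      stringsAsFactors = FALSE)
    class(out) <- c("karyotype_calls", "data.frame")
    attr(out, "rejected") <- "degenerate k-means (fewer than 3 clusters)"
    return(out)
  }
  ord <- order(km$centers)
  centers <- km$centers[ord]
  cl <- match(km$cluster, ord)          # 1 = low flank, 2 = mid, 3 = high

  het <- rowMeans(gm$dosage[, driver_loci, drop = FALSE] == 1, na.rm = TRUE)
  het_by <- tapply(het, cl, mean, na.rm = TRUE)
  # heterokaryotypes are heterozygous at (nearly) every diagnostic locus, so
  # the middle cluster must clearly lead in driver-locus heterozygosity
  if (which.max(het_by) != 2 || het_by[2] < 0.5)
    stop("classification rejected: middle cluster is not distinctly the ",
         "most heterozygous at the driver loci (mean het by cluster: ",
         paste(round(het_by, 3), collapse = ", "), ")")

  # A-allele dosage at driver loci (allele_a is the A code): 2 - B dosage
  a_dose <- 2 - gm$dosage[, driver_loci, drop = FALSE]
  a_freq_by <- tapply(rowMeans(a_dose, na.rm = TRUE) / 2, cl, mean,
                      na.rm = TRUE)
  groups <- if (!is.null(metadata)) align_metadata(gm, metadata)$group
  if (!is.null(groups) && ocean_group %in% groups) {
    oc <- table(factor(cl[groups == ocean_group], 1:3))
    aa_flank <- if (oc[1] >= oc[3]) 1L else 3L
    convention <- sprintf("AA = flank most frequent in %s group", ocean_group)
  } else {
    aa_flank <- if (a_freq_by[1] >= a_freq_by[3]) 1L else 3L
    convention <- "AA = flank with higher driver-locus first-allele frequency"
  }
  labels <- c("AB", "AB", "AB")
  labels[aa_flank] <- "AA"
  labels[c(1, 3)[c(1, 3) != aa_flank]] <- "BB"
  labels[2] <- "AB"

  bounds <- (centers[-3] + centers[-1]) / 2
  spacing <- diff(centers)
  margin <- vapply(seq_along(sc), function(i) {
    k <- cl[i]
    near <- min(abs(sc[i] - bounds))
    sp <- if (k == 1) spacing[1] else if (k == 3) spacing[2] else min(spacing)
    near / sp
  }, numeric(1))
  karyo <- labels[cl]
  karyo[margin < unassigned_margin] <- "unassigned"

  out <- data.frame(individual = individuals(gm), karyotype = karyo,
                    quality = margin, stringsAsFactors = FALSE)
  class(out) <- c("karyotype_calls", "data.frame")
  attr(out, "driver_loci") <- driver_loci
  attr(out, "mode") <- mode
  attr(out, "convention") <- convention
  attr(out, "centers") <- setNames(centers, labels)
  out
}

#' Per-karyotype allele frequency table
#'
#' For each locus and karyotype class, the frequency of the A allele (the
#' allele more frequent in the AA class), computed overall and within each
#' group. Loci whose frequencies match the (1, 0.5, 0) diagnostic signature
#' within `tol` are flagged.
#'
#' @param gm a [genotype_matrix()].
#' @param calls a `karyotype_calls` data.frame.
#' @param loci_sel loci to tabulate (default: the calls' driver loci).
#' @param metadata optional [sample_metadata()] for per-group columns.
#' @param tol tolerance for the diagnostic flag.
#' @return data.frame with columns `locus`, `scope` (group name or
#'   `"Total"`), `f_AA`, `f_AB`, `f_BB`, `diagnostic`.
#' @export
karyotype_frequency_table <- function(gm, calls,
                                      loci_sel = attr(calls, "driver_loci"),
                                      metadata = NULL, tol = 0.02) {
  stopifnot(all(loci_sel %in% loci(gm)))
  k <- calls$karyotype[match(individuals(gm), calls$individual)]
  groups <- if (!is.null(metadata)) align_metadata(gm, metadata)$group
  scopes <- c(if (!is.null(groups)) unique(groups), "Total")
  rows <- list()
  for (loc in loci_sel) {
    dos_b <- gm$dosage[, loc]
    # the A allele at this locus: allele with higher frequency among AA calls
    aa_idx <- which(k == "AA" & !is.na(dos_b))
    fB_in_AA <- if (length(aa_idx)) mean(dos_b[aa_idx]) / 2 else 0.5
    a_dose <- if (fB_in_AA <= 0.5) 2 - dos_b else dos_b
    for (sc in scopes) {
      idx <- if (sc == "Total") seq_along(a_dose) else which(groups == sc)
      f <- vapply(c("AA", "AB", "BB"), function(kk) {
        i <- idx[k[idx] == kk & !is.na(a_dose[idx])]
        if (!length(i)) NA_real_ else mean(a_dose[i]) / 2
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, scope = sc, f_AA = f[1], f_AB = f[2], f_BB = f[3],
        diagnostic = !anyNA(f) && abs(f[1] - 1) <= tol &&
          abs(f[2] - 0.5) <= tol && abs(f[3]) <= tol,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Haplogroup (karyotype) frequencies per sample
#'
#' @param calls a `karyotype_calls` data.frame.
#' @param metadata a [sample_metadata()].
#' @return data.frame per site with `n_assigned`, `f_AA`, `f_AB`, `f_BB`
#'   (proportions over assigned individuals).
#' @export
haplogroup_frequencies_by_sample <- function(calls, metadata) {
  idx <- match(calls$individual, metadata$individual)
  if (anyNA(idx)) stop("metadata missing for some called individuals")
  site <- metadata$site[idx]
  ok <- calls$karyotype != "unassigned"
  rows <- lapply(split(which(ok), site[ok]), function(i) {
    tab <- table(factor(calls$karyotype[i], c("AA", "AB", "BB")))
    data.frame(site = site[i][1], n_assigned = length(i),
               f_AA = unname(tab[1]) / length(i),
               f_AB = unname(tab[2]) / length(i),
               f_BB = unname(tab[3]) / length(i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[match(intersect(unique(metadata$site), out$site), out$site), ]
  rownames(out) <- NULL
  out
}

#' Flag putative migrants from cluster memberships
#'
#' @param memberships numeric matrix (individuals x habitat-level clusters,
#'   column names = group names), e.g. a DAPC posterior or an aligned
#'   admixture Q matrix with clusters mapped to groups.
#' @param metadata a [sample_metadata()] giving each individual's home
#'   group.
#' @param q_threshold membership level above which a non-home assignment is
#'   flagged.
#' @param calls optional `karyotype_calls` to annotate flags.
#' @return data.frame of flagged individuals: home site/group, assigned
#'   cluster, membership and (if given) karyotype.
#' @export
detect_migrants <- function(memberships, metadata, q_threshold = 0.7,
                            calls = NULL) {
  stopifnot(!is.null(rownames(memberships)), !is.null(colnames(memberships)))
  idx <- match(rownames(memberships), metadata$individual)
  if (anyNA(idx)) stop("metadata missing for some individuals")
  home <- metadata$group[idx]
  rows <- list()
  for (i in seq_len(nrow(memberships))) {
    others <- setdiff(colnames(memberships), home[i])
    j <- others[which.max(memberships[i, others])]
    if (length(j) && memberships[i, j] > q_threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        individual = rownames(memberships)[i],
        site = metadata$site[idx[i]], home_group = home[i],
        assigned_cluster = j, membership = memberships[i, j],
        karyotype = if (!is.null(calls))
          calls$karyotype[match(rownames(memberships)[i], calls$individual)]
        else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(individual = character(0), site = character(0),
                      home_group = character(0),
                      assigned_cluster = character(0),
                      membership = numeric(0), karyotype = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Habitat-level membership matrix for migrant screening
#'
#' Produces the membership matrix consumed by [detect_migrants()]. The
#' default `"assignment"` method is the classical leave-one-out genotype
#' likelihood assignment test: each group's allele frequencies are
#' estimated with the focal individual excluded (for its home group) and
#' the posterior membership is the normalised multilocus genotype
#' likelihood across groups. `"dapc"` instead returns a DAPC posterior
#' (faster but with overconfident boundaries). An aligned admixture Q
#' matrix with columns renamed to groups can also be fed straight to
#' [detect_migrants()].
#'
#' @param gm a [genotype_matrix()] (typically LD-pruned).
#' @param metadata a [sample_metadata()].
#' @param method `"assignment"` or `"dapc"`.
#' @param n_pcs retained PCs for the DAPC method.
#' @param seed RNG seed (DAPC method only).
#' @return numeric matrix individuals x groups of posterior memberships.
#' @export
habitat_memberships <- function(gm, metadata,
                                method = c("assignment", "dapc"),
                                n_pcs = 40, seed = 1) {
  method <- match.arg(method)
  md <- align_metadata(gm, metadata)
  if (method == "dapc") {
    fit <- dapc_fit(gm, md$group, n_pcs = n_pcs, seed = seed)
    post <- fit$posterior
    rownames(post) <- individuals(gm)
    return(post)
  }
  d <- gm$dosage
  gn <- unique(md$group)
  ll <- matrix(0, nrow(d), length(gn),
               dimnames = list(individuals(gm), gn))
  typed <- !is.na(d)
  for (g in gn) {
    idx <- which(md$group == g)
    cntB <- colSums(d[idx, , drop = FALSE], na.rm = TRUE)
    cntT <- 2 * colSums(typed[idx, , drop = FALSE])
    for (i in seq_len(nrow(d))) {
      x <- d[i, ]
      ok <- typed[i, ]
      if (i %in% idx) {                # leave-one-out for the home group
        b <- cntB - ifelse(ok, x, 0)
        t <- cntT - 2 * ok
      } else {
        b <- cntB; t <- cntT
      }
      p <- (b + 0.5) / (t + 1)         # Jeffreys-smoothed frequencies
      ll[i, g] <- sum(dbinom(x[ok], 2, p[ok], log = TRUE))
    }
  }
  post <- exp(ll - apply(ll, 1, max))
  post / rowSums(post)
}

#' One-dimensional stripe count via a gap statistic
#'
#' Estimates the number of clusters ("stripes") along a score vector, e.g.
#' PC1, by comparing log within-cluster dispersion of k-means against
#' uniform reference data.
#'
#' @param scores numeric vector (e.g. PC1 scores).
#' @param k_max largest cluster count considered.
#' @param B reference datasets.
#' @param seed RNG seed.
#' @return Estimated cluster count: the global gap maximum, accepted only
#'   when it beats the unimodal (k = 1) gap by more than `se_factor`
#'   standard errors — otherwise 1. Diffuse structure without crisp
#'   multimodality (e.g. habitat clouds rather than karyotype stripes)
#'   therefore counts as a single stripe.
#' @param se_factor required significance of the multimodal gap advantage.
#' @export
stripe_count <- function(scores, k_max = 5, B = 50, seed = 1,
                         se_factor = 2) {
  with_seed(derive_seed(seed, "gap"), {
    wk <- function(x, k) {
      if (k == 1) return(sum((x - mean(x))^2))
      km <- kmeans(x, centers = k, nstart = 10)
      km$tot.withinss
    }
    lw <- vapply(1:k_max, function(k) log(wk(scores, k)), numeric(1))
    ref <- vapply(seq_len(B), function(b) {
      x <- runif(length(scores), min(scores), max(scores))
      vapply(1:k_max, function(k) log(wk(x, k)), numeric(1))
    }, numeric(k_max))
    gap <- rowMeans(ref) - lw
    se <- apply(ref, 1, sd) * sqrt(1 + 1 / B)
    k_star <- which.max(gap)
    if (k_star == 1 || gap[k_star] - gap[1] <= se_factor * se[k_star])
      return(1L)
    as.integer(k_star)
  })
}
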