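# Dosage matrix with per-locus mean imputation of missing calls;
# all-missing loci are dropped with a warning.
imputed_dosage <- function(gm) {
  d <- gm$dosage
  allmiss <- colSums(!is.na(d)) == 0
  if (any(allmiss)) {
    warning("dropping ", sum(allmiss), " all-missing loci")
    d <- d[, !allmiss, drop = FALSE]
  }
  for (j in seq_len(ncol(d))) {
    x <- d[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    d[, j] <- x
  }
  storage.mode(d) <- "double"
  d
}

#' PCA of genotype dosages
#'
#' Missing calls are replaced by the locus mean dosage, columns are centred
#' and not variance-scaled, and the covariance matrix is
#' eigendecomposed. Each axis is oriented so its largest-magnitude locus
#' loading is positive, making scores reproducible across runs and input
#' orderings.
#'
#' @param gm a [genotype_matrix()].
#' @return list of class `pca_result` with `scores` (individuals x axes),
#'   `loadings` (loci x axes) and `explained` (variance fractions).
#' @export
pca_genotypes <- function(gm) {
  x <- imputed_dosage(gm)
  if (nrow(x) < 2) stop("need at least two individuals")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  sc <- pc$x
  for (a in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, a])), a] < 0) {
      rot[, a] <- -rot[, a]
      sc[, a] <- -sc[, a]
    }
  }
  ev <- pc$sdev^2
  structure(list(scores = sc, loadings = rot, explained = ev / sum(ev)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "individuals,", ncol(x$scores), "axes;",
      "PC1-3 explain", paste(sprintf("%.1f%%",
                                     100 * x$explained[1:min(3, length(x$explained))]),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Driver loci from PCA loadings
#'
#' Ranks loci by squared loading on an axis and cuts the ranking where a
#' linked block dominating the axis separates from the genomic background.
#' The default `"gap"` method places the cut at the largest ratio between
#' consecutive sorted squared loadings (within the top `max_frac` of loci),
#' and returns an empty set when no ratio reaches `min_ratio` — squared
#' loadings of unstructured panels decay smoothly, so a sharp break is the
#' signature of a tightly linked block such as a non-recombining inversion.
#' The `"sd"` method instead selects loci whose squared loading exceeds
#' `mean + n_sd * SD` of all squared loadings.
#'
#' @param pca a `pca_result`.
#' @param axis axis number.
#' @param method `"gap"` (changepoint on the sorted squared loadings) or
#'   `"sd"` (mean + `n_sd` SD threshold).
#' @param max_frac largest fraction of loci considered for the cut
#'   (`"gap"`).
#' @param min_ratio smallest consecutive-loading ratio accepted as a break
#'   (`"gap"`).
#' @param n_sd threshold in standard deviations (`"sd"`).
#' @return data.frame of selected loci, ranked by squared loading, with a
#'   `loading` column; zero rows (with a warning) if none pass.
#' @export
driver_loci_from_loadings <- function(pca, axis = 1,
                                      method = c("gap", "sd"),
                                      max_frac = 0.25, min_ratio = 1.5,
                                      n_sd = 3) {
  method <- match.arg(method)
  l2 <- pca$loadings[, axis]^2
  if (method == "gap") {
    s <- sort(l2, decreasing = TRUE)
    kmax <- max(2, floor(length(l2) * max_frac))
    ratios <- s[seq_len(kmax - 1)] / s[2:kmax]
    cut <- which.max(ratios)
    sel <- if (ratios[cut] < min_ratio) integer(0) else
      match(names(s)[seq_len(cut)], names(l2))
  } else {
    thr <- mean(l2) + n_sd * sd(l2)
    sel <- which(l2 > thr)
  }
  if (!length(sel)) warning("no locus exceeds the loading threshold")
  sel <- sel[order(l2[sel], decreasing = TRUE)]
  data.frame(locus = names(l2)[sel], loading = pca$loadings[sel, axis],
             squared_loading = l2[sel], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Reduces the centred (mean-imputed, unscaled) dosage matrix by PCA and
#' fits a canonical discriminant analysis on the group labels. With
#' `n_pcs = "auto"` a stratified cross-validation (90% train / 10% test)
#' over a grid of retained-PC counts picks the count with the highest mean
#' assignment success, ties resolved toward fewer PCs.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping per-individual group labels.
#' @param n_pcs number of PCs to retain, or `"auto"`.
#' @param n_da number of discriminant functions (default `groups - 1`).
#' @param xval_reps cross-validation replicates per grid point.
#' @param seed RNG seed.
#' @return list of class `dapc_result` with `ind.coord`, `posterior`,
#'   `assign`, `centroids`, `n_pcs`, `n_da`, `xval` table and the training
#'   `success` rate.
#' @export
dapc_fit <- function(gm, grouping, n_pcs = "auto", n_da = NULL,
                     xval_reps = 30, seed = 1) {
  grouping <- factor(as.character(grouping))
  if (nlevels(grouping) < 2) stop("need at least two groups")
  x <- imputed_dosage(gm)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  maxpc <- min(nrow(x) - nlevels(grouping), ncol(pc$x))
  xval <- NULL
  if (identical(n_pcs, "auto")) {
    grid <- unique(pmin(maxpc, c(5, 10, 20, 30, 40, 60, 80)))
    grid <- grid[grid >= 1]
    xval <- with_seed(derive_seed(seed, "dapc_xval"), {
      succ <- vapply(grid, function(np) {
        mean(vapply(seq_len(xval_reps), function(r) {
          test <- unlist(lapply(split(seq_along(grouping), grouping),
                                function(i) sample(i, max(1, round(0.1 * length(i))))))
          train <- setdiff(seq_along(grouping), test)
          if (length(unique(grouping[train])) < nlevels(grouping)) return(NA)
          fit <- tryCatch(suppressWarnings(
            MASS::lda(pc$x[train, seq_len(np), drop = FALSE],
                      grouping = grouping[train])),
            error = function(e) NULL)
          if (is.null(fit)) return(NA)
          pred <- stats::predict(fit, pc$x[test, seq_len(np), drop = FALSE])
          mean(pred$class == grouping[test])
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      data.frame(n_pcs = grid, success = succ)
    })
    n_pcs <- xval$n_pcs[which.max(xval$success)]
  }
  if (n_pcs > maxpc) {
    warning("n_pcs capped at ", maxpc)
    n_pcs <- maxpc
  }
  n_da <- min(n_da %||% (nlevels(grouping) - 1), nlevels(grouping) - 1)
  fit <- suppressWarnings(MASS::lda(pc$x[, seq_len(n_pcs), drop = FALSE],
                                    grouping = grouping))
  pred <- stats::predict(fit)
  coord <- pred$x[, seq_len(min(n_da, ncol(pred$x))), drop = FALSE]
  centroids <- apply(coord, 2, tapply, grouping, mean)
  structure(list(ind.coord = coord, posterior = pred$posterior,
                 assign = pred$class, grouping = grouping,
                 centroids = centroids, n_pcs = n_pcs, n_da = n_da,
                 xval = xval, success = mean(pred$class == grouping)),
            class = "dapc_result")
}
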