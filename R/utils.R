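#' @useDynLib karyopop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd median quantile setNames p.adjust kruskal.test
#'   fisher.test rbinom rbeta runif rnorm rmultinom prcomp kmeans hclust
#'   as.dist cutree dbinom complete.cases aggregate
#' @importFrom utils read.table write.table combn head
NULL

# Derive a reproducible 31-bit sub-seed from a global seed and a stage tag, so
# each pipeline stage owns an independent RNG stream and adding draws to one
# stage never perturbs another.
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1009
  as.integer((as.numeric(seed) * 1013 + h * 7919 + 17) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Cheap polynomial hash of an R object's deparsed form, for provenance
# records (not cryptographic).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483629
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
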