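#' Marker quality control
#'
#' Removes markers with a minor allele frequency at or below `maf_min` or a
#' proportion of missing calls at or above `max_missing` (both computed on
#' the observed calls), then assigns any surviving missing genotype to the
#' heterozygote (code 1).
#'
#' @param geno line x marker matrix of codes in \{0, 1, 2, NA\}, lines named
#'   in rownames.
#' @param maf_min minimum minor allele frequency (markers must exceed it).
#' @param max_missing maximum missing proportion (markers must be below it).
#' @return Genotype matrix with failing markers dropped and no missing
#'   values. Attributes `n_removed_maf` and `n_removed_missing` record the
#'   filter counts.
#' @export
qc_markers <- function(geno, maf_min = 0.05, max_missing = 0.20) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("L%04d", seq_len(nrow(geno)))
  if (anyDuplicated(rownames(geno)))
    stop("qc_markers: duplicate line ids", call. = FALSE)
  bad <- !(geno %in% c(0, 1, 2, NA))
  if (any(bad))
    stop("qc_markers: genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  miss_prop <- colMeans(is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_missing <- miss_prop >= max_missing
  fail_maf <- !fail_missing & (is.na(maf) | maf <= maf_min)
  keep <- !(fail_missing | fail_maf)
  if (!any(keep))
    stop(sprintf(paste0("qc_markers: no markers survive QC ",
                        "(%d failed missingness >= %.2f, %d failed MAF <= %.2f)"),
                 sum(fail_missing), max_missing, sum(fail_maf), maf_min),
         call. = FALSE)
  out <- geno[, keep, drop = FALSE]
  out[is.na(out)] <- 1
  storage.mode(out) <- "double"
  attr(out, "n_removed_maf") <- sum(fail_maf)
  attr(out, "n_removed_missing") <- sum(fail_missing)
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = ZZ' / (2 sum_i p_i (1 - p_i)) with Z the genotype codes centered by
#' twice the allele frequency. Frequencies are always computed from the
#' supplied lines.
#'
#' @param geno line x marker matrix of codes in \{0, 1, 2\}, no missing
#'   values (run [qc_markers()] first).
#' @return Symmetric line x line matrix with attribute `mean_diag`, the
#'   average of its diagonal elements.
#' @export
compute_G <- function(geno) {
  geno <- as.matrix(geno)
  if (anyNA(geno))
    stop("compute_G: missing genotypes present; run qc_markers() first",
         call. = FALSE)
  if (nrow(geno) < 2L)
    stop("compute_G: at least two lines required", call. = FALSE)
  p <- colMeans(geno) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("compute_G: all markers monomorphic (zero denominator)",
         call. = FALSE)
  Z <- sweep(geno, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "mean_diag") <- mean(diag(G))
  G
}

## Center and scale feature columns (population-sd convention: denominator
## n). Zero-variance columns are dropped; their count is reported via the
## "n_dropped" attribute of standardize_features().
.standardize_matrix <- function(M) {
  M <- as.matrix(M)
  ctr <- colMeans(M)
  Mc <- sweep(M, 2L, ctr)
  sc <- sqrt(colMeans(Mc^2))
  kept <- which(sc > 0)
  if (length(kept) == 0L)
    stop("standardize_features: every feature has zero variance",
         call. = FALSE)
  Ms <- sweep(Mc[, kept, drop = FALSE], 2L, sc[kept], "/")
  list(M = Ms, center = ctr[kept], scale = sc[kept], kept = kept,
       n_dropped = ncol(M) - length(kept))
}

#' Standardize metabolomic feature intensities
#'
#' Centers and scales each feature column to mean 0 and standard deviation 1
#' under the population convention (denominator n), which makes the average
#' diagonal of Q = MM'/q exactly 1. Zero-variance features are dropped and
#' counted. Any study-specific "adjustment" preprocessing can be supplied as
#' a function applied before centering and scaling.
#'
#' @param raw plot x feature matrix of raw intensities, plots named in
#'   rownames.
#' @param adjust optional function `raw -> matrix` applied first.
#' @param denominator `"n"` (population sd, default) or `"n-1"` (sample sd).
#' @return Standardized matrix with attributes `n_dropped`, `center`,
#'   `scale` and `standardized = TRUE`.
#' @export
standardize_features <- function(raw, adjust = NULL,
                                 denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L)
    stop("standardize_features: at least two plots required", call. = FALSE)
  if (!is.null(adjust)) raw <- as.matrix(adjust(raw))
  std <- .standardize_matrix(raw)
  M <- std$M
  if (denominator == "n-1") {
    n <- nrow(M)
    M <- M * sqrt((n - 1) / n) # rescale so the sample (n-1) sd is 1
  }
  attr(M, "n_dropped") <- std$n_dropped
  attr(M, "center") <- std$center
  attr(M, "scale") <- std$scale
  attr(M, "standardized") <- TRUE
  M
}

#' Metabolomic similarity matrix
#'
#' Q = MM'/q over the standardized feature matrix, with q the number of
#' retained features. Under the population-sd standardization the average
#' diagonal of Q is exactly 1.
#'
#' @param M standardized plot x feature matrix (see
#'   [standardize_features()]).
#' @return Symmetric plot x plot matrix with attribute `mean_diag`.
#' @export
compute_Q <- function(M) {
  M <- as.matrix(M)
  q <- ncol(M)
  if (q == 0L)
    stop("compute_Q: feature matrix has zero columns", call. = FALSE)
  Q <- tcrossprod(M) / q
  Q <- (Q + t(Q)) / 2
  dimnames(Q) <- list(rownames(M), rownames(M))
  attr(Q, "mean_diag") <- mean(diag(Q))
  Q
}
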