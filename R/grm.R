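#' Genomic relationship matrix (VanRaden method 1, fixed base frequency)
#'
#' Computes `G = Z Z' / (2 m p0 (1 - p0))` where `Z = dosage - 2 p0` and
#' `p0` is a fixed base allele frequency applied to every SNP (default 0.5).
#' With `p0 = 0.5` the denominator is `m / 2`, every diagonal element lies
#' in `[0, 2]`, and the genomic inbreeding coefficient `G_ii - 1` equals
#' `1 - 2 * het_i` exactly.
#'
#' @param panel A `genotype_panel` with no missing dosages (QC'd, imputed or
#'   synthetic).
#' @param base_freq Fixed base allele frequency `p0` in `(0, 1)`.
#' @return An object of class `subpop_grm`: list with `matrix` (samples x
#'   samples), `base_freq`, `m` (number of SNPs), `samples`, `subpop`.
#' @export
compute_grm <- function(panel, base_freq = 0.5) {
  stopifnot(base_freq > 0, base_freq < 1)
  if (n_snps(panel) == 0L) stop("panel has no SNPs", call. = FALSE)
  if (anyNA(panel$dosage)) {
    stop("GRM requires complete dosages; run QC/imputation first",
         call. = FALSE)
  }
  z <- panel$dosage - 2 * base_freq
  g <- tcrossprod(z) / (2 * n_snps(panel) * base_freq * (1 - base_freq))
  dimnames(g) <- list(panel$samples, panel$samples)
  structure(list(matrix = g, base_freq = base_freq, m = n_snps(panel),
                 samples = panel$samples, subpop = panel$subpop),
            class = "subpop_grm")
}

#' @export
print.subpop_grm <- function(x, ...) {
  cat("<subpop_grm> ", length(x$samples), " samples, m = ", x$m,
      " SNPs, base_freq = ", x$base_freq, "\n", sep = "")
  cat("  diagonal range: ",
      paste(signif(range(diag(x$matrix)), 4), collapse = " to "), "\n",
      sep = "")
  invisible(x)
}

#' Genomic inbreeding from the GRM diagonal
#'
#' `F_GRM = G_ii - 1`. With the default base frequency of 0.5 this is
#' algebraically identical to `1 - 2 * observed heterozygosity`.
#'
#' @param grm A `subpop_grm`.
#' @return A tibble with `sample`, `subpop`, `f_grm`.
#' @export
f_grm <- function(grm) {
  stopifnot(inherits(grm, "subpop_grm"))
  tibble::tibble(sample = grm$samples, subpop = grm$subpop,
                 f_grm = unname(diag(grm$matrix)) - 1)
}

#' Principal component analysis of a GRM
#'
#' Full eigendecomposition of the (symmetric) relationship matrix. Sample
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalue; variance proportions are eigenvalues divided by the total,
#' with small negative eigenvalues floored at zero.
#'
#' @param grm A `subpop_grm`.
#' @param n_components Number of components to keep in the coordinates
#'   (default: all).
#' @return An object of class `subpop_pca`: list with `eigenvalues`
#'   (descending), `variance_proportions`, `coordinates` (tibble: `sample`,
#'   `subpop`, `PC1`, ...).
#' @export
pca_grm <- function(grm, n_components = NULL) {
  stopifnot(inherits(grm, "subpop_grm"))
  if (any(!is.finite(grm$matrix))) {
    stop("GRM contains non-finite entries", call. = FALSE)
  }
  eg <- eigen(grm$matrix, symmetric = TRUE)
  lam <- eg$values
  prop <- pmax(lam, 0)
  prop <- prop / sum(prop)
  k <- if (is.null(n_components)) length(lam) else
    min(n_components, length(lam))
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(lam[seq_len(k)], 0)), k, k)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(eigenvalues = lam, variance_proportions = prop,
         coordinates = dplyr::bind_cols(
           tibble::tibble(sample = grm$samples, subpop = grm$subpop),
           tibble::as_tibble(coords))),
    class = "subpop_pca"
  )
}

#' @export
print.subpop_pca <- function(x, ...) {
  cat("<subpop_pca> ", length(x$eigenvalues), " components; PC1 ",
      sprintf("%.2f%%", 100 * x$variance_proportions[1]), ", PC2 ",
      if (length(x$variance_proportions) > 1)
        sprintf("%.2f%%", 100 * x$variance_proportions[2]) else "-",
      " of variance\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GRM into a long pairwise tibble
#'
#' @param x A `subpop_grm`.
#' @param ... Unused.
#' @return Tibble with one row per unordered sample pair (diagonal
#'   included): `sample_1`, `sample_2`, `subpop_1`, `subpop_2`,
#'   `relationship`.
#' @method tidy subpop_grm
#' @export
tidy.subpop_grm <- function(x, ...) {
  n <- length(x$samples)
  idx <- which(upper.tri(x$matrix, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(sample_1 = x$samples[idx[, 1]],
                 sample_2 = x$samples[idx[, 2]],
                 subpop_1 = x$subpop[idx[, 1]],
                 subpop_2 = x$subpop[idx[, 2]],
                 relationship = x$matrix[idx])
}

#' One-row GRM summary: mean relationships within and between groups
#'
#' @param x A `subpop_grm`.
#' @param ... Unused.
#' @return Tibble with `m`, `base_freq`, mean/sd of off-diagonal
#'   relationships overall, within each subpopulation, and across them, and
#'   mean F_GRM.
#' @method glance subpop_grm
#' @export
glance.subpop_grm <- function(x, ...) {
  pairs <- tidy(x)
  off <- pairs[pairs$sample_1 != pairs$sample_2, ]
  within <- off$subpop_1 == off$subpop_2
  labs <- unique(x$subpop)
  out <- tibble::tibble(
    m = x$m, base_freq = x$base_freq,
    rel_mean = mean(off$relationship), rel_sd = stats::sd(off$relationship),
    rel_between_mean = mean(off$relationship[!within]),
    f_grm_mean = mean(diag(x$matrix) - 1)
  )
  for (l in labs) {
    sel <- within & off$subpop_1 == l
    out[[paste0("rel_", l, "_mean")]] <- mean(off$relationship[sel])
  }
  out
}

#' Tidy PCA coordinates
#'
#' @param x A `subpop_pca`.
#' @param ... Unused.
#' @return The coordinates tibble (`sample`, `subpop`, `PC1`, ...).
#' @method tidy subpop_pca
#' @export
tidy.subpop_pca <- function(x, ...) x$coordinates

#' One-row-per-component PCA summary
#'
#' @param x A `subpop_pca`.
#' @param ... Unused.
#' @return Tibble with `component`, `eigenvalue`, `variance_proportion`,
#'   `cumulative_proportion`.
#' @method glance subpop_pca
#' @export
glance.subpop_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_proportion = x$variance_proportions,
                 cumulative_proportion = cumsum(x$variance_proportions))
}
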