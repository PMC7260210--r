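#' Regional LD contrast between two subpopulations (varLD)
#'
#' The varLD statistic compares the local LD structure of two populations
#' over sliding windows holding a fixed number of SNPs: within each window a
#' symmetric `r^2` matrix is built per population, the eigenvalues of the
#' homologous matrices are ranked, and the raw score is the sum of absolute
#' differences between ranked eigenvalues. Raw scores are standardized
#' genome-wide and regions with consecutive extreme windows flag divergent
#' LD — a signal of population-specific selection.
#'
#' @name varld
NULL

#' Windowed r-squared matrix for one subpopulation
#'
#' Entry `(a, b)` is the squared haplotype correlation between window SNPs
#' `a` and `b`; the diagonal is 1. Pairs involving a SNP monomorphic within
#' the subpopulation carry no information and their off-diagonal entries are
#' set to 0, keeping the two populations' matrices homologous (same
#' dimension, same SNPs).
#'
#' @param panel A `genotype_panel` with haplotypes.
#' @param snps Integer vector of SNP indices (one chromosome).
#' @param pop Subpopulation label.
#' @return A symmetric `length(snps)` square matrix with unit diagonal.
#' @export
window_ld_matrix <- function(panel, snps, pop) {
  if (length(unique(panel$map$chrom[snps])) != 1L) {
    stop("window SNPs must lie on one chromosome", call. = FALSE)
  }
  hap <- pop_haplotypes(panel, pop)
  cm <- chrom_r_matrix(hap, snps)^2
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  cm
}

#' Raw varLD score of two homologous LD matrices
#'
#' Eigenvalues of each symmetric matrix are sorted descending and the score
#' is `sum(|lambda_A,k - lambda_B,k|)`. Because both matrices carry a unit
#' diagonal their eigenvalues each sum to the window size, so the score is
#' a pure shape contrast.
#'
#' @param mat_a,mat_b Symmetric matrices of equal dimension.
#' @return Non-negative numeric score.
#' @export
raw_varld <- function(mat_a, mat_b) {
  if (!isSymmetric(unname(mat_a)) || !isSymmetric(unname(mat_b))) {
    stop("varLD requires symmetric matrices", call. = FALSE)
  }
  if (!all(dim(mat_a) == dim(mat_b))) {
    stop("matrices must have the same dimension", call. = FALSE)
  }
  la <- eigen(mat_a, symmetric = TRUE, only.values = TRUE)$values
  lb <- eigen(mat_b, symmetric = TRUE, only.values = TRUE)$values
  sum(abs(sort(la, decreasing = TRUE) - sort(lb, decreasing = TRUE)))
}

#' Genome-wide varLD scan with region calling
#'
#' Slides windows of `window_snps` SNPs in one-SNP steps along each
#' chromosome (windows never span chromosomes; a chromosome with fewer SNPs
#' than the window is skipped with a warning), computes the raw varLD score
#' per window, standardizes scores genome-wide to mean 0 / sd 1 (a monotone
#' transform that leaves percentile calls unchanged), and calls regions of
#' at least `min_consecutive` consecutive windows with standardized score
#' strictly above the genome-wide `percentile`. Regions span the first SNP
#' of their first window to the last SNP of their last window.
#'
#' @param panel A two-subpopulation `genotype_panel` with haplotypes.
#' @param window_snps SNPs per window (default 15).
#' @param percentile Percentile (0-100) for the empirical threshold.
#' @param min_consecutive Minimum run of extreme windows.
#' @return A list with `track` (tibble: `chrom`, `start_bp`, `end_bp`,
#'   `first_snp_index`, `n_snps`, `raw_score`, `std_score`) and `regions`
#'   (region tibble with `source = "VARLD"`).
#' @export
varld_scan <- function(panel, window_snps = 15L, percentile = 99.9,
                       min_consecutive = 2L) {
  labs <- assert_two_pops(panel)
  hap_a <- pop_haplotypes(panel, labs[1])
  hap_b <- pop_haplotypes(panel, labs[2])
  rows <- list()
  for (ch in unique(panel$map$chrom)) {
    cols <- which(panel$map$chrom == ch)
    n <- length(cols)
    if (n < window_snps) {
      warning("chromosome ", ch, " has ", n, " SNPs < window of ",
              window_snps, "; skipped", call. = FALSE)
      next
    }
    ra <- chrom_r_matrix(hap_a, cols)^2
    rb <- chrom_r_matrix(hap_b, cols)^2
    ra[is.na(ra)] <- 0; rb[is.na(rb)] <- 0
    diag(ra) <- 1; diag(rb) <- 1
    nw <- n - window_snps + 1L
    score <- numeric(nw)
    for (wst in seq_len(nw)) {
      sel <- wst:(wst + window_snps - 1L)
      score[wst] <- raw_varld(ra[sel, sel], rb[sel, sel])
    }
    rows[[ch]] <- tibble::tibble(
      chrom = ch,
      start_bp = panel$map$pos_bp[cols[seq_len(nw)]],
      end_bp = panel$map$pos_bp[cols[window_snps:n]],
      first_snp_index = cols[seq_len(nw)],
      n_snps = window_snps,
      raw_score = score)
  }
  if (!length(rows)) stop("no chromosome long enough to scan", call. = FALSE)
  track <- dplyr::bind_rows(rows)
  mu <- mean(track$raw_score)
  sg <- stats::sd(track$raw_score)
  track$std_score <- if (is.na(sg) || sg == 0) 0 * track$raw_score else
    (track$raw_score - mu) / sg
  thr <- score_percentile(track$std_score, percentile)
  regions <- call_flagged_regions(track, track$std_score > thr,
                                  min_consecutive, "VARLD")
  list(track = track, regions = regions)
}
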