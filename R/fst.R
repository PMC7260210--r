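#' Weir & Cockerham F_ST for two subpopulations
#'
#' Per-SNP variance components of the Weir & Cockerham (1984) estimator for
#' two populations: `a` (among populations), `b` (among individuals within
#' populations), `c` (within individuals), with `theta = a / (a + b + c)`.
#' Windowed values combine SNPs as the low-bias ratio of averages
#' `sum(a) / sum(a + b + c)`. Outlier windows are called against empirical
#' thresholds computed within heterozygosity bins, controlling the
#' dependence of F_ST's null range on allele frequency.
#'
#' @name fst
NULL

#' Per-SNP Weir-Cockerham components
#'
#' @param panel A two-subpopulation `genotype_panel`.
#' @return A tibble with one row per SNP: `snp_id`, `chrom`, `pos_bp`,
#'   sample sizes `n1`/`n2`, alt frequencies `p1`/`p2`, observed
#'   heterozygosities `h1`/`h2`, components `a`, `b`, `c_w`, `theta`, and
#'   `defined` (FALSE for SNPs monomorphic in the pooled sample or with
#'   fewer than two genotyped samples in either subpopulation, whose
#'   `theta` is `NA`).
#' @export
wc_fst_components <- function(panel) {
  labs <- assert_two_pops(panel)
  d1 <- panel$dosage[panel$subpop == labs[1], , drop = FALSE]
  d2 <- panel$dosage[panel$subpop == labs[2], , drop = FALSE]
  n1 <- colSums(!is.na(d1))
  n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  h1 <- colMeans(d1 == 1L, na.rm = TRUE)
  h2 <- colMeans(d2 == 1L, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_w <- hbar / 2
  defined <- n1 >= 2 & n2 >= 2 & !is.na(pbar) & pbar > 0 & pbar < 1
  theta <- ifelse(defined, a / (a + b + c_w), NA_real_)
  tibble::tibble(snp_id = panel$map$snp_id, chrom = panel$map$chrom,
                 pos_bp = panel$map$pos_bp,
                 n1 = unname(n1), n2 = unname(n2), p1 = unname(p1),
                 p2 = unname(p2), h1 = unname(h1), h2 = unname(h2),
                 a = unname(a), b = unname(b), c_w = unname(c_w),
                 pbar = unname(pbar), theta = unname(theta),
                 defined = unname(defined))
}

#' Mean and sd of per-SNP F_ST
#'
#' @param panel A two-subpopulation `genotype_panel`.
#' @return A tibble with `n_snps` (defined SNPs), `fst_mean`, `fst_sd` (0
#'   when only one SNP is defined).
#' @export
global_fst <- function(panel) {
  comp <- wc_fst_components(panel)
  th <- comp$theta[comp$defined]
  tibble::tibble(n_snps = length(th),
                 fst_mean = mean(th),
                 fst_sd = if (length(th) > 1) stats::sd(th) else 0)
}

#' Sliding-window F_ST and heterozygosity track
#'
#' Windows of `window_snps` SNPs advancing one SNP at a time within each
#' chromosome. Window `theta` is the ratio of averages
#' `sum(a) / sum(a + b + c)` over the window's defined SNPs; window
#' heterozygosity is the mean expected total heterozygosity
#' `2 pbar (1 - pbar)`. Windows whose SNPs are all undefined are dropped
#' with a message.
#'
#' @param panel A two-subpopulation `genotype_panel`.
#' @param window_snps SNPs per window (default 15, matching the varLD scan).
#' @param components Optional precomputed [wc_fst_components()] tibble.
#' @return A tibble: `chrom`, `start_bp`, `end_bp`, `first_snp_index`,
#'   `n_snps`, `theta`, `het`.
#' @export
fst_window_track <- function(panel, window_snps = 15L, components = NULL) {
  comp <- if (is.null(components)) wc_fst_components(panel) else components
  rows <- list()
  for (ch in unique(comp$chrom)) {
    on_ch <- which(comp$chrom == ch)
    n <- length(on_ch)
    if (n < window_snps) next
    a <- comp$a[on_ch]
    tot <- comp$a[on_ch] + comp$b[on_ch] + comp$c_w[on_ch]
    het <- 2 * comp$pbar[on_ch] * (1 - comp$pbar[on_ch])
    def <- comp$defined[on_ch]
    a[!def] <- 0; tot[!def] <- 0; het[!def] <- 0
    nw <- n - window_snps + 1L
    sum_a <- rolling_sum(a, window_snps)
    sum_tot <- rolling_sum(tot, window_snps)
    sum_het <- rolling_sum(het, window_snps)
    n_def <- rolling_sum(as.numeric(def), window_snps)
    keep <- n_def > 0
    if (any(!keep)) {
      message(sum(!keep), " window(s) on chromosome ", ch,
              " dropped: all SNPs undefined")
    }
    rows[[ch]] <- tibble::tibble(
      chrom = ch,
      start_bp = comp$pos_bp[on_ch[seq_len(nw)]],
      end_bp = comp$pos_bp[on_ch[window_snps:n]],
      first_snp_index = on_ch[seq_len(nw)],
      n_snps = window_snps,
      theta = sum_a / sum_tot,
      het = sum_het / n_def)[keep, ]
  }
  dplyr::bind_rows(rows)
}

#' Call F_ST outlier regions with heterozygosity-binned thresholds
#'
#' Windows are assigned to `n_bins` equal-count (quantile) heterozygosity
#' bins; bins holding fewer than `min_bin_size` windows are merged with
#' their neighbor (with a message). The per-bin threshold is the
#' `percentile` of window `theta` inside the bin; by default thresholds are
#' then smoothed across adjacent bins with a centered 3-bin moving average,
#' so a bin dominated by one strong signal is judged against the tail of
#' comparable-heterozygosity windows rather than against the signal itself
#' (`smooth = FALSE` keeps the raw per-bin thresholds). A window is flagged
#' when its `theta` strictly exceeds its bin's threshold, and regions are
#' maximal runs of at least `min_consecutive` consecutive flagged windows
#' on one chromosome, spanning first to last window SNP.
#'
#' @param windows Window tibble from [fst_window_track()].
#' @param n_bins Number of heterozygosity bins (default 20).
#' @param percentile Percentile (0-100) for the per-bin threshold.
#' @param min_consecutive Minimum run of flagged windows.
#' @param min_bin_size Bins smaller than this are merged with a neighbor.
#' @param smooth Smooth per-bin thresholds across neighboring bins.
#' @return A list with `windows` (the input plus `het_bin`, `threshold`,
#'   `flagged`) and `regions` (region tibble with `source = "FST"`).
#' @export
fst_outlier_regions <- function(windows, n_bins = 20L, percentile = 99.9,
                                min_consecutive = 2L, min_bin_size = 50L,
                                smooth = TRUE) {
  stopifnot(nrow(windows) > 0)
  n_bins <- max(1L, min(n_bins, nrow(windows)))
  bin <- dplyr::ntile(windows$het, n_bins)
  # merge small bins into their left neighbor (leftmost merges right)
  repeat {
    sizes <- table(factor(bin, levels = sort(unique(bin))))
    small <- names(sizes)[sizes < min_bin_size]
    if (!length(small) || length(sizes) == 1L) break
    b <- as.integer(small[1L])
    lv <- sort(unique(bin))
    target <- if (b == lv[1L]) lv[which(lv == b) + 1L] else
      lv[which(lv == b) - 1L]
    message("heterozygosity bin ", b, " (", sizes[small[1L]],
            " windows) merged with bin ", target)
    bin[bin == b] <- target
  }
  lv <- sort(unique(bin))
  thr_by_bin <- vapply(lv, function(b) {
    score_percentile(windows$theta[bin == b], percentile)
  }, numeric(1))
  if (smooth && length(lv) > 1L) {
    sm <- thr_by_bin
    for (k in seq_along(lv)) {
      lo <- max(1L, k - 1L); hi <- min(length(lv), k + 1L)
      sm[k] <- mean(thr_by_bin[lo:hi])
    }
    thr_by_bin <- sm
  }
  thr <- thr_by_bin[match(bin, lv)]
  out <- windows
  out$het_bin <- match(bin, lv)
  out$threshold <- thr
  out$flagged <- out$theta > thr
  ord <- order(match(out$chrom, unique(out$chrom)), out$first_snp_index)
  out <- out[ord, ]
  regions <- call_flagged_regions(out, out$flagged, min_consecutive, "FST")
  list(windows = out, regions = regions)
}
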