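#' Linkage disequilibrium from phased haplotypes
#'
#' All LD statistics here are computed on haplotype columns: the signed
#' correlation `r = D / sqrt(p_i (1 - p_i) p_j (1 - p_j))` with
#' `D = P(11) - p_i p_j`, which equals the Pearson correlation of the two
#' binary alternate-allele indicator columns. Pairs involving a SNP that is
#' monomorphic within the analyzed group are undefined and excluded (never
#' set to zero). The shared map coding guarantees the sign of `r` is
#' comparable across subpopulations.
#'
#' @name ld
NULL

# haplotype submatrix of one subpopulation (or all samples)
pop_haplotypes <- function(panel, pop = NULL) {
  if (!has_haplotypes(panel)) {
    stop("panel carries no phased haplotypes", call. = FALSE)
  }
  idx <- if (is.null(pop)) seq_len(n_samples(panel)) else
    which(panel$subpop == pop)
  if (!length(idx)) stop("no samples in subpopulation ", pop, call. = FALSE)
  panel$haplotypes[hap_rows(idx), , drop = FALSE]
}

# per-chromosome signed-r matrix (NA where undefined)
chrom_r_matrix <- function(hap, cols) {
  h <- hap[, cols, drop = FALSE]
  suppressWarnings(stats::cor(h))
}

#' Signed r and r-squared for one SNP pair
#'
#' @param panel A `genotype_panel` with haplotypes.
#' @param i,j SNP indices (rows of the map), on the same chromosome.
#' @param pop Optional subpopulation label; default uses all haplotypes.
#' @return A one-row tibble: `i`, `j`, `chrom`, `distance_bp`, `r_signed`,
#'   `r2` (`NA` when either SNP is monomorphic in the group).
#' @export
pair_r <- function(panel, i, j, pop = NULL) {
  if (panel$map$chrom[i] != panel$map$chrom[j]) {
    stop("SNPs ", i, " and ", j, " are on different chromosomes",
         call. = FALSE)
  }
  hap <- pop_haplotypes(panel, pop)
  r <- suppressWarnings(stats::cor(hap[, i], hap[, j]))
  tibble::tibble(i = i, j = j, chrom = panel$map$chrom[i],
                 distance_bp = abs(panel$map$pos_bp[j] - panel$map$pos_bp[i]),
                 r_signed = r, r2 = r^2)
}

# all syntenic pairs within max_dist as a tibble of (distance, r) for one
# subpopulation, using per-chromosome correlation matrices
syntenic_pairs <- function(panel, pop, max_dist) {
  hap <- pop_haplotypes(panel, pop)
  out <- list()
  for (ch in unique(panel$map$chrom)) {
    cols <- which(panel$map$chrom == ch)
    pos <- panel$map$pos_bp[cols]
    cm <- chrom_r_matrix(hap, cols)
    n <- length(cols)
    pr <- which(upper.tri(cm), arr.ind = TRUE)
    d <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- d <= max_dist
    out[[ch]] <- tibble::tibble(chrom = ch, i = cols[pr[keep, 1]],
                                j = cols[pr[keep, 2]],
                                distance_bp = d[keep],
                                r_signed = cm[pr[keep, , drop = FALSE]])
  }
  dplyr::bind_rows(out)
}

#' LD decay: mean r-squared within physical distance bins
#'
#' Enumerates all syntenic SNP pairs up to the largest bin edge and averages
#' `r^2` within half-open distance bins `[lo, hi)`. Defaults: 10 kb steps
#' from 10 to 100 kb, then 100-200, 200-500 and 500-1000 kb.
#'
#' @param panel A `genotype_panel` with haplotypes.
#' @param breaks_bp Increasing vector of bin edges in bp.
#' @param by_subpop Compute per subpopulation (default) or pooled.
#' @return A tibble: `subpop`, `bin_lo`, `bin_hi`, `n_pairs`, `mean_r2`
#'   (`NA` for empty bins, which are still reported).
#' @export
ld_decay <- function(panel,
                     breaks_bp = c(seq(10e3, 100e3, by = 10e3),
                                   200e3, 500e3, 1000e3),
                     by_subpop = TRUE) {
  pops <- if (by_subpop) unique(panel$subpop) else list(NULL)
  purrr::map_dfr(pops, function(pop) {
    pr <- syntenic_pairs(panel, pop, max_dist = max(breaks_bp))
    pr <- pr[!is.na(pr$r_signed), ]
    bin <- findInterval(pr$distance_bp, breaks_bp)
    r2 <- pr$r_signed^2
    purrr::map_dfr(seq_len(length(breaks_bp) - 1L), function(b) {
      sel <- bin == b
      tibble::tibble(subpop = if (is.null(pop)) "pooled" else pop,
                     bin_lo = breaks_bp[b], bin_hi = breaks_bp[b + 1L],
                     n_pairs = sum(sel),
                     mean_r2 = if (any(sel)) mean(r2[sel]) else NA_real_)
    })
  })
}

#' Adjacent-SNP r-squared summaries under MAF thresholds
#'
#' For each positive MAF threshold, SNPs whose within-subpopulation MAF
#' exceeds the threshold in every subpopulation are retained (a threshold of
#' 0 means no filter); adjacency is consecutive retained SNPs per
#' chromosome. Pairs whose r is undefined within a subpopulation are
#' excluded from that subpopulation's averages and counts. Reports the overall adjacent-pair mean and
#' standard error of `r^2` per subpopulation, plus means within distance
#' classes — disjoint bands `(0, 100]`, `(100, 300]`, `(300, 500]` kb by
#' default, or cumulative `<= X kb` classes with `cumulative = TRUE`.
#'
#' @param panel A `genotype_panel` with haplotypes.
#' @param maf_thresholds Numeric vector of (strict) MAF thresholds.
#' @param class_breaks_kb Upper edges of the distance classes in kb.
#' @param cumulative Use cumulative (`<= edge`) classes instead of disjoint
#'   bands.
#' @return A tibble: `subpop`, `maf_threshold`, `class`, `n_pairs`,
#'   `mean_r2`, `se_r2` (sd over pairs / sqrt(pairs)).
#' @export
adjacent_r2_summary <- function(panel, maf_thresholds = c(0, 0.01, 0.05),
                                class_breaks_kb = c(100, 300, 500),
                                cumulative = FALSE) {
  labs <- unique(panel$subpop)
  freqs <- lapply(labs, function(l) {
    d <- panel$dosage[panel$subpop == l, , drop = FALSE]
    f <- colMeans(d, na.rm = TRUE) / 2
    pmin(f, 1 - f)
  })
  haps <- lapply(labs, function(l) pop_haplotypes(panel, l))
  purrr::map_dfr(maf_thresholds, function(thr) {
    keep <- if (thr <= 0) rep(TRUE, n_snps(panel)) else
      Reduce(`&`, lapply(freqs, function(m) !is.na(m) & m > thr))
    kept <- which(keep)
    if (length(kept) < 2L) return(NULL)
    chrom <- panel$map$chrom[kept]
    pos <- panel$map$pos_bp[kept]
    adj <- which(chrom[-length(chrom)] == chrom[-1L])
    if (!length(adj)) return(NULL)
    d_bp <- pos[adj + 1L] - pos[adj]
    purrr::map_dfr(seq_along(labs), function(pi) {
      h <- haps[[pi]]
      r <- vapply(adj, function(a) {
        suppressWarnings(stats::cor(h[, kept[a]], h[, kept[a + 1L]]))
      }, numeric(1))
      r2 <- r^2
      ok <- !is.na(r2)
      mk_row <- function(class, sel) {
        sel <- sel & ok
        tibble::tibble(subpop = labs[pi], maf_threshold = thr,
                       class = class, n_pairs = sum(sel),
                       mean_r2 = if (any(sel)) mean(r2[sel]) else NA_real_,
                       se_r2 = if (sum(sel) > 1)
                         stats::sd(r2[sel]) / sqrt(sum(sel)) else NA_real_)
      }
      rows <- mk_row("adjacent", rep(TRUE, length(r2)))
      lo <- 0
      for (edge in class_breaks_kb) {
        sel <- if (cumulative) d_bp <= edge * 1e3 else
          d_bp > lo * 1e3 & d_bp <= edge * 1e3
        lab <- if (cumulative) sprintf("<=%gkb", edge) else
          sprintf("(%g,%g]kb", lo, edge)
        rows <- dplyr::bind_rows(rows, mk_row(lab, sel))
        lo <- edge
      }
      rows
    })
  })
}

#' Cross-population persistence of linkage phase
#'
#' For every syntenic SNP pair up to `max_pair_dist`, the signed `r` is
#' computed within each of the two subpopulations; pairs undefined in either
#' are excluded. Pairs are then grouped into physical-distance bins
#' (`bin_width_bp` wide, up to `max_bin_bp`), and within each bin the
#' persistence of phase is the Pearson correlation between the two
#' subpopulations' signed `r` across pairs (the sum-of-products over
#' `s_m s_n` normalization). Bins with fewer than two pairs are reported
#' with `phase_corr = NA`.
#'
#' @param panel A two-subpopulation `genotype_panel` with haplotypes.
#' @param bin_width_bp Bin width (default 100 kb).
#' @param max_bin_bp Upper edge of the last bin (default 5 Mb).
#' @param max_pair_dist Maximum pair distance enumerated (default 10 Mb;
#'   only pairs inside the bin range enter the result).
#' @return A tibble: `bin_lo`, `bin_hi`, `n_pairs`, `r_mean_m`, `r_sd_m`,
#'   `r_mean_n`, `r_sd_n`, `phase_corr`, with subpopulation labels in
#'   attribute `"pops"` (`m` = first label, `n` = second).
#' @export
phase_persistence <- function(panel, bin_width_bp = 100e3, max_bin_bp = 5e6,
                              max_pair_dist = 10e6) {
  labs <- assert_two_pops(panel)
  lim <- min(max_bin_bp, max_pair_dist)
  pm <- syntenic_pairs(panel, labs[1], max_dist = lim)
  pn <- syntenic_pairs(panel, labs[2], max_dist = lim)
  stopifnot(nrow(pm) == nrow(pn))  # same map, same enumeration order
  ok <- !is.na(pm$r_signed) & !is.na(pn$r_signed)
  d <- pm$distance_bp[ok]
  rm_ <- pm$r_signed[ok]
  rn_ <- pn$r_signed[ok]
  edges <- seq(0, max_bin_bp, by = bin_width_bp)
  bin <- findInterval(d, edges, rightmost.closed = FALSE)
  out <- purrr::map_dfr(seq_len(length(edges) - 1L), function(b) {
    sel <- bin == b
    n <- sum(sel)
    tibble::tibble(
      bin_lo = edges[b], bin_hi = edges[b + 1L], n_pairs = n,
      r_mean_m = if (n) mean(rm_[sel]) else NA_real_,
      r_sd_m = if (n > 1) stats::sd(rm_[sel]) else NA_real_,
      r_mean_n = if (n) mean(rn_[sel]) else NA_real_,
      r_sd_n = if (n > 1) stats::sd(rn_[sel]) else NA_real_,
      phase_corr = if (n >= 2) stats::cor(rm_[sel], rn_[sel]) else NA_real_)
  })
  attr(out, "pops") <- stats::setNames(labs, c("m", "n"))
  out
}

#' Minimum marker density for a target adjacent-SNP spacing
#'
#' How many SNPs a genome needs so that adjacent markers sit within the
#' spacing at which their LD still supports prediction (e.g. the spacing up
#' to which mean adjacent r-squared exceeds 0.2).
#'
#' @param genome_length_mb Genome length in Mb.
#' @param max_spacing_kb Largest acceptable adjacent spacing in kb.
#' @return Integer SNP count, `floor(genome_length / spacing)`.
#' @export
required_marker_density <- function(genome_length_mb, max_spacing_kb) {
  stopifnot(genome_length_mb > 0, max_spacing_kb > 0)
  as.integer(floor(genome_length_mb * 1e3 / max_spacing_kb))
}
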