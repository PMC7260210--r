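#' Parameters for runs-of-homozygosity detection
#'
#' Defaults follow the standard PLINK-style criteria for medium-density
#' panels: a 30-SNP scanning window allowing one heterozygote and no missing
#' call, a 5% window hit-rate threshold, a minimum segment length of 1 Mb,
#' a mean density of at least 1 SNP per 120 kb over the segment, and no
#' internal adjacent-SNP gap above 1 Mb.
#'
#' @param window_snps Scanning window size in SNPs (sliding method).
#' @param het_allowed Heterozygous genotypes permitted per window (sliding)
#'   or per run (consecutive method).
#' @param missing_allowed Missing genotypes permitted per window.
#' @param hit_rate_threshold Minimum fraction of spanning windows that must
#'   pass for a SNP to be "in run" (sliding method), in `(0, 1]`.
#' @param min_len_bp Minimum segment length in bp.
#' @param min_density_bp_per_snp Maximum mean bp per SNP over a segment.
#' @param max_gap_bp Maximum adjacent-SNP gap inside a segment.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 30L, het_allowed = 1L,
                       missing_allowed = 0L, hit_rate_threshold = 0.05,
                       min_len_bp = 1e6, min_density_bp_per_snp = 120e3,
                       max_gap_bp = 1e6) {
  stopifnot(window_snps >= 1, het_allowed >= 0, missing_allowed >= 0,
            hit_rate_threshold > 0, hit_rate_threshold <= 1,
            min_len_bp > 0, min_density_bp_per_snp > 0, max_gap_bp > 0)
  structure(list(window_snps = as.integer(window_snps),
                 het_allowed = as.integer(het_allowed),
                 missing_allowed = as.integer(missing_allowed),
                 hit_rate_threshold = hit_rate_threshold,
                 min_len_bp = min_len_bp,
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 max_gap_bp = max_gap_bp),
            class = "roh_params")
}

# split candidate index stretches at long gaps, then apply the final
# length / mean-density screens; returns segment tibble rows
finish_stretches <- function(stretches, pos, params) {
  segs <- list()
  for (k in seq_len(nrow(stretches))) {
    idx <- stretches$start[k]:stretches$end[k]
    if (length(idx) < 2L) next
    gaps <- diff(pos[idx])
    cut_after <- which(gaps > params$max_gap_bp)
    bounds <- c(0L, cut_after, length(idx))
    for (b in seq_len(length(bounds) - 1L)) {
      sub <- idx[(bounds[b] + 1L):bounds[b + 1L]]
      if (length(sub) < 2L) next
      len <- pos[sub[length(sub)]] - pos[sub[1L]] + 1
      if (len < params$min_len_bp) next
      if (len / length(sub) > params$min_density_bp_per_snp) next
      segs[[length(segs) + 1L]] <-
        c(start_bp = pos[sub[1L]], end_bp = pos[sub[length(sub)]],
          n_snps = length(sub))
    }
  }
  segs
}

roh_segment_skeleton <- function() {
  tibble::tibble(sample = character(), subpop = character(),
                 chrom = character(), start_bp = numeric(),
                 end_bp = numeric(), n_snps = integer(),
                 length_bp = numeric())
}

#' Detect runs of homozygosity with a sliding scanning window
#'
#' The PLINK-style two-stage algorithm. Stage 1: every window of
#' `window_snps` consecutive SNPs fully inside a chromosome "passes" for a
#' sample when it holds at most `het_allowed` heterozygotes and
#' `missing_allowed` missing calls; a SNP is "in run" when the fraction of
#' spanning windows that pass is at least `hit_rate_threshold`. Stage 2:
#' maximal stretches of in-run SNPs are split at adjacent gaps above
#' `max_gap_bp` and kept when at least `min_len_bp` long with mean inter-SNP
#' spacing at most `min_density_bp_per_snp`. A chromosome with fewer SNPs
#' than the window is scanned with a window equal to its SNP count (with a
#' message).
#'
#' @param panel A `genotype_panel`.
#' @param params A [roh_params()].
#' @return A tibble of segments: `sample`, `subpop`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp` (`end - start + 1`).
#' @export
detect_roh_sliding <- function(panel, params = roh_params()) {
  chrom_idx <- split(seq_len(n_snps(panel)), panel$map$chrom)
  chrom_idx <- chrom_idx[unique(panel$map$chrom)]
  out <- list()
  for (ch in names(chrom_idx)) {
    idx <- chrom_idx[[ch]]
    pos <- panel$map$pos_bp[idx]
    n <- length(idx)
    w <- params$window_snps
    if (n < w) {
      message("chromosome ", ch, " has ", n, " SNPs < window of ", w,
              "; scanning with window = ", n)
      w <- n
    }
    nw <- n - w + 1L
    cum_pass_at <- function(pass) c(0, cumsum(pass))
    for (si in seq_len(n_samples(panel))) {
      d <- panel$dosage[si, idx]
      het <- as.integer(!is.na(d) & d == 1L)
      mis <- as.integer(is.na(d))
      pass <- rolling_sum(het, w) <= params$het_allowed &
        rolling_sum(mis, w) <= params$missing_allowed
      cp <- cum_pass_at(pass)
      i <- seq_len(n)
      lo <- pmax(1L, i - w + 1L)
      hi <- pmin(i, nw)
      n_span <- hi - lo + 1L
      n_hit <- cp[hi + 1L] - cp[lo]
      in_run <- n_hit / n_span >= params$hit_rate_threshold
      stretches <- true_runs(in_run)
      segs <- finish_stretches(stretches, pos, params)
      if (length(segs)) {
        mat <- do.call(rbind, segs)
        out[[length(out) + 1L]] <- tibble::tibble(
          sample = panel$samples[si], subpop = panel$subpop[si], chrom = ch,
          start_bp = unname(mat[, "start_bp"]),
          end_bp = unname(mat[, "end_bp"]),
          n_snps = as.integer(unname(mat[, "n_snps"])))
      }
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else roh_segment_skeleton()
  dplyr::mutate(res, length_bp = end_bp - start_bp + 1)
}

#' Detect runs of homozygosity by consecutive-SNP runs
#'
#' Single pass per chromosome and sample: a run extends while it holds at
#' most `het_allowed` heterozygotes, no missing call, and no adjacent gap
#' above `max_gap_bp`. A heterozygote exceeding the budget (or a missing
#' call) closes the run just before it and a fresh run starts just after
#' it. Closed runs pass the same length and mean-density screens as the
#' sliding method.
#'
#' @inheritParams detect_roh_sliding
#' @return A tibble of segments with the same columns as
#'   [detect_roh_sliding()].
#' @export
detect_roh_consecutive <- function(panel, params = roh_params()) {
  chrom_idx <- split(seq_len(n_snps(panel)), panel$map$chrom)
  chrom_idx <- chrom_idx[unique(panel$map$chrom)]
  out <- list()
  for (ch in names(chrom_idx)) {
    idx <- chrom_idx[[ch]]
    pos <- panel$map$pos_bp[idx]
    n <- length(idx)
    gap_break <- c(FALSE, diff(pos) > params$max_gap_bp)
    for (si in seq_len(n_samples(panel))) {
      d <- panel$dosage[si, idx]
      het <- !is.na(d) & d == 1L
      mis <- is.na(d)
      stretches <- list()
      run_start <- 1L
      het_count <- 0L
      i <- 1L
      close_run <- function(a, b) {
        if (b >= a) stretches[[length(stretches) + 1L]] <<- c(a, b)
      }
      while (i <= n) {
        if (gap_break[i] && i > run_start) {
          close_run(run_start, i - 1L)
          run_start <- i
          het_count <- 0L
        }
        if (mis[i]) {
          close_run(run_start, i - 1L)
          run_start <- i + 1L
          het_count <- 0L
        } else if (het[i]) {
          het_count <- het_count + 1L
          if (het_count > params$het_allowed) {
            close_run(run_start, i - 1L)
            run_start <- i + 1L
            het_count <- 0L
          }
        }
        i <- i + 1L
      }
      close_run(run_start, n)
      if (length(stretches)) {
        mat <- do.call(rbind, stretches)
        segs <- finish_stretches(
          tibble::tibble(start = mat[, 1L], end = mat[, 2L]), pos, params)
        if (length(segs)) {
          sm <- do.call(rbind, segs)
          out[[length(out) + 1L]] <- tibble::tibble(
            sample = panel$samples[si], subpop = panel$subpop[si],
            chrom = ch, start_bp = unname(sm[, "start_bp"]),
            end_bp = unname(sm[, "end_bp"]),
            n_snps = as.integer(unname(sm[, "n_snps"])))
        }
      }
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else roh_segment_skeleton()
  dplyr::mutate(res, length_bp = end_bp - start_bp + 1)
}

#' ROH-based genomic inbreeding
#'
#' `F_ROH` per sample: total ROH length divided by the genome length covered
#' by the map (sum over chromosomes of last minus first SNP position).
#' Samples without any segment get `F_ROH = 0`.
#'
#' @param segments Segment tibble from a ROH detector.
#' @param panel The `genotype_panel` the segments came from (provides the
#'   map and the full sample list).
#' @return A tibble with `sample`, `subpop`, `f_roh`.
#' @export
f_roh <- function(segments, panel) {
  denom <- sum(tapply(panel$map$pos_bp, panel$map$chrom,
                      function(p) max(p) - min(p)))
  if (denom <= 0) stop("map covers zero genome length", call. = FALSE)
  tot <- tapply(segments$length_bp, factor(segments$sample,
                                           levels = panel$samples), sum)
  tot[is.na(tot)] <- 0
  tibble::tibble(sample = panel$samples, subpop = panel$subpop,
                 f_roh = as.numeric(tot) / denom)
}

#' Summarize ROH segment lengths per subpopulation
#'
#' @param segments Segment tibble from a ROH detector.
#' @param thresholds_mb Length thresholds (Mb) for the percentage columns.
#' @return A tibble per subpopulation: segment count, mean/sd/min/max length
#'   in Mb, percentage of segments longer than each threshold, and
#'   percentage of samples carrying at least one such segment.
#' @export
roh_length_summary <- function(segments, thresholds_mb = c(4, 8, 16)) {
  if (!nrow(segments)) {
    return(tibble::tibble(subpop = character(), n_segments = 0L))
  }
  segments %>%
    dplyr::group_by(subpop) %>%
    dplyr::group_modify(function(d, key) {
      mb <- d$length_bp / 1e6
      row <- tibble::tibble(
        n_segments = nrow(d),
        mean_mb = mean(mb),
        sd_mb = if (nrow(d) > 1) stats::sd(mb) else 0,
        min_mb = min(mb), max_mb = max(mb))
      n_samp <- length(unique(d$sample))
      for (th in thresholds_mb) {
        row[[sprintf("pct_gt_%gMb", th)]] <- 100 * mean(mb > th)
        row[[sprintf("pct_samples_gt_%gMb", th)]] <-
          100 * length(unique(d$sample[mb > th])) / n_samp
      }
      row
    }) %>%
    dplyr::ungroup()
}

#' Per-SNP autozygosity score track
#'
#' For each subpopulation, the proportion of its samples whose ROH set
#' covers each SNP (segment boundaries inclusive).
#'
#' @param segments Segment tibble from a ROH detector.
#' @param panel The source `genotype_panel`.
#' @return A tibble with `subpop`, `chrom`, `pos_bp`, `snp_id`, `score`.
#' @export
autozygosity_track <- function(segments, panel) {
  labs <- unique(panel$subpop)
  purrr::map_dfr(labs, function(lab) {
    n_in_pop <- sum(panel$subpop == lab)
    count <- numeric(n_snps(panel))
    segs <- segments[segments$subpop == lab, , drop = FALSE]
    for (ch in unique(segs$chrom)) {
      on_ch <- which(panel$map$chrom == ch)
      pos <- panel$map$pos_bp[on_ch]
      sc <- segs[segs$chrom == ch, , drop = FALSE]
      a <- findInterval(sc$start_bp - 0.5, pos) + 1L  # first SNP >= start
      b <- findInterval(sc$end_bp + 0.5, pos)         # last SNP <= end
      ok <- b >= a
      if (!any(ok)) next
      delta <- numeric(length(pos) + 1L)
      for (k in which(ok)) {
        delta[a[k]] <- delta[a[k]] + 1
        delta[b[k] + 1L] <- delta[b[k] + 1L] - 1
      }
      count[on_ch] <- cumsum(delta[seq_along(pos)])
    }
    tibble::tibble(subpop = lab, chrom = panel$map$chrom,
                   pos_bp = panel$map$pos_bp, snp_id = panel$map$snp_id,
                   score = count / n_in_pop)
  })
}

#' Call ROH islands from an autozygosity track
#'
#' The threshold is the genome-wide `percentile` of the track's scores
#' (linear-interpolation percentile); islands are maximal runs of at least
#' `min_adjacent` map-adjacent SNPs with score strictly above it, bounded by
#' their first and last SNP positions. A constant track yields no islands.
#' Multi-subpopulation tracks are processed per subpopulation.
#'
#' @param track Tibble from [autozygosity_track()].
#' @param percentile Percentile (0-100) defining the empirical threshold.
#' @param min_adjacent Minimum run length in SNPs.
#' @return A region tibble: `chrom`, `start_bp`, `end_bp`, `source`
#'   (`"ROH_<subpop>"`), `n_units`.
#' @export
roh_islands <- function(track, percentile = 99.9, min_adjacent = 2L) {
  purrr::map_dfr(unique(track$subpop), function(lab) {
    tr <- track[track$subpop == lab, , drop = FALSE]
    thr <- score_percentile(tr$score, percentile)
    df <- tibble::tibble(chrom = tr$chrom, start_bp = tr$pos_bp,
                         end_bp = tr$pos_bp)
    call_flagged_regions(df, tr$score > thr, min_adjacent,
                         paste0("ROH_", lab))
  })
}

#' Generations to the common ancestor of an autozygous segment
#'
#' Under the 1 cM/Mb convention, a segment of length `L` cM points to a
#' common ancestor about `100 / (2 L)` generations back; the integer part is
#' returned.
#'
#' @param length_mb Segment length in Mb (= cM at 1 cM/Mb).
#' @return Integer generations, `floor(100 / (2 * length_mb))`.
#' @export
generations_to_ancestor <- function(length_mb) {
  stopifnot(all(length_mb > 0))
  as.integer(floor(100 / (2 * length_mb)))
}
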