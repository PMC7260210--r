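#' Consensus selection signatures across tests
#'
#' Candidate regions from the ROH island scans (one per subpopulation), the
#' F_ST outlier scan and the varLD scan are overlap-merged: regions from
#' different sources overlapping by at least 1 bp form one cluster, whose
#' span is the union of its members. Clusters supported by at least two
#' distinct sources become selection signatures; two or more regions from
#' the same test never qualify on their own. A signature supported only by
#' the two subpopulations' ROH islands is classified `shared_selection`
#' (the same region autozygous in both groups); any support from a
#' between-population differentiation test (F_ST or varLD) classifies it
#' `divergent_selection`.
#'
#' @param ... Region tibbles (`chrom`, `start_bp`, `end_bp`, `source`,
#'   `n_units`), in any order; may be passed as one list.
#' @return A tibble of signatures sorted by position, pairwise
#'   non-overlapping: `chrom`, `start_bp`, `end_bp`, `sources`
#'   (comma-separated, alphabetical), `n_sources`, `classification`.
#' @export
consensus_signatures <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !is.data.frame(parts[[1L]])) {
    parts <- parts[[1L]]
  }
  regions <- dplyr::bind_rows(parts)
  empty <- tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), sources = character(),
                          n_sources = integer(), classification = character())
  if (!nrow(regions)) return(empty)
  stopifnot(all(regions$start_bp <= regions$end_bp))
  out <- list()
  for (ch in unique(regions$chrom)) {
    rg <- regions[regions$chrom == ch, , drop = FALSE]
    rg <- rg[order(rg$start_bp, rg$end_bp), , drop = FALSE]
    cl_start <- rg$start_bp[1L]; cl_end <- rg$end_bp[1L]
    cl_src <- rg$source[1L]
    flush <- function(start, end, srcs) {
      usrc <- sort(unique(srcs))
      if (length(usrc) < 2L) return(NULL)
      diff_test <- any(usrc %in% c("FST", "VARLD"))
      tibble::tibble(chrom = ch, start_bp = start, end_bp = end,
                     sources = paste(usrc, collapse = ","),
                     n_sources = length(usrc),
                     classification = if (diff_test) "divergent_selection"
                     else "shared_selection")
    }
    if (nrow(rg) > 1L) {
      for (k in 2:nrow(rg)) {
        if (rg$start_bp[k] <= cl_end) {
          cl_end <- max(cl_end, rg$end_bp[k])
          cl_src <- c(cl_src, rg$source[k])
        } else {
          out[[length(out) + 1L]] <- flush(cl_start, cl_end, cl_src)
          cl_start <- rg$start_bp[k]; cl_end <- rg$end_bp[k]
          cl_src <- rg$source[k]
        }
      }
    }
    out[[length(out) + 1L]] <- flush(cl_start, cl_end, cl_src)
  }
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) return(empty)
  num <- suppressWarnings(as.numeric(out$chrom))
  out[order(is.na(num), num, out$chrom, out$start_bp), ]
}

#' Human-readable signature report
#'
#' One row per signature with coordinates rendered as
#' `BTA<chrom>:<start_Mb>-<end_Mb>` (two decimals), supporting tests,
#' classification, and — when score tracks are supplied — the peak score of
#' each supporting test inside the signature.
#'
#' @param signatures Tibble from [consensus_signatures()].
#' @param autozygosity Optional track from [autozygosity_track()] (both
#'   subpopulations).
#' @param fst_windows Optional window tibble from [fst_window_track()] /
#'   [fst_outlier_regions()].
#' @param varld_track Optional track from [varld_scan()].
#' @return A tibble: `region`, `chrom`, `start_bp`, `end_bp`, `sources`,
#'   `classification`, plus `peak_roh`, `peak_fst`, `peak_varld` where the
#'   corresponding track was given.
#' @export
signature_report <- function(signatures, autozygosity = NULL,
                             fst_windows = NULL, varld_track = NULL) {
  base <- tibble::tibble(
    region = sprintf("BTA%s:%.2f-%.2f", signatures$chrom,
                     signatures$start_bp / 1e6, signatures$end_bp / 1e6),
    chrom = signatures$chrom, start_bp = signatures$start_bp,
    end_bp = signatures$end_bp, sources = signatures$sources,
    classification = signatures$classification)
  peak_in <- function(track, value, chrom, lo, hi, pos_lo, pos_hi) {
    sel <- track$chrom == chrom & pos_hi >= lo & pos_lo <= hi
    if (any(sel)) max(value[sel]) else NA_real_
  }
  if (nrow(base)) {
    if (!is.null(autozygosity)) {
      base$peak_roh <- vapply(seq_len(nrow(base)), function(k) {
        peak_in(autozygosity, autozygosity$score, base$chrom[k],
                base$start_bp[k], base$end_bp[k],
                autozygosity$pos_bp, autozygosity$pos_bp)
      }, numeric(1))
    }
    if (!is.null(fst_windows)) {
      base$peak_fst <- vapply(seq_len(nrow(base)), function(k) {
        peak_in(fst_windows, fst_windows$theta, base$chrom[k],
                base$start_bp[k], base$end_bp[k],
                fst_windows$start_bp, fst_windows$end_bp)
      }, numeric(1))
    }
    if (!is.null(varld_track)) {
      base$peak_varld <- vapply(seq_len(nrow(base)), function(k) {
        peak_in(varld_track, varld_track$std_score, base$chrom[k],
                base$start_bp[k], base$end_bp[k],
                varld_track$start_bp, varld_track$end_bp)
      }, numeric(1))
    }
  } else {
    if (!is.null(autozygosity)) base$peak_roh <- numeric(0)
    if (!is.null(fst_windows)) base$peak_fst <- numeric(0)
    if (!is.null(varld_track)) base$peak_varld <- numeric(0)
  }
  base
}
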