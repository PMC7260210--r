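# shared internal helpers

# rolling sum of x over windows of length w (length(x) - w + 1 values)
rolling_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]
}

# maximal runs of TRUE: tibble(start, end, length) of index ranges
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep],
                 length = r$lengths[keep])
}

# linear-interpolation percentile (type-7 quantile) of finite scores
score_percentile <- function(scores, percentile) {
  stats::quantile(scores, probs = percentile / 100, type = 7, names = FALSE,
                  na.rm = TRUE)
}

# call regions of >= min_consecutive consecutive flagged rows, never
# crossing a chromosome; rows must already be in genomic order.
# start_bp/end_bp columns give the per-row span contributing to the region.
call_flagged_regions <- function(df, flagged, min_consecutive, source) {
  out <- list()
  for (ch in unique(df$chrom)) {
    rows <- which(df$chrom == ch)
    runs <- true_runs(flagged[rows])
    runs <- runs[runs$length >= min_consecutive, , drop = FALSE]
    if (!nrow(runs)) next
    out[[ch]] <- tibble::tibble(
      chrom = ch,
      start_bp = df$start_bp[rows[runs$start]],
      end_bp = df$end_bp[rows[runs$end]],
      source = source,
      n_units = runs$length
    )
  }
  if (!length(out)) {
    tibble::tibble(chrom = character(), start_bp = numeric(),
                   end_bp = numeric(), source = character(),
                   n_units = integer())
  } else {
    dplyr::bind_rows(out)
  }
}
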