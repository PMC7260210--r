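#' Configuration for the two-population forward simulator
#'
#' Bundles every knob of [simulate_two_pops()]. The defaults describe the
#' desk-scale study system the package is tested against: two subpopulations
#' of a few hundred animals that share recent ancestry, a few thousand SNPs
#' at array-like spacing (~100 kb), a U-shaped ancestral frequency spectrum
#' giving a mean MAF near 0.26, baseline LD that decays below r^2 = 0.2
#' within roughly 100 kb, and a uniform 1 cM/Mb recombination map.
#'
#' @param seed Integer RNG seed; the same config is bit-reproducible.
#' @param n_chrom Number of autosomes.
#' @param snps_per_chrom SNPs per chromosome (positions drawn uniformly).
#' @param chrom_length_bp Chromosome length in bp.
#' @param n_templates Size of the ancestral template pool the founder
#'   haplotypes copy from; smaller pools give stronger baseline LD.
#' @param template_switch_rate Per-bp rate of switching templates while
#'   copying; controls how fast baseline LD decays with distance.
#' @param ancestral_generations Wright-Fisher generations run in the
#'   ancestral population before the split, to settle the LD structure.
#' @param split_generations Generations `g >= 0` each daughter population
#'   evolves independently after the split; differentiation (F_ST) grows
#'   with `g`.
#' @param effective_size Length-2 vector: diploid effective size of each
#'   daughter population (the ancestral population uses their sum).
#' @param n_samples_per_pop Diploid samples drawn per population at the end.
#' @param recomb_rate Recombination rate in Morgans per bp (default
#'   `1e-8`, i.e. 1 cM/Mb).
#' @param maf_beta Shape parameters of the Beta distribution of ancestral
#'   allele frequencies.
#' @param maf_trunc Truncation interval for ancestral frequencies.
#' @param selected_loci `NULL`, or a data frame with columns `chrom`,
#'   `pos_bp` (nearest SNP is used), `shift` (per-generation allele
#'   frequency shift `s`) and `target_pop` (`1` or `2`), plus an optional
#'   `direction` column: `"up"`, `"down"`, or the default `"away"`, which
#'   picks the sign at the split so the target population is driven toward
#'   the extreme farther from its current frequency. Frequencies are
#'   clamped to `[0.02, 0.98]`.
#' @param inbred_fraction Length-2 vector: fraction of each population's
#'   samples produced by full-sib matings, creating long autozygous runs.
#' @param pop_labels Length-2 character vector of subpopulation labels.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 5L,
                       snps_per_chrom = 600L,
                       chrom_length_bp = 60e6,
                       n_templates = 6L,
                       template_switch_rate = 4e-6,
                       ancestral_generations = 10L,
                       split_generations = 20L,
                       effective_size = c(100L, 100L),
                       n_samples_per_pop = 200L,
                       recomb_rate = 1e-8,
                       maf_beta = c(0.8, 0.8),
                       maf_trunc = c(0.05, 0.95),
                       selected_loci = NULL,
                       inbred_fraction = c(0, 0),
                       pop_labels = c("popA", "popB")) {
  stopifnot(split_generations >= 0, n_chrom >= 1, snps_per_chrom >= 2,
            chrom_length_bp > 0, n_templates >= 2,
            all(effective_size >= 2), n_samples_per_pop >= 1,
            recomb_rate >= 0, length(pop_labels) == 2,
            all(inbred_fraction >= 0), all(inbred_fraction <= 1))
  if (!is.null(selected_loci)) {
    selected_loci <- tibble::as_tibble(selected_loci)
    stopifnot(all(c("chrom", "pos_bp", "shift", "target_pop") %in%
                    names(selected_loci)))
  }
  structure(
    list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
         snps_per_chrom = as.integer(snps_per_chrom),
         chrom_length_bp = chrom_length_bp,
         n_templates = as.integer(n_templates),
         template_switch_rate = template_switch_rate,
         ancestral_generations = as.integer(ancestral_generations),
         split_generations = as.integer(split_generations),
         effective_size = as.integer(effective_size),
         n_samples_per_pop = as.integer(n_samples_per_pop),
         recomb_rate = recomb_rate, maf_beta = maf_beta,
         maf_trunc = maf_trunc, selected_loci = selected_loci,
         inbred_fraction = inbred_fraction, pop_labels = pop_labels),
    class = "sim_config"
  )
}

# one recombined gamete from a parent's two haplotypes on one chromosome
recombine_gamete <- function(h1, h2, pos, chrom_len, recomb_rate) {
  k <- stats::rpois(1L, chrom_len * recomb_rate)
  start <- sample.int(2L, 1L)
  if (k == 0L) return(if (start == 1L) h1 else h2)
  cuts <- sort(stats::runif(k, 0, chrom_len))
  seg <- findInterval(pos, cuts)
  use2 <- (seg + start) %% 2L == 0L
  out <- h1
  out[use2] <- h2[use2]
  out
}

# one Wright-Fisher generation: haps is a list (per chromosome) of
# (2N_in x S) matrices; returns the same structure with 2*n_out rows
wf_generation <- function(haps, pos_list, n_out, chrom_len, recomb_rate) {
  n_in <- nrow(haps[[1L]]) / 2L
  p1 <- sample.int(n_in, n_out, replace = TRUE)
  p2 <- sample.int(n_in, n_out, replace = TRUE)
  lapply(seq_along(haps), function(ci) {
    h <- haps[[ci]]
    pos <- pos_list[[ci]]
    out <- matrix(0L, 2L * n_out, ncol(h))
    for (k in seq_len(n_out)) {
      out[2L * k - 1L, ] <- recombine_gamete(h[2L * p1[k] - 1L, ],
                                             h[2L * p1[k], ], pos,
                                             chrom_len, recomb_rate)
      out[2L * k, ] <- recombine_gamete(h[2L * p2[k] - 1L, ],
                                        h[2L * p2[k], ], pos,
                                        chrom_len, recomb_rate)
    }
    out
  })
}

# deterministic per-generation frequency shift at a selected locus,
# realized by whole-haplotype replacement so flanking linkage is preserved
apply_shift <- function(haps, ci, j_local, shift) {
  col <- haps[[ci]][, j_local]
  n2 <- length(col)
  p <- mean(col)
  target <- min(max(p + shift, 0.02), 0.98)
  k <- round((target - p) * n2)
  if (k == 0L) return(list(haps = haps, freq = p, ok = TRUE))
  gain <- k > 0L
  donors <- which(col == as.integer(gain))
  losers <- which(col == as.integer(!gain))
  if (!length(donors) || !length(losers)) {
    return(list(haps = haps, freq = p, ok = FALSE))
  }
  k <- min(abs(k), length(losers))
  repl <- losers[sample.int(length(losers), k)]
  src <- donors[sample.int(length(donors), k, replace = TRUE)]
  haps[[ci]][repl, ] <- haps[[ci]][src, , drop = FALSE]
  list(haps = haps, freq = mean(haps[[ci]][, j_local]), ok = TRUE)
}

#' Simulate two diverging subpopulations of phased diploid genotypes
#'
#' Forward Wright-Fisher simulation on haplotypes. Founder haplotypes are
#' mosaics of a small template pool (a Li-Stephens-style copying process
#' that creates distance-decaying baseline LD); the ancestral population
#' evolves, splits into two populations of the configured effective sizes,
#' and each evolves `split_generations` of random mating with recombination
#' (exponential crossover spacing at `recomb_rate`). Selected loci are
#' shifted deterministically by `shift` per generation in their target
#' population via whole-haplotype replacement, so flanking linkage
#' hitchhikes as under genuine selection. Finally diploid samples are drawn,
#' optionally with a fraction produced by full-sib matings to create long
#' autozygous runs. The output is phased and complete (no missing calls).
#'
#' @param config A [sim_config()].
#' @return A `genotype_panel` with haplotypes; the simulation truth is
#'   attached and retrievable with [sim_truth()]: `$selected_loci` (per
#'   locus realized frequencies and whether the shift stayed on track),
#'   `$trajectories` (per-generation frequencies at selected loci),
#'   `$ibd_segments` (filled by [plant_roh_cohort()]) and `$sib_mated`
#'   (samples produced by sib mating).
#' @export
simulate_two_pops <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cl <- config$chrom_length_bp
  pos_list <- lapply(seq_len(config$n_chrom), function(ci) {
    sort(sample.int(cl, config$snps_per_chrom))
  })
  map <- tibble::tibble(
    chrom = rep(as.character(seq_len(config$n_chrom)),
                each = config$snps_per_chrom),
    pos_bp = as.numeric(unlist(pos_list)),
    snp_id = sprintf("snp%d_%d", rep(seq_len(config$n_chrom),
                                     each = config$snps_per_chrom),
                     rep(seq_len(config$snps_per_chrom), config$n_chrom)),
    allele_ref = "A", allele_alt = "B"
  )
  m_per <- config$snps_per_chrom

  # ancestral frequencies: truncated Beta
  freq_list <- lapply(seq_len(config$n_chrom), function(ci) {
    p <- stats::rbeta(m_per, config$maf_beta[1], config$maf_beta[2])
    pmin(pmax(p, config$maf_trunc[1]), config$maf_trunc[2])
  })

  # template pool and mosaic founders
  n_anc <- sum(config$effective_size)
  haps <- lapply(seq_len(config$n_chrom), function(ci) {
    tmpl <- matrix(stats::rbinom(config$n_templates * m_per, 1L,
                                 rep(freq_list[[ci]],
                                     each = config$n_templates)),
                   config$n_templates, m_per)
    t(vapply(seq_len(2L * n_anc), function(h) {
      k <- stats::rpois(1L, cl * config$template_switch_rate)
      cuts <- if (k) sort(stats::runif(k, 0, cl)) else numeric(0)
      seg <- findInterval(pos_list[[ci]], cuts) + 1L
      pick <- sample.int(config$n_templates, k + 1L, replace = TRUE)
      tmpl[cbind(pick[seg], seq_len(m_per))]
    }, integer(m_per)))
  })
  for (i in seq_len(config$ancestral_generations)) {
    haps <- wf_generation(haps, pos_list, n_anc, cl, config$recomb_rate)
  }

  # split
  pops <- list(
    wf_generation(haps, pos_list, config$effective_size[1], cl,
                  config$recomb_rate),
    wf_generation(haps, pos_list, config$effective_size[2], cl,
                  config$recomb_rate)
  )

  # selected locus bookkeeping: snap to nearest simulated SNP
  sel <- config$selected_loci
  traj <- NULL
  if (!is.null(sel) && nrow(sel)) {
    sel$ci <- match(as.character(sel$chrom), as.character(seq_len(config$n_chrom)))
    if (!"direction" %in% names(sel)) sel$direction <- "away"
    sel$j_local <- NA_integer_
    sel$snp_pos <- NA_real_
    # snap each locus to the nearest SNP at which the target population
    # still segregates a low-frequency allele at the split (MAF in
    # [0.05, 0.3]): a deterministic shift can then act on it, and driving
    # the rare allele up emulates a hard selective sweep — the scenario
    # with both a frequency and an LD footprint. "away" resolves the sign
    # toward the extreme farther from the split frequency.
    for (i in seq_len(nrow(sel))) {
      pos <- pos_list[[sel$ci[i]]]
      f_split <- colMeans(pops[[sel$target_pop[i]]][[sel$ci[i]]])
      maf <- pmin(f_split, 1 - f_split)
      eligible <- which(maf >= 0.05 & maf <= 0.30)
      if (!length(eligible)) eligible <- which(maf >= 0.02)
      if (!length(eligible)) eligible <- seq_along(pos)
      sel$j_local[i] <- eligible[which.min(abs(pos[eligible] - sel$pos_bp[i]))]
      sel$snp_pos[i] <- pos[sel$j_local[i]]
      p_split <- f_split[sel$j_local[i]]
      sel$shift[i] <- switch(sel$direction[i],
        up = abs(sel$shift[i]),
        down = -abs(sel$shift[i]),
        away = if (p_split <= 0.5) abs(sel$shift[i]) else -abs(sel$shift[i]),
        stop("direction must be 'up', 'down' or 'away'", call. = FALSE))
    }
    sel$ok <- TRUE
    traj <- vector("list", nrow(sel))
  }

  for (gen in seq_len(config$split_generations)) {
    for (pp in 1:2) {
      pops[[pp]] <- wf_generation(pops[[pp]], pos_list,
                                  config$effective_size[pp], cl,
                                  config$recomb_rate)
    }
    if (!is.null(sel) && nrow(sel)) {
      for (i in seq_len(nrow(sel))) {
        pp <- sel$target_pop[i]
        res <- apply_shift(pops[[pp]], sel$ci[i], sel$j_local[i],
                           sel$shift[i])
        pops[[pp]] <- res$haps
        if (!res$ok && sel$ok[i]) {
          message("selected locus ", i, " could not be shifted at ",
                  "generation ", gen, " (allele lost); dropped from truth")
          sel$ok[i] <- FALSE
        }
        traj[[i]] <- rbind(traj[[i]],
                           data.frame(locus = i, generation = gen,
                                      pop = config$pop_labels[pp],
                                      freq = res$freq))
      }
    }
  }

  # draw final diploid samples (sib-mated fraction creates autozygosity)
  samples <- character(0); subpop <- character(0); sib_mated <- character(0)
  hap_out <- lapply(seq_len(config$n_chrom),
                    function(ci) matrix(0L, 0L, m_per))
  for (pp in 1:2) {
    n <- config$n_samples_per_pop
    n_sib <- round(config$inbred_fraction[pp] * n)
    ne <- config$effective_size[pp]
    ids <- sprintf("%s_%03d", config$pop_labels[pp], seq_len(n))
    samples <- c(samples, ids)
    subpop <- c(subpop, rep(config$pop_labels[pp], n))
    if (n_sib) sib_mated <- c(sib_mated, ids[seq_len(n_sib)])
    for (ci in seq_len(config$n_chrom)) {
      h <- pops[[pp]][[ci]]
      pos <- pos_list[[ci]]
      block <- matrix(0L, 2L * n, m_per)
      for (k in seq_len(n)) {
        if (k <= n_sib) {
          # full-sib mating: two sibs from one couple, then their offspring
          par <- sample.int(ne, 2L)
          sib <- lapply(1:2, function(s) {
            list(recombine_gamete(h[2L * par[1] - 1L, ], h[2L * par[1], ],
                                  pos, cl, config$recomb_rate),
                 recombine_gamete(h[2L * par[2] - 1L, ], h[2L * par[2], ],
                                  pos, cl, config$recomb_rate))
          })
          block[2L * k - 1L, ] <- recombine_gamete(sib[[1]][[1]], sib[[1]][[2]],
                                                   pos, cl, config$recomb_rate)
          block[2L * k, ] <- recombine_gamete(sib[[2]][[1]], sib[[2]][[2]],
                                              pos, cl, config$recomb_rate)
        } else {
          par <- sample.int(ne, 2L, replace = TRUE)
          block[2L * k - 1L, ] <- recombine_gamete(h[2L * par[1] - 1L, ],
                                                   h[2L * par[1], ], pos, cl,
                                                   config$recomb_rate)
          block[2L * k, ] <- recombine_gamete(h[2L * par[2] - 1L, ],
                                              h[2L * par[2], ], pos, cl,
                                              config$recomb_rate)
        }
      }
      hap_out[[ci]] <- rbind(hap_out[[ci]], block)
    }
  }
  # interleave chromosome blocks into one (2n x S_total) matrix
  n_tot <- length(samples)
  hap <- matrix(0L, 2L * n_tot, nrow(map))
  off <- 0L
  for (ci in seq_len(config$n_chrom)) {
    # rows for pop 1 then pop 2 were stacked per chromosome already
    hap[, off + seq_len(m_per)] <- hap_out[[ci]]
    off <- off + m_per
  }
  dosage <- hap[seq(1L, 2L * n_tot, 2L), , drop = FALSE] +
    hap[seq(2L, 2L * n_tot, 2L), , drop = FALSE]
  panel <- genotype_panel(map, dosage, samples, subpop, haplotypes = hap)

  truth <- list(
    config = config,
    selected_loci = if (is.null(sel) || !nrow(sel)) {
      tibble::tibble(chrom = character(), snp_pos = numeric(),
                     shift = numeric(), target_pop = integer(),
                     ok = logical())
    } else {
      tibble::as_tibble(sel[c("chrom", "snp_pos", "shift", "target_pop",
                              "ok")])
    },
    trajectories = if (is.null(traj)) {
      tibble::tibble(locus = integer(), generation = integer(),
                     pop = character(), freq = numeric())
    } else {
      tibble::as_tibble(do.call(rbind, traj))
    },
    ibd_segments = tibble::tibble(sample = character(), chrom = character(),
                                  start_bp = numeric(), end_bp = numeric()),
    sib_mated = sib_mated
  )
  attr(panel, "sim_truth") <- truth
  panel
}

#' Retrieve the simulation truth attached to a simulated panel
#'
#' @param panel A `genotype_panel` produced by [simulate_two_pops()] (and
#'   possibly modified by [plant_roh_cohort()]).
#' @return The truth list, or `NULL` for non-simulated panels.
#' @export
sim_truth <- function(panel) attr(panel, "sim_truth")

#' Plant true autozygous segments into a phased panel
#'
#' For a fraction of one subpopulation's samples, copies one haplotype
#' interval of at least `min_len_bp` onto the homologous chromosome,
#' creating a genuine identical-by-descent segment whose coordinates are
#' recorded in the simulation truth. Used to give ROH detectors a known
#' answer.
#'
#' @param panel A `genotype_panel` with haplotypes.
#' @param pop Subpopulation label to plant into.
#' @param fraction Fraction of that subpopulation's samples to modify, in
#'   `[0, 1]`.
#' @param min_len_bp Segment length in bp (shrunk with a warning when a
#'   chromosome is shorter).
#' @return The modified `genotype_panel`; planted segments are appended to
#'   `sim_truth(panel)$ibd_segments`.
#' @export
plant_roh_cohort <- function(panel, pop, fraction, min_len_bp = 5e6) {
  stopifnot(has_haplotypes(panel), fraction >= 0, fraction <= 1,
            min_len_bp > 0)
  idx <- which(panel$subpop == pop)
  if (!length(idx)) stop("no samples in subpopulation ", pop, call. = FALSE)
  n_pick <- round(fraction * length(idx))
  truth <- attr(panel, "sim_truth")
  if (is.null(truth)) {
    truth <- list(ibd_segments = tibble::tibble(
      sample = character(), chrom = character(),
      start_bp = numeric(), end_bp = numeric()))
  }
  if (n_pick == 0L) {
    attr(panel, "sim_truth") <- truth
    return(panel)
  }
  picked <- idx[sample.int(length(idx), n_pick)]
  chroms <- unique(panel$map$chrom)
  segs <- vector("list", n_pick)
  for (t in seq_along(picked)) {
    i <- picked[t]
    ch <- sample(chroms, 1L)
    on_ch <- which(panel$map$chrom == ch)
    lo <- min(panel$map$pos_bp[on_ch]); hi <- max(panel$map$pos_bp[on_ch])
    len <- min_len_bp
    if (hi - lo + 1 < len) {
      warning("chromosome ", ch, " shorter than min_len_bp; segment shrunk",
              call. = FALSE)
      len <- hi - lo + 1
    }
    start <- if (hi - len > lo) stats::runif(1L, lo, hi - len) else lo
    end <- start + len - 1
    in_seg <- on_ch[panel$map$pos_bp[on_ch] >= start &
                      panel$map$pos_bp[on_ch] <= end]
    panel$haplotypes[2L * i, in_seg] <- panel$haplotypes[2L * i - 1L, in_seg]
    panel$dosage[i, in_seg] <- 2L * panel$haplotypes[2L * i - 1L, in_seg]
    segs[[t]] <- tibble::tibble(sample = panel$samples[i], chrom = ch,
                                start_bp = floor(start), end_bp = floor(end))
  }
  truth$ibd_segments <- dplyr::bind_rows(truth$ibd_segments,
                                         dplyr::bind_rows(segs))
  attr(panel, "sim_truth") <- truth
  panel
}
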