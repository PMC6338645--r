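# Seeded synthetic-data generators emulating the statistical structure of
# the study's measurements: densitometry time courses (multiplicative
# lognormal noise, median-unbiased), per-worm GFP::LGG-1 area fractions
# (Beta), hourly paralysis cohorts (discrete hazard), and DNA sequences with
# planted motif instances. All generators are pure functions of
# (arguments, seed).

DENSITOMETRY_ANALYTES <- c("AMPK-T" = "A", "AMPK-P" = "Ap", "NRF2" = "N",
                           "NQO1" = "N", "HO-1" = "N",
                           "LC3-II/LC3-I" = "L", "p62" = "P",
                           "ULK555-P" = "U")

#' Synthetic densitometry table
#'
#' Samples Western-blot-style band intensities from model trajectories at
#' the blot time points. Each value is the model readout times a
#' median-unbiased multiplicative lognormal factor,
#' \code{value = x * exp(rnorm(0, noise_sd))}. NQO1 and HO-1 are reported as
#' NRF2-activity proxies (they track the N state).
#'
#' @param traj_map Named list (condition -> \code{model_trajectory}).
#' @param noise_sd Lognormal sigma (0 = exact model readouts).
#' @param n_reps Replicates per cell of the design.
#' @param times Blot time points (hours).
#' @param seed Integer seed.
#' @return data.frame with \code{analyte}, \code{condition}, \code{time},
#'   \code{replicate}, \code{value}.
#' @export
gen_densitometry <- function(traj_map, noise_sd = 0.2, n_reps = 3,
                             times = c(0, 0.5, 1, 2, 3, 4), seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_reps < 1) stop("n_reps must be >= 1")
  stopifnot(is.list(traj_map), !is.null(names(traj_map)))
  design <- expand.grid(analyte = names(DENSITOMETRY_ANALYTES),
                        condition = names(traj_map), time = times,
                        replicate = seq_len(n_reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[order(design$analyte, design$condition, design$time,
                         design$replicate), , drop = FALSE]
  rownames(design) <- NULL
  mu <- vapply(seq_len(nrow(design)), function(i) {
    tr <- traj_map[[design$condition[i]]]
    st <- DENSITOMETRY_ANALYTES[[design$analyte[i]]]
    stats::approx(tr$time, tr[[st]], xout = design$time[i])$y
  }, numeric(1))
  noise <- with_seed(seed, exp(stats::rnorm(nrow(design), 0, noise_sd)))
  design$value <- mu * noise
  design
}

#' Synthetic per-worm puncta-area cohort
#'
#' Per-worm GFP::LGG-1 area fractions drawn from a Beta distribution with
#' the given mean and concentration (shape1 + shape2); the concentration is
#' capped at 1e6 (degenerate limit).
#'
#' @param mean_fraction Mean area fraction in (0, 1).
#' @param concentration Beta concentration (> 0).
#' @param n_worms Cohort size (0 gives an empty cohort).
#' @param seed Integer seed.
#' @param genotype Label attached to the cohort.
#' @return data.frame with \code{worm}, \code{genotype}, \code{fraction}.
#' @export
gen_puncta_cohort <- function(mean_fraction, concentration, n_worms,
                              seed = 1, genotype = "WT") {
  if (mean_fraction <= 0 || mean_fraction >= 1) {
    stop("mean_fraction must lie in (0, 1)")
  }
  if (concentration <= 0) stop("concentration must be > 0")
  concentration <- min(concentration, 1e6)
  if (n_worms == 0) {
    return(data.frame(worm = integer(), genotype = character(),
                      fraction = numeric()))
  }
  frac <- with_seed(seed, stats::rbeta(n_worms,
                                       shape1 = mean_fraction * concentration,
                                       shape2 = (1 - mean_fraction) *
                                         concentration))
  data.frame(worm = seq_len(n_worms), genotype = genotype, fraction = frac)
}

#' Synthetic paralysis cohort
#'
#' Each worm's paralysis hour is drawn from the discrete distribution implied
#' by the expected curve F(t) observed hourly; worms not paralyzed by the end
#' of the assay are censored.
#'
#' @param curve A \code{paralysis_curve} (or data.frame with \code{time},
#'   \code{fraction}).
#' @param n_worms Cohort size (>= 1).
#' @param seed Integer seed.
#' @param genotype Label attached to the cohort.
#' @return data.frame with \code{worm}, \code{genotype}, \code{time} (hour of
#'   paralysis, or the final hour if censored), \code{status} (1 = paralyzed,
#'   0 = censored).
#' @export
gen_paralysis_cohort <- function(curve, n_worms, seed = 1, genotype = "WT") {
  if (n_worms < 1) stop("n_worms must be >= 1")
  t_max <- floor(max(curve$time))
  hours <- seq_len(t_max)
  Fh <- stats::approx(curve$time, curve$fraction, xout = hours)$y
  u <- with_seed(seed, stats::runif(n_worms))
  idx <- vapply(u, function(ui) {
    k <- which(Fh >= ui)
    if (length(k) == 0) NA_integer_ else k[1]
  }, integer(1))
  data.frame(worm = seq_len(n_worms), genotype = genotype,
             time = ifelse(is.na(idx), t_max, hours[idx]),
             status = as.integer(!is.na(idx)))
}

#' Random sequences with planted motif instances
#'
#' Uniform-ACGT background with concrete instances of a degenerate motif
#' (codes resolved uniformly; pattern N resolves to a random base) planted at
#' the requested anchor-relative offsets, one sequence per species. With
#' \code{exclusive = TRUE} the background is re-drawn until a double-strand
#' scan recovers exactly the planted sites.
#'
#' @param n_species Number of sequences.
#' @param length Sequence length (>= motif length).
#' @param site_offsets Anchor-relative plant offsets (site start - anchor).
#' @param motif A \code{consensus_motif}, motif name, or IUPAC pattern.
#' @param seed Integer seed.
#' @param anchor_pos 0-based anchor position; default: centred so all sites
#'   fit.
#' @param anchor_kind Anchor metadata (\code{"ATG"} or \code{"TSS"}).
#' @param exclusive Re-draw background on accidental extra hits.
#' @return Named list of \code{anchored_seq} (species1, species2, ...).
#' @export
gen_planted_sequences <- function(n_species, length, site_offsets, motif,
                                  seed = 1, anchor_pos = NULL,
                                  anchor_kind = "ATG", exclusive = FALSE) {
  len <- as.integer(length)
  rm(length)   # unshadow base::length
  if (is.character(motif)) {
    motif <- if (motif %in% c("ARE", "SKN1")) consensus_motifs(motif)
             else consensus_motif("custom", motif)
  }
  m <- motif$length
  if (len < m) stop("sequence length shorter than the motif")
  site_offsets <- sort(as.integer(site_offsets))
  if (any(diff(site_offsets) < m)) stop("planted sites overlap")
  if (is.null(anchor_pos)) {
    lo <- -min(c(site_offsets, 0))
    hi <- len - m - max(c(site_offsets, 0))
    if (hi < lo) stop("sites do not fit in the sequence; increase length")
    anchor_pos <- as.integer(floor((lo + hi) / 2))
  }
  starts <- anchor_pos + site_offsets
  n_sites <- length(starts)
  if (any(starts < 0) || any(starts + m > len)) {
    stop("site offsets fall outside the sequence for this anchor")
  }
  pc <- strsplit(motif$pattern, "", fixed = TRUE)[[1]]
  resolve <- function() {
    paste(vapply(pc, function(code) {
      opts <- setdiff(IUPAC_CODES[[code]], "N")
      if (length(opts) == 1) opts else sample(opts, 1)
    }, character(1)), collapse = "")
  }
  out <- lapply(seq_len(n_species), function(sp) {
    with_seed(derive_seed(seed, sp), {
      for (try in seq_len(200)) {
        chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        for (st in starts) {
          inst <- strsplit(resolve(), "", fixed = TRUE)[[1]]
          chars[(st + 1):(st + m)] <- inst
        }
        s <- anchored_seq(paste0("species", sp), paste(chars, collapse = ""),
                          anchor_pos, anchor_kind)
        if (!exclusive) return(s)
        hits <- scan_motif(s, motif, "both")
        if (nrow(hits) == n_sites && setequal(hits$start, starts)) {
          return(s)
        }
      }
      stop("could not generate an exclusive background in 200 attempts")
    })
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}
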