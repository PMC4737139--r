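# Umbrella windows, harmonic angular bias, WHAM, anchoring and two-run errors.

#' Boltzmann constant in kcal/(mol*K)
#' @export
kB <- 0.0019872041

#' Default simulation temperature (K)
#'
#' Matches the thermophile-optimum temperature at which the umbrella
#' simulations are run.
#' @export
default_temperature <- 330

#' Harmonic angular bias potential
#'
#' Restraint-style convention without the 1/2 prefactor:
#' `U(theta) = k * (theta - center)^2` on the unwrapped angle scale.
#'
#' @param center bias center, degrees (unwrapped scale).
#' @param k force constant, kcal/(mol*degree^2); must be > 0 (use exactly
#'   0 only for an unbiased window).
#' @return a `bias_potential`.
#' @export
bias_potential <- function(center, k) {
  if (k < 0) .validation_error("force constant must be >= 0")
  structure(list(center = center, k = k), class = "bias_potential")
}

#' Build an evenly spaced umbrella window plan
#'
#' @param start first bias center, degrees.
#' @param spacing center spacing, degrees (> 0).
#' @param count number of windows (>= 1).
#' @param k force constant, kcal/(mol*degree^2).
#' @return list of `bias_potential`s with centers `start + i*spacing`.
#' @export
make_windows <- function(start, spacing, count, k) {
  if (spacing <= 0) .validation_error("spacing must be > 0")
  if (count < 1) .validation_error("count must be >= 1")
  lapply(seq_len(count) - 1L, function(i) bias_potential(start + i * spacing, k))
}

#' Bias energy at an angle
#'
#' @param bias a `bias_potential`.
#' @param theta angle(s), degrees (unwrapped scale).
#' @param half use the `1/2 k dtheta^2` convention instead of the default
#'   restraint convention `k dtheta^2`.
#' @return energy in kcal/mol.
#' @export
bias_energy <- function(bias, theta, half = FALSE) {
  pref <- if (half) 0.5 else 1
  pref * bias$k * (theta - bias$center)^2
}

#' An umbrella window: bias plus sampled angle series
#'
#' @param bias a `bias_potential`.
#' @param samples numeric vector of sampled angles, degrees (>= 1 sample).
#' @param run_id independent-run identifier (1 or 2).
#' @param temperature simulation temperature, K.
#' @return an `umbrella_window`.
#' @export
umbrella_window <- function(bias, samples, run_id = 1L,
                            temperature = default_temperature) {
  stopifnot(inherits(bias, "bias_potential"))
  samples <- as.numeric(samples)
  if (length(samples) < 1L || anyNA(samples)) .validation_error("window needs >= 1 finite sample")
  if (temperature <= 0) .validation_error("temperature must be > 0")
  if (!run_id %in% c(1L, 2L)) .validation_error("run_id must be 1 or 2")
  structure(list(bias = bias, samples = samples, run_id = as.integer(run_id),
                 temperature = temperature), class = "umbrella_window")
}

new_pmf_profile <- function(bins, G, error, counts, anchor = NA_real_,
                            temperature = default_temperature) {
  structure(list(bins = bins, G = G, error = error, counts = counts,
                 anchor = anchor, temperature = temperature),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- !is.na(x$G)
  cat(sprintf("<pmf_profile> %d bins (%.1f..%.1f deg), %d covered, anchor %s\n",
              length(x$bins), min(x$bins), max(x$bins), sum(ok),
              ifelse(is.na(x$anchor), "none", sprintf("%.1f deg", x$anchor))))
  invisible(x)
}

#' Solve the WHAM equations for a set of umbrella windows
#'
#' Histograms all windows on a common grid and iterates the standard
#' self-consistent weighted-histogram equations
#' `P(b) = sum_i n_i(b) / sum_i N_i exp(-beta (U_i(b) - f_i))`,
#' `f_i = -kT log sum_b P(b) exp(-beta U_i(b))`,
#' until the window free-energy shifts change by less than `tol`. The
#' unbiased free energy is `G(b) = -kT log P(b)`; bins with zero total
#' counts are masked (`NA`), never extrapolated.
#'
#' @param windows list of `umbrella_window`s sharing one temperature.
#' @param bin_width reporting bin width, degrees.
#' @param tol convergence tolerance on `max |delta f_i|`, kcal/mol.
#' @param max_iter maximum iterations.
#' @param range optional c(lo, hi) forcing the bin grid (needed when two
#'   runs must share binning); default spans the samples.
#' @param half bias convention flag, see [bias_energy()].
#' @param grid_refine internal grid subdivisions per reporting bin. The
#'   self-consistent equations are solved on the fine grid — the
#'   restrained window distributions are narrow (about 1.3 degrees at the
#'   default force constant), so coarse histogram cells bias the window
#'   matching by O(width^2) — and probabilities are then pooled back into
#'   the reporting bins, which keeps per-bin counting noise low.
#' @return an unanchored `pmf_profile`.
#' @export
wham <- function(windows, bin_width = 1.0, tol = 1e-7, max_iter = 100000L,
                 range = NULL, half = FALSE, grid_refine = 8L) {
  if (length(windows) < 1L) .validation_error("need >= 1 window")
  for (w in windows) stopifnot(inherits(w, "umbrella_window"))
  if (grid_refine < 1L) .validation_error("grid_refine must be >= 1")
  temps <- vapply(windows, function(w) w$temperature, numeric(1))
  if (diff(range(temps)) > 1e-9) .validation_error("windows must share one temperature")
  temperature <- temps[1]
  beta <- 1 / (kB * temperature)

  all_s <- unlist(lapply(windows, function(w) w$samples))
  if (is.null(range)) range <- c(min(all_s), max(all_s))
  lo <- floor(range[1] / bin_width) * bin_width
  hi <- ceiling(range[2] / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  nc <- as.integer(round((hi - lo) / bin_width))
  centers <- lo + (seq_len(nc) - 0.5) * bin_width

  wf <- bin_width / grid_refine
  nb <- nc * grid_refine
  fine_centers <- lo + (seq_len(nb) - 0.5) * wf
  coarse_of <- rep(seq_len(nc), each = grid_refine)

  nwin <- length(windows)
  counts <- matrix(0, nwin, nb)
  for (i in seq_len(nwin)) {
    s <- windows[[i]]$samples
    s <- s[s >= lo & s < hi]
    if (length(s) == 0L) next
    bidx <- pmin(nb, floor((s - lo) / wf) + 1L)
    counts[i, ] <- tabulate(bidx, nbins = nb)
  }
  Ni <- rowSums(counts)
  ntot <- colSums(counts)
  ntot_c <- as.numeric(tapply(ntot, coarse_of, sum))

  # coverage: the sampled support (on the reporting grid) must form one
  # dominant contiguous block. Stray far-tail bins are masked; two
  # substantial separated blocks mean the windows genuinely fail to overlap.
  ci <- which(ntot_c > 0)
  if (length(ci) == 0L) .validation_error("no samples fall in the binned range")
  block_id <- cumsum(c(1L, diff(ci) > 1L))
  block_counts <- tapply(ntot_c[ci], block_id, sum)
  main <- as.integer(names(block_counts)[which.max(block_counts)])
  if (any(block_counts[-which.max(block_counts)] > 0.01 * sum(ntot_c))) {
    .validation_error("disconnected histogram coverage: windows do not overlap")
  }
  covered_c <- rep(FALSE, nc)
  covered_c[ci[block_id == main]] <- TRUE
  covered <- covered_c[coarse_of] & ntot > 0
  ntot[!covered] <- 0L
  ntot_c[!covered_c] <- 0

  # bias Boltzmann factor averaged within each fine grid cell
  quad <- (c(1, 2, 3) - 2) / 3 * wf
  expU <- matrix(0, nwin, nb)
  for (i in seq_len(nwin)) {
    for (qo in quad) {
      expU[i, ] <- expU[i, ] +
        exp(-beta * bias_energy(windows[[i]]$bias, fine_centers + qo, half = half))
    }
  }
  expU <- expU / length(quad)

  f <- rep(0, nwin)
  P <- rep(0, nb)
  for (iter in seq_len(max_iter)) {
    denom <- colSums(Ni * expU * exp(beta * f))
    P[covered] <- ntot[covered] / denom[covered]
    P <- P / sum(P)
    fnew <- -(1 / beta) * log(expU[, covered, drop = FALSE] %*% P[covered])
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- as.numeric(fnew)
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop("WHAM did not converge in ", max_iter, " iterations (residual ",
         signif(delta, 3), " kcal/mol)")
  }
  P_c <- as.numeric(tapply(P, coarse_of, sum))
  G <- rep(NA_real_, nc)
  G[covered_c] <- -(1 / beta) * log(P_c[covered_c])
  new_pmf_profile(centers, G, rep(NA_real_, nc), ntot_c, NA_real_, temperature)
}

.anchor_bin <- function(profile, anchor) {
  which.min(abs(profile$bins - anchor))
}

#' Anchor a PMF to zero at a reference angle
#'
#' Shifts the whole profile so the bin containing the anchor angle (the
#' intrahelical endpoint, conventionally) has `G = 0`; errors are
#' unchanged.
#'
#' @param profile a `pmf_profile`.
#' @param anchor anchor angle, degrees.
#' @return the shifted `pmf_profile`.
#' @export
anchor_zero <- function(profile, anchor = 0) {
  b <- .anchor_bin(profile, anchor)
  if (is.na(profile$G[b])) .validation_error("anchor bin is masked (no samples)")
  profile$G <- profile$G - profile$G[b]
  profile$anchor <- anchor
  profile
}

#' Combine two independent runs into a mean PMF with run-difference errors
#'
#' Per bin: `G = (G1 + G2)/2`, `error = |G1 - G2|/2`; a bin masked in
#' either run is masked in the result. Both profiles must share binning
#' and anchor.
#'
#' @param profile_run1,profile_run2 anchored `pmf_profile`s.
#' @return combined `pmf_profile`.
#' @export
two_run_error <- function(profile_run1, profile_run2) {
  p1 <- profile_run1; p2 <- profile_run2
  if (length(p1$bins) != length(p2$bins) ||
      max(abs(p1$bins - p2$bins)) > 1e-9) {
    .validation_error("binning mismatch between runs")
  }
  if (!isTRUE(all.equal(p1$anchor, p2$anchor))) {
    .validation_error("runs anchored at different angles")
  }
  G <- (p1$G + p2$G) / 2
  err <- abs(p1$G - p2$G) / 2
  mask <- is.na(p1$G) | is.na(p2$G)
  G[mask] <- NA_real_
  err[mask] <- NA_real_
  new_pmf_profile(p1$bins, G, err, p1$counts + p2$counts, p1$anchor,
                  p1$temperature)
}

#' Endpoint free-energy difference and barrier over a segment
#'
#' @param profile a `pmf_profile`.
#' @param segment c(start, end) angles in degrees; nearest covered bins
#'   are used as endpoints.
#' @param interpolate linearly fill masked interior bins instead of
#'   erroring.
#' @return list with `dG_endpoints` (`G(end) - G(start)`) and `barrier`
#'   (`max_segment G - G(start)`), kcal/mol.
#' @export
barrier_and_endpoint_stats <- function(profile, segment, interpolate = FALSE) {
  b1 <- .anchor_bin(profile, segment[1])
  b2 <- .anchor_bin(profile, segment[2])
  if (b2 < b1) { tmp <- b1; b1 <- b2; b2 <- tmp }
  G <- profile$G[b1:b2]
  if (anyNA(G)) {
    if (!interpolate) .validation_error("masked bins inside segment")
    G <- stats::approx(seq_along(G)[!is.na(G)], G[!is.na(G)],
                       xout = seq_along(G), rule = 2)$y
  }
  gstart <- if (profile$bins[b1] <= profile$bins[b2]) G[1] else G[length(G)]
  gend <- if (profile$bins[b1] <= profile$bins[b2]) G[length(G)] else G[1]
  # segment was given as (start, end); respect the caller's direction
  if (segment[2] < segment[1]) { tmp <- gstart; gstart <- gend; gend <- tmp }
  list(dG_endpoints = gend - gstart, barrier = max(G) - gstart)
}

#' Free energy by direct Boltzmann inversion of an unbiased sample
#'
#' `G(b) = -kT log p(b)` from the histogram of a long unbiased run; the
#' independent cross-check for WHAM on synthetic landscapes.
#'
#' @param samples unbiased angle samples, degrees.
#' @param bin_width histogram bin width, degrees.
#' @param temperature temperature, K.
#' @param range optional c(lo, hi) bin grid range.
#' @return an unanchored `pmf_profile`.
#' @export
boltzmann_invert <- function(samples, bin_width = 1.0,
                             temperature = default_temperature, range = NULL) {
  if (length(samples) == 0L) .validation_error("no samples")
  if (is.null(range)) range <- c(min(samples), max(samples))
  lo <- floor(range[1] / bin_width) * bin_width
  hi <- ceiling(range[2] / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  s <- samples[samples >= lo & samples < hi]
  bidx <- pmin(length(centers), floor((s - lo) / bin_width) + 1L)
  n <- tabulate(bidx, nbins = length(centers))
  G <- rep(NA_real_, length(centers))
  G[n > 0] <- -kB * temperature * log(n[n > 0] / sum(n))
  new_pmf_profile(centers, G, rep(NA_real_, length(centers)), n, NA_real_,
                  temperature)
}

#' Write a PMF profile as TSV
#'
#' Columns: bin_center_deg, G_kcal_mol, error_kcal_mol, n_samples.
#' Masked bins are written as NA.
#'
#' @param profile a `pmf_profile`.
#' @param path output path.
#' @param header optional comment lines (written with `#`).
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(profile, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("# bin_center_deg\tG_kcal_mol\terror_kcal_mol\tn_samples", con)
  writeLines(sprintf("%.4f\t%s\t%s\t%d", profile$bins,
                     ifelse(is.na(profile$G), "NA", sprintf("%.6f", profile$G)),
                     ifelse(is.na(profile$error), "NA", sprintf("%.6f", profile$error)),
                     as.integer(profile$counts)), con)
  invisible(path)
}
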