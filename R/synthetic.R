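# Seeded synthetic-data generators: analytic free-energy landscapes with
# Metropolis umbrella sampling, toy eversion trajectories with known
# angles, and noisy Michaelis-Menten datasets.

#' Analytic 1-D free-energy landscape (sum of Gaussians)
#'
#' `G(theta) = offset + sum_j amp_j exp(-(theta - center_j)^2 / (2 width_j^2))`
#' on the unwrapped eversion axis.
#'
#' @param amp,center,width parallel vectors of Gaussian amplitudes
#'   (kcal/mol), centers (deg) and widths (deg, > 0).
#' @param offset constant offset, kcal/mol.
#' @return a `landscape`.
#' @export
landscape <- function(amp, center, width, offset = 0) {
  if (!(length(amp) == length(center) && length(amp) == length(width))) {
    .validation_error("amp, center, width must have equal length")
  }
  if (any(width <= 0)) .validation_error("Gaussian widths must be > 0")
  structure(list(amp = amp, center = center, width = width, offset = offset),
            class = "landscape")
}

#' Evaluate a landscape
#'
#' @param ls a `landscape`.
#' @param theta angle(s), degrees.
#' @return free energy G(theta), kcal/mol.
#' @export
eval_landscape <- function(ls, theta) {
  g <- rep(ls$offset, length(theta))
  for (j in seq_along(ls$amp)) {
    g <- g + ls$amp[j] * exp(-((theta - ls$center[j])^2) / (2 * ls$width[j]^2))
  }
  g
}

#' Analytic gradient of a landscape
#'
#' @param ls a `landscape`.
#' @param theta angle(s), degrees.
#' @return dG/dtheta, kcal/(mol*deg).
#' @export
landscape_gradient <- function(ls, theta) {
  g <- rep(0, length(theta))
  for (j in seq_along(ls$amp)) {
    d <- theta - ls$center[j]
    g <- g - ls$amp[j] * d / ls$width[j]^2 * exp(-d^2 / (2 * ls$width[j]^2))
  }
  g
}

# Frozen preset coefficients. Feature values emulate the published
# eversion free-energy phenomenology: for the lesion (oxoG-like) profile,
# metastable minima near 40 and 90 deg, an overall barrier of ~7 kcal/mol
# and an extrahelical endpoint ~7 kcal/mol below the intrahelical state;
# for the normal-base (G-like) profile, a ~10 kcal/mol step after the
# first minimum, an overall barrier of ~22 kcal/mol and an endpoint ~20
# kcal/mol above the intrahelical state. Offsets make G(0) = 0 exactly.
.presets <- list(
  flat = list(amp = numeric(0), center = numeric(0), width = numeric(0)),
  double_well = list(amp = c(-3, 4, -3), center = c(60, 130, 200),
                     width = c(25, 20, 25)),
  # oxoG_like features: minima 40 deg (-3.5) and 88 deg (-4.5), overall
  # barrier 6.9 kcal/mol at 140 deg, endpoint G(280) = -7.5 kcal/mol
  oxoG_like = list(amp = c(3.0, -3.0, -4.5, 7.6, -7.4),
                   center = c(15, 40, 90, 140, 300),
                   width = c(8, 10, 14, 22, 60)),
  # G_like features: shallow minimum at 37 deg, mid-path crest 11.5
  # kcal/mol, overall barrier 22.0 kcal/mol at 242 deg, endpoint
  # G(280) = +19.2 kcal/mol
  G_like = list(amp = c(-2.5, 9.8, -3.5, 23.2, -2.3),
                center = c(40, 80, 115, 250, 295),
                width = c(9, 18, 12, 75, 40))
)

#' Build a landscape from a preset or an explicit specification
#'
#' Presets: `"flat"` (G = 0 everywhere), `"double_well"` (two wells with a
#' central crest), `"oxoG_like"` and `"G_like"` (emulating the published
#' lesion and normal-base eversion profiles; see the methods vignette).
#' All presets are offset so `G(0) = 0`.
#'
#' @param spec a preset name, or a list with `amp`, `center`, `width` and
#'   optionally `offset`.
#' @return a `landscape`.
#' @export
make_landscape <- function(spec = "flat") {
  if (is.character(spec)) {
    if (!spec %in% names(.presets)) {
      .validation_error("unknown preset '", spec, "'; available: ",
                        paste(names(.presets), collapse = ", "))
    }
    spec <- .presets[[spec]]
  }
  if (!is.list(spec) || !all(c("amp", "center", "width") %in% names(spec))) {
    .validation_error("landscape spec needs amp, center, width")
  }
  ls <- landscape(spec$amp, spec$center, spec$width,
                  offset = if (is.null(spec$offset)) 0 else spec$offset)
  # anchor the intrahelical origin at zero
  ls$offset <- ls$offset - eval_landscape(ls, 0)
  ls
}

#' Metropolis sampler configuration
#'
#' @param temperature K.
#' @param step_sd Gaussian proposal standard deviation, degrees.
#' @param n_samples post-burn-in samples to return.
#' @param burn_in discarded initial updates.
#' @param stride Metropolis updates per recorded sample. Recording every
#'   10th update makes consecutive recorded samples effectively
#'   independent, emulating the information content of the much longer
#'   every-timestep records the desk-scale sample count stands in for.
#' @param seed RNG seed (required for reproducibility).
#' @param theta0 initial angle; defaults to the bias center (or 0).
#' @return a `sampler_config`.
#' @export
sampler_config <- function(temperature = default_temperature, step_sd = 2,
                           n_samples = 5000L, burn_in = 1000L, stride = 10L,
                           seed = 1L, theta0 = NULL) {
  if (step_sd <= 0 || temperature <= 0 || n_samples < 1L || burn_in < 0L ||
      stride < 1L) {
    .validation_error("invalid sampler configuration")
  }
  structure(list(temperature = temperature, step_sd = step_sd,
                 n_samples = as.integer(n_samples), burn_in = as.integer(burn_in),
                 stride = as.integer(stride), seed = as.integer(seed),
                 theta0 = theta0),
            class = "sampler_config")
}

#' Sample one umbrella window by Metropolis Monte Carlo
#'
#' Markov chain targeting `exp(-beta (G(theta) + U_bias(theta)))` with a
#' Gaussian random-walk proposal; exact detailed balance, deterministic
#' under the configured seed. Warns when the post-burn-in acceptance rate
#' drops below 1%.
#'
#' @param ls a `landscape`.
#' @param bias a `bias_potential`, or `NULL` for an unbiased run.
#' @param cfg a `sampler_config`.
#' @param run_id run identifier stored on the window.
#' @return an `umbrella_window`.
#' @export
sample_window <- function(ls, bias = NULL, cfg = sampler_config(), run_id = 1L) {
  if (is.null(bias)) bias <- bias_potential(0, 0)
  beta <- 1 / (kB * cfg$temperature)
  stride <- cfg$stride
  burn <- cfg$burn_in
  ntot <- burn + cfg$n_samples * stride
  set.seed(cfg$seed)
  prop <- stats::rnorm(ntot, 0, cfg$step_sd)
  logu <- log(stats::runif(ntot))
  amp <- ls$amp; cen <- ls$center; wid2 <- 2 * ls$width^2
  kbias <- bias$k; cbias <- bias$center
  ng <- length(amp)
  th <- if (is.null(cfg$theta0)) cbias else cfg$theta0
  e <- kbias * (th - cbias)^2 +
    (if (ng) sum(amp * exp(-((th - cen)^2) / wid2)) else 0)
  out <- numeric(cfg$n_samples)
  acc <- 0L
  for (i in seq_len(ntot)) {
    thn <- th + prop[i]
    en <- kbias * (thn - cbias)^2 +
      (if (ng) sum(amp * exp(-((thn - cen)^2) / wid2)) else 0)
    if (logu[i] < -beta * (en - e)) {
      th <- thn; e <- en
      if (i > burn) acc <- acc + 1L
    }
    if (i > burn && (i - burn) %% stride == 0L) out[(i - burn) %/% stride] <- th
  }
  if (acc / (cfg$n_samples * stride) < 0.01) {
    warning("Metropolis acceptance rate below 1%; proposal step likely too large")
  }
  umbrella_window(bias, out, run_id = run_id, temperature = cfg$temperature)
}

#' Synthesize a two-run umbrella-sampling campaign
#'
#' Samples every window of a plan twice (two independently seeded runs),
#' writes one series file per window per run plus a JSON manifest of
#' `{center, k, series_path, run_id, temperature}` entries, and returns
#' the manifest path.
#'
#' @param ls a `landscape`.
#' @param windows list of `bias_potential`s (see [make_windows()]).
#' @param seeds length-2 integer vector: base seed per run.
#' @param dir output directory (created if needed).
#' @param n_samples,burn_in,step_sd,stride,temperature sampler settings
#'   applied to every window.
#' @return path to the manifest JSON, invisibly; the parsed manifest as
#'   the `manifest` attribute.
#' @export
synthesize_us_campaign <- function(ls, windows, seeds, dir,
                                   n_samples = 5000L, burn_in = 1000L,
                                   step_sd = 2, stride = 10L,
                                   temperature = default_temperature) {
  if (length(seeds) != 2L) .validation_error("need one seed per run")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (run in 1:2) {
    for (i in seq_along(windows)) {
      cfg <- sampler_config(temperature = temperature, step_sd = step_sd,
                            n_samples = n_samples, burn_in = burn_in,
                            stride = stride,
                            seed = (seeds[run] + 7919L * i) %% 2147483647L)
      w <- sample_window(ls, windows[[i]], cfg, run_id = run)
      fn <- file.path(dir, sprintf("run%d_window%03d.tsv", run, i))
      write_series(data.frame(time = seq_along(w$samples), value = w$samples), fn,
                   header = sprintf("center %.4f k %.4f run %d", windows[[i]]$center,
                                    windows[[i]]$k, run))
      entries[[length(entries) + 1L]] <- list(
        center = windows[[i]]$center, k = windows[[i]]$k,
        series_path = basename(fn), run_id = run, temperature = temperature)
    }
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest_path, auto_unbox = TRUE, digits = NA)
  attr(manifest_path, "manifest") <- entries
  invisible(manifest_path)
}

# --- toy eversion trajectory -------------------------------------------------

# Rigid scaffold in which the four COM groups realise an exactly known
# pseudodihedral: the two phosphate-group COMs sit on the z axis (the
# rotation axis), the flanking-base COM has azimuth exactly 0, and the
# Watson-Crick-edge group is rotated about z by the scheduled angle.
.toy_topology <- function() {
  at <- function(name, resname, resid, element, x, y, z) {
    data.frame(name = name, resname = resname, resid = resid,
               element = element, x = x, y = y, z = z,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    # four flanking "bases": mirror pairs in y so the joint COM azimuth is 0
    at("C1", "FLA", 1L, "C",  7.5,  2.0, -7.0), at("N1", "FLA", 1L, "N", 8.5,  1.2, -6.4),
    at("C1", "FLA", 2L, "C",  7.5, -2.0, -7.0), at("N1", "FLA", 2L, "N", 8.5, -1.2, -6.4),
    at("C1", "FLA", 3L, "C",  7.0,  2.6, -3.0), at("N1", "FLA", 3L, "N", 8.0,  1.6, -2.4),
    at("C1", "FLA", 4L, "C",  7.0, -2.6, -3.0), at("N1", "FLA", 4L, "N", 8.0, -1.6, -2.4),
    # 5' phosphate group: COM exactly (0, 0, 0)
    at("P", "PH5", 5L, "P", 0, 0, 0),
    at("OP1", "PH5", 5L, "O",  1.4, 0,  0.4), at("OP2", "PH5", 5L, "O", -1.4, 0,  0.4),
    at("O5'", "PH5", 5L, "O", 0,  1.4, -0.4), at("O3'", "PH5", 5L, "O", 0, -1.4, -0.4),
    # 3' phosphate group: COM exactly (0, 0, 6)
    at("P", "PH3", 6L, "P", 0, 0, 6),
    at("OP1", "PH3", 6L, "O",  1.4, 0, 6.4), at("OP2", "PH3", 6L, "O", -1.4, 0, 6.4),
    at("O5'", "PH3", 6L, "O", 0,  1.4, 5.6), at("O3'", "PH3", 6L, "O", 0, -1.4, 5.6),
    # Watson-Crick edge of the everting base (rotates about z)
    at("O6", "EVB", 7L, "O", 6.0,  0.8, 3.4),
    at("N1", "EVB", 7L, "N", 6.4,  0.0, 2.6),
    at("N2", "EVB", 7L, "N", 6.0, -0.9, 3.1),
    # co-rotating probe pair (fixed mutual distance) and a static probe
    at("PX", "PRB", 8L, "C", 8.0, 0.0, 3.0),
    at("PZ", "PRB", 8L, "C", 8.0, 0.0, 5.0),
    at("PY", "STP", 9L, "N", 11.0, 0.0, 0.0)
  )
  df <- do.call(rbind, rows)
  atoms <- data.frame(serial = seq_len(nrow(df)), name = df$name,
                      resname = df$resname, chain = "A", resid = df$resid,
                      element = df$element, mass = atomic_mass(df$element),
                      stringsAsFactors = FALSE)
  xyz <- as.matrix(df[, c("x", "y", "z")])
  # pre-rotate the edge template so its COM azimuth is exactly 0: the
  # scheduled rotation then equals the analytic pseudodihedral exactly
  evb <- atoms$resname == "EVB"
  m <- atoms$mass[evb]
  com <- colSums(xyz[evb, ] * m) / sum(m)
  xyz[evb, ] <- xyz[evb, ] %*% t(.rotz(-atan2(com[2], com[1]) * 180 / pi))
  list(atoms = atoms, xyz = xyz)
}

.rotz <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

#' Random proper rotation matrix
#'
#' Uniform over SO(3) (QR of a Gaussian matrix with determinant fix);
#' used for rigid-motion invariance checks.
#'
#' @param seed optional RNG seed.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Apply a rigid motion to every frame of a trajectory
#'
#' @param traj a `flip_traj`.
#' @param R 3x3 proper rotation matrix.
#' @param t length-3 translation (angstrom).
#' @return the transformed `flip_traj`.
#' @export
transform_traj <- function(traj, R = diag(3), t = c(0, 0, 0)) {
  for (f in seq_len(n_frames(traj))) {
    traj$xyz[, , f] <- traj$xyz[, , f] %*% t(R) +
      matrix(t, nrow(traj$atoms), 3, byrow = TRUE)
  }
  traj
}

#' Generate a toy eversion trajectory with exactly known angles
#'
#' A minimal duplex-like scaffold (flanking-base pseudo-atoms for P1, two
#' phosphate groups for P2/P3, a Watson-Crick-edge group for P4, plus
#' probe atoms) in which frame t is built by rotating the edge group and
#' probes about the P2-P3 axis so the analytic pseudodihedral equals
#' `schedule[t]` exactly. Optionally each frame is additionally tumbled by
#' a random rigid motion, which leaves all internal observables unchanged.
#'
#' @param schedule vector of target eversion angles, degrees; must lie in
#'   the principal unwrapped range (reference - 90, reference + 270).
#' @param seed RNG seed for tumbling.
#' @param tumble apply a random rigid motion per frame.
#' @param path optional output path; when given, the trajectory is also
#'   written as multi-model PDB.
#' @return a `flip_traj` with an attribute `definition`, the matching
#'   `eversion_definition` (reference angle 0).
#' @export
generate_toy_eversion_trajectory <- function(schedule, seed = 1L,
                                             tumble = FALSE, path = NULL) {
  if (length(schedule) < 1L) .validation_error("empty angle schedule")
  if (any(schedule <= -90 | schedule >= 270)) {
    .validation_error("schedule angles out of range: must lie in (-90, 270) ",
                      "for reference 0")
  }
  topo <- .toy_topology()
  rotating <- topo$atoms$resname %in% c("EVB", "PRB")
  nf <- length(schedule)
  xyz <- array(NA_real_, c(nrow(topo$atoms), 3L, nf))
  set.seed(seed)
  for (f in seq_len(nf)) {
    x <- topo$xyz
    x[rotating, ] <- x[rotating, , drop = FALSE] %*% t(.rotz(schedule[f]))
    if (tumble) {
      R <- random_rotation()
      tr <- stats::rnorm(3, 0, 10)
      x <- x %*% t(R) + matrix(tr, nrow(x), 3, byrow = TRUE)
    }
    xyz[, , f] <- x
  }
  traj <- new_flip_traj(topo$atoms, xyz)
  attr(traj, "definition") <- toy_eversion_definition()
  if (!is.null(path)) write_pdb(traj, path)
  traj
}

#' Eversion-angle definition matching the toy scaffold
#'
#' @return an `eversion_definition` with reference angle 0.
#' @export
toy_eversion_definition <- function() {
  p1 <- selection("flanking bases", "A", rep(1:4, each = 2),
                  rep(c("C1", "N1"), 4))
  p2 <- selection("5' phosphate", "A", 5L, c("P", "OP1", "OP2", "O5'", "O3'"))
  p3 <- selection("3' phosphate", "A", 6L, c("P", "OP1", "OP2", "O5'", "O3'"))
  p4 <- selection("WC edge", "A", 7L, c("O6", "N1", "N2"))
  eversion_definition(p1, p2, p3, p4, reference_angle = 0)
}

#' Generate a noisy Michaelis-Menten dataset
#'
#' `v0 = k_cat * phi * E_total * S / (K_M + S) * (1 + eps)`,
#' `eps ~ Normal(0, noise_sd)`, fully seeded.
#'
#' @param K_M Michaelis constant, nM.
#' @param k_cat turnover number, 1/s.
#' @param E_total total enzyme concentration, nM.
#' @param active_fraction active-enzyme fraction in (0, 1].
#' @param S substrate concentrations, nM.
#' @param noise_sd relative velocity noise (>= 0).
#' @param replicates number of replicates.
#' @param seed RNG seed.
#' @param enzyme,substrate labels.
#' @return a `kinetics_dataset`.
#' @export
generate_kinetics_data <- function(K_M, k_cat, E_total, active_fraction = 1,
                                   S = c(2, 5, 10, 20, 35, 50, 75, 100),
                                   noise_sd = 0.05, replicates = 3L, seed = 1L,
                                   enzyme = "WT", substrate = "oxoG") {
  if (K_M <= 0 || k_cat <= 0 || E_total <= 0 || noise_sd < 0) {
    .validation_error("parameters must be positive (noise_sd >= 0)")
  }
  set.seed(seed)
  Sv <- rep(S, replicates)
  rep_id <- rep(seq_len(replicates), each = length(S))
  v <- k_cat * active_fraction * E_total * Sv / (K_M + Sv)
  v <- v * (1 + stats::rnorm(length(Sv), 0, noise_sd))
  v <- pmax(v, 0)
  kinetics_dataset(Sv, v, rep_id, E_total = E_total,
                   active_fraction = active_fraction,
                   enzyme = enzyme, substrate = substrate)
}
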