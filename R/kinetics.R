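# Steady-state Michaelis-Menten kinetics: fits, specificity constants,
# active-fraction normalization and relative-activity reporting.

#' Assemble a steady-state kinetics dataset
#'
#' @param S substrate concentrations, nM (> 0).
#' @param v0 initial velocities, nM/s (>= 0), aligned with `S`.
#' @param replicate replicate identifiers aligned with `S`.
#' @param E_total total enzyme concentration, nM.
#' @param active_fraction fraction of catalytically competent enzyme
#'   (borohydride-trapping measurement), in (0, 1].
#' @param enzyme,substrate labels.
#' @return a `kinetics_dataset`.
#' @export
kinetics_dataset <- function(S, v0, replicate = 1L, E_total, active_fraction = 1,
                             enzyme = "WT", substrate = "oxoG") {
  if (any(S <= 0)) .validation_error("[S] must be > 0")
  if (any(v0 < 0)) .validation_error("v0 must be >= 0")
  if (length(S) != length(v0)) .validation_error("S and v0 lengths differ")
  if (active_fraction <= 0 || active_fraction > 1) {
    .validation_error("active_fraction must lie in (0, 1]")
  }
  if (E_total <= 0) .validation_error("E_total must be > 0")
  records <- data.frame(S = S, v0 = v0,
                        replicate = rep_len(replicate, length(S)))
  structure(list(records = records, E_total = E_total,
                 active_fraction = active_fraction, enzyme = enzyme,
                 substrate = substrate),
            class = "kinetics_dataset")
}

#' @export
print.kinetics_dataset <- function(x, ...) {
  cat(sprintf("<kinetics_dataset> %s / %s: %d points, %d replicate(s), [E]_active %.3g nM\n",
              x$enzyme, x$substrate, nrow(x$records),
              length(unique(x$records$replicate)), normalize_active(x)))
  invisible(x)
}

#' Active-enzyme concentration
#'
#' `[E]_active = active_fraction * [E]_total`; all turnover numbers
#' downstream refer to the active-enzyme concentration.
#'
#' @param dataset a `kinetics_dataset`.
#' @return active enzyme concentration, nM.
#' @export
normalize_active <- function(dataset) {
  phi <- dataset$active_fraction
  if (phi <= 0 || phi > 1) .validation_error("active_fraction must lie in (0, 1]")
  phi * dataset$E_total
}

new_mm_fit <- function(enzyme, substrate, mode, K_M, K_M_sd, k_cat, k_cat_sd,
                       k_sp, k_sp_sd, n_replicates) {
  structure(list(enzyme = enzyme, substrate = substrate, mode = mode,
                 K_M = K_M, K_M_sd = K_M_sd, k_cat = k_cat, k_cat_sd = k_cat_sd,
                 k_sp = k_sp, k_sp_sd = k_sp_sd, n_replicates = n_replicates),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (x$mode == "saturable") {
    cat(sprintf("<mm_fit> %s/%s: K_M %.3g +/- %.2g nM, k_cat %.3g +/- %.2g /s, k_sp %.3g +/- %.2g /nM/s (%d replicate(s))\n",
                x$enzyme, x$substrate, x$K_M, x$K_M_sd, x$k_cat, x$k_cat_sd,
                x$k_sp, x$k_sp_sd, x$n_replicates))
  } else {
    cat(sprintf("<mm_fit> %s/%s: linear-slope, k_sp %.3g +/- %.2g /nM/s (%d replicate(s))\n",
                x$enzyme, x$substrate, x$k_sp, x$k_sp_sd, x$n_replicates))
  }
  invisible(x)
}

.fit_one_replicate <- function(S, v0, Ea) {
  kcat0 <- max(v0) / Ea
  Km0 <- stats::median(S)
  fit <- minpack.lm::nlsLM(
    v0 ~ kcat * Ea * S / (Km + S),
    data = data.frame(S = S, v0 = v0, Ea = Ea),
    start = list(kcat = kcat0, Km = Km0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  if (any(!is.finite(co)) || any(co <= 0)) {
    stop("saturable fit converged to non-physical parameters")
  }
  co
}

#' Fit Michaelis-Menten parameters
#'
#' Nonlinear least-squares fit of `v0 = k_cat [E]_active [S] / (K_M + [S])`
#' per replicate; reported `K_M` and `k_cat` are replicate means with
#' replicate standard deviations. The specificity constant is
#' `k_sp = k_cat / K_M` (ratio of the reported means) with a
#' first-order-propagated standard deviation.
#'
#' @param dataset a `kinetics_dataset` with >= 3 distinct substrate
#'   concentrations per replicate.
#' @param pooled fit all points jointly instead of per replicate.
#' @return an `mm_fit` with `mode = "saturable"`. Warns when the largest
#'   sampled `[S]` is not comfortably above the fitted `K_M` (saturation
#'   poorly constrained).
#' @export
mm_fit <- function(dataset, pooled = FALSE) {
  Ea <- normalize_active(dataset)
  rec <- dataset$records
  reps <- if (pooled) list(rec) else split(rec, rec$replicate)
  for (r in reps) {
    if (length(unique(r$S)) < 3L) {
      .validation_error("need >= 3 distinct [S] per replicate for a saturable fit")
    }
  }
  co <- t(vapply(reps, function(r) .fit_one_replicate(r$S, r$v0, Ea), numeric(2)))
  kcat <- mean(co[, "kcat"]); kcat_sd <- stats::sd(co[, "kcat"])
  Km <- mean(co[, "Km"]); Km_sd <- stats::sd(co[, "Km"])
  ksp <- kcat / Km
  ksp_sd <- if (length(reps) > 1L) {
    ksp * sqrt((kcat_sd / kcat)^2 + (Km_sd / Km)^2)
  } else NA_real_
  if (max(rec$S) <= Km / 2) {
    warning("max [S] (", max(rec$S), " nM) does not exceed K_M/2; ",
            "saturation poorly constrained")
  }
  new_mm_fit(dataset$enzyme, dataset$substrate, "saturable", Km, Km_sd,
             kcat, kcat_sd, ksp, ksp_sd, length(reps))
}

#' Specificity constant from the linear part of v0 vs [S]
#'
#' For enzymes too impaired to resolve `K_M` and `k_cat` separately:
#' ordinary least squares of `v0` on `[S]` through the origin, per
#' replicate; `k_sp = slope / [E]_active`. Caller asserts the sampled
#' `[S]` lie well below saturation.
#'
#' @param dataset a `kinetics_dataset`.
#' @return an `mm_fit` with `mode = "linear-slope"` (`K_M`, `k_cat` NA).
#' @export
linear_ksp <- function(dataset) {
  Ea <- normalize_active(dataset)
  rec <- dataset$records
  reps <- split(rec, rec$replicate)
  slopes <- vapply(reps, function(r) sum(r$S * r$v0) / sum(r$S^2), numeric(1))
  if (any(slopes <= 0)) .validation_error("non-positive v0 vs [S] slope")
  ksp <- mean(slopes) / Ea
  ksp_sd <- if (length(reps) > 1L) stats::sd(slopes) / Ea else NA_real_
  new_mm_fit(dataset$enzyme, dataset$substrate, "linear-slope",
             NA_real_, NA_real_, NA_real_, NA_real_, ksp, ksp_sd, length(reps))
}

#' Relative activity of a mutant versus wild type
#'
#' `100 * k_sp(mutant) / k_sp(wild-type)`, rounded to one decimal. The
#' ratio uses the k_sp values as reported (2 significant figures), the
#' convention of published kinetics tables.
#'
#' @param mutant_ksp,wildtype_ksp specificity constants (or `mm_fit`s).
#' @param round_inputs round each k_sp to 2 significant figures before
#'   taking the ratio (default TRUE, the reporting convention).
#' @return percent, one decimal.
#' @export
relative_activity <- function(mutant_ksp, wildtype_ksp, round_inputs = TRUE) {
  if (inherits(mutant_ksp, "mm_fit")) mutant_ksp <- mutant_ksp$k_sp
  if (inherits(wildtype_ksp, "mm_fit")) wildtype_ksp <- wildtype_ksp$k_sp
  if (!is.finite(wildtype_ksp) || wildtype_ksp <= 0) {
    .validation_error("wild-type k_sp must be > 0")
  }
  if (round_inputs) {
    mutant_ksp <- signif(mutant_ksp, 2)
    wildtype_ksp <- signif(wildtype_ksp, 2)
  }
  round(100 * mutant_ksp / wildtype_ksp, 1)
}

.fmt_2sf <- function(x) {
  ifelse(is.na(x), "n/d",
         vapply(x, function(v) format(signif(v, 2), scientific = FALSE, trim = TRUE),
                character(1)))
}

#' Kinetic-parameter report table
#'
#' One row per enzyme with `K_M`, `k_cat` and `k_sp` at 2 significant
#' figures (linear-slope rows render `K_M`/`k_cat` as "n/d") and the
#' relative-activity column as 100 x the ratio of reported k_sp values,
#' one decimal.
#'
#' @param fits list of `mm_fit`s.
#' @param wildtype label of the wild-type (reference) entry.
#' @return data frame with columns enzyme, K_M_nM, k_cat_per_s,
#'   k_sp_per_nM_s, relative_activity_pct plus numeric `.k_sp` for
#'   downstream use.
#' @export
table_report <- function(fits, wildtype = "Wild-type") {
  labels <- vapply(fits, function(f) f$enzyme, character(1))
  if (anyDuplicated(labels)) .validation_error("duplicate enzyme labels")
  wt <- which(labels == wildtype)
  if (length(wt) != 1L) .validation_error("wild-type entry '", wildtype, "' not found")
  ksp <- vapply(fits, function(f) f$k_sp, numeric(1))
  rel <- vapply(ksp, relative_activity, numeric(1), wildtype_ksp = ksp[wt])
  data.frame(
    enzyme = labels,
    K_M_nM = .fmt_2sf(vapply(fits, function(f) f$K_M, numeric(1))),
    k_cat_per_s = .fmt_2sf(vapply(fits, function(f) f$k_cat, numeric(1))),
    k_sp_per_nM_s = .fmt_2sf(ksp),
    relative_activity_pct = rel,
    .k_sp = ksp,
    stringsAsFactors = FALSE
  )
}

#' Read kinetics measurements from CSV
#'
#' Columns: enzyme, substrate, replicate, S_nM, v0_nM_per_s, E_total_nM,
#' active_fraction. Returns one `kinetics_dataset` per (enzyme, substrate)
#' pair.
#'
#' @param path CSV path.
#' @return named list of `kinetics_dataset`s (names `enzyme/substrate`).
#' @export
read_kinetics_csv <- function(path) {
  if (!file.exists(path)) .validation_error("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("enzyme", "substrate", "replicate", "S_nM", "v0_nM_per_s",
            "E_total_nM", "active_fraction")
  missing <- setdiff(need, names(df))
  if (length(missing)) .validation_error("missing column(s): ",
                                         paste(missing, collapse = ", "))
  groups <- split(df, paste(df$enzyme, df$substrate, sep = "/"))
  lapply(groups, function(g) {
    kinetics_dataset(g$S_nM, g$v0_nM_per_s, g$replicate,
                     E_total = g$E_total_nM[1],
                     active_fraction = g$active_fraction[1],
                     enzyme = g$enzyme[1], substrate = g$substrate[1])
  })
}

#' Write a kinetics dataset as CSV
#'
#' @param dataset a `kinetics_dataset`.
#' @param path output path.
#' @param append append rows without a header.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(dataset, path, append = FALSE) {
  df <- data.frame(enzyme = dataset$enzyme, substrate = dataset$substrate,
                   replicate = dataset$records$replicate,
                   S_nM = dataset$records$S,
                   v0_nM_per_s = dataset$records$v0,
                   E_total_nM = dataset$E_total,
                   active_fraction = dataset$active_fraction)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(path)
}
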