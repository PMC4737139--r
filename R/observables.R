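# Eversion-angle binning of per-frame observables with two-run error bars.

new_binned_series <- function(centers, mean, error, n, width, label = "",
                              units = "", n_run1 = NULL, n_run2 = NULL) {
  structure(list(centers = centers, mean = mean, error = error, n = n,
                 width = width, label = label, units = units,
                 n_run1 = n_run1, n_run2 = n_run2),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  ok <- !is.na(x$mean)
  cat(sprintf("<binned_series> '%s'%s: %d bins of %.1f deg, %d non-empty\n",
              x$label, ifelse(nzchar(x$units), paste0(" (", x$units, ")"), ""),
              length(x$centers), x$width, sum(ok)))
  invisible(x)
}

#' Bin a per-frame observable by eversion angle (single run)
#'
#' Values whose paired angle falls in `[b, b+width)` are averaged
#' arithmetically; empty bins are masked.
#'
#' @param angle_series numeric vector of per-frame eversion angles (deg).
#' @param value_series numeric vector of per-frame observable values,
#'   aligned with `angle_series`.
#' @param width bin width in degrees (default 5, the reporting convention
#'   for angle-binned observables).
#' @param origin angle at which bin edges start.
#' @param label,units metadata carried into reports.
#' @return a `binned_series` with per-bin mean, count and masked error.
#' @export
bin_observable <- function(angle_series, value_series, width = 5,
                           origin = NULL, label = "", units = "") {
  if (length(angle_series) != length(value_series)) {
    .validation_error("angle and value series lengths differ (",
                      length(angle_series), " vs ", length(value_series), ")")
  }
  if (length(angle_series) == 0L) .validation_error("empty series")
  if (width <= 0) .validation_error("bin width must be > 0")
  if (is.null(origin)) origin <- floor(min(angle_series) / width) * width
  nb <- ceiling((max(angle_series) - origin) / width + 1e-12)
  nb <- max(nb, 1L)
  idx <- floor((angle_series - origin) / width) + 1L
  keep <- idx >= 1L & idx <= nb
  idx <- idx[keep]; vals <- value_series[keep]
  n <- tabulate(idx, nbins = nb)
  sums <- rep(0, nb)
  agg <- tapply(vals, idx, sum)
  sums[as.integer(names(agg))] <- agg
  m <- ifelse(n > 0, sums / pmax(n, 1L), NA_real_)
  centers <- origin + (seq_len(nb) - 0.5) * width
  new_binned_series(centers, m, rep(NA_real_, nb), n, width, label, units)
}

#' Combine two independent runs of a binned observable
#'
#' Mean of per-run means with run-difference errors:
#' `mean = (m1 + m2)/2`, `error = |m1 - m2|/2`. A bin is reported only
#' where both runs have at least `min_count` samples; otherwise it is
#' masked.
#'
#' @param binned_run1,binned_run2 `binned_series` with identical binning.
#' @param min_count minimum per-run samples for an unmasked bin.
#' @return combined `binned_series` carrying per-run counts.
#' @export
combine_runs <- function(binned_run1, binned_run2, min_count = 10L) {
  b1 <- binned_run1; b2 <- binned_run2
  if (length(b1$centers) != length(b2$centers) ||
      max(abs(b1$centers - b2$centers)) > 1e-9 ||
      abs(b1$width - b2$width) > 1e-12) {
    .validation_error("binning mismatch between runs")
  }
  ok <- !is.na(b1$mean) & !is.na(b2$mean) & b1$n >= min_count & b2$n >= min_count
  m <- ifelse(ok, (b1$mean + b2$mean) / 2, NA_real_)
  e <- ifelse(ok, abs(b1$mean - b2$mean) / 2, NA_real_)
  new_binned_series(b1$centers, m, e, b1$n + b2$n, b1$width, b1$label,
                    b1$units, n_run1 = b1$n, n_run2 = b2$n)
}

#' Compute and bin an observable along the eversion coordinate
#'
#' Evaluates the eversion angle and an arbitrary per-frame observable on
#' every frame of a trajectory, then bins the observable by angle.
#'
#' @param traj a `flip_traj`.
#' @param defn an `eversion_definition`.
#' @param observable a function `f(frame) -> scalar` (e.g. a closure over
#'   [atom_distance()] or [nonbonded_energy()] selections).
#' @param width bin width in degrees.
#' @param origin bin-edge origin (degrees).
#' @param label,units metadata.
#' @return a single-run `binned_series`.
#' @export
observable_pipeline <- function(traj, defn, observable, width = 5,
                                origin = NULL, label = "", units = "") {
  nf <- n_frames(traj)
  if (nf == 0L) .validation_error("empty trajectory")
  ang <- vals <- numeric(nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    ang[i] <- eversion_angle(fr, defn)
    vals[i] <- observable(fr)
  }
  bin_observable(ang, vals, width = width, origin = origin, label = label,
                 units = units)
}

#' Write a combined binned series as TSV
#'
#' Columns: bin_center_deg, mean, error, n_run1, n_run2.
#'
#' @param binned a `binned_series` (combined over runs, or single-run with
#'   `n_run2` absent).
#' @param path output path.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
write_binned_tsv <- function(binned, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("# bin_center_deg\tmean\terror\tn_run1\tn_run2", con)
  n1 <- if (is.null(binned$n_run1)) binned$n else binned$n_run1
  n2 <- if (is.null(binned$n_run2)) rep(0L, length(binned$centers)) else binned$n_run2
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  writeLines(sprintf("%.4f\t%s\t%s\t%d\t%d", binned$centers, fmt(binned$mean),
                     fmt(binned$error), as.integer(n1), as.integer(n2)), con)
  invisible(path)
}
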