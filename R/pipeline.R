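# End-to-end orchestration: manifest -> WHAM -> anchored two-run PMF,
# trajectory observables, and kinetics tables, with provenance headers.

.file_md5 <- function(path) unname(tools::md5sum(path))

.provenance <- function(config_path = NULL, seeds = NULL) {
  parts <- c(sprintf("generated by baseflip %s",
                     as.character(utils::packageVersion("baseflip"))))
  if (!is.null(config_path)) {
    parts <- c(parts, sprintf("config_md5 %s", .file_md5(config_path)))
  }
  if (!is.null(seeds)) parts <- c(parts, sprintf("seeds %s", paste(seeds, collapse = ",")))
  parts
}

#' Load an umbrella-window manifest
#'
#' JSON array of objects with fields `center`, `k`, `series_path`,
#' `run_id` and optionally `temperature`; relative series paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest JSON path.
#' @return list of `umbrella_window`s.
#' @export
read_window_manifest <- function(path) {
  if (!file.exists(path)) .validation_error("manifest not found: ", path)
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(entries) == 0L) .validation_error("empty manifest: ", path)
  base <- dirname(path)
  lapply(entries, function(e) {
    need <- c("center", "k", "series_path", "run_id")
    missing <- setdiff(need, names(e))
    if (length(missing)) .validation_error("manifest entry missing: ",
                                           paste(missing, collapse = ", "))
    sp <- e$series_path
    if (!file.exists(sp)) sp <- file.path(base, sp)
    if (!file.exists(sp)) .validation_error("series file not found: ", e$series_path)
    temp <- if (is.null(e$temperature)) default_temperature else e$temperature
    umbrella_window(bias_potential(e$center, e$k), read_series(sp)$value,
                    run_id = e$run_id, temperature = temp)
  })
}

#' Run the full free-energy pipeline on a two-run window manifest
#'
#' Per-run WHAM on a shared bin grid, anchoring at the intrahelical
#' reference, two-run combination with run-difference error bars, and
#' endpoint/barrier summary statistics. Optionally writes the PMF TSV and
#' a JSON summary with provenance.
#'
#' @param manifest_path path to the window manifest (both runs present).
#' @param bin_width WHAM bin width, degrees.
#' @param anchor anchor angle, degrees.
#' @param segment c(start, end) for summary statistics; defaults to the
#'   anchored range of covered bins.
#' @param out_dir optional output directory for `pmf.tsv` and
#'   `summary.json`.
#' @param half bias convention flag, see [bias_energy()].
#' @param tol,max_iter WHAM convergence settings.
#' @return list with `profile` (combined `pmf_profile`), `per_run`
#'   profiles, and `summary` (dG_endpoints, barrier).
#' @export
run_freeenergy <- function(manifest_path, bin_width = 1.0, anchor = 0,
                           segment = NULL, out_dir = NULL, half = FALSE,
                           tol = 1e-7, max_iter = 100000L) {
  windows <- read_window_manifest(manifest_path)
  run_ids <- vapply(windows, function(w) w$run_id, integer(1))
  if (!all(c(1L, 2L) %in% run_ids)) {
    .validation_error("manifest must contain both runs; missing run ",
                      setdiff(c(1L, 2L), run_ids))
  }
  all_s <- unlist(lapply(windows, function(w) w$samples))
  rng <- c(min(all_s), max(all_s))
  profiles <- lapply(1:2, function(r) {
    p <- wham(windows[run_ids == r], bin_width = bin_width, tol = tol,
              max_iter = max_iter, range = rng, half = half)
    anchor_zero(p, anchor)
  })
  combined <- two_run_error(profiles[[1]], profiles[[2]])
  if (is.null(segment)) {
    ok <- which(!is.na(combined$G))
    segment <- c(combined$bins[ok[1]], combined$bins[ok[length(ok)]])
  }
  summary <- barrier_and_endpoint_stats(combined, segment, interpolate = TRUE)
  summary$segment <- segment
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pmf_tsv(combined, file.path(out_dir, "pmf.tsv"),
                  header = .provenance(manifest_path))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(profile = combined, per_run = profiles, summary = summary)
}

#' Read an eversion-coordinate definition from JSON
#'
#' JSON object with arrays `p1`..`p4` of `"chain:resid:atomname"` triples
#' and an optional `reference_angle` (degrees, default 0).
#'
#' @param path JSON path.
#' @return an `eversion_definition`.
#' @export
read_eversion_config <- function(path) {
  if (!file.exists(path)) .validation_error("coordinate config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("p1", "p2", "p3", "p4")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) .validation_error("coordinate config missing: ",
                                         paste(missing, collapse = ", "))
  ref <- if (is.null(cfg$reference_angle)) 0 else cfg$reference_angle
  eversion_definition(parse_selection("p1", unlist(cfg$p1)),
                      parse_selection("p2", unlist(cfg$p2)),
                      parse_selection("p3", unlist(cfg$p3)),
                      parse_selection("p4", unlist(cfg$p4)),
                      reference_angle = ref)
}

#' Run angle-binned observables over two trajectory runs
#'
#' @param traj_run1,traj_run2 `flip_traj`s, one per independent run.
#' @param defn an `eversion_definition`.
#' @param observables named list of per-frame observable functions
#'   `f(frame) -> scalar`.
#' @param width bin width, degrees.
#' @param min_count per-run minimum bin count, see [combine_runs()].
#' @param out_dir optional directory; one TSV per observable.
#' @return named list of combined `binned_series`.
#' @export
run_observables <- function(traj_run1, traj_run2, defn, observables,
                            width = 5, min_count = 10L, out_dir = NULL) {
  if (is.null(names(observables)) || any(!nzchar(names(observables)))) {
    .validation_error("observables must be a named list")
  }
  # shared bin origin so the two runs can be combined
  origin <- floor(min(eversion_series(traj_run1, defn)$angle,
                      eversion_series(traj_run2, defn)$angle) / width) * width
  out <- lapply(names(observables), function(nm) {
    b1 <- observable_pipeline(traj_run1, defn, observables[[nm]], width = width,
                              origin = origin, label = nm)
    b2 <- observable_pipeline(traj_run2, defn, observables[[nm]], width = width,
                              origin = origin, label = nm)
    n <- min(length(b1$centers), length(b2$centers))
    for (f in c("centers", "mean", "error", "n")) {
      b1[[f]] <- b1[[f]][seq_len(n)]; b2[[f]] <- b2[[f]][seq_len(n)]
    }
    combine_runs(b1, b2, min_count = min_count)
  })
  names(out) <- names(observables)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      write_binned_tsv(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       header = .provenance())
    }
  }
  out
}

#' Run the kinetics reporting pipeline
#'
#' Reads a kinetics CSV, fits every enzyme (saturable Michaelis-Menten
#' fit, falling back to the linear-slope specificity constant when the
#' saturable fit is unavailable or fails) and assembles the report table
#' with relative activities versus the wild type.
#'
#' @param csv_path kinetics CSV (see [read_kinetics_csv()]).
#' @param wildtype wild-type enzyme label.
#' @param mode named character vector mapping enzyme labels to
#'   `"saturable"` or `"linear"`; unlisted enzymes use `"auto"`.
#' @param out_path optional TSV output path.
#' @return list with `fits` and `table` (see [table_report()]).
#' @export
run_kinetics <- function(csv_path, wildtype = "Wild-type", mode = character(),
                         out_path = NULL) {
  datasets <- read_kinetics_csv(csv_path)
  fits <- lapply(datasets, function(ds) {
    m <- if (ds$enzyme %in% names(mode)) mode[[ds$enzyme]] else "auto"
    if (m == "linear") return(linear_ksp(ds))
    if (m == "saturable") return(mm_fit(ds))
    tryCatch(mm_fit(ds), error = function(e) linear_ksp(ds))
  })
  tab <- table_report(unname(fits), wildtype = wildtype)
  if (!is.null(out_path)) {
    hdr <- paste0("# ", .provenance(csv_path))
    writeLines(hdr, out_path)
    suppressWarnings(utils::write.table(
      tab[, setdiff(names(tab), ".k_sp")], out_path, sep = "\t",
      row.names = FALSE, quote = FALSE, append = TRUE))
  }
  list(fits = fits, table = tab)
}
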