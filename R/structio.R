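# Structure, trajectory, time-series and parameter-table I/O.

# Standard atomic weights (amu) for the elements that occur in protein/DNA
# systems; lookups outside this set are an error rather than a silent zero.
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA. = 22.990, MG = 24.305, P = 30.973762, S = 32.06, CL = 35.45,
  K = 39.0983, CA = 40.078, MN = 54.938, FE = 55.845, ZN = 65.38,
  BR = 79.904, I = 126.904
)

#' Infer an element symbol from a PDB atom name
#'
#' Uses the leading alphabetic characters of the atom name, preferring a
#' two-letter match (e.g. `ZN`) and falling back to the first letter.
#' Digits and primes are ignored, so `C1'`, `OP1` and `1HB` resolve to
#' C, O and H respectively.
#'
#' @param name character vector of PDB atom names.
#' @return character vector of element symbols.
#' @export
element_from_name <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[^A-Za-z]", "", toupper(trimws(nm)))
    if (nchar(s) == 0L) stop("cannot infer element from atom name '", nm, "'")
    if (nchar(s) >= 2L && substr(s, 1, 2) %in% names(.atomic_masses) &&
        !substr(s, 1, 1) %in% c("C", "N", "O", "H", "P", "S")) {
      return(substr(s, 1, 2))
    }
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Standard atomic mass of an element
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses (amu).
#' @export
atomic_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    stop("no standard atomic mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

.validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("baseflip_validation_error", "error")))
}

# Pre-scan raw PDB lines so parse failures are reported with a line number
# and inconsistent MODEL atom counts are caught before handing off to bio3d.
.scan_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | rec == "ATOM" | rec == "HETATM"
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      .validation_error("malformed ATOM record at line ", i, ": too short")
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(xyz) || any(!is.finite(xyz))) {
      .validation_error("malformed ATOM record at line ", i,
                        ": non-numeric coordinates")
    }
  }
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    counts <- integer(0)
    cur <- NA_integer_
    for (i in seq_along(lines)) {
      if (model_starts[i]) cur <- 0L
      else if (grepl("^ENDMDL", lines[i])) { counts <- c(counts, cur); cur <- NA_integer_ }
      else if (is_atom[i] && !is.na(cur)) cur <- cur + 1L
    }
    if (length(unique(counts)) > 1L) {
      .validation_error("inconsistent atom counts across MODEL blocks: ",
                        paste(unique(counts), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records yields a single frame. All frames share one topology (atom
#' names, residues, chains, elements, masses); coordinates are in
#' angstroms and atom order is preserved as written.
#'
#' @param path path to a PDB file.
#' @return an object of class `flip_traj`: a list with `atoms` (data frame
#'   with columns serial, name, resname, chain, resid, element, mass) and
#'   `xyz`, an `n_atoms x 3 x n_frames` array.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) .validation_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  .scan_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  ele <- at$elesy
  missing_ele <- is.na(ele) | trimws(ele) == ""
  ele[missing_ele] <- element_from_name(at$elety[missing_ele])
  ele <- toupper(trimws(ele))
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    resname = at$resid,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resid = at$resno,
    element = ele,
    mass = atomic_mass(ele),
    stringsAsFactors = FALSE
  )
  xyz_mat <- pdb$xyz
  if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1)
  n_frames <- nrow(xyz_mat)
  n_atoms <- nrow(atoms)
  xyz <- array(NA_real_, c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    xyz[, , f] <- matrix(xyz_mat[f, ], ncol = 3, byrow = TRUE)
  }
  new_flip_traj(atoms, xyz)
}

new_flip_traj <- function(atoms, xyz) {
  stopifnot(nrow(atoms) == dim(xyz)[1], dim(xyz)[2] == 3)
  if (any(!is.finite(xyz))) .validation_error("non-finite coordinates in trajectory")
  structure(list(atoms = atoms, xyz = xyz), class = "flip_traj")
}

#' @export
print.flip_traj <- function(x, ...) {
  cat("<flip_traj> ", n_frames(x), " frame(s), ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), " residues\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `flip_traj`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Extract a single frame
#'
#' @param traj a `flip_traj`.
#' @param i frame index (1-based).
#' @return a `flip_frame`: list with `atoms` and an `n x 3` coordinate
#'   matrix `xyz`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) .validation_error("frame index out of range: ", i)
  structure(list(atoms = traj$atoms, xyz = traj$xyz[, , i, drop = TRUE]),
            class = "flip_frame")
}

#' @export
print.flip_frame <- function(x, ...) {
  cat("<flip_frame> ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' Writes fixed-column ATOM records; multiple frames are wrapped in
#' MODEL/ENDMDL blocks. Round-trips through [read_pdb()] to PDB precision
#' (1e-3 angstrom).
#'
#' @param traj a `flip_traj` (or `flip_frame`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  if (inherits(traj, "flip_frame")) {
    traj <- new_flip_traj(traj$atoms, array(traj$xyz, c(nrow(traj$atoms), 3, 1)))
  }
  at <- traj$atoms
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  fmt_atom <- function(i, xyz) {
    nm <- at$name[i]
    # PDB convention: 1-3 char names start in column 14
    nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            at$serial[i], nm_fmt, at$resname[i], at$chain[i], at$resid[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, at$element[i])
  }
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$xyz[, , f, drop = TRUE]
    writeLines(vapply(seq_len(nrow(at)), fmt_atom, character(1), xyz = xyz), con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Define an atom-group selection
#'
#' A selection is a set of (chain, resid, atom-name) triples resolved
#' against a frame's topology in the order given.
#'
#' @param label short label for error messages and reports.
#' @param chain,resid,name vectors (recycled to common length) identifying
#'   the member atoms.
#' @return a `group_selection`.
#' @export
selection <- function(label, chain, resid, name) {
  df <- data.frame(chain = as.character(chain), resid = as.integer(resid),
                   name = as.character(name), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) .validation_error("empty selection '", label, "'")
  if (anyDuplicated(df)) .validation_error("duplicate members in selection '", label, "'")
  structure(list(label = label, members = df), class = "group_selection")
}

#' Parse selections from "chain:resid:atomname" strings
#'
#' @param label selection label.
#' @param spec character vector of `"chain:resid:atomname"` triples.
#' @return a `group_selection`.
#' @export
parse_selection <- function(label, spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) .validation_error("bad selection triple(s): ",
                                  paste(spec[bad], collapse = ", "))
  m <- do.call(rbind, parts)
  selection(label, m[, 1], as.integer(m[, 2]), m[, 3])
}

#' Resolve a selection against a frame
#'
#' @param frame a `flip_frame` (or `flip_traj`; topology only is used).
#' @param sel a `group_selection`.
#' @return integer vector of atom row indices, in selection order.
#' @export
resolve_selection <- function(frame, sel) {
  stopifnot(inherits(sel, "group_selection"))
  at <- frame$atoms
  key <- paste(at$chain, at$resid, at$name, sep = ":")
  want <- paste(sel$members$chain, sel$members$resid, sel$members$name, sep = ":")
  idx <- match(want, key)
  if (anyNA(idx)) {
    .validation_error("selection '", sel$label, "': unresolved member(s): ",
                      paste(want[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Read a two-column (time, value) series
#'
#' Plain text, whitespace- or tab-separated, `#` comment lines allowed.
#'
#' @param path input path.
#' @return data frame with columns `time` and `value`.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) .validation_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) .validation_error("empty series file: ", path)
  out_t <- out_v <- numeric(sum(keep))
  j <- 0L
  for (i in which(keep)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[1:2]))
    if (length(tok) < 2L || anyNA(vals)) {
      .validation_error("non-numeric series row at line ", i, " of ", path)
    }
    j <- j + 1L
    out_t[j] <- vals[1]; out_v[j] <- vals[2]
  }
  data.frame(time = out_t, value = out_v)
}

#' Write a two-column (time, value) series
#'
#' @param series data frame with columns `time` and `value` (or two numeric
#'   columns).
#' @param path output path.
#' @param header optional comment lines written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("%.10g\t%.10g", series[[1]], series[[2]]), con)
  invisible(path)
}

#' Read a nonbonded parameter table
#'
#' Tab-separated columns: `resname`, `atom`, `charge` (e), `epsilon`
#' (kcal/mol), `rmin_half` (angstrom). `#` comments allowed.
#'
#' @param path input path.
#' @return a `param_set` data frame keyed by (resname, atom).
#' @export
read_param_table <- function(path) {
  if (!file.exists(path)) .validation_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) .validation_error("empty parameter table: ", path)
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 5L) .validation_error("short parameter row at line ", i, " of ", path)
    num <- suppressWarnings(as.numeric(tok[3:5]))
    if (anyNA(num)) .validation_error("non-numeric parameter row at line ", i, " of ", path)
    rows[[k]] <- data.frame(resname = tok[1], atom = tok[2], charge = num[1],
                            epsilon = num[2], rmin_half = num[3],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (any(out$epsilon < 0)) .validation_error("negative epsilon in ", path)
  if (any(out$rmin_half <= 0)) .validation_error("non-positive rmin_half in ", path)
  if (anyDuplicated(out[, c("resname", "atom")])) {
    .validation_error("duplicate (resname, atom) key in ", path)
  }
  class(out) <- c("param_set", "data.frame")
  out
}

#' Build a parameter set from vectors
#'
#' @param resname,atom,charge,epsilon,rmin_half parallel vectors.
#' @return a `param_set` data frame.
#' @export
param_set <- function(resname, atom, charge, epsilon, rmin_half) {
  out <- data.frame(resname = resname, atom = atom, charge = charge,
                    epsilon = epsilon, rmin_half = rmin_half,
                    stringsAsFactors = FALSE)
  if (any(out$epsilon < 0) || any(out$rmin_half <= 0)) {
    .validation_error("epsilon must be >= 0 and rmin_half > 0")
  }
  if (anyDuplicated(out[, c("resname", "atom")])) .validation_error("duplicate parameter key")
  class(out) <- c("param_set", "data.frame")
  out
}

#' Write a parameter table
#' @param params a `param_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# resname\tatom\tcharge\tepsilon\trmin_half", con)
  writeLines(sprintf("%s\t%s\t%.6f\t%.6f\t%.6f", params$resname, params$atom,
                     params$charge, params$epsilon, params$rmin_half), con)
  invisible(path)
}

#' Attach nonbonded parameters to a frame or trajectory
#'
#' Matches atoms by (resname, atom name); any unmatched atom is an error,
#' never a silent zero charge.
#'
#' @param x a `flip_frame` or `flip_traj`.
#' @param params a `param_set`.
#' @return `x` with `charge`, `epsilon`, `rmin_half` columns added to
#'   `x$atoms`.
#' @export
attach_params <- function(x, params) {
  at <- x$atoms
  key <- paste(at$resname, at$name)
  idx <- match(key, paste(params$resname, params$atom))
  if (anyNA(idx)) {
    .validation_error("unparameterized atom(s): ",
                      paste(unique(key[is.na(idx)]), collapse = ", "))
  }
  at$charge <- params$charge[idx]
  at$epsilon <- params$epsilon[idx]
  at$rmin_half <- params$rmin_half[idx]
  x$atoms <- at
  x
}
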