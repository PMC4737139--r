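# Shared fixtures: all built in code at test time.

rms <- function(x) sqrt(mean(x^2))

# Hand-written PDB text with 5 atoms (fixed columns), used as a parsing fixture.
write_tiny_pdb <- function(path, models = 1L, jitter = 0) {
  atom_line <- function(serial, name, resname, chain, resid, x, y, z, ele) {
    nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
    sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, nm, resname, chain, resid, x, y, z, ele)
  }
  body <- function(dz) c(
    atom_line(1, "N", "GLY", "A", 264, 0.0, 0.0, 0.0 + dz, "N"),
    atom_line(2, "CA", "GLY", "A", 264, 1.458, 0.0, 0.0 + dz, "C"),
    atom_line(3, "C", "GLY", "A", 264, 2.0, 1.4, 0.0 + dz, "C"),
    atom_line(4, "O", "GLY", "A", 264, 3.2, 1.5, 0.1 + dz, "O"),
    atom_line(5, "P", "DG", "B", 7, -1.0, 2.0, 3.0 + dz, "P")
  )
  lines <- character(0)
  if (models == 1L) {
    lines <- body(0)
  } else {
    for (m in seq_len(models)) {
      lines <- c(lines, sprintf("MODEL     %4d", m), body((m - 1) * jitter), "ENDMDL")
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Frame with arbitrary atoms at given positions; masses from elements.
make_frame <- function(names, resnames, resids, elements, xyz, chain = "A",
                       charge = NULL, epsilon = NULL, rmin_half = NULL) {
  atoms <- data.frame(serial = seq_along(names), name = names,
                      resname = resnames, chain = chain, resid = resids,
                      element = elements, mass = atomic_mass(elements),
                      stringsAsFactors = FALSE)
  if (!is.null(charge)) {
    atoms$charge <- charge
    atoms$epsilon <- epsilon
    atoms$rmin_half <- rmin_half
  }
  structure(list(atoms = atoms, xyz = xyz), class = "flip_frame")
}

# Toy guanine-like residue: base ring atoms plus a Watson-Crick edge.
make_toy_guanine_frame <- function() {
  nm <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4")
  ele <- substr(nm, 1, 1)
  n <- length(nm)
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  xyz <- cbind(2.2 * cos(ang), 2.2 * sin(ang), rep(0, n))
  make_frame(nm, rep("DG", n), rep(7L, n), ele, xyz, chain = "B")
}

# Two-group frame for energetics: groups A (resid 1) and B (resid 2).
make_energy_frame <- function(xyzA, xyzB, qA, qB, epsA, epsB, rhA, rhB) {
  nA <- nrow(xyzA); nB <- nrow(xyzB)
  make_frame(paste0("A", seq_len(nA + nB)),
             rep(c("GRA", "GRB"), c(nA, nB)),
             rep(c(1L, 2L), c(nA, nB)),
             rep("C", nA + nB),
             rbind(xyzA, xyzB),
             charge = c(qA, qB), epsilon = c(epsA, epsB),
             rmin_half = c(rhA, rhB))
}

sel_resid <- function(frame, resid, label = paste0("resid", resid)) {
  at <- frame$atoms[frame$atoms$resid == resid, ]
  selection(label, at$chain, at$resid, at$name)
}

sel_atom <- function(chain, resid, name) selection(name, chain, resid, name)

# Anchored analytic landscape evaluated on a profile's bins.
analytic_on_profile <- function(ls, profile) {
  stopifnot(!is.na(profile$anchor))
  ab <- which.min(abs(profile$bins - profile$anchor))
  eval_landscape(ls, profile$bins) - eval_landscape(ls, profile$bins[ab])
}

# RMS deviation of an anchored profile from the generating landscape.
recovery_rms <- function(ls, profile) {
  ana <- analytic_on_profile(ls, profile)
  ok <- !is.na(profile$G)
  rms(profile$G[ok] - ana[ok])
}

# Build a pmf_profile directly from an analytic landscape (no sampling).
analytic_profile <- function(ls, bins) {
  G <- eval_landscape(ls, bins)
  baseflip:::new_pmf_profile(bins, G, rep(NA_real_, length(bins)),
                             rep(1000L, length(bins)))
}
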