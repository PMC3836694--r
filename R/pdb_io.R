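#' Structure and trajectory containers
#'
#' A `structure3d` holds one conformation: an atom table (name, element,
#' residue number/name, chain, coordinates in Angstrom) plus free-form
#' metadata. A `trajectory` couples a topology `structure3d` with an
#' `F x 3A` coordinate matrix (one flat `x1,y1,z1,x2,...` row per frame,
#' the bio3d xyz convention).
#'
#' @param atoms data.frame with columns `elety` (atom name), `element`,
#'   `resno` (1-based residue number), `resid` (3-letter residue name),
#'   `chain`, `x`, `y`, `z` and optionally `type` ("ATOM"/"HETATM").
#' @param metadata named list carried along unchanged.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, metadata = list()) {
  need <- c("elety", "element", "resno", "resid", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1) stopf("a structure needs at least one atom")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stopf("non-finite coordinates in atom table")
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  ## residue numbers must be non-decreasing within each chain
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch & atoms$type == "ATOM"]
    if (length(r) > 1 && any(diff(r) < 0))
      stopf("residue numbers decrease within chain '%s'", ch)
  }
  structure(list(atoms = atoms, metadata = metadata), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure3d: %d atoms, %d residues, chain(s) %s\n",
              nrow(a), length(unique(a$resno[a$type == "ATOM"])),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

natoms <- function(x) nrow(x$atoms)

#' @rdname structure3d
#' @param topology a `structure3d`.
#' @param xyz numeric matrix, frames by 3*atoms.
#' @param label free-text trajectory label (e.g. `"apo_run1"`).
#' @param frame_interval_ps frame spacing in picoseconds (metadata only).
#' @export
trajectory <- function(topology, xyz, label = "", frame_interval_ps = NA_real_) {
  if (!inherits(topology, "structure3d")) stopf("topology must be a structure3d")
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * natoms(topology))
    stopf("xyz has %d columns; topology has %d atoms (expected %d columns)",
          ncol(xyz), natoms(topology), 3 * natoms(topology))
  if (nrow(xyz) < 1) stopf("a trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stopf("non-finite coordinates in trajectory")
  structure(list(topology = topology, xyz = xyz, label = label,
                 frame_interval_ps = frame_interval_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s': %d frames x %d atoms\n",
              x$label, nrow(x$xyz), natoms(x$topology)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @export
nframes <- function(traj) nrow(traj$xyz)

## convert a bio3d pdb object into our atom table, applying the altLoc and
## insertion-code policy from the reader contract
atoms_from_bio3d <- function(pdb, path) {
  a <- pdb$atom
  ins <- !(is.na(a$insert) | a$insert == "")
  if (any(ins))
    stopf("%s: insertion codes are not supported (first at record %d)",
          path, which(ins)[1])
  keep_alt <- is.na(a$alt) | a$alt %in% c("", "A")
  if (!all(keep_alt)) {
    warnf("%s: dropping %d alternate-location atoms (keeping altLoc 'A'/blank)",
          path, sum(!keep_alt))
  }
  a <- a[keep_alt, , drop = FALSE]
  if (nrow(a) == 0) stopf("%s: no atoms after altLoc filtering", path)
  data.frame(elety = a$elety, element = a$elesy %||% "", resno = a$resno,
             resid = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
             x = a$x, y = a$y, z = a$z, type = a$type,
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records of the first model (a warning is issued when
#' additional models are present). Only the first protein chain -- or the
#' chain given by `chain` -- is kept, together with all HETATM records.
#' Files with insertion codes are rejected; alternate locations other than
#' "A"/blank are dropped with a warning.
#'
#' @param path PDB file.
#' @param chain chain identifier; default: first chain among ATOM records.
#' @return A [structure3d()].
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stopf("%s: unparsable PDB (%s)",
                                            path, conditionMessage(e)))
  nmodel <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  if (nmodel > 1)
    warnf("%s: %d models present; reading model 1 only", path, nmodel)
  atoms <- atoms_from_bio3d(pdb, path)
  xyz1 <- if (is.matrix(pdb$xyz)) pdb$xyz[1, ] else as.numeric(pdb$xyz)
  ## altLoc filtering may have dropped rows: recover coordinates from table
  keep_chain <- chain %||% atoms$chain[atoms$type == "ATOM"][1] %||% atoms$chain[1]
  if (!keep_chain %in% atoms$chain) stopf("%s: no chain '%s'", path, keep_chain)
  atoms <- atoms[atoms$chain == keep_chain | atoms$type == "HETATM", , drop = FALSE]
  if (nrow(atoms) == 0) stopf("%s: zero atoms", path)
  structure3d(atoms, metadata = list(source = path, n_models = nmodel))
}

## count ATOM/HETATM records per MODEL block (for precise mismatch reporting)
count_atoms_per_model <- function(path) {
  ln <- readLines(path, warn = FALSE)
  rec <- substr(ln, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(substr(ln, 1, 5) == "MODEL")
  if (length(model_starts) == 0) return(sum(is_atom))
  bounds <- c(model_starts, length(ln) + 1L)
  vapply(seq_along(model_starts), function(k) {
    sum(is_atom[bounds[k]:(bounds[k + 1] - 1L)])
  }, integer(1))
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL becomes one frame; every model must contain the same atoms in
#' the same order as `topology` (defaults to the first model of the first
#' file). Several files may be concatenated in the order given.
#'
#' @param paths one or more multi-model PDB files.
#' @param topology optional [structure3d()] the frames must match.
#' @param label trajectory label.
#' @param frame_interval_ps metadata, picoseconds between frames.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(paths, topology = NULL, label = "",
                            frame_interval_ps = NA_real_) {
  if (length(paths) < 1) stopf("no input files")
  frames <- NULL
  for (p in paths) {
    if (!file.exists(p)) stopf("no such file: %s", p)
    counts <- count_atoms_per_model(p)
    if (length(counts) == 0 || sum(counts) == 0) stopf("%s: empty file", p)
    if (is.null(topology)) {
      suppressWarnings(topology <- read_pdb(p))
    }
    bad <- which(counts != natoms(topology))
    if (length(bad))
      stopf("%s: model %d has %d atoms; topology has %d",
            p, bad[1], counts[bad[1]], natoms(topology))
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
    frames <- rbind(frames, xyz)
  }
  trajectory(topology, frames, label = label,
             frame_interval_ps = frame_interval_ps)
}

#' Write a trajectory (or structure) as a multi-model PDB file
#'
#' @param x a [trajectory()] or [structure3d()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  if (inherits(x, "structure3d")) {
    x <- trajectory(x, matrix(as.vector(t(as.matrix(x$atoms[, c("x", "y", "z")]))),
                              nrow = 1))
  }
  a <- x$topology$atoms
  pdb_frame <- function(v) {
    m <- frame_mat(v)
    sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$type, seq_len(nrow(a)),
            ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
            a$resid, a$chain, a$resno, m[, 1], m[, 2], m[, 3], 1, 0,
            a$element)
  }
  con <- file(path, "w")
  on.exit(close(con))
  nf <- nrow(x$xyz)
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(pdb_frame(x$xyz[f, ]), con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atom indices by residue range and/or atom name
#'
#' @param structure a [structure3d()].
#' @param resno integer vector of residue numbers to keep (default: all).
#' @param elety atom name(s) to keep, e.g. `"CA"` (default: all).
#' @param chain restrict to a chain (error if unknown).
#' @param type record type, e.g. `"ATOM"`.
#' @return Sorted integer indices into the atom table; an empty selection
#'   triggers a warning.
#' @export
select_atoms <- function(structure, resno = NULL, elety = NULL, chain = NULL,
                         type = NULL) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) {
    if (!chain %in% a$chain) stopf("unknown chain '%s'", chain)
    keep <- keep & a$chain == chain
  }
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(type)) keep <- keep & a$type %in% type
  idx <- sort(which(keep))
  if (length(idx) == 0) warnf("atom selection is empty")
  idx
}

## Ca indices for a residue set (ATOM records only), in residue-number order
ca_indices <- function(structure, resno = NULL) {
  a <- structure$atoms
  keep <- a$elety == "CA" & a$type == "ATOM"
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  which(keep)
}

#' Subdomain residue-range maps
#'
#' A subdomain map names groups of inclusive 1-based residue ranges, e.g.
#' the four NBD subdomains of DnaK. `"dnak_default"` gives
#' I-A 1-36 + 111-180, I-B 37-110, II-A 181-226 + 311-383, II-B 230-310
#' (residues 227-229, the II-A/II-B junction coil, are deliberately
#' unassigned). Ranges must not overlap, within or across groups.
#'
#' @param spec `"dnak_default"` or a named list of groups, each a list of
#'   `c(first, last)` ranges.
#' @return An object of class `subdomain_map`.
#' @export
make_subdomain_map <- function(spec = "dnak_default") {
  if (identical(spec, "dnak_default")) {
    spec <- list(
      "I-A"  = list(c(1, 36), c(111, 180)),
      "I-B"  = list(c(37, 110)),
      "II-A" = list(c(181, 226), c(311, 383)),
      "II-B" = list(c(230, 310)))
  }
  if (!is.list(spec) || is.null(names(spec)) || any(names(spec) == ""))
    stopf("subdomain spec must be a named list of range lists")
  seen <- integer(0)
  for (g in names(spec)) {
    if (!is.list(spec[[g]])) spec[[g]] <- list(spec[[g]])
    for (r in spec[[g]]) {
      if (length(r) != 2 || r[1] > r[2])
        stopf("group '%s': invalid range [%s]", g, paste(r, collapse = ", "))
      res <- seq.int(r[1], r[2])
      if (any(res %in% seen))
        stopf("group '%s': range %d-%d overlaps another group", g, r[1], r[2])
      seen <- c(seen, res)
    }
  }
  structure(spec, class = "subdomain_map")
}

#' @rdname make_subdomain_map
#' @param map a `subdomain_map`.
#' @param groups group name(s); residues of all named groups are pooled.
#' @return `subdomain_residues`: sorted residue numbers of the group union.
#' @export
subdomain_residues <- function(map, groups) {
  bad <- setdiff(groups, names(map))
  if (length(bad)) stopf("unknown subdomain group(s): %s", paste(bad, collapse = ", "))
  sort(unique(unlist(lapply(groups, function(g)
    unlist(lapply(map[[g]], function(r) seq.int(r[1], r[2])))))))
}

#' @rdname make_subdomain_map
#' @param n_residues chain length to scale the DnaK map onto.
#' @details `scaled_subdomain_map()` rescales the DnaK subdomain boundaries
#'   proportionally onto a chain of `n_residues` residues; used by the
#'   synthetic generator for short test chains.
#' @export
scaled_subdomain_map <- function(n_residues) {
  if (n_residues == 383) return(make_subdomain_map("dnak_default"))
  if (n_residues < 40) stopf("chain too short for a scaled subdomain map")
  s <- function(i) max(1L, min(n_residues, as.integer(round(i * n_residues / 383))))
  make_subdomain_map(list(
    "I-A"  = list(c(1, s(36)), c(s(110) + 1, s(180))),
    "I-B"  = list(c(s(36) + 1, s(110))),
    "II-A" = list(c(s(180) + 1, s(226)), c(s(310) + 1, n_residues)),
    "II-B" = list(c(s(226) + 1, s(310)))))
}
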