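#' Structure model for property calculations
#'
#' A light container for per-atom coordinates: a data.frame with columns
#' `resno` (residue number, mapping to insertion positions), `resid`
#' (three- or one-letter residue name), `elety` (atom name, e.g. "CA"),
#' `element` (e.g. "C", "N"), `x`, `y`, `z`.
#'
#' @param atoms Data.frame as described above.
#' @return A `dip_structure`.
#' @export
structure_model <- function(atoms) {
  need <- c("resno", "elety", "element", "x", "y", "z")
  assert_that(all(need %in% names(atoms)),
              "atoms must have columns: %s", paste(need, collapse = ", "))
  assert_that(all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))),
              "coordinates must be finite")
  if (is.null(atoms$resid)) atoms$resid <- NA_character_
  structure(list(atoms = atoms), class = "dip_structure")
}

#' Read a PDB file into a structure model
#'
#' First model only; optional chain selection; ions, waters and other
#' non-protein records are discarded.
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier.
#' @return A `dip_structure`.
#' @export
read_structure <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  sel <- bio3d::atom.select(pdb, "protein", chain = chain)
  at <- pdb$atom[sel$atom, ]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  structure_model(data.frame(
    resno = at$resno, resid = at$resid, elety = trimws(at$elety),
    element = trimws(elem), x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE))
}

calpha_coords <- function(struct) {
  stopifnot(inherits(struct, "dip_structure"))
  ca <- struct$atoms[struct$atoms$elety == "CA", ]
  ca <- ca[order(ca$resno), ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

#' Inter-residue heavy-atom contact count
#'
#' Number of heavy-atom (non-hydrogen) pairs within `cutoff` between a
#' residue and residues at sequence separation of at least 2 (i, i+-1
#' excluded). A distance-cutoff stand-in for typed contact detection.
#'
#' @param struct A `dip_structure`.
#' @param position Residue number(s); default all residues.
#' @param cutoff Heavy-atom distance cutoff (Angstrom), default 4.5.
#' @return Named integer vector of contact counts (NA for residues with no
#'   resolved atoms).
#' @export
contact_density <- function(struct, position = NULL, cutoff = 4.5) {
  stopifnot(inherits(struct, "dip_structure"))
  at <- struct$atoms[struct$atoms$element != "H", ]
  if (is.null(position)) position <- sort(unique(at$resno))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  sep_ok <- abs(outer(at$resno, at$resno, "-")) >= 2
  close <- d <= cutoff & sep_ok
  out <- vapply(position, function(p) {
    rows <- at$resno == p
    if (!any(rows)) return(NA_integer_)
    as.integer(sum(close[rows, , drop = FALSE]))
  }, integer(1))
  stats::setNames(out, position)
}

#' Dihedral angle defined by four points
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi  # IUPAC sign
  if (ang <= -180) ang <- ang + 360
  ang
}

backbone_atom <- function(struct, resno, name) {
  at <- struct$atoms
  row <- which(at$resno == resno & at$elety == name)
  if (length(row) != 1) return(NULL)
  as.numeric(at[row, c("x", "y", "z")])
}

#' Backbone phi/psi dihedrals per residue
#'
#' @param struct A `dip_structure` with N, CA, C backbone atoms.
#' @return Data.frame with `position`, `phi`, `psi` in degrees (NA where
#'   neighbouring backbone atoms are missing, e.g. chain termini).
#' @export
phi_psi <- function(struct) {
  stopifnot(inherits(struct, "dip_structure"))
  resnos <- sort(unique(struct$atoms$resno))
  out <- data.frame(position = resnos, phi = NA_real_, psi = NA_real_)
  for (k in seq_along(resnos)) {
    r <- resnos[k]
    N <- backbone_atom(struct, r, "N")
    CA <- backbone_atom(struct, r, "CA")
    C <- backbone_atom(struct, r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    Cprev <- if (k > 1) backbone_atom(struct, resnos[k - 1], "C") else NULL
    Nnext <- if (k < length(resnos)) backbone_atom(struct, resnos[k + 1], "N") else NULL
    if (!is.null(Cprev)) out$phi[k] <- dihedral_angle(Cprev, N, CA, C)
    if (!is.null(Nnext)) out$psi[k] <- dihedral_angle(N, CA, C, Nnext)
  }
  out
}

# van der Waals radii (Angstrom) by element for SASA
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# near-uniform points on the unit sphere (golden-spiral construction)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake--Rupley)
#'
#' Sphere-point SASA with a rolling probe: each heavy atom is sampled with
#' `n_points` near-uniform points on its solvent-extended sphere; the
#' exposed fraction times the sphere area is the atom's SASA. The polar
#' component sums N/O atoms, the nonpolar component C/S atoms.
#'
#' @param struct A `dip_structure`.
#' @param probe Probe radius (Angstrom), default 1.4 (water).
#' @param n_points Sample points per atom (default 256).
#' @return Data.frame with `position`, `sasa_total`, `sasa_polar`,
#'   `sasa_nonpolar` (A^2) per residue.
#' @export
shrake_rupley_sasa <- function(struct, probe = 1.4, n_points = 256) {
  stopifnot(inherits(struct, "dip_structure"))
  at <- struct$atoms[struct$atoms$element != "H", ]
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .vdw_radii[at$element]
  assert_that(!anyNA(rad), "unknown element(s): %s",
              paste(unique(at$element[is.na(rad)]), collapse = ", "))
  rext <- rad + probe
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (rext[i] + rext)^2 & seq_len(n) != i)
    p <- sweep(pts * rext[i], 2, xyz[i, ], "+")
    if (length(neigh)) {
      buried <- rep(FALSE, n_points)
      for (j in neigh) {
        dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        buried <- buried | dj < rext[j]^2
        if (all(buried)) break
      }
      frac <- mean(!buried)
    } else frac <- 1
    atom_sasa[i] <- frac * 4 * pi * rext[i]^2
  }
  polar <- at$element %in% c("N", "O")
  resnos <- sort(unique(at$resno))
  out <- data.frame(
    position = resnos,
    sasa_total = vapply(resnos, function(r) sum(atom_sasa[at$resno == r]), 1),
    sasa_polar = vapply(resnos, function(r)
      sum(atom_sasa[at$resno == r & polar]), 1),
    sasa_nonpolar = vapply(resnos, function(r)
      sum(atom_sasa[at$resno == r & !polar]), 1))
  out
}

#' Backbone geometry, surface area and secondary-structure flags
#'
#' Combines per-residue phi/psi dihedrals, Shrake--Rupley SASA (total /
#' polar / nonpolar) and, when an annotation table is supplied,
#' alpha-helix and beta-sheet membership flags (no secondary-structure
#' assignment is computed from coordinates).
#'
#' @param struct A `dip_structure`.
#' @param ss_annotation Optional data.frame with `position` and `ss`
#'   (labels containing "H"/"helix" or "E"/"sheet").
#' @param probe,n_points Passed to [shrake_rupley_sasa()].
#' @return Per-residue data.frame: `position`, `phi`, `psi`, `sasa_total`,
#'   `sasa_polar`, `sasa_nonpolar`, and `helix`/`sheet` flags when
#'   annotated.
#' @export
backbone_and_surface <- function(struct, ss_annotation = NULL,
                                 probe = 1.4, n_points = 256) {
  ang <- phi_psi(struct)
  sas <- shrake_rupley_sasa(struct, probe = probe, n_points = n_points)
  out <- merge(ang, sas, by = "position", all = TRUE)
  if (!is.null(ss_annotation)) {
    assert_that(all(c("position", "ss") %in% names(ss_annotation)),
                "ss_annotation needs columns position, ss")
    ss <- ss_annotation$ss[match(out$position, ss_annotation$position)]
    out$helix <- grepl("H|helix", ss, ignore.case = TRUE)
    out$sheet <- grepl("E|sheet|strand", ss, ignore.case = TRUE)
  }
  out[order(out$position), ]
}
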