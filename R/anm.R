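#' Build an anisotropic network model from C-alpha coordinates
#'
#' Standard ANM: residues within `cutoff` of one another are connected by
#' Hookean springs of constant `gamma`; the 3N x 3N Hessian has
#' super-elements \eqn{H_{ij} = -\gamma (r_{ij} r_{ij}^T)/|r_{ij}|^2} for
#' connected pairs and diagonal blocks that enforce translational/rotational
#' invariance. A connected network has exactly six numerically zero
#' (rigid-body) modes.
#'
#' @param coords N x 3 matrix of C-alpha coordinates (Angstrom), or a
#'   `dip_structure` (its C-alpha records are used).
#' @param cutoff Spring cutoff distance (Angstrom), default 15.
#' @param gamma Uniform spring constant, default 1.
#' @param zero_tol Relative eigenvalue threshold below which a mode counts
#'   as rigid-body.
#' @return `dip_anm`: list with `hessian`, `evalues` (ascending),
#'   `evectors`, `n_zero` (must be 6), `coords`, `cutoff`, `gamma`.
#' @export
build_anm <- function(coords, cutoff = 15, gamma = 1, zero_tol = 1e-8) {
  if (inherits(coords, "dip_structure")) coords <- calpha_coords(coords)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  n <- nrow(coords)
  assert_that(n >= 4, "need at least 4 residues")
  assert_that(all(is.finite(coords)), "coordinates must be finite")
  d <- as.matrix(stats::dist(coords))
  contact <- d <= cutoff & upper.tri(d)
  pairs <- which(contact, arr.ind = TRUE)
  comp <- components_from_pairs(n, pairs)
  if (length(unique(comp)) > 1) {
    tab <- table(comp)
    stopf("network disconnected at cutoff %.1f A: %d components (sizes %s)",
          cutoff, length(tab), paste(tab, collapse = ", "))
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    rij <- coords[j, ] - coords[i, ]
    blk <- -gamma * tcrossprod(rij) / sum(rij^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  eig <- eigen(H, symmetric = TRUE)
  ev <- rev(eig$values)
  vec <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  n_zero <- sum(abs(ev) < zero_tol * max(abs(ev)))
  if (n_zero != 6) {
    stopf(paste0("degenerate network: %d near-zero modes (expected 6); ",
                 "collinear or otherwise singular geometry"), n_zero)
  }
  structure(list(hessian = H, evalues = ev, evectors = vec, n_zero = 6L,
                 coords = coords, cutoff = cutoff, gamma = gamma),
            class = "dip_anm")
}

#' Per-residue mean effective stiffness from an ANM
#'
#' Mechanical-stiffness formulation: for each residue pair (i, j) the
#' compliance is the mode-sum of squared relative displacements projected on
#' the inter-residue direction, weighted by inverse eigenvalue over the
#' internal (non-rigid) modes; the effective force constant is its
#' reciprocal. The per-residue profile is the mean over all partners.
#' Stiffness scales linearly with the spring constant gamma and is invariant
#' under rigid-body transforms of the input coordinates.
#'
#' @param anm A `dip_anm`.
#' @return Numeric vector (length N) of strictly positive mean stiffness.
#' @export
stiffness_profile <- function(anm) {
  stopifnot(inherits(anm, "dip_anm"))
  n <- nrow(anm$coords)
  internal <- (anm$n_zero + 1):(3 * n)
  lam <- anm$evalues[internal]
  U <- anm$evectors[, internal, drop = FALSE]
  kappa <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ii <- (3 * i - 2):(3 * i)
    for (j in seq_len(n)) {
      if (j <= i) next
      jj <- (3 * j - 2):(3 * j)
      e <- anm$coords[j, ] - anm$coords[i, ]
      e <- e / sqrt(sum(e^2))
      proj <- crossprod(U[ii, , drop = FALSE] - U[jj, , drop = FALSE], e)
      compliance <- sum(proj^2 / lam)
      kappa[i, j] <- kappa[j, i] <- 1 / compliance
    }
  }
  rowSums(kappa) / (n - 1)
}

#' Per-residue mean-square fluctuation from an ANM
#'
#' RMSF surrogate: the trace of each residue's 3 x 3 block of the Hessian
#' pseudo-inverse, i.e. the inverse-eigenvalue-weighted mode sum of squared
#' displacements, normalised to mean 1.
#'
#' @param anm A `dip_anm`.
#' @return Non-negative numeric vector of length N with mean 1.
#' @export
fluctuation_profile <- function(anm) {
  stopifnot(inherits(anm, "dip_anm"))
  n <- nrow(anm$coords)
  internal <- (anm$n_zero + 1):(3 * n)
  lam <- anm$evalues[internal]
  U <- anm$evectors[, internal, drop = FALSE]
  msf <- vapply(seq_len(n), function(i) {
    ii <- (3 * i - 2):(3 * i)
    sum(colSums(U[ii, , drop = FALSE]^2) / lam)
  }, numeric(1))
  msf / mean(msf)
}
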