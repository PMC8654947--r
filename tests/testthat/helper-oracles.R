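# Independent oracle implementations and fixtures. These transcribe the
# published formulas directly (written before and independently of the
# package internals) so the pipeline can be checked against them.

# ---- enrichment statistic oracles ----

# per-position log-ratio enrichment, bare formula
oracle_raw <- function(h, l) {
  log((0.5 + h) / sum(0.5 + h)) - log((0.5 + l) / sum(0.5 + l))
}

oracle_se <- function(ch, cl, th, tl) {
  sqrt(1 / (ch + 0.5) + 1 / (cl + 0.5) + 1 / (th + 0.5) + 1 / (tl + 0.5))
}

# closed-form REML between-replicate variance for exactly two replicates:
# the single contrast z1 - z2 ~ N(0, v1 + v2 + 2M)
oracle_M_2rep <- function(z1, z2, v1, v2) {
  max(0, ((z1 - z2)^2 - v1 - v2) / 2)
}

oracle_combine <- function(z, se, M) {
  w <- sqrt(M + se^2)
  sum(z * w / sum(w))
}

# ---- toy structures ----

# non-planar helical bead chain (alpha-helix-like geometry)
helix_chain <- function(n, radius = 2.3, rise = 1.5, turn = 100) {
  t <- (seq_len(n) - 1) * turn * pi / 180
  cbind(radius * cos(t), radius * sin(t), rise * (seq_len(n) - 1))
}

compact_cluster <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 4), n, 3)
}

rigid_transform <- function(xyz, angle = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  xyz %*% R + matrix(rep(shift, each = nrow(xyz)), nrow(xyz))
}

# independently coded ANM Hessian (explicit spring loop) for oracle use
oracle_hessian <- function(coords, cutoff, gamma = 1) {
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- coords[j, ] - coords[i, ]
      d2 <- sum(r^2)
      if (sqrt(d2) > cutoff) next
      for (a in 1:3) {
        for (b in 1:3) {
          v <- -gamma * r[a] * r[b] / d2
          H[3 * (i - 1) + a, 3 * (j - 1) + b] <- v
          H[3 * (j - 1) + a, 3 * (i - 1) + b] <- v
          H[3 * (i - 1) + a, 3 * (i - 1) + b] <-
            H[3 * (i - 1) + a, 3 * (i - 1) + b] - v
          H[3 * (j - 1) + a, 3 * (j - 1) + b] <-
            H[3 * (j - 1) + a, 3 * (j - 1) + b] - v
        }
      }
    }
  }
  H
}

# per-residue MSF from the Moore-Penrose pseudo-inverse of the oracle Hessian
oracle_msf <- function(coords, cutoff, gamma = 1) {
  H <- oracle_hessian(coords, cutoff, gamma)
  G <- MASS::ginv(H)
  n <- nrow(coords)
  vapply(seq_len(n), function(i) {
    ii <- (3 * i - 2):(3 * i)
    sum(diag(G[ii, ii]))
  }, numeric(1))
}

# ---- backbone construction (NeRF internal-coordinate placement) ----

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

place_atom <- function(A, B, C, r, theta_deg, chi_deg) {
  theta <- theta_deg * pi / 180
  chi <- chi_deg * pi / 180
  d2 <- c(-r * cos(theta), r * cos(chi) * sin(theta), r * sin(chi) * sin(theta))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  nv <- cross3(ab, bc); nv <- nv / sqrt(sum(nv^2))
  m <- cbind(bc, cross3(nv, bc), nv)
  as.numeric(m %*% d2 + C)
}

# backbone N/CA/C trace with the given phi/psi (omega fixed at 180)
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  atoms <- list()
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C <- CA + 1.525 * c(-cos(ang), sin(ang), 0)
  atoms[[1]] <- rbind(N, CA, C)
  for (i in 2:n) {
    Np <- atoms[[i - 1]][1, ]; CAp <- atoms[[i - 1]][2, ]; Cp <- atoms[[i - 1]][3, ]
    N <- place_atom(Np, CAp, Cp, 1.329, 116.2, psi[i - 1])
    CA <- place_atom(CAp, Cp, N, 1.458, 121.7, 180)
    C <- place_atom(Cp, N, CA, 1.525, 111.2, phi[i])
    atoms[[i]] <- rbind(N, CA, C)
  }
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(resno = i, elety = c("N", "CA", "C"),
               element = c("N", "C", "C"),
               x = atoms[[i]][, 1], y = atoms[[i]][, 2], z = atoms[[i]][, 3])
  }))
  structure_model(df)
}

# ---- exact-test enumeration oracle ----

# two-sided Fisher's exact p for a 2x2 table by full enumeration of all
# tables with the observed margins (sum of probabilities <= observed)
fisher_enum_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n, k), numeric(1))
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# read-name truth extraction for simulated reads
truth_from_names <- function(ids) {
  list(position = as.integer(sub("^.*pos=([0-9]+).*$", "\\1", ids)),
       motif_id = sub("^.*motif=([^|]+).*$", "\\1", ids))
}

# small planted dataset reused across annotate/acceptance tests
planted_dataset <- function(L = 60, n_motifs = 30, seed_design = 21,
                            seed_truth = 22) {
  design <- make_design(L, n_motifs, seed = seed_design)
  truth <- simulate_true_fitness(design, seed = seed_truth)
  fm <- truth$fitness[, setdiff(colnames(truth$fitness),
                                design$control_motif_id)]
  list(design = design, truth = truth, fitness = fm)
}
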