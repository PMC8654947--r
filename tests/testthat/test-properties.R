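test_that("ANM has six rigid-body modes and rejects degenerate geometry", {
  xyz <- helix_chain(10)
  anm <- build_anm(xyz, cutoff = 8)
  expect_equal(anm$n_zero, 6L)
  expect_true(all(anm$evalues[-(1:6)] > 0))
  expect_equal(anm$hessian, t(anm$hessian))
  # eigenvalue spectrum agrees with an independently coded Hessian
  Ho <- oracle_hessian(xyz, cutoff = 8)
  expect_equal(sort(eigen(Ho, symmetric = TRUE)$values), anm$evalues,
               tolerance = 1e-10)
  # collinear chain is singular, disconnected network is reported
  expect_error(build_anm(cbind(3.5 * 1:6, 0, 0), cutoff = 8), "degenerate")
  far <- rbind(helix_chain(5), helix_chain(5) + 500)
  expect_error(build_anm(far, cutoff = 8), "disconnected")
  expect_error(build_anm(xyz[1:3, ], cutoff = 8), "at least 4")
})

test_that("ANM spectrum and profiles are invariant under rigid transforms", {
  xyz <- helix_chain(10)
  anm <- build_anm(xyz, cutoff = 8)
  anm_t <- build_anm(rigid_transform(xyz), cutoff = 8)
  expect_lt(max(abs(anm$evalues[-(1:6)] - anm_t$evalues[-(1:6)]) /
                  anm$evalues[-(1:6)]), 1e-8)
  st <- stiffness_profile(anm)
  fl <- fluctuation_profile(anm)
  expect_lt(max(abs(st - stiffness_profile(anm_t)) / st), 1e-8)
  expect_lt(max(abs(fl - fluctuation_profile(anm_t)) / fl), 1e-8)
})

test_that("chain fluctuations peak at the ends and match the oracle", {
  xyz <- helix_chain(10)
  anm <- build_anm(xyz, cutoff = 8)
  fl <- fluctuation_profile(anm)
  expect_true(all(fl >= 0))
  expect_gt(fl[1], fl[5])
  expect_gt(fl[10], fl[6])
  # profile proportional to the pseudo-inverse trace oracle
  skip_if_not_installed("MASS")
  msf_o <- oracle_msf(xyz, cutoff = 8)
  expect_equal(fl, msf_o / mean(msf_o), tolerance = 1e-6)
})

test_that("stiffness scales with gamma, opposes fluctuation on chains", {
  xyz <- helix_chain(10)
  anm <- build_anm(xyz, cutoff = 8)
  st <- stiffness_profile(anm)
  expect_true(all(st > 0))
  # terminal beads are the softest on a chain
  expect_true(which.min(st) %in% c(1, 10))
  # linearity in the spring constant
  st_g <- stiffness_profile(build_anm(xyz, cutoff = 8, gamma = 2.5))
  expect_equal(st_g, 2.5 * st, tolerance = 1e-10)
  # stiffness and fluctuation anti-correlate on the chain fixture
  fl <- fluctuation_profile(anm)
  expect_lt(stats::cor(st, fl, method = "spearman"), 0)
  # extended chain is globally softer than a compact cluster
  anm_c <- build_anm(compact_cluster(10), cutoff = 15)
  expect_lt(mean(anm$evalues[-(1:6)]), mean(anm_c$evalues[-(1:6)]))
})

test_that("windowed scale sums follow the published tables and add up", {
  # Kyte-Doolittle lookup: 3 alanines
  expect_equal(unname(windowed_scale_scores("AAA", "hydropathy",
                                            anchor = "whole")), 5.4)
  seqs <- "MKTAYIAKQR"
  # window length 1 "before" is the residue's own value
  w1 <- windowed_scale_scores(seqs, "hydropathy", lengths = 1,
                              anchor = "before")
  kd <- scale_table("hydropathy")
  expect_equal(unname(w1[, 1]), unname(kd[strsplit(seqs, "")[[1]]]))
  # additivity: window 3 "centered" equals the sum of three window-1 values
  w3 <- windowed_scale_scores(seqs, "hydropathy", lengths = 3,
                              anchor = "centered")
  vals <- kd[strsplit(seqs, "")[[1]]]
  for (i in 2:9) {
    expect_equal(unname(w3[i, 1]), sum(vals[(i - 1):(i + 1)]))
  }
  # truncation at termini: flagged, summed over available residues
  tr <- attr(w3, "truncated")
  expect_true(tr[1, 1]); expect_true(tr[10, 1])
  expect_false(any(tr[2:9, 1]))
  expect_equal(unname(w3[1, 1]), sum(vals[1:2]))
  # terminal windows for motifs
  wn <- windowed_scale_scores(seqs, "hydropathy", lengths = c(2, 4),
                              anchor = "nterm")
  expect_equal(as.vector(wn), unname(c(sum(vals[1:2]), sum(vals[1:4]))))
  wc <- windowed_scale_scores(seqs, "hydropathy", lengths = 2,
                              anchor = "cterm")
  expect_equal(as.vector(wc), unname(sum(vals[9:10])))
  # unknown residues rejected unless a fallback is supplied
  expect_error(windowed_scale_scores("AXA", "hydropathy", anchor = "whole"),
               "unknown residue")
  expect_equal(unname(windowed_scale_scores("AXA", "hydropathy",
                                            anchor = "whole", fallback = 0)),
               3.6)
  expect_error(scale_table("nope"), "unknown scale")
  expect_length(aa_scales(), 14)
})

test_that("contact counts respect the cutoff, exclusions and rigid motion", {
  # isolated residue: zero contacts
  iso <- structure_model(data.frame(resno = 1, elety = "CA", element = "C",
                                    x = 0, y = 0, z = 0))
  expect_equal(unname(contact_density(iso)), 0L)
  # two residues with exactly one atom pair at 4.0 A: one contact each;
  # adjacent residue pairs (|i-j| < 2) are excluded
  at <- data.frame(
    resno = c(1, 3, 4), elety = "CA", element = "C",
    x = c(0, 4, 8.2), y = 0, z = 0)
  s <- structure_model(at)
  cd <- contact_density(s, cutoff = 4.5)
  expect_equal(unname(cd), c(1L, 1L, 0L))  # 3-4 adjacent, excluded
  # invariant under rigid transforms
  xyz_t <- rigid_transform(as.matrix(at[, c("x", "y", "z")]))
  s_t <- structure_model(transform(at, x = xyz_t[, 1], y = xyz_t[, 2],
                                   z = xyz_t[, 3]))
  expect_equal(contact_density(s_t, cutoff = 4.5), cd)
})

test_that("backbone dihedrals round-trip through a constructed chain", {
  skip_if_not_installed("MASS")
  phi <- c(-57, -57, -135, -70, -57, -100)
  psi <- c(-47, -47, 135, 150, -47, 30)
  s <- build_backbone(phi, psi)
  ang <- phi_psi(s)
  expect_equal(ang$phi[-1], phi[-1], tolerance = 1e-6)
  expect_equal(ang$psi[-length(psi)], psi[-length(psi)], tolerance = 1e-6)
  expect_true(is.na(ang$phi[1]))
  expect_true(is.na(ang$psi[length(psi)]))
  expect_true(all(ang$phi[-1] > -180 & ang$phi[-1] <= 180))
})

test_that("Shrake-Rupley SASA matches the sphere closed form and burial", {
  iso <- structure_model(data.frame(resno = 1, elety = "CA", element = "C",
                                    x = 0, y = 0, z = 0))
  sa <- shrake_rupley_sasa(iso)
  expect_equal(sa$sasa_total, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
  expect_equal(sa$sasa_nonpolar, sa$sasa_total)
  expect_equal(sa$sasa_polar, 0)
  # nitrogen sphere is polar
  iso_n <- structure_model(data.frame(resno = 1, elety = "N", element = "N",
                                      x = 0, y = 0, z = 0))
  sa_n <- shrake_rupley_sasa(iso_n)
  expect_equal(sa_n$sasa_polar, 4 * pi * (1.55 + 1.4)^2, tolerance = 1e-12)
  # burying a residue among neighbours strictly reduces its SASA
  centre <- data.frame(resno = 1, elety = "CA", element = "C",
                       x = 0, y = 0, z = 0)
  shell <- expand.grid(x = c(-3, 3), y = c(-3, 3), z = c(-3, 3))
  shell$resno <- 3:10; shell$elety <- "CA"; shell$element <- "C"
  buried <- shrake_rupley_sasa(structure_model(rbind(centre, shell)))
  expect_lt(buried$sasa_total[1], sa$sasa_total)
  # rigid-transform invariance holds to the sphere-sampling resolution
  both <- rbind(centre, shell)
  xyz_t <- rigid_transform(as.matrix(both[, c("x", "y", "z")]))
  s_t <- structure_model(transform(both, x = xyz_t[, 1], y = xyz_t[, 2],
                                   z = xyz_t[, 3]))
  expect_equal(shrake_rupley_sasa(s_t)$sasa_total, buried$sasa_total,
               tolerance = 0.02)
})

test_that("PDB files round-trip through the structure reader", {
  s <- build_backbone(c(-57, -57, -57, -57), c(-47, -47, -47, -47))
  pdb <- tempfile(fileext = ".pdb")
  at <- s$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)), at$elety, "ALA", at$resno, at$x, at$y, at$z,
    at$element)
  writeLines(c(lines, "END"), pdb)
  s2 <- read_structure(pdb)
  expect_equal(nrow(s2$atoms), nrow(at))
  expect_equal(s2$atoms$x, at$x, tolerance = 1e-3)
  ang <- phi_psi(s2)
  expect_equal(ang$phi[-1], rep(-57, 3), tolerance = 1e-2)
})

test_that("feature assembly checks keys and provenance, round-trips tables", {
  d <- make_design(8, 3, seed = 70)
  tr <- simulate_true_fitness(d, seed = 71)
  props <- simulate_property_tables(d, tr, n_nuisance = 1, seed = 72)
  asm <- assemble_feature_table(
    d, recipient_sources = list(sim = props$recipient),
    motif_sources = list(sim = props$motif))
  expect_identical(asm$recipient$stiffness, props$recipient$stiffness)
  expect_identical(asm$motif$length_aa, props$motif$length_aa)
  prov <- attr(asm$recipient, "provenance")
  expect_true(all(prov == "sim"))
  # no structural source: sequence-only table, structural columns absent
  seq_only <- assemble_feature_table(
    d, recipient_sources = list(
      seq = recipient_scale_features(d$recipient_aa, scales = "hydropathy",
                                     lengths = c(1, 3), anchors = "before")))
  expect_false("stiffness" %in% names(seq_only$recipient))
  expect_equal(nrow(seq_only$recipient), 8)
  # duplicate feature names across sources rejected
  expect_error(assemble_feature_table(
    d, recipient_sources = list(a = props$recipient, b = props$recipient)),
    "duplicate")
  # partial key coverage rejected with the missing keys named
  expect_error(assemble_feature_table(
    d, recipient_sources = list(short = props$recipient[-1, ])),
    "missing key")
})
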