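test_that("dihedral angle follows the IUPAC convention on the half-open range", {
  # cis arrangement (both outer atoms on the same side) -> 0
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  # trans -> 180 mapped to -180 by the half-open convention
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)),
               -180)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")

  # random tetrads against an independently coded projection formula,
  # plus rigid-motion invariance
  for (s in 1:20) {
    set.seed(600 + s)
    pts <- matrix(rnorm(12), 4, 3)
    got <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(got, brute_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
    R <- random_rotation(s)
    tr <- rnorm(3, 0, 10)
    rot <- sweep(pts %*% R, 2, tr, `+`)
    expect_equal(dihedral_angle(rot[1, ], rot[2, ], rot[3, ], rot[4, ]), got,
                 tolerance = 1e-8)
  }
})

test_that("the ideal helix builder reproduces the requested torsions exactly", {
  h <- build_helix(strrep("A", 18))
  tor <- measure_torsions(h)
  expect_lt(max(abs(tor$phi[-1] + 57)), 1e-6)
  expect_lt(max(abs(tor$psi[-18] + 47)), 1e-6)
  # psi(i) + phi(i+1) is exactly -104 at the defaults
  expect_equal(unique(round(tor$psi[-18] + tor$phi[-1], 9)), -104)

  # rebuild from measured torsions -> identical backbone
  h2 <- build_helix(strrep("A", 18),
                    phi = c(-57, tor$phi[-1]),
                    psi = c(tor$psi[-18], -47),
                    omega = c(tor$omega[-18], 180))
  A <- as.matrix(h[h$elety != "O", c("x", "y", "z")])
  B <- as.matrix(h2[h2$elety != "O", c("x", "y", "z")])
  expect_lt(kabsch_rmsd(A, B), 1e-6)

  # builder bond lengths
  n1 <- as.numeric(h[h$resno == 5 & h$elety == "N", c("x", "y", "z")])
  ca1 <- as.numeric(h[h$resno == 5 & h$elety == "CA", c("x", "y", "z")])
  c1 <- as.numeric(h[h$resno == 5 & h$elety == "C", c("x", "y", "z")])
  expect_equal(sqrt(sum((ca1 - n1)^2)), 1.458, tolerance = 1e-6)
  expect_equal(sqrt(sum((c1 - ca1)^2)), 1.525, tolerance = 1e-6)

  expect_error(build_helix("A"), "at least 2")
  expect_error(build_helix("AZA"), "non-standard")
})

test_that("Kabsch superposition is optimal, proper, and bounded", {
  set.seed(71)
  A <- matrix(rnorm(30, 0, 3), 10, 3)

  # exact rigid copy -> zero RMSD, proper rotation
  R <- random_rotation(5)
  B <- sweep(A %*% R, 2, c(4, -2, 7), `+`)
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # one atom displaced by d -> aligned RMSD at most d/sqrt(N)
  B2 <- A
  B2[3, ] <- B2[3, ] + c(0.9, 0, 0)
  expect_lte(kabsch_rmsd(A, B2), 0.9 / sqrt(10) + 1e-9)

  # aligned RMSD never exceeds unaligned RMSD; matches bio3d
  for (s in 1:10) {
    set.seed(800 + s)
    X <- matrix(rnorm(24), 8, 3)
    Y <- X + matrix(rnorm(24, 0, 0.3), 8, 3)
    aligned <- kabsch_rmsd(X, Y)
    unaligned <- sqrt(mean(rowSums((X - Y)^2)))
    expect_lte(aligned, unaligned + 1e-12)
    ref <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE)
    expect_lt(abs(aligned - ref), 6e-4)  # bio3d rounds to 3 decimals
  }

  expect_error(kabsch_superpose(A, A[1:5, ]), "atom count")
})

test_that("backbone atom counts are three per residue of the interval", {
  expect_equal(backbone_atom_count(221, 238), 54L)
  expect_equal(backbone_atom_count(220, 238), 57L)
  expect_equal(backbone_atom_count(10, 9), 0L)
  expect_equal(backbone_atom_count(1, 5, atoms = c("N", "CA", "C", "O")), 20L)
})

test_that("trajectory RMSD series is exact for still frames and calibrated for noise", {
  h <- build_helix(strrep("L", 12))
  still <- dplyr::bind_rows(lapply(1:4, function(m) dplyr::mutate(h, model = m)))
  rs <- rmsd_series(still)
  expect_true(all(rs$rmsd < 1e-9))
  expect_equal(attr(rs, "sd_rmsd"), 0, tolerance = 1e-9)

  # isotropic Gaussian noise sigma: mean aligned RMSD ~ sqrt(3)*sigma with a
  # small alignment deflation; band verified against a direct simulation
  sigma <- 0.1
  set.seed(72)
  noisy <- dplyr::bind_rows(lapply(1:30, function(m) {
    f <- h
    f$x <- f$x + rnorm(nrow(f), 0, sigma)
    f$y <- f$y + rnorm(nrow(f), 0, sigma)
    f$z <- f$z + rnorm(nrow(f), 0, sigma)
    dplyr::mutate(f, model = m)
  }))
  ref <- coord_ref <- as.matrix(h[h$elety %in% c("N", "CA", "C"), c("x", "y", "z")])
  rs2 <- rmsd_series(noisy, reference = ref)
  expect_gt(attr(rs2, "mean_rmsd"), sqrt(3) * sigma * 0.85)
  expect_lt(attr(rs2, "mean_rmsd"), sqrt(3) * sigma * 1.1)

  # permutation invariance of the mean (last-frame reference held fixed)
  perm <- dplyr::mutate(noisy, model = dplyr::recode(model, `1` = 2L, `2` = 1L,
                                                     .default = model))
  rs3 <- rmsd_series(perm, reference = ref)
  expect_equal(attr(rs3, "mean_rmsd"), attr(rs2, "mean_rmsd"), tolerance = 1e-12)

  # mean-structure reference mode yields smaller or equal mean RMSD
  rs4 <- rmsd_series(noisy, reference = "mean")
  expect_lte(attr(rs4, "mean_rmsd"), attr(rs2, "mean_rmsd") + 1e-9)

  expect_error(rmsd_series(h), "at least 2 frames")
})

test_that("Ramachandran histograms conserve counts and localize the ideal helix", {
  h <- build_helix(strrep("A", 12))
  traj <- dplyr::bind_rows(lapply(1:10, function(m) dplyr::mutate(h, model = m)))
  rh <- rama_histogram(traj)
  expect_equal(sum(rh$count), 10L * 10L)       # 10 interior residues x 10 frames
  occupied <- rh[rh$count > 0, ]
  expect_equal(nrow(occupied), 1L)
  expect_equal(c(occupied$phi_lo, occupied$psi_lo), c(-60, -50))

  # jitter smaller than the bin width stays within one bin of the ideal bin
  set.seed(73)
  jit <- dplyr::bind_rows(lapply(1:15, function(m) {
    hj <- build_helix(strrep("A", 12),
                      phi = -57 + runif(12, -5, 5),
                      psi = -47 + runif(12, -5, 5))
    dplyr::mutate(hj, model = m)
  }))
  rhj <- rama_histogram(jit)
  expect_equal(sum(rhj$count), 15L * 10L)
  near <- rhj$phi_lo >= -70 & rhj$phi_lo <= -50 &
    rhj$psi_lo >= -60 & rhj$psi_lo <= -40
  expect_gte(sum(rhj$count[near]) / sum(rhj$count), 0.95)
})

test_that("helical wheel azimuths and hydrophobic moment match direct arithmetic", {
  # homopolymer: all weights equal, moment = |w| * |sum of unit vectors|
  hw <- helical_wheel(strrep("L", 18))
  az <- ((0:17) * 100) %% 360
  kd_l <- hydropathy_scale("kd")[["L"]]
  expected <- sqrt(sum(kd_l * cos(az * pi / 180))^2 +
                     sum(kd_l * sin(az * pi / 180))^2)
  expect_equal(attr(hw, "moment_magnitude"), expected, tolerance = 1e-9)

  # alternating strongly hydrophobic / strongly polar 18-mer
  seq_alt <- strrep("IR", 9)
  hw2 <- helical_wheel(seq_alt, scale = "eisenberg")
  w <- hydropathy_scale("eisenberg")[strsplit(seq_alt, "")[[1]]]
  mx <- sum(w * cos(az * pi / 180)); my <- sum(w * sin(az * pi / 180))
  expect_equal(attr(hw2, "moment_magnitude"), sqrt(mx^2 + my^2),
               tolerance = 1e-9)
  expect_gt(attr(hw2, "moment_magnitude"), 0)

  expect_error(helical_wheel("LLL"), "at least 5")
  expect_error(helical_wheel(strrep("L", 9), scale = "nope"))
})

test_that("an amphipathic helix puts its two residue classes on opposite faces", {
  # place leucines wherever the wheel azimuth points into the +x half
  # and glutamates elsewhere; the two classes must face apart and the
  # hydrophobic moment must point into the leucine face
  az <- ((0:17) * 100) %% 360
  aa <- ifelse(cos(az * pi / 180) > 0, "L", "E")
  hw <- helical_wheel(paste(aa, collapse = ""))
  circ_mean <- function(a) {
    (atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180))) * 180 / pi) %% 360
  }
  face_l <- circ_mean(hw$azimuth[hw$aa == "L"])
  face_e <- circ_mean(hw$azimuth[hw$aa == "E"])
  sep <- abs(face_l - face_e); sep <- min(sep, 360 - sep)
  expect_gt(sep, 90)
  dir_err <- abs(attr(hw, "moment_direction") - face_l)
  expect_lt(min(dir_err, 360 - dir_err), 45)
  # and the moment dwarfs that of a compositionally uniform helix
  expect_gt(attr(hw, "moment_magnitude"),
            attr(helical_wheel(strrep("L", 18)), "moment_magnitude"))
})

test_that("radial distribution functions bin pairs correctly and conserve counts", {
  # two atoms at a fixed distance: all mass in the bin containing d
  ref <- tibble::tibble(model = 1L, x = 0, y = 0, z = 0)
  tgt <- tibble::tibble(model = 1L, x = 3.27, y = 0, z = 0)
  prof <- rdf_profile(ref, tgt, bin_width = 0.1, r_max = 5)
  expect_equal(sum(prof$count), 1)
  expect_equal(prof$r_lo[prof$count == 1], 3.2)

  # count conservation when the bin width doubles
  set.seed(74)
  frames <- dplyr::bind_rows(lapply(1:3, function(m) {
    tibble::tibble(model = m, x = runif(40, 0, 10), y = runif(40, 0, 10),
                   z = runif(40, 0, 10))
  }))
  p1 <- rdf_profile(frames, frames, bin_width = 0.2, r_max = 4)
  p2 <- rdf_profile(frames, frames, bin_width = 0.4, r_max = 4)
  expect_equal(sum(p1$count), sum(p2$count))

  # uniform points in a box: g(r) plateaus near 1 at intermediate r
  set.seed(75)
  gas <- dplyr::bind_rows(lapply(1:8, function(m) {
    tibble::tibble(model = m, x = runif(250, 0, 20), y = runif(250, 0, 20),
                   z = runif(250, 0, 20))
  }))
  pg <- rdf_profile(gas, gas, bin_width = 0.25, r_max = 6, box = c(20, 20, 20))
  plateau <- pg$g[pg$r_mid > 3 & pg$r_mid < 6]
  expect_lt(abs(mean(plateau) - 1), 0.15)

  expect_error(rdf_profile(ref[0, ], tgt, bin_width = 0.1, r_max = 5),
               "non-empty")
})

test_that("span distances are rigid-motion invariant", {
  h <- build_helix(strrep("A", 18))
  expect_equal(helix_span_distance(h, 4, 4), 0)
  d0 <- helix_span_distance(h, 1, 14)
  # approximately 13 rises of ~1.5 A plus the radial chord
  expect_gt(d0, 17); expect_lt(d0, 23)

  R <- random_rotation(9)
  moved <- h
  xyz <- as.matrix(h[, c("x", "y", "z")]) %*% R
  moved$x <- xyz[, 1] + 5; moved$y <- xyz[, 2] - 3; moved$z <- xyz[, 3] + 11
  expect_equal(helix_span_distance(moved, 1, 14), d0, tolerance = 1e-9)

  expect_error(helix_span_distance(h, 1, 99), "missing")
})

test_that("torsion-window helix assignment flags interior alpha residues", {
  ideal <- assign_helix(measure_torsions(build_helix(strrep("A", 10))))
  expect_true(all(ideal$helical[2:9]))
  expect_false(ideal$helical[1])      # no phi at the N-terminus
  expect_false(ideal$helical[10])     # no psi at the C-terminus

  ext <- assign_helix(measure_torsions(
    build_helix(strrep("A", 10), phi = -120, psi = 120)))
  expect_false(any(ext$helical))

  # closed bounds: phi exactly -100 (and psi exactly -5) is still helical
  edge <- assign_helix(tibble::tibble(resno = 1:3,
                                      phi = c(NA, -100, -100.0001),
                                      psi = c(-40, -5, -40),
                                      omega = 180))
  expect_equal(edge$helical, c(FALSE, TRUE, FALSE))
})
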