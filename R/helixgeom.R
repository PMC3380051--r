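# Helix-geometry toolkit: ideal alpha-helix construction from internal
# coordinates, backbone dihedrals, Kabsch superposition/RMSD,
# Ramachandran histograms, helical-wheel hydrophobic moments and radial
# distribution functions.  Coordinates live in tibbles with columns
# model, resno, resid, elety, x, y, z (Angstrom), the same layout
# read_pdb() returns.

# Fixed builder geometry (Engh-Huber-style ideal values), recorded in
# the PDB REMARKs of written helices.
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# map to the half-open torsion range [-180, 180)
wrap_deg <- function(x) ((x + 180) %% 360) - 180

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention; the result lives on the half-open interval
#' `[-180, 180)` degrees (so an exact trans arrangement reports -180).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) {
    abort("dihedral undefined: three consecutive points are collinear")
  }
  m1 <- cross3(b2 / sqrt(sum(b2^2)), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_deg(rad2deg(atan2(y, x)))
}

# Natural-extension-reference-frame placement: position atom D given
# the three preceding atoms A-B-C, the C-D bond length, the B-C-D bond
# angle and the A-B-C-D torsion (degrees).
place_atom <- function(a, b, c_, length, angle, torsion) {
  th <- deg2rad(angle); chi <- deg2rad(torsion)
  d_local <- length * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(c_ + rot %*% d_local)
}

#' Build an ideal alpha-helix backbone
#'
#' Constructs N, CA, C' and O positions for each residue from internal
#' coordinates (N-CA 1.458, CA-C' 1.525, C'-N 1.329 Angstrom; angles
#' N-CA-C' 111.2, CA-C'-N 116.2, C'-N-CA 121.7 degrees), constraining
#' every backbone torsion to the requested `phi`, `psi` and `omega`.
#' Defaults build the canonical alpha helix (-57, -47).
#'
#' @param sequence Residue string (length >= 2).
#' @param phi,psi,omega Backbone torsions in degrees; scalars are
#'   recycled per residue.
#' @param first_resno Residue number of the first residue (default 1),
#'   so a helix can carry protein numbering such as 220-238.
#' @return A coordinate tibble (class `helix_model`) with columns
#'   `model`, `resno`, `resid`, `elety`, `x`, `y`, `z`.
#' @examples
#' h <- build_helix("GSVQCAGLISLPIAIEFT", first_resno = 220)
#' measure_torsions(h)
#' @export
build_helix <- function(sequence, phi = -57, psi = -47, omega = 180,
                        first_resno = 1L) {
  n <- nchar(sequence)
  if (n < 2L) abort("helix construction needs at least 2 residues")
  codes <- strsplit(sequence, "")[[1]]
  if (any(!codes %in% AA_ALPHABET)) {
    abort("sequence contains a non-standard residue")
  }
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)

  N <- matrix(NA_real_, n, 3); CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3); O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th <- deg2rad(ANGLE_N_CA_C)
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BOND_N_CA, ANGLE_C_N_CA, omega[i - 1])
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BOND_CA_C, ANGLE_N_CA_C, phi[i])
  }
  for (i in 1:n) {
    # carbonyl O anti-periplanar to the following N (psi + 180)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANGLE_CA_C_O, psi[i] + 180)
  }
  resno <- seq.int(first_resno, length.out = n)
  out <- tibble::tibble(
    model = 1L,
    resno = rep(resno, each = 4L),
    resid = rep(unname(AA_THREE[codes]), each = 4L),
    elety = rep(c("N", "CA", "C", "O"), n),
    x = as.numeric(t(cbind(N[, 1], CA[, 1], C[, 1], O[, 1]))),
    y = as.numeric(t(cbind(N[, 2], CA[, 2], C[, 2], O[, 2]))),
    z = as.numeric(t(cbind(N[, 3], CA[, 3], C[, 3], O[, 3]))))
  class(out) <- c("helix_model", class(out))
  out
}

backbone_xyz <- function(atoms, elety, resno) {
  row <- atoms[atoms$resno == resno & atoms$elety == elety, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  c(row$x[1L], row$y[1L], row$z[1L])
}

#' Measure backbone torsions of a coordinate set
#'
#' phi(i) = C'(i-1)-N(i)-CA(i)-C'(i); psi(i) = N(i)-CA(i)-C'(i)-N(i+1);
#' omega(i) = CA(i)-C'(i)-N(i+1)-CA(i+1).  Torsions without the needed
#' neighbor residue are `NA` (so phi is undefined at the first residue
#' and psi/omega at the last).
#'
#' @param atoms Coordinate tibble with one model (or a `model` column
#'   equal to a single value).
#' @return A tibble with columns `resno`, `phi`, `psi`, `omega`
#'   (degrees in `[-180, 180)`).
#' @export
measure_torsions <- function(atoms) {
  if ("model" %in% names(atoms) && length(unique(atoms$model)) > 1L) {
    abort("measure_torsions expects a single model; split by model first")
  }
  resnos <- sort(unique(atoms$resno))
  get <- function(el, r) backbone_xyz(atoms, el, r)
  res <- purrr::map(resnos, function(r) {
    phi <- psi <- omega <- NA_real_
    Np <- get("N", r); CAp <- get("CA", r); Cp <- get("C", r)
    if ((r - 1L) %in% resnos) {
      Cm <- get("C", r - 1L)
      if (!is.null(Cm) && !is.null(Np) && !is.null(CAp) && !is.null(Cp)) {
        phi <- dihedral_angle(Cm, Np, CAp, Cp)
      }
    }
    if ((r + 1L) %in% resnos) {
      Nn <- get("N", r + 1L); CAn <- get("CA", r + 1L)
      if (!is.null(Nn) && !is.null(Np) && !is.null(CAp) && !is.null(Cp)) {
        psi <- dihedral_angle(Np, CAp, Cp, Nn)
        if (!is.null(CAn)) omega <- dihedral_angle(CAp, Cp, Nn, CAn)
      }
    }
    tibble::tibble(resno = r, phi = phi, psi = psi, omega = omega)
  })
  dplyr::bind_rows(res)
}

coord_matrix <- function(atoms, resno_range = NULL,
                         atom_names = c("N", "CA", "C")) {
  sel <- atoms$elety %in% atom_names
  if (!is.null(resno_range)) {
    sel <- sel & atoms$resno >= resno_range[1L] & atoms$resno <= resno_range[2L]
  }
  sub <- atoms[sel, , drop = FALSE]
  sub <- sub[order(sub$resno, match(sub$elety, atom_names)), , drop = FALSE]
  as.matrix(sub[, c("x", "y", "z")])
}

#' Kabsch superposition
#'
#' Least-squares optimal rigid superposition of `B` onto `A` (matched
#' rows, N x 3 matrices); the rotation is proper (det = +1).
#'
#' @param A,B Matched coordinate matrices (rows = atoms, columns
#'   x, y, z), at least 3 non-degenerate atoms.
#' @return A list with `rmsd` (Angstrom), `rotation` (3 x 3),
#'   `translation` (length 3) such that `B %*% rotation + translation`
#'   superposes onto `A`, and `B_aligned`.
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) abort("coordinate sets differ in atom count")
  if (nrow(A) < 3L) abort("superposition needs at least 3 atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  H <- t(B0) %*% A0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  B_aligned <- B0 %*% R
  rmsd <- sqrt(mean(rowSums((B_aligned - A0)^2)))
  list(rmsd = rmsd, rotation = R, translation = ca - as.numeric(cb %*% R),
       B_aligned = sweep(B_aligned, 2L, ca, `+`))
}

#' Backbone RMSD after Kabsch superposition
#'
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(A, B) kabsch_superpose(A, B)$rmsd

#' Number of backbone atoms in a residue interval
#'
#' @param start,end Residue interval (1-based inclusive).
#' @param atoms Atom names counted per residue (default the alignment
#'   backbone `N`, `CA`, `C'`).
#' @return Integer count (`length(atoms) * region length`), 0 for an
#'   empty region.
#' @examples
#' backbone_atom_count(221, 238)  # 54
#' backbone_atom_count(220, 238)  # 57
#' @export
backbone_atom_count <- function(start, end, atoms = c("N", "CA", "C")) {
  len <- pmax(end - start + 1L, 0L)
  as.integer(length(atoms) * len)
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' Every frame is superposed (Kabsch, backbone selection) on the
#' reference and its RMSD recorded.  `reference = "last"` uses the last
#' frame; `reference = "mean"` uses the mean structure computed after
#' aligning all frames to the last frame.
#'
#' @param trajectory Multi-model coordinate tibble.
#' @param resno_range Optional residue interval used for alignment.
#' @param atom_names Backbone atom selection (default `N`, `CA`, `C'`).
#' @param reference `"last"`, `"mean"`, or a coordinate matrix.
#' @return A tibble `model`, `rmsd` with attributes `mean_rmsd` and
#'   `sd_rmsd`.
#' @export
rmsd_series <- function(trajectory, resno_range = NULL,
                        atom_names = c("N", "CA", "C"),
                        reference = c("last", "mean")) {
  models <- sort(unique(trajectory$model))
  if (length(models) < 2L) abort("a trajectory needs at least 2 frames")
  frames <- purrr::map(models, function(m) {
    fr <- coord_matrix(trajectory[trajectory$model == m, , drop = FALSE],
                       resno_range, atom_names)
    if (nrow(fr) == 0L) {
      abort(sprintf("selection is empty in frame %d", m))
    }
    fr
  })
  n_atoms <- vapply(frames, nrow, integer(1))
  if (length(unique(n_atoms)) != 1L) {
    abort(sprintf("selection is inconsistent across frames (frame %d)",
                  models[which(n_atoms != n_atoms[1L])[1L]]))
  }
  if (is.matrix(reference)) {
    ref <- reference
  } else {
    reference <- match.arg(reference)
    last <- frames[[length(frames)]]
    if (reference == "last") {
      ref <- last
    } else {
      aligned <- purrr::map(frames, function(f) kabsch_superpose(last, f)$B_aligned)
      ref <- Reduce(`+`, aligned) / length(aligned)
    }
  }
  rmsd <- vapply(frames, function(f) kabsch_rmsd(ref, f), numeric(1))
  out <- tibble::tibble(model = models, rmsd = rmsd)
  attr(out, "mean_rmsd") <- mean(rmsd)
  attr(out, "sd_rmsd") <- sd(rmsd)
  out
}

#' Ramachandran (phi, psi) histogram over a trajectory
#'
#' Bins the backbone torsions of the region's interior residues over
#' all frames on the half-open torus `[-180, 180)` with half-open bins
#' `[lo, lo + width)`; counts are conserved (their sum equals frames
#' times torsion-bearing residues).
#'
#' @param trajectory Multi-model coordinate tibble.
#' @param resno_range Optional residue interval.
#' @param bin_width Bin width in degrees (default 10; must divide 360).
#' @return A tibble (class `rama_histogram`) with columns `phi_lo`,
#'   `psi_lo` (lower bin edges) and `count`, carrying attributes
#'   `bin_width`, `n_frames` and `n_obs`.
#' @export
rama_histogram <- function(trajectory, resno_range = NULL, bin_width = 10) {
  stopifnot(360 %% bin_width == 0)
  models <- sort(unique(trajectory$model))
  edges <- seq(-180, 180 - bin_width, by = bin_width)
  nb <- length(edges)
  counts <- matrix(0L, nb, nb)
  n_obs <- 0L
  for (m in models) {
    tor <- measure_torsions(trajectory[trajectory$model == m, , drop = FALSE])
    if (!is.null(resno_range)) {
      tor <- tor[tor$resno >= resno_range[1L] & tor$resno <= resno_range[2L], ]
    }
    tor <- tor[!is.na(tor$phi) & !is.na(tor$psi), , drop = FALSE]
    if (nrow(tor) == 0L) next
    i <- floor((wrap_deg(tor$phi) + 180) / bin_width) + 1L
    j <- floor((wrap_deg(tor$psi) + 180) / bin_width) + 1L
    for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
    n_obs <- n_obs + nrow(tor)
  }
  out <- tidyr::expand_grid(phi_lo = edges, psi_lo = edges)
  out$count <- as.integer(counts[cbind(
    match(out$phi_lo, edges), match(out$psi_lo, edges))])
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- length(models)
  attr(out, "n_obs") <- n_obs
  class(out) <- c("rama_histogram", class(out))
  out
}

#' Helical wheel and hydrophobic moment
#'
#' Projects residues on the helical wheel (azimuth `(i - 1) * angle`
#' modulo 360) and computes the hydrophobic moment as the vector sum of
#' unit azimuth vectors weighted by a named hydropathy scale.
#'
#' @param sequence Residue string (length >= 5).
#' @param angle Rotation per residue in degrees (default 100, the ideal
#'   alpha helix).
#' @param scale Hydropathy scale name, `"kd"` or `"eisenberg"`.
#' @param first_resno Residue numbering offset for the output.
#' @return A tibble (class `helical_wheel`) with columns `resno`, `aa`,
#'   `azimuth` (degrees in [0, 360)) and `weight`, with attributes
#'   `moment_magnitude` and `moment_direction` (degrees).
#' @export
helical_wheel <- function(sequence, angle = 100, scale = "kd",
                          first_resno = 1L) {
  n <- nchar(sequence)
  if (n < 5L) abort("helical wheel needs at least 5 residues")
  w <- hydropathy_scale(scale)
  aa <- strsplit(sequence, "")[[1]]
  if (any(!aa %in% AA_ALPHABET)) abort("sequence contains a non-standard residue")
  az <- ((seq_len(n) - 1L) * angle) %% 360
  weight <- unname(w[aa])
  mx <- sum(weight * cos(deg2rad(az)))
  my <- sum(weight * sin(deg2rad(az)))
  out <- tibble::tibble(
    resno = seq.int(first_resno, length.out = n),
    aa = aa, azimuth = az, weight = weight)
  attr(out, "moment_magnitude") <- sqrt(mx^2 + my^2)
  attr(out, "moment_direction") <- (rad2deg(atan2(my, mx))) %% 360
  class(out) <- c("helical_wheel", class(out))
  out
}

#' Radial distribution function between two atom sets
#'
#' `g(r)` is the observed reference-target pair count per spherical
#' shell, normalized by the shell volume and the mean target density
#' (in `box` when given, else in the bounding box of each frame's
#' coordinates), averaged over frames.
#'
#' @param reference,target Coordinate tibbles with columns `model`,
#'   `x`, `y`, `z`; frames are matched by `model`.
#' @param bin_width Shell width in Angstrom (default 0.1).
#' @param r_max Maximum distance (must exceed `bin_width`).
#' @param box Optional periodic box lengths `c(lx, ly, lz)`: distances
#'   then use the minimum-image convention and the box volume defines
#'   the reference density (requires `r_max <= min(box)/2`).
#' @return A tibble (class `rdf_profile`) with columns `r_lo`, `r_hi`,
#'   `r_mid`, `count` (pairs summed over frames) and `g`, carrying
#'   attributes `n_frames` and `total_pairs_in_range`.
#' @export
rdf_profile <- function(reference, target, bin_width = 0.1, r_max,
                        box = NULL) {
  stopifnot(r_max > bin_width)
  models <- sort(unique(reference$model))
  if (length(models) == 0L || nrow(target) == 0L) {
    abort("rdf needs non-empty reference and target atom sets")
  }
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  g_acc <- numeric(nb)
  shell_vol <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  if (!is.null(box) && r_max > min(box) / 2) {
    abort("with a periodic box, r_max must not exceed half the shortest box length")
  }
  for (m in models) {
    rxyz <- as.matrix(reference[reference$model == m, c("x", "y", "z")])
    txyz <- as.matrix(target[target$model == m, c("x", "y", "z")])
    if (nrow(rxyz) == 0L || nrow(txyz) == 0L) {
      abort(sprintf("empty atom set in frame %d", m))
    }
    if (is.null(box)) {
      d2 <- outer(rowSums(rxyz^2), rep(1, nrow(txyz))) +
        outer(rep(1, nrow(rxyz)), rowSums(txyz^2)) -
        2 * rxyz %*% t(txyz)
      d <- sqrt(pmax(d2, 0))  # clamp tiny negatives from cancellation
    } else {
      # minimum-image distances in the periodic box
      d2 <- matrix(0, nrow(rxyz), nrow(txyz))
      for (k in 1:3) {
        dk <- outer(rxyz[, k], txyz[, k], `-`)
        dk <- dk - box[k] * round(dk / box[k])
        d2 <- d2 + dk^2
      }
      d <- sqrt(d2)
    }
    d <- d[d < r_max & d > 0]
    h <- tabulate(pmin(floor(d / bin_width) + 1L, nb), nbins = nb)
    counts <- counts + h
    if (is.null(box)) {
      all_xyz <- rbind(rxyz, txyz)
      vol <- prod(pmax(apply(all_xyz, 2L, max) - apply(all_xyz, 2L, min),
                       bin_width))
    } else {
      vol <- prod(box)
    }
    rho <- nrow(txyz) / vol
    g_acc <- g_acc + h / (nrow(rxyz) * shell_vol * rho)
  }
  out <- tibble::tibble(
    r_lo = edges[-length(edges)], r_hi = edges[-1L],
    r_mid = (edges[-1L] + edges[-length(edges)]) / 2,
    count = counts, g = g_acc / length(models))
  attr(out, "n_frames") <- length(models)
  attr(out, "total_pairs_in_range") <- sum(counts)
  class(out) <- c("rdf_profile", class(out))
  out
}

#' Distance between two named atoms of a model
#'
#' @param atoms Coordinate tibble (single model).
#' @param i,j Residue numbers.
#' @param atom Atom name (default `CA`).
#' @return Euclidean distance in Angstrom.
#' @export
helix_span_distance <- function(atoms, i, j, atom = "CA") {
  a <- backbone_xyz(atoms, atom, i)
  b <- backbone_xyz(atoms, atom, j)
  if (is.null(a) || is.null(b)) {
    abort(sprintf("atom %s missing for residue %d or %d", atom, i, j))
  }
  sqrt(sum((a - b)^2))
}

#' Flag helical residues by torsion windows
#'
#' An interior residue is helical iff its (phi, psi) pair falls inside
#' both closed windows; residues lacking phi or psi (the termini) are
#' never flagged.
#'
#' @param torsions Tibble from [measure_torsions()].
#' @param phi_window,psi_window Closed intervals in degrees (defaults
#'   `[-100, -30]` and `[-80, -5]`).
#' @return The torsion tibble with a logical `helical` column.
#' @export
assign_helix <- function(torsions, phi_window = c(-100, -30),
                         psi_window = c(-80, -5)) {
  torsions$helical <-
    !is.na(torsions$phi) & !is.na(torsions$psi) &
    torsions$phi >= phi_window[1L] & torsions$phi <= phi_window[2L] &
    torsions$psi >= psi_window[1L] & torsions$psi <= psi_window[2L]
  torsions
}

#' Write a built helix to PDB with geometry REMARKs
#'
#' @param helix A `helix_model` tibble from [build_helix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_helix_pdb <- function(helix, path) {
  write_pdb(helix, path, remarks = c(
    "IDEAL HELIX BUILT FROM INTERNAL COORDINATES",
    sprintf("BONDS (A): N-CA %.3f CA-C %.3f C-N %.3f C-O %.3f",
            BOND_N_CA, BOND_CA_C, BOND_C_N, BOND_C_O),
    sprintf("ANGLES (DEG): N-CA-C %.1f CA-C-N %.1f C-N-CA %.1f",
            ANGLE_N_CA_C, ANGLE_CA_C_N, ANGLE_C_N_CA)))
}
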