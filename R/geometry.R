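# Internal 3D geometry: vector helpers, dihedral measurement, NeRF-style
# internal-coordinate atom placement, and ideal alpha-helix generation.
# Coordinates are plain numeric length-3 vectors or n x 3 matrices, in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Measure a bond angle in degrees
#' @noRd
bond_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Measure the dihedral a-b-c-d in degrees, in (-180, 180]
#' @noRd
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Place atom D given reference atoms A, B, C so that |C-D| = bond,
# angle(B,C,D) = angle_deg and dihedral(A,B,C,D) = torsion_deg (NeRF).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Place CB from backbone N, CA, C: symmetric tetrahedral construction with
# L-amino-acid handedness. Both N-CA-CB and C-CA-CB equal `angle_deg`.
place_cb <- function(n, ca, c, bond = 1.53, angle_deg = 110.5) {
  u <- vunit(n - ca)
  v <- vunit(c - ca)
  a <- vunit(u + v)
  nrm <- vunit(vcross(u, v))
  cth <- cos(deg2rad(angle_deg))
  alpha <- cth / sum(a * u)
  beta2 <- 1 - alpha * alpha
  if (beta2 < 0) stop("backbone frame too distorted to place CB")
  beta <- sqrt(beta2)  # sign fixed for L-amino acids (calibrated on 1HEL)
  ca + bond * (alpha * a + beta * nrm)
}

# Ideal backbone geometry used throughout (lengths in Angstrom, angles deg).
.ideal_bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  phi = -57, psi = -47, omega = 180
)

# Generate n residues of ideal alpha-helical backbone (N, CA, C per residue)
# by sequential internal-coordinate construction. Returns a list of per-residue
# lists with N, CA, C coordinates.
nerf_helix_backbone <- function(n) {
  g <- .ideal_bb
  res <- vector("list", n)
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b_n_ca, 0, 0)
  ang <- deg2rad(g$a_n_ca_c)
  C1 <- CA1 + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  res[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n)[-1]) {
    p <- res[[i - 1]]
    Ni <- place_atom(p$N, p$CA, p$C, g$b_c_n, g$a_ca_c_n, g$psi)
    CAi <- place_atom(p$CA, p$C, Ni, g$b_n_ca, g$a_c_n_ca, g$omega)
    Ci <- place_atom(p$C, Ni, CAi, g$b_ca_c, g$a_n_ca_c, g$phi)
    res[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  res
}

# Cylindrical parameterization of the ideal helix, calibrated once per session
# from a long internal-coordinate helix: per-atom radius rho, azimuth offset
# relative to the residue phase, and z offset relative to the residue rise.
.helix_cal_env <- new.env(parent = emptyenv())

helix_calibration <- function() {
  if (!is.null(.helix_cal_env$cal)) return(.helix_cal_env$cal)
  n <- 50
  bb <- nerf_helix_backbone(n)
  ca <- t(vapply(bb, function(r) r$CA, numeric(3)))
  ctr <- colMeans(ca)
  sv <- svd(sweep(ca, 2, ctr))
  axis <- sv$v[, 1]
  # orient along increasing residue index
  if (sum((ca[n, ] - ca[1, ]) * axis) < 0) axis <- -axis
  e1 <- vunit(ca[1, ] - ctr - sum((ca[1, ] - ctr) * axis) * axis)
  e2 <- vcross(axis, e1)
  cyl <- function(p) {
    d <- p - ctr
    z <- sum(d * axis)
    r <- d - z * axis
    c(rho = vnorm(r), phi = atan2(sum(r * e2), sum(r * e1)), z = z)
  }
  # per-residue CA phase/rise from interior residues
  idx <- 10:40
  cac <- t(vapply(idx, function(i) cyl(bb[[i]]$CA), numeric(3)))
  dphi <- diff(cac[, "phi"])
  dphi <- ifelse(dphi < 0, dphi + 2 * pi, dphi)
  omega <- mean(dphi)          # rad per residue (~1.745 = 100 deg)
  rise <- mean(diff(cac[, "z"]))
  cal <- list(omega = omega, rise = rise, rho = numeric(0))
  # offsets of N, CA, C relative to the residue's CA phase and z
  for (at in c("N", "CA", "C")) {
    m <- t(vapply(idx, function(i) cyl(bb[[i]][[at]]), numeric(3)))
    dph <- m[, "phi"] - cac[, "phi"]
    dph <- atan2(sin(dph), cos(dph))
    cal[[at]] <- c(rho = mean(m[, "rho"]), dphi = mean(dph),
                   dz = mean(m[, "z"] - cac[, "z"]))
  }
  .helix_cal_env$cal <- cal
  cal
}

# Analytic ideal-helix backbone atoms for arbitrary residue numbers, phase and
# z placement; direction +1 (N->C along +z) or -1 (flipped about the x axis).
# phase_ref/z_ref: the CA of residue `ref_resno` sits at azimuth `phase_deg`
# (degrees) and height `z_ref`. Returns per-residue list of N, CA, C, O.
# `ref_resno` may be fractional (e.g. 109.5 to center between two residues).
analytic_helix <- function(resnos, axis_x = 0, axis_y = 0, direction = 1L,
                           phase_deg = 0, ref_resno = resnos[1], z_ref = 0) {
  cal <- helix_calibration()
  g <- .ideal_bb
  phase0 <- deg2rad(phase_deg)
  atom_pos <- function(i, at) {
    phi <- phase0 + cal$omega * (i - ref_resno) + cal[[at]][["dphi"]]
    z <- z_ref + cal$rise * (i - ref_resno) + cal[[at]][["dz"]]
    rho <- cal[[at]][["rho"]]
    p <- c(rho * cos(phi), rho * sin(phi), z)
    if (direction < 0) p <- c(p[1], -p[2], -p[3])  # 180 deg about x axis
    p + c(axis_x, axis_y, 0)
  }
  out <- vector("list", length(resnos))
  names(out) <- as.character(resnos)
  for (k in seq_along(resnos)) {
    i <- resnos[k]
    N <- atom_pos(i, "N"); CA <- atom_pos(i, "CA"); C <- atom_pos(i, "C")
    # O anti to the next residue's N across the C=O bond
    Nn <- atom_pos(i + 1, "N")
    O <- place_atom(Nn, CA, C, g$b_c_o, g$a_ca_c_o, 180)
    out[[k]] <- list(N = N, CA = CA, C = C, O = O)
  }
  out
}
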