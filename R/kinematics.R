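# Forward kinematics for building idealized backbones: the standard
# NeRF construction (place an atom at a given bond length, bond angle
# and dihedral from three reference atoms). Used by the synthetic
# fixture generator and as an independent construction against which
# the dihedral measurement is tested.

# ideal backbone geometry (Angstrom, degrees)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7)

#' Place an atom by internal coordinates
#'
#' Given three reference atoms `a`, `b`, `c`, returns the point `d` at
#' distance `bond` from `c`, with angle `b-c-d` equal to `angle`, and
#' dihedral `a-b-c-d` equal to `dihedral`.
#'
#' @param a,b,c numeric length-3 coordinates.
#' @param bond bond length (Angstrom).
#' @param angle bond angle (degrees).
#' @param dihedral dihedral angle (degrees).
#' @return numeric length-3 coordinate.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * cos(dih) * sin(ang),
          bond * sin(dih) * sin(ang))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nv <- cross3(ab, bc)
  nv <- nv / sqrt(sum(nv^2))
  m <- cbind(bc, cross3(nv, bc), nv)
  as.numeric(m %*% d2 + c)
}

#' Build an idealized backbone from torsion angles
#'
#' Places N, CA, C atoms for every residue by forward kinematics with
#' ideal bond lengths and angles, omega fixed at 180 degrees. The phi of
#' the first residue and the psi of the last are not used (they are
#' undefined on a chain).
#'
#' @param phi,psi numeric vectors of torsion angles (degrees), one per
#'   residue.
#' @return list of per-residue lists with `N`, `CA`, `C` coordinates.
#' @export
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  g <- BB_GEOM
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C <- CA + g$ca_c * c(cos(pi - ang), sin(pi - ang), 0)
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)[-1]) {
    p <- res[[i - 1]]
    Ni <- place_atom(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n, psi[i - 1])
    CAi <- place_atom(p$CA, p$C, Ni, g$n_ca, g$ang_c_n_ca, 180)
    Ci <- place_atom(p$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi[i])
    res[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  res
}
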