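# Backbone geometry: dihedral angles, the seven-domain (phi, psi)
# partition used as the structural motif of the torsion potentials, and
# the distance binning used by the pair potentials.

#' Dihedral angle of four points
#'
#' IUPAC sign convention; result in degrees in `[-180, 180)`.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return dihedral angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang >= 180) ang <- ang - 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone torsion angles of a chain
#'
#' Computes (phi, psi) for every residue. phi is undefined at the
#' N-terminus and psi at the C-terminus; both are undefined (`NA`)
#' wherever any required backbone atom (N, CA, C of the residue or its
#' neighbor) is missing.
#'
#' @param chain a [chain_structure] object.
#' @return data.frame with columns `phi` and `psi` (degrees, `NA` when
#'   undefined), one row per residue.
#' @export
torsion_angles <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  res <- chain$residues
  n <- length(res)
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  bb <- function(i, atom) res[[i]]$backbone[[atom]]
  has_bb <- function(i) {
    b <- res[[i]]$backbone
    !is.null(b$N) && !is.null(b$CA) && !is.null(b$C)
  }
  for (i in seq_len(n)) {
    if (!has_bb(i)) next
    if (i > 1 && has_bb(i - 1)) {
      phi[i] <- dihedral_angle(bb(i - 1, "C"), bb(i, "N"), bb(i, "CA"), bb(i, "C"))
    }
    if (i < n && has_bb(i + 1)) {
      psi[i] <- dihedral_angle(bb(i, "N"), bb(i, "CA"), bb(i, "C"), bb(i + 1, "N"))
    }
  }
  data.frame(phi = phi, psi = psi)
}

#' Default seven-region torsion-angle-domain table
#'
#' Partition of the (phi, psi) plane into seven labelled regions:
#' A (right-handed helical), C (helix C-cap region), B (extended),
#' P (polyproline-like), G (left-handed helical), E (extended,
#' positive phi), and O (everything else). Regions are half-open
#' `[lo, hi)` intervals so every angle pair maps to exactly one label.
#' The table is a plain configuration object: all downstream counting is
#' agnostic to the particular boundaries, which can be swapped for any
#' consistent seven-way partition.
#'
#' @param fallback_label label returned by [assign_domain] for undefined
#'   angles; never counted by the potentials.
#' @return an object of class `domain_table`.
#' @export
default_domain_table <- function(fallback_label = "-") {
  regions <- list(
    list(label = "A", phi = list(c(-120, 0)),    psi = list(c(-90, 30))),
    list(label = "C", phi = list(c(-120, 0)),    psi = list(c(30, 90))),
    list(label = "B", phi = list(c(-180, -120)), psi = list(c(60, 180), c(-180, -150))),
    list(label = "P", phi = list(c(-120, -30)),  psi = list(c(90, 180))),
    list(label = "G", phi = list(c(0, 120)),     psi = list(c(-30, 90))),
    list(label = "E", phi = list(c(0, 180)),     psi = list(c(90, 180), c(-180, -150)))
  )
  out <- list(regions = regions,
              labels = c(vapply(regions, `[[`, "", "label"), "O"),
              other_label = "O",
              fallback_label = fallback_label)
  class(out) <- "domain_table"
  out
}

in_intervals <- function(x, intervals) {
  for (iv in intervals) {
    if (x >= iv[1] && x < iv[2]) return(TRUE)
  }
  FALSE
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a
}

#' Assign a torsion-angle domain label
#'
#' Maps a (phi, psi) pair to one of the seven domain labels of `table`;
#' undefined (`NA`) angles map to the table's fallback label, which is
#' excluded from all potential counting.
#'
#' @param phi,psi angles in degrees (vectors allowed; recycled pairwise).
#' @param table a `domain_table`, by default [default_domain_table()].
#' @return character vector of labels.
#' @export
assign_domain <- function(phi, psi, table = default_domain_table()) {
  stopifnot(inherits(table, "domain_table"))
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  out <- character(n)
  for (i in seq_len(n)) {
    if (is.na(phi[i]) || is.na(psi[i])) {
      out[i] <- table$fallback_label
      next
    }
    ph <- wrap_angle(phi[i])
    ps <- wrap_angle(psi[i])
    lab <- table$other_label
    for (reg in table$regions) {
      if (in_intervals(ph, reg$phi) && in_intervals(ps, reg$psi)) {
        lab <- reg$label
        break
      }
    }
    out[i] <- lab
  }
  out
}

#' Distance binning for side-chain-center pair distances
#'
#' 25 core bins of 0.2 Angstrom width covering [3.0, 8.0) plus an
#' underflow bin (< 3.0) and an overflow bin (>= 8.0): 27 bins total.
#' Bin index 1 is underflow, 2..26 are the core bins (half-open
#' `[low + k*width, low + (k+1)*width)`), 27 is overflow.
#'
#' @param low,high core range bounds in Angstrom.
#' @param width core bin width in Angstrom.
#' @return an object of class `distance_binning`.
#' @export
distance_binning <- function(low = 3.0, high = 8.0, width = 0.2) {
  n_core <- round((high - low) / width)
  stopifnot(abs(n_core * width - (high - low)) < 1e-9, n_core >= 1)
  out <- list(low = low, high = high, width = width,
              n_core = n_core, n_bins = n_core + 2L)
  class(out) <- "distance_binning"
  out
}

#' Bin a side-chain-center distance
#'
#' @param d distance(s) in Angstrom; must be finite and non-negative.
#' @param binning a [distance_binning] object.
#' @return integer bin index in `1..binning$n_bins` (1 = underflow,
#'   `n_bins` = overflow).
#' @export
bin_distance <- function(d, binning = distance_binning()) {
  stopifnot(inherits(binning, "distance_binning"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("bin_distance: distances must be finite and non-negative")
  }
  k <- floor((d - binning$low) / binning$width)
  idx <- as.integer(k) + 2L
  idx[d < binning$low] <- 1L
  idx[d >= binning$high] <- binning$n_bins
  idx
}
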