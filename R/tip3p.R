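#' TIP3P interaction parameters
#'
#' Parameter set of the rigid three-site TIP3P water model used to score
#' water-water pair interactions: point charges on O and the two H sites, a
#' single oxygen-oxygen Lennard-Jones term, and the energy criterion below
#' which a pair is counted as hydrogen-bonded.
#'
#' @param q_O oxygen partial charge in e.
#' @param q_H hydrogen partial charge in e.
#' @param A Lennard-Jones repulsion coefficient, kcal A^12 / mol.
#' @param C Lennard-Jones attraction coefficient, kcal A^6 / mol.
#' @param coulomb_constant electrostatic prefactor in kcal A / (mol e^2), so
#'   that charges in e and distances in Angstrom give kcal/mol.
#' @param hbond_energy_criterion pair energy at or below which two waters are
#'   considered hydrogen-bonded, kcal/mol.
#' @return an object of class `tip3p_params`.
#' @export
tip3p_params <- function(q_O = -0.834, q_H = 0.417, A = 582000, C = 595,
                         coulomb_constant = 332.0636,
                         hbond_energy_criterion = -2.25) {
  stopifnot(A > 0, C > 0, q_O < 0, q_H > 0, hbond_energy_criterion < 0)
  structure(
    list(q_O = q_O, q_H = q_H, A = A, C = C,
         coulomb_constant = coulomb_constant,
         hbond_energy_criterion = hbond_energy_criterion),
    class = "tip3p_params")
}

#' Construct a water molecule
#'
#' A rigid three-site water: one oxygen and two hydrogens with 3D coordinates
#' in Angstrom. The three positions carry the TIP3P charge sites.
#'
#' @param oxygen,hydrogen1,hydrogen2 numeric xyz coordinates (length 3).
#' @param index integer identifier of the water within its frame.
#' @return an object of class `twn_water` with a 3 x 3 position matrix
#'   (rows O, H1, H2).
#' @export
water_molecule <- function(oxygen, hydrogen1, hydrogen2, index = 1L) {
  pos <- rbind(O = as.numeric(oxygen),
               H1 = as.numeric(hydrogen1),
               H2 = as.numeric(hydrogen2))
  if (ncol(pos) != 3 || !all(is.finite(pos)))
    stop("water atom positions must be finite xyz triples")
  for (h in 2:3) {
    d <- vnorm(pos[h, ] - pos[1, ])
    if (d <= 0.5 || d >= 1.5)
      stop(sprintf("O-H distance %.3f A outside (0.5, 1.5) for water %d",
                   d, as.integer(index)))
  }
  structure(list(index = as.integer(index), pos = pos), class = "twn_water")
}

#' TIP3P pair interaction energy
#'
#' Interaction energy between two rigid waters: the Coulomb sum over all nine
#' charge-site pairs plus the oxygen-oxygen Lennard-Jones term
#' A/r_OO^12 - C/r_OO^6, in kcal/mol.
#'
#' @param a,b `twn_water` objects.
#' @param params `tip3p_params`.
#' @return energy in kcal/mol (symmetric in a and b).
#' @export
pair_energy <- function(a, b, params = tip3p_params()) {
  stopifnot(inherits(a, "twn_water"), inherits(b, "twn_water"))
  pa <- a$pos
  pb <- b$pos
  # 3 x 3 site-site distance matrix, rows = sites of a, cols = sites of b;
  # distances from coordinate differences (no large-coordinate cancellation)
  r <- matrix(sqrt(rowSums((pa[rep(1:3, times = 3), ] -
                            pb[rep(1:3, each = 3), ])^2)), 3, 3)
  if (any(r < 1e-12))
    stop("singular geometry: coincident interaction sites between waters ",
         a$index, " and ", b$index)
  q <- c(params$q_O, params$q_H, params$q_H)
  roo <- r[1, 1]
  params$coulomb_constant * sum(outer(q, q) / r) +
    params$A / roo^12 - params$C / roo^6
}

# Vectorised pair energies for m water pairs. W1, W2 are m x 9 coordinate
# matrices (Ox Oy Oz H1x H1y H1z H2x H2y H2z); shift (m x 3), if given, is a
# rigid translation applied to every atom of the second water (minimum image).
pair_energies_bulk <- function(W1, W2, params, shift = NULL) {
  m <- nrow(W1)
  if (m == 0) return(numeric(0))
  if (!is.null(shift)) W2 <- W2 + shift[, rep(1:3, 3), drop = FALSE]
  q <- c(params$q_O, params$q_H, params$q_H)
  e <- numeric(m)
  roo <- NULL
  for (i in 1:3) {
    ci <- (3 * i - 3) + 1:3
    for (j in 1:3) {
      cj <- (3 * j - 3) + 1:3
      r <- sqrt(rowSums((W1[, ci, drop = FALSE] - W2[, cj, drop = FALSE])^2))
      if (any(r < 1e-12)) stop("singular geometry: coincident sites in pair list")
      e <- e + params$coulomb_constant * q[i] * q[j] / r
      if (i == 1 && j == 1) roo <- r
    }
  }
  e + params$A / roo^12 - params$C / roo^6
}
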