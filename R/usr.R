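# Ultrafast shape recognition (USR): alignment-free shape descriptors for 3D
# point sets and the Manhattan-based similarity score. Used here to compare
# the cloud of water-ring centers of mass against a ligand's heavy atoms.

.usr_refs <- c("ctd", "cst", "fct", "ftf")

# first three moments of a distance vector: mean, population standard
# deviation, signed cube root of the third central moment -- all in Angstrom
.moments3 <- function(d) {
  mu1 <- mean(d)
  mu2 <- sqrt(mean((d - mu1)^2))
  m3 <- mean((d - mu1)^3)
  c(mu1, mu2, sign(m3) * abs(m3)^(1 / 3))
}

#' USR shape descriptor of a point set
#'
#' Encodes a 3D point cloud by the first three moments of its distance
#' distributions to four reference locations: the centroid (ctd), the point
#' closest to the centroid (cst), the point farthest from the centroid
#' (fct), and the point farthest from fct (ftf). The 12 moments are laid out
#' in reference order ctd, cst, fct, ftf, three moments each. Rigid motions
#' of the point set leave the descriptor unchanged.
#'
#' @param points n x 3 numeric matrix of coordinates in Angstrom.
#' @return a `usr_descriptor`: numeric vector of 12 moments with attribute
#'   `n_points`; sets with 2 or 3 points are flagged `degenerate`.
#' @export
usr_descriptor <- function(points) {
  pts <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(pts)
  if (n < 2) stop("degenerate input: USR descriptor needs at least 2 points")
  ctd <- colMeans(pts)
  d_ctd <- sqrt(colSums((t(pts) - ctd)^2))
  cst <- pts[which.min(d_ctd), ]   # which.min/max break ties at lowest index
  fct <- pts[which.max(d_ctd), ]
  d_fct <- sqrt(colSums((t(pts) - fct)^2))
  ftf <- pts[which.max(d_fct), ]
  refs <- rbind(ctd = ctd, cst = cst, fct = fct, ftf = ftf)
  m <- as.vector(apply(refs, 1, function(r)
    .moments3(sqrt(colSums((t(pts) - r)^2)))))
  names(m) <- paste0(rep(.usr_refs, each = 3), "_mu", 1:3)
  structure(m, n_points = n, degenerate = n < 4, class = "usr_descriptor")
}

#' USR similarity score
#'
#' S = 1 / (1 + mean absolute difference of the 12 moments); in (0, 1],
#' symmetric, and equal to 1 exactly when the descriptors coincide.
#'
#' @param q,i `usr_descriptor` objects (or plain 12-vectors).
#' @return similarity score.
#' @export
usr_similarity <- function(q, i) {
  q <- as.numeric(q); i <- as.numeric(i)
  if (length(q) != 12 || length(i) != 12)
    stop("USR descriptors must have 12 moments")
  1 / (1 + mean(abs(q - i)))
}

#' TWN-ligand shape similarity
#'
#' Compares the shape of a set of water-ring centers of mass against a
#' ligand's heavy-atom cloud: 100 x USR similarity of the two descriptors,
#' reported as a percentage with one decimal. Both sides need at least 4
#' points for a non-degenerate descriptor.
#'
#' @param rings ring table (see [rings_table()]) pooled over frames and ring
#'   classes.
#' @param ligand_atoms atom data.frame (columns element, x, y, z).
#' @param include_h also use ligand hydrogens (default FALSE: heavy atoms
#'   only, standard USR practice).
#' @param max_dist optional distance filter in Angstrom: keep only ring COMs
#'   within `max_dist` of some ligand atom used.
#' @return percentage in (0, 100].
#' @export
twn_ligand_shape_similarity <- function(rings, ligand_atoms,
                                        include_h = FALSE, max_dist = NULL) {
  tab <- rings_table(rings)
  lig <- ligand_atoms
  if (!include_h) lig <- lig[lig$element != "H", , drop = FALSE]
  L <- as.matrix(lig[, c("x", "y", "z")])
  P <- as.matrix(tab[, c("x", "y", "z")])
  if (!is.null(max_dist)) {
    keep <- vapply(seq_len(nrow(P)), function(k)
      min(sqrt(colSums((t(L) - P[k, ])^2))) <= max_dist, logical(1))
    P <- P[keep, , drop = FALSE]
  }
  if (nrow(P) < 4)
    stop("degenerate input on the TWN side: need at least 4 ring COMs, have ",
         nrow(P))
  if (nrow(L) < 4)
    stop("degenerate input on the ligand side: need at least 4 heavy atoms, have ",
         nrow(L))
  round_half_away(100 * usr_similarity(usr_descriptor(P), usr_descriptor(L)), 1)
}
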