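# Binding-site comparison: spatially consistent matching of element-typed
# heavy atoms between two pockets, scored with the Tanimoto-like ratio
# n_match / (n_site1 + n_site2 - n_match).
#
# The matching itself is a triplet-seeded rigid alignment: congruent
# element-typed atom triplets seed a least-squares superposition, which is
# extended greedily by nearest same-element pairs within tolerance and
# refined by refitting on the current matching. "Largest possible matching"
# is therefore approximated, not proven optimal; the test-suite checks the
# heuristic against an exhaustive oracle on small sites.

#' Construct a binding site
#'
#' @param atoms atom data.frame (columns element, x, y, z); hydrogens are
#'   dropped.
#' @param label site name for reports.
#' @return a `binding_site` with >= 3 heavy atoms.
#' @export
binding_site <- function(atoms, label = "site") {
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  if (nrow(heavy) < 3)
    stop("binding site '", label, "' needs at least 3 heavy atoms, has ",
         nrow(heavy))
  rownames(heavy) <- NULL
  structure(list(atoms = heavy, label = label), class = "binding_site")
}

#' Extract a binding site from a PDB file
#'
#' Pocket atoms are selected either by an explicit residue-id list or as all
#' protein heavy atoms within `radius` Angstrom of a reference ligand.
#'
#' @param path PDB file.
#' @param resids integer vector of residue ids to keep (optional).
#' @param ligand_resnames residue names of the reference ligand (used when
#'   `resids` is NULL).
#' @param radius proximity cutoff in Angstrom around the ligand.
#' @param label site name.
#' @return a `binding_site`.
#' @export
site_from_pdb <- function(path, resids = NULL, ligand_resnames = character(),
                          radius = 5.0, label = basename(path)) {
  fr <- parse_frame(path, ligand_resnames = ligand_resnames)
  prot <- fr$protein_atoms
  if (!is.null(resids)) {
    sel <- prot[prot$resid %in% resids, , drop = FALSE]
  } else {
    if (nrow(fr$ligand_atoms) == 0)
      stop("no ligand atoms found; give resids= or ligand_resnames=")
    L <- as.matrix(fr$ligand_atoms[, c("x", "y", "z")])
    P <- as.matrix(prot[, c("x", "y", "z")])
    keep <- vapply(seq_len(nrow(P)), function(k)
      min(sqrt(colSums((t(L) - P[k, ])^2))) <= radius, logical(1))
    sel <- prot[keep, , drop = FALSE]
  }
  binding_site(sel, label)
}

# Least-squares rigid fit (Kabsch): returns R (3x3) and t so that
# Q %*% R + t best superposes onto P (row-vector convention).
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(Q, 2, cq)) %*% sweep(P, 2, cp)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = cp - as.vector(cq %*% R))
}

# Greedy mutual pairing of same-element atoms within tol after transform:
# candidate pairs sorted by distance, closest first, each atom used once.
.greedy_extend <- function(XA, XB_t, elA, elB, tol) {
  cand_i <- integer(0); cand_j <- integer(0); cand_d <- numeric(0)
  for (el in unique(elA)) {
    ia <- which(elA == el); ib <- which(elB == el)
    if (length(ib) == 0) next
    D2 <- outer(rowSums(XA[ia, , drop = FALSE]^2), rep(1, length(ib))) +
          outer(rep(1, length(ia)), rowSums(XB_t[ib, , drop = FALSE]^2)) -
          2 * XA[ia, , drop = FALSE] %*% t(XB_t[ib, , drop = FALSE])
    D <- sqrt(pmax(D2, 0))  # clamp fp cancellation for coincident points
    ok <- which(D <= tol, arr.ind = TRUE)
    if (nrow(ok) > 0) {
      cand_i <- c(cand_i, ia[ok[, 1]])
      cand_j <- c(cand_j, ib[ok[, 2]])
      cand_d <- c(cand_d, D[ok])
    }
  }
  if (length(cand_i) == 0)
    return(matrix(integer(0), 0, 2))
  ord <- order(cand_d, cand_i, cand_j)
  used_a <- logical(nrow(XA)); used_b <- logical(nrow(XB_t))
  pi <- integer(0); pj <- integer(0)
  for (k in ord) {
    i <- cand_i[k]; j <- cand_j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pi <- c(pi, i); pj <- c(pj, j)
    }
  }
  cbind(pi, pj)
}

# One direction of the seeded search: A fixed, B transformed onto A.
.match_one <- function(A, B, tol, max_seeds) {
  XA <- as.matrix(A$atoms[, c("x", "y", "z")])
  XB <- as.matrix(B$atoms[, c("x", "y", "z")])
  elA <- A$atoms$element; elB <- B$atoms$element
  nA <- nrow(XA); nB <- nrow(XB)
  best <- list(n_match = 0L, pairs = matrix(integer(0), 0, 2),
               R = diag(3), t = c(0, 0, 0))
  if (length(intersect(elA, elB)) == 0) return(best)
  cap <- min(nA, nB)

  trip_info <- function(X, el) {
    tr <- utils::combn(nrow(X), 3)
    key <- apply(tr, 2, function(ix) paste(sort(el[ix]), collapse = ""))
    sides <- apply(tr, 2, function(ix)
      sort(c(vnorm(X[ix[1], ] - X[ix[2], ]), vnorm(X[ix[1], ] - X[ix[3], ]),
             vnorm(X[ix[2], ] - X[ix[3], ]))))
    list(tr = tr, key = key, sides = sides)
  }
  ta <- trip_info(XA, elA)
  tb <- trip_info(XB, elB)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  seeds <- 0L
  for (a in seq_len(ncol(ta$tr))) {
    ia <- ta$tr[, a]
    grp <- which(tb$key == ta$key[a])
    if (length(grp) == 0) next
    # congruence prefilter on sorted side lengths; each matched endpoint may
    # sit up to tol from its partner, so side lengths can differ by 2*tol
    ok <- grp[apply(abs(tb$sides[, grp, drop = FALSE] - ta$sides[, a]) <=
                      2 * tol, 2, all)]
    dA <- c(vnorm(XA[ia[1], ] - XA[ia[2], ]), vnorm(XA[ia[1], ] - XA[ia[3], ]),
            vnorm(XA[ia[2], ] - XA[ia[3], ]))
    for (b in ok) {
      jb0 <- tb$tr[, b]
      for (p in seq_len(nrow(perms))) {
        jb <- jb0[perms[p, ]]
        if (!all(elA[ia] == elB[jb])) next
        dB <- c(vnorm(XB[jb[1], ] - XB[jb[2], ]), vnorm(XB[jb[1], ] - XB[jb[3], ]),
                vnorm(XB[jb[2], ] - XB[jb[3], ]))
        if (any(abs(dA - dB) > 2 * tol)) next
        seeds <- seeds + 1L
        fit <- kabsch_fit(XA[ia, , drop = FALSE], XB[jb, , drop = FALSE])
        pairs <- NULL
        for (it in 1:3) {  # extend, then refit on the extension, twice
          XB_t <- XB %*% fit$R + matrix(fit$t, nB, 3, byrow = TRUE)
          pairs <- .greedy_extend(XA, XB_t, elA, elB, tol)
          if (nrow(pairs) < 3) break
          fit <- kabsch_fit(XA[pairs[, 1], , drop = FALSE],
                            XB[pairs[, 2], , drop = FALSE])
        }
        if (nrow(pairs) > best$n_match) {
          best <- list(n_match = nrow(pairs), pairs = pairs,
                       R = fit$R, t = fit$t)
          if (best$n_match >= cap) return(best)
        }
        if (seeds >= max_seeds) return(best)
      }
    }
  }
  best
}

#' Binding-site similarity score
#'
#' Finds a large spatially consistent matching of element-equivalent heavy
#' atoms between two sites and scores it as
#' `n_match / (n_site1 + n_site2 - n_match)` in `[0, 1]`; 1 means a perfect
#' bijection within tolerance (e.g. a site compared against itself). The
#' greedy search runs in both seed directions and keeps the larger matching,
#' making the score symmetric.
#'
#' @param s1,s2 `binding_site` objects.
#' @param distance_tolerance pairwise/post-superposition distance tolerance
#'   in Angstrom (default 1.0).
#' @param max_seeds cap on evaluated seed alignments per direction
#'   (deterministic order; early exit on a perfect matching).
#' @return a `twn_match`: n_match, n_site1, n_site2, score, correspondence
#'   (index pairs into s1/s2), transform (R, t mapping s2 onto s1 when
#'   available).
#' @export
binding_site_similarity <- function(s1, s2, distance_tolerance = 1.0,
                                    max_seeds = 5000L) {
  stopifnot(inherits(s1, "binding_site"), inherits(s2, "binding_site"),
            distance_tolerance > 0)
  n1 <- nrow(s1$atoms); n2 <- nrow(s2$atoms)
  r12 <- .match_one(s1, s2, distance_tolerance, max_seeds)
  if (r12$n_match < min(n1, n2)) {
    r21 <- .match_one(s2, s1, distance_tolerance, max_seeds)
    if (r21$n_match > r12$n_match)
      r12 <- list(n_match = r21$n_match,
                  pairs = r21$pairs[, c(2, 1), drop = FALSE],
                  R = r21$R, t = r21$t)
  }
  n <- r12$n_match
  colnames(r12$pairs) <- c("site1", "site2")
  structure(list(n_match = n, n_site1 = n1, n_site2 = n2,
                 score = if (n1 + n2 - n > 0) n / (n1 + n2 - n) else 0,
                 correspondence = r12$pairs,
                 transform = list(R = r12$R, t = r12$t),
                 label1 = s1$label, label2 = s2$label),
            class = "twn_match")
}

#' @export
print.twn_match <- function(x, ...) {
  cat(sprintf("<twn_match %s vs %s: n_match %d / (%d, %d), score %.3f>\n",
              x$label1, x$label2, x$n_match, x$n_site1, x$n_site2, x$score))
  invisible(x)
}
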