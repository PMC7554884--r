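# Independent oracles used across the suite. Each one recomputes a quantity
# by a route deliberately different from the production code path: scalar
# loops instead of vectorised algebra, exhaustive enumeration instead of
# pruned search, optimal assignment instead of greedy extension.

# --- TIP3P pair energy: explicit 9-term site-site summation -----------------

oracle_pair_energy <- function(a, b, params = tip3p_params()) {
  q <- c(params$q_O, params$q_H, params$q_H)
  e <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      dx <- a$pos[i, 1] - b$pos[j, 1]
      dy <- a$pos[i, 2] - b$pos[j, 2]
      dz <- a$pos[i, 3] - b$pos[j, 3]
      r <- sqrt(dx * dx + dy * dy + dz * dz)
      e <- e + params$coulomb_constant * q[i] * q[j] / r
    }
  }
  roo <- sqrt(sum((a$pos[1, ] - b$pos[1, ])^2))
  e + params$A / roo^12 - params$C / roo^6
}

# a rigid water with a random orientation at a given oxygen position
random_water <- function(center, index = 1L) {
  g <- 104.52 * pi / 180
  tmpl <- rbind(c(0, 0, 0),
                c(0.9572, 0, 0),
                c(0.9572 * cos(g), 0.9572 * sin(g), 0))
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  pos <- tmpl %*% t(Q) + matrix(center, 3, 3, byrow = TRUE)
  water_molecule(pos[1, ], pos[2, ], pos[3, ], index)
}

# ideal linear hydrogen-bond dimer: donor O-H aimed at the acceptor oxygen at
# an O-O separation of `roo`; acceptor hydrogens point away from the donor
ideal_dimer <- function(roo = 2.75) {
  g <- 104.52 * pi / 180
  donor <- water_molecule(c(0, 0, 0),
                          c(0.9572, 0, 0),
                          0.9572 * c(cos(g), sin(g), 0), 1L)
  half <- g / 2
  aO <- c(roo, 0, 0)
  acceptor <- water_molecule(aO,
                             aO + 0.9572 * c(cos(half), sin(half), 0),
                             aO + 0.9572 * c(cos(half), -sin(half), 0), 2L)
  list(donor = donor, acceptor = acceptor)
}

unitv_helper <- function(v) v / sqrt(sum(v^2))

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# --- chordless cycles: exhaustive subset/ordering enumeration ---------------

# all permutations of a vector (small n only)
.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Enumerate every chordless simple cycle of length min..max in an undirected
# graph given as an adjacency matrix with rownames/colnames = node ids.
# Route: all node subsets of each size, all cyclic orderings (first element
# fixed to the subset minimum, direction fixed by second < last), keep
# orderings whose consecutive pairs are all edges and whose non-consecutive
# pairs are all non-edges.
oracle_chordless_cycles <- function(adjmat, min_size = 3, max_size = 6) {
  ids <- as.integer(rownames(adjmat))
  n <- length(ids)
  found <- list()
  for (k in min_size:min(max_size, n)) {
    for (subset in asplit(utils::combn(n, k), 2)) {
      sub <- as.integer(subset)
      A <- adjmat[sub, sub, drop = FALSE]
      if (any(rowSums(A) < 2)) next    # every cycle node needs degree >= 2
      rest <- 2:k
      for (p in .perms(rest)) {
        if (p[1] > p[k - 1]) next      # direction canonicalisation
        ord <- c(1L, p)
        ok <- TRUE
        for (a in 1:k) {
          for (b in a:k) {
            consecutive <- (b == a + 1) || (a == 1 && b == k)
            if (a == b) next
            if (consecutive && !A[ord[a], ord[b]]) { ok <- FALSE; break }
            if (!consecutive && A[ord[a], ord[b]]) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok)
          found[[length(found) + 1L]] <- canonical_cycle(ids[sub][ord])
      }
    }
  }
  keys <- vapply(found, paste, "", collapse = "-")
  found[!duplicated(keys)]
}

# random hbond_graph-shaped object (edge energies are irrelevant to ring
# perception, set to a constant below any criterion)
random_graph <- function(n, p) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- which(runif(nrow(pairs)) < p)
  edges <- data.frame(i = as.integer(pairs[keep, 1]),
                      j = as.integer(pairs[keep, 2]),
                      energy = rep(-5, length(keep)))
  structure(list(nodes = seq_len(n), edges = edges, criterion = -2.25),
            class = "hbond_graph")
}

adjacency_matrix <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(graph$nodes, graph$nodes))
  for (r in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges$i[r], graph$nodes)
    j <- match(graph$edges$j[r], graph$nodes)
    A[i, j] <- A[j, i] <- TRUE
  }
  A
}

ring_key_set <- function(rings) {
  sort(vapply(rings, function(r) paste(r$members, collapse = "-"), ""))
}

# --- USR moments: direct summation ------------------------------------------

oracle_usr_moments <- function(points) {
  pts <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(pts)
  ctd <- c(mean(pts[, 1]), mean(pts[, 2]), mean(pts[, 3]))
  dist_to <- function(r) {
    d <- numeric(n)
    for (i in 1:n) d[i] <- sqrt(sum((pts[i, ] - r)^2))
    d
  }
  d_ctd <- dist_to(ctd)
  cst <- pts[order(d_ctd)[1], ]
  fct <- pts[order(-d_ctd)[1], ]
  ftf <- pts[order(-dist_to(fct))[1], ]
  out <- numeric(0)
  for (r in list(ctd, cst, fct, ftf)) {
    d <- dist_to(r)
    m1 <- sum(d) / n
    m2 <- sqrt(sum((d - m1)^2) / n)
    m3c <- sum((d - m1)^3) / n
    out <- c(out, m1, m2, sign(m3c) * abs(m3c)^(1 / 3))
  }
  out
}

# --- binding-site matching: exhaustive seeds + optimal assignment -----------

# maximum bipartite matching by Kuhn's augmenting-path algorithm;
# adj = list over left vertices of right-neighbour index vectors
oracle_max_matching <- function(adj, n_right) {
  match_r <- integer(n_right)          # 0 = unmatched
  augment <- function(u, visited) {
    for (v in adj[[u]]) {
      if (visited[v]) next
      visited[v] <- TRUE
      res <- if (match_r[v] == 0L) list(ok = TRUE, vis = visited)
             else augment(match_r[v], visited)
      visited <- res$vis
      if (res$ok) {
        match_r[v] <<- u
        return(list(ok = TRUE, vis = visited))
      }
    }
    list(ok = FALSE, vis = visited)
  }
  n <- 0L
  for (u in seq_along(adj))
    if (augment(u, logical(n_right))$ok) n <- n + 1L
  n
}

# All ordered element-compatible triplet correspondences seed a rigid fit
# (no congruence prefilter); the candidate same-element pairs within
# tolerance after the fit are resolved by an optimal bipartite matching,
# not greedily. Feasible only for small sites.
oracle_site_match <- function(s1, s2, tol = 1.0) {
  XA <- as.matrix(s1$atoms[, c("x", "y", "z")])
  XB <- as.matrix(s2$atoms[, c("x", "y", "z")])
  elA <- s1$atoms$element; elB <- s2$atoms$element
  nA <- nrow(XA); nB <- nrow(XB)
  el_ok <- outer(elA, elB, "==")
  best <- 0L
  trA <- utils::combn(nA, 3)
  idxB <- seq_len(nB)
  for (a in seq_len(ncol(trA))) {
    ia <- trA[, a]
    for (j1 in idxB) for (j2 in idxB) for (j3 in idxB) {
      jb <- c(j1, j2, j3)
      if (anyDuplicated(jb)) next
      if (!all(elA[ia] == elB[jb])) next
      fit <- twnring:::kabsch_fit(XA[ia, , drop = FALSE],
                                  XB[jb, , drop = FALSE])
      XB_t <- XB %*% fit$R + matrix(fit$t, nB, 3, byrow = TRUE)
      D2 <- outer(rowSums(XA^2), rep(1, nB)) +
            outer(rep(1, nA), rowSums(XB_t^2)) - 2 * XA %*% t(XB_t)
      feas <- el_ok & (D2 <= tol^2 + 1e-12)
      if (sum(feas) < best) next
      adj <- lapply(seq_len(nA), function(i) which(feas[i, ]))
      m <- oracle_max_matching(adj, nB)
      if (m > best) best <- m
      if (best >= min(nA, nB)) return(best)
    }
  }
  best
}

oracle_site_score <- function(n_match, n1, n2) n_match / (n1 + n2 - n_match)
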