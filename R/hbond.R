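# Hydrogen-bond graph construction over a frame's waters.

#' Build the water hydrogen-bond graph of a frame
#'
#' Candidate pairs are prefiltered by oxygen-oxygen distance (no rigid TIP3P
#' pair beyond ~3.5 A reaches the bonding criterion), then scored with the
#' full pair potential; an edge is kept when the energy is at or below
#' `params$hbond_energy_criterion`.
#'
#' @param frame a `twn_frame`.
#' @param params `tip3p_params`.
#' @param cutoff O-O prefilter distance in Angstrom.
#' @param minimum_image apply the minimum-image convention using the frame
#'   box (error if the frame has no box).
#' @return an `hbond_graph`: list with `nodes` (water indices) and `edges`
#'   (data.frame i, j, energy with i < j, kcal/mol).
#' @export
build_hbond_graph <- function(frame, params = tip3p_params(), cutoff = 3.5,
                              minimum_image = FALSE) {
  stopifnot(inherits(frame, "twn_frame"), cutoff > 0)
  if (minimum_image && is.null(frame$box))
    stop("minimum_image requested but frame ", frame$frame_id, " has no box")
  idx <- frame_water_indices(frame)
  n <- length(idx)
  edges <- data.frame(i = integer(0), j = integer(0), energy = numeric(0))
  if (n >= 2) {
    W <- frame_water_matrix(frame)
    O <- W[, 1:3, drop = FALSE]
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dvec <- O[pr[, 2], , drop = FALSE] - O[pr[, 1], , drop = FALSE]
    shift <- NULL
    if (minimum_image) {
      box <- matrix(frame$box, nrow(pr), 3, byrow = TRUE)
      # translate water j so its oxygen is in the minimum image of oxygen i
      shift <- -box * round(dvec / box)
      dvec <- dvec + shift
    }
    keep <- rowSums(dvec^2) <= cutoff^2
    pr <- pr[keep, , drop = FALSE]
    if (nrow(pr) > 0) {
      if (!is.null(shift)) shift <- shift[keep, , drop = FALSE]
      e <- pair_energies_bulk(W[pr[, 1], , drop = FALSE],
                              W[pr[, 2], , drop = FALSE], params, shift)
      hb <- e <= params$hbond_energy_criterion
      edges <- data.frame(i = idx[pr[hb, 1]], j = idx[pr[hb, 2]],
                          energy = e[hb])
      flip <- edges$i > edges$j
      tmp <- edges$i[flip]; edges$i[flip] <- edges$j[flip]; edges$j[flip] <- tmp
      edges <- edges[order(edges$i, edges$j), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = sort(idx), edges = edges,
                 criterion = params$hbond_energy_criterion),
            class = "hbond_graph")
}

#' @export
print.hbond_graph <- function(x, ...) {
  cat(sprintf("<hbond_graph: %d waters, %d hydrogen bonds (criterion %.2f kcal/mol)>\n",
              length(x$nodes), nrow(x$edges), x$criterion))
  invisible(x)
}

# adjacency list keyed by node id (named list of integer vectors)
graph_adjacency <- function(graph) {
  adj <- lapply(graph$nodes, function(n) integer(0))
  names(adj) <- as.character(graph$nodes)
  for (k in seq_len(nrow(graph$edges))) {
    i <- as.character(graph$edges$i[k]); j <- as.character(graph$edges$j[k])
    adj[[i]] <- c(adj[[i]], graph$edges$j[k])
    adj[[j]] <- c(adj[[j]], graph$edges$i[k])
  }
  lapply(adj, sort)
}
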