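# Ring perception: chordless cycles of 3-6 waters in the hydrogen-bond graph,
# their canonical form, centers of mass, and the multi-frame driver.

ring_class_of <- function(size) paste0("R", size)

#' Canonical form of a cycle
#'
#' Among all rotations and both orientations of the member sequence, the
#' lexicographically smallest one: smallest index first, then the smaller of
#' its two neighbours second. Guarantees a unique representation per ring.
#'
#' @param members integer vector of cyclically ordered node ids.
#' @return integer vector, canonical ordering.
#' @export
canonical_cycle <- function(members) {
  n <- length(members)
  s <- which.min(members)
  fwd <- members[((s - 1 + 0:(n - 1)) %% n) + 1]
  rev_ <- members[((s - 1 - 0:(n - 1)) %% n) + 1]
  if (isTRUE(fwd[2] <= rev_[2])) fwd else rev_
}

#' Enumerate chordless rings R3-R6
#'
#' Finds every chordless simple cycle of length `min_size` to `max_size` in
#' the hydrogen-bond graph, each reported exactly once in canonical form.
#' Cycles with an internal chord (an edge between two non-consecutive
#' members) are never reported: a chorded hexagon contributes only its
#' smaller constituent rings, matching the usual ring-perception convention.
#'
#' The search grows paths from each start node s using only nodes > s
#' (making s the cycle minimum); a path may only be extended by a node
#' adjacent to its tip and to no earlier path node, which enforces
#' chordlessness incrementally. Orientation duplicates are removed by
#' requiring the second node to be smaller than the closing node.
#'
#' @param graph an `hbond_graph`.
#' @param min_size,max_size ring sizes to report (3..6 by default).
#' @return list of rings, each a list with `members` (canonical order) and
#'   `ring_class`.
#' @export
enumerate_rings <- function(graph, min_size = 3L, max_size = 6L) {
  stopifnot(min_size >= 3, max_size >= min_size)
  adj <- graph_adjacency(graph)
  rings <- list()
  nodes <- graph$nodes
  for (s in nodes) {
    schr <- as.character(s)
    nbrs <- adj[[schr]]
    nbrs <- nbrs[nbrs > s]
    for (v1 in nbrs) {
      # DFS stack of paths s -> v1 -> ...; all path nodes > s
      stack <- list(c(v1))
      while (length(stack) > 0) {
        path <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (u in adj[[as.character(path[length(path)])]]) {
          if (u <= s || u %in% path) next
          adj_u <- adj[[as.character(u)]]
          # chord check: u may touch the path only at its tip
          interior <- path[-length(path)]
          if (length(interior) > 0 && any(interior %in% adj_u)) next
          if (s %in% adj_u) {
            # closure s - path - u - s; a node adjacent to s can never be an
            # interior node of a chordless cycle through s (the u-s edge
            # would be a chord), so record and do not extend
            cyc_len <- length(path) + 2L
            if (cyc_len >= min_size && cyc_len <= max_size && path[1] < u)
              rings[[length(rings) + 1L]] <-
                list(members = canonical_cycle(c(s, path, u)),
                     ring_class = ring_class_of(cyc_len))
          } else if (length(path) + 2L <= max_size) {
            stack[[length(stack) + 1L]] <- c(path, u)
          }
        }
      }
    }
  }
  # canonical form makes duplicates (if any) identical; dedup + stable order
  if (length(rings) > 0) {
    keys <- vapply(rings, function(r) paste(r$members, collapse = "-"), "")
    rings <- rings[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
    ord <- order(vapply(rings, function(r) length(r$members), 1L), keys)
    rings <- rings[ord]
  }
  rings
}

#' Center of mass of a water ring
#'
#' Mass-weighted mean over all atoms (O + 2 H per member water, masses from
#' the internal element table). `com_mode = "oxygen"` gives the unweighted
#' oxygen centroid instead, for sensitivity checks.
#'
#' @param ring a ring (list with `members`) from [enumerate_rings()].
#' @param frame the `twn_frame` the ring was found in.
#' @param com_mode `"all"` (mass-weighted, default) or `"oxygen"`.
#' @return xyz vector in Angstrom.
#' @export
ring_center_of_mass <- function(ring, frame, com_mode = c("all", "oxygen")) {
  com_mode <- match.arg(com_mode)
  idx <- frame_water_indices(frame)
  pos <- match(ring$members, idx)
  if (anyNA(pos))
    stop("ring member(s) ", paste(ring$members[is.na(pos)], collapse = ", "),
         " not present in frame ", frame$frame_id)
  if (com_mode == "oxygen") {
    O <- t(vapply(frame$waters[pos], function(w) w$pos[1, ], numeric(3)))
    return(colMeans(O))
  }
  m <- atomic_mass(c("O", "H", "H"))
  num <- c(0, 0, 0); den <- 0
  for (w in frame$waters[pos]) {
    num <- num + colSums(w$pos * m)
    den <- den + sum(m)
  }
  num / den
}

#' Detect water rings across frames
#'
#' Runs graph construction, chordless-ring enumeration and COM computation on
#' every frame and concatenates the results. Rings are deduplicated within a
#' frame only: the same water cycle recurring in several frames is counted
#' once per frame, which is what per-region occupancy tables tally.
#'
#' @param frames list of `twn_frame`.
#' @param params `tip3p_params`.
#' @param cutoff O-O prefilter in Angstrom.
#' @param minimum_image use minimum-image distances (requires a box).
#' @param com_mode passed to [ring_center_of_mass()].
#' @return data.frame with columns frame_id, ring_class, members
#'   ("i-j-k" canonical order), x, y, z (ring COM).
#' @export
analyze_frames <- function(frames, params = tip3p_params(), cutoff = 3.5,
                           minimum_image = FALSE, com_mode = "all") {
  if (inherits(frames, "twn_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  rows <- list()
  for (fr in frames) {
    res <- tryCatch({
      g <- build_hbond_graph(fr, params, cutoff, minimum_image)
      rings <- enumerate_rings(g)
      if (length(rings) == 0) NULL else do.call(rbind, lapply(rings, function(r) {
        com <- ring_center_of_mass(r, fr, com_mode)
        data.frame(frame_id = fr$frame_id, ring_class = r$ring_class,
                   members = paste(r$members, collapse = "-"),
                   x = com[1], y = com[2], z = com[3],
                   stringsAsFactors = FALSE)
      }))
    }, error = function(e)
      stop("frame ", fr$frame_id, ": ", conditionMessage(e), call. = FALSE))
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0)
    return(data.frame(frame_id = integer(0), ring_class = character(0),
                      members = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalise ring results to the standard ring table
#'
#' Accepts the data.frame from [analyze_frames()] (returned unchanged) or a
#' list of rings with attached `com`/`frame_id` fields.
#'
#' @param rings ring results.
#' @return data.frame frame_id, ring_class, members, x, y, z.
#' @export
rings_table <- function(rings) {
  if (is.data.frame(rings)) {
    need <- c("frame_id", "ring_class", "members", "x", "y", "z")
    if (!all(need %in% names(rings)))
      stop("ring table must have columns ", paste(need, collapse = ", "))
    return(rings)
  }
  do.call(rbind, lapply(rings, function(r)
    data.frame(frame_id = r$frame_id %||% 1L, ring_class = r$ring_class,
               members = paste(r$members, collapse = "-"),
               x = r$com[1], y = r$com[2], z = r$com[3],
               stringsAsFactors = FALSE)))
}
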