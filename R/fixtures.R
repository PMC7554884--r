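# Synthetic, fully controlled inputs: water boxes with planted hydrogen-
# bonded rings, toy ligands and toy binding sites. Everything is driven by a
# single integer seed so the whole pipeline is testable without downloads or
# an MD engine. No thermodynamic realism is claimed: planted rings are ideal
# regular polygons and noise waters are a sparse hard-sphere gas.

.tip3p_OH <- 0.9572     # rigid O-H bond length, Angstrom
.tip3p_HOH <- 104.52    # rigid H-O-H angle, degrees
.plant_OO <- 2.75       # planted O-O spacing: canonical H-bond distance

# uniform random rotation matrix (from the current RNG stream)
.rand_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(q)
  Q <- Q %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# template rigid water at the origin: O at 0, H1 along +x, H2 in the xy plane
.template_water <- function() {
  g <- .tip3p_HOH * pi / 180
  rbind(c(0, 0, 0),
        c(.tip3p_OH, 0, 0),
        c(.tip3p_OH * cos(g), .tip3p_OH * sin(g), 0))
}

#' Plant an ideal hydrogen-bonded water ring
#'
#' Places n waters on a regular n-gon with O-O spacing 2.75 Angstrom, each
#' water's first O-H bond donated along the ring edge toward its next
#' neighbour's oxygen (bent 20 deg outward for the strained trimer; rigid
#' TIP3P internal geometry: O-H 0.9572 A, H-O-H 104.52 deg, second hydrogen
#' in the ring plane pointing outward). Every consecutive pair's energy is
#' asserted to satisfy the hydrogen-bond criterion at generation time, so a
#' parameter regression is caught here, not downstream.
#'
#' @param ring_class "R3".."R6".
#' @param center ring center, xyz in Angstrom.
#' @param orientation_seed integer seed for the rigid orientation of the
#'   ring plane.
#' @param params `tip3p_params` used for the generation-time assertion.
#' @return list of `twn_water` (indices 1..n).
#' @export
plant_ring <- function(ring_class = c("R3", "R4", "R5", "R6"),
                       center = c(0, 0, 0), orientation_seed = 1L,
                       params = tip3p_params()) {
  ring_class <- match.arg(ring_class)
  n <- as.integer(substring(ring_class, 2))
  rot <- with_seed(orientation_seed, .rand_rotation())
  rc <- .plant_OO / (2 * sin(pi / n))
  theta <- 2 * pi * (seq_len(n) - 1) / n
  O <- cbind(rc * cos(theta), rc * sin(theta), 0)
  nrm <- c(0, 0, 1)
  g <- .tip3p_HOH * pi / 180
  waters <- vector("list", n)
  # Trimer edges are strained (60 deg interior angle): an O-H aimed exactly
  # along the edge leaves only ~1 kcal/mol of margin below the criterion,
  # which per-water jitter erodes. Real trimer hydrogen bonds are bent, so
  # the R3 donor O-H is tilted 20 deg outward in the ring plane (pair energy
  # ~ -5.6 kcal/mol); larger rings donate straight along the edge.
  tilt <- if (n == 3) 20 * pi / 180 else 0
  for (k in seq_len(n)) {
    u <- unitv(O[(k %% n) + 1, ] - O[k, ])   # ring edge direction
    rad <- unitv(O[k, ])                     # outward radial direction
    t_out <- unitv(rad - sum(rad * u) * u)   # in-plane, perpendicular to u
    ud <- cos(tilt) * u + sin(tilt) * t_out  # donor O-H direction
    vp <- -sin(tilt) * u + cos(tilt) * t_out # in-plane unit, perp to ud
    w <- cos(g) * ud + sin(g) * vp           # second H in plane, outward
    pos <- rbind(O[k, ],
                 O[k, ] + .tip3p_OH * ud,
                 O[k, ] + .tip3p_OH * w)
    pos <- pos %*% t(rot) + matrix(center, 3, 3, byrow = TRUE)
    waters[[k]] <- water_molecule(pos[1, ], pos[2, ], pos[3, ], index = k)
  }
  for (k in seq_len(n)) {
    e <- pair_energy(waters[[k]], waters[[(k %% n) + 1]], params)
    if (e > params$hbond_energy_criterion)
      stop(sprintf("planted %s edge %d has energy %.3f kcal/mol above the criterion %.2f (generator parameter bug)",
                   ring_class, k, e, params$hbond_energy_criterion))
  }
  waters
}

#' Specification of a synthetic water-box scenario
#'
#' Defaults describe the canonical planted-truth scenario used throughout
#' the test-suite: two trimers and one hexamer per frame, 20 sparse noise
#' waters in a 40 A cubic box, 10 frames, no jitter.
#'
#' @param rings_to_plant list of lists with fields `ring_class`, `center`,
#'   `orientation_seed`.
#' @param n_noise_waters randomly placed waters per frame.
#' @param box three box lengths in Angstrom.
#' @param n_frames number of frames to generate.
#' @param jitter_sigma per-water rigid Gaussian displacement, Angstrom.
#' @param random_seed master seed; all randomness flows from it.
#' @return a `plant_spec`.
#' @export
plant_spec <- function(rings_to_plant = list(
                         list(ring_class = "R3", center = c(10, 10, 10),
                              orientation_seed = 11L),
                         list(ring_class = "R3", center = c(25, 25, 13),
                              orientation_seed = 12L),
                         list(ring_class = "R6", center = c(14, 28, 26),
                              orientation_seed = 13L)),
                       n_noise_waters = 20L, box = c(40, 40, 40),
                       n_frames = 10L, jitter_sigma = 0,
                       random_seed = 1L) {
  stopifnot(n_noise_waters >= 0, jitter_sigma >= 0, n_frames >= 1,
            all(box > 0))
  structure(list(rings_to_plant = rings_to_plant,
                 n_noise_waters = as.integer(n_noise_waters),
                 box = as.numeric(box), n_frames = as.integer(n_frames),
                 jitter_sigma = jitter_sigma,
                 random_seed = as.integer(random_seed)),
            class = "plant_spec")
}

#' Generate synthetic frames with planted rings
#'
#' Each frame contains the planted rings -- independently displaced per
#' water by a rigid Gaussian jitter of `jitter_sigma` (the water keeps its
#' exact internal geometry, consistent with a rigid water model) -- plus
#' `n_noise_waters` uniformly placed, randomly oriented waters rejected when
#' their oxygen lands within 2.5 Angstrom of any already placed oxygen.
#' Fully reproducible from `random_seed`.
#'
#' @param spec a `plant_spec`.
#' @return list of `twn_frame`.
#' @export
generate_frames <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  tmpl <- .template_water()
  planted <- lapply(spec$rings_to_plant, function(r)
    plant_ring(r$ring_class, r$center, r$orientation_seed))
  with_seed(spec$random_seed, {
    lapply(seq_len(spec$n_frames), function(f) {
      waters <- list()
      oxy <- matrix(numeric(0), 0, 3)
      add_water <- function(pos) {
        waters[[length(waters) + 1L]] <<-
          water_molecule(pos[1, ], pos[2, ], pos[3, ],
                         index = length(waters) + 1L)
        oxy <<- rbind(oxy, pos[1, ])
      }
      for (ring in planted)
        for (w in ring) {
          shift <- stats::rnorm(3, 0, spec$jitter_sigma)
          add_water(w$pos + matrix(shift, 3, 3, byrow = TRUE))
        }
      attempts <- 0L
      placed <- 0L
      while (placed < spec$n_noise_waters) {
        attempts <- attempts + 1L
        if (attempts > 10000L)
          stop("box too small: could not place ", spec$n_noise_waters,
               " noise waters after 10000 attempts")
        o <- stats::runif(3) * spec$box
        if (nrow(oxy) > 0 && min(sqrt(colSums((t(oxy) - o)^2))) < 2.5) next
        rot <- .rand_rotation()
        add_water(tmpl %*% t(rot) + matrix(o, 3, 3, byrow = TRUE))
        placed <- placed + 1L
      }
      twn_frame(waters = waters, box = spec$box, frame_id = f)
    })
  })
}

#' Ground truth of a plant specification
#'
#' @param spec a `plant_spec`.
#' @return data.frame of planted rings per frame (frame_id, ring_class,
#'   center x/y/z) -- what a perfect detector should recover.
#' @export
plant_truth <- function(spec) {
  per_frame <- do.call(rbind, lapply(spec$rings_to_plant, function(r)
    data.frame(ring_class = r$ring_class, x = r$center[1], y = r$center[2],
               z = r$center[3], stringsAsFactors = FALSE)))
  out <- do.call(rbind, lapply(seq_len(spec$n_frames), function(f)
    cbind(frame_id = f, per_frame)))
  rownames(out) <- NULL
  out
}

#' Write the ground truth as JSON
#'
#' @param spec a `plant_spec`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(spec, path) {
  jsonlite::write_json(plant_truth(spec), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deterministic toy ligand point clouds
#'
#' Heavy-atom clouds of three shape families for exercising the shape
#' similarity path: an elongated `rod`, a planar `ring`, and an isotropic
#' `blob`.
#'
#' @param shape one of "rod", "ring", "blob".
#' @param n_atoms number of atoms (>= 4).
#' @param seed integer seed for the shape jitter.
#' @param element element symbol given to every atom.
#' @return atom data.frame (name, element, resname, resid, x, y, z).
#' @export
make_toy_ligand <- function(shape = c("rod", "ring", "blob"), n_atoms = 12L,
                            seed = 1L, element = "C") {
  shape <- match.arg(shape)
  if (n_atoms < 4) stop("a toy ligand needs at least 4 atoms")
  pts <- with_seed(seed, switch(shape,
    rod = cbind(1.4 * seq_len(n_atoms),
                stats::rnorm(n_atoms, 0, 0.2),
                stats::rnorm(n_atoms, 0, 0.2)),
    ring = {
      r <- 1.4 * n_atoms / (2 * pi)
      th <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
      cbind(r * cos(th), r * sin(th), stats::rnorm(n_atoms, 0, 0.1))
    },
    blob = matrix(stats::rnorm(3 * n_atoms, 0, 1.5), ncol = 3)))
  data.frame(name = paste0(element, seq_len(n_atoms)), element = element,
             resname = "LIG", resid = 1L,
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             stringsAsFactors = FALSE)
}

#' Random toy binding site
#'
#' Uniformly placed heavy atoms (elements drawn from C/N/O) in a cube, with
#' a 1.5 Angstrom minimum separation -- a stand-in pocket for exercising and
#' benchmarking the site-similarity matcher.
#'
#' @param n_atoms number of atoms (>= 3).
#' @param seed integer seed.
#' @param side cube edge length in Angstrom.
#' @param elements element pool to sample from.
#' @param label site name.
#' @return a `binding_site`.
#' @export
make_toy_site <- function(n_atoms = 20L, seed = 1L, side = 10,
                          elements = c("C", "N", "O"), label = "toy") {
  stopifnot(n_atoms >= 3)
  atoms <- with_seed(seed, {
    pos <- matrix(numeric(0), 0, 3)
    attempts <- 0L
    while (nrow(pos) < n_atoms) {
      attempts <- attempts + 1L
      if (attempts > 10000L) stop("cube too small for ", n_atoms, " atoms")
      p <- stats::runif(3) * side
      if (nrow(pos) > 0 && min(sqrt(colSums((t(pos) - p)^2))) < 1.5) next
      pos <- rbind(pos, p)
    }
    data.frame(name = paste0("X", seq_len(n_atoms)),
               element = sample(elements, n_atoms, replace = TRUE),
               resname = "SIT", resid = 1L,
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               stringsAsFactors = FALSE)
  })
  binding_site(atoms, label)
}
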