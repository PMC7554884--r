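params <- tip3p_params()

test_that("pair_energy agrees with the 9-term site-site summation oracle", {
  set.seed(101)
  for (k in 1:100) {
    a <- random_water(runif(3, 0, 5), 1L)
    dir <- unitv_helper(rnorm(3))
    b <- random_water(a$pos[1, ] + runif(1, 2.5, 6) * dir, 2L)
    expect_lt(abs(pair_energy(a, b, params) -
                  oracle_pair_energy(a, b, params)), 1e-9)
    expect_identical(pair_energy(a, b, params), pair_energy(b, a, params))
  }
})

test_that("pair_energy physical sanity: decay, rigid invariance, singularity", {
  set.seed(102)
  a <- random_water(c(0, 0, 0), 1L)
  b <- random_water(c(50, 0, 0), 2L)
  expect_lt(abs(pair_energy(a, b, params)), 0.05)

  # rigid-body moves of the pair leave the energy unchanged to 1e-9
  for (k in 1:20) {
    a <- random_water(c(0, 0, 0), 1L)
    b <- random_water(c(2.9, 0.4, -0.2), 2L)
    e0 <- pair_energy(a, b, params)
    Q <- random_rotation(); t <- runif(3, -20, 20)
    mv <- function(w) water_molecule(w$pos[1, ] %*% Q + t,
                                     w$pos[2, ] %*% Q + t,
                                     w$pos[3, ] %*% Q + t, w$index)
    expect_lt(abs(pair_energy(mv(a), mv(b), params) - e0), 1e-9)
  }

  expect_error(pair_energy(a, a, params), "singular|coincident")
})

test_that("ideal hydrogen-bond dimer passes the criterion and matches the oracle", {
  d <- ideal_dimer(2.75)
  e <- pair_energy(d$donor, d$acceptor, params)
  expect_lt(abs(e - oracle_pair_energy(d$donor, d$acceptor, params)), 1e-9)
  expect_lte(e, params$hbond_energy_criterion)
})

test_that("build_hbond_graph applies cutoff, criterion and minimum image", {
  d <- ideal_dimer(2.75)
  fr <- twnring:::twn_frame(waters = list(d$donor, d$acceptor), frame_id = 1L)
  g <- build_hbond_graph(fr, params)
  expect_equal(nrow(g$edges), 1)
  expect_lte(g$edges$energy[1], params$hbond_energy_criterion)

  single <- twnring:::twn_frame(waters = list(d$donor), frame_id = 1L)
  g1 <- build_hbond_graph(single, params)
  expect_length(g1$nodes, 1)
  expect_equal(nrow(g1$edges), 0)

  far <- ideal_dimer(6.0)
  fr6 <- twnring:::twn_frame(waters = list(far$donor, far$acceptor),
                             frame_id = 1L)
  expect_equal(nrow(build_hbond_graph(fr6, params)$edges), 0)

  expect_error(build_hbond_graph(fr, params, minimum_image = TRUE), "box")

  # a bonded pair split across the periodic boundary is seen only under
  # the minimum-image convention
  shift_w <- function(w, t) water_molecule(w$pos[1, ] + t, w$pos[2, ] + t,
                                           w$pos[3, ] + t, w$index)
  box <- c(20, 20, 20)
  wrapped <- twnring:::twn_frame(
    waters = list(d$donor, shift_w(d$acceptor, c(20, 0, 0))),
    box = box, frame_id = 1L)
  expect_equal(nrow(build_hbond_graph(wrapped, params)$edges), 0)
  expect_equal(nrow(build_hbond_graph(wrapped, params,
                                      minimum_image = TRUE)$edges), 1)
})

test_that("raising the criterion toward zero never removes edges or rings", {
  spec <- plant_spec(n_noise_waters = 30L, n_frames = 1L, jitter_sigma = 0.3,
                     random_seed = 11L)
  fr <- generate_frames(spec)[[1]]
  crits <- c(-4, -2.25, -1, -0.25)
  prev_edges <- NULL
  prev_rings <- -1L
  for (cr in crits) {
    p <- tip3p_params(hbond_energy_criterion = cr)
    g <- build_hbond_graph(fr, p)
    keys <- paste(g$edges$i, g$edges$j)
    if (!is.null(prev_edges)) expect_true(all(prev_edges %in% keys))
    nr <- length(enumerate_rings(g))
    expect_gte(nr, prev_rings)
    prev_edges <- keys
    prev_rings <- nr
  }
})

test_that("enumerate_rings handles canonical small cases", {
  tri <- random_graph(3, 0)
  tri$edges <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3), energy = -5)
  rings <- enumerate_rings(tri)
  expect_length(rings, 1)
  expect_equal(rings[[1]]$members, c(1, 2, 3))
  expect_equal(rings[[1]]$ring_class, "R3")

  path4 <- random_graph(4, 0)
  path4$edges <- data.frame(i = 1:3, j = 2:4, energy = -5)
  expect_length(enumerate_rings(path4), 0)

  expect_length(enumerate_rings(random_graph(0, 0)), 0)
})

test_that("a chorded 6-cycle yields only its chordless sub-rings", {
  hexchord <- random_graph(6, 0)
  # hexagon 1-2-3-4-5-6 plus chord 1-4: two R4s, never the 6-cycle
  hexchord$edges <- data.frame(i = c(1, 2, 3, 4, 5, 6, 1),
                               j = c(2, 3, 4, 5, 6, 1, 4), energy = -5)
  keys <- ring_key_set(enumerate_rings(hexchord))
  expect_equal(keys, c("1-2-3-4", "1-4-5-6"))
  # chord 1-3 instead: an R3 and an R5
  hexchord$edges$j[7] <- 3
  keys <- ring_key_set(enumerate_rings(hexchord))
  expect_equal(keys, c("1-2-3", "1-3-4-5-6"))
  # against the exhaustive oracle as well
  expect_equal(keys, sapply(oracle_chordless_cycles(
    adjacency_matrix(hexchord)), paste, collapse = "-") |> sort())
})

test_that("enumerate_rings matches exhaustive enumeration on random graphs", {
  set.seed(103)
  for (trial in 1:60) {
    n <- sample(4:12, 1)
    g <- random_graph(n, runif(1, 0.15, 0.45))
    got <- ring_key_set(enumerate_rings(g))
    want <- sort(vapply(oracle_chordless_cycles(adjacency_matrix(g)),
                        paste, "", collapse = "-"))
    expect_identical(got, want)
  }
})

test_that("ring COM: symmetry, translation equivariance, direct-sum oracle", {
  # four waters with identical orientation at the corners of a square
  base <- plant_ring("R3")[[1]]
  mk_at <- function(t, idx) water_molecule(base$pos[1, ] + t,
                                           base$pos[2, ] + t,
                                           base$pos[3, ] + t, idx)
  sq <- list(mk_at(c(0, 0, 0), 1L), mk_at(c(4, 0, 0), 2L),
             mk_at(c(4, 4, 0), 3L), mk_at(c(0, 4, 0), 4L))
  fr <- twnring:::twn_frame(waters = sq, frame_id = 1L)
  ring <- list(members = 1:4, ring_class = "R4")
  com <- ring_center_of_mass(ring, fr)
  com_shift <- com - ring_center_of_mass(ring, twnring:::twn_frame(
    waters = lapply(sq, function(w)
      water_molecule(w$pos[1, ] - c(1, 2, 3), w$pos[2, ] - c(1, 2, 3),
                     w$pos[3, ] - c(1, 2, 3), w$index)), frame_id = 1L))
  expect_equal(com_shift, c(1, 2, 3))
  # identical orientations: ring COM = single-water COM shifted to the
  # square center (translation by the mean corner offset (2, 2, 0))
  single_com <- ring_center_of_mass(list(members = 1L), fr)
  expect_equal(com, single_com + c(2, 2, 0), tolerance = 1e-12)

  # direct-sum oracle on a planted R5
  ws <- plant_ring("R5", center = c(3, -2, 7), orientation_seed = 5L)
  fr5 <- twnring:::twn_frame(waters = ws, frame_id = 1L)
  m <- c(15.999, 1.008, 1.008)
  num <- c(0, 0, 0); den <- 0
  for (w in ws) for (s in 1:3) {
    num <- num + m[s] * w$pos[s, ]
    den <- den + m[s]
  }
  expect_equal(ring_center_of_mass(list(members = 1:5), fr5), num / den,
               tolerance = 1e-12)
})

test_that("analyze_frames tags frames, deduplicates within frame only, and is
           order-independent", {
  spec <- plant_spec(rings_to_plant = list(
                       list(ring_class = "R4", center = c(12, 12, 12),
                            orientation_seed = 3L)),
                     n_noise_waters = 0L, n_frames = 3L, random_seed = 5L)
  frames <- generate_frames(spec)
  tab <- analyze_frames(frames)
  expect_equal(nrow(tab), 3)                      # once per frame
  expect_equal(tab$frame_id, 1:3)
  expect_equal(unique(tab$ring_class), "R4")

  # permuting water storage order leaves the canonical ring list unchanged
  fr <- frames[[1]]
  perm <- rev(seq_along(fr$waters))
  fr_shuffled <- twnring:::twn_frame(waters = fr$waters[perm],
                                     box = fr$box, frame_id = fr$frame_id)
  t1 <- analyze_frames(list(fr))
  t2 <- analyze_frames(list(fr_shuffled))
  expect_equal(t1[, c("ring_class", "x", "y", "z")],
               t2[, c("ring_class", "x", "y", "z")], tolerance = 1e-12)

  empty <- twnring:::twn_frame(frame_id = 1L)
  expect_equal(nrow(analyze_frames(list(empty))), 0)
})
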