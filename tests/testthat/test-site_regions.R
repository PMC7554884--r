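spec5 <- region_spec(LETTERS[1:5],
                     rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0),
                           c(9, 5, 0), c(3, 5, 0)),
                     radius = rep(3.5, 5))

test_that("assign_region: containment, nearest-center, declaration-order ties", {
  expect_equal(assign_region(c(0, 0, 0), spec5), "A")
  expect_equal(assign_region(c(100, 0, 0), spec5), NA_character_)
  # inside overlapping spheres of A and B, nearer to B
  expect_equal(assign_region(c(3.4, 0, 0), spec5), "B")
  # exact tie between A and B: first declared wins
  expect_equal(assign_region(c(3, 0, 0), spec5), "A")

  # brute-force scan oracle on random points
  set.seed(21)
  for (k in 1:200) {
    p <- runif(3, -2, 14)
    d <- apply(spec5[, c("cx", "cy", "cz")], 1, function(cc)
      sqrt(sum((cc - p)^2)))
    inside <- which(d <= spec5$radius)
    want <- if (length(inside) == 0) NA_character_ else
      spec5$name[inside[order(d[inside], inside)[1]]]
    expect_identical(assign_region(p, spec5), want)
  }
})

ring_row <- function(x, y, z, frame = 1L)
  data.frame(frame_id = frame, ring_class = "R3", members = "1-2-3",
             x = x, y = y, z = z, stringsAsFactors = FALSE)

test_that("twn_distribution counts, excludes unassigned, and rounds ratios", {
  rings <- rbind(ring_row(0, 0, 0), ring_row(6, 0.5, 0), ring_row(6, -0.5, 0),
                 ring_row(50, 50, 50))
  d <- twn_distribution(rings, spec5)
  expect_equal(unname(d$counts[c("A", "B")]), c(1L, 2L))
  expect_equal(d$total, 3L)
  expect_equal(d$unassigned, 1L)
  expect_equal(unname(d$ratios[["A"]]), 33.3)
  expect_equal(unname(d$ratios[["B"]]), 66.7)
  # conservation
  expect_equal(sum(d$counts) + d$unassigned, nrow(rings))

  # permutation invariance and count doubling
  d_perm <- twn_distribution(rings[c(3, 1, 4, 2), ], spec5)
  expect_equal(d_perm$counts, d$counts)
  d_double <- twn_distribution(rbind(rings, rings), spec5)
  expect_equal(d_double$counts, 2L * d$counts)
  expect_equal(d_double$ratios, d$ratios)

  # all rings in one region
  one <- twn_distribution(rbind(ring_row(0, 0, 0), ring_row(0.5, 0, 0)), spec5)
  expect_equal(unname(one$ratios[["A"]]), 100.0)
  expect_equal(sum(one$ratios), 100.0)

  # nothing assigned -> all-zero ratios with a warning
  expect_warning(z <- twn_distribution(ring_row(99, 99, 99), spec5),
                 "undefined")
  expect_true(all(z$ratios == 0))
  expect_true(z$empty_warning)
})

test_that("published occupancy tables reproduce under the ratio arithmetic", {
  d1 <- distribution_from_counts(c(A = 11, B = 0, C = 31, D = 4, E = 11))
  expect_equal(d1$total, 57L)
  expect_equal(unname(d1$ratios), c(19.3, 0.0, 54.4, 7.0, 19.3))

  d3 <- distribution_from_counts(c(A = 0, B = 6, C = 26, D = 0, E = 9))
  expect_equal(d3$total, 41L)
  expect_equal(unname(d3$ratios[["C"]]), 63.4)

  # ratios always sum to 100 within rounding slack
  set.seed(22)
  for (k in 1:50) {
    cnt <- rpois(5, 10)
    if (sum(cnt) == 0) next
    d <- distribution_from_counts(setNames(cnt, LETTERS[1:5]))
    expect_lt(abs(sum(d$ratios) - 100), 0.21)
    expect_equal(unname(d$ratios),
                 twnring:::round_half_away(100 * cnt / sum(cnt), 1))
  }
})

test_that("region spec round-trips through CSV and ligand-derived spheres work", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_spec(spec5, path)
  expect_equal(load_region_spec(path), spec5, ignore_attr = TRUE)

  lig <- make_toy_ligand("rod", 8, seed = 3)
  rs <- make_region_spec_from_ligand(lig, list(head = 1:4, tail = 5:8))
  expect_equal(rs$name, c("head", "tail"))
  expect_equal(rs$radius, c(3, 3))
  expect_equal(unname(unlist(rs[1, c("cx", "cy", "cz")])),
               unname(colMeans(lig[1:4, c("x", "y", "z")])))
})
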