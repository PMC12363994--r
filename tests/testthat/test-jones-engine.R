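# closed planar curve with a single kink (polygonal limacon, inner loop);
# the z-offset separates the two strands at the crossing
kinked_unknot <- function(flip = FALSE) {
  th <- 2 * pi * (0:23) / 24
  r <- 0.5 + cos(th)
  z <- 0.1 * sin(th) * (if (flip) -1 else 1)
  curve_collection(polyline(cbind(r * cos(th), r * sin(th), z), closed = TRUE))
}

test_that("segment cycle counts reproduce the worked two-component example", {
  l_hat <- c(2L, 1L, 4L, 3L)            # (1,2)(3,4)
  expect_identical(segment_cycle_count(l_hat, c(3L, 4L, 1L, 2L)), 1L)  # (1,3)(2,4)
  expect_identical(segment_cycle_count(l_hat, l_hat), 2L)              # (1,2)(3,4)
  expect_identical(segment_cycle_count(c(2L, 1L), c(2L, 1L)), 1L)
  expect_error(segment_cycle_count(c(1L, 2L), c(2L, 1L)), "involution")
  expect_error(segment_cycle_count(c(2L, 1L, 4L, 3L), c(2L, 1L)), "different sets")
})

test_that("every state of random small diagrams satisfies the segment-cycle bound", {
  for (seed in 1:30) {
    D <- random_diagram(seed, max_crossings = 6)
    n_open <- D$n_open
    c <- nrow(D$crossings)
    l_hat <- diagram_pairing(D)
    for (s in 0:(2^c - 1)) {
      lab <- if (c > 0) as.logical(intToBits(s)[1:c]) else logical(0)
      tr <- smooth_and_trace(D, lab)
      cyc <- segment_cycle_count(l_hat, tr$s_hat)
      expect_gte(cyc, 1L)
      expect_lte(cyc, n_open)
    }
  }
})

test_that("smoothing a two-arc double crossing yields the two reported pairings", {
  # two open arcs crossing twice (open analogue of the Hopf diagram)
  hl <- curve_collection(list(
    polyline(rbind(c(-2, 0, 0), c(2, 0, 0))),
    polyline(rbind(c(-1, -1, 1), c(-1, 1, 1), c(1, 1, 1), c(1, -1, 1)))))
  D <- project_curves(hl, c(0, 0, 1))
  expect_equal(nrow(D$crossings), 2L)
  pairings <- unique(lapply(0:3, function(s)
    smooth_and_trace(D, as.logical(intToBits(s)[1:2]))$s_hat))
  expect_setequal(lapply(pairings, as.integer),
                  list(c(3L, 4L, 1L, 2L), c(2L, 1L, 4L, 3L)))
})

test_that("crossingless brackets take their closed-form values", {
  arc <- curve_collection(polyline(rbind(c(0, 0, 0), c(1, 0, 0))))
  D1 <- project_curves(arc, c(0, 0, 1))
  expect_true(lp_equal(bracket(D1), laurent(1, 0L)))           # single arc -> 1
  expect_true(lp_equal(normalized_bracket(D1), laurent(1, 0L)))

  two <- curve_collection(list(polyline(rbind(c(0, 0, 0), c(1, 0, 0))),
                               polyline(rbind(c(0, 5, 0), c(1, 5, 0)))))
  expect_true(lp_equal(bracket(project_curves(two, c(0, 0, 1))), lp_d()))

  tr <- smooth_and_trace(D1, logical(0))
  expect_equal(tr$circ, 0L)
  expect_equal(tr$s_hat, c(2L, 1L))
})

test_that("state enumeration agrees with the recursive skein oracle", {
  diagrams <- list(
    project_curves(make_polygonal_knot("trefoil"), c(0, 0, 1)),
    project_curves(make_polygonal_knot("hopf"), c(0, 0, 1)),
    project_curves(kinked_unknot(), c(0, 0, 1)))
  for (seed in 1:10) diagrams <- c(diagrams, list(random_diagram(seed + 100)))
  for (D in diagrams) {
    expect_true(lp_equal(bracket(D), oracle_bracket(D)))
  }
})

test_that("normalization cancels kinks and the crossing cap errors loudly", {
  ku <- kinked_unknot()
  Dk <- project_curves(ku, c(0, 0, 1))
  expect_equal(nrow(Dk$crossings), 1L)
  expect_true(lp_equal(bracket(Dk),
                       laurent(-1, if (writhe(Dk) > 0) 3L else -3L)))
  expect_true(lp_equal(normalized_bracket(Dk), laurent(1, 0L)))
  expect_true(lp_equal(normalized_bracket(project_curves(kinked_unknot(TRUE),
                                                         c(0, 0, 1))),
                       laurent(1, 0L)))
  Dt <- project_curves(make_polygonal_knot("trefoil"), c(0, 0, 1))
  expect_error(bracket(Dt, max_crossings = 2), class = "pjones_too_many_crossings")
})

test_that("closed fixtures reproduce their classical Jones polynomials", {
  # trefoil: identical normalized bracket in >= 50 directions, V(10) = 0.1009
  tre <- make_polygonal_knot("trefoil")
  dirs <- sample_directions(50, "fibonacci")
  jv <- jones(tre, directions = dirs, t = 10, keep_directions = TRUE)
  for (p in jv$per_direction) expect_true(lp_equal(p, jv$polynomial))
  expect_equal(jv$t_evaluations[[1]], -1e-4 + 1e-3 + 1e-1, tolerance = 1e-12)

  mir <- make_polygonal_knot("mirror_trefoil")
  jm <- jones(mir, n_directions = 5, t = 10)
  expect_true(lp_equal(jm$polynomial, lp_mirror(jv$polynomial)))

  un <- make_polygonal_knot("unknot")
  ju <- jones(un, n_directions = 10, t = c(2, 10))
  expect_true(lp_equal(ju$polynomial, laurent(1, 0L)))
  expect_equal(unname(ju$t_evaluations), c(1, 1))

  # Hopf link: oracle-computed invariant, same in every direction
  hp <- make_polygonal_knot("hopf")
  Dh <- project_curves(hp, c(0, 0, 1))
  f_oracle <- lp_scale(oracle_bracket(Dh), s = (-1)^writhe(Dh),
                       k = -3L * writhe(Dh))
  jh <- jones(hp, n_directions = 10, t = 10)
  expect_true(lp_equal(jh$polynomial, f_oracle, tol = 1e-12))
  expect_equal(jh$t_evaluations[[1]], -(sqrt(10) + 10^2.5), tolerance = 1e-9)
})

test_that("sphere-averaged Jones of trivial configurations is exact", {
  one <- curve_collection(polyline(rbind(c(0, 0, 0), c(3, 1, 2))))
  jv <- jones(one, n_directions = 20, t = c(2, 10, 100))
  expect_equal(unname(jv$t_evaluations), c(1, 1, 1))

  two <- curve_collection(list(polyline(rbind(c(0, 0, 0), c(1, 0, 0))),
                               polyline(rbind(c(0, 50, 0), c(1, 50, 0)))))
  jv2 <- jones(two, n_directions = 20, t = 10)
  expect_equal(jv2$t_evaluations[[1]], -(sqrt(10) + 1 / sqrt(10)),
               tolerance = 1e-12)

  expect_equal(trivial_jones_value(1, 10), 1)
  expect_equal(trivial_jones_value(2, 10), -(sqrt(10) + 1 / sqrt(10)))
  expect_equal(trivial_jones_value(3, 10), (sqrt(10) + 1 / sqrt(10))^2)
})

test_that("open arcs approach the closed invariant as the endpoint gap shrinks", {
  dirs <- sample_directions(40, "fibonacci")
  closed_val <- -1e-4 + 1e-3 + 1e-1
  diffs <- vapply(c(0.5, 0.05), function(g) {
    jv <- jones(open_trefoil_arc(g), directions = dirs, t = 10)
    abs(jv$t_evaluations[[1]] - closed_val)
  }, 1.0)
  expect_lt(diffs[2], diffs[1])
})

test_that("the Jones value at t = 10 is stable under small perturbations", {
  dirs <- sample_directions(40, "fibonacci")
  L <- open_trefoil_arc(0.1)
  base <- jones(L, directions = dirs, t = 10)$t_evaluations[[1]]
  diam <- collection_diameter(L)
  drift <- vapply(c(5e-2, 5e-3), function(rel) {
    Lp <- perturb_curves(L, rel * diam, seed = 8)
    abs(jones(Lp, directions = dirs, t = 10)$t_evaluations[[1]] - base)
  }, 1.0)
  expect_lte(drift[2], drift[1])
  expect_lt(drift[1], 0.2)
})
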