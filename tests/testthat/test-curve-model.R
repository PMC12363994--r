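helix_chord <- function(k, radius = 2.3, rise = 1.5, twist = 100) {
  sqrt((2 * radius * sin(k * twist * pi / 180 / 2))^2 + (k * rise)^2)
}

test_that("midpoint segmentation cuts at forced breakpoints and reconstructs the chain", {
  ch <- polyline(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  seg <- segment_at_midpoints(ch)
  expect_length(seg$segments, 3)
  expect_equal(seg$segments[[1]]$vertices[2, 1], 1)  # midpoint x = 1
  expect_equal(seg$segments[[3]]$vertices[1, 1], 3)  # midpoint x = 3
  expect_equal(seg$representative_points, ch$vertices)

  hx <- make_ideal_helix(19)
  segh <- segment_at_midpoints(hx)
  expect_length(segh$segments, 19)
  # each segment contains its Calpha as an interior (or terminal) vertex
  for (i in 1:19) {
    expect_true(any(apply(segh$segments[[i]]$vertices, 1,
                          function(v) all(abs(v - hx$vertices[i, ]) < 1e-12))))
  }
  # concatenated segments reproduce the parent path: consecutive segments
  # share their breakpoint, and each breakpoint is the edge midpoint
  for (i in 1:18) {
    a <- segh$segments[[i]]$vertices
    b <- segh$segments[[i + 1]]$vertices
    expect_equal(a[nrow(a), ], b[1, ])
    expect_equal(a[nrow(a), ], (hx$vertices[i, ] + hx$vertices[i + 1, ]) / 2)
  }
  expect_error(segment_at_midpoints(polyline(diag(3), closed = TRUE)),
               "open chains")
})

test_that("segment distances follow the representative and sup metrics", {
  a <- polyline(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(segment_distance(a, a, "sup"), 0)
  expect_equal(segment_distance(a, a, "representative",
                                rep_a = c(0.5, 0, 0), rep_b = c(0.5, 0, 0)), 0)
  expect_equal(segment_distance(a, a, "representative",
                                rep_a = c(0, 0, 0), rep_b = c(3.8, 0, 0)), 3.8)
  b <- polyline(rbind(c(0, 1, 0), c(1, 1, 0)))  # parallel, offset 1 in y
  expect_equal(segment_distance(a, b, "sup"), 1.0, tolerance = 1e-12)
  expect_error(segment_distance(a, b, "nonsense"))
})

test_that("distance matrices satisfy the metric-output invariants", {
  one <- segment_at_midpoints(polyline(rbind(c(0, 0, 0), c(1, 0, 0))))
  expect_equal(unclass(segment_distance_matrix(one, "sup"))[1, 1],
               0, ignore_attr = TRUE)

  ch <- segment_at_midpoints(polyline(cbind(c(0, 3.8, 7.6), 0, 0)))
  D <- segment_distance_matrix(ch, "representative")
  expect_equal(sort(D[upper.tri(D)]), c(3.8, 3.8, 7.6))

  segh <- segment_at_midpoints(make_ideal_helix(19))
  Dh <- segment_distance_matrix(segh, "representative")
  for (k in 1:4) {
    expect_equal(Dh[1, 1 + k], helix_chord(k), tolerance = 1e-9)
  }
  expect_lt(Dh[1, 4], Dh[1, 3])  # d(i,i+3) < d(i,i+2) on the ideal helix

  for (seed in 1:3) {
    L <- random_collection(seed, n_comp = 3)
    seg <- combine_segmentations(lapply(L$components, function(p)
      segment_at_midpoints(polyline(p$vertices))))
    for (metric in c("representative", "sup")) {
      M <- segment_distance_matrix(seg, metric, n_samples = 8)
      expect_equal(unclass(M), t(unclass(M)), ignore_attr = TRUE)
      expect_equal(diag(M), rep(0, nrow(M)))
      expect_true(all(M >= 0))
    }
  }
})

test_that("perturbation respects the sup-norm bound and is reproducible", {
  L <- curve_collection(make_ideal_helix(10))
  expect_identical(perturb_curves(L, 0, seed = 1), L)
  for (eps in c(0.1, 0.01)) {
    Lp <- perturb_curves(L, eps, seed = 42)
    disp <- abs(Lp$components[[1]]$vertices - L$components[[1]]$vertices)
    expect_lt(max(sqrt(rowSums(disp^2))), eps)
  }
  expect_identical(perturb_curves(L, 0.1, seed = 7),
                   perturb_curves(L, 0.1, seed = 7))
  expect_error(perturb_curves(L, -1, seed = 1), "non-negative")
})

test_that("synthetic fixtures realize their stated geometry", {
  hx <- make_ideal_helix(2)
  expect_equal(nrow(hx$vertices), 2)
  expect_equal(sqrt(sum(diff(hx$vertices)^2)), helix_chord(1), tolerance = 1e-9)

  st <- make_parallel_strands(8)
  expect_equal(sum(vapply(st$components, function(p) nrow(p$vertices), 1L)), 16L)
  expect_equal(sqrt(sum((st$components[[1]]$vertices[1, ] -
                           st$components[[2]]$vertices[1, ])^2)), 4.8)
  expect_equal(sqrt(sum((st$components[[1]]$vertices[1, ] -
                           st$components[[2]]$vertices[2, ])^2)),
               sqrt(3.8^2 + 4.8^2))

  un <- make_polygonal_knot("unknot")
  expect_equal(nrow(project_curves(un, c(0, 0, 1))$crossings), 0L)

  tre <- make_polygonal_knot("trefoil")
  Dt <- project_curves(tre, c(0, 0, 1))
  expect_equal(nrow(Dt$crossings), 3L)
  expect_length(unique(Dt$crossings$sign), 1)

  hp <- make_polygonal_knot("hopf")
  expect_length(hp$components, 2)
  Dh <- project_curves(hp, c(0, 0, 1))
  expect_equal(abs(sum(Dh$crossings$sign) / 2), 1)  # projection linking number
})

test_that("plain-text curve format round-trips", {
  L <- curve_collection(list(make_ideal_helix(4),
                             make_polygonal_knot("unknot")$components[[1]]))
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_curves(L, path)
  L2 <- read_curves(path)
  expect_equal(length(L2$components), 2)
  expect_equal(L2$components[[1]]$vertices, L$components[[1]]$vertices)
  expect_true(L2$components[[2]]$closed)
})
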