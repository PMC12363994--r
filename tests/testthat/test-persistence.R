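test_that("critical values are the distinct pairwise distances", {
  D3 <- as.matrix(dist(cbind(c(0, 1, 2), 0, 0)))
  expect_equal(vr_critical_values(D3), c(1, 2))
  expect_equal(vr_critical_values(matrix(0, 1, 1)), numeric(0))
  seg <- segment_at_midpoints(make_ideal_helix(19))
  Dh <- segment_distance_matrix(seg, "representative")
  expect_equal(vr_critical_values(Dh)[1:3], c(3.8298, 5.0537, 5.4334),
               tolerance = 1e-4)
})

test_that("the three-point facet filtration matches the hand enumeration", {
  D3 <- as.matrix(dist(cbind(c(0, 1, 2), 0, 0)))
  ff <- facet_filtration(D3)
  expect_equal(nrow(ff), 6L)  # 3 vertices + 2 edges + 1 triangle
  f0 <- ff[ff$dim == 0, ]
  expect_equal(f0$birth, rep(0, 3))
  expect_equal(f0$death, rep(1, 3))
  f1 <- ff[ff$dim == 1, ]
  expect_setequal(f1$key, c("1-2", "2-3"))
  expect_equal(f1$birth, rep(1, 2))
  expect_equal(f1$death, rep(2, 2))
  f2 <- ff[ff$dim == 2, ]
  expect_equal(f2$key, "1-2-3")
  expect_equal(f2$birth, 2)
  expect_equal(f2$death, Inf)
})

test_that("facet tracking equals exhaustive subset enumeration on random configurations", {
  for (seed in 1:20) {
    n <- sample(3:8, 1)
    D <- random_distance_matrix(seed, n)
    ff <- facet_filtration(D)
    or <- oracle_facets(D)
    ff <- ff[order(ff$key), ]
    expect_equal(ff$key, or$key)
    expect_equal(ff$birth, or$birth)
    expect_equal(ff$death, or$death)
  }
})

test_that("Vietoris-Rips complexes are nested along the filtration", {
  for (seed in 31:34) {
    D <- random_distance_matrix(seed, 7)
    crit <- vr_critical_values(D)
    prev <- NULL
    for (r in c(0, crit)) {
      cl <- pjones:::.cliques_at(D, r, 1e-9)
      if (!is.null(prev)) {
        # every earlier facet is contained in some current facet
        for (f in prev) {
          expect_true(any(vapply(cl, function(g) all(f %in% g), TRUE)))
        }
      }
      prev <- cl
    }
  }
})

test_that("helix and strand-pair barcodes reproduce the secondary-structure counts", {
  seg <- segment_at_midpoints(make_ideal_helix(19))
  D <- segment_distance_matrix(seg, "representative")
  ff <- facet_filtration(D)
  f0 <- ff[ff$dim == 0, ]
  expect_equal(nrow(f0), 19L)
  expect_equal(unique(round(f0$death - f0$birth, 3)), 3.83)
  f1 <- ff[ff$dim == 1, ]
  adj <- vapply(f1$vertices, function(v) diff(v) == 1L, TRUE)
  expect_equal(sum(adj), 18L)
  expect_equal(sum(!adj), 16L)
  expect_equal(unique(round(f1$death[adj], 2)), 5.43)
  expect_equal(unique(round(f1$birth[!adj], 2)), 5.05)

  seg2 <- strand_segmentation(8)
  D2 <- segment_distance_matrix(seg2, "representative")
  ff2 <- facet_filtration(D2)
  expect_equal(sum(ff2$dim == 0), 16L)
  f12 <- ff2[ff2$dim == 1, ]
  adj2 <- vapply(f12$vertices, function(v)
    diff(v) == 1L && !(v[1] == 8L && v[2] == 9L), TRUE)
  expect_equal(sum(adj2), 14L)   # sequence-adjacent within a strand
  expect_equal(sum(!adj2), 8L)   # cross-strand pairs
})

test_that("facet weights follow the raw and relative conventions", {
  one <- segment_at_midpoints(polyline(rbind(c(0, 0, 0), c(3.8, 0, 0),
                                             c(7.6, 0, 0))))
  # two far-apart straight segments: raw weight d(10), relative weight 0
  far <- combine_segmentations(list(
    segment_at_midpoints(polyline(rbind(c(0, 0, 0), c(1, 0, 0)))),
    segment_at_midpoints(polyline(rbind(c(0, 40, 0), c(1, 40, 0))))))
  Df <- segment_distance_matrix(far, "representative")
  js <- jones_settings(n_directions = 10)
  raw <- weighted_barcode(far, Df, settings = js, weight_convention = "raw")
  rel <- weighted_barcode(far, Df, settings = js, weight_convention = "relative")
  # 4 vertices + 4 pair facets (2 intra, 2 shortest-cross) + the full set
  expect_equal(nrow(raw$bars), 9L)
  pair <- raw$bars[raw$bars$dim == 1, ]
  expect_equal(pair$weight, rep(-(sqrt(10) + 1 / sqrt(10)), nrow(pair)),
               tolerance = 1e-10)
  expect_equal(rel$bars$weight[rel$bars$dim == 1],
               rep(0, sum(rel$bars$dim == 1)), tolerance = 1e-10)
  expect_equal(rel$bars$weight[rel$bars$dim == 0],
               rep(0, sum(rel$bars$dim == 0)))
  expect_equal(raw$bars$weight[raw$bars$dim == 0],
               rep(1, sum(raw$bars$dim == 0)))

  # 3-collinear toy: 6 bars in total across dimensions
  D1 <- segment_distance_matrix(one, "representative")
  wb <- weighted_barcode(one, D1, settings = js)
  expect_equal(nrow(wb$bars), 6L)
})

test_that("facets above the weight cap stay uncomputed unless forced", {
  seg <- segment_at_midpoints(make_ideal_helix(6))
  D <- segment_distance_matrix(seg, "representative")
  wb <- weighted_barcode(seg, D, settings = jones_settings(n_directions = 5),
                         max_weight_size = 2)
  expect_true(all(is.na(wb$bars$weight[wb$bars$size > 2])))
  expect_true(all(!is.na(wb$bars$weight[wb$bars$size <= 2])))
})

test_that("diagram multiplicities match the alternating corner sums and are nonnegative", {
  seg <- segment_at_midpoints(make_ideal_helix(19))
  D <- segment_distance_matrix(seg, "representative")
  wb <- weighted_barcode(seg, D, settings = jones_settings(n_directions = 5),
                         max_weight_size = 1)
  crit <- wb$critical_values
  dg <- barcode_diagram(wb, dimensions = 1L)
  pts <- dg$points[order(dg$points$birth), ]
  expect_equal(nrow(pts), 2L)
  expect_equal(pts$multiplicity, c(18L, 16L))
  expect_equal(pts$birth, c(crit[1], crit[2]), tolerance = 1e-9)
  expect_equal(pts$death, rep(crit[3], 2), tolerance = 1e-9)
  bars1 <- wb$bars[wb$bars$dim == 1L, ]
  for (i in seq_len(nrow(pts))) {
    expect_equal(pts$multiplicity[i],
                 oracle_multiplicity(bars1, pts$birth[i], pts$death[i], crit))
  }
  expect_true(all(dg$points$multiplicity >= 0))

  empty <- barcode_diagram(wb, dimensions = 99L)
  expect_equal(nrow(empty$points), 0L)
})
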