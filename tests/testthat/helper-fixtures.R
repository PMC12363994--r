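# Synthetic fixtures shared across the suite.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

# random collection of short open/closed polylines in a flat box (flat in z
# so projections along generic directions pick up a few crossings)
random_collection <- function(seed, n_comp = NULL, closed_prob = 0.3) {
  set.seed(seed)
  if (is.null(n_comp)) n_comp <- sample(2:5, 1)
  comps <- lapply(seq_len(n_comp), function(i) {
    nv <- sample(3:5, 1)
    repeat {
      v <- cbind(runif(nv, 0, 2), runif(nv, 0, 2), runif(nv, 0, 0.5))
      d <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nv, , drop = FALSE])^2))
      if (all(d > 1e-3)) break
    }
    closed <- nv >= 3 && runif(1) < closed_prob
    if (closed) {
      # guard the closing edge too
      if (sqrt(sum((v[1, ] - v[nv, ])^2)) < 1e-3) closed <- FALSE
    }
    polyline(v, closed = closed)
  })
  curve_collection(comps)
}

# random linkoid diagram with at most max_crossings crossings and at least
# one open component (regenerates until the cap is met)
random_diagram <- function(seed, max_crossings = 8) {
  for (k in 0:50) {
    L <- random_collection(seed + 1000L * k)
    if (!any(!vapply(L$components, `[[`, TRUE, "closed"))) next
    xi <- sample_directions(1, "uniform_random", seed = seed + 1000L * k + 1)
    D <- project_curves(L, xi[1, ], jitter_seed = seed + 2L)
    if (nrow(D$crossings) <= max_crossings) return(D)
  }
  stop("could not generate a small diagram")
}

# random configuration of n points in 3-space and its distance matrix
random_distance_matrix <- function(seed, n) {
  set.seed(seed)
  pts <- matrix(runif(3 * n, 0, 2), n, 3)
  D <- as.matrix(dist(pts))
  dimnames(D) <- NULL
  D
}

# midpoint segmentation of the two-strand fixture
strand_segmentation <- function(n_per_strand = 8) {
  st <- make_parallel_strands(n_per_strand)
  combine_segmentations(lapply(st$components, segment_at_midpoints))
}

# open arc cut from the closed polygonal trefoil, leaving an endpoint gap of
# gap_frac * diameter
open_trefoil_arc <- function(gap_frac) {
  tre <- make_polygonal_knot("trefoil")
  v <- tre$components[[1]]$vertices
  gap <- gap_frac * collection_diameter(tre)
  vv <- rbind(v, v[1, ])
  el <- sqrt(rowSums(diff(vv)^2))
  keep_len <- sum(el) - gap
  acc <- cumsum(el)
  k <- max(which(acc <= keep_len))
  pts <- vv[1:(k + 1), , drop = FALSE]
  rem <- keep_len - acc[k]
  if (rem > 1e-9) {
    dirv <- vv[k + 2, ] - vv[k + 1, ]
    dirv <- dirv / sqrt(sum(dirv^2))
    pts <- rbind(pts, vv[k + 1, ] + dirv * rem)
  }
  curve_collection(polyline(pts))
}

# hand-rolled weighted diagram for bottleneck tests
toy_diagram <- function(birth = numeric(), death = numeric(),
                        weight = numeric(), multiplicity = NULL) {
  if (is.null(multiplicity)) multiplicity <- rep(1L, length(birth))
  structure(list(points = data.frame(dim = rep(0L, length(birth)),
                                     birth = birth, death = death,
                                     weight = weight,
                                     multiplicity = multiplicity),
                 t = 10),
            class = "weighted_diagram")
}

# minimal PDB text fixtures (column-exact), written to a temp file
write_toy_pdb <- function(path, altloc = FALSE) {
  fmt <- function(serial, alt, resno, x, y, z, occ, b, chain = "A") {
    sprintf("ATOM  %5d  CA %1sALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial, alt, chain, resno, x, y, z, occ, b)
  }
  lines <- c(
    fmt(1, " ", 1, 0.0, 0.0, 0.0, 1.00, 10.0),
    if (altloc) c(fmt(2, "A", 2, 3.8, 0.0, 0.0, 0.60, 20.0),
                  fmt(3, "B", 2, 3.9, 0.1, 0.0, 0.40, 99.0))
    else fmt(2, " ", 2, 3.8, 0.0, 0.0, 1.00, 20.0),
    fmt(4, " ", 3, 7.6, 0.0, 0.0, 1.00, 30.0),
    "END")
  writeLines(lines, path)
  path
}
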