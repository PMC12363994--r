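#' Polygonal curves in 3-space
#'
#' A polyline is an ordered list of 3D vertices (in Angstrom), open or
#' closed.  Closed polylines have an implicit edge from the last vertex back
#' to the first.  Polylines are the components of a [curve_collection()],
#' the universe every Jones computation acts on.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z) or an object
#'   coercible to one.
#' @param closed logical; is the curve closed?
#' @return An object of class `polyline`.
#' @export
polyline <- function(vertices, closed = FALSE) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 3) stop("vertices must have 3 columns")
  if (nrow(v) < 2) stop("a polyline needs at least 2 vertices")
  if (closed && nrow(v) < 3) stop("a closed polyline needs at least 3 vertices")
  if (!all(is.finite(v))) stop("vertices must be finite")
  d <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  if (closed) d <- c(d, sqrt(sum((v[1, ] - v[nrow(v), ])^2)))
  if (any(d == 0)) stop("consecutive vertices must be distinct")
  structure(list(vertices = v, closed = isTRUE(closed)), class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline> %d vertices, %s\n", nrow(x$vertices),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Collections of disjoint open or closed curves
#'
#' @param components a list of [polyline()] objects (or a single polyline).
#' @return An object of class `curve_collection`.
#' @export
curve_collection <- function(components) {
  if (inherits(components, "polyline")) components <- list(components)
  stopifnot(is.list(components), length(components) >= 1)
  if (!all(vapply(components, inherits, TRUE, "polyline")))
    stop("all components must be polylines")
  n <- length(components)
  if (n > 1) {
    key <- vapply(components, function(p)
      paste(c(p$closed, as.vector(p$vertices)), collapse = ","), "")
    if (anyDuplicated(key)) stop("components must be pairwise non-identical")
  }
  structure(list(components = components), class = "curve_collection")
}

#' @export
print.curve_collection <- function(x, ...) {
  nc <- length(x$components)
  no <- sum(!vapply(x$components, `[[`, TRUE, "closed"))
  cat(sprintf("<curve_collection> %d component(s): %d open, %d closed\n",
              nc, no, nc - no))
  invisible(x)
}

all_vertices <- function(L) do.call(rbind, lapply(L$components, `[[`, "vertices"))

#' Diameter of a curve collection
#'
#' Largest pairwise vertex distance; used to scale tolerances and
#' perturbations.
#' @param L a `curve_collection`.
#' @export
collection_diameter <- function(L) {
  v <- all_vertices(L)
  if (nrow(v) > 600) v <- v[seq(1, nrow(v), length.out = 600), , drop = FALSE]
  max(stats::dist(v))
}

#' Segment an open chain at inter-vertex midpoints
#'
#' Cuts an open chain at the midpoint between each representative vertex
#' (e.g. Calpha atom) and its neighbour, the segmentation used for protein
#' chains.  Segment i runs from midpoint(c[i-1], c[i]) through c[i] to
#' midpoint(c[i], c[i+1]); the first and last segments are half-length.
#'
#' @param chain an open `polyline` whose vertices are the representative
#'   points.
#' @return A `segmentation`: list of open polyline segments, one
#'   representative point per segment, and the parent collection.
#' @export
segment_at_midpoints <- function(chain) {
  stopifnot(inherits(chain, "polyline"))
  if (chain$closed) stop("midpoint segmentation is defined for open chains only")
  v <- chain$vertices
  n <- nrow(v)
  mid <- (v[-n, , drop = FALSE] + v[-1, , drop = FALSE]) / 2
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    pts <- rbind(if (i > 1) mid[i - 1, ], v[i, ], if (i < n) mid[i, ])
    segs[[i]] <- polyline(pts, closed = FALSE)
  }
  structure(list(segments = segs, representative_points = v,
                 parent = curve_collection(chain)),
            class = "segmentation")
}

#' Combine several segmentations into one
#'
#' Used for multi-chain systems such as beta-sheet strand pairs: the
#' segments and representative points are concatenated in order.
#' @param segs a list of `segmentation` objects.
#' @export
combine_segmentations <- function(segs) {
  stopifnot(length(segs) >= 1, all(vapply(segs, inherits, TRUE, "segmentation")))
  structure(list(
    segments = do.call(c, lapply(segs, `[[`, "segments")),
    representative_points = do.call(rbind, lapply(segs, `[[`, "representative_points")),
    parent = curve_collection(do.call(c, lapply(segs, function(s) s$parent$components)))
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d segments\n", length(x$segments)))
  invisible(x)
}

# minimum distance from points (m x 3) to an edge [a, b]
.points_to_edge <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
          (p[, 3] - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- p[, 1] - (a[1] + t * ab[1])
  dy <- p[, 2] - (a[2] + t * ab[2])
  dz <- p[, 3] - (a[3] + t * ab[3])
  sqrt(dx^2 + dy^2 + dz^2)
}

.polyline_edges <- function(pl) {
  v <- pl$vertices
  n <- nrow(v)
  idx <- if (pl$closed) cbind(seq_len(n), c(2:n, 1)) else cbind(1:(n - 1), 2:n)
  idx
}

# dense sample of points along a polyline: vertices plus n interior points/edge
.sample_polyline <- function(pl, n_samples) {
  v <- pl$vertices
  idx <- .polyline_edges(pl)
  out <- v
  if (n_samples > 0) {
    t <- seq_len(n_samples) / (n_samples + 1)
    for (k in seq_len(nrow(idx))) {
      a <- v[idx[k, 1], ]; b <- v[idx[k, 2], ]
      out <- rbind(out, outer(1 - t, a) + outer(t, b))
    }
  }
  out
}

# one-sided sup_{x in a} dist(x, b), sampled on a
.sup_dist_one_sided <- function(a, b, n_samples) {
  pts <- .sample_polyline(a, n_samples)
  idx <- .polyline_edges(b)
  mind <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(idx))) {
    mind <- pmin(mind, .points_to_edge(pts, b$vertices[idx[k, 1], ],
                                       b$vertices[idx[k, 2], ]))
  }
  max(mind)
}

#' Distance between two curve segments
#'
#' Two metrics are supported.  `"representative"` is the Euclidean distance
#' between the representative points (for protein work, the Calpha atoms).
#' `"sup"` is the symmetrized supremum distance: the larger of the two
#' one-sided suprema of point-to-polyline distance, evaluated on a dense
#' sampling of edge points; an upper bound on how far the two segments
#' stray from each other.
#'
#' @param a,b `polyline` segments.
#' @param metric `"representative"` or `"sup"`.
#' @param rep_a,rep_b representative points (length-3 numeric), required for
#'   the representative metric.
#' @param n_samples interior sample points per edge for the sup metric.
#' @return Distance in Angstrom.
#' @export
segment_distance <- function(a, b, metric = c("representative", "sup"),
                             rep_a = NULL, rep_b = NULL, n_samples = 32) {
  metric <- match.arg(metric)
  if (metric == "representative") {
    if (is.null(rep_a) || is.null(rep_b))
      stop("representative metric requires representative points")
    return(sqrt(sum((rep_a - rep_b)^2)))
  }
  max(.sup_dist_one_sided(a, b, n_samples), .sup_dist_one_sided(b, a, n_samples))
}

#' Inter-segment distance matrix of a segmentation
#'
#' @param seg a `segmentation`.
#' @param metric see [segment_distance()].
#' @param n_samples sup-metric sampling density.
#' @return A symmetric n x n matrix with zero diagonal, with the metric
#'   name in attribute `metric`.
#' @export
segment_distance_matrix <- function(seg, metric = c("representative", "sup"),
                                    n_samples = 32) {
  metric <- match.arg(metric)
  n <- length(seg$segments)
  if (metric == "representative") {
    D <- as.matrix(stats::dist(seg$representative_points))
    dimnames(D) <- NULL
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      D[i, j] <- D[j, i] <- segment_distance(seg$segments[[i]], seg$segments[[j]],
                                             "sup", n_samples = n_samples)
    }
  }
  attr(D, "metric") <- metric
  D
}

#' Randomly perturb a curve collection
#'
#' Displaces every vertex by an independent random vector drawn uniformly
#' from the open ball of radius `eps`, so that the sup-norm displacement is
#' strictly below `eps`.  The vertex/component structure is unchanged.
#'
#' @param L a `curve_collection`.
#' @param eps non-negative perturbation radius in Angstrom.
#' @param seed integer seed (required; perturbation is reproducible).
#' @export
perturb_curves <- function(L, eps, seed) {
  stopifnot(inherits(L, "curve_collection"))
  if (eps < 0) stop("eps must be non-negative")
  if (eps == 0) return(L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  comps <- lapply(L$components, function(p) {
    n <- nrow(p$vertices)
    dir <- matrix(stats::rnorm(3 * n), n, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    r <- eps * pmin(stats::runif(n)^(1 / 3), 1 - 1e-12)
    polyline(p$vertices + dir * r, closed = p$closed)
  })
  curve_collection(comps)
}

#' Ideal alpha-helix Calpha trace
#'
#' Vertex k sits at (radius cos(k twist), radius sin(k twist), k rise).
#' The defaults give the canonical alpha-helix geometry with consecutive
#' Calpha distance of about 3.83 Angstrom.
#'
#' @param n_residues number of residues (>= 2).
#' @param radius helix radius in Angstrom.
#' @param rise rise per residue in Angstrom.
#' @param twist twist per residue in degrees.
#' @return An open `polyline`.
#' @export
make_ideal_helix <- function(n_residues, radius = 2.3, rise = 1.5, twist = 100) {
  stopifnot(n_residues >= 2)
  k <- seq_len(n_residues) - 1
  th <- k * twist * pi / 180
  polyline(cbind(radius * cos(th), radius * sin(th), k * rise), closed = FALSE)
}

#' Two straight parallel strands
#'
#' A stand-in for a parallel beta-strand pair: residues of strand 1 at
#' (k intra, 0, 0) and of strand 2 at (k intra, inter, 0).
#'
#' @param n_per_strand residues per strand (>= 2).
#' @param intra intra-strand Calpha spacing in Angstrom.
#' @param inter inter-strand spacing in Angstrom.
#' @return A `curve_collection` with two open components.
#' @export
make_parallel_strands <- function(n_per_strand = 8, intra = 3.8, inter = 4.8) {
  stopifnot(n_per_strand >= 2)
  k <- (seq_len(n_per_strand) - 1) * intra
  curve_collection(list(
    polyline(cbind(k, 0, 0)),
    polyline(cbind(k, inter, 0))
  ))
}

#' Closed polygonal knot and link fixtures
#'
#' Fixed-coordinate closed polygonal curves realizing the named link types:
#' an unknotted planar octagon, a Hopf link built from two tilted circles,
#' and a polygonal trefoil sampled from the (2,3) torus-knot curve (the
#' `"trefoil"` chirality is the one whose Jones polynomial is
#' -t^-4 + t^-3 + t^-1).
#'
#' @param kind one of `"unknot"`, `"hopf"`, `"trefoil"`, `"mirror_trefoil"`.
#' @return A `curve_collection` of closed components.
#' @export
make_polygonal_knot <- function(kind = c("unknot", "hopf", "trefoil",
                                         "mirror_trefoil")) {
  kind <- match.arg(kind)
  if (kind == "unknot") {
    th <- 2 * pi * (0:7) / 8
    return(curve_collection(polyline(cbind(cos(th), sin(th), 0), closed = TRUE)))
  }
  if (kind == "hopf") {
    th <- 2 * pi * (0:23) / 24
    c1 <- cbind(cos(th), sin(th), 0)
    e1 <- c(1, 0, 0)
    e2 <- c(0, sin(pi / 6), cos(pi / 6))  # tilted so z-projections stay generic
    c2 <- cbind(1 + cos(th) * e1[1], cos(th) * e1[2] + sin(th) * e2[2],
                sin(th) * e2[3])
    return(curve_collection(list(polyline(c1, closed = TRUE),
                                 polyline(c2, closed = TRUE))))
  }
  s <- 2 * pi * (0:59) / 60
  v <- cbind(sin(s) + 2 * sin(2 * s), cos(s) - 2 * cos(2 * s), sin(3 * s))
  if (kind == "mirror_trefoil") v[, 3] <- -v[, 3]
  curve_collection(polyline(v, closed = TRUE))
}

#' Retract an open polyline slightly at both ends
#'
#' Moves each terminal vertex toward its neighbour by `frac` of the total
#' polyline length.  Used when assembling sub-collections from midpoint
#' segments, whose adjacent segments share an endpoint: the retraction
#' makes the components disjoint open curves without measurably moving
#' them.
#'
#' @param pl an open `polyline`.
#' @param frac retraction fraction of the total length (default 1e-6).
#' @export
retract_polyline <- function(pl, frac = 1e-6) {
  stopifnot(inherits(pl, "polyline"), !pl$closed)
  if (frac <= 0) return(pl)
  v <- pl$vertices
  n <- nrow(v)
  len <- sum(sqrt(rowSums((v[-1, , drop = FALSE] - v[-n, , drop = FALSE])^2)))
  eps <- frac * len
  d1 <- v[2, ] - v[1, ]
  v[1, ] <- v[1, ] + d1 / sqrt(sum(d1^2)) * min(eps, 0.4 * sqrt(sum(d1^2)))
  dn <- v[n - 1, ] - v[n, ]
  v[n, ] <- v[n, ] + dn / sqrt(sum(dn^2)) * min(eps, 0.4 * sqrt(sum(dn^2)))
  polyline(v, closed = FALSE)
}

# sub-collection of segments idx, retracted so components are disjoint
as_disjoint_collection <- function(seg, idx, retract = 1e-6) {
  curve_collection(lapply(seg$segments[idx], retract_polyline, frac = retract))
}

#' Read / write the plain-text curve format
#'
#' One component per block: a header line `open` or `closed`, then one
#' `x y z` triple per line; blocks are separated by blank lines.
#'
#' @param path file path.
#' @return `read_curves` returns a `curve_collection`.
#' @export
read_curves <- function(path) {
  lines <- trimws(readLines(path))
  blocks <- split(lines, cumsum(lines == ""))
  comps <- list()
  for (b in blocks) {
    b <- b[b != ""]
    if (!length(b)) next
    closed <- match.arg(tolower(b[1]), c("open", "closed")) == "closed"
    v <- do.call(rbind, lapply(strsplit(b[-1], "\\s+"), as.numeric))
    comps[[length(comps) + 1L]] <- polyline(v, closed = closed)
  }
  curve_collection(comps)
}

#' @rdname read_curves
#' @param L a `curve_collection` to write.
#' @export
write_curves <- function(L, path) {
  stopifnot(inherits(L, "curve_collection"))
  out <- character()
  for (p in L$components) {
    out <- c(out, if (p$closed) "closed" else "open",
             apply(p$vertices, 1, function(r) paste(format(r, digits = 17),
                                                    collapse = " ")),
             "")
  }
  writeLines(out[-length(out)], path)
  invisible(path)
}
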