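#' Sample projection directions on the sphere
#'
#' The sphere average of the normalized bracket is discretized over a set
#' of unit directions: either the deterministic spherical Fibonacci lattice
#' or i.i.d. uniform directions.
#'
#' @param n number of directions (>= 1).
#' @param scheme `"fibonacci"` (deterministic) or `"uniform_random"`.
#' @param seed integer seed for the random scheme.
#' @return An n x 3 matrix of unit vectors with attributes `scheme`, `seed`.
#' @export
sample_directions <- function(n, scheme = c("fibonacci", "uniform_random"),
                              seed = 1) {
  if (n < 1) stop("n must be >= 1")
  scheme <- match.arg(scheme)
  if (scheme == "fibonacci") {
    i <- seq_len(n) - 1
    z <- 1 - (2 * i + 1) / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- i * pi * (3 - sqrt(5))
    xi <- cbind(r * cos(phi), r * sin(phi), z)
  } else {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    xi <- matrix(stats::rnorm(3 * n), n, 3)
    xi <- xi / sqrt(rowSums(xi^2))
  }
  attr(xi, "scheme") <- scheme
  attr(xi, "seed") <- seed
  xi
}

# orthonormal frame (u, v) spanning the plane with unit normal xi
.projection_frame <- function(xi) {
  xi <- xi / sqrt(sum(xi^2))
  a <- if (abs(xi[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * xi) * xi
  u <- u / sqrt(sum(u^2))
  v <- c(xi[2] * u[3] - xi[3] * u[2],
         xi[3] * u[1] - xi[1] * u[3],
         xi[1] * u[2] - xi[2] * u[1])
  list(u = u, v = v, xi = xi)
}

# rotate a unit vector by a small random angle about a random axis
.jitter_direction <- function(xi, seed, max_angle = 1e-4) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, max_angle / 10, max_angle)
  ct <- cos(th); st <- sin(th)
  cross <- c(ax[2] * xi[3] - ax[3] * xi[2],
             ax[3] * xi[1] - ax[1] * xi[3],
             ax[1] * xi[2] - ax[2] * xi[1])
  out <- xi * ct + cross * st + ax * sum(ax * xi) * (1 - ct)
  out / sqrt(sum(out^2))
}

# attempt one projection; returns a diagram or a character irregularity reason
.project_once <- function(L, xi, tol = 1e-9) {
  fr <- .projection_frame(xi)
  comps <- lapply(L$components, function(p) {
    xy <- p$vertices %*% cbind(fr$u, fr$v)
    list(xy = xy, depth = as.vector(p$vertices %*% fr$xi), closed = p$closed)
  })
  # edge table
  ec <- ei <- integer(0)
  for (ci in seq_along(comps)) {
    m <- nrow(comps[[ci]]$xy)
    ne <- if (comps[[ci]]$closed) m else m - 1L
    ec <- c(ec, rep.int(ci, ne)); ei <- c(ei, seq_len(ne))
  }
  nE <- length(ec)
  P1 <- P2 <- matrix(0, nE, 2); Z1 <- Z2 <- numeric(nE)
  for (k in seq_len(nE)) {
    cp <- comps[[ec[k]]]
    i1 <- ei[k]
    i2 <- if (i1 == nrow(cp$xy)) 1L else i1 + 1L
    P1[k, ] <- cp$xy[i1, ]; P2[k, ] <- cp$xy[i2, ]
    Z1[k] <- cp$depth[i1]; Z2[k] <- cp$depth[i2]
  }
  scale <- max(1, max(abs(P1), abs(P2)))
  tol_xy <- tol * scale
  elen <- sqrt(rowSums((P2 - P1)^2))
  if (any(elen < tol_xy)) return("an edge projects to (near) zero length")

  if (nE >= 2) {
    pr <- utils::combn(nE, 2)
    a <- pr[1, ]; b <- pr[2, ]
    # skip edge pairs sharing a vertex of the same component
    nedge <- tabulate(ec)
    same <- ec[a] == ec[b]
    adj <- same & (abs(ei[a] - ei[b]) == 1L |
                     (vapply(ec[a], function(c) comps[[c]]$closed, TRUE) &
                        abs(ei[a] - ei[b]) == nedge[ec[a]] - 1L))
    keep <- !adj
    a <- a[keep]; b <- b[keep]
  } else {
    a <- b <- integer(0)
  }

  cross2 <- function(x, y) x[, 1] * y[, 2] - x[, 2] * y[, 1]
  r <- P2[a, , drop = FALSE] - P1[a, , drop = FALSE]
  w <- P2[b, , drop = FALSE] - P1[b, , drop = FALSE]
  q_p <- P1[b, , drop = FALSE] - P1[a, , drop = FALSE]
  den <- cross2(r, w)
  near_par <- abs(den) < 1e-12 * elen[a] * elen[b]
  if (any(near_par)) {
    # parallel pair: irregular only if the segments (almost) overlap
    for (k in which(near_par)) {
      d1 <- min(.seg_seg_dist2d(P1[a[k], ], P2[a[k], ], P1[b[k], ], P2[b[k], ]))
      if (d1 < tol_xy) return("collinear overlapping edges in projection")
    }
  }
  s <- ifelse(near_par, NA_real_, cross2(q_p, w) / den)
  t <- ifelse(near_par, NA_real_, cross2(q_p, r) / den)
  tol_par <- 1e-9  # parameter-space tolerance at edge endpoints
  inside <- !is.na(s) & s > tol_par & s < 1 - tol_par &
    t > tol_par & t < 1 - tol_par
  near_end <- !is.na(s) & !inside &
    s > -tol_par & s < 1 + tol_par & t > -tol_par & t < 1 + tol_par
  if (any(near_end)) return("a crossing falls on an edge endpoint or vertex")

  ia <- a[inside]; ib <- b[inside]
  sa <- s[inside]; tb <- t[inside]
  if (!length(ia)) {
    crossings <- .empty_crossings()
  } else {
    za <- Z1[ia] + sa * (Z2[ia] - Z1[ia])
    zb <- Z1[ib] + tb * (Z2[ib] - Z1[ib])
    if (any(abs(za - zb) < tol * max(1, max(abs(c(Z1, Z2))))))
      return("two strands at (near) equal depth at a crossing")
    x <- P1[ia, 1] + sa * (P2[ia, 1] - P1[ia, 1])
    y <- P1[ia, 2] + sa * (P2[ia, 2] - P1[ia, 2])
    if (length(x) > 1) {
      dd <- as.matrix(stats::dist(cbind(x, y)))
      diag(dd) <- Inf
      if (min(dd) < tol_xy) return("two crossings coincide (triple point)")
    }
    a_over <- za > zb
    oc <- ifelse(a_over, ec[ia], ec[ib]); oe <- ifelse(a_over, ei[ia], ei[ib])
    os <- ifelse(a_over, sa, tb)
    uc <- ifelse(a_over, ec[ib], ec[ia]); ue <- ifelse(a_over, ei[ib], ei[ia])
    us <- ifelse(a_over, tb, sa)
    odir <- matrix(0, length(ia), 2); udir <- matrix(0, length(ia), 2)
    for (k in seq_along(ia)) {
      eo <- if (a_over[k]) ia[k] else ib[k]
      eu <- if (a_over[k]) ib[k] else ia[k]
      odir[k, ] <- (P2[eo, ] - P1[eo, ]) / elen[eo]
      udir[k, ] <- (P2[eu, ] - P1[eu, ]) / elen[eu]
    }
    sgn <- ifelse(udir[, 1] * odir[, 2] - udir[, 2] * odir[, 1] > 0, 1L, -1L)
    crossings <- data.frame(
      over_comp = oc, over_edge = oe, over_s = os,
      under_comp = uc, under_edge = ue, under_s = us,
      sign = sgn, x = x, y = y,
      over_dx = odir[, 1], over_dy = odir[, 2],
      under_dx = udir[, 1], under_dy = udir[, 2])
  }

  # endpoint labels: open component j (in component order) gets head 2j-1
  # (first vertex) and leg 2j (last vertex)
  jopen <- 0L
  for (ci in seq_along(comps)) {
    if (!comps[[ci]]$closed) {
      jopen <- jopen + 1L
      comps[[ci]]$labels <- c(head = 2L * jopen - 1L, leg = 2L * jopen)
    }
  }
  structure(list(components = comps, crossings = crossings,
                 n_open = jopen, xi = fr$xi),
            class = "linkoid_diagram")
}

.empty_crossings <- function() {
  data.frame(over_comp = integer(), over_edge = integer(), over_s = numeric(),
             under_comp = integer(), under_edge = integer(), under_s = numeric(),
             sign = integer(), x = numeric(), y = numeric(),
             over_dx = numeric(), over_dy = numeric(),
             under_dx = numeric(), under_dy = numeric())
}

# minimum distance between two 2D segments (used for the parallel check)
.seg_seg_dist2d <- function(a1, a2, b1, b2) {
  pt <- function(p, q1, q2) {
    d <- q2 - q1
    t <- sum((p - q1) * d) / sum(d^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (q1 + t * d))^2))
  }
  c(pt(a1, b1, b2), pt(a2, b1, b2), pt(b1, a1, a2), pt(b2, a1, a2))
}

#' Project a curve collection to a linkoid diagram
#'
#' Orthogonal projection onto the plane with unit normal `xi`.  All
#' transverse crossings between projected edges are detected, with over /
#' under assigned from depth along `xi` and the sign from the right-handed
#' convention (positive when the under-strand direction rotated
#' counterclockwise by less than pi aligns with the over-strand direction).
#' Open components are labeled in order: component j carries head 2j-1 and
#' leg 2j, so the diagram pairing is always (1,2)(3,4)...
#'
#' Irregular projections (tangential or collinear overlaps, triple points,
#' crossings at vertices or endpoints, depth ties) are evaded by jittering
#' `xi` with a small seeded rotation (at most 1e-4 rad) and retrying.
#'
#' @param L a `curve_collection`.
#' @param xi length-3 direction (normalized internally).
#' @param jitter_seed seed for the jitter rotations.
#' @param max_retries retry cap before an irregular-projection error.
#' @param tol irregularity tolerance (relative to the projected scale).
#' @return A `linkoid_diagram` with components (2D vertices plus depth),
#'   endpoint labels, and a crossing table; attribute `retries` records the
#'   number of jitters used.
#' @export
project_curves <- function(L, xi, jitter_seed = 1, max_retries = 10,
                           tol = 1e-9) {
  stopifnot(inherits(L, "curve_collection"), length(xi) == 3)
  xi_cur <- xi / sqrt(sum(xi^2))
  for (attempt in 0:max_retries) {
    if (attempt > 0) {
      xi_cur <- .jitter_direction(xi_cur, seed = (jitter_seed + 7L * attempt) %% .Machine$integer.max)
    }
    res <- .project_once(L, xi_cur, tol = tol)
    if (!is.character(res)) {
      attr(res, "retries") <- attempt
      return(res)
    }
  }
  stop("irregular projection after ", max_retries, " jitter retries: ", res)
}

#' @export
print.linkoid_diagram <- function(x, ...) {
  cat(sprintf("<linkoid_diagram> %d component(s) (%d open), %d crossing(s), writhe %d\n",
              length(x$components), x$n_open, nrow(x$crossings), writhe(x)))
  invisible(x)
}

#' Writhe of a linkoid diagram
#'
#' Sum of the crossing signs.
#' @param D a `linkoid_diagram`.
#' @export
writhe <- function(D) {
  stopifnot(inherits(D, "linkoid_diagram"))
  as.integer(sum(D$crossings$sign))
}

#' Mirror image of a linkoid diagram
#'
#' Negates all depths: every crossing swaps over and under and flips sign.
#' @param D a `linkoid_diagram`.
#' @export
mirror_diagram <- function(D) {
  stopifnot(inherits(D, "linkoid_diagram"))
  cr <- D$crossings
  D$crossings <- data.frame(
    over_comp = cr$under_comp, over_edge = cr$under_edge, over_s = cr$under_s,
    under_comp = cr$over_comp, under_edge = cr$over_edge, under_s = cr$over_s,
    sign = -cr$sign, x = cr$x, y = cr$y,
    over_dx = cr$under_dx, over_dy = cr$under_dy,
    under_dx = cr$over_dx, under_dy = cr$over_dy)
  D$components <- lapply(D$components, function(cp) {
    cp$depth <- -cp$depth
    cp
  })
  D
}

#' Dump a linkoid diagram as JSON text
#'
#' Components (2D vertices, depths, labels) and the crossing table, for
#' inspection and the command-line `--dump-diagram` flag.
#' @param D a `linkoid_diagram`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
dump_diagram <- function(D, path = NULL) {
  obj <- list(
    n_open = D$n_open,
    components = lapply(D$components, function(cp)
      list(xy = unname(cp$xy), depth = cp$depth, closed = cp$closed,
           labels = if (!is.null(cp$labels)) unname(cp$labels))),
    crossings = D$crossings)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
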