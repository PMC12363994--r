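#' Critical values of a Vietoris-Rips filtration
#'
#' The sorted distinct positive pairwise distances (grouped within `tol`):
#' the only parameters at which the Vietoris-Rips complex of the distance
#' matrix changes.
#'
#' @param D symmetric distance matrix.
#' @param tol grouping tolerance for (numerically) tied distances.
#' @return Sorted numeric vector (possibly empty).
#' @export
vr_critical_values <- function(D, tol = 1e-9) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) return(numeric(0))
  d <- sort(D[upper.tri(D)])
  d <- d[d > tol]
  if (!length(d)) return(numeric(0))
  out <- d[1]
  for (v in d[-1]) if (v - out[length(out)] > tol) out <- c(out, v)
  out
}

# maximal cliques of the threshold graph with edges d <= r (closed rule)
.cliques_at <- function(D, r, tol) {
  n <- nrow(D)
  A <- (D <= r + tol)
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  lapply(igraph::max_cliques(g), function(cl) sort(as.integer(cl)))
}

.facet_key <- function(v) paste(v, collapse = "-")

#' Facet filtration of a Vietoris-Rips complex
#'
#' Tracks the facets (maximal cliques, for the Vietoris-Rips complex) of
#' the threshold graph across the critical values.  Every vertex set that
#' is ever maximal yields one record with its birth (0 for vertices, else
#' the first critical value at which it is maximal) and death (the first
#' critical value at which it stops being maximal; `Inf` for the final
#' all-vertex facet).  A set absorbed into a larger clique at the same
#' critical value it would appear at is never recorded.
#'
#' @param D symmetric distance matrix.
#' @param tol critical-value grouping tolerance.
#' @return A data frame with list-column `vertices`, and columns `key`,
#'   `dim` (|vertices| - 1), `birth`, `death`; attribute `critical_values`.
#' @export
facet_filtration <- function(D, tol = 1e-9) {
  D <- as.matrix(D)
  n <- nrow(D)
  crit <- vr_critical_values(D, tol)
  thresholds <- c(0, crit)
  born <- list()    # key -> list(vertices, birth)
  records <- list() # finished facets
  prev_keys <- character(0)
  for (r in thresholds) {
    cl <- .cliques_at(D, r, tol)
    keys <- vapply(cl, .facet_key, "")
    for (k in setdiff(prev_keys, keys)) {
      rec <- born[[k]]
      rec$death <- r
      records[[length(records) + 1L]] <- rec
      born[[k]] <- NULL
    }
    new <- !(keys %in% prev_keys)
    for (m in which(new)) {
      born[[keys[m]]] <- list(vertices = cl[[m]], birth = r, key = keys[m])
    }
    prev_keys <- keys
  }
  for (k in names(born)) {
    rec <- born[[k]]
    rec$death <- Inf
    records[[length(records) + 1L]] <- rec
  }
  out <- data.frame(
    key = vapply(records, `[[`, "", "key"),
    dim = vapply(records, function(r) length(r$vertices) - 1L, 1L),
    birth = vapply(records, `[[`, 1.0, "birth"),
    death = vapply(records, `[[`, 1.0, "death"))
  out$vertices <- lapply(records, `[[`, "vertices")
  out <- out[order(out$dim, out$birth, out$key), ]
  rownames(out) <- NULL
  attr(out, "critical_values") <- crit
  out
}

#' Jones-weighted facet barcode (persistent Jones polynomial)
#'
#' Builds the facet filtration of the segmentation's distance matrix and
#' weights every facet with the Jones polynomial of its curve segments,
#' evaluated at `t`.  Under the default `"relative"` convention the weight
#' is J(t) minus the crossing-free baseline d(t)^(|F|-1), so geometrically
#' trivial facets weigh exactly 0; `"raw"` reports J(t) itself.
#'
#' Facets with more segments than `max_weight_size` keep an `NA`
#' ("uncomputed") weight unless `force_weights` is set: the bracket state
#' sum is exponential in the projected crossing number.
#'
#' @param seg a `segmentation`.
#' @param D optional precomputed distance matrix (defaults to the
#'   representative metric).
#' @param metric metric used when `D` is not supplied.
#' @param t Jones evaluation point.
#' @param settings a [jones_settings()] bundle.
#' @param weight_convention `"relative"` or `"raw"`.
#' @param max_weight_size largest facet (in segments) whose weight is
#'   computed.
#' @param force_weights compute all weights regardless of size.
#' @param tol critical-value grouping tolerance.
#' @return A `weighted_barcode`: data frame `bars` (key, dim, birth, death,
#'   size, weight, vertices), plus `critical_values`, `t`,
#'   `weight_convention`, `settings`.
#' @export
weighted_barcode <- function(seg, D = NULL,
                             metric = c("representative", "sup"),
                             t = 10, settings = jones_settings(n_directions = 20),
                             weight_convention = c("relative", "raw"),
                             max_weight_size = 8, force_weights = FALSE,
                             tol = 1e-9) {
  stopifnot(inherits(seg, "segmentation"))
  weight_convention <- match.arg(weight_convention)
  if (is.null(D)) D <- segment_distance_matrix(seg, match.arg(metric))
  bars <- facet_filtration(D, tol)
  bars$size <- bars$dim + 1L
  bars$weight <- NA_real_
  for (b in seq_len(nrow(bars))) {
    sz <- bars$size[b]
    if (sz > max_weight_size && !force_weights) next
    sub <- as_disjoint_collection(seg, bars$vertices[[b]],
                                  retract = settings$retract)
    raw <- if (sz == 1L && nrow(sub$components[[1]]$vertices) <= 3) {
      1  # a lone midpoint segment admits no crossing in any projection
    } else {
      jv <- tryCatch(.jones_with_settings(sub, settings, t),
                     error = function(e)
                       stop("Jones weight failed for facet {",
                            bars$key[b], "}: ", conditionMessage(e)))
      jv$t_evaluations[[1]]
    }
    bars$weight[b] <- if (weight_convention == "relative")
      raw - trivial_jones_value(sz, t) else raw
  }
  structure(list(bars = bars,
                 critical_values = attr(bars, "critical_values"),
                 t = t, weight_convention = weight_convention,
                 settings = settings),
            class = "weighted_barcode")
}

#' @export
print.weighted_barcode <- function(x, ...) {
  cat(sprintf("<weighted_barcode> %d facet bar(s), t = %g, %s weights\n",
              nrow(x$bars), x$t, x$weight_convention))
  tab <- table(x$bars$dim)
  for (d in names(tab))
    cat(sprintf("  %s-facets: %d bar(s)\n", d, tab[[d]]))
  invisible(x)
}

#' Weighted persistence diagram of a facet barcode
#'
#' Collapses bars with equal (birth, death, weight) -- within `tol`, per
#' dimension -- into diagram points carrying a multiplicity.  The diagonal
#' is implicit (infinite multiplicity).
#'
#' @param B a `weighted_barcode`.
#' @param dimensions optional integer vector restricting the facet
#'   dimensions retained.
#' @param drop_uncomputed drop bars whose weight is `NA` instead of keeping
#'   them (the weighted bottleneck distance requires computed weights).
#' @param drop_infinite drop bars with infinite death.
#' @param tol grouping tolerance.
#' @return A `weighted_diagram`: data frame `points` with columns `dim`,
#'   `birth`, `death`, `weight`, `multiplicity`.
#' @export
barcode_diagram <- function(B, dimensions = NULL, drop_uncomputed = FALSE,
                            drop_infinite = FALSE, tol = 1e-9) {
  stopifnot(inherits(B, "weighted_barcode"))
  bars <- B$bars
  if (!is.null(dimensions)) bars <- bars[bars$dim %in% dimensions, ]
  if (drop_uncomputed) bars <- bars[!is.na(bars$weight), ]
  if (drop_infinite) bars <- bars[is.finite(bars$death), ]
  if (!nrow(bars)) {
    pts <- data.frame(dim = integer(), birth = numeric(), death = numeric(),
                      weight = numeric(), multiplicity = integer())
  } else {
    gb <- round(bars$birth / tol) * tol
    gd <- ifelse(is.finite(bars$death), round(bars$death / tol) * tol, Inf)
    gw <- ifelse(is.na(bars$weight), NA, round(bars$weight / tol) * tol)
    key <- paste(bars$dim, gb, gd, gw, sep = "|")
    agg <- !duplicated(key)
    pts <- data.frame(dim = bars$dim[agg], birth = bars$birth[agg],
                      death = bars$death[agg], weight = bars$weight[agg],
                      multiplicity = as.integer(table(key)[key[agg]]))
  }
  rownames(pts) <- NULL
  structure(list(points = pts, t = B$t), class = "weighted_diagram")
}

#' @export
print.weighted_diagram <- function(x, ...) {
  cat(sprintf("<weighted_diagram> %d off-diagonal point(s) (total multiplicity %d)\n",
              nrow(x$points), sum(x$points$multiplicity)))
  invisible(x)
}

#' Export a weighted barcode as CSV
#'
#' Columns: vertex set (dash-separated), dimension, birth, death, weight.
#' @param B a `weighted_barcode`.
#' @param path output file.
#' @export
write_barcode <- function(B, path) {
  df <- data.frame(vertex_set = B$bars$key, dimension = B$bars$dim,
                   birth = B$bars$birth, death = B$bars$death,
                   weight = B$bars$weight)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a weighted facet barcode
#'
#' One panel per facet dimension; bars run from birth to death (infinite
#' deaths are drawn to the right margin with an arrow) and are colored by
#' their Jones weight (grey when uncomputed).
#'
#' @param x a `weighted_barcode`.
#' @param dimensions facet dimensions to draw (default: all present).
#' @param ... unused.
#' @export
plot.weighted_barcode <- function(x, dimensions = NULL, ...) {
  bars <- x$bars
  if (is.null(dimensions)) dimensions <- sort(unique(bars$dim))
  xmax <- max(bars$birth, bars$death[is.finite(bars$death)], 1) * 1.05
  op <- graphics::par(mfrow = c(length(dimensions), 1),
                      mar = c(3.5, 3.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  w <- bars$weight[!is.na(bars$weight)]
  pal <- grDevices::colorRampPalette(c("blue", "grey80", "red"))(101)
  wmax <- if (length(w)) max(abs(w), 1e-12) else 1
  for (d in dimensions) {
    sub <- bars[bars$dim == d, ]
    sub <- sub[order(sub$birth, sub$death), ]
    graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, nrow(sub) + 1),
                   xlab = "Vietoris-Rips parameter (A)", ylab = "",
                   yaxt = "n", main = sprintf("%d-facets", d))
    for (i in seq_len(nrow(sub))) {
      col <- if (is.na(sub$weight[i])) "grey60"
      else pal[1 + round(50 * (1 + sub$weight[i] / wmax))]
      d_i <- if (is.finite(sub$death[i])) sub$death[i] else xmax
      graphics::segments(sub$birth[i], i, d_i, i, lwd = 3, col = col)
      if (!is.finite(sub$death[i]))
        graphics::arrows(d_i - 0.02 * xmax, i, d_i, i, length = 0.06, col = col)
    }
  }
  invisible(x)
}
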