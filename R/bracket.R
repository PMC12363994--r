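#' Count segment cycles of a state
#'
#' Endpoint labels G = 1..2n carry two fixed-point-free involutions: the
#' diagram pairing L-hat (head/leg pairs of the original components) and the
#' state pairing S-hat (endpoint pairs of the smoothed strands).  A segment
#' cycle is the union of an orbit of the composition L-hat o S-hat with the
#' orbit of its L-hat translate; the number of segment cycles enters the
#' bracket state sum as a generalized loop count.
#'
#' @param l_hat,s_hat integer permutation vectors on 1..2n
#'   (`l_hat[i]` is the partner of `i`); both must be fixed-point-free
#'   involutions.
#' @return The number of distinct segment cycles (between 1 and n).
#' @export
segment_cycle_count <- function(l_hat, s_hat) {
  .check_involution(l_hat, "l_hat")
  .check_involution(s_hat, "s_hat")
  if (length(l_hat) != length(s_hat)) stop("pairings act on different sets")
  g <- length(l_hat)
  # orbits of phi = l_hat o s_hat
  orb <- integer(g)
  nxt <- l_hat[s_hat]
  oid <- 0L
  for (a in seq_len(g)) {
    if (orb[a]) next
    oid <- oid + 1L
    cur <- a
    while (!orb[cur]) {
      orb[cur] <- oid
      cur <- nxt[cur]
    }
  }
  # merge orbit(a) with orbit(l_hat(a)) via union-find
  parent <- seq_len(oid)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (a in seq_len(g)) {
    ra <- find(orb[a]); rb <- find(orb[l_hat[a]])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(oid), find, 1L)))
}

.check_involution <- function(p, name) {
  p <- as.integer(p)
  n <- length(p)
  if (n %% 2 != 0 || n < 2) stop(name, " must act on an even-sized set")
  if (!all(sort(p) == seq_len(n))) stop(name, " is not a permutation")
  if (any(p == seq_len(n)) || any(p[p] != seq_len(n)))
    stop(name, " must be a fixed-point-free involution")
  invisible(p)
}

# build the per-diagram combinatorial machine for the state sum:
# node ids: crossing i owns ends o_in=4i-3, o_out=4i-2, u_in=4i-1, u_out=4i;
# endpoint label g lives at node 4c+g.  sp is the strand matching, ap/bp the
# A- and B-smoothing matchings (0 where undefined).
.state_machine <- function(D) {
  cr <- D$crossings
  c <- nrow(cr)
  n_open <- D$n_open
  N <- 4L * c + 2L * n_open
  sp <- integer(N)
  ap <- integer(N)
  bp <- integer(N)
  free_loops <- 0L

  connect <- function(a, b) {
    sp[a] <<- b; sp[b] <<- a
  }

  # passes along each component, ordered by position
  jopen <- 0L
  for (ci in seq_along(D$components)) {
    cp <- D$components[[ci]]
    rows_o <- which(cr$over_comp == ci)
    rows_u <- which(cr$under_comp == ci)
    pos <- c(cr$over_edge[rows_o] + cr$over_s[rows_o],
             cr$under_edge[rows_u] + cr$under_s[rows_u])
    ins <- c(4L * rows_o - 3L, 4L * rows_u - 1L)
    outs <- c(4L * rows_o - 2L, 4L * rows_u)
    o <- order(pos)
    ins <- ins[o]; outs <- outs[o]
    k <- length(ins)
    if (!cp$closed) {
      jopen <- jopen + 1L
      head_node <- 4L * c + 2L * jopen - 1L
      leg_node <- 4L * c + 2L * jopen
      if (k == 0L) {
        connect(head_node, leg_node)
      } else {
        connect(head_node, ins[1])
        if (k > 1) for (m in seq_len(k - 1)) connect(outs[m], ins[m + 1])
        connect(outs[k], leg_node)
      }
    } else {
      if (k == 0L) {
        free_loops <- free_loops + 1L
      } else if (k == 1L) {
        connect(outs[1], ins[1])
      } else {
        for (m in seq_len(k - 1)) connect(outs[m], ins[m + 1])
        connect(outs[k], ins[1])
      }
    }
  }

  # A/B smoothings from the planar geometry at each crossing: the A-smoothing
  # joins the two regions swept by rotating the over strand counterclockwise
  # onto the under strand (fixed jointly with the crossing-sign convention so
  # the normalized bracket is invariant for closed curves).
  angdiff <- function(a, b) abs(((a - b + pi) %% (2 * pi)) - pi)
  for (i in seq_len(nrow(cr))) {
    th_o <- atan2(cr$over_dy[i], cr$over_dx[i])
    th_u <- atan2(cr$under_dy[i], cr$under_dx[i])
    delta <- (th_u - th_o) %% pi
    target <- th_o + delta - pi
    o_in <- 4L * i - 3L; o_out <- 4L * i - 2L
    u_in <- 4L * i - 1L; u_out <- 4L * i
    if (angdiff(target, th_u) < pi / 2) {
      apairs <- rbind(c(o_out, u_in), c(o_in, u_out))
      bpairs <- rbind(c(o_out, u_out), c(o_in, u_in))
    } else {
      apairs <- rbind(c(o_out, u_out), c(o_in, u_in))
      bpairs <- rbind(c(o_out, u_in), c(o_in, u_out))
    }
    ap[apairs[, 1]] <- apairs[, 2]; ap[apairs[, 2]] <- apairs[, 1]
    bp[bpairs[, 1]] <- bpairs[, 2]; bp[bpairs[, 2]] <- bpairs[, 1]
  }

  list(c = c, N = N, sp = sp, ap = ap, bp = bp,
       n_open = n_open, free_loops = free_loops)
}

# trace one state: count closed loops and read off the endpoint pairing
.trace_state <- function(sm, smp) {
  c4 <- 4L * sm$c
  visited <- logical(sm$N)
  s_hat <- integer(2L * sm$n_open)
  if (sm$n_open > 0) {
    for (g in seq_len(2L * sm$n_open)) {
      lab <- c4 + g
      if (visited[lab]) next
      visited[lab] <- TRUE
      cur <- sm$sp[lab]
      use_smooth <- TRUE
      while (cur <= c4) {
        visited[cur] <- TRUE
        cur <- if (use_smooth) smp[cur] else sm$sp[cur]
        use_smooth <- !use_smooth
      }
      visited[cur] <- TRUE
      g2 <- cur - c4
      s_hat[g] <- g2; s_hat[g2] <- g
    }
  }
  circ <- sm$free_loops
  if (c4 > 0) {
    for (v in seq_len(c4)) {
      if (visited[v]) next
      circ <- circ + 1L
      cur <- v
      use_sp <- TRUE
      repeat {
        visited[cur] <- TRUE
        cur <- if (use_sp) sm$sp[cur] else smp[cur]
        use_sp <- !use_sp
        if (cur == v) break
      }
    }
  }
  list(circ = circ, s_hat = s_hat)
}

.state_smoothing <- function(sm, labels_a) {
  smp <- sm$ap
  if (any(!labels_a)) {
    sel <- rep(!labels_a, each = 4L)
    idx <- which(c(sel, logical(sm$N - 4L * sm$c)))
    smp[idx] <- sm$bp[idx]
  }
  smp
}

#' Smooth every crossing of a diagram and trace the result
#'
#' Applies the chosen Kauffman smoothing (A or B) at every crossing and
#' traces the resulting strands: closed loops are counted, and each open
#' strand contributes a 2-cycle of the state pairing S-hat.
#'
#' @param D a `linkoid_diagram`.
#' @param labels character (`"A"`/`"B"`) or logical (TRUE = A) vector, one
#'   entry per crossing.
#' @return List with `circ` (closed-loop count) and `s_hat` (integer
#'   involution on the endpoint labels; empty when no open components).
#' @export
smooth_and_trace <- function(D, labels) {
  stopifnot(inherits(D, "linkoid_diagram"))
  if (is.character(labels)) labels <- toupper(labels) == "A"
  labels <- as.logical(labels)
  if (length(labels) != nrow(D$crossings))
    stop("need one smoothing label per crossing")
  sm <- .state_machine(D)
  .trace_state(sm, .state_smoothing(sm, labels))
}

#' Diagram pairing L-hat of a linkoid diagram
#'
#' With the package's labeling convention this is always
#' (1,2)(3,4)...(2n-1,2n).
#' @param D a `linkoid_diagram`.
#' @export
diagram_pairing <- function(D) {
  n <- D$n_open
  if (n == 0) return(integer(0))
  as.integer(rbind(2 * seq_len(n), 2 * seq_len(n) - 1))
}

#' Bracket polynomial of a linkoid diagram
#'
#' Exact Kauffman-style state sum over all 2^c smoothing choices:
#' `<L> = sum_S A^sigma(S) d^(|S|circ + |S|cyc - 1)` with loop value
#' `d = -A^2 - A^-2`, where `sigma(S)` is (#A - #B) smoothings, `|S|circ`
#' counts closed loops and `|S|cyc` counts segment cycles of the endpoint
#' pairing (0 when the diagram has no open components, which recovers the
#' classical bracket).
#'
#' @param D a `linkoid_diagram`.
#' @param max_crossings refuse diagrams with more crossings than this
#'   (the state sum is exponential); the error carries condition class
#'   `pjones_too_many_crossings`.
#' @return A [laurent()] polynomial in A.
#' @export
bracket <- function(D, max_crossings = 20) {
  stopifnot(inherits(D, "linkoid_diagram"))
  c <- nrow(D$crossings)
  if (c > max_crossings) {
    stop(structure(class = c("pjones_too_many_crossings", "error", "condition"),
                   list(message = sprintf("diagram has %d crossings (cap %d)",
                                          c, max_crossings),
                        call = sys.call())))
  }
  sm <- .state_machine(D)
  l_hat <- diagram_pairing(D)
  # tally states by (sigma, d-exponent), then assemble the polynomial
  tal <- new.env(parent = emptyenv())
  n_states <- 2L^c
  for (s in 0:(n_states - 1L)) {
    labels_a <- if (c > 0) as.logical(intToBits(s)[seq_len(c)]) else logical(0)
    tr <- .trace_state(sm, .state_smoothing(sm, labels_a))
    cyc <- if (sm$n_open > 0) segment_cycle_count(l_hat, tr$s_hat) else 0L
    sigma <- 2L * sum(labels_a) - c
    e <- tr$circ + cyc - 1L
    key <- paste0(sigma, ":", e)
    tal[[key]] <- (if (is.null(tal[[key]])) 0L else tal[[key]]) + 1L
  }
  out <- lp_zero()
  for (key in ls(tal)) {
    se <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
    out <- lp_add(out, lp_scale(lp_d_pow(se[2]), s = tal[[key]], k = se[1]))
  }
  out
}

#' Writhe-normalized bracket polynomial
#'
#' `f_L = (-A^3)^(-Wr(L)) <L>`; for a closed link diagram this is the
#' Kauffman normalization whose evaluation at A = t^(-1/4) is the Jones
#' polynomial.
#'
#' @inheritParams bracket
#' @export
normalized_bracket <- function(D, max_crossings = 20) {
  w <- writhe(D)
  lp_scale(bracket(D, max_crossings = max_crossings),
           s = (-1)^abs(w), k = -3L * w)
}

#' Settings bundle for sphere-averaged Jones computations
#'
#' @param n_directions number of projection directions.
#' @param scheme direction scheme, `"fibonacci"` or `"uniform_random"`.
#' @param seed integer seed (direction sampling and jitter).
#' @param max_crossings per-projection crossing cap for the state sum.
#' @param skip_overfull if TRUE, projections exceeding the cap are skipped
#'   (and counted) instead of raising an error.
#' @param retract end-retraction fraction applied when sub-collections are
#'   assembled from midpoint segments that share endpoints.
#' @export
jones_settings <- function(n_directions = 100, scheme = "fibonacci", seed = 1,
                           max_crossings = 20, skip_overfull = FALSE,
                           retract = 1e-6) {
  list(n_directions = n_directions, scheme = scheme, seed = as.integer(seed),
       max_crossings = max_crossings, skip_overfull = isTRUE(skip_overfull),
       retract = retract)
}

#' Sphere-averaged Jones polynomial of a curve collection
#'
#' Monte-Carlo average, over projection directions, of the writhe-normalized
#' bracket of each linkoid projection; evaluations use A = t^(-1/4).  For a
#' collection of closed curves every regular projection gives the same
#' polynomial (the classical Jones polynomial); for open curves the average
#' is a continuous real-coefficient measure of entanglement.
#'
#' @param L a `curve_collection`.
#' @param n_directions,scheme,seed direction sampling (see
#'   [sample_directions()]).
#' @param t numeric vector of evaluation points (t > 0).
#' @param directions optional explicit k x 3 matrix of directions,
#'   overriding the sampling arguments.
#' @param max_crossings per-projection crossing cap.
#' @param skip_overfull skip (and count) over-cap projections instead of
#'   erroring.
#' @param keep_directions retain each direction's normalized bracket.
#' @return A `jones_value`: averaged polynomial, named `t_evaluations`,
#'   direction metadata, and the number of skipped directions.
#' @export
jones <- function(L, n_directions = 100, scheme = "fibonacci", seed = 1,
                  t = 10, directions = NULL, max_crossings = 20,
                  skip_overfull = FALSE, keep_directions = FALSE) {
  stopifnot(inherits(L, "curve_collection"))
  if (is.null(directions)) {
    if (n_directions < 1) stop("n_directions must be >= 1")
    directions <- sample_directions(n_directions, scheme, seed)
  }
  polys <- list()
  skipped <- 0L
  for (i in seq_len(nrow(directions))) {
    jseed <- (as.integer(seed) %% 100000L) * 20011L + i
    f <- tryCatch({
      Dg <- project_curves(L, directions[i, ], jitter_seed = jseed)
      normalized_bracket(Dg, max_crossings = max_crossings)
    }, pjones_too_many_crossings = function(e) {
      if (!skip_overfull) stop(e)
      NULL
    })
    if (is.null(f)) skipped <- skipped + 1L else polys[[length(polys) + 1L]] <- f
  }
  if (!length(polys)) stop("all projection directions were skipped")
  avg <- lp_mean(polys)
  ev <- vapply(t, function(tt) lp_eval_t(avg, tt), 1.0)
  names(ev) <- format(t, trim = TRUE)
  structure(list(polynomial = avg, t_evaluations = ev,
                 n_directions = nrow(directions),
                 scheme = if (!is.null(attr(directions, "scheme")))
                   attr(directions, "scheme") else "explicit",
                 seed = seed, skipped = skipped,
                 per_direction = if (keep_directions) polys),
            class = "jones_value")
}

#' @export
print.jones_value <- function(x, ...) {
  cat(sprintf("<jones_value> averaged over %d direction(s) (%d skipped)\n",
              x$n_directions, x$skipped))
  print(x$polynomial)
  for (nm in names(x$t_evaluations))
    cat(sprintf("  J(t=%s) = %.6g\n", nm, x$t_evaluations[[nm]]))
  invisible(x)
}

#' Jones value of a crossing-free n-component collection
#'
#' `d(t)^(n-1)` with `d(t) = -(sqrt(t) + 1/sqrt(t))`: the value every
#' collection of n far-separated straight arcs attains.  Used as the
#' baseline of the `"relative"` facet-weight convention.
#'
#' @param n_components number of components (>= 1).
#' @param t evaluation point (t > 0).
#' @export
trivial_jones_value <- function(n_components, t) {
  stopifnot(n_components >= 1, t > 0)
  (-(sqrt(t) + 1 / sqrt(t)))^(n_components - 1)
}

# jones() driven by a jones_settings bundle (internal plumbing)
.jones_with_settings <- function(L, settings, t) {
  jones(L, n_directions = settings$n_directions, scheme = settings$scheme,
        seed = settings$seed, t = t, max_crossings = settings$max_crossings,
        skip_overfull = settings$skip_overfull)
}

#' Serialize a Jones result as JSON
#'
#' @param jv a `jones_value`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
jones_to_json <- function(jv, path = NULL) {
  obj <- list(coefficients = stats::setNames(as.list(jv$polynomial$coefs),
                                             jv$polynomial$exps),
              t_evaluations = as.list(jv$t_evaluations),
              n_directions = jv$n_directions, scheme = jv$scheme,
              seed = jv$seed, skipped = jv$skipped)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
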