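# Independent oracles.  These re-derive results through different
# algorithmic routes than the package implementation and are deliberately
# self-contained: the bracket oracle is a recursive skein expansion with
# incremental arc merging (the package enumerates states and traces a
# matching graph); the facet oracle enumerates all vertex subsets; the
# bottleneck oracle enumerates all matchings.

# --- recursive skein expansion -------------------------------------------

# ends of crossing i are tokens o_in/o_out/u_in/u_out; arcs are unordered
# pairs of extremities (tokens or endpoint labels "L<g>")
.or_ends <- function(i) {
  c(o_in = paste0("c", i, ".oi"), o_out = paste0("c", i, ".oo"),
    u_in = paste0("c", i, ".ui"), u_out = paste0("c", i, ".uo"))
}

# strand arcs of a diagram: walk each component through its ordered passes
.or_strand_arcs <- function(D) {
  cr <- D$crossings
  arcs <- list()
  loops <- 0L
  jopen <- 0L
  for (ci in seq_along(D$components)) {
    cp <- D$components[[ci]]
    ro <- which(cr$over_comp == ci)
    ru <- which(cr$under_comp == ci)
    pos <- c(cr$over_edge[ro] + cr$over_s[ro], cr$under_edge[ru] + cr$under_s[ru])
    ins <- c(vapply(ro, function(i) .or_ends(i)[["o_in"]], ""),
             vapply(ru, function(i) .or_ends(i)[["u_in"]], ""))
    outs <- c(vapply(ro, function(i) .or_ends(i)[["o_out"]], ""),
              vapply(ru, function(i) .or_ends(i)[["u_out"]], ""))
    o <- order(pos)
    ins <- ins[o]; outs <- outs[o]
    k <- length(ins)
    if (!cp$closed) {
      jopen <- jopen + 1L
      ends <- c(paste0("L", 2 * jopen - 1), paste0("L", 2 * jopen))
      if (k == 0) {
        arcs[[length(arcs) + 1L]] <- c(ends[1], ends[2])
      } else {
        arcs[[length(arcs) + 1L]] <- c(ends[1], ins[1])
        if (k > 1) for (m in 1:(k - 1))
          arcs[[length(arcs) + 1L]] <- c(outs[m], ins[m + 1])
        arcs[[length(arcs) + 1L]] <- c(outs[k], ends[2])
      }
    } else {
      if (k == 0) loops <- loops + 1L
      else if (k == 1) arcs[[length(arcs) + 1L]] <- c(outs[1], ins[1])
      else {
        for (m in 1:(k - 1)) arcs[[length(arcs) + 1L]] <- c(outs[m], ins[m + 1])
        arcs[[length(arcs) + 1L]] <- c(outs[k], ins[1])
      }
    }
  }
  list(arcs = arcs, loops = loops, n_open = jopen)
}

# A-smoothing joins for crossing i (same geometric convention as the
# package, derived here from scratch from the stored 2D directions)
.or_smoothing <- function(cr, i) {
  e <- .or_ends(i)
  th_o <- atan2(cr$over_dy[i], cr$over_dx[i])
  th_u <- atan2(cr$under_dy[i], cr$under_dx[i])
  delta <- (th_u - th_o) %% pi
  target <- th_o + delta - pi
  ad <- abs(((target - th_u + pi) %% (2 * pi)) - pi)
  if (ad < pi / 2) {
    list(A = list(c(e[["o_out"]], e[["u_in"]]), c(e[["o_in"]], e[["u_out"]])),
         B = list(c(e[["o_out"]], e[["u_out"]]), c(e[["o_in"]], e[["u_in"]])))
  } else {
    list(A = list(c(e[["o_out"]], e[["u_out"]]), c(e[["o_in"]], e[["u_in"]])),
         B = list(c(e[["o_out"]], e[["u_in"]]), c(e[["o_in"]], e[["u_out"]])))
  }
}

# merge a join (x, y) into the arc set; returns updated arcs and loop delta
.or_join <- function(arcs, x, y) {
  ix <- which(vapply(arcs, function(a) x %in% a, TRUE))
  iy <- which(vapply(arcs, function(a) y %in% a, TRUE))
  stopifnot(length(ix) == 1, length(iy) == 1)
  if (ix == iy) return(list(arcs = arcs[-ix], loops = 1L))
  a <- arcs[[ix]]; b <- arcs[[iy]]
  merged <- c(setdiff(a, x), setdiff(b, y))
  arcs <- arcs[-c(ix, iy)]
  arcs[[length(arcs) + 1L]] <- merged
  list(arcs = arcs, loops = 0L)
}

# recursive skein expansion of the bracket
oracle_bracket <- function(D) {
  cr <- D$crossings
  st <- .or_strand_arcs(D)
  l_hat <- diagram_pairing(D)
  recurse <- function(i, arcs, loops, sigma) {
    if (i > nrow(cr)) {
      if (st$n_open > 0) {
        s_hat <- integer(2 * st$n_open)
        for (a in arcs) {
          g <- as.integer(sub("^L", "", a))
          s_hat[g[1]] <- g[2]; s_hat[g[2]] <- g[1]
        }
        cyc <- segment_cycle_count(l_hat, s_hat)
      } else {
        stopifnot(length(arcs) == 0)
        cyc <- 0L
      }
      p <- laurent(1, 0L)
      for (k in seq_len(loops + cyc - 1L)) p <- lp_mul(p, lp_d())
      return(lp_scale(p, s = 1, k = sigma))
    }
    sm <- .or_smoothing(cr, i)
    out <- laurent()
    for (lab in c("A", "B")) {
      arcs2 <- arcs; dl <- 0L
      for (j in sm[[lab]]) {
        r <- .or_join(arcs2, j[1], j[2])
        arcs2 <- r$arcs; dl <- dl + r$loops
      }
      out <- lp_add(out, recurse(i + 1L, arcs2, loops + dl,
                                 sigma + if (lab == "A") 1L else -1L))
    }
    out
  }
  recurse(1L, st$arcs, st$loops, 0L)
}

# --- facet filtration by exhaustive subset enumeration -------------------

oracle_facets <- function(D, tol = 1e-9) {
  n <- nrow(D)
  stopifnot(n <= 10)
  crit <- vr_critical_values(D, tol)
  thresholds <- c(0, crit)
  masks <- seq_len(2^n - 1)
  bit <- 2^(0:(n - 1))
  key_of <- vapply(masks, function(m) paste(which(bitwAnd(m, bit) > 0),
                                            collapse = "-"), "")
  per_thresh <- lapply(thresholds, function(r) {
    adj <- (D <= r + tol)
    diag(adj) <- TRUE
    nbr <- vapply(seq_len(n), function(i) sum(bit[adj[i, ]]), 1.0)
    # m is a clique iff every member's closed neighborhood contains m
    cliq <- vapply(masks, function(m) {
      all(bitwAnd(nbr[bitwAnd(m, bit) > 0], m) == m)
    }, TRUE)
    # maximal iff no single vertex can be added while staying a clique
    maximal <- vapply(masks, function(m) {
      if (!cliq[m]) return(FALSE)
      out <- which(bitwAnd(m, bit) == 0)
      !any(cliq[m + bit[out]])
    }, TRUE)
    key_of[maximal]
  })
  recs <- list()
  alive <- list()
  for (k in seq_along(thresholds)) {
    keys <- per_thresh[[k]]
    for (dead in setdiff(names(alive), keys)) {
      recs[[length(recs) + 1L]] <- data.frame(key = dead, birth = alive[[dead]],
                                              death = thresholds[k])
      alive[[dead]] <- NULL
    }
    for (new in setdiff(keys, names(alive))) alive[[new]] <- thresholds[k]
  }
  for (k in names(alive))
    recs[[length(recs) + 1L]] <- data.frame(key = k, birth = alive[[k]], death = Inf)
  out <- do.call(rbind, recs)
  out[order(out$key), ]
}

# --- beta-based multiplicity (alternating corner sum) --------------------

# bars: data frame with birth/death for a fixed facet dimension
oracle_multiplicity <- function(bars, ri, rj, crit) {
  beta <- function(x, y) sum(bars$birth <= x & bars$death > y)
  mids <- c(-Inf, (crit[-1] + crit[-length(crit)]) / 2, Inf)
  # interleaved values b_{i-1} < r_i < b_i over the critical grid
  bval <- function(r, side) {
    if (is.infinite(r)) return(r)
    i <- which(abs(crit - r) < 1e-9)
    stopifnot(length(i) == 1)
    mids[i + side]  # side 0: below, 1: above
  }
  beta(bval(ri, 0), bval(rj, 1)) - beta(bval(ri, 1), bval(rj, 1)) +
    beta(bval(ri, 1), bval(rj, 0)) - beta(bval(ri, 0), bval(rj, 0))
}

# --- weighted bottleneck by matching enumeration -------------------------

oracle_bottleneck <- function(p1, p2) {
  # p1, p2: data frames birth/death/weight (finite deaths only), small
  n1 <- nrow(p1); n2 <- nrow(p2)
  stopifnot(n1 <= 4, n2 <= 4)
  cost_pair <- function(i, j)
    max(abs(p1$birth[i] - p2$birth[j]), abs(p1$death[i] - p2$death[j]),
        abs(p1$weight[i] - p2$weight[j]))
  best <- Inf
  assign_rec <- function(i, used2, cost) {
    if (cost >= best) return()
    if (i > n1) {
      un2 <- setdiff(seq_len(n2), used2)
      tot <- max(c(cost, (p2$death[un2] - p2$birth[un2]) / 2, 0))
      best <<- min(best, tot)
      return()
    }
    # leave point i of p1 unmatched
    assign_rec(i + 1, used2, max(cost, (p1$death[i] - p1$birth[i]) / 2))
    for (j in setdiff(seq_len(n2), used2))
      assign_rec(i + 1, c(used2, j), max(cost, cost_pair(i, j)))
  }
  assign_rec(1L, integer(0), 0)
  best
}
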