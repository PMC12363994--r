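# expand diagram points by multiplicity into a plain data frame
.expand_points <- function(Dg) {
  p <- Dg$points
  if (!nrow(p)) return(p[, c("birth", "death", "weight")])
  idx <- rep(seq_len(nrow(p)), p$multiplicity)
  out <- p[idx, c("birth", "death", "weight")]
  rownames(out) <- NULL
  out
}

# cost of matching two points: max of birth, death and weight differences
# (death difference of two infinite-death points counts as 0)
.pair_cost <- function(b1, d1, w1, b2, d2, w2) {
  dd <- if (is.infinite(d1) && is.infinite(d2)) 0 else abs(d1 - d2)
  max(abs(b1 - b2), dd, abs(w1 - w2))
}

# perfect-matching feasibility at threshold lam (bipartite, igraph)
.bottleneck_feasible <- function(P, Q, lam, slack) {
  nC <- nrow(P); nD <- nrow(Q)
  nL <- nC + nD  # left: C points then diagonal copies of D
  nR <- nD + nC  # right: D points then diagonal copies of C
  ok <- lam + slack
  el <- matrix(integer(0), 0, 2)
  add <- function(l, r) el <<- rbind(el, c(l, nL + r))
  for (i in seq_len(nC)) {
    for (j in seq_len(nD)) {
      fin_i <- is.finite(P$death[i]); fin_j <- is.finite(Q$death[j])
      if (fin_i != fin_j) next
      if (.pair_cost(P$birth[i], P$death[i], P$weight[i],
                     Q$birth[j], Q$death[j], Q$weight[j]) <= ok)
        add(i, j)  # C point i (left) -- D point j (right)
    }
    if (is.finite(P$death[i]) && (P$death[i] - P$birth[i]) / 2 <= ok)
      add(i, nD + i)  # C point i -- its own diagonal copy
  }
  for (j in seq_len(nD)) {
    if (is.finite(Q$death[j]) && (Q$death[j] - Q$birth[j]) / 2 <= ok)
      add(nC + j, j)  # diagonal copy of D j -- D point j
  }
  for (j in seq_len(nD)) for (i in seq_len(nC)) add(nC + j, nD + i)  # diag-diag
  g <- igraph::make_empty_graph(n = nL + nR, directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, nL), rep(TRUE, nR))
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  igraph::max_bipartite_match(g)$matching_size == nL
}

#' Weighted bottleneck distance between two weighted diagrams
#'
#' The infimum over matchings of the largest cost incurred, where matching
#' two points costs `max(|birth diff|, |death diff|, |weight diff|)` and
#' leaving a point unmatched (matching it to the diagonal) costs half its
#' lifespan.  Points with infinite death can only be matched to each other
#' (an unmatched infinite point makes the distance infinite).  Computed
#' exactly by a binary search over candidate costs with a bipartite
#' perfect-matching feasibility test.
#'
#' @param d1,d2 `weighted_diagram` objects (see [barcode_diagram()]); all
#'   weights must be computed.
#' @return A non-negative number (possibly `Inf`).
#' @export
bottleneck_weighted <- function(d1, d2) {
  stopifnot(inherits(d1, "weighted_diagram"), inherits(d2, "weighted_diagram"))
  P <- .expand_points(d1)
  Q <- .expand_points(d2)
  if (anyNA(P$weight) || anyNA(Q$weight))
    stop("diagrams contain uncomputed weights; recompute or drop those bars")
  if (sum(is.infinite(P$death)) != sum(is.infinite(Q$death))) return(Inf)
  if (!nrow(P) && !nrow(Q)) return(0)
  cand <- c(0, (P$death[is.finite(P$death)] - P$birth[is.finite(P$death)]) / 2,
            (Q$death[is.finite(Q$death)] - Q$birth[is.finite(Q$death)]) / 2)
  for (i in seq_len(nrow(P))) for (j in seq_len(nrow(Q))) {
    if (is.finite(P$death[i]) != is.finite(Q$death[j])) next
    cand <- c(cand, .pair_cost(P$birth[i], P$death[i], P$weight[i],
                               Q$birth[j], Q$death[j], Q$weight[j]))
  }
  cand <- sort(unique(cand))
  slack <- 1e-12 * max(1, cand[length(cand)])
  lo <- 1L; hi <- length(cand)
  # the largest candidate always admits a full matching or all-diagonal
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (.bottleneck_feasible(P, Q, cand[mid], slack)) hi <- mid else lo <- mid + 1L
  }
  if (!.bottleneck_feasible(P, Q, cand[lo], slack)) return(Inf)
  cand[lo]
}
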