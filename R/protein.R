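#' Read the Calpha trace of a protein chain from a PDB file
#'
#' Extracts the Calpha atom of every residue of one chain (one model),
#' together with the experimental B-factors from the temperature-factor
#' column.  Alternate locations are resolved by highest occupancy, ties
#' alphabetically; residues without a Calpha are skipped with a warning.
#'
#' @param path PDB file.
#' @param chain_id chain identifier; defaults to the first chain present.
#' @param model model number for multi-model files.
#' @return A `protein_chain`: residue numbers and insertion codes, an
#'   n x 3 coordinate matrix (Angstrom), B-factors (Angstrom^2), chain id
#'   and source path.
#' @export
read_pdb_calpha <- function(path, chain_id = NULL, model = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(chain_id)) chain_id <- at$chain[1]
  sel <- at$type == "ATOM" & at$chain %in% chain_id & at$elety == "CA"
  if (!any(at$chain %in% chain_id)) stop("chain ", chain_id, " not found")
  if (!any(sel)) stop("no Calpha atoms in chain ", chain_id)
  at <- at[sel, , drop = FALSE]
  idx_all <- which(sel)
  ins <- ifelse(is.na(at$insert), "", at$insert)
  res_key <- paste(at$resno, ins, sep = "|")
  keep <- logical(nrow(at))
  for (k in unique(res_key)) {
    rows <- which(res_key == k)
    if (length(rows) > 1) {
      occ <- ifelse(is.na(at$o[rows]), 1, at$o[rows])
      alt <- ifelse(is.na(at$alt[rows]), "", at$alt[rows])
      rows <- rows[order(-occ, alt)]
    }
    keep[rows[1]] <- TRUE
  }
  at <- at[keep, , drop = FALSE]
  idx_all <- idx_all[keep]
  nmod <- nrow(pdb$xyz)
  if (model < 1 || model > nmod) stop("model ", model, " not present")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)[idx_all, , drop = FALSE]
  if (nrow(xyz) < 2) stop("need at least 2 Calpha residues")
  # residues present in SEQRES but without a Calpha simply do not appear;
  # report gaps in the numbering as skipped residues
  gaps <- diff(at$resno)
  if (any(gaps > 1))
    warning(sum(gaps[gaps > 1] - 1), " residue(s) without a Calpha skipped")
  structure(list(resno = at$resno,
                 insert = ifelse(is.na(at$insert), "", at$insert),
                 xyz = unname(xyz), b = at$b,
                 chain = chain_id, source = path),
            class = "protein_chain")
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("<protein_chain> %s chain %s: %d residues\n",
              basename(x$source), x$chain, length(x$resno)))
  invisible(x)
}

#' Calpha chain of a protein as an open polyline
#' @param chain a `protein_chain`.
#' @export
chain_polyline <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  polyline(chain$xyz, closed = FALSE)
}

#' Multi-scale Jones B-factor features of a protein chain
#'
#' The flexibility feature pipeline: midpoint segmentation of the Calpha
#' chain, Calpha-distance metric, shells r = 4, 4.25, ..., 15 Angstrom with
#' R = r + 1, Jones polynomial at t = 10, followed by column z-scoring.
#' Yields an n-residue x 45-shell normalized characteristic matrix.
#'
#' @param chain a `protein_chain` (or an open `polyline` of Calpha
#'   positions).
#' @param settings a [jones_settings()] bundle.
#' @param scheme shell scheme, defaulting to the protein ladder above.
#' @param t Jones evaluation point.
#' @param normalize z-score columns (the regression input convention).
#' @return A `characteristic_matrix` (n x 45 by default).
#' @export
bfactor_features <- function(chain, settings = jones_settings(n_directions = 20),
                             scheme = shell_scheme(), t = 10, normalize = TRUE) {
  pl <- if (inherits(chain, "protein_chain")) chain_polyline(chain) else chain
  seg <- segment_at_midpoints(pl)
  D <- segment_distance_matrix(seg, "representative")
  M <- characteristic_matrix(seg, D, scheme = scheme, t = t, settings = settings)
  if (normalize) normalize_matrix(M) else M
}

#' Lasso fit of experimental B-factors on Jones features
#'
#' Per-protein in-sample fit: an L1-penalized linear model (penalty 0.16 by
#' default) of the experimental B-factors on the normalized characteristic
#' matrix, reporting fitted values and the Pearson correlation between
#' fitted and experimental B-factors.  The penalty is interpreted on the
#' standardized scale: features are expected z-scored (the
#' [bfactor_features()] convention) and the response is standardized
#' internally for the fit, so 0.16 means the same thing whatever the
#' B-factor units; fitted values are returned in the original units.
#'
#' @param features numeric matrix (residues x shells), typically from
#'   [bfactor_features()].
#' @param b experimental B-factors, one per residue.
#' @param lasso_penalty L1 regularization strength.
#' @return A `bfactor_result`: fitted values, `correlation`, the
#'   coefficient vector, and the penalty used.
#' @export
fit_bfactor <- function(features, b, lasso_penalty = 0.16) {
  X <- unclass(as.matrix(features))
  stopifnot(nrow(X) == length(b), !anyNA(b))
  if (stats::sd(b) == 0)
    stop("degenerate B-factor vector (constant): correlation undefined")
  mu <- mean(b)
  s <- stats::sd(b)
  fit <- glmnet::glmnet(X, (b - mu) / s, alpha = 1, lambda = lasso_penalty,
                        standardize = FALSE, intercept = TRUE)
  fitted <- as.vector(stats::predict(fit, newx = X)) * s + mu
  correlation <- if (stats::sd(fitted) == 0) NA_real_ else stats::cor(fitted, b)
  structure(list(fitted = fitted, correlation = correlation,
                 coefficients = as.vector(stats::coef(fit)),
                 lasso_penalty = lasso_penalty),
            class = "bfactor_result")
}

#' @export
print.bfactor_result <- function(x, ...) {
  cat(sprintf("<bfactor_result> %d residues, Pearson r = %.4f (penalty %g)\n",
              length(x$fitted), x$correlation, x$lasso_penalty))
  invisible(x)
}

#' Persistent Jones barcode of a secondary-structure selection
#'
#' Builds the Jones-weighted facet barcode of a residue selection (one
#' contiguous run for a helix, two runs for a strand pair) using midpoint
#' segmentation and the Calpha-distance metric.
#'
#' @param chain a `protein_chain`.
#' @param ranges an integer vector of residue numbers (one run) or a list
#'   of such vectors (at most two contiguous runs).
#' @param settings a [jones_settings()] bundle.
#' @param ... passed to [weighted_barcode()].
#' @return A `weighted_barcode`.
#' @export
secondary_structure_barcode <- function(chain, ranges,
                                        settings = jones_settings(n_directions = 20),
                                        ...) {
  stopifnot(inherits(chain, "protein_chain"))
  if (!is.list(ranges)) ranges <- list(ranges)
  if (length(ranges) < 1 || length(ranges) > 2)
    stop("selection must be one or two contiguous residue runs")
  segs <- lapply(ranges, function(rng) {
    idx <- match(rng, chain$resno)
    if (anyNA(idx)) stop("residues not in chain: ",
                         paste(rng[is.na(idx)], collapse = ", "))
    if (length(idx) < 2 || any(diff(idx) != 1))
      stop("each run must be a contiguous stretch of >= 2 residues")
    segment_at_midpoints(polyline(chain$xyz[idx, , drop = FALSE]))
  })
  seg <- if (length(segs) == 1) segs[[1]] else combine_segmentations(segs)
  weighted_barcode(seg, metric = "representative", settings = settings, ...)
}
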