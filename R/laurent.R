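#' Laurent polynomials in the bracket variable A
#'
#' Sparse real-coefficient Laurent polynomials used throughout the bracket
#' state sum.  A polynomial is stored as parallel vectors of integer
#' exponents and numeric coefficients; zero coefficients are dropped.
#'
#' @param coefs numeric coefficients.
#' @param exps integer exponents of the same length as `coefs`.
#' @return An object of class `laurent`.
#' @examples
#' d <- laurent(c(-1, -1), c(2, -2))   # loop value d = -A^2 - A^-2
#' lp_eval_t(d, 10)                    # -(sqrt(10) + 1/sqrt(10))
#' @export
laurent <- function(coefs = numeric(), exps = integer()) {
  stopifnot(length(coefs) == length(exps))
  if (length(coefs)) {
    e <- as.integer(round(exps))
    o <- order(e)
    e <- e[o]; cf <- as.numeric(coefs)[o]
    # collapse repeated exponents
    grp <- cumsum(c(TRUE, diff(e) != 0L))
    cf <- as.numeric(tapply(cf, grp, sum))
    e <- e[!duplicated(grp)]
    keep <- cf != 0
    e <- e[keep]; cf <- cf[keep]
  } else {
    e <- integer(); cf <- numeric()
  }
  structure(list(exps = e, coefs = cf), class = "laurent")
}

#' @export
print.laurent <- function(x, digits = 6, ...) {
  if (!length(x$exps)) {
    cat("<laurent> 0\n")
    return(invisible(x))
  }
  term <- function(c, e) {
    cs <- format(c, digits = digits)
    if (e == 0) cs else if (e == 1) paste0(cs, "*A") else paste0(cs, "*A^", e)
  }
  cat("<laurent>", paste(mapply(term, x$coefs, x$exps), collapse = " + "), "\n")
  invisible(x)
}

lp_zero <- function() laurent()
lp_one <- function() laurent(1, 0L)

#' Loop value d = -A^2 - A^-2
#' @return A `laurent` polynomial.
#' @export
lp_d <- function() laurent(c(-1, -1), c(2L, -2L))

lp_is_zero <- function(p) length(p$exps) == 0L

#' Add two Laurent polynomials
#' @param a,b `laurent` objects.
#' @export
lp_add <- function(a, b) laurent(c(a$coefs, b$coefs), c(a$exps, b$exps))

#' Multiply two Laurent polynomials
#' @param a,b `laurent` objects.
#' @export
lp_mul <- function(a, b) {
  if (lp_is_zero(a) || lp_is_zero(b)) return(lp_zero())
  e <- outer(a$exps, b$exps, `+`)
  cf <- outer(a$coefs, b$coefs)
  laurent(as.vector(cf), as.vector(e))
}

#' Scale a Laurent polynomial by s * A^k
#' @param p a `laurent` object.
#' @param s numeric scalar.
#' @param k integer exponent shift.
#' @export
lp_scale <- function(p, s = 1, k = 0L) laurent(p$coefs * s, p$exps + as.integer(k))

#' Substitute A with its inverse (mirror image)
#' @param p a `laurent` object.
#' @export
lp_mirror <- function(p) laurent(p$coefs, -p$exps)

#' Evaluate at a numeric value of A
#' @param p a `laurent` object.
#' @param A positive numeric value of the bracket variable.
#' @export
lp_eval <- function(p, A) {
  stopifnot(is.finite(A), A > 0)
  if (lp_is_zero(p)) return(0)
  sum(p$coefs * A^p$exps)
}

#' Evaluate at a Jones variable t via A = t^(-1/4)
#' @param p a `laurent` object.
#' @param t positive numeric value of the Jones variable.
#' @export
lp_eval_t <- function(p, t) {
  stopifnot(is.finite(t), t > 0)
  lp_eval(p, t^(-0.25))
}

#' Compare two Laurent polynomials coefficient-wise
#' @param a,b `laurent` objects.
#' @param tol absolute coefficient tolerance (0 for exact).
#' @export
lp_equal <- function(a, b, tol = 0) {
  e <- sort(unique(c(a$exps, b$exps)))
  ca <- cb <- numeric(length(e))
  ca[match(a$exps, e)] <- a$coefs
  cb[match(b$exps, e)] <- b$coefs
  all(abs(ca - cb) <= tol)
}

# mean of a list of laurent polynomials, coefficient-wise
lp_mean <- function(ps) {
  e <- sort(unique(unlist(lapply(ps, `[[`, "exps"))))
  if (!length(e)) return(lp_zero())
  acc <- numeric(length(e))
  for (p in ps) acc[match(p$exps, e)] <- acc[match(p$exps, e)] + p$coefs
  laurent(acc / length(ps), e)
}

# cache of powers of d; exponents in the bracket never exceed a few dozen
lp_d_pow <- local({
  cache <- list(lp_one(), lp_d())
  function(k) {
    k <- as.integer(k)
    stopifnot(k >= 0)
    while (length(cache) < k + 1L) {
      cache[[length(cache) + 1L]] <<- lp_mul(cache[[length(cache)]], lp_d())
    }
    cache[[k + 1L]]
  }
})
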