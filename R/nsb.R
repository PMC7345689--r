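## B-spline design matrix by the Cox-de Boor recursion.
## Aknots: full (augmented) knot vector; returns the deriv-th derivative of
## every order-`ord` B-spline at x.  x must lie within the boundary knots.
.bspl <- function(Aknots, x, ord = 4L, deriv = 0L) {
  t <- as.numeric(Aknots)
  n <- length(x)
  if (deriv > 0L) {
    lower <- .bspl(t, x, ord - 1L, deriv - 1L)
    ncols <- length(t) - ord
    out <- matrix(0, n, ncols)
    for (j in seq_len(ncols)) {
      d1 <- t[j + ord - 1L] - t[j]
      d2 <- t[j + ord] - t[j + 1L]
      v <- 0
      if (d1 > 0) v <- v + lower[, j] / d1
      if (d2 > 0) v <- v - lower[, j + 1L] / d2
      out[, j] <- (ord - 1L) * v
    }
    return(out)
  }
  # order 1: indicator of the knot interval, right boundary closed
  B <- matrix(0, n, length(t) - 1L)
  for (j in seq_len(length(t) - 1L))
    B[, j] <- as.numeric(x >= t[j] & x < t[j + 1L])
  right <- t[length(t)]
  at_right <- x == right
  if (any(at_right)) {
    jr <- max(which(t < right))
    B[at_right, ] <- 0
    B[at_right, jr] <- 1
  }
  if (ord == 1L) return(B)
  for (k in 2:ord) {
    Bk <- matrix(0, n, length(t) - k)
    for (j in seq_len(length(t) - k)) {
      d1 <- t[j + k - 1L] - t[j]
      d2 <- t[j + k] - t[j + 1L]
      v <- 0
      if (d1 > 0) v <- v + (x - t[j]) / d1 * B[, j]
      if (d2 > 0) v <- v + (t[j + k] - x) / d2 * B[, j + 1L]
      Bk[, j] <- v
    }
    B <- Bk
  }
  B
}

#' Natural cubic spline basis
#'
#' Builds the `df`-column natural cubic spline basis used for the smooth
#' temperature adjustment: a cubic B-spline basis constrained to be
#' linear beyond the boundary knots (zero second derivative there).
#' Without an intercept column, `df` degrees of freedom place
#' `df - 1` internal knots at equally spaced quantiles of `x` — for the
#' default `df = 3`, at the 33.3rd and 66.7th percentiles — with boundary
#' knots at the range of `x`.  Values outside the boundary knots are
#' extended linearly.  The construction follows the conventional
#' natural-spline basis of regression modelling so that fitted models
#' match those of the widely used `ns()` parameterisation.
#'
#' Usable directly inside model formulas, e.g.
#' `ccpois(count ~ no2_lag1 + nsb(temp_lag1, 3), ...)`.
#'
#' @param x numeric vector to evaluate the basis at.
#' @param df degrees of freedom (number of basis columns), default 3.
#' @param knots internal knot locations; defaults to quantiles of `x`.
#' @param boundary_knots boundary knot pair; defaults to `range(x)`.
#' @return An `n` x `df` matrix with attributes `knots`,
#'   `boundary_knots` and class `"nsb"`.  Rows for missing `x` are `NA`.
#' @export
nsb <- function(x, df = 3L, knots = NULL, boundary_knots = NULL) {
  nax <- is.na(x)
  xs <- as.numeric(x[!nax])
  if (is.null(boundary_knots)) {
    if (!length(xs)) stop("no non-missing values to place boundary knots")
    boundary_knots <- range(xs)
  }
  b <- as.numeric(boundary_knots)
  outside <- xs < b[1L] | xs > b[2L]
  if (is.null(knots)) {
    if (length(unique(xs)) < df + 1L)
      stop("too few distinct values for the requested degrees of freedom")
    n_internal <- df - 1L
    if (n_internal < 0L) stop("df must be at least 1")
    knots <- if (n_internal > 0L) {
      probs <- seq.int(0, 1, length.out = n_internal + 2L)[-c(1L, n_internal + 2L)]
      quantile(xs[!outside], probs, names = FALSE, type = 7)
    } else numeric()
  }
  if (length(unique(c(b, knots))) < length(knots) + 2L)
    stop("degenerate knot placement: knots and boundaries must be distinct")
  Aknots <- sort(c(rep(b, 4L), as.numeric(knots)))
  ncols <- length(knots) + 4L

  basis <- matrix(0, length(xs), ncols)
  if (any(outside)) {
    ol <- xs < b[1L]
    or <- xs > b[2L]
    if (any(ol)) {
      tt <- rbind(.bspl(Aknots, b[1L], 4L, 0L), .bspl(Aknots, b[1L], 4L, 1L))
      basis[ol, ] <- cbind(1, xs[ol] - b[1L]) %*% tt
    }
    if (any(or)) {
      tt <- rbind(.bspl(Aknots, b[2L], 4L, 0L), .bspl(Aknots, b[2L], 4L, 1L))
      basis[or, ] <- cbind(1, xs[or] - b[2L]) %*% tt
    }
    if (any(!outside))
      basis[!outside, ] <- .bspl(Aknots, xs[!outside], 4L, 0L)
  } else {
    basis <- .bspl(Aknots, xs, 4L, 0L)
  }
  # natural constraint: zero second derivative at both boundary knots
  const <- .bspl(Aknots, b, 4L, 2L)
  const <- const[, -1L, drop = FALSE]   # drop the intercept-carrying column
  basis <- basis[, -1L, drop = FALSE]
  qr_const <- qr(t(const))
  basis <- as.matrix((t(qr.qty(qr_const, t(basis))))[, -(1L:2L), drop = FALSE])

  if (any(nax)) {
    full <- matrix(NA_real_, length(x), ncol(basis))
    full[!nax, ] <- basis
    basis <- full
  }
  colnames(basis) <- as.character(seq_len(ncol(basis)))
  structure(basis, knots = as.numeric(knots), boundary_knots = b,
            class = c("nsb", "basis", "matrix"))
}

#' @export
makepredictcall.nsb <- function(var, call) {
  if (as.character(call)[1L] != "nsb") return(call)
  at <- attributes(var)[c("knots", "boundary_knots")]
  call <- call[1:2]
  call[names(at)] <- at
  call
}
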