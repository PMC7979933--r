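#' Box-Cox power transform and its inverse
#'
#' The standard one-parameter power transform used to normalize the
#' positively skewed SOC stock distribution:
#' `z = (y^lambda - 1) / lambda` for `lambda != 0` and `z = log(y)` at
#' `lambda = 0`. The inverse is defined for `lambda * z + 1 > 0`
#' (always, at `lambda = 0`).
#'
#' @param y Strictly positive values (Mg/ha stocks).
#' @param z Transformed values.
#' @param lambda Transform exponent.
#' @param missing_on_domain If `TRUE`, values of `z` outside the inverse's
#'   domain are returned as `NA` instead of raising an error (used when
#'   back-transforming model predictions, where the count of undefined
#'   cells is reported rather than fatal).
#' @return `boxcox_apply`: the transformed vector. `boxcox_invert`: the
#'   back-transformed positive vector.
#' @export
boxcox_apply <- function(y, lambda) {
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop_invalid("boxcox_apply() requires strictly positive finite values")
  }
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

#' @rdname boxcox_apply
#' @export
boxcox_invert <- function(z, lambda, missing_on_domain = FALSE) {
  if (lambda == 0) return(exp(z))
  arg <- lambda * z + 1
  bad <- which(is.finite(arg) & arg <= 0)
  if (length(bad)) {
    if (!missing_on_domain) {
      stop_invalid("Box-Cox inverse undefined: lambda * z + 1 <= 0 for ",
                   length(bad), " value(s)")
    }
    arg[bad] <- NA_real_
  }
  arg^(1 / lambda)
}

# Golden-section maximization of f on [lo, hi] to tolerance tol.
golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1)
  f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 >= f2) {
      hi <- x2
      x2 <- x1
      f2 <- f1
      x1 <- hi - gr * (hi - lo)
      f1 <- f(x1)
    } else {
      lo <- x1
      x1 <- x2
      f1 <- f2
      x2 <- lo + gr * (hi - lo)
      f2 <- f(x2)
    }
  }
  x <- (lo + hi) / 2
  list(maximum = x, objective = f(x))
}

#' Fit a Box-Cox transform by profile likelihood
#'
#' Maximizes the profile log-likelihood
#' `ll(lambda) = -(n/2) log(RSS(lambda)/n) + (lambda - 1) sum(log y)`,
#' where `RSS(lambda)` is the sum of squares of the transformed values
#' about their mean. The search is a coarse grid over `[-2, 2]` in steps
#' of 0.01 followed by golden-section refinement to a tolerance of 1e-4,
#' so the returned exponent does not depend on starting values.
#'
#' @param y Strictly positive response values, at least 10 of them.
#' @param lower,upper Search interval for the exponent.
#' @return An object of class `boxcox_transform` with elements `lambda`
#'   and `loglik`.
#' @examples
#' bc <- fit_boxcox(rlnorm(200))          # lambda near 0 (log transform)
#' y2 <- boxcox_invert(boxcox_apply(rlnorm(200), bc$lambda), bc$lambda)
#' @export
fit_boxcox <- function(y, lower = -2, upper = 2) {
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop_invalid("fit_boxcox() requires strictly positive finite values")
  }
  n <- length(y)
  if (n < 10L) stop_invalid("fit_boxcox() needs at least 10 observations")
  sly <- sum(log(y))
  ll <- function(lambda) {
    z <- boxcox_apply(y, lambda)
    rss <- sum((z - mean(z))^2)
    -(n / 2) * log(rss / n) + (lambda - 1) * sly
  }
  lams <- seq(lower, upper, by = 0.01)
  vals <- vapply(lams, ll, numeric(1L))
  i <- which.max(vals)
  opt <- golden_max(ll,
                    lams[max(1L, i - 1L)],
                    lams[min(length(lams), i + 1L)])
  structure(list(lambda = opt$maximum, loglik = opt$objective),
            class = "boxcox_transform")
}

#' @export
print.boxcox_transform <- function(x, ...) {
  cat(sprintf("Box-Cox transform: lambda = %.4f (profile loglik %.2f)\n",
              x$lambda, x$loglik))
  invisible(x)
}
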