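## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

checkScalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}

## Trapezoidal integral on a (possibly non-uniform) grid.
trapint <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Relative change between two lengths, in percent
#'
#' Convenience for expressing a thickness (or spacing) change as a percent of
#' the reference value, e.g. a bilayer thinning of 3.68 Angstrom on a
#' 30.44 Angstrom half-thickness is a 12\% reduction.
#'
#' @param delta numeric, the change (same units as \code{reference}).
#' @param reference numeric(1), the reference value (> 0).
#' @return numeric, 100 * delta / reference.
#' @examples
#' relativeChangePercent(3.68, 30.44)
#' @export
relativeChangePercent <- function(delta, reference) {
  checkScalar(reference, "reference", 0, strict = TRUE)
  100 * delta / reference
}

## Split-walker potential-scale-reduction (R-hat) across ensemble walkers.
## x: iterations x walkers matrix of one parameter.
rhatWalkers <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  chains <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

## Integrated autocorrelation time (Sokal windowing) of a vector.
autocorrTime <- function(x, c = 5) {
  n <- length(x)
  if (n < 16 || stats::sd(x) == 0) return(1)
  ac <- stats::acf(x, lag.max = min(n - 2, 400), plot = FALSE)$acf[-1]
  tau <- 1
  for (k in seq_along(ac)) {
    tau <- tau + 2 * ac[k]
    if (k >= c * tau) break
  }
  max(1, tau)
}
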