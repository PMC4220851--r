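#' Immune functional response
#'
#' The per-immune-cell kill rate f(x) as a function of tumour biomass x.
#' The analysis requires f to be smooth, vanish at 0, increase strictly and
#' stay bounded, and the per-tumour-cell risk P(x) = f(x)/x to decrease
#' strictly with limit f'(0) at the origin. The Monod (Holling type II)
#' form c*x/(a + x) satisfies all of these and is the response used in the
#' numerical work.
#'
#' @param a half-saturation biomass (positive).
#' @param c maximal kill rate, per day (positive).
#' @return An object of class \code{functional_response}: a list with
#'   \code{f(x)}, derivative \code{df(x)}, per-capita risk \code{P(x)}
#'   (continuously extended to \code{P(0) = f'(0)}), and metadata.
#' @examples
#' fr <- monod_response(a = 0.25, c = 0.81)
#' fr$f(0.25)   # half-saturation: c/2
#' @export
monod_response <- function(a, c) {
  if (a <= 0 || c <= 0) stop("a and c must be positive")
  f <- function(x) {
    if (any(x < 0)) stop("functional response needs x >= 0")
    c * x / (a + x)
  }
  structure(list(
    f = f,
    df = function(x) c * a / (a + x)^2,
    P = function(x) c / (a + x),
    name = "monod",
    pars = list(a = a, c = c)
  ), class = "functional_response")
}

#' Wrap a user-supplied response
#'
#' Builds a \code{functional_response} from an arbitrary evaluator; the
#' derivative, when not supplied, is taken by central differences with step
#' \code{max(1e-6, 1e-6 * x)}, and P(x) = f(x)/x with P(0) = f'(0).
#'
#' @param f evaluator, vectorized over x >= 0.
#' @param df optional analytic derivative.
#' @param name label for reports.
#' @return A \code{functional_response}.
#' @export
custom_response <- function(f, df = NULL, name = "custom") {
  if (is.null(df)) {
    df <- function(x) {
      h <- pmax(1e-6, 1e-6 * x)
      xm <- pmax(x - h, 0)
      (f(x + h) - f(xm)) / (x + h - xm)
    }
  }
  structure(list(
    f = f, df = df,
    P = function(x) ifelse(x > 0, f(x) / x, df(0)),
    name = name, pars = list()
  ), class = "functional_response")
}

#' Audit the contract of a functional response
#'
#' Numerically checks, on a user grid, the properties the model analysis
#' assumes of f: f(0+) = 0, strict monotone increase, boundedness, strict
#' monotone decrease of P(x) = f(x)/x, and agreement of P(0+) with f'(0).
#'
#' @param fr a \code{functional_response}.
#' @param grid strictly positive, sorted evaluation grid.
#' @param bounded_slope_tol slope threshold (relative to f at the grid end)
#'   below which the tail is accepted as bounded.
#' @return A list of class \code{response_audit}: logical flags per property
#'   and an overall \code{pass}.
#' @export
response_audit <- function(fr, grid = 10^seq(-6, 3, length.out = 200),
                           bounded_slope_tol = 1e-3) {
  if (!length(grid)) stop("grid must be non-empty")
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly positive and strictly increasing")
  fv <- vapply(grid, fr$f, numeric(1))
  Pv <- vapply(grid, fr$P, numeric(1))
  zero_at_origin <- abs(fr$f(min(grid) * 1e-3)) <= 1e-8 * max(abs(fv), 1e-12)
  increasing <- all(diff(fv) > 0)
  # bounded: by the grid end the local slope times x must be negligible
  # against the attained level (true for any saturating response)
  n <- length(grid)
  tail_slope <- (fv[n] - fv[n - 1]) / (grid[n] - grid[n - 1])
  bounded <- is.finite(fv[n]) &&
    tail_slope * grid[n] <= bounded_slope_tol * max(fv)
  P_decreasing <- all(diff(Pv) < 0)
  d0 <- fr$df(0)
  P_origin_ok <- abs(fr$P(min(grid)) - d0) <= 1e-3 * max(abs(d0), 1e-12) ||
    abs(fr$P(1e-9) - d0) <= 1e-6 * max(abs(d0), 1e-12)
  out <- list(zero_at_origin = zero_at_origin, increasing = increasing,
              bounded = bounded, P_decreasing = P_decreasing,
              P_origin_matches_derivative = P_origin_ok,
              name = fr$name)
  out$pass <- all(unlist(out[1:5]))
  class(out) <- "response_audit"
  out
}

#' @export
print.response_audit <- function(x, ...) {
  cat("Functional-response audit (", x$name, ")\n", sep = "")
  for (f in c("zero_at_origin", "increasing", "bounded", "P_decreasing",
              "P_origin_matches_derivative"))
    cat(sprintf("  %-30s %s\n", f, if (x[[f]]) "pass" else "FAIL"))
  cat("overall:", if (x$pass) "pass" else "FAIL", "\n")
  invisible(x)
}

#' Build the response encoded in a parameter set
#' @param params a \code{stoich_params} object.
#' @return the Monod response with the set's \code{a} and \code{c}.
#' @keywords internal
response_from <- function(params) monod_response(params$a, params$c)
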