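#' Model parameter set
#'
#' Construct the full parameter vector of the stoichiometric tumour-immune
#' model. Biomass is expressed in carbon units; rates are per day. The system
#' is closed for potassium: the total mass \code{K_t} is partitioned between
#' the tumour pool (variable quota \code{Q} with floor \code{q}), the immune
#' pool (fixed quota \code{theta}) and the free pool in the surroundings.
#'
#' @param b tumour intrinsic growth rate (per day).
#' @param L carbon-limited tumour carrying capacity (carbon biomass).
#' @param K_t total potassium mass in the closed system.
#' @param theta fixed immune-cell potassium:carbon quota.
#' @param q tumour minimal potassium:carbon quota.
#' @param mu_m tumour true maximal growth rate (per day), used inside the
#'   quasi-steady-state quota closure.
#' @param alpha potassium uptake proportionality constant (per day).
#' @param e maximal immune recruitment efficiency (dimensionless, expected
#'   at most 1).
#' @param d immune apoptosis rate (per day).
#' @param l coercion rate coefficient (per biomass per day): loss of immune
#'   cells recruited by the tumour into a servile role.
#' @param u constant immune-cell influx (biomass per day), e.g. a treatment.
#' @param c maximal per-capita kill rate of the immune functional response
#'   (per day).
#' @param a half-saturation tumour biomass of the functional response.
#'
#' @return An object of class \code{stoich_params} (a named list).
#' @seealso [reference_parameters()], [scale_params()], [validate_params()]
#' @export
stoich_params <- function(b, L, K_t, theta, q, mu_m, alpha, e, d,
                          l = 0, u = 0, c, a) {
  p <- structure(
    list(b = b, L = L, K_t = K_t, theta = theta, q = q, mu_m = mu_m,
         alpha = alpha, e = e, d = d, l = l, u = u, c = c, a = a),
    class = "stoich_params")
  diag <- validate_params(p)
  errs <- vapply(diag, function(d) d$severity == "error", logical(1))
  if (any(errs))
    stop("invalid parameters: ",
         paste(vapply(diag[errs], `[[`, character(1), "message"),
               collapse = "; "))
  for (w in diag[!errs]) warning(w$message, call. = FALSE)
  p
}

param_fields <- function() {
  c("b", "L", "K_t", "theta", "q", "mu_m", "alpha", "e", "d", "l", "u",
    "c", "a")
}

#' Reference parameter set
#'
#' The reference data set used throughout the numerical work, adapted from
#' classic stoichiometric producer-grazer experiments. The carrying capacity
#' \code{L} is the free choice (its admissible range is 0.25-2.0); the
#' coercion rate \code{l} and the treatment influx \code{u} are
#' scenario-specific and default to 0, which reduces the model to its
#' stoichiometric predator-prey (KHE) core.
#'
#' @param L carrying capacity choice; a warning is issued outside 0.25-2.0.
#' @param ... overrides for any other field (e.g. \code{l}, \code{u},
#'   \code{K_t}).
#' @return A \code{stoich_params} object.
#' @examples
#' p <- reference_parameters(L = 1.0, l = 0.2, u = 0.05)
#' p$theta
#' @export
reference_parameters <- function(L = 1.0, ...) {
  if (L < 0.25 || L > 2.0)
    warning("L = ", L, " is outside the reference range 0.25-2.0",
            call. = FALSE)
  base <- list(b = 1.2, L = L, K_t = 0.025, theta = 0.03, q = 0.0038,
               mu_m = 1.2, alpha = 10, e = 0.8, d = 0.25, l = 0, u = 0,
               c = 0.81, a = 0.25)
  over <- list(...)
  bad <- setdiff(names(over), param_fields())
  if (length(bad)) stop("unknown parameter field(s): ",
                        paste(bad, collapse = ", "))
  base[names(over)] <- over
  do.call(stoich_params, base)
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the parameter vector and returns a
#' list of diagnostics rather than throwing: each diagnostic has a
#' \code{severity} ("error" or "warning"), the offending \code{field} and a
#' \code{message}. An empty list means all invariants hold.
#'
#' @param params a \code{stoich_params} object or plain named list.
#' @return A list of diagnostics (empty if valid).
#' @export
validate_params <- function(params) {
  out <- list()
  add <- function(severity, field, message)
    out[[length(out) + 1L]] <<- list(severity = severity, field = field,
                                     message = message)
  for (f in param_fields()) {
    v <- params[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      add("error", f, paste0(f, " must be a finite numeric scalar"))
      next
    }
    if (v < 0) add("error", f, paste0(f, " must be nonnegative"))
  }
  if (length(out)) return(out)
  for (f in c("b", "d", "theta", "q", "mu_m", "alpha", "c", "a", "L"))
    if (params[[f]] <= 0) add("error", f, paste0(f, " must be positive"))
  if (params$q >= params$theta)
    add("warning", "q",
        "q >= theta: s >= 1; invariant region becomes degenerate")
  if (params$e > 1)
    add("warning", "e", "e > 1: recruitment efficiency above unity")
  out
}

#' Scale out the immune quota
#'
#' Rewrite the model in the gauge where the immune quota theta is scaled out:
#' \code{p = K_t/theta} is the maximal immune density allowed by the total
#' potassium and \code{s = q/theta} is the dimensionless quota ratio. All
#' other parameters are retained. The scaled and unscaled forms define the
#' same vector field.
#'
#' @param params a \code{stoich_params} object.
#' @return An object of class \code{scaled_params} with fields \code{p},
#'   \code{s} and the remaining model parameters.
#' @export
scale_params <- function(params) {
  if (params$theta <= 0) stop("theta must be positive to scale")
  out <- unclass(params)
  out$p <- params$K_t / params$theta
  out$s <- params$q / params$theta
  out$K_t <- NULL
  out$q <- NULL
  out$theta <- NULL
  structure(out, class = "scaled_params")
}

#' Rebuild an unscaled parameter set from a scaled one
#'
#' The theta-gauge is unobservable: any positive \code{theta} together with
#' \code{K_t = p * theta} and \code{q = s * theta} reproduces an equivalent
#' model.
#'
#' @param scaled a \code{scaled_params} object.
#' @param theta the immune quota to reintroduce (any positive value).
#' @return A \code{stoich_params} object.
#' @export
unscale_params <- function(scaled, theta = 1) {
  if (theta <= 0) stop("theta must be positive")
  stoich_params(b = scaled$b, L = scaled$L, K_t = scaled$p * theta,
                theta = theta, q = scaled$s * theta, mu_m = scaled$mu_m,
                alpha = scaled$alpha, e = scaled$e, d = scaled$d,
                l = scaled$l, u = scaled$u, c = scaled$c, a = scaled$a)
}

#' @export
print.stoich_params <- function(x, ...) {
  cat("Stoichiometric tumour-immune model parameters\n")
  v <- unlist(x[param_fields()])
  print(v)
  cat(sprintf("derived: p = K_t/theta = %.6g, s = q/theta = %.6g\n",
              x$K_t / x$theta, x$q / x$theta))
  invisible(x)
}

#' @export
print.scaled_params <- function(x, ...) {
  cat("Scaled (theta-free) tumour-immune model parameters\n")
  print(unlist(x[c("p", "s", "b", "L", "mu_m", "alpha", "e", "d", "l", "u",
                   "c", "a")]))
  invisible(x)
}

#' Read or write a parameter set as flat JSON
#'
#' Keys are exactly the parameter field names.
#' @param path file path.
#' @return \code{read_params} returns a \code{stoich_params} object.
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(stoich_params, as.list(x)[param_fields()])
}

#' @rdname read_params
#' @param params a \code{stoich_params} object to serialize.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params)[param_fields()], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
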