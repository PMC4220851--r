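#' Detect the period of a sampled attractor
#'
#' Returns the smallest k (up to \code{max_period}) such that samples k
#' apart agree within \code{tol} everywhere, or 0 if no such k exists
#' (aperiodic / chaotic sample).
#'
#' @param samples numeric vector, or matrix with one state per row.
#' @param tol absolute agreement tolerance (applied after scaling by the
#'   sample magnitude).
#' @param max_period largest period tested; capped at half the sample
#'   length.
#' @return Integer period >= 1, or 0 for aperiodic.
#' @export
detect_period <- function(samples, tol = 1e-5, max_period = 64) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  n <- nrow(samples)
  if (n < 4) stop("need at least 4 samples to estimate a period")
  max_period <- min(max_period, floor(n / 2))
  scale <- max(abs(samples), 1)
  for (k in seq_len(max_period)) {
    d <- abs(samples[seq_len(n - k), , drop = FALSE] -
               samples[seq_len(n - k) + k, , drop = FALSE])
    if (max(d) < tol * scale) return(k)
  }
  0L
}

#' Maximal Lyapunov exponent of a map
#'
#' Average logarithmic growth rate of a tangent vector propagated by the
#' map's Jacobian along an orbit, with periodic renormalization.
#'
#' @param step_fn function(state) -> next state.
#' @param jac_fn function(state) -> Jacobian matrix at state.
#' @param state0 initial state (any dimension).
#' @param N iterates used for averaging (after burn-in).
#' @param burn_in transient iterates discarded first.
#' @param renorm_every renormalize the tangent vector every this many
#'   iterates.
#' @return The exponent, per iterate.
#' @export
lyapunov_max <- function(step_fn, jac_fn, state0, N = 2000,
                         burn_in = 200, renorm_every = 1) {
  s <- state0
  for (i in seq_len(burn_in)) {
    s <- step_fn(s)
    if (any(!is.finite(s)))
      stop("orbit escaped during burn-in at iterate ", i)
  }
  d <- length(s)
  v <- rep(1 / sqrt(d), d)
  total <- 0
  for (i in seq_len(N)) {
    J <- jac_fn(s)
    v <- as.numeric(J %*% v)
    s <- step_fn(s)
    if (any(!is.finite(s)) || any(!is.finite(v)))
      stop("orbit escaped at iterate ", burn_in + i)
    if (i %% renorm_every == 0) {
      nv <- sqrt(sum(v^2))
      if (nv == 0) return(-Inf)
      total <- total + log(nv)
      v <- v / nv
    }
  }
  nv <- sqrt(sum(v^2))
  if (nv > 0 && N %% renorm_every != 0) total <- total + log(nv)
  total / N
}

#' Maximal Lyapunov exponent of the discrete tumour-immune map
#'
#' @param params a \code{stoich_params} object.
#' @param state0 start, default c(0.3, 0.3).
#' @param closure quota closure.
#' @inheritParams lyapunov_max
#' @return The exponent, per iterate (per day).
#' @export
model_lyapunov <- function(params, state0 = c(0.3, 0.3),
                           closure = c("qss", "lke"), N = 2000,
                           burn_in = 500, renorm_every = 1) {
  closure <- match.arg(closure)
  lyapunov_max(
    step_fn = function(s) unname(map_step(s[1], s[2], params, closure)),
    jac_fn = function(s) unclass(model_jacobian("discrete", s[1], s[2],
                                                params, closure))[1:2, 1:2],
    state0 = state0, N = N, burn_in = burn_in,
    renorm_every = renorm_every)
}

#' One-parameter bifurcation sweep
#'
#' Sweeps a single model parameter over \code{values} for the continuous
#' model or the discrete map, records post-transient attractor samples at
#' each value, estimates the attractor period, and (for the map) the
#' maximal Lyapunov exponent. By default the final state at one value
#' seeds the next (warm start); cold starts restart every value from
#' \code{start}.
#'
#' @param model "continuous" or "discrete".
#' @param param_name name of the swept field (e.g. "L", "b").
#' @param values strictly monotone sweep values.
#' @param params base parameter set.
#' @param closure quota closure.
#' @param start initial state.
#' @param warm_start carry the final state between values (default TRUE).
#' @param transient,record continuous protocol: days discarded, then days
#'   over which extrema/samples are recorded.
#' @param burn_in,n_sample discrete protocol: iterates discarded, then
#'   iterates kept as attractor samples.
#' @param lyapunov compute the maximal Lyapunov exponent per value
#'   (discrete model only).
#' @return A \code{bifurcation_diagram}: list with a tidy \code{samples}
#'   data frame (value, sample, x, y) and a \code{summary} data frame
#'   (value, x_min, x_max, y_min, y_max, period, lyapunov, failed).
#' @examples
#' p <- reference_parameters(L = 1.6, l = 0.009, u = 0.02)
#' bd <- bifurcation_sweep("discrete", "b", seq(1, 3, by = 0.5), p,
#'                         burn_in = 200, n_sample = 60)
#' bd$summary
#' @export
bifurcation_sweep <- function(model = c("continuous", "discrete"),
                              param_name, values, params,
                              closure = c("qss", "lke"),
                              start = c(0.3, 0.3), warm_start = TRUE,
                              transient = 500, record = 200,
                              burn_in = 2000, n_sample = 300,
                              lyapunov = (model == "discrete")) {
  model <- match.arg(model)
  closure <- match.arg(closure)
  if (!param_name %in% param_fields())
    stop("unknown parameter: ", param_name)
  if (is.unsorted(values, strictly = TRUE) &&
      is.unsorted(rev(values), strictly = TRUE))
    stop("values must be strictly monotone")
  state <- start
  samples <- list(); summ <- list(); n_failed <- 0L
  for (v in values) {
    pv <- params; pv[[param_name]] <- v
    row <- data.frame(value = v, x_min = NA_real_, x_max = NA_real_,
                      y_min = NA_real_, y_max = NA_real_,
                      period = NA_integer_, lyapunov = NA_real_,
                      failed = FALSE)
    res <- tryCatch({
      if (model == "continuous") {
        tr <- simulate_model(state, transient + record, pv, closure,
                             times = c(0, seq(transient,
                                              transient + record,
                                              length.out = n_sample)))
        post <- tr[-1, c("x", "y")]
      } else {
        ob <- map_orbit(state, burn_in + n_sample, burn_in, pv, closure)
        post <- ob[!ob$transient, c("x", "y")]
      }
      post
    }, error = function(e) NULL)
    if (is.null(res)) {
      row$failed <- TRUE
      n_failed <- n_failed + 1L
      if (!warm_start) state <- start
      summ[[length(summ) + 1L]] <- row
      next
    }
    row$x_min <- min(res$x); row$x_max <- max(res$x)
    row$y_min <- min(res$y); row$y_max <- max(res$y)
    row$period <- if (nrow(res) >= 8)
      detect_period(as.matrix(res),
                    tol = if (model == "continuous") 1e-4 else 1e-5)
    else NA_integer_
    if (lyapunov && model == "discrete")
      row$lyapunov <- tryCatch(
        model_lyapunov(pv, state0 = as.numeric(res[nrow(res), ]),
                       closure = closure, N = 1000, burn_in = 100),
        error = function(e) NA_real_)
    samples[[length(samples) + 1L]] <-
      data.frame(value = v, sample = seq_len(nrow(res)),
                 x = res$x, y = res$y)
    if (warm_start) state <- as.numeric(res[nrow(res), ])
    else state <- start
    summ[[length(summ) + 1L]] <- row
  }
  if (n_failed == length(values))
    stop("sweep failed at every value; see per-value log")
  structure(list(
    model = model, param_name = param_name, values = values,
    samples = do.call(rbind, samples), summary = do.call(rbind, summ),
    closure = closure, warm_start = warm_start,
    protocol = list(transient = transient, record = record,
                    burn_in = burn_in, n_sample = n_sample)
  ), class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("Bifurcation sweep (%s model) over %s: %d values\n",
              x$model, x$param_name, length(x$values)))
  per <- x$summary$period
  cat("periods observed:",
      paste(sort(unique(per[!is.na(per)])), collapse = ", "), "\n")
  if (any(!is.na(x$summary$lyapunov)))
    cat(sprintf("max Lyapunov exponent: %.4g\n",
                max(x$summary$lyapunov, na.rm = TRUE)))
  if (any(x$summary$failed))
    cat("failed values:", sum(x$summary$failed), "\n")
  invisible(x)
}

#' @export
plot.bifurcation_diagram <- function(x, variable = c("x", "y"), ...) {
  variable <- match.arg(variable)
  graphics::plot(x$samples$value, x$samples[[variable]], pch = 20,
                 cex = 0.2, xlab = x$param_name,
                 ylab = paste(variable, "attractor samples"), ...)
  invisible(x)
}

#' Export a bifurcation diagram as tidy CSV
#'
#' Columns: value, variable, sample, state, period, lyapunov.
#' @param bd a \code{bifurcation_diagram}.
#' @param path output path.
#' @export
write_bifurcation <- function(bd, path) {
  long <- rbind(
    data.frame(value = bd$samples$value, variable = "x",
               sample = bd$samples$sample, state = bd$samples$x),
    data.frame(value = bd$samples$value, variable = "y",
               sample = bd$samples$sample, state = bd$samples$y))
  long <- merge(long, bd$summary[, c("value", "period", "lyapunov")],
                by = "value", sort = FALSE)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
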