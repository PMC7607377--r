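#' Natural cubic spline basis on log time
#'
#' The baseline cumulative hazard of the flexible parametric survival model
#' is represented through a restricted ("natural") cubic spline in log time:
#' piecewise cubic between knots, with continuous second derivative across
#' every knot, and constrained to be linear beyond the boundary knots. This
#' file provides the knot container, a data-driven knot chooser, and exact
#' closed-form evaluation of the basis functions and their first derivative
#' (the derivative is needed for the hazard term of the likelihood).
#'
#' With boundary knots \eqn{k_{min} < k_{max}} and internal knots
#' \eqn{k_1 < \dots < k_m}, the j-th basis function is
#' \deqn{\nu_j(y) = (y-k_j)_+^3 - \lambda_j (y-k_{min})_+^3
#'       - (1-\lambda_j)(y-k_{max})_+^3,}
#' where \eqn{\lambda_j = (k_{max}-k_j)/(k_{max}-k_{min})} and
#' \eqn{(\cdot)_+} is the positive part. \eqn{m = 0} gives an empty basis,
#' so that the spline part of the model reduces to a function linear in log
#' time (a Weibull-type baseline).
#'
#' @name spline_basis
NULL

#' Construct a knot set for the log-time spline
#'
#' @param boundary numeric length-2 vector, lower and upper boundary knots
#'   (log-time scale), strictly increasing.
#' @param internal numeric vector of m >= 0 internal knots, strictly
#'   increasing and strictly inside the boundary interval.
#' @return An object of class `knot_set` with elements `boundary` and
#'   `internal`.
#' @export
knot_set <- function(boundary, internal = numeric(0)) {
  boundary <- as.numeric(boundary)
  internal <- as.numeric(internal)
  if (length(boundary) != 2L || any(!is.finite(boundary)))
    stop("`boundary` must be two finite log-time values", call. = FALSE)
  if (length(internal) && any(!is.finite(internal)))
    stop("internal knots must be finite", call. = FALSE)
  k <- c(boundary[1L], internal, boundary[2L])
  if (any(diff(k) <= 0))
    stop("knots must be strictly increasing: boundary_low < internal < boundary_high",
         call. = FALSE)
  structure(list(boundary = boundary, internal = internal),
            class = "knot_set")
}

#' @export
print.knot_set <- function(x, ...) {
  cat(sprintf("<knot_set> boundary [%.4g, %.4g], %d internal knot%s",
              x$boundary[1L], x$boundary[2L], length(x$internal),
              if (length(x$internal) == 1L) "" else "s"))
  if (length(x$internal))
    cat(":", paste(signif(x$internal, 4), collapse = ", "))
  cat("\n")
  invisible(x)
}

n_internal_knots <- function(knots) length(knots$internal)

#' Place knots at quantiles of observed log event times
#'
#' Boundary knots are placed at the minimum and maximum of the supplied log
#' times; the `m` internal knots at the equally spaced quantiles
#' j/(m+1), j = 1..m, strictly between them. This is the standard placement
#' for this model family and is reproducible from the data alone.
#'
#' @param log_times numeric vector of log event times (finite, non-empty).
#' @param m number of internal knots (non-negative integer).
#' @return A [knot_set()].
#' @export
make_knots <- function(log_times, m = 2L) {
  log_times <- as.numeric(log_times)
  if (!length(log_times) || any(!is.finite(log_times)))
    stop("`log_times` must be non-empty and finite", call. = FALSE)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 0L)
    stop("`m` must be a single non-negative integer", call. = FALSE)
  if (length(unique(log_times)) < m + 2L)
    stop(sprintf(
      "degenerate knots: need at least %d distinct log times for m = %d internal knots",
      m + 2L, m), call. = FALSE)
  boundary <- range(log_times)
  internal <- if (m > 0L)
    as.numeric(stats::quantile(log_times, probs = seq_len(m) / (m + 1),
                               names = FALSE, type = 7))
  else numeric(0)
  k <- c(boundary[1L], internal, boundary[2L])
  if (any(diff(k) <= 0))
    stop("degenerate knots: quantiles of `log_times` are not distinct; reduce `m`",
         call. = FALSE)
  knot_set(boundary, internal)
}

# Shared positive-part weights for value/derivative evaluation.
knot_lambda <- function(knots) {
  kmin <- knots$boundary[1L]; kmax <- knots$boundary[2L]
  (kmax - knots$internal) / (kmax - kmin)
}

#' Evaluate the spline basis functions
#'
#' @param knots a [knot_set()].
#' @param y numeric vector of log-time values.
#' @return A `length(y) x m` matrix of basis values (0 columns when there
#'   are no internal knots).
#' @export
basis_value <- function(knots, y) {
  stopifnot(inherits(knots, "knot_set"))
  y <- as.numeric(y)
  m <- n_internal_knots(knots)
  out <- matrix(0, nrow = length(y), ncol = m)
  if (m == 0L) return(out)
  kmin <- knots$boundary[1L]; kmax <- knots$boundary[2L]
  lam <- knot_lambda(knots)
  pp3 <- function(u) pmax(u, 0)^3
  for (j in seq_len(m)) {
    out[, j] <- pp3(y - knots$internal[j]) -
      lam[j] * pp3(y - kmin) - (1 - lam[j]) * pp3(y - kmax)
  }
  colnames(out) <- paste0("nu", seq_len(m))
  out
}

#' First derivative of the spline basis functions
#'
#' Exact closed-form derivative of [basis_value()] with respect to log time.
#'
#' @inheritParams basis_value
#' @return A `length(y) x m` matrix of derivative values.
#' @export
basis_derivative <- function(knots, y) {
  stopifnot(inherits(knots, "knot_set"))
  y <- as.numeric(y)
  m <- n_internal_knots(knots)
  out <- matrix(0, nrow = length(y), ncol = m)
  if (m == 0L) return(out)
  kmin <- knots$boundary[1L]; kmax <- knots$boundary[2L]
  lam <- knot_lambda(knots)
  pp2 <- function(u) pmax(u, 0)^2
  for (j in seq_len(m)) {
    out[, j] <- 3 * (pp2(y - knots$internal[j]) -
                       lam[j] * pp2(y - kmin) - (1 - lam[j]) * pp2(y - kmax))
  }
  colnames(out) <- paste0("dnu", seq_len(m))
  out
}
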