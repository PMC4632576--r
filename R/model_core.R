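#' @useDynLib tcelltol, .registration = TRUE
#' @importFrom stats approx setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single strictly positive finite number", name),
         call. = FALSE)
  }
  as.numeric(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative finite number", name),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Dimensional model parameters
#'
#' The four positive rates of the inertial/elastic clonal-response model
#' \deqn{T''(t) = -k\,T(t) + \lambda P(t), \qquad
#'       P'(t) = \alpha P(t) - \beta\,T(t)\,P(t).}
#' `k` is the elastic restoring coefficient (time^-2) pulling the effector
#' population back to baseline, `lam` the antigenic force coefficient
#' (cells pathogen^-1 time^-2) — a proxy for TCR/epitope affinity — `alpha`
#' the pathogen per-capita growth rate (time^-1) and `beta` the clearance
#' coefficient (cell^-1 time^-1).
#'
#' All four rates are positive in the model proper; `lam` and `beta` may be
#' set to zero to access the uncoupled analytic limits (harmonic oscillator,
#' pure exponential pathogen growth) used for solver validation.
#'
#' @param k Elastic restoring coefficient (> 0).
#' @param lam Antigenic force coefficient (>= 0; 0 only for analytic limits).
#' @param alpha Pathogen growth rate (> 0).
#' @param beta Clearance coefficient (>= 0; 0 only for analytic limits).
#' @return An object of class `dim_params`.
#' @seealso [reduced_params()], [to_reduced()]
#' @export
#' @examples
#' dim_params(k = 1, lam = 1, alpha = 2, beta = 1)
dim_params <- function(k, lam, alpha, beta) {
  structure(
    list(k = .check_positive(k, "k"),
         lam = .check_nonneg(lam, "lam"),
         alpha = .check_positive(alpha, "alpha"),
         beta = .check_nonneg(beta, "beta")),
    class = "dim_params")
}

#' Non-dimensional model parameters
#'
#' The reduced two-parameter form of the model. After rescaling time by the
#' elastic frequency and the state by its natural scales (see [to_reduced()]),
#' the dynamics depend only on `alpha_star`, the pathogen growth rate relative
#' to the elastic frequency, and `beta_star`, the dimensionless clearance
#' strength. The tolerance/elimination phase diagram lives in this plane.
#'
#' @param alpha_star Dimensionless pathogen growth rate (> 0).
#' @param beta_star Dimensionless clearance strength (> 0).
#' @return An object of class `reduced_params`.
#' @export
#' @examples
#' reduced_params(alpha_star = 0.5, beta_star = 1)
reduced_params <- function(alpha_star, beta_star) {
  structure(
    list(alpha_star = .check_positive(alpha_star, "alpha_star"),
         beta_star = .check_positive(beta_star, "beta_star")),
    class = "reduced_params")
}

#' Initial state of a single-clone run
#'
#' The model describes the effector population from the instant of naive
#' T-cell activation, so the default starts with an empty effector pool
#' (`T0 = 0`, `dT0 = 0`) facing a unit pathogen load.
#'
#' @param T0 Initial effector T-cell level (>= 0).
#' @param dT0 Initial rate of change of T.
#' @param P0 Initial pathogen load (> 0).
#' @return An object of class `initial_state`.
#' @export
initial_state <- function(T0 = 0, dT0 = 0, P0 = 1) {
  if (!is.numeric(T0) || length(T0) != 1L || !is.finite(T0) || T0 < 0)
    stop("'T0' must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(dT0) || length(dT0) != 1L || !is.finite(dT0))
    stop("'dT0' must be a single finite number", call. = FALSE)
  structure(
    list(T0 = as.numeric(T0), dT0 = as.numeric(dT0),
         P0 = .check_positive(P0, "P0")),
    class = "initial_state")
}

#' Per-clone parameters for the multi-clone model
#'
#' In the multi-clone extension each activated clone is driven by the same
#' pathogen population through its own antigenic coefficient `lam`, and the
#' clones' clearance contributions add in proportion to their abundances:
#' \deqn{T_i'' = -k_i T_i + \lambda_i P, \qquad
#'       P' = \alpha P - P \sum_i \beta_i T_i.}
#'
#' @param label Character identifier, unique within a clone list.
#' @param k Per-clone elastic coefficient (> 0).
#' @param lam Per-clone antigenic/affinity coefficient (> 0).
#' @param beta Per-clone clearance coefficient (> 0).
#' @return An object of class `clone_params`.
#' @export
#' @examples
#' clones <- list(clone_params("dominant", k = 1, lam = 2, beta = 0.5),
#'                clone_params("subdominant", k = 1, lam = 1, beta = 0.5))
clone_params <- function(label, k, lam, beta) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be a non-empty string", call. = FALSE)
  structure(
    list(label = label,
         k = .check_positive(k, "k"),
         lam = .check_positive(lam, "lam"),
         beta = .check_positive(beta, "beta")),
    class = "clone_params")
}

.check_clones <- function(clones) {
  if (!is.list(clones) || length(clones) == 0L)
    stop("'clones' must be a non-empty list of clone_params", call. = FALSE)
  if (!all(vapply(clones, inherits, logical(1), "clone_params")))
    stop("every element of 'clones' must be a clone_params object",
         call. = FALSE)
  labels <- vapply(clones, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("clone labels must be unique", call. = FALSE)
  invisible(labels)
}

#' Simulation controls
#'
#' Integration horizon, event thresholds and solver tolerances. `p_min` is
#' the minimum population size at which the pathogen is still infective: a
#' downward crossing of `p_min` terminates the run as pathogen control.
#' `peak_guard_eps` arms the contraction-end event: the total effector
#' population must first exceed its baseline by this margin before a return
#' to baseline counts as the end of clonal contraction (otherwise the event
#' would fire trivially at t = 0).
#'
#' @param t_max Integration horizon (default 200 reduced-time units).
#' @param p_min Pathogen infectivity threshold (default 0.05, i.e. 5% of a
#'   unit initial load in reduced form).
#' @param peak_guard_eps Minimum T excursion above baseline before the
#'   contraction-end event is armed.
#' @param rel_tol,abs_tol Adaptive integrator tolerances.
#' @param dt_out Output sampling interval.
#' @return An object of class `sim_controls`.
#' @export
sim_controls <- function(t_max = 200, p_min = 0.05, peak_guard_eps = 1e-6,
                         rel_tol = 1e-8, abs_tol = 1e-10, dt_out = 0.01) {
  ctl <- list(t_max = .check_positive(t_max, "t_max"),
              p_min = .check_positive(p_min, "p_min"),
              peak_guard_eps = .check_positive(peak_guard_eps,
                                              "peak_guard_eps"),
              rel_tol = .check_positive(rel_tol, "rel_tol"),
              abs_tol = .check_positive(abs_tol, "abs_tol"),
              dt_out = .check_positive(dt_out, "dt_out"))
  structure(ctl, class = "sim_controls")
}

#' Right-hand side of the single-clone system
#'
#' First-order form of the model with the auxiliary variable `V = T'`:
#' returns `(dT/dt, dV/dt, dP/dt) = (V, -k T + lam P, alpha P - beta T P)`.
#' Pure function; state components may be any real numbers (domain
#' restrictions are the integrator's business, not the RHS's).
#'
#' @param state Numeric vector `(T, V, P)`.
#' @param params A [dim_params()] object.
#' @return Numeric vector of derivatives `(dT, dV, dP)`.
#' @export
#' @examples
#' rhs_single(c(T = 2, V = 0, P = 3), dim_params(1, 1, 1, 1))
rhs_single <- function(state, params) {
  stopifnot(inherits(params, "dim_params"), length(state) == 3L)
  Tt <- state[[1]]; V <- state[[2]]; P <- state[[3]]
  c(V,
    -params$k * Tt + params$lam * P,
    params$alpha * P - params$beta * Tt * P)
}

#' Right-hand side of the multi-clone system
#'
#' State is `(T_1, V_1, ..., T_n, V_n, P)`. Each clone obeys
#' `T_i'' = -k_i T_i + lam_i P`; the pathogen is cleared by all clones in
#' proportion to their abundances: `P' = alpha P - P sum(beta_i T_i)`.
#'
#' @param state Numeric vector of length `2 n + 1`.
#' @param clones Non-empty list of [clone_params()] objects.
#' @param alpha Pathogen growth rate (> 0).
#' @return Numeric vector of derivatives, same length as `state`.
#' @export
rhs_multi <- function(state, clones, alpha) {
  .check_clones(clones)
  n <- length(clones)
  if (length(state) != 2L * n + 1L)
    stop(sprintf("state must have length %d for %d clones", 2L * n + 1L, n),
         call. = FALSE)
  alpha <- .check_positive(alpha, "alpha")
  P <- state[[2L * n + 1L]]
  d <- numeric(2L * n + 1L)
  clearance <- 0
  for (i in seq_len(n)) {
    Ti <- state[[2L * i - 1L]]
    d[2L * i - 1L] <- state[[2L * i]]
    d[2L * i] <- -clones[[i]]$k * Ti + clones[[i]]$lam * P
    clearance <- clearance + clones[[i]]$beta * Ti
  }
  d[2L * n + 1L] <- alpha * P - clearance * P
  d
}

#' Non-dimensionalize the model
#'
#' Rescales time by the elastic frequency, `tau = sqrt(k) t`, and the state
#' by its natural scales, `x = T k / (lam P0)`, `y = P / P0`. The system
#' becomes `x'' = -x + y`, `y' = alpha_star y - beta_star x y` with
#' `y(0) = 1`, where
#' \deqn{\alpha^* = \alpha/\sqrt{k}, \qquad
#'       \beta^* = \beta \lambda P_0 / k^{3/2}.}
#' This is the unique two-parameter reduction that fixes `y(0) = 1` and
#' absorbs `k` and `lam` into the state scales; it reads `alpha_star` as the
#' pathogen growth rate relative to the elastic frequency of the clone.
#'
#' @param params A [dim_params()] object.
#' @param P0 Initial pathogen load used as the pathogen scale (> 0).
#' @return A [reduced_params()] object.
#' @export
#' @examples
#' to_reduced(dim_params(k = 4, lam = 1, alpha = 2, beta = 8), P0 = 1)
to_reduced <- function(params, P0 = 1) {
  stopifnot(inherits(params, "dim_params"))
  P0 <- .check_positive(P0, "P0")
  reduced_params(alpha_star = params$alpha / sqrt(params$k),
                 beta_star = params$beta * params$lam * P0 / params$k^1.5)
}

#' Embed reduced parameters back into dimensional form
#'
#' Canonical embedding `k = 1`, `lam = 1`, `P0 = 1`, so that
#' `alpha = alpha_star`, `beta = beta_star`, with the empty-pool initial
#' state `T0 = 0`, `dT0 = 0`. Exact round trip:
#' `to_reduced(from_reduced(rp)$params, 1)` equals `rp`.
#'
#' @param rp A [reduced_params()] object.
#' @return A list with components `params` ([dim_params()]) and
#'   `init` ([initial_state()]).
#' @export
from_reduced <- function(rp) {
  stopifnot(inherits(rp, "reduced_params"))
  list(params = dim_params(k = 1, lam = 1, alpha = rp$alpha_star,
                           beta = rp$beta_star),
       init = initial_state(T0 = 0, dT0 = 0, P0 = 1))
}

#' @export
print.dim_params <- function(x, ...) {
  cat(sprintf("Model parameters: k = %g, lam = %g, alpha = %g, beta = %g\n",
              x$k, x$lam, x$alpha, x$beta))
  invisible(x)
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf("Reduced parameters: alpha* = %g, beta* = %g\n",
              x$alpha_star, x$beta_star))
  invisible(x)
}
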