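#' @importFrom deSolve ode
NULL

.TCT_MAXN <- 64L

.pad_parms <- function(n, alpha, p_min, T_thresh, kk, lam, bb) {
  p <- numeric(4L + 3L * .TCT_MAXN)
  p[1:4] <- c(n, alpha, p_min, T_thresh)
  p[4L + seq_len(n)] <- kk
  p[4L + .TCT_MAXN + seq_len(n)] <- lam
  p[4L + 2L * .TCT_MAXN + seq_len(n)] <- bb
  p
}

.state_colnames <- function(labels) {
  if (length(labels) == 1L && labels == "T") {
    c("T", "dT", "P")
  } else {
    c(rbind(paste0("T_", labels), paste0("dT_", labels)), "P")
  }
}

.new_trajectory <- function(times, states, labels, events, params_echo) {
  colnames(states) <- .state_colnames(labels)
  structure(
    list(times = times, states = states, labels = labels,
         events = events, params_echo = params_echo),
    class = "tct_trajectory")
}

.total_T <- function(states, n) {
  if (n == 1L) states[, 1L] else rowSums(states[, 2L * seq_len(n) - 1L,
                                                drop = FALSE])
}

.event_record <- function(kind, time, state) {
  list(kind = kind, time = time, state = state)
}

# Runs lsodar over the compiled RHS, stopping at the first root.
# Returns list(times, states, root = NA / 1 (P crossed p_min) / 2 (total T
# crossed T_thresh), troot).
.lsodar_phase <- function(y0, times, parms, controls) {
  out <- deSolve::ode(
    y = y0, times = times, func = "tct_deriv_clones", parms = parms,
    dllname = "tcelltol", initfunc = "tct_init_clones",
    rootfunc = "tct_root_clones", nroot = 2L, method = "lsodar",
    rtol = controls$rel_tol, atol = controls$abs_tol)
  istate <- attr(out, "istate")[1L]
  if (!is.null(istate) && istate < 0)
    stop(sprintf(
      "integrator failure (istate = %d) with parms alpha = %g; %s",
      istate, parms[2L],
      "try looser tolerances or a smaller t_max"), call. = FALSE)
  iroot <- attr(out, "iroot")
  troot <- attr(out, "troot")
  root <- NA_integer_
  if (!is.null(iroot) && any(iroot != 0)) {
    which_root <- which(iroot != 0)
    # pathogen control takes priority when both roots fall in one step
    root <- if (1L %in% which_root) 1L else 2L
  }
  m <- as.matrix(unclass(out))
  list(times = m[, 1L], states = m[, -1L, drop = FALSE],
       root = root, troot = if (length(troot)) troot[1L] else NA_real_)
}

# Event-driven adaptive integration. The model describes the response from
# activation to the end of clonal contraction, so the first downward
# crossing of p_min (pathogen controlled) is recorded but not terminal:
# integration continues until total T returns to its baseline after the
# guarded excursion (contraction end) or until t_max. Implemented as a
# small state machine over lsodar phases; each phase's root thresholds
# encode which events are still being watched.
.integrate_core <- function(kk, lam, bb, alpha, y0, labels, controls,
                            params_echo) {
  n <- length(kk)
  if (n > .TCT_MAXN)
    stop(sprintf("at most %d clones are supported", .TCT_MAXN), call. = FALSE)
  T_idx <- 2L * seq_len(n) - 1L
  T0tot <- sum(y0[T_idx])
  P0 <- y0[2L * n + 1L]
  if (P0 <= controls$p_min)
    stop("initial pathogen load P0 must exceed the infectivity threshold p_min",
         call. = FALSE)

  grid <- seq(0, controls$t_max, by = controls$dt_out)
  if (grid[length(grid)] < controls$t_max)
    grid <- c(grid, controls$t_max)

  controlled <- FALSE
  armed <- T0tot + controls$peak_guard_eps < sum(y0[T_idx])  # FALSE at start
  events <- list()
  t_cur <- 0
  y_cur <- y0
  times <- numeric(0)
  states <- NULL

  for (phase in 1:6) {
    # armed and already at/below baseline: contraction ends right here
    if (armed && sum(y_cur[T_idx]) <= T0tot) {
      events <- c(events, list(.event_record("CONTRACTION_END", t_cur, y_cur)))
      break
    }
    tt <- c(t_cur, grid[grid > t_cur + 1e-12])
    if (length(tt) < 2L) {
      if (t_cur < controls$t_max) tt <- c(t_cur, controls$t_max)
      else {
        events <- c(events,
                    list(.event_record("HORIZON_REACHED", t_cur, y_cur)))
        break
      }
    }
    p_thr <- if (controlled) -1 else controls$p_min
    T_thr <- if (armed) T0tot else T0tot + controls$peak_guard_eps
    ph <- .lsodar_phase(y_cur, tt,
                        .pad_parms(n, alpha, p_thr, T_thr, kk, lam, bb),
                        controls)
    drop_first <- length(times) > 0L
    times <- c(times, if (drop_first) ph$times[-1L] else ph$times)
    states <- rbind(states,
                    if (drop_first) ph$states[-1L, , drop = FALSE]
                    else ph$states)
    t_cur <- times[length(times)]
    y_cur <- states[nrow(states), ]

    if (is.na(ph$root)) {
      events <- c(events, list(.event_record("HORIZON_REACHED", t_cur, y_cur)))
      break
    }
    if (ph$root == 1L) {
      controlled <- TRUE
      events <- c(events,
                  list(.event_record("PATHOGEN_CONTROLLED", t_cur, y_cur)))
    } else if (armed) {
      events <- c(events,
                  list(.event_record("CONTRACTION_END", t_cur, y_cur)))
      break
    } else {
      armed <- TRUE
    }
  }

  terminal <- c("CONTRACTION_END", "HORIZON_REACHED")
  if (length(events) == 0L ||
      !events[[length(events)]]$kind %in% terminal) {
    events <- c(events, list(.event_record("HORIZON_REACHED", t_cur, y_cur)))
  }
  .finish_trajectory(times, states, labels, events, params_echo)
}

.finish_trajectory <- function(times, states, labels, events, params_echo) {
  keep <- c(TRUE, diff(times) > 0)
  traj <- .new_trajectory(times[keep], states[keep, , drop = FALSE],
                          labels, events, params_echo)
  for (i in seq_along(traj$events))
    names(traj$events[[i]]$state) <- colnames(traj$states)
  traj
}

#' Simulate a single-clone immune response
#'
#' Integrates the coupled effector/pathogen system with adaptive step-size
#' control (lsodar) and two terminal event functions: a downward crossing of
#' the pathogen infectivity threshold `p_min` (pathogen controlled), and the
#' return of T to its baseline `T0` after an excursion above
#' `T0 + peak_guard_eps` (end of clonal contraction). Integration stops at
#' the first event or at `t_max`; the model is only meant to describe the
#' response up to the end of contraction, so no state is sampled beyond the
#' terminating event.
#'
#' Reduced parameters are integrated through the canonical embedding
#' `k = 1`, `lam = 1`, `P0 = 1` (see [from_reduced()]), under which the
#' dimensional trajectory *is* the reduced trajectory.
#'
#' @param params A [dim_params()] or [reduced_params()] object.
#' @param init An [initial_state()]; defaults to the empty effector pool.
#'   For reduced parameters the default is the canonical `y(0) = 1` state.
#' @param controls A [sim_controls()] object.
#' @return A `tct_trajectory`: sampled `times`, a `states` matrix with
#'   columns `T, dT, P`, the terminating event record in `events`, and an
#'   echo of parameters and controls in `params_echo`.
#' @seealso [classify_outcome()], [rk4_reference()]
#' @export
#' @examples
#' traj <- simulate_response(reduced_params(2, 1))
#' classify_outcome(traj)
simulate_response <- function(params, init = NULL, controls = sim_controls()) {
  stopifnot(inherits(controls, "sim_controls"))
  if (inherits(params, "reduced_params")) {
    emb <- from_reduced(params)
    dp <- emb$params
    if (is.null(init)) init <- emb$init
  } else if (inherits(params, "dim_params")) {
    dp <- params
    if (is.null(init)) init <- initial_state()
  } else {
    stop("'params' must be a dim_params or reduced_params object",
         call. = FALSE)
  }
  stopifnot(inherits(init, "initial_state"))
  y0 <- c(init$T0, init$dT0, init$P0)
  .integrate_core(dp$k, dp$lam, dp$beta, dp$alpha, y0, "T", controls,
                  list(params = params, init = init, controls = controls))
}

.clone_vectors <- function(clones) {
  list(labels = vapply(clones, `[[`, character(1), "label"),
       k = vapply(clones, `[[`, numeric(1), "k"),
       lam = vapply(clones, `[[`, numeric(1), "lam"),
       beta = vapply(clones, `[[`, numeric(1), "beta"))
}

.multi_y0 <- function(n, init) {
  if (is.null(init)) init <- list(T0 = 0, dT0 = 0, P0 = 1)
  T0 <- rep_len(init$T0, n)
  dT0 <- rep_len(init$dT0, n)
  P0 <- .check_positive(init$P0, "P0")
  if (any(T0 < 0)) stop("'T0' entries must be >= 0", call. = FALSE)
  c(rbind(T0, dT0), P0)
}

#' Simulate a multi-clone immune response
#'
#' As [simulate_response()], for several clones responding simultaneously to
#' one pathogen. The contraction-end event is defined on the *total*
#' effector population `sum(T_i)` returning to its baseline after the
#' guarded excursion; per-clone series are retained in the trajectory.
#'
#' @param clones Non-empty list of [clone_params()] with unique labels.
#' @param alpha Pathogen growth rate (> 0).
#' @param init `NULL` (empty pools, unit pathogen load) or a list with
#'   components `T0`, `dT0` (scalars or per-clone vectors) and `P0`.
#' @param controls A [sim_controls()] object.
#' @return A `tct_trajectory` with per-clone columns `T_<label>`,
#'   `dT_<label>` and the shared `P`.
#' @export
simulate_clones <- function(clones, alpha, init = NULL,
                            controls = sim_controls()) {
  labels <- .check_clones(clones)
  stopifnot(inherits(controls, "sim_controls"))
  alpha <- .check_positive(alpha, "alpha")
  cv <- .clone_vectors(clones)
  y0 <- .multi_y0(length(clones), init)
  .integrate_core(cv$k, cv$lam, cv$beta, alpha, y0, cv$labels, controls,
                  list(clones = clones, alpha = alpha, init = init,
                       controls = controls))
}

.rk4_core <- function(kk, lam, bb, alpha, y0, labels, controls, h,
                      params_echo) {
  n <- length(kk)
  T0tot <- sum(y0[2L * seq_len(n) - 1L])
  if (y0[2L * n + 1L] <= controls$p_min)
    stop("initial pathogen load P0 must exceed the infectivity threshold p_min",
         call. = FALSE)
  res <- .Call(C_rk4_run, as.numeric(y0), as.numeric(kk), as.numeric(lam),
               as.numeric(bb), as.numeric(alpha), as.numeric(h),
               as.numeric(controls$t_max), as.numeric(controls$p_min),
               as.numeric(T0tot), as.numeric(controls$peak_guard_eps),
               as.numeric(controls$dt_out))
  events <- list()
  if (!is.na(res$t_control))
    events <- c(events, list(.event_record("PATHOGEN_CONTROLLED",
                                           res$t_control,
                                           res$state_control)))
  if (!is.na(res$t_end)) {
    events <- c(events, list(.event_record("CONTRACTION_END", res$t_end,
                                           res$state_end)))
  } else {
    last <- length(res$times)
    events <- c(events, list(.event_record("HORIZON_REACHED",
                                           res$times[last],
                                           res$states[last, ])))
  }
  .finish_trajectory(res$times, res$states, labels, events, params_echo)
}

#' Fixed-step Runge-Kutta reference integrator
#'
#' Classical 4th-order Runge-Kutta at a fixed step `h`, with event crossings
#' located by sign change and linear interpolation inside the step. Fully
#' deterministic; serves as a brute-force cross-check of the adaptive
#' integrator, never as a replacement for it.
#'
#' @inheritParams simulate_response
#' @param h Fixed step size (> 0, at most `dt_out`).
#' @return A `tct_trajectory`.
#' @export
rk4_reference <- function(params, init = NULL, controls = sim_controls(),
                          h = 1e-4) {
  stopifnot(inherits(controls, "sim_controls"))
  h <- .check_positive(h, "h")
  if (h > controls$dt_out)
    stop("'h' must not exceed the output interval dt_out", call. = FALSE)
  if (inherits(params, "reduced_params")) {
    emb <- from_reduced(params)
    dp <- emb$params
    if (is.null(init)) init <- emb$init
  } else {
    stopifnot(inherits(params, "dim_params"))
    dp <- params
    if (is.null(init)) init <- initial_state()
  }
  y0 <- c(init$T0, init$dT0, init$P0)
  .rk4_core(dp$k, dp$lam, dp$beta, dp$alpha, y0, "T", controls, h,
            list(params = params, init = init, controls = controls, h = h))
}

#' @rdname rk4_reference
#' @inheritParams simulate_clones
#' @export
rk4_reference_clones <- function(clones, alpha, init = NULL,
                                 controls = sim_controls(), h = 1e-4) {
  labels <- .check_clones(clones)
  stopifnot(inherits(controls, "sim_controls"))
  h <- .check_positive(h, "h")
  if (h > controls$dt_out)
    stop("'h' must not exceed the output interval dt_out", call. = FALSE)
  cv <- .clone_vectors(clones)
  y0 <- .multi_y0(length(clones), init)
  .rk4_core(cv$k, cv$lam, cv$beta, alpha, y0, cv$labels, controls, h,
            list(clones = clones, alpha = alpha, init = init,
                 controls = controls, h = h))
}

#' Closed-form solution of the uncoupled (beta = 0) limit
#'
#' With clearance removed the pathogen grows exponentially,
#' `P(t) = P0 exp(alpha t)`, and the T equation becomes a forced harmonic
#' oscillator with the particular solution `C exp(alpha t)`,
#' `C = lam P0 / (alpha^2 + k)`:
#' \deqn{T(t) = (T_0 - C)\cos(\sqrt{k} t)
#'   + \frac{T_0' - C\alpha}{\sqrt{k}} \sin(\sqrt{k} t) + C e^{\alpha t}.}
#'
#' @param params A [dim_params()] with `beta = 0` exactly (anything else is
#'   a misuse of the analytic limit and an error).
#' @param init An [initial_state()].
#' @param times Numeric vector of evaluation times.
#' @return A list with numeric vectors `T` and `P` matching `times`.
#' @export
closed_form_uncoupled <- function(params, init, times) {
  stopifnot(inherits(params, "dim_params"), inherits(init, "initial_state"))
  if (params$beta != 0)
    stop("closed_form_uncoupled requires beta = 0 exactly", call. = FALSE)
  k <- params$k; lam <- params$lam; alpha <- params$alpha
  C <- lam * init$P0 / (alpha^2 + k)
  sk <- sqrt(k)
  Tt <- (init$T0 - C) * cos(sk * times) +
    ((init$dT0 - C * alpha) / sk) * sin(sk * times) +
    C * exp(alpha * times)
  list(T = Tt, P = init$P0 * exp(alpha * times))
}

#' Classify the outcome of a simulated response
#'
#' Maps a trajectory's terminating event to one of three labels:
#' `ELIMINATION` if the pathogen fell below its infectivity threshold before
#' the end of clonal contraction; `TOLERANCE` if the effector population
#' returned to baseline (contraction ended) while residual pathogen remained
#' above the threshold — tolerance by early contraction; `UNRESOLVED` if the
#' integration horizon was reached with neither event.
#'
#' @param traj A `tct_trajectory` from [simulate_response()],
#'   [simulate_clones()] or the RK4 reference.
#' @param controls The [sim_controls()] used to produce the trajectory;
#'   defaults to the controls echoed in the trajectory itself.
#' @return An object of class `tct_outcome` with fields `label`,
#'   `t_control`, `t_contraction_end`, `peak_T`, `t_peak_T` and
#'   `residual_P` (peak statistics are for the total effector population).
#' @export
classify_outcome <- function(traj, controls = NULL) {
  stopifnot(inherits(traj, "tct_trajectory"))
  if (is.null(controls)) controls <- traj$params_echo$controls
  stopifnot(inherits(controls, "sim_controls"))
  if (length(traj$events) == 0L)
    stop("trajectory carries no terminating event record: corrupted input",
         call. = FALSE)
  kinds <- vapply(traj$events, `[[`, character(1), "kind")
  terminal <- kinds[length(kinds)]
  if (!terminal %in% c("CONTRACTION_END", "HORIZON_REACHED"))
    stop("trajectory has no terminating event record: corrupted input",
         call. = FALSE)
  ic <- match("PATHOGEN_CONTROLLED", kinds)
  t_control <- if (is.na(ic)) NA_real_ else traj$events[[ic]]$time
  t_cend <- if (terminal == "CONTRACTION_END")
    traj$events[[length(kinds)]]$time else NA_real_

  n <- length(traj$labels)
  totT <- .total_T(traj$states, n)
  ip <- which.max(totT)
  last <- nrow(traj$states)
  residual_P <- traj$states[last, ncol(traj$states)]
  label <- if (!is.na(t_control)) "ELIMINATION"
           else if (!is.na(t_cend)) "TOLERANCE"
           else "UNRESOLVED"
  structure(
    list(label = label,
         t_control = t_control,
         t_contraction_end = t_cend,
         peak_T = totT[ip],
         t_peak_T = traj$times[ip],
         residual_P = residual_P),
    class = "tct_outcome")
}

#' @export
print.tct_outcome <- function(x, ...) {
  cat(sprintf("Outcome: %s\n", x$label))
  if (!is.na(x$t_control))
    cat(sprintf("  pathogen controlled at t = %.4f\n", x$t_control))
  if (!is.na(x$t_contraction_end))
    cat(sprintf("  contraction ended at t = %.4f\n", x$t_contraction_end))
  cat(sprintf("  peak T = %.4f at t = %.4f; residual P = %.4g\n",
              x$peak_T, x$t_peak_T, x$residual_P))
  invisible(x)
}

#' @export
print.tct_trajectory <- function(x, ...) {
  ev <- x$events[[length(x$events)]]
  cat(sprintf(
    "Trajectory: %d samples on [0, %.4f], %d state column(s); final event %s\n",
    length(x$times), x$times[length(x$times)], ncol(x$states), ev$kind))
  invisible(x)
}

#' @export
as.data.frame.tct_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}
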