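.classify_reduced <- function(alpha_star, beta_star, controls) {
  classify_outcome(
    simulate_response(reduced_params(alpha_star, beta_star),
                      controls = controls),
    controls)
}

#' Tolerance/elimination phase diagram in the reduced parameter plane
#'
#' Integrates the reduced system from the canonical initial state
#' (`x = x' = 0`, `y = 1`) at every point of an `(alpha*, beta*)` grid and
#' records the outcome label. Tolerance by early contraction concentrates at
#' low `alpha*`: slow-growing targets exert too weak an antigenic force to
#' outbalance the elastic pull, so the clone contracts before control.
#' Cells where the integrator fails are recorded as `UNRESOLVED` with a
#' warning; the sweep never aborts.
#'
#' @param alpha_star_values,beta_star_values Strictly increasing positive
#'   grids for the two reduced parameters.
#' @param controls A [sim_controls()] object.
#' @return An `outcome_grid`: the two axes, a `labels` character matrix of
#'   shape `(length(beta_star_values), length(alpha_star_values))`, matching
#'   numeric matrices `t_control`, `t_contraction_end`, `peak_T`,
#'   `residual_P`, and `controls_echo`. Convert with `as.data.frame()` for
#'   the long tabular form.
#' @export
#' @examples
#' pg <- phase_diagram(c(0.2, 1, 2), c(0.5, 1), sim_controls(t_max = 100))
#' pg$labels
phase_diagram <- function(alpha_star_values, beta_star_values,
                          controls = sim_controls()) {
  .check_axis <- function(x, name) {
    if (!is.numeric(x) || length(x) == 0L || any(x <= 0) ||
        any(diff(x) <= 0))
      stop(sprintf("'%s' must be a non-empty strictly increasing positive vector",
                   name), call. = FALSE)
    as.numeric(x)
  }
  av <- .check_axis(alpha_star_values, "alpha_star_values")
  bv <- .check_axis(beta_star_values, "beta_star_values")
  shape <- c(length(bv), length(av))
  labels <- matrix(NA_character_, shape[1], shape[2],
                   dimnames = list(format(bv), format(av)))
  t_control <- t_cend <- peak <- resid <- matrix(NA_real_, shape[1], shape[2])
  for (j in seq_along(av)) {
    for (i in seq_along(bv)) {
      oc <- tryCatch(.classify_reduced(av[j], bv[i], controls),
                     error = function(e) {
                       warning(sprintf(
                         "cell (alpha* = %g, beta* = %g) failed: %s",
                         av[j], bv[i], conditionMessage(e)), call. = FALSE)
                       NULL
                     })
      if (is.null(oc)) {
        labels[i, j] <- "UNRESOLVED"
      } else {
        labels[i, j] <- oc$label
        t_control[i, j] <- oc$t_control
        t_cend[i, j] <- oc$t_contraction_end
        peak[i, j] <- oc$peak_T
        resid[i, j] <- oc$residual_P
      }
    }
  }
  structure(
    list(alpha_star_values = av, beta_star_values = bv, labels = labels,
         t_control = t_control, t_contraction_end = t_cend, peak_T = peak,
         residual_P = resid, controls_echo = controls),
    class = "outcome_grid")
}

#' @export
as.data.frame.outcome_grid <- function(x, ...) {
  grid <- expand.grid(beta_star = x$beta_star_values,
                      alpha_star = x$alpha_star_values,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(alpha_star = grid$alpha_star, beta_star = grid$beta_star,
             label = as.vector(x$labels),
             t_control = as.vector(x$t_control),
             t_contraction_end = as.vector(x$t_contraction_end),
             peak_T = as.vector(x$peak_T),
             residual_P = as.vector(x$residual_P))
}

#' @export
print.outcome_grid <- function(x, ...) {
  tab <- table(factor(x$labels,
                      levels = c("TOLERANCE", "ELIMINATION", "UNRESOLVED")))
  cat(sprintf("Outcome grid: %d x %d cells (beta* x alpha*)\n",
              nrow(x$labels), ncol(x$labels)))
  print(tab)
  invisible(x)
}

.alpha_classifier <- function(fixed, controls) {
  if (inherits(fixed, "reduced_params") ||
      (is.list(fixed) && !is.null(fixed$beta_star))) {
    beta_star <- .check_positive(fixed$beta_star, "beta_star")
    function(alpha) .classify_reduced(alpha, beta_star, controls)$label
  } else if (is.list(fixed) && !is.null(fixed$k)) {
    k <- .check_positive(fixed$k, "k")
    lam <- .check_positive(fixed$lam, "lam")
    beta <- .check_positive(fixed$beta, "beta")
    init <- if (!is.null(fixed$init)) fixed$init else initial_state()
    function(alpha) {
      classify_outcome(
        simulate_response(dim_params(k, lam, alpha, beta), init, controls),
        controls)$label
    }
  } else {
    stop("'fixed' must supply either beta_star (reduced) or k, lam, beta (dimensional)",
         call. = FALSE)
  }
}

#' Critical pathogen growth rate by bisection
#'
#' For a fixed clone, the phase diagram predicts a growth-rate threshold:
#' growth rates below it are tolerated by early contraction, rates above it
#' provoke elimination. `critical_alpha` locates that threshold by bisection
#' on the outcome label. The bracket must straddle the transition:
#' `TOLERANCE` at `bracket[1]` and `ELIMINATION` at `bracket[2]`.
#'
#' @param fixed Either a list with `beta_star` (reduced form) or a list with
#'   `k`, `lam`, `beta` and optionally `init` (dimensional form); everything
#'   but the growth rate.
#' @param bracket Length-2 increasing positive vector `(alpha_lo, alpha_hi)`.
#' @param tol Bisection tolerance on alpha (default 1e-4).
#' @param controls A [sim_controls()] object.
#' @return The critical growth rate (bracket midpoint at convergence), with
#'   attributes `bracket` (the final bracket) and `tol`.
#' @export
#' @examples
#' \donttest{
#' critical_alpha(list(beta_star = 1), bracket = c(0.1, 2))
#' }
critical_alpha <- function(fixed, bracket, tol = 1e-4,
                           controls = sim_controls()) {
  if (!is.numeric(bracket) || length(bracket) != 2L || any(bracket <= 0) ||
      bracket[1] >= bracket[2])
    stop("'bracket' must be an increasing positive pair (alpha_lo, alpha_hi)",
         call. = FALSE)
  tol <- .check_positive(tol, "tol")
  lab_at <- .alpha_classifier(fixed, controls)
  lo <- bracket[1]; hi <- bracket[2]
  lab_lo <- lab_at(lo); lab_hi <- lab_at(hi)
  if (lab_lo == "UNRESOLVED" || lab_hi == "UNRESOLVED")
    stop("bracket endpoint is UNRESOLVED; increase t_max", call. = FALSE)
  if (lab_lo != "TOLERANCE" || lab_hi != "ELIMINATION")
    stop(sprintf(
      "invalid bracket: alpha_lo = %g is %s, alpha_hi = %g is %s (need TOLERANCE then ELIMINATION)",
      lo, lab_lo, hi, lab_hi), call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    lab <- lab_at(mid)
    if (lab == "TOLERANCE") lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi), tol = tol)
}

#' Growth-rate threshold as a function of antigenic affinity
#'
#' Sweeps the antigenic coefficient `lam` (the TCR/epitope affinity proxy)
#' and computes the critical growth rate for each value. High-affinity
#' clones eliminate targets at every growth rate tested; those sweep entries
#' are explicitly marked undefined rather than given placeholder values.
#' The bracket is automatically widened downward as affinity grows, since
#' the threshold falls with affinity.
#'
#' @param lam_values Strictly increasing positive affinity sweep.
#' @param k,beta,P0 Remaining dimensional clone parameters.
#' @param controls A [sim_controls()] object.
#' @param bracket Initial `(alpha_lo, alpha_hi)` bracket, valid for at least
#'   the first sweep entry.
#' @param tol Bisection tolerance.
#' @param alpha_floor Smallest growth rate tried when widening the bracket
#'   downward; below it the entry is marked undefined.
#' @return A `threshold_curve`: `sweep_values`, `critical_alpha` (NA where
#'   undefined), logical `defined`, and `bracket_echo`.
#' @export
threshold_vs_affinity <- function(lam_values, k = 1, beta = 1, P0 = 1,
                                  controls = sim_controls(),
                                  bracket = c(0.01, 3), tol = 1e-4,
                                  alpha_floor = 1e-4) {
  if (!is.numeric(lam_values) || length(lam_values) == 0L ||
      any(lam_values <= 0) || any(diff(lam_values) <= 0))
    stop("'lam_values' must be strictly increasing and positive",
         call. = FALSE)
  crit <- rep(NA_real_, length(lam_values))
  defined <- rep(FALSE, length(lam_values))
  lo <- bracket[1]; hi <- bracket[2]
  for (i in seq_along(lam_values)) {
    fixed <- list(k = k, lam = lam_values[i], beta = beta,
                  init = initial_state(P0 = P0))
    lab_at <- .alpha_classifier(fixed, controls)
    lo_i <- lo
    # widen downward until the low endpoint is tolerated (or give up)
    while (lab_at(lo_i) != "TOLERANCE" && lo_i > alpha_floor) lo_i <- lo_i / 2
    if (lab_at(lo_i) == "TOLERANCE" && lab_at(hi) == "ELIMINATION") {
      crit[i] <- as.numeric(
        critical_alpha(fixed, c(lo_i, hi), tol = tol, controls = controls))
      defined[i] <- TRUE
      lo <- lo_i
    }
  }
  structure(
    list(sweep_values = as.numeric(lam_values), critical_alpha = crit,
         defined = defined,
         bracket_echo = list(bracket = bracket, tol = tol,
                             alpha_floor = alpha_floor)),
    class = "threshold_curve")
}

#' @export
as.data.frame.threshold_curve <- function(x, ...) {
  data.frame(sweep_value = x$sweep_values, critical_alpha = x$critical_alpha,
             defined = x$defined)
}

.peak_table <- function(traj) {
  n <- length(traj$labels)
  idx <- 2L * seq_len(n) - 1L
  peaks <- vapply(idx, function(jc) max(traj$states[, jc]), numeric(1))
  t_peaks <- vapply(idx, function(jc) traj$times[which.max(traj$states[, jc])],
                    numeric(1))
  data.frame(label = traj$labels, peak_T = peaks, t_peak = t_peaks,
             stringsAsFactors = FALSE)
}

#' Immunodominance experiment
#'
#' Simulates several clones responding simultaneously to one pathogen and
#' tabulates each clone's peak expansion. The model predicts that clones
#' with higher antigenic affinity (`lam`) expand more — immunodominance —
#' when all other per-clone parameters are equal.
#'
#' @inheritParams simulate_clones
#' @return A list with `peaks` (data frame `label`, `peak_T`, `t_peak`,
#'   ordered as the input clones), `dominance_order` (labels sorted by
#'   decreasing peak), `outcome` and the `trajectory`.
#' @export
immunodominance_experiment <- function(clones, alpha, init = NULL,
                                       controls = sim_controls()) {
  if (length(clones) < 2L)
    stop("immunodominance requires at least 2 clones", call. = FALSE)
  traj <- simulate_clones(clones, alpha, init, controls)
  peaks <- .peak_table(traj)
  list(peaks = peaks,
       dominance_order = peaks$label[order(-peaks$peak_T)],
       outcome = classify_outcome(traj, controls),
       trajectory = traj)
}

#' Compensatory expansion experiment
#'
#' Runs the multi-clone system twice under identical controls: once with all
#' clones and once with one clone removed. If the removed clone was
#' immunodominant, the model predicts the surviving (subdominant) clones
#' expand more in its absence — compensatory expansion — and can still
#' control the infection.
#'
#' @inheritParams simulate_clones
#' @param removed_label Label of the clone to deplete; must be present, and
#'   at least two clones are required.
#' @return A list with `full` and `depleted` sublists (each `peaks` +
#'   `outcome`), and `comparison`: per surviving clone, the peak in both
#'   runs and the ratio depleted/full.
#' @export
compensation_experiment <- function(clones, removed_label, alpha,
                                    init = NULL, controls = sim_controls()) {
  labels <- .check_clones(clones)
  if (length(clones) < 2L)
    stop("compensation requires at least 2 clones", call. = FALSE)
  if (!removed_label %in% labels)
    stop(sprintf("unknown clone label '%s'", removed_label), call. = FALSE)
  keep <- labels != removed_label
  full <- simulate_clones(clones, alpha, init, controls)
  sub_init <- init
  if (!is.null(init)) {
    n <- length(clones)
    sub_init$T0 <- rep_len(init$T0, n)[keep]
    sub_init$dT0 <- rep_len(init$dT0, n)[keep]
  }
  depleted <- simulate_clones(clones[keep], alpha, sub_init, controls)
  pf <- .peak_table(full)
  pd <- .peak_table(depleted)
  surv <- pf[keep, , drop = FALSE]
  comparison <- data.frame(
    label = pd$label,
    peak_full = surv$peak_T[match(pd$label, surv$label)],
    peak_depleted = pd$peak_T,
    stringsAsFactors = FALSE)
  comparison$ratio <- comparison$peak_depleted / comparison$peak_full
  list(full = list(peaks = pf, outcome = classify_outcome(full, controls)),
       depleted = list(peaks = pd,
                       outcome = classify_outcome(depleted, controls)),
       comparison = comparison)
}

#' Acute versus tolerated response of one clone
#'
#' Simulates the same clone against two target populations that differ only
#' in growth rate, one below and one above the clone's critical growth rate.
#' The model predicts the eliminated fast-growing target provokes the
#' *larger* clonal expansion — tolerance of the slow grower is not a limit
#' on expansion capacity. The function reports both outcomes and peak sizes;
#' it asserts nothing itself.
#'
#' @param fixed As in [critical_alpha()]: the clone with the growth rate
#'   left free.
#' @param alpha_lo Growth rate expected to be tolerated.
#' @param alpha_hi Growth rate expected to be eliminated.
#' @param controls A [sim_controls()] object.
#' @return A list with `tolerated` and `acute` outcome objects, `peak_lo`,
#'   `peak_hi` and `peak_ratio` (`peak_hi / peak_lo`).
#' @export
acute_vs_tolerated <- function(fixed, alpha_lo, alpha_hi,
                               controls = sim_controls()) {
  alpha_lo <- .check_positive(alpha_lo, "alpha_lo")
  alpha_hi <- .check_positive(alpha_hi, "alpha_hi")
  if (alpha_lo >= alpha_hi)
    stop("'alpha_lo' must be strictly below 'alpha_hi'", call. = FALSE)
  run_at <- function(alpha) {
    if (!is.null(fixed$beta_star)) {
      classify_outcome(simulate_response(
        reduced_params(alpha, fixed$beta_star), controls = controls),
        controls)
    } else {
      init <- if (!is.null(fixed$init)) fixed$init else initial_state()
      classify_outcome(simulate_response(
        dim_params(fixed$k, fixed$lam, alpha, fixed$beta), init, controls),
        controls)
    }
  }
  oc_lo <- run_at(alpha_lo)
  oc_hi <- run_at(alpha_hi)
  if (oc_lo$label != "TOLERANCE" || oc_hi$label != "ELIMINATION")
    stop(sprintf(
      "alphas do not straddle the threshold: alpha_lo = %g is %s, alpha_hi = %g is %s",
      alpha_lo, oc_lo$label, alpha_hi, oc_hi$label), call. = FALSE)
  list(tolerated = oc_lo, acute = oc_hi,
       peak_lo = oc_lo$peak_T, peak_hi = oc_hi$peak_T,
       peak_ratio = oc_hi$peak_T / oc_lo$peak_T)
}
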