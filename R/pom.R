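## Constrained performance-planning optimizer: a trade-off objective
## J(u) = -P(u) + beta * R(u) minimized by projected gradient descent under
## box and step-smoothness constraints, plus the squared-hinge constraint
## penalties and the generic value-refinement utility.
##
## This module is a conceptual extension of the imaging pipeline: it is fully
## specified and reproducible but not empirically validated on benchmark
## data (no public dataset provides controllable action variables).

#' Define a performance-optimization objective
#'
#' @param P performance function of the action vector `u` (maximized).
#' @param R injury-risk function of `u` (minimized); defaults to 0.
#' @param beta trade-off weight on the risk term (> 0).
#' @param eta gradient step size (> 0).
#' @param iterations iteration budget.
#' @param tol stop when the successive objective change falls below this.
#' @param gradP,gradR optional analytic gradients; central finite differences
#'   are used when omitted.
#' @return list of class `PomObjective`.
#' @export
pomObjective <- function(P, R = NULL, beta = 1, eta = 0.1, iterations = 500L,
                         tol = 0, gradP = NULL, gradR = NULL) {
  if (beta <= 0) stop("pomObjective: beta must be > 0")
  if (eta <= 0) stop("pomObjective: eta must be > 0")
  structure(list(P = P, R = R, beta = beta, eta = eta,
                 iterations = as.integer(iterations), tol = tol,
                 gradP = gradP, gradR = gradR), class = "PomObjective")
}

#' Constraint set for the planning optimizer
#'
#' @param lower,upper elementwise box bounds (recycled to the action length).
#' @param delta smoothness budget: maximum Euclidean step per iterate
#'   (`Inf` disables).
#' @return list of class `ConstraintSet`.
#' @export
constraintSet <- function(lower = -Inf, upper = Inf, delta = Inf) {
  if (delta < 0) stop("constraintSet: delta must be >= 0")
  if (any(lower > upper))
    stop("constraintSet: lower bound exceeds upper bound")
  structure(list(lower = lower, upper = upper, delta = delta),
            class = "ConstraintSet")
}

#' Evaluate the trade-off objective
#'
#' `J(u) = -P(u) + beta * R(u)`.
#'
#' @param u action vector.
#' @param obj a [pomObjective()].
#' @return scalar J.
#' @export
objectiveJ <- function(u, obj) {
  J <- -obj$P(u) + if (is.null(obj$R)) 0 else obj$beta * obj$R(u)
  if (!is.finite(J))
    stop("objectiveJ: non-finite objective at u = (",
         paste(signif(u, 4), collapse = ", "), ")")
  J
}

#' Project onto a box
#'
#' Elementwise clamp to `[lower, upper]`; idempotent, identity on the
#' feasible set.
#'
#' @param u action vector.
#' @param lower,upper bounds (recycled).
#' @return clamped vector.
#' @export
projectBox <- function(u, lower, upper) pmin(pmax(u, lower), upper)

#' Project onto the smoothness ball
#'
#' Returns `u` when the step from `u_prev` is within the budget, otherwise
#' scales the step back to Euclidean length exactly `delta`.
#'
#' @param u proposed point.
#' @param u_prev previous iterate.
#' @param delta step budget (>= 0).
#' @return projected point.
#' @export
projectSmoothness <- function(u, u_prev, delta) {
  if (delta < 0) stop("projectSmoothness: delta must be >= 0")
  d <- u - u_prev
  nrm <- sqrt(sum(d^2))
  if (nrm <= delta) u else u_prev + delta * d / nrm
}

numGradient <- function(f, u, h = 1e-6) {
  g <- numeric(length(u))
  for (i in seq_along(u)) {
    hp <- h * max(1, abs(u[i]))
    up <- u; up[i] <- up[i] + hp
    um <- u; um[i] <- um[i] - hp
    g[i] <- (f(up) - f(um)) / (2 * hp)
  }
  g
}

objectiveGradient <- function(u, obj) {
  gP <- if (!is.null(obj$gradP)) obj$gradP(u) else numGradient(obj$P, u)
  g <- -gP
  if (!is.null(obj$R))
    g <- g + obj$beta *
      (if (!is.null(obj$gradR)) obj$gradR(u) else numGradient(obj$R, u))
  g
}

#' Projected gradient descent
#'
#' Iterates `u <- project(u - eta * grad J(u))`, with the box projection
#' applied first and the smoothness projection (relative to the previous
#' iterate) second, until the iteration budget is exhausted or the successive
#' objective change drops below the tolerance. Optional backtracking halves
#' the step when the objective increases.
#'
#' @param obj a [pomObjective()].
#' @param constraints a [constraintSet()].
#' @param u0 finite starting point.
#' @param backtrack halve the step on objective increase?
#' @return list of class `PomSolution`: `u` (final iterate), `J` (final
#'   objective), `trace` (data.frame iteration/J/feasible), `converged`,
#'   `iterations`.
#' @export
pgdSolve <- function(obj, constraints, u0, backtrack = FALSE) {
  if (!all(is.finite(u0))) stop("pgdSolve: u0 must be finite")
  u <- projectBox(u0, constraints$lower, constraints$upper)
  J <- objectiveJ(u, obj)
  trace <- data.frame(iteration = 0L, J = J, feasible = TRUE)
  converged <- FALSE
  it <- 0L
  while (it < obj$iterations) {
    it <- it + 1L
    g <- objectiveGradient(u, obj)
    if (!all(is.finite(g)))
      stop("pgdSolve: non-finite gradient at iteration ", it)
    eta <- obj$eta
    repeat {
      cand <- projectBox(u - eta * g, constraints$lower, constraints$upper)
      if (is.finite(constraints$delta))
        cand <- projectSmoothness(cand, u, constraints$delta)
      Jc <- objectiveJ(cand, obj)
      if (!backtrack || Jc <= J || eta < 1e-12) break
      eta <- eta / 2
    }
    if (!is.finite(Jc)) stop("pgdSolve: objective diverged at iteration ", it)
    feas <- all(cand >= constraints$lower - 1e-12) &&
      all(cand <= constraints$upper + 1e-12)
    trace <- rbind(trace, data.frame(iteration = it, J = Jc, feasible = feas))
    done <- abs(Jc - J) < obj$tol
    u <- cand
    J <- Jc
    if (done) { converged <- TRUE; break }
  }
  structure(list(u = u, J = J, trace = trace, converged = converged,
                 iterations = it), class = "PomSolution")
}

#' Squared-hinge constraint penalty
#'
#' `sum(max(0, c_i)^2)`: zero exactly when every constraint value is
#' feasible (`c_i <= 0`).
#'
#' @param values constraint values `c_1..c_J`.
#' @return nonnegative scalar.
#' @export
constraintPenalty <- function(values) sum(pmax(0, values)^2)

#' Joint-torque constraint value
#'
#' Returns `tau - tau_max`, the signed violation fed to
#' [constraintPenalty()].
#'
#' @param tau predicted joint torque(s).
#' @param tau_max physiological limit.
#' @return constraint value(s).
#' @export
torqueViolation <- function(tau, tau_max) tau - tau_max

#' Bilateral force-symmetry loss
#'
#' Squared Euclidean distance between left- and right-limb force vectors.
#'
#' @param F_left,F_right equal-length force vectors.
#' @return nonnegative scalar.
#' @export
symmetryLoss <- function(F_left, F_right) {
  if (length(F_left) != length(F_right))
    stop("symmetryLoss: force vectors must have equal length")
  sum((F_left - F_right)^2)
}

#' Weighted total training objective
#'
#' `L_total = L_risk + lambda * L_performance + mu * L_constraints`.
#'
#' @param L_risk,L_performance,L_constraints component losses.
#' @param lambda,mu nonnegative weights.
#' @return scalar.
#' @export
totalLoss <- function(L_risk, L_performance, L_constraints, lambda, mu) {
  if (lambda < 0 || mu < 0) stop("totalLoss: lambda and mu must be >= 0")
  L_risk + lambda * L_performance + mu * L_constraints
}

#' Iterative value refinement
#'
#' Plain gradient descent applied directly to prediction values:
#' `value <- value - eta * grad(value)` for a fixed number of steps.
#'
#' @param values numeric start values.
#' @param gradFn function returning the gradient of the loss at the values.
#' @param eta learning rate (> 0).
#' @param steps number of updates.
#' @return refined values.
#' @export
iterativeRefine <- function(values, gradFn, eta, steps) {
  if (eta <= 0) stop("iterativeRefine: eta must be > 0")
  for (i in seq_len(steps)) {
    g <- gradFn(values)
    if (!all(is.finite(g)))
      stop("iterativeRefine: non-finite gradient at step ", i)
    values <- values - eta * g
  }
  values
}
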