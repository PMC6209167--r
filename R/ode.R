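#' Well-mixed ODE systems for producer / non-producer / sensitive dynamics
#'
#' Two mean-field three-species systems are provided. The bacteriostatic
#' system, in which the antibiotic reduces the sensitive birth rate via its
#' quasi-steady-state concentration `A = a*P/b`:
#' \deqn{dP/dt = (r_1 - a c) P (1 - T) - P}
#' \deqn{dN/dt = r_1 N (1 - T) - N}
#' \deqn{dS/dt = (r_2 - a P / b) S (1 - T) - S}
#' with `T = P + N + S`, and the classical bactericidal colicin system in
#' which the toxin adds a kill term `-sigma*P*S` to the sensitive equation:
#' \deqn{dS/dt = r_S S (1 - T) - S - \sigma P S.}
#' Both assume a death rate of 1 (one time unit = mean cell lifetime).
#'
#' @param state numeric vector `c(P, N, S)` of densities (>= 0).
#' @param params an [model_params()] object (`r1`, `r2`, `b`, `c` are used).
#' @param a antibiotic production rate of the producer strain.
#' @return the derivative `c(P, N, S)`.
#' @examples
#' rhs_bacteriostatic(c(0.05, 0.05, 0.05), model_params(), a = 110)
#' @export
rhs_bacteriostatic <- function(state, params, a) {
  P <- state[[1]]; N <- state[[2]]; S <- state[[3]]
  T <- P + N + S
  c((params$r1 - a * params$c) * P * (1 - T) - P,
    params$r1 * N * (1 - T) - N,
    (params$r2 - a * P / params$b) * S * (1 - T) - S)
}

#' Parameters of the colicin (bactericidal) ODE system
#'
#' The rock-paper-scissors regime requires `rP < rN < rS`.
#'
#' @param rP,rN,rS growth rates of producer, non-producer and sensitive.
#' @param sigma colicin kill coefficient (`>= 0`).
#' @export
colicin_params <- function(rP, rN, rS, sigma) {
  stopifnot(is.finite(rP), is.finite(rN), is.finite(rS),
            is.finite(sigma), sigma >= 0)
  if (!(rP < rN && rN < rS))
    warning("colicin model expects rP < rN < rS for the rock-paper-scissors regime")
  structure(list(rP = rP, rN = rN, rS = rS, sigma = sigma),
            class = "abx_colicin_params")
}

#' @rdname rhs_bacteriostatic
#' @param cparams a [colicin_params()] object.
#' @export
rhs_colicin <- function(state, cparams) {
  P <- state[[1]]; N <- state[[2]]; S <- state[[3]]
  T <- P + N + S
  c(cparams$rP * P * (1 - T) - P,
    cparams$rN * N * (1 - T) - N,
    cparams$rS * S * (1 - T) - S - cparams$sigma * P * S)
}

# Adaptive Dormand-Prince RK5(4). Small and self-contained; the systems
# integrated here are 3-dimensional and non-stiff, but trajectories pass
# slowly near the axes, hence the tight default tolerances. Densities are
# clipped at 0 after every accepted step (solver undershoot is unphysical).
.dopri5_step <- function(f, t, y, h, k1) {
  a21 <- 1/5
  a31 <- 3/40;        a32 <- 9/40
  a41 <- 44/45;       a42 <- -56/15;      a43 <- 32/9
  a51 <- 19372/6561;  a52 <- -25360/2187; a53 <- 64448/6561;  a54 <- -212/729
  a61 <- 9017/3168;   a62 <- -355/33;     a63 <- 46732/5247;  a64 <- 49/176
  a65 <- -5103/18656
  b1 <- 35/384; b3 <- 500/1113; b4 <- 125/192; b5 <- -2187/6784; b6 <- 11/84
  e1 <- 71/57600; e3 <- -71/16695; e4 <- 71/1920; e5 <- -17253/339200
  e6 <- 22/525; e7 <- -1/40
  k2 <- f(t + h/5,     y + h * a21 * k1)
  k3 <- f(t + 3*h/10,  y + h * (a31*k1 + a32*k2))
  k4 <- f(t + 4*h/5,   y + h * (a41*k1 + a42*k2 + a43*k3))
  k5 <- f(t + 8*h/9,   y + h * (a51*k1 + a52*k2 + a53*k3 + a54*k4))
  k6 <- f(t + h,       y + h * (a61*k1 + a62*k2 + a63*k3 + a64*k4 + a65*k5))
  ynew <- y + h * (b1*k1 + b3*k3 + b4*k4 + b5*k5 + b6*k6)
  k7 <- f(t + h, ynew)
  err <- h * (e1*k1 + e3*k3 + e4*k4 + e5*k5 + e6*k6 + e7*k7)
  list(y = ynew, err = err, k7 = k7)
}

.dopri5 <- function(f, y, t0, t1, rtol, atol, h0 = NULL) {
  t <- t0
  h <- if (is.null(h0)) min(0.1, (t1 - t0) / 10) else min(h0, t1 - t0)
  k1 <- f(t, y)
  n_reject <- 0L
  while (t < t1) {
    h <- min(h, t1 - t)
    st <- .dopri5_step(f, t, y, h, k1)
    sc <- atol + rtol * pmax(abs(y), abs(st$y))
    errnorm <- sqrt(mean((st$err / sc)^2))
    if (is.finite(errnorm) && errnorm <= 1) {
      t <- t + h
      y <- pmax(st$y, 0)      # negative-density guard
      k1 <- if (any(st$y < 0)) f(t, y) else st$k7   # FSAL unless clipped
      h <- h * min(5, max(0.2, 0.9 * errnorm^-0.2))
    } else {
      n_reject <- n_reject + 1L
      if (n_reject > 10000L || h < 1e-14)
        stop("integration error: step size underflow at t = ", t, call. = FALSE)
      h <- h * max(0.1, 0.9 * if (is.finite(errnorm)) errnorm^-0.2 else 0.1)
    }
  }
  list(y = y, h = h)
}

#' Integrate a three-species ODE system
#'
#' Adaptive Dormand-Prince RK5(4) integration of [rhs_bacteriostatic()] or
#' [rhs_colicin()], with densities clipped at 0 after each accepted step.
#'
#' @param system `"bacteriostatic"` or `"colicin"`, or any function
#'   `f(state)` returning the derivative.
#' @param init numeric `c(P, N, S)` initial state, all `>= 0`.
#' @param t_end final time (`> 0`).
#' @param params an [model_params()] object (bacteriostatic) or a
#'   [colicin_params()] object (colicin); ignored when `system` is a
#'   function.
#' @param a production rate (bacteriostatic system only).
#' @param n_out number of output samples (equally spaced in time).
#' @param rtol,atol relative and absolute solver tolerances. The defaults
#'   are tight enough that the residual at an attracting fixed point falls
#'   below the `1e-9` convergence declaration of
#'   [classify_ode_outcome()]; a looser `rtol` leaves a fixed-point bias
#'   of the same order as that threshold.
#' @return an object of class `abx_ode_trajectory`: a list with `times`,
#'   `states` (matrix with columns P, N, S) and the rhs function used.
#' @examples
#' tr <- ode_integrate("bacteriostatic", c(0.05, 0.05, 0.05), 500,
#'                     model_params(), a = 110)
#' tail(tr$states, 1)   # approaches the S-only equilibrium 1 - 1/r2
#' @export
ode_integrate <- function(system, init, t_end, params = NULL, a = NULL,
                          n_out = 201, rtol = 1e-10, atol = 1e-12) {
  stopifnot(t_end > 0, length(init) == 3L, all(init >= 0), all(is.finite(init)))
  f <- if (is.function(system)) {
    function(t, y) system(y)
  } else {
    switch(match.arg(system, c("bacteriostatic", "colicin")),
           bacteriostatic = {
             if (is.null(a)) stop("the bacteriostatic system needs a production rate a")
             function(t, y) rhs_bacteriostatic(y, params, a)
           },
           colicin = function(t, y) rhs_colicin(y, params))
  }
  times <- seq(0, t_end, length.out = n_out)
  states <- matrix(NA_real_, n_out, 3, dimnames = list(NULL, c("P", "N", "S")))
  y <- as.numeric(init)
  states[1, ] <- y
  h <- NULL
  for (i in 2:n_out) {
    sol <- .dopri5(f, y, times[i - 1], times[i], rtol, atol, h0 = h)
    y <- sol$y; h <- sol$h
    states[i, ] <- y
  }
  structure(list(times = times, states = states, rhs = function(y) f(0, y)),
            class = "abx_ode_trajectory")
}

#' Single-species equilibrium density
#'
#' With only one species present the logistic balance `r (1 - x) = v` gives
#' the equilibrium density `1 - v/r` (with `v = 1`, `1 - 1/r`); densities
#' below 0 mean extinction (`r <= v`).
#'
#' @param r net intrinsic growth rate (`> 0`); for a producer strain pass
#'   `producer_growth_rate(r1, a, c)`.
#' @param v death rate (default 1).
#' @return the equilibrium density, `max(0, 1 - v/r)`.
#' @examples
#' single_species_equilibrium(2.5)  # 0.6
#' @export
single_species_equilibrium <- function(r, v = 1) {
  if (!is.finite(r) || r <= 0)
    stop("invalid parameter: r must be a finite rate > 0", call. = FALSE)
  max(0, 1 - v / r)
}

#' Unstable producer/sensitive coexistence point
#'
#' With only P and S present there is a producer density `P0` at which the
#' two growth rates balance, `r1 - a c = r2 - a P0 / b`, i.e.
#' `P0 = b ((r2 - r1)/a + c)`; the corresponding sensitive density is
#' `S0 = 1 - 1/(r1 - a c) - P0`. The point `(P0, 0, S0)` is an unstable
#' fixed point of the bacteriostatic system and exists only when `S0 > 0`.
#'
#' @inheritParams rhs_bacteriostatic
#' @return a list of class `abx_coexistence_point` with `P0`, `S0` and
#'   `exists` (`S0 > 0` with a viable producer, `r1 - a c > 1`).
#' @examples
#' unstable_coexistence_point(model_params(), a = 110)
#' @export
unstable_coexistence_point <- function(params, a) {
  stopifnot(is.finite(a), a > 0)
  rP <- producer_growth_rate(params$r1, a, params$c)
  P0 <- params$b * ((params$r2 - params$r1) / a + params$c)
  S0 <- if (rP > 0) 1 - 1 / rP - P0 else NA_real_
  structure(list(P0 = P0, S0 = S0,
                 exists = isTRUE(rP > 1 && S0 > 0)),
            class = "abx_coexistence_point")
}

# S0 as a function of a (the quantity whose roots bound the window)
.S0_of_a <- function(a, params) {
  rP <- params$r1 - a * params$c
  ifelse(rP > 0,
         1 - 1 / rP - params$b * ((params$r2 - params$r1) / a + params$c),
         -Inf)
}

#' Production-rate window in which producers can exclude sensitives
#'
#' The unstable P/S coexistence point exists (`S0 > 0`) for production
#' rates between `a_min` and `a_max`, found by setting `S0(a) = 0`. Below
#' `a_min` too little antibiotic is made to inhibit S; above `a_max` the
#' metabolic cost outweighs the benefit. The roots are located by a sign
#' scan on a logarithmic grid over `(0, (r1-1)/c)` followed by bracketed
#' root refinement to relative tolerance `1e-9`.
#'
#' @param params an [model_params()] object.
#' @param n_grid number of scan points.
#' @return a list of class `abx_window` with `a_min`, `a_max`, `exists`
#'   (whether a window was found), `roots` (all sign-change roots) and
#'   `anomalous` (`TRUE` if more than two roots were found).
#' @examples
#' production_rate_window(model_params())
#' @export
production_rate_window <- function(params, n_grid = 2000) {
  a_hi <- if (params$c > 0) (params$r1 - 1) / params$c * (1 - 1e-9) else 1e9
  if (a_hi <= 1e-3)
    return(structure(list(a_min = NA_real_, a_max = NA_real_, exists = FALSE,
                          roots = numeric(0), anomalous = FALSE),
                     class = "abx_window"))
  grid <- exp(seq(log(1e-3), log(a_hi), length.out = n_grid))
  vals <- .S0_of_a(grid, params)
  sc <- which(diff(sign(vals)) != 0 & is.finite(vals[-1]) & is.finite(vals[-length(vals)]))
  roots <- vapply(sc, function(i) {
    r <- stats::uniroot(.S0_of_a, c(grid[i], grid[i + 1]), params = params,
                        tol = 1e-13)$root
    # polish to relative tolerance 1e-9
    stats::uniroot(.S0_of_a, c(r * (1 - 1e-6), min(r * (1 + 1e-6), a_hi)),
                   params = params, tol = 1e-9 * max(1, r), extendInt = "yes")$root
  }, numeric(1))
  if (length(roots) < 2)
    return(structure(list(a_min = NA_real_, a_max = NA_real_, exists = FALSE,
                          roots = roots, anomalous = FALSE),
                     class = "abx_window"))
  structure(list(a_min = min(roots), a_max = max(roots), exists = TRUE,
                 roots = roots, anomalous = length(roots) > 2),
            class = "abx_window")
}

#' Classify the end state of an ODE trajectory
#'
#' Labels the trajectory by the set of species whose final density exceeds
#' the extinction threshold, but only once the system has converged
#' (`max |dX/dt| < conv_tol` at the final state); otherwise the label is
#' `"indeterminate"` rather than a possibly false winner.
#'
#' @param trajectory an `abx_ode_trajectory` from [ode_integrate()].
#' @param threshold extinction threshold on densities.
#' @param conv_tol convergence tolerance on the final derivative.
#' @return a label: `"S_only"`, `"P_only"`, `"N_only"`, `"extinct"`,
#'   `"indeterminate"`, or a `+`-joined multi-survivor label.
#' @export
classify_ode_outcome <- function(trajectory, threshold = 1e-6, conv_tol = 1e-9) {
  stopifnot(inherits(trajectory, "abx_ode_trajectory"))
  y <- trajectory$states[nrow(trajectory$states), ]
  if (max(abs(trajectory$rhs(as.numeric(y)))) >= conv_tol) return("indeterminate")
  alive <- names(y)[y > threshold]
  if (length(alive) == 0) return("extinct")
  if (length(alive) == 1) return(paste0(alive, "_only"))
  paste(alive, collapse = "+")
}

#' @export
print.abx_window <- function(x, ...) {
  if (x$exists)
    cat(sprintf("production-rate window: a_min = %.6g, a_max = %.6g%s\n",
                x$a_min, x$a_max,
                if (x$anomalous) "  [anomalous: >2 roots found]" else ""))
  else cat("production-rate window: empty (S0(a) <= 0 everywhere)\n")
  invisible(x)
}

#' @export
print.abx_coexistence_point <- function(x, ...) {
  cat(sprintf("unstable P/S point: P0 = %.6g, S0 = %.6g (exists: %s)\n",
              x$P0, x$S0, x$exists))
  invisible(x)
}
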