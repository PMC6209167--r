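#' Pointwise growth-rate formulas
#'
#' The per-capita growth rates shared by the mean-field and lattice models:
#' a producer strain grows at `r1 - a*c` (cost of production), the
#' non-producer at `r1` (the `a = 0` limit), a sensitive cell at
#' `r2 - A_loc` where `A_loc` is the local antibiotic concentration, and a
#' resistant cell at `r2 - c_R` independent of the antibiotic. Rates may be
#' negative; conversion to a birth probability `max(0, r)*dt` happens in
#' the lattice sweep.
#'
#' @param r1,r2 intrinsic growth rates of species 1 and 2.
#' @param a antibiotic production rate (`a >= 0`).
#' @param c metabolic cost per unit of production (`c >= 0`).
#' @return a growth rate (per unit time); possibly negative.
#' @examples
#' producer_growth_rate(2, 110, 0.001)  # 1.89
#' @export
producer_growth_rate <- function(r1, a, c) {
  if (!all(is.finite(r1), is.finite(a), is.finite(c)))
    stop("invalid parameter: non-finite input to producer_growth_rate", call. = FALSE)
  if (any(r1 <= 0) || any(a < 0) || any(c < 0))
    stop("invalid parameter: need r1 > 0, a >= 0, c >= 0", call. = FALSE)
  r1 - a * c
}

#' @rdname producer_growth_rate
#' @param A_loc local antibiotic concentration (`>= 0`).
#' @export
sensitive_growth_rate <- function(r2, A_loc) {
  if (!all(is.finite(r2), is.finite(A_loc)))
    stop("invalid parameter: non-finite input to sensitive_growth_rate", call. = FALSE)
  if (any(A_loc < 0))
    stop("invalid parameter: A_loc must be >= 0", call. = FALSE)
  r2 - A_loc
}

#' @rdname producer_growth_rate
#' @param c_R cost of resistance (`>= 0`).
#' @export
resistant_growth_rate <- function(r2, c_R) {
  if (!all(is.finite(r2), is.finite(c_R)))
    stop("invalid parameter: non-finite input to resistant_growth_rate", call. = FALSE)
  if (any(c_R < 0))
    stop("invalid parameter: c_R must be >= 0", call. = FALSE)
  r2 - c_R
}

#' Local antibiotic concentration in a Moore neighbourhood
#'
#' The antibiotic is produced at rate `a_i` by each producer in the 9-site
#' Moore neighbourhood (the site plus its 8 neighbours) and decays at rate
#' `b`; at quasi-steady state the local concentration is
#' `sum(a_i) / (9*b)`. Vacant and species-2 sites contribute rate 0. For a
#' single producer strain this reduces to `a * n_P / (9*b)` with `n_P` the
#' neighbourhood producer count; heterogeneous strains contribute
#' additively (production is linear in the producer configuration).
#'
#' @param neighborhood_rates numeric vector of exactly 9 production rates,
#'   one per neighbourhood site.
#' @param b antibiotic decay rate (`> 0`).
#' @return the local antibiotic concentration.
#' @examples
#' local_antibiotic(rep(150, 9), b = 10)  # 15
#' @export
local_antibiotic <- function(neighborhood_rates, b) {
  if (length(neighborhood_rates) != 9L)
    stop("neighborhood_rates must have exactly 9 entries (Moore neighbourhood)",
         call. = FALSE)
  if (!all(is.finite(neighborhood_rates)) || any(neighborhood_rates < 0))
    stop("invalid parameter: production rates must be finite and >= 0", call. = FALSE)
  if (!is.finite(b) || b <= 0)
    stop("invalid parameter: b must be > 0", call. = FALSE)
  sum(neighborhood_rates) / (9 * b)
}
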