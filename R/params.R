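#' Model parameters for the lattice and mean-field models
#'
#' Bundles every rate constant and simulation control of the model: two
#' species share a lattice, species 1 is split into producer strains that
#' secrete antibiotic at a per-strain rate `a` (the strain with `a = 0` is
#' the non-producer, N) and species 2 into sensitive (S) and resistant (R)
#' cells. Growth rates are `r1 - a*c` for a producer strain, `r1` for N,
#' `r2 - A_loc` for S (where `A_loc` is the local antibiotic concentration)
#' and `r2 - c_R` for R.
#'
#' Defaults are the parameter set used throughout the experiments:
#' `r1 = 2`, `r2 = 2.5`, `v = 1`, `b = 10`, `dt = 0.01`.
#'
#' @param r1 intrinsic growth rate of species 1 (per unit time).
#' @param r2 intrinsic growth rate of species 2.
#' @param b antibiotic decay rate.
#' @param c metabolic cost per unit of antibiotic production.
#' @param v death rate, identical for all cell types. `v = 1` makes one time
#'   unit the mean cell lifetime.
#' @param u mutation probability per birth event.
#' @param c_R growth-rate cost of resistance (so `r_R = r2 - c_R`).
#' @param dt time step of the lattice update; one sweep advances time by
#'   `dt`. Must satisfy `max(r1, r2)*dt <= 1` and `v*dt <= 1` so that birth
#'   and death probabilities stay valid.
#' @param L lattice side length (the lattice has `L^2` sites, torus
#'   boundary).
#' @param allowed_a sorted, duplicate-free vector of permitted production
#'   rates for species-1 strains; `0` denotes the non-producer.
#' @param active_a subset of `allowed_a` that mutation may currently draw
#'   from (the full set by default). Staged protocols extend this mid-run.
#' @param mutate_production logical; allow mutation among species-1 strains
#'   (P <-> N and between producer rates).
#' @param mutate_resistance logical; allow the S <-> R mutation within
#'   species 2.
#' @param init_fractions optional named vector of initial occupancy
#'   fractions (names as in [lattice_composition()]); kept for config
#'   round-trips, `run_lattice()` takes its composition explicitly.
#' @param seed integer PRNG seed recorded with every run.
#'
#' @return An object of class `abx_params` (a validated list).
#' @examples
#' p <- model_params(allowed_a = c(0, 150))
#' producer_growth_rate(p$r1, 150, p$c)
#' @export
model_params <- function(r1 = 2, r2 = 2.5, b = 10, c = 0.001, v = 1,
                         u = 0, c_R = 0, dt = 0.01, L = 256,
                         allowed_a = c(0, 150), active_a = allowed_a,
                         mutate_production = TRUE, mutate_resistance = FALSE,
                         init_fractions = NULL, seed = 1L) {
  p <- list(r1 = as.numeric(r1), r2 = as.numeric(r2), b = as.numeric(b),
            c = as.numeric(c), v = as.numeric(v), u = as.numeric(u),
            c_R = as.numeric(c_R), dt = as.numeric(dt), L = as.integer(L),
            allowed_a = as.numeric(allowed_a),
            active_a = as.numeric(active_a),
            mutate_production = isTRUE(mutate_production),
            mutate_resistance = isTRUE(mutate_resistance),
            init_fractions = init_fractions,
            seed = as.integer(seed))
  class(p) <- "abx_params"
  validate_params(p)
}

#' @rdname model_params
#' @param p an `abx_params` object.
#' @export
validate_params <- function(p) {
  sc <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(ok, msg) if (!ok) stop("invalid parameter: ", msg, call. = FALSE)
  chk(sc(p$r1) && p$r1 > 0, "r1 must be a finite scalar > 0")
  chk(sc(p$r2) && p$r2 > 0, "r2 must be a finite scalar > 0")
  chk(sc(p$b)  && p$b  > 0, "b must be a finite scalar > 0")
  chk(sc(p$c)  && p$c  >= 0, "c must be a finite scalar >= 0")
  chk(sc(p$v)  && p$v  > 0, "v must be a finite scalar > 0")
  chk(sc(p$u)  && p$u >= 0 && p$u <= 1, "u must lie in [0, 1]")
  chk(sc(p$c_R) && p$c_R >= 0, "c_R must be a finite scalar >= 0")
  chk(sc(p$dt) && p$dt > 0, "dt must be a finite scalar > 0")
  chk(max(p$r1, p$r2) * p$dt <= 1, "max(r1, r2)*dt must be <= 1 (birth probability)")
  chk(p$v * p$dt <= 1, "v*dt must be <= 1 (death probability)")
  chk(is.numeric(p$L) && length(p$L) == 1L && p$L >= 3, "L must be an integer >= 3")
  a <- p$allowed_a
  chk(length(a) >= 1L && all(is.finite(a)) && all(a >= 0), "allowed_a must be non-negative and finite")
  chk(!is.unsorted(a, strictly = TRUE), "allowed_a must be sorted and duplicate-free")
  chk(length(a) <= 99L, "at most 99 species-1 strains are supported")
  chk(all(p$active_a %in% a), "active_a must be a subset of allowed_a")
  chk(length(p$active_a) >= 1L, "active_a must be non-empty")
  if (!is.null(p$init_fractions)) {
    f <- p$init_fractions
    chk(is.numeric(f) && all(f >= 0) && sum(f) <= 1 + 1e-12,
        "init_fractions must be >= 0 and sum to <= 1")
  }
  invisible(p)
}

#' @export
print.abx_params <- function(x, ...) {
  cat("<abx_params>\n")
  cat(sprintf("  r1=%g r2=%g b=%g c=%g v=%g u=%g c_R=%g dt=%g L=%d seed=%d\n",
              x$r1, x$r2, x$b, x$c, x$v, x$u, x$c_R, x$dt, x$L, x$seed))
  cat("  allowed_a:", paste(x$allowed_a, collapse = " "), "\n")
  cat(sprintf("  mutate_production=%s mutate_resistance=%s\n",
              x$mutate_production, x$mutate_resistance))
  invisible(x)
}

# Integer codes used on the grid and in snapshots:
#   0            vacant
#   1..K         species-1 strain with the k-th value of allowed_a
#                (allowed_a[1] == 0 makes code 1 the non-producer)
#   100          sensitive (S)
#   101          resistant (R)
CODE_S <- 100L
CODE_R <- 101L

#' Cell states
#'
#' A cell state is identified by a compact label: `"S"` (sensitive), `"R"`
#' (resistant), `"N"` (non-producer, the species-1 strain with `a = 0`) or
#' `"P<a>"` for a producer strain, e.g. `"P150"`. `cell_state()` builds a
#' label from its parts; `state_code()`/`code_state()` convert between
#' labels and the integer codes used on the grid (0 vacant, `1..K` the k-th
#' entry of `allowed_a`, 100 S, 101 R).
#'
#' @param kind one of `"P"`, `"N"`, `"S"`, `"R"`.
#' @param a production rate, required for `kind = "P"`.
#' @return `cell_state()` returns a label string.
#' @examples
#' cell_state("P", 110)
#' state_code("N", model_params(allowed_a = c(0, 110)))
#' @export
cell_state <- function(kind = c("P", "N", "S", "R"), a = NULL) {
  kind <- match.arg(kind)
  switch(kind,
         P = {
           if (is.null(a) || !is.finite(a) || a < 0)
             stop("a producer state needs a finite production rate a >= 0", call. = FALSE)
           if (a == 0) "N" else paste0("P", format(a, scientific = FALSE))
         },
         N = "N", S = "S", R = "R")
}

#' @rdname cell_state
#' @param label a state label (`"S"`, `"R"`, `"N"`, `"P<a>"`).
#' @param params an `abx_params` object supplying `allowed_a`.
#' @export
state_code <- function(label, params) {
  vapply(label, function(lb) {
    if (lb == "S") return(CODE_S)
    if (lb == "R") return(CODE_R)
    a <- if (lb == "N") 0 else if (grepl("^P", lb)) as.numeric(sub("^P", "", lb)) else NA_real_
    if (is.na(a)) stop("unknown cell-state label: ", lb, call. = FALSE)
    k <- match(a, params$allowed_a)
    if (is.na(k)) stop("production rate ", a, " not in allowed_a", call. = FALSE)
    as.integer(k)
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname cell_state
#' @param code integer grid code(s).
#' @export
code_state <- function(code, params) {
  vapply(as.integer(code), function(k) {
    if (k == 0L) return("vacant")
    if (k == CODE_S) return("S")
    if (k == CODE_R) return("R")
    if (k >= 1L && k <= length(params$allowed_a)) {
      a <- params$allowed_a[k]
      return(if (a == 0) "N" else paste0("P", format(a, scientific = FALSE)))
    }
    stop("invalid grid code: ", k, call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Production rate carried by each grid code
#'
#' @param params an `abx_params` object.
#' @return numeric vector indexed by code `1..101`: the production rate of
#'   species-1 codes, `0` for S/R and unused codes.
#' @keywords internal
code_a_table <- function(params) {
  tab <- numeric(101)
  tab[seq_along(params$allowed_a)] <- params$allowed_a
  tab
}
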