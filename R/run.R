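#' Low-level sweep interface
#'
#' `sweep_rng()` creates the deterministic random stream used by the
#' compiled kernel; `sweep_lattice()` advances a lattice by a given number
#' of sweeps (each sweep is one time step `dt`: every site is visited once
#' in a fresh uniform random order). Exposed mainly for tests and custom
#' protocols; most users call [run_lattice()].
#'
#' @param seed integer seed.
#' @return `sweep_rng()`: an opaque RNG state object (class `abx_rng`).
#' @export
sweep_rng <- function(seed) {
  structure(list(state = cpp_rng_state(as.integer(seed)),
                 seed = as.integer(seed)), class = "abx_rng")
}

#' @rdname sweep_rng
#' @param lattice an `abx_lattice`.
#' @param params an [model_params()] object.
#' @param n_sweeps number of sweeps (time advanced is `n_sweeps * dt`).
#' @param rng an `abx_rng` state from [sweep_rng()].
#' @param dispersal `"local"` (offspring to a uniformly chosen Moore
#'   neighbour) or `"global"` (offspring to a uniformly chosen lattice
#'   site; the well-mixed control).
#' @return `sweep_lattice()`: a list with the updated `lattice`, advanced
#'   `rng`, per-type `counts` (102-vector indexed by code + 1) and event
#'   totals `births`, `deaths`.
#' @export
sweep_lattice <- function(lattice, params, n_sweeps = 1L, rng,
                          dispersal = c("local", "global")) {
  stopifnot(inherits(lattice, "abx_lattice"), inherits(rng, "abx_rng"))
  validate_params(params)
  if (lattice$side != params$L)
    stop("lattice side does not match params$L", call. = FALSE)
  dispersal <- match.arg(dispersal)
  act <- match(params$active_a, params$allowed_a)
  res <- cpp_advance(lattice$cells, lattice$side, params$allowed_a,
                     as.integer(act),
                     params$r1, params$r2, params$b, params$c, params$v,
                     params$c_R, params$dt, params$u,
                     params$mutate_production, params$mutate_resistance,
                     dispersal == "global",
                     as.integer(n_sweeps), rng$state)
  list(lattice = new_lattice(res$grid, lattice$side, params$allowed_a),
       rng = structure(list(state = res$rng_state, seed = rng$seed),
                       class = "abx_rng"),
       counts = res$counts, births = res$births, deaths = res$deaths)
}

# Can mutation still create a type that is not currently present?
types_can_diversify <- function(counts102, params) {
  if (params$u <= 0) return(FALSE)
  K <- length(params$allowed_a)
  sp1 <- sum(counts102[2:(K + 1)])
  sp2 <- counts102[CODE_S + 1L] + counts102[CODE_R + 1L]
  (params$mutate_production && length(params$active_a) > 1 && sp1 > 0) ||
    (params$mutate_resistance && sp2 > 0)
}

n_types_present <- function(counts102) {
  sum(counts102[-1] > 0)
}

#' Run a lattice simulation
#'
#' Initialises an `L x L` lattice from `composition` (or resumes from a
#' supplied lattice) and executes `t_end / dt` sweeps, recording the
#' occupancy fraction of every distinct cell type each `record_every` time
#' units. A run stops early once a single cell type remains and no enabled
#' mutation channel could restore diversity (checked every `record_every`
#' units, the spec default 10). Identical `(seed, params, composition)`
#' give bit-identical results.
#'
#' `hooks` implements staged protocols: a list of `list(time =, set =)`
#' entries applied in time order, where `set` is a named list of parameter
#' changes (`u`, `active_a`, `mutate_production`, `mutate_resistance`,
#' `c_R`). The lattice strain coding is fixed by `allowed_a` for the whole
#' run, so a hook may activate strains (via `active_a`) but not introduce
#' production rates outside `allowed_a`.
#'
#' @param params an [model_params()] object.
#' @param composition named initial fractions ([lattice_composition()]).
#' @param t_end run length in time units.
#' @param record_every recording (and early-stop check) interval in time
#'   units.
#' @param hooks optional stage schedule (see Details).
#' @param dispersal `"local"` or `"global"` (well-mixed control).
#' @param init optional `abx_lattice` to resume from instead of random
#'   initialisation.
#' @param seed seed for this run (defaults to `params$seed`).
#' @return an object of class `abx_run`: list with `series` (data.frame:
#'   `time`, one column per type label, `vacant`), `final` lattice,
#'   `params`, `seed`, and `t_stop` (the time actually reached).
#' @examples
#' p <- model_params(L = 48, allowed_a = c(0, 150), seed = 7)
#' r <- run_lattice(p, lattice_composition(P150 = .05, N = .05, S = .05),
#'                  t_end = 20)
#' tail(r$series, 2)
#' @export
run_lattice <- function(params, composition, t_end, record_every = 10,
                        hooks = NULL, dispersal = c("local", "global"),
                        init = NULL, seed = params$seed) {
  validate_params(params)
  stopifnot(t_end > 0, record_every > 0)
  dispersal <- match.arg(dispersal)
  if (!is.null(hooks)) {
    tms <- vapply(hooks, `[[`, numeric(1), "time")
    if (is.unsorted(tms)) stop("hooks must be sorted by time", call. = FALSE)
    if (any(tms > t_end)) stop("config error: hook scheduled beyond t_end", call. = FALSE)
  }
  lat <- if (is.null(init)) initialize_lattice(params, composition, seed = seed)
         else init
  rng <- sweep_rng(seed)

  # segment boundaries: recording times plus hook times
  rec_times <- seq(record_every, t_end, by = record_every)
  if (length(rec_times) == 0 || max(rec_times) < t_end)
    rec_times <- c(rec_times, t_end)
  bounds <- sort(unique(c(rec_times, vapply(hooks, `[[`, numeric(1), "time"))))
  bounds <- bounds[bounds > 0 & bounds <= t_end]

  counts <- lattice_counts(lat)
  rec <- list(c(time = 0, counts_row(counts, params)))
  t_now <- 0
  hook_i <- 1L
  stopped <- FALSE
  for (tb in bounds) {
    n_sw <- round((tb - t_now) / params$dt)
    if (n_sw > 0) {
      step <- sweep_lattice(lat, params, n_sw, rng, dispersal)
      lat <- step$lattice; rng <- step$rng; counts <- step$counts
    }
    t_now <- tb
    while (hook_i <= length(hooks) && hooks[[hook_i]]$time <= t_now + 1e-9) {
      params <- apply_hook(params, hooks[[hook_i]]$set)
      hook_i <- hook_i + 1L
    }
    if (tb %in% rec_times || tb == t_end)
      rec[[length(rec) + 1L]] <- c(time = t_now, counts_row(counts, params))
    if (n_types_present(counts) <= 1L && !types_can_diversify(counts, params)) {
      stopped <- TRUE
      break
    }
  }
  series <- as.data.frame(do.call(rbind, rec))
  structure(list(series = series, final = lat, params = params,
                 seed = as.integer(seed), t_stop = t_now,
                 stopped_early = stopped && t_now < t_end),
            class = "abx_run")
}

apply_hook <- function(params, set) {
  allowed <- c("u", "active_a", "mutate_production", "mutate_resistance", "c_R")
  bad <- setdiff(names(set), allowed)
  if (length(bad)) stop("config error: unknown hook key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (k in names(set)) params[[k]] <- set[[k]]
  validate_params(params)
}

counts_row <- function(counts102, params) {
  K <- length(params$allowed_a)
  n <- params$L^2
  labs <- c("vacant", code_state(seq_len(K), params), "S", "R")
  setNames(counts102[c(1L, 1L + seq_len(K), CODE_S + 1L, CODE_R + 1L)] / n, labs)
}

#' @export
print.abx_run <- function(x, ...) {
  cat(sprintf("<abx_run> t_stop = %g%s, seed = %d\n", x$t_stop,
              if (isTRUE(x$stopped_early)) " (stopped early)" else "", x$seed))
  print(round(utils::tail(x$series, 1), 4))
  invisible(x)
}

#' Export a recorded time series as CSV
#'
#' Columns: `time`, one column per cell-type label, `vacant`.
#'
#' @param run an `abx_run` object (or its `series` data.frame).
#' @param path output file.
#' @export
write_timeseries <- function(run, path) {
  series <- if (inherits(run, "abx_run")) run$series else run
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}
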