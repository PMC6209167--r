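#' Classify the outcome of a finished run
#'
#' The surviving set is the set of cell types with non-zero count on the
#' final lattice; the label is a pure function of that set, following the
#' phase-diagram legend: producers (any strain with `a > 0`), non-producer
#' (`a = 0`), sensitive and resistant. `S_only`, `P_only`, `N_only`,
#' `coexist_PNS` (P, N and S), `coexist_SP` (S and P, no N),
#' `four_type` (P, N, S and R), `extinct`, and `coexist_other` for any
#' other multi-type set.
#'
#' @param x an `abx_run`, an `abx_lattice`, or a 102-element count vector.
#' @param params an [model_params()] object (needed for count vectors).
#' @return an object of class `abx_outcome`: list with `label` and the
#'   `surviving` type labels.
#' @export
classify_outcome <- function(x, params = NULL) {
  counts <- if (inherits(x, "abx_run")) {
    params <- x$params
    lattice_counts(x$final)
  } else if (inherits(x, "abx_lattice")) {
    if (is.null(params)) params <- model_params(L = x$side, allowed_a = x$allowed_a)
    lattice_counts(x)
  } else {
    if (is.null(params)) stop("params required for a raw count vector", call. = FALSE)
    x
  }
  K <- length(params$allowed_a)
  sp1 <- counts[1L + seq_len(K)]
  hasP <- any(sp1 > 0 & params$allowed_a > 0)
  hasN <- any(sp1 > 0 & params$allowed_a == 0)
  hasS <- counts[CODE_S + 1L] > 0
  hasR <- counts[CODE_R + 1L] > 0
  groups <- c(P = hasP, N = hasN, S = hasS, R = hasR)
  present <- names(groups)[groups]
  label <- if (length(present) == 0) "extinct"
  else if (identical(present, "S")) "S_only"
  else if (identical(present, "P")) "P_only"
  else if (identical(present, "N")) "N_only"
  else if (setequal(present, c("P", "N", "S"))) "coexist_PNS"
  else if (setequal(present, c("P", "S"))) "coexist_SP"
  else if (setequal(present, c("P", "N", "S", "R"))) "four_type"
  else "coexist_other"
  surviving <- code_state(which(counts[-1] > 0), params)
  structure(list(label = label, surviving = surviving), class = "abx_outcome")
}

#' @export
print.abx_outcome <- function(x, ...) {
  cat(sprintf("outcome: %s  (surviving: %s)\n", x$label,
              if (length(x$surviving)) paste(x$surviving, collapse = ", ") else "none"))
  invisible(x)
}

outcome_levels <- c("S_only", "P_only", "N_only", "coexist_PNS", "coexist_SP",
                    "four_type", "coexist_other", "extinct")

#' Replicate ensembles of lattice runs
#'
#' Runs `n_runs` independent simulations (seeds `seed_base + 1 ... +
#' n_runs`), classifies each, and aggregates outcome frequencies together
#' with time-averaged concentrations over the trailing `window` fraction of
#' each run, conditioned on outcome.
#'
#' @param params an [model_params()] object.
#' @param composition initial mixture ([lattice_composition()]).
#' @param n_runs number of replicates (`>= 1`).
#' @param t_end run length (time units).
#' @param seed_base base seed; replicate `i` uses `seed_base + i`.
#' @param window trailing fraction of each run to average over.
#' @param ... passed to [run_lattice()] (e.g. `hooks`, `dispersal`).
#' @return an object of class `abx_replicates`: `n_runs`, `outcomes`
#'   (per-run labels), `counts` (table over outcome labels), `majority`
#'   (modal label; ties broken by the fixed label order and flagged via
#'   `majority_tied`), and `mean_concentrations` (list per outcome label).
#' @export
replicate_outcomes <- function(params, composition, n_runs, t_end,
                               seed_base = params$seed, window = 0.5, ...) {
  stopifnot(n_runs >= 1)
  outcomes <- character(n_runs)
  means <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    run <- run_lattice(params, composition, t_end, seed = seed_base + i, ...)
    outcomes[i] <- classify_outcome(run)$label
    means[[i]] <- time_averaged_concentrations(run$series, window = window)
  }
  tab <- table(factor(outcomes, levels = outcome_levels))
  top <- max(tab)
  winners <- names(tab)[tab == top]
  cond <- lapply(split(seq_len(n_runs), outcomes), function(idx) {
    Reduce(`+`, means[idx]) / length(idx)
  })
  structure(list(n_runs = n_runs, outcomes = outcomes, counts = tab,
                 majority = winners[1], majority_tied = length(winners) > 1,
                 mean_concentrations = cond),
            class = "abx_replicates")
}

#' @export
print.abx_replicates <- function(x, ...) {
  cat(sprintf("<abx_replicates> n = %d, majority = %s%s\n", x$n_runs, x$majority,
              if (x$majority_tied) " (tie)" else ""))
  print(x$counts[x$counts > 0])
  invisible(x)
}

#' Majority-outcome phase diagram over production rate and cost
#'
#' For every `(a, c)` combination, runs a replicate ensemble from a 5% P /
#' 5% N / 5% S start and records the majority outcome (the colour of the
#' phase-diagram cell).
#'
#' @param a_values production rates to scan.
#' @param c_values production costs to scan.
#' @param n_runs replicates per combination.
#' @param params base [model_params()] (its `allowed_a` is replaced by
#'   `c(0, a)` per cell).
#' @param t_end run length per replicate.
#' @param init_fraction initial fraction for each of P, N, S.
#' @param seed_base base seed; each grid cell gets an offset block.
#' @return data.frame with columns `a`, `c`, `majority`, and one count
#'   column per outcome label.
#' @export
phase_diagram <- function(a_values, c_values, n_runs, params = model_params(),
                          t_end = 2000, init_fraction = 0.05,
                          seed_base = params$seed) {
  stopifnot(length(a_values) >= 1, length(c_values) >= 1)
  grid <- expand.grid(a = a_values, c = c_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    a <- grid$a[i]; cc <- grid$c[i]
    p <- params
    p$c <- cc
    p$allowed_a <- sort(unique(c(0, a)))
    p$active_a <- p$allowed_a
    p <- validate_params(p)
    comp <- lattice_composition(setNames(
      rep(init_fraction, 3), c(cell_state("P", a), "N", "S")))
    rep_res <- replicate_outcomes(p, comp, n_runs, t_end,
                                  seed_base = seed_base + (i - 1L) * n_runs)
    c(list(a = a, c = cc, majority = rep_res$majority),
      as.list(as.integer(rep_res$counts)))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  names(out) <- c("a", "c", "majority", outcome_levels)
  out
}

#' Time-averaged concentrations over the trailing window of a run
#'
#' Arithmetic mean of each type's occupancy fraction over the last
#' `window` fraction of the recorded series (e.g. `window = 0.5` averages
#' the second half of the run).
#'
#' @param series an `abx_run` or its `series` data.frame.
#' @param window fraction of the run to average, in `(0, 1]`.
#' @return named numeric vector of mean fractions.
#' @export
time_averaged_concentrations <- function(series, window = 0.5) {
  if (inherits(series, "abx_run")) series <- series$series
  if (!is.numeric(window) || length(window) != 1 || window <= 0 || window > 1)
    stop("contract violation: window must lie in (0, 1]", call. = FALSE)
  tt <- series$time
  t_cut <- max(tt) - window * (max(tt) - min(tt))
  sel <- tt >= t_cut - 1e-9
  colMeans(series[sel, setdiff(names(series), "time"), drop = FALSE])
}

#' Staged protocols: parameter changes at scheduled times
#'
#' A thin wrapper around [run_lattice()]'s hook mechanism for experiments
#' that switch mutation on, extend the set of active production rates, or
#' change the cost of resistance mid-run. With no stages it is identical
#' to [run_lattice()].
#'
#' @param params an [model_params()] object; `allowed_a` must already
#'   contain every rate any stage will activate.
#' @param composition initial mixture.
#' @param stages list of `list(time =, set =)` entries, times increasing.
#' @param t_end run length.
#' @param ... passed to [run_lattice()].
#' @return an `abx_run`.
#' @export
staged_protocol <- function(params, composition, stages = NULL, t_end, ...) {
  run_lattice(params, composition, t_end, hooks = stages, ...)
}

#' Evolution of the antibiotic production rate
#'
#' Multi-strain protocol: producers may take any rate in `allowed_a`
#' (default 0, 10, ..., 200, where rate 0 is the non-producer). The run
#' starts without mutation for `burn_in` time units so that spatial
#' structure establishes, then production-rate mutation is switched on at
#' rate `u` (a mutated offspring redraws its rate uniformly from the other
#' active values). Returns the strain-frequency distribution time-averaged
#' over the trailing half of the run.
#'
#' @param composition initial mixture, e.g.
#'   `lattice_composition(P150 = 0.05, N = 0.05, S = 0.05)`.
#' @param params an [model_params()] object; its `allowed_a` defines the
#'   strain space.
#' @param burn_in time units before mutation is enabled.
#' @param t_end total run length.
#' @param u mutation rate once enabled.
#' @param ... passed to [run_lattice()].
#' @return list of class `abx_evolved`: `strain_distribution` (named mean
#'   fraction per producer strain), `mean_concentrations` (all types),
#'   `modal_strain` (production rate with the highest mean frequency) and
#'   the full `run`.
#' @export
evolve_production_rates <- function(composition,
                                    params = model_params(allowed_a = seq(0, 200, 10)),
                                    burn_in = 1000, t_end = 1e5, u = 1e-4, ...) {
  stopifnot(burn_in > 0, t_end > burn_in)
  p <- params
  p$u <- 0
  p <- validate_params(p)
  run <- staged_protocol(p, composition,
                         stages = list(list(time = burn_in,
                                            set = list(u = u, mutate_production = TRUE))),
                         t_end = t_end, ...)
  avg <- time_averaged_concentrations(run$series, window = 0.5)
  strain_labels <- code_state(seq_along(params$allowed_a), params)
  dist <- avg[strain_labels]
  names(dist) <- strain_labels
  dist[is.na(dist)] <- 0
  modal <- params$allowed_a[which.max(dist)]
  structure(list(strain_distribution = dist,
                 mean_concentrations = avg,
                 modal_strain = modal, run = run),
            class = "abx_evolved")
}

#' Sweep over the growth rate of the resistant type
#'
#' For each resistant growth rate `r_R` (cost of resistance
#' `c_R = r2 - r_R`): a P/N/S lattice establishes spatial structure for
#' `burn_in` time units, then mutation is switched on both within species 1
#' (P <-> N) and species 2 (S <-> R) at rate `u`, and the run continues to
#' `t_end`. Equilibrium concentrations are trailing-window means.
#'
#' @param r_R_values resistant growth rates, each in `(0, r2]`.
#' @param params an [model_params()] object (typically `a = 110` via
#'   `allowed_a = c(0, 110)`, `c = 0.001`).
#' @param composition initial P/N/S mixture.
#' @param burn_in burn-in before mutations are enabled.
#' @param t_end total run length.
#' @param u mutation rate after burn-in.
#' @param window trailing averaging window.
#' @param share_burn_in logical; if `TRUE`, the burn-in phase is simulated
#'   once and every `r_R` value resumes from the same burned-in lattice.
#'   Valid because the cost of resistance is inert while no R cell exists
#'   and mutation is off during burn-in, so the burn-in dynamics are
#'   identical across the sweep; it correlates the sweep rows but not any
#'   single row's distribution. The trailing average then covers the
#'   post-burn-in phase.
#' @param burn_attempts maximum number of burn-in attempts (shared
#'   burn-in only). The protocol requires a lattice that has *established*
#'   P/N/S coexistence before mutation starts; on desk-scale lattices a
#'   type is occasionally lost to a finite-size fluctuation, in which case
#'   the burn-in is repeated with the next seed (each attempt offsets the
#'   seed by 1000) rather than silently sweeping over a broken state.
#' @param ... passed to [run_lattice()].
#' @return data.frame: one row per `r_R` with mean concentrations of P
#'   (all producing strains pooled), N, S, R, and the run's outcome label.
#' @export
resistance_sweep <- function(r_R_values, params = model_params(allowed_a = c(0, 110)),
                             composition = lattice_composition(P110 = .05, N = .05, S = .05),
                             burn_in = 5000, t_end = 10000, u = 1e-4,
                             window = 0.5, share_burn_in = FALSE,
                             burn_attempts = 5, ...) {
  stopifnot(all(r_R_values > 0), all(r_R_values <= params$r2 + 1e-12))
  burn_lat <- NULL
  if (share_burn_in) {
    p0 <- params
    p0$u <- 0
    p0$mutate_resistance <- FALSE
    p0 <- validate_params(p0)
    for (att in seq_len(burn_attempts)) {
      burn <- run_lattice(p0, composition, t_end = burn_in,
                          seed = p0$seed + (att - 1L) * 1000L, ...)
      burn_lat <- burn$final
      if (classify_outcome(burn)$label == "coexist_PNS") break
      if (att == burn_attempts)
        warning("burn-in never established P/N/S coexistence; ",
                "sweeping from the last attempt anyway")
    }
  }
  rows <- lapply(seq_along(r_R_values), function(i) {
    rR <- r_R_values[i]
    p <- params
    p$c_R <- params$r2 - rR
    if (share_burn_in) {
      p$u <- u
      p$mutate_production <- TRUE
      p$mutate_resistance <- TRUE
      p <- validate_params(p)
      run <- run_lattice(p, composition, t_end = t_end - burn_in,
                         init = burn_lat, seed = params$seed + 7919L * i, ...)
      avg <- time_averaged_concentrations(run$series, window = window)
    } else {
      p$u <- 0
      p$mutate_resistance <- FALSE
      p <- validate_params(p)
      run <- staged_protocol(p, composition,
                             stages = list(list(time = burn_in,
                                                set = list(u = u,
                                                           mutate_production = TRUE,
                                                           mutate_resistance = TRUE))),
                             t_end = t_end, ...)
      avg <- time_averaged_concentrations(run$series, window = window)
    }
    a_tab <- p$allowed_a
    strain_labels <- code_state(seq_along(a_tab), p)
    getf <- function(lb) if (lb %in% names(avg)) unname(avg[lb]) else 0
    data.frame(r_R = rR,
               P = sum(vapply(strain_labels[a_tab > 0], getf, numeric(1))),
               N = sum(vapply(strain_labels[a_tab == 0], getf, numeric(1))),
               S = getf("S"), R = getf("R"),
               outcome = classify_outcome(run)$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
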