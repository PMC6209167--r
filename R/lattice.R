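#' Lattice construction and initialisation
#'
#' The habitat is an `L x L` square lattice with torus (periodic) boundary;
#' each site is vacant or carries one cell. `lattice_composition()` builds
#' the initial mixture as named occupancy fractions, e.g.
#' `lattice_composition(P150 = 0.05, N = 0.05, S = 0.05)` (85% vacant).
#' `initialize_lattice()` assigns every site independently according to
#' those probabilities.
#'
#' @param ... named fractions; names are cell-state labels as in
#'   [cell_state()] (`"S"`, `"R"`, `"N"`, `"P<a>"`).
#' @return `lattice_composition()`: a named numeric vector.
#' @examples
#' p <- model_params(L = 64, allowed_a = c(0, 150))
#' lat <- initialize_lattice(p, lattice_composition(P150 = .05, N = .05, S = .05))
#' concentrations(lat)
#' @export
lattice_composition <- function(...) {
  f <- c(...)
  if (length(f) == 0) return(setNames(numeric(0), character(0)))
  if (is.null(names(f)) || any(names(f) == ""))
    stop("all composition entries must be named by cell-state labels", call. = FALSE)
  if (any(f < 0) || sum(f) > 1 + 1e-12)
    stop("invalid parameter: fractions must be >= 0 and sum to <= 1", call. = FALSE)
  f
}

#' @rdname lattice_composition
#' @param params an [model_params()] object (`L`, `allowed_a`, `seed`).
#' @param composition named fractions from [lattice_composition()].
#' @param seed optional integer seed for the initial placement (defaults to
#'   `params$seed`).
#' @return `initialize_lattice()`: an object of class `abx_lattice`.
#' @export
initialize_lattice <- function(params, composition = lattice_composition(),
                               seed = params$seed) {
  validate_params(params)
  composition <- lattice_composition(composition)
  n <- params$L^2
  codes <- c(0L, if (length(composition)) state_code(names(composition), params))
  probs <- c(1 - sum(composition), composition)
  if (!is.null(seed)) set.seed(seed)
  cells <- if (length(composition) == 0) rep(0L, n) else
    sample(codes, n, replace = TRUE, prob = probs)
  new_lattice(as.raw(cells), params$L, params$allowed_a)
}

new_lattice <- function(cells, side, allowed_a) {
  structure(list(side = as.integer(side), cells = cells,
                 allowed_a = as.numeric(allowed_a)),
            class = "abx_lattice")
}

#' @export
print.abx_lattice <- function(x, ...) {
  cat(sprintf("<abx_lattice %dx%d (torus)>\n", x$side, x$side))
  print(round(concentrations_from_counts(lattice_counts(x), x), 4))
  invisible(x)
}

lattice_counts <- function(lattice) {
  tabulate(as.integer(lattice$cells) + 1L, nbins = 102L)  # index 1 = vacant
}

#' Per-type occupancy fractions
#'
#' Counts every distinct cell type present (each producer strain
#' separately) plus vacancy and divides by `L^2`; the fractions sum to 1
#' exactly.
#'
#' @param lattice an `abx_lattice`.
#' @return named numeric vector of fractions (`vacant`, then type labels).
#' @export
concentrations <- function(lattice) {
  stopifnot(inherits(lattice, "abx_lattice"))
  concentrations_from_counts(lattice_counts(lattice), lattice)
}

concentrations_from_counts <- function(counts102, lattice) {
  n <- lattice$side^2
  present <- which(counts102 > 0)
  codes <- present - 1L
  params_like <- list(allowed_a = lattice$allowed_a)
  labs <- vapply(codes, function(k) {
    if (k == 0L) "vacant" else code_state(k, params_like)
  }, character(1))
  setNames(counts102[present] / n, labs)
}

#' Moore-neighbourhood antibiotic field
#'
#' The quasi-steady-state antibiotic concentration at every site: the sum
#' of production rates over the 9-site Moore neighbourhood (site plus 8
#' neighbours, torus wrap) divided by `9*b`. Computed by summing the nine
#' torus shifts of the per-site production-rate matrix.
#'
#' @param lattice an `abx_lattice`.
#' @param b antibiotic decay rate (`> 0`).
#' @return an `L x L` numeric matrix of concentrations.
#' @examples
#' p <- model_params(L = 16, allowed_a = c(0, 110))
#' lat <- initialize_lattice(p, lattice_composition(P110 = 0.1))
#' range(antibiotic_field(lat, b = 10))
#' @export
antibiotic_field <- function(lattice, b) {
  stopifnot(inherits(lattice, "abx_lattice"))
  if (!is.finite(b) || b <= 0)
    stop("invalid parameter: b must be > 0", call. = FALSE)
  L <- lattice$side
  codes <- matrix(as.integer(lattice$cells), L, L)
  atab <- c(lattice$allowed_a, numeric(101 - length(lattice$allowed_a)))
  amat <- matrix(0, L, L)
  sp1 <- codes >= 1L & codes < 100L
  amat[sp1] <- atab[codes[sp1]]
  shift <- function(m, dr, dc) {
    ri <- ((seq_len(L) - 1 - dr) %% L) + 1
    ci <- ((seq_len(L) - 1 - dc) %% L) + 1
    m[ri, ci]
  }
  field <- matrix(0, L, L)
  for (dr in -1:1) for (dc in -1:1) field <- field + shift(amat, dr, dc)
  field / (9 * b)
}

#' Offspring mutation
#'
#' Applied at each birth: with probability `1 - u` the offspring is an
#' exact copy of the parent. With probability `u`, a species-1 offspring's
#' production rate is redrawn uniformly from the currently active rates
#' excluding the parent's (for two strains this is the P <-> N flip), and a
#' species-2 offspring toggles its resistance flag (S <-> R) when
#' resistance mutation is enabled. Mutation never changes species.
#'
#' This is the reference R implementation used in tests; the sweep kernel
#' applies the identical rule in compiled code.
#'
#' @param parent a cell-state label (see [cell_state()]); not `"vacant"`.
#' @param params an [model_params()] object (`u`, `active_a`,
#'   `mutate_production`, `mutate_resistance`).
#' @return the offspring's cell-state label.
#' @export
mutate_offspring <- function(parent, params) {
  if (identical(parent, "vacant"))
    stop("contract violation: vacant sites cannot reproduce", call. = FALSE)
  code <- state_code(parent, params)
  if (params$u == 0 || runif(1) >= params$u) return(parent)
  if (code < 100L) {
    if (!params$mutate_production) return(parent)
    act <- state_code_for_a(params$active_a, params)
    others <- setdiff(act, code)
    if (length(others) == 0) return(parent)
    code_state(others[sample.int(length(others), 1L)], params)
  } else if (params$mutate_resistance) {
    if (code == CODE_S) "R" else "S"
  } else parent
}

state_code_for_a <- function(a, params) {
  match(a, params$allowed_a)
}

#' Snapshot files
#'
#' Writes/reads the full simulation state as plain text: a `#`-prefixed
#' header (side length, time, seed, allowed production rates) followed by
#' `L` lines of `L` integer site codes (0 vacant, `1+k` the k-th allowed
#' production rate so 1 is the non-producer, 100 S, 101 R). Round-trips
#' bit-exactly.
#'
#' @param lattice an `abx_lattice`.
#' @param path file path.
#' @param time simulation time of the snapshot.
#' @param seed seed recorded in the header.
#' @export
write_snapshot <- function(lattice, path, time = 0, seed = NA_integer_) {
  stopifnot(inherits(lattice, "abx_lattice"))
  L <- lattice$side
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# spatabx snapshot v1",
               paste("# L", L),
               paste("# time", sprintf("%.17g", time)),
               paste("# seed", seed),
               paste("# allowed_a", paste(sprintf("%.17g", lattice$allowed_a),
                                          collapse = " "))), con)
  codes <- as.integer(lattice$cells)
  rows <- vapply(seq_len(L), function(i)
    paste(codes[((i - 1) * L + 1):(i * L)], collapse = " "), character(1))
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_snapshot
#' @return `read_snapshot()`: a list with `lattice`, `time`, `seed`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, " "), "", grep(paste0("^# ", key, " "),
                                                             hdr, value = TRUE)[1])
  L <- as.integer(get("L"))
  time <- as.numeric(get("time"))
  seed <- suppressWarnings(as.integer(get("seed")))
  allowed_a <- as.numeric(strsplit(get("allowed_a"), " +")[[1]])
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) != L) stop("snapshot corrupt: expected ", L, " rows", call. = FALSE)
  cells <- unlist(lapply(strsplit(body, " +"), as.integer), use.names = FALSE)
  if (length(cells) != L * L) stop("snapshot corrupt: wrong cell count", call. = FALSE)
  list(lattice = new_lattice(as.raw(cells), L, allowed_a), time = time, seed = seed)
}

#' Render a lattice snapshot as a plain-text PPM image
#'
#' One pixel per site with a fixed palette by ecological role: vacant
#' black, producers red (darker for lower rates), non-producer blue,
#' sensitive green, resistant violet.
#'
#' @param lattice an `abx_lattice`.
#' @param path output path (`.ppm`, text P3 format).
#' @export
render_snapshot <- function(lattice, path) {
  stopifnot(inherits(lattice, "abx_lattice"))
  L <- lattice$side
  codes <- as.integer(lattice$cells)
  K <- length(lattice$allowed_a)
  col <- matrix(0L, 3, length(codes))
  for (k in seq_len(K)) {
    a <- lattice$allowed_a[k]
    sel <- codes == k
    if (a == 0) col[, sel] <- c(40L, 80L, 255L)           # non-producer: blue
    else {
      amax <- max(lattice$allowed_a)
      col[, sel] <- c(120L + as.integer(135 * a / amax), 30L, 30L)  # producer: red
    }
  }
  col[, codes == CODE_S] <- c(30L, 200L, 60L)             # sensitive: green
  col[, codes == CODE_R] <- c(170L, 60L, 200L)            # resistant: violet
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(L, L), "255"), con)
  for (row in seq_len(L)) {
    idx <- ((row - 1) * L + 1):(row * L)
    writeLines(paste(col[, idx], collapse = " "), con)
  }
  invisible(path)
}
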