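#' Kinetic connectivity schemes
#'
#' A `kinetic_scheme` describes a set of species coupled by irreversible
#' first-order reactions, i.e. the linear ODE system `dc/dt = K c`.
#' Each reaction transfers population from a source species either to
#' another species or to `"loss"` (radiationless disappearance from the
#' model). A rate constant of exactly zero encodes a non-decaying
#' ("Infinite" / long-lived) component.
#'
#' @param species character vector of species labels (unique, non-empty).
#' @param reactions data frame with columns `from`, `to`, `k`: source
#'   species, sink species or `"loss"`, and the rate constant in 1/time.
#' @param c0 named numeric vector of initial concentrations, one per
#'   species (names must match `species`).
#'
#' @return An object of class `kinetic_scheme` with elements `species`,
#'   `reactions` and `c0`.
#' @examples
#' kinetic_scheme(c("A", "B"),
#'                data.frame(from = "A", to = "B", k = 0.5),
#'                c(A = 1, B = 0))
#' @export
kinetic_scheme <- function(species, reactions, c0) {
  species <- as.character(species)
  if (length(species) == 0L)
    stop("a kinetic scheme needs at least one species", call. = FALSE)
  if (anyDuplicated(species))
    stop("species labels must be unique", call. = FALSE)
  if (is.null(reactions) || nrow(reactions) == 0L) {
    reactions <- data.frame(from = character(), to = character(),
                            k = numeric(), stringsAsFactors = FALSE)
  }
  reactions <- data.frame(from = as.character(reactions$from),
                          to = as.character(reactions$to),
                          k = as.numeric(reactions$k),
                          stringsAsFactors = FALSE)
  if (any(!is.finite(reactions$k)) || any(reactions$k < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  if (any(!reactions$from %in% species))
    stop("reaction source must be a declared species", call. = FALSE)
  if (any(!reactions$to %in% c(species, "loss")))
    stop("reaction sink must be a declared species or \"loss\"", call. = FALSE)
  if (any(reactions$from == reactions$to))
    stop("a reaction may not have identical source and sink", call. = FALSE)
  c0 <- c0[species]
  if (any(is.na(c0)))
    stop("initial concentrations must cover every species", call. = FALSE)
  if (all(c0 == 0))
    stop("at least one species needs a nonzero initial concentration",
         call. = FALSE)
  structure(list(species = species, reactions = reactions,
                 c0 = stats::setNames(as.numeric(c0), species)),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", length(x$species), " species, ",
      nrow(x$reactions), " reactions\n", sep = "")
  for (i in seq_len(nrow(x$reactions))) {
    r <- x$reactions[i, ]
    cat(sprintf("  %s -> %s : %g\n", r$from, r$to, r$k))
  }
  cat("  c0:", paste(sprintf("%s=%g", x$species, x$c0), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rate matrix of a kinetic scheme
#'
#' Returns the matrix `K` of the linear system `dc/dt = K c`. Off-diagonal
#' entry `K[j, i]` collects flow from species i into species j; each
#' reaction also drains its source on the diagonal (including flow to
#' `"loss"`).
#'
#' @param scheme a [kinetic_scheme()].
#' @return numeric matrix, species x species, dimnames set.
#' @export
rate_matrix <- function(scheme) {
  ns <- length(scheme$species)
  K <- matrix(0, ns, ns, dimnames = list(scheme$species, scheme$species))
  for (i in seq_len(nrow(scheme$reactions))) {
    r <- scheme$reactions[i, ]
    K[r$from, r$from] <- K[r$from, r$from] - r$k
    if (r$to != "loss")
      K[r$to, r$from] <- K[r$to, r$from] + r$k
  }
  K
}

#' Is every sink of a scheme an explicit species?
#'
#' Closed schemes conserve total concentration; schemes with `"loss"`
#' sinks do not.
#' @param scheme a [kinetic_scheme()].
#' @return logical flag.
#' @export
is_closed_scheme <- function(scheme) {
  nrow(scheme$reactions) == 0L || all(scheme$reactions$to != "loss")
}

#' Build a parallel decay model
#'
#' Independently decaying species, one per rate constant, each with unit
#' initial concentration. The concentration profiles are then plain
#' exponentials `exp(-k_i t)`; a rate of zero gives a constant
#' (long-lived) component.
#'
#' @param rates numeric vector of rate constants (1/time), all >= 0.
#' @return a [kinetic_scheme()] with species `S1`, `S2`, ...
#' @examples
#' build_parallel_scheme(c(1 / 1.87, 1 / 34.8, 0))
#' @export
build_parallel_scheme <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) == 0L)
    stop("at least one rate is required", call. = FALSE)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and >= 0", call. = FALSE)
  sp <- paste0("S", seq_along(rates))
  kinetic_scheme(sp,
                 data.frame(from = sp, to = "loss", k = rates,
                            stringsAsFactors = FALSE),
                 stats::setNames(rep(1, length(rates)), sp))
}

#' Build a sequential (cascade) model
#'
#' Chain `S1 -> S2 -> ... -> Sn`, only `S1` initially populated (unit
#' amplitude); each exponential determines the starting amplitude of the
#' next. The last rate is the decay of the terminal species to `"loss"`
#' and may be zero, giving a terminal long-lived species.
#'
#' @inheritParams build_parallel_scheme
#' @return a [kinetic_scheme()].
#' @examples
#' build_sequential_scheme(c(1 / 1.87, 1 / 34.8, 0))
#' @export
build_sequential_scheme <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) == 0L)
    stop("at least one rate is required", call. = FALSE)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and >= 0", call. = FALSE)
  n <- length(rates)
  sp <- paste0("S", seq_len(n))
  to <- c(if (n > 1) sp[2:n], "loss")
  reactions <- data.frame(from = sp, to = to, k = rates,
                          stringsAsFactors = FALSE)
  # k = 0 entries describe non-decaying species; drop the no-op reactions
  reactions <- reactions[reactions$k > 0 | reactions$to != "loss", ]
  kinetic_scheme(sp, reactions,
                 stats::setNames(c(1, rep(0, n - 1)), sp))
}

# Eigen-decomposition (matrix-exponential) solution of dc/dt = K c.
# Returns NULL when eigenvalues collide within 1e-12 relative or the
# eigenvector basis is ill conditioned; the caller then falls back to
# stiff numerical integration.
.concentrations_eigen <- function(K, c0, times) {
  eg <- eigen(K)
  ev <- eg$values
  if (is.complex(ev)) {
    if (max(abs(Im(ev))) > 1e-10 * max(1, max(abs(ev)))) return(NULL)
    ev <- Re(ev)
    V <- Re(eg$vectors)
  } else V <- eg$vectors
  scale <- max(abs(ev), 1)
  d <- outer(ev, ev, function(a, b) abs(a - b))
  diag(d) <- Inf
  if (min(d) <= 1e-12 * scale) return(NULL)   # rate collision
  w <- tryCatch(solve(V, c0), error = function(e) NULL)
  if (is.null(w) || kappa(V) > 1e10) return(NULL)
  E <- exp(outer(times, ev))                  # n_times x n_modes
  E %*% t(V %*% diag(w, length(w)))           # n_times x n_species
}

.concentrations_ode <- function(K, c0, times, tol) {
  t0 <- times[1]
  tt <- times
  prepend <- FALSE
  if (t0 > 0) { tt <- c(0, times); prepend <- TRUE }
  deriv <- function(t, y, parms) list(as.vector(K %*% y))
  sol <- deSolve::lsoda(y = c0, times = tt, func = deriv, parms = NULL,
                        rtol = tol, atol = tol * 1e-3)
  vals <- unname(as.matrix(sol[, -1, drop = FALSE]))
  if (prepend) vals <- vals[-1, , drop = FALSE]
  vals
}

#' Solve a kinetic scheme to concentration profiles
#'
#' Integrates `dc/dt = K c` on the requested delay-time grid. For
#' time-independent first-order schemes the default path is the exact
#' matrix-exponential solution through the eigendecomposition of `K`;
#' when eigenvalues collide within 1e-12 relative (e.g. equal-rate
#' sequential chains) or the eigenvector basis is ill conditioned, a
#' stiff numerical integrator ([deSolve::lsoda()]) is used instead.
#'
#' @param scheme a [kinetic_scheme()].
#' @param times numeric vector of delay times, sorted strictly ascending.
#' @param tolerance relative precision, in `[1e-12, 1e-3]`; default 1e-6.
#' @return An object of class `concentration_matrix`: list with `times`,
#'   `values` (time x species matrix), `species`, `tolerance` and
#'   `method` (`"eigen"` or `"ode"`).
#' @examples
#' sch <- build_sequential_scheme(c(1 / 1.87, 1 / 34.8, 0))
#' cm <- solve_concentrations(sch, c(0, 1, 10, 100))
#' cm$values
#' @export
solve_concentrations <- function(scheme, times, tolerance = 1e-6) {
  times <- as.numeric(times)
  if (length(times) == 0L || is.unsorted(times, strictly = TRUE))
    stop("times must be sorted strictly ascending", call. = FALSE)
  if (!is.numeric(tolerance) || tolerance < 1e-12 || tolerance > 1e-3)
    stop("tolerance must lie in [1e-12, 1e-3]", call. = FALSE)
  K <- rate_matrix(scheme)
  vals <- .concentrations_eigen(K, scheme$c0, times)
  method <- "eigen"
  if (is.null(vals)) {
    vals <- .concentrations_ode(K, scheme$c0, times, tolerance)
    method <- "ode"
  }
  colnames(vals) <- scheme$species
  structure(list(times = times, values = vals, species = scheme$species,
                 tolerance = tolerance, method = method),
            class = "concentration_matrix")
}

#' @export
print.concentration_matrix <- function(x, ...) {
  cat("<concentration_matrix> ", length(x$times), " times x ",
      length(x$species), " species (", x$method, " path)\n", sep = "")
  invisible(x)
}

#' Serialise a kinetic scheme to a declarative text block
#'
#' Plain-text format: one reaction per line, `A -> B : k` (sink `loss`
#' allowed), plus `init A = c0` lines; `#` starts a comment.
#'
#' @param scheme a [kinetic_scheme()].
#' @param path file to write; if `NULL`, the lines are returned.
#' @return the character lines, invisibly when written to a file.
#' @export
write_scheme <- function(scheme, path = NULL) {
  lines <- c("# photokin kinetic scheme",
             paste("species", paste(scheme$species, collapse = " ")),
             sprintf("%s -> %s : %.17g", scheme$reactions$from,
                     scheme$reactions$to, scheme$reactions$k),
             sprintf("init %s = %.17g", scheme$species, scheme$c0))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a kinetic scheme from its declarative text form
#'
#' @param path file name, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return a [kinetic_scheme()].
#' @export
read_scheme <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  sp_line <- grep("^species\\b", lines, value = TRUE)
  rx_lines <- grep("->", lines, value = TRUE, fixed = TRUE)
  init_lines <- grep("^init\\b", lines, value = TRUE)
  m <- regmatches(rx_lines,
                  regexec("^(\\S+)\\s*->\\s*(\\S+)\\s*:\\s*(\\S+)$", rx_lines))
  if (any(lengths(m) != 4L))
    stop("malformed reaction line in scheme file", call. = FALSE)
  reactions <- data.frame(from = vapply(m, `[`, "", 2L),
                          to = vapply(m, `[`, "", 3L),
                          k = as.numeric(vapply(m, `[`, "", 4L)),
                          stringsAsFactors = FALSE)
  species <- if (length(sp_line))
    strsplit(trimws(sub("^species", "", sp_line[1])), "\\s+")[[1]]
  else unique(c(reactions$from, setdiff(reactions$to, "loss")))
  c0 <- stats::setNames(rep(0, length(species)), species)
  mi <- regmatches(init_lines,
                   regexec("^init\\s+(\\S+)\\s*=\\s*(\\S+)$", init_lines))
  for (p in mi) c0[p[2]] <- as.numeric(p[3])
  kinetic_scheme(species, reactions, c0)
}
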