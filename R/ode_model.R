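#' Construct a set of prophage evolutionary rates
#'
#' The four rates drive the analytical model of prophage gene content:
#' selection on host-beneficial genes (`r_S`), per-gene mutational
#' degradation (`r_D`), lysis/re-infection (`r_L`) and induction (`r_I`).
#' All rates are per prophage generation; the time unit is arbitrary since
#' only the relative magnitudes matter.
#'
#' @param r_S selective benefit rate conferred by the beneficial gene.
#' @param r_D per-gene loss rate through mutational degradation.
#' @param r_L rate of gain through lysis, re-infection and lysogeny.
#' @param r_I induction rate (loss of the host through the lytic switch).
#' @return An object of class `rate_set`: a named numeric vector.
#' @examples
#' rate_set(r_S = 0.52, r_D = 0.01, r_L = 1.2, r_I = 1)
#' @export
rate_set <- function(r_S, r_D, r_L, r_I = 1) {
  r <- c(r_S = r_S, r_D = r_D, r_L = r_L, r_I = r_I)
  if (anyNA(r) || !is.numeric(r) || length(r) != 4L)
    stop("rates must be four non-missing numbers")
  if (any(r < 0))
    stop("all rates must be >= 0; got ", paste(names(r)[r < 0], collapse = ", "))
  structure(r, class = "rate_set")
}

#' Construct a genotype frequency state
#'
#' The state of the analytical model is the vector of frequencies of
#' bacterial genomes carrying each of the eight prophage genotypes,
#' indexed by presence (1) or absence (0) of the Beneficial, Excision and
#' Re-infection genes. `P_000` is the genome whose prophage has been
#' completely lost.
#'
#' @param P111,P011,P101,P110,P001,P010,P100,P000 genotype frequencies;
#'   they must be non-negative and sum to one.
#' @param tol tolerance on the sum-to-one constraint.
#' @return An object of class `genotype_state`: a named numeric vector in
#'   the canonical ordering `P111, P011, P101, P110, P001, P010, P100, P000`.
#' @examples
#' genotype_state(P111 = 1)                 # population founded by full prophages
#' genotype_state(P111 = 0.5, P100 = 0.5)
#' @export
genotype_state <- function(P111 = 0, P011 = 0, P101 = 0, P110 = 0,
                           P001 = 0, P010 = 0, P100 = 0, P000 = 0,
                           tol = 1e-9) {
  p <- c(P111 = P111, P011 = P011, P101 = P101, P110 = P110,
         P001 = P001, P010 = P010, P100 = P100, P000 = P000)
  validate_state(p, tol = tol)
  structure(p, class = "genotype_state")
}

validate_state <- function(p, tol = 1e-6) {
  if (!is.numeric(p) || length(p) != 8L)
    stop("a genotype state must be 8 numeric frequencies")
  if (any(p < -tol))
    stop("genotype frequencies must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("genotype frequencies must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}

#' Mean fitness of the prophage genotype distribution
#'
#' The normalization term of the replicator-style ODE system: the mean net
#' growth rate of the population,
#' \deqn{\phi = (r_L+r_S-r_I)P_{111} + (r_L-r_I)P_{011} + r_S P_{101} +
#'       (r_S-r_I)P_{110} - r_I P_{010} + r_S P_{100},}
#' which keeps the frequencies summing to one.
#'
#' @param state a [genotype_state()] (or an 8-vector in canonical order).
#' @param rates a [rate_set()].
#' @param tol validation tolerance for `state`.
#' @return The scalar mean fitness.
#' @examples
#' r <- rate_set(0.52, 0.01, 1.2, 1)
#' mean_fitness(genotype_state(P111 = 1), r)   # r_L + r_S - r_I = 0.72
#' @export
mean_fitness <- function(state, rates, tol = 1e-6) {
  validate_state(state, tol = tol)
  phi_unchecked(as.numeric(state), rates)
}

phi_unchecked <- function(p, r) {
  (r[["r_L"]] + r[["r_S"]] - r[["r_I"]]) * p[1L] +
    (r[["r_L"]] - r[["r_I"]]) * p[2L] +
    r[["r_S"]] * p[3L] +
    (r[["r_S"]] - r[["r_I"]]) * p[4L] -
    r[["r_I"]] * p[6L] +
    r[["r_S"]] * p[7L]
}

# Time derivative of the eight genotype frequencies. Degradation moves
# density down the gene-loss lattice at r_D per gene; induction removes
# excision-carrying genotypes at r_I; r_L feeds back into P111/P011; the
# phi terms renormalize. Written for a bare numeric 8-vector so the
# integrator can call it without validation overhead.
dstate_unchecked <- function(p, r) {
  r_S <- r[["r_S"]]; r_D <- r[["r_D"]]; r_L <- r[["r_L"]]; r_I <- r[["r_I"]]
  phi <- phi_unchecked(p, r)
  c(
    (r_L + r_S - 3 * r_D - r_I) * p[1L] - phi * p[1L],
    (r_L - 2 * r_D - r_I) * p[2L] + r_D * p[1L] - phi * p[2L],
    (r_S - 2 * r_D) * p[3L] + r_D * p[1L] - phi * p[3L],
    (r_S - 2 * r_D - r_I) * p[4L] + r_D * p[1L] - phi * p[4L],
    -r_D * p[5L] + r_D * p[2L] + r_D * p[3L] - phi * p[5L],
    (-r_D - r_I) * p[6L] + r_D * p[2L] + r_D * p[4L] - phi * p[6L],
    (r_S - r_D) * p[7L] + r_D * p[3L] + r_D * p[4L] - phi * p[7L],
    r_D * (p[7L] + p[6L] + p[5L]) - phi * p[8L]
  )
}

#' Time derivative of the genotype frequencies
#'
#' Evaluates the right-hand side of the eight-genotype selection/degradation
#' ODE system at a state. Frequency conservation holds exactly: the eight
#' components sum to zero.
#'
#' @inheritParams mean_fitness
#' @return A named numeric 8-vector `dP/dt` in canonical genotype order.
#' @examples
#' r <- rate_set(0.52, 0.01, 1.2, 1)
#' ode_derivative(genotype_state(P111 = 1), r)  # -3 r_D for P111, r_D into each double
#' @export
ode_derivative <- function(state, rates, tol = 1e-6) {
  validate_state(state, tol = tol)
  setNames(dstate_unchecked(as.numeric(state), rates), GENOTYPES)
}

#' Numerically integrate the genotype dynamics
#'
#' Integrates the eight-genotype system with a stiff-safe adaptive solver
#' (`deSolve::lsoda`). States are stored as computed -- there is no hard
#' renormalization that could mask numerical drift -- and the final sum of
#' frequencies is required to stay within `1e-6` of one.
#'
#' @param rates a [rate_set()].
#' @param initial starting [genotype_state()]; defaults to a population
#'   founded entirely by full prophages (`P111 = 1`).
#' @param duration total integration time (same arbitrary unit as the rates).
#' @param n_out number of stored time points (including time 0).
#' @param rtol,atol relative/absolute solver tolerances.
#' @return An object of class `ode_trajectory`: a data frame with a `time`
#'   column and one column per genotype frequency.
#' @examples
#' tr <- ode_integrate(rate_set(0.52, 0.01, 0.2, 1), duration = 50)
#' tail(mean_gene_counts(tr), 1)   # domestication: B -> 1, E and R -> 0
#' @export
ode_integrate <- function(rates, initial = genotype_state(P111 = 1),
                          duration, n_out = 201L,
                          rtol = 1e-8, atol = 1e-10) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  validate_state(initial, tol = 1e-6)
  times <- seq(0, duration, length.out = n_out)
  rhs <- function(t, y, parms) list(dstate_unchecked(y, parms))
  sol <- deSolve::lsoda(y = setNames(as.numeric(initial), GENOTYPES),
                        times = times, func = rhs, parms = rates,
                        rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0)
    stop("ODE solver failed (istate = ", diagn[1L], ") for rates ",
         paste(sprintf("%s=%g", names(rates), rates), collapse = ", "))
  out <- as.data.frame(unclass(sol))
  final_sum <- sum(out[nrow(out), GENOTYPES])
  if (abs(final_sum - 1) > 1e-6)
    stop("frequency drift exceeded tolerance: final sum = ", format(final_sum))
  structure(out, class = c("ode_trajectory", "data.frame"), rates = rates)
}

#' Mean number of genes of each class per bacterial genome
#'
#' For a genotype state, the average number of beneficial genes per genome
#' is the total frequency of genotypes carrying the B gene (and likewise for
#' E and R); equivalently, the fraction of genomes carrying that gene.
#'
#' @param state a [genotype_state()], an `ode_trajectory`, or a numeric
#'   8-vector in canonical order.
#' @return For a single state, a named numeric vector `c(B, E, R)`; for a
#'   trajectory, a data frame with columns `time`, `B`, `E`, `R`.
#' @examples
#' mean_gene_counts(genotype_state(P111 = 0.5, P100 = 0.5))  # (1, 0.5, 0.5)
#' @export
mean_gene_counts <- function(state) {
  if (inherits(state, "ode_trajectory")) {
    m <- as.matrix(state[GENOTYPES])
    return(data.frame(time = state$time,
                      B = rowSums(m[, c("P111", "P110", "P101", "P100"), drop = FALSE]),
                      E = rowSums(m[, c("P111", "P110", "P011", "P010"), drop = FALSE]),
                      R = rowSums(m[, c("P111", "P101", "P011", "P001"), drop = FALSE])))
  }
  p <- setNames(as.numeric(state), GENOTYPES)
  c(B = unname(p["P111"] + p["P110"] + p["P101"] + p["P100"]),
    E = unname(p["P111"] + p["P110"] + p["P011"] + p["P010"]),
    R = unname(p["P111"] + p["P101"] + p["P011"] + p["P001"]))
}

#' Classify the long-term regime from the rates
#'
#' Two threshold conditions determine which prophage gene classes persist:
#' beneficial genes persist when `r_S > r_D` (a beneficial gene copies
#' itself faster than it degrades), and the excision/re-infection gene
#' combination persists when `r_L > 2 r_D + r_I` (re-infection outruns
#' degradation of either gene plus loss through induction). The four
#' combinations give extinction, domestication, parasitism and persistence.
#' Boundary equalities are classified as non-persistence for that gene set
#' (marginal stability), with a warning.
#'
#' @param rates a [rate_set()].
#' @return One of `"extinction"`, `"domestication"`, `"parasitism"`,
#'   `"persistence"`.
#' @examples
#' classify_regime(rate_set(0.52, 0.01, 1.2, 1))  # persistence
#' classify_regime(rate_set(0.01, 0.1, 0.2, 1))   # extinction
#' @export
classify_regime <- function(rates) {
  r <- unclass(rate_set(rates[["r_S"]], rates[["r_D"]], rates[["r_L"]], rates[["r_I"]]))
  if (r[["r_S"]] == r[["r_D"]])
    warning("r_S == r_D: boundary case classified as B not persisting")
  if (r[["r_L"]] == 2 * r[["r_D"]] + r[["r_I"]])
    warning("r_L == 2 r_D + r_I: boundary case classified as ER not persisting")
  b <- r[["r_S"]] > r[["r_D"]]
  er <- r[["r_L"]] > 2 * r[["r_D"]] + r[["r_I"]]
  regime_from_flags(b, er)
}

regime_from_flags <- function(b_persists, er_persists) {
  if (b_persists && er_persists) "persistence"
  else if (b_persists) "domestication"
  else if (er_persists) "parasitism"
  else "extinction"
}

#' Infer the realized regime from a trajectory
#'
#' Maps the final mean gene counts of an integrated trajectory to a regime:
#' the beneficial gene persists if its final mean exceeds `tol`, and the
#' excision/re-infection combination persists if both the E and R means
#' exceed `tol`. The trajectory must have converged: the mean-gene-count
#' vectors at the last two stored time points must differ by less than
#' `tol`, otherwise the result is `"undetermined"` rather than a guess.
#'
#' @param trajectory an `ode_trajectory` from [ode_integrate()].
#' @param tol convergence and persistence tolerance on mean gene counts.
#' @return One of the four regime labels, or `"undetermined"`.
#' @export
infer_outcome <- function(trajectory, tol = 1e-3) {
  stopifnot(inherits(trajectory, "ode_trajectory"))
  mg <- mean_gene_counts(trajectory)
  n <- nrow(mg)
  if (n < 2L) stop("trajectory must contain at least two time points")
  last <- as.numeric(mg[n, c("B", "E", "R")])
  prev <- as.numeric(mg[n - 1L, c("B", "E", "R")])
  if (max(abs(last - prev)) >= tol) return("undetermined")
  regime_from_flags(last[1L] > tol, min(last[2L], last[3L]) > tol)
}

#' Integrate until the regime can be read off
#'
#' Convenience wrapper around [ode_integrate()] and [infer_outcome()] that
#' doubles the integration horizon until the trajectory has converged (or a
#' cap is reached).
#'
#' @inheritParams ode_integrate
#' @param t0 initial horizon.
#' @param t_max horizon cap.
#' @param tol tolerance passed to [infer_outcome()].
#' @return As [infer_outcome()].
#' @export
ode_outcome <- function(rates, initial = genotype_state(P111 = 1),
                        t0 = 200, t_max = 25600, tol = 1e-3) {
  t <- t0
  repeat {
    out <- infer_outcome(ode_integrate(rates, initial, duration = t), tol = tol)
    if (out != "undetermined" || t >= t_max) return(out)
    t <- t * 2
  }
}

#' Rate grid for threshold-vs-integration comparisons
#'
#' Builds a factorial grid over the four rates and drops combinations lying
#' within `margin` of either persistence boundary (`r_S = r_D` or
#' `r_L = 2 r_D + r_I`), where the dynamics are marginal and numerical
#' classification is ill-posed.
#'
#' @param r_S,r_D,r_L,r_I numeric vectors of candidate rates.
#' @param margin minimum absolute distance from each boundary.
#' @return A data frame with columns `r_S`, `r_D`, `r_L`, `r_I`.
#' @export
rate_grid <- function(r_S = c(0.03, 0.25, 0.6, 1.0),
                      r_D = c(0.02, 0.1, 0.35),
                      r_L = c(0.3, 0.7, 1.0, 1.45, 2.0, 2.6),
                      r_I = 1, margin = 0.05) {
  g <- expand.grid(r_S = r_S, r_D = r_D, r_L = r_L, r_I = r_I,
                   KEEP.OUT.ATTRS = FALSE)
  keep <- abs(g$r_S - g$r_D) > margin &
    abs(g$r_L - (2 * g$r_D + g$r_I)) > margin
  g[keep, , drop = FALSE]
}
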