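#' Configuration for the individual-based prophage simulator
#'
#' A full prophage carries `n_B` beneficial, `n_E` excision, `n_R`
#' re-infection and `n_N` neutral genes; the defaults (1:1:8, no neutral
#' genes) follow the approximate partition of the phage lambda genome into
#' host-beneficial, lytic-switch and particle-production/lysogeny genes.
#' Rates are per prophage generation; one simulation timestep is a bacterial
#' generation of length `dt` prophage generations, so an event with rate `r`
#' occurs with probability `r * dt` per step. The approximation requires
#' `max(r) * dt <= 0.1`, which is enforced.
#'
#' @param n_B,n_E,n_R,n_N gene counts per class (non-negative integers,
#'   at least one gene in total).
#' @param r_D,r_I,r_L,r_S,r_T rates of gene deletion, induction,
#'   re-infection, selection, and TE disruption (all >= 0).
#' @param K bacterial carrying capacity (positive integer).
#' @param dt bacterial generation as a fraction of a prophage generation.
#' @param n_steps number of bacterial generations to simulate.
#' @param seed RNG seed used by [run_simulation()].
#' @param intact_mode how [classify_prophage()] defines "intact":
#'   `"strict"` (all excision and re-infection genes functional) or
#'   `"threshold"` (at least `theta` of all genes present, as a
#'   sequence-based detector would see them).
#' @param theta intact threshold fraction for `intact_mode = "threshold"`.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' sim_config(r_D = 0.05, r_I = 1, r_L = 1.5, r_S = 1.5, K = 1000, n_steps = 500)
#' @export
sim_config <- function(n_B = 1L, n_E = 1L, n_R = 8L, n_N = 0L,
                       r_D, r_I = 1, r_L, r_S, r_T = 0,
                       K, dt = 0.01, n_steps, seed = 1L,
                       intact_mode = c("strict", "threshold"),
                       theta = 0.8) {
  intact_mode <- match.arg(intact_mode)
  cfg <- list(n_B = as.integer(n_B), n_E = as.integer(n_E),
              n_R = as.integer(n_R), n_N = as.integer(n_N),
              r_D = r_D, r_I = r_I, r_L = r_L, r_S = r_S, r_T = r_T,
              K = as.integer(K), dt = dt, n_steps = as.integer(n_steps),
              seed = as.integer(seed), intact_mode = intact_mode,
              theta = theta)
  genes <- c(cfg$n_B, cfg$n_E, cfg$n_R, cfg$n_N)
  if (any(genes < 0L)) stop("gene counts must be non-negative")
  if (sum(genes) < 1L) stop("a prophage must contain at least one gene")
  rates <- c(r_D = cfg$r_D, r_I = cfg$r_I, r_L = cfg$r_L,
             r_S = cfg$r_S, r_T = cfg$r_T)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (cfg$dt <= 0) stop("dt must be > 0")
  if (max(rates) * cfg$dt > 0.1)
    stop("max(rate) * dt = ", format(max(rates) * cfg$dt),
         " exceeds 0.1; the per-step probability approximation breaks down")
  if (cfg$K < 1L) stop("carrying capacity K must be positive")
  if (cfg$n_steps < 1L) stop("n_steps must be positive")
  if (cfg$n_B == 0L && cfg$r_S > 0)
    stop("r_S > 0 requires n_B >= 1 (selection copy probability is r_S dt n_b/n_B)")
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  structure(cfg, class = "sim_config")
}

gene_class_index <- function(config) {
  rep(c("B", "E", "R", "N"),
      times = c(config$n_B, config$n_E, config$n_R, config$n_N))
}

#' Initialize a bacterial population of full prophages
#'
#' All `K` genomes start with every gene present and no TE disruptions.
#'
#' @param config a [sim_config()].
#' @return An object of class `abm_population`: a list with logical matrix
#'   `present` and integer matrix `te` (`K` genomes by genes, columns laid
#'   out `[B | E | R | N]`), and the generation index.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_B + config$n_E + config$n_R + config$n_N
  new_population(matrix(TRUE, config$K, G),
                 matrix(0L, config$K, G), generation = 0L)
}

new_population <- function(present, te, generation = 0L) {
  stopifnot(all(dim(present) == dim(te)), all(te[!present] == 0L))
  structure(list(present = present, te = te, generation = generation),
            class = "abm_population")
}

#' @export
print.abm_population <- function(x, ...) {
  cat("<abm_population> ", nrow(x$present), " genomes x ", ncol(x$present),
      " genes, generation ", x$generation, "\n", sep = "")
  invisible(x)
}

functional_matrix <- function(pop) pop$present & pop$te == 0L

block_cols <- function(config, classes) {
  which(gene_class_index(config) %in% classes)
}

er_intact <- function(pop, config) {
  cols <- block_cols(config, c("E", "R"))
  if (length(cols) == 0L) return(rep(TRUE, nrow(pop$present)))
  rowSums(functional_matrix(pop)[, cols, drop = FALSE]) == length(cols)
}

#' Elementary simulation steps (reference implementation)
#'
#' These functions apply one sub-step of a simulated bacterial generation to
#' a population, in plain vectorized R. They define the model semantics and
#' are cross-checked against the compiled whole-run engine used by
#' [run_simulation()].
#'
#' * `step_degrade()`: each present gene is deleted (and its TE record
#'   erased -- deletion removes the sequence, IS copies included) with
#'   probability `r_D * dt`.
#' * `step_te()`: each present gene sustains a TE disruption with
#'   probability `r_T * dt`; disrupted genes stay present (the transposase
#'   signature remains visible) but are non-functional, and repeated hits
#'   accumulate.
#' * `step_induce()`: each genome whose excision genes are all functional is
#'   removed (host lysed) with probability `r_I * dt`.
#' * `step_reproduce_pool()`: every genome contributes one copy to the pool;
#'   an additional copy with probability `r_S * dt * n_b / n_B` where `n_b`
#'   is its number of functional beneficial genes; and, independently, an
#'   additional copy with probability `r_L * dt` if all excision and
#'   re-infection genes are functional.
#' * `step_regulate()`: if the pool exceeds the carrying capacity `K`, each
#'   genome is retained independently with probability `K / N`.
#'
#' @param pop an `abm_population`.
#' @param config a [sim_config()].
#' @return The transformed `abm_population`.
#' @name abm_steps
NULL

#' @rdname abm_steps
#' @export
step_degrade <- function(pop, config) {
  p <- config$r_D * config$dt
  if (p > 0 && length(pop$present) > 0L) {
    del <- pop$present & matrix(runif(length(pop$present)) < p,
                                nrow(pop$present))
    pop$present[del] <- FALSE
    pop$te[del] <- 0L
  }
  pop
}

#' @rdname abm_steps
#' @export
step_te <- function(pop, config) {
  p <- config$r_T * config$dt
  if (p > 0 && length(pop$present) > 0L) {
    hit <- pop$present & matrix(runif(length(pop$present)) < p,
                                nrow(pop$present))
    pop$te[hit] <- pop$te[hit] + 1L
  }
  pop
}

#' @rdname abm_steps
#' @export
step_induce <- function(pop, config) {
  p <- config$r_I * config$dt
  n <- nrow(pop$present)
  if (p <= 0 || n == 0L) return(pop)
  ecols <- block_cols(config, "E")
  inducible <- if (length(ecols) == 0L) rep(TRUE, n) else
    rowSums(functional_matrix(pop)[, ecols, drop = FALSE]) == length(ecols)
  lysed <- inducible & runif(n) < p
  new_population(pop$present[!lysed, , drop = FALSE],
                 pop$te[!lysed, , drop = FALSE], pop$generation)
}

#' @rdname abm_steps
#' @export
step_reproduce_pool <- function(pop, config) {
  n <- nrow(pop$present)
  if (n == 0L) return(pop)
  if (config$n_B == 0L && config$r_S > 0)
    stop("r_S > 0 with n_B = 0: selection probability undefined")
  keep <- seq_len(n)
  extra <- integer(0)
  if (config$r_S > 0) {
    bcols <- block_cols(config, "B")
    nb <- rowSums(functional_matrix(pop)[, bcols, drop = FALSE])
    sel <- runif(n) < config$r_S * config$dt * nb / config$n_B
    extra <- c(extra, which(sel))
  }
  if (config$r_L > 0) {
    lys <- er_intact(pop, config) & runif(n) < config$r_L * config$dt
    extra <- c(extra, which(lys))
  }
  idx <- c(keep, extra)
  new_population(pop$present[idx, , drop = FALSE],
                 pop$te[idx, , drop = FALSE], pop$generation)
}

#' @rdname abm_steps
#' @export
step_regulate <- function(pop, config) {
  n <- nrow(pop$present)
  if (n <= config$K) return(pop)
  kept <- runif(n) < config$K / n
  new_population(pop$present[kept, , drop = FALSE],
                 pop$te[kept, , drop = FALSE], pop$generation)
}

# One full bacterial generation composed from the reference steps.
step_generation <- function(pop, config) {
  pop <- step_degrade(pop, config)
  pop <- step_te(pop, config)
  pop <- step_induce(pop, config)
  pop <- step_reproduce_pool(pop, config)
  pop <- step_regulate(pop, config)
  pop$generation <- pop$generation + 1L
  pop
}
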