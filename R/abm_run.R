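#' Run the individual-based prophage simulation
#'
#' Simulates `n_steps` bacterial generations of a population of `K` genomes
#' founded with full prophages, applying per generation: gene deletion, TE
#' disruption, induction, reproduction (baseline + selection + re-infection
#' copies) and carrying-capacity regulation. The whole-population loop runs
#' in compiled code; semantics match the reference [step_degrade()] family.
#' Runs are bit-reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param record_every recording stride in generations.
#' @param halt_on_extinction if `TRUE`, stop early once the population is
#'   empty (remaining scheduled records are emitted as zero-size rows);
#'   if `FALSE` (default) the run continues emitting zero-size records.
#' @param return_population if `TRUE` (default) attach the final population.
#' @return An object of class `abm_run`: a list with
#'   \describe{
#'     \item{summary}{data frame, one row per recorded generation: population
#'       size, mean functional gene count per class per genome, mean TE count
#'       per class per genome, and the fraction of genomes with all excision
#'       and re-infection genes functional.}
#'     \item{population}{the final `abm_population` (or `NULL`).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cfg <- sim_config(r_D = 0.1, r_I = 1, r_L = 0.2, r_S = 0.01,
#'                   K = 200, n_steps = 400, seed = 7)
#' run <- run_simulation(cfg, record_every = 100)
#' tail(run$summary)   # extinction: all gene means decay toward 0
#' @export
run_simulation <- function(config, record_every = 50L,
                           halt_on_extinction = FALSE,
                           return_population = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  record_every <- as.integer(record_every)
  stopifnot(record_every >= 1L)
  set.seed(config$seed)
  res <- abm_run_cpp(config$n_B, config$n_E, config$n_R, config$n_N,
                     config$r_D, config$r_I, config$r_L, config$r_S,
                     config$r_T, config$K, config$dt, config$n_steps,
                     record_every, halt_on_extinction)
  summary <- as.data.frame(res$summary)
  pop <- NULL
  if (return_population) {
    pres <- matrix(as.logical(res$present), nrow = nrow(res$present),
                   ncol = ncol(res$present))
    pop <- new_population(pres, res$te,
                          generation = as.integer(config$n_steps))
  }
  structure(list(summary = summary, population = pop, config = config,
                 halted = res$halted),
            class = "abm_run")
}

#' @export
print.abm_run <- function(x, ...) {
  n <- nrow(x$summary)
  cat("<abm_run> ", x$config$n_steps, " generations, K = ", x$config$K,
      "; final population ", x$summary$pop_size[n], "\n", sep = "")
  invisible(x)
}

#' Predicted long-term outcome of a simulator configuration
#'
#' Generalization of the analytical two-condition table to multi-gene
#' prophages with TE disruption: the beneficial function persists when
#' `r_S > r_D + r_T`; the excision/re-infection function, which is lost by
#' deletion or disruption of any of its `n_E + n_R` genes or by induction,
#' persists when `r_L > (n_E + n_R) (r_D + r_T) + r_I`. TE disruption acts
#' as additional per-gene loss on top of mutational degradation.
#'
#' @param config a [sim_config()].
#' @return One of `"extinction"`, `"domestication"`, `"parasitism"`,
#'   `"persistence"`.
#' @examples
#' predicted_outcome(sim_config(r_D = 0.05, r_I = 1, r_L = 1.5, r_S = 1.5,
#'                              K = 1000, n_steps = 100))  # persistence
#' @export
predicted_outcome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  loss <- config$r_D + config$r_T
  b <- config$r_S > loss
  er <- config$r_L > (config$n_E + config$n_R) * loss + config$r_I
  regime_from_flags(b, er)
}

#' Realized outcome of a finished simulation
#'
#' Classifies which gene functions persisted in a run from its recorded
#' summary series. The excision/re-infection function persists if the final
#' fraction of genomes carrying all E and R genes functional exceeds
#' `tol_er`. The beneficial function persists if the final functional-B
#' frequency exceeds `tol_b` *and* is not in material exponential decline:
#' because selection differentials can be far slower than the simulated
#' horizon, a log-linear trend is fitted over the second half of the series,
#' and B is called transient when the slope is negative beyond three
#' standard errors *and* the fitted trend sheds more than 10% of the
#' frequency across the window (drift on an equilibrium series produces
#' nominally significant but immaterial slopes). Final levels are averaged
#' over the last tenth of the records to damp sampling noise.
#'
#' @param run an `abm_run` from [run_simulation()].
#' @param tol_b persistence threshold on the functional-B frequency.
#' @param tol_er persistence threshold on the ER-intact genome fraction.
#' @return One of the four regime labels.
#' @export
realized_outcome <- function(run, tol_b = 0.05, tol_er = 0.01) {
  stopifnot(inherits(run, "abm_run"))
  s <- run$summary
  cfg <- run$config
  n <- nrow(s)
  tail_rows <- seq.int(max(1L, n - max(1L, n %/% 10L) + 1L), n)
  f_er <- mean(s$frac_er_intact[tail_rows])
  f_b <- if (cfg$n_B > 0) mean(s$func_B[tail_rows]) / cfg$n_B else 0
  b_persists <- f_b > tol_b
  if (b_persists) {
    half <- s[seq.int(n %/% 2L, n), , drop = FALSE]
    fb <- pmax(half$func_B / cfg$n_B, 1e-12)
    # trend in units of prophage generations
    t_pg <- half$generation * cfg$dt
    fit <- lm(log(fb) ~ t_pg)
    slope <- coef(fit)[["t_pg"]]
    se <- sqrt(vcov(fit)["t_pg", "t_pg"])
    # transient only if the decline is both significant and material: the
    # fitted trend must shed more than 10% of the frequency across the
    # window (drift noise on an autocorrelated equilibrium series produces
    # nominally significant but immaterial slopes)
    material <- slope * (max(t_pg) - min(t_pg)) < log(0.9)
    if (is.finite(se) && se > 0 && slope < -3 * se && material)
      b_persists <- FALSE
  }
  regime_from_flags(b_persists, f_er > tol_er)
}

#' Classify prophages as intact or incomplete
#'
#' Two operational definitions are supported. `"strict"`: a prophage is
#' intact iff all of its excision and re-infection genes are functional
#' (present and undisrupted) -- the model-level notion of retaining full
#' lytic function. `"threshold"`: a prophage is intact iff at least `theta`
#' of its possible genes are *present*, TE-disrupted genes included --
#' emulating a sequence-based detector, which sees a disrupted gene as
#' present.
#'
#' @param pop an `abm_population`.
#' @param config a [sim_config()]; `config$intact_mode` and `config$theta`
#'   supply the defaults.
#' @param mode,theta optional overrides of the configured mode/threshold.
#' @return A character vector (`"intact"`/`"incomplete"`), one per genome.
#' @export
classify_prophage <- function(pop, config, mode = config$intact_mode,
                              theta = config$theta) {
  mode <- match.arg(mode, c("strict", "threshold"))
  n <- nrow(pop$present)
  if (mode == "strict") {
    intact <- er_intact(pop, config)
  } else {
    G <- ncol(pop$present)
    intact <- rowSums(pop$present) / G >= theta
  }
  ifelse(intact, "intact", "incomplete")
}

#' Gene-class repertoire of intact versus incomplete prophages
#'
#' For each gene class (B, E, R, N) the frequency is the number of present
#' genes of that class divided by the total number of present genes, within
#' each completeness stratum. The transposase signature is an overlay: the
#' fraction of present genes bearing at least one TE disruption. Percent
#' change from intact to incomplete uses [percent_change()], or `NA` where
#' the intact frequency is zero (change from an empty baseline is
#' undefined).
#'
#' @inheritParams classify_prophage
#' @return A data frame with one row per class (`B`, `E`, `R`, `N`,
#'   `transposase`): frequencies in intact and incomplete prophages and the
#'   percent change between them.
#' @export
repertoire_summary <- function(pop, config, mode = config$intact_mode,
                               theta = config$theta) {
  status <- classify_prophage(pop, config, mode, theta)
  if (!any(status == "intact") || !any(status == "incomplete"))
    stop("repertoire comparison needs at least one intact and one ",
         "incomplete prophage (got ", sum(status == "intact"), " intact of ",
         length(status), ")")
  cls <- gene_class_index(config)
  stratum_freq <- function(rows) {
    pres <- pop$present[rows, , drop = FALSE]
    total <- sum(pres)
    if (total == 0L)
      stop("stratum contains no present genes; frequencies undefined")
    by_class <- vapply(c("B", "E", "R", "N"), function(k)
      sum(pres[, cls == k, drop = FALSE]) / total, numeric(1))
    te_sig <- sum(pop$te[rows, , drop = FALSE] > 0L & pres) / total
    c(by_class, transposase = te_sig)
  }
  f_int <- stratum_freq(status == "intact")
  f_inc <- stratum_freq(status == "incomplete")
  pct <- ifelse(f_int > 0, 100 * (f_inc - f_int) / f_int, NA_real_)
  data.frame(class = names(f_int), f_intact = unname(f_int),
             f_incomplete = unname(f_inc), pct_change = unname(pct),
             row.names = NULL)
}

#' Length spectrum of a prophage population
#'
#' Prophage length is the number of present genes (genes are the length
#' quantum of the model; TE insertions do not add length). Returns the
#' histogram over lengths `0..G` together with, at each length, the
#' frequency of each gene class among present genes and the overlay
#' frequency of TE-bearing (transposase-signature) genes. Frequencies at
#' length 0 are undefined and reported as `NA`.
#'
#' @inheritParams classify_prophage
#' @return A data frame with columns `length`, `count`, `freq_B`, `freq_E`,
#'   `freq_R`, `freq_N`, `freq_transposase`.
#' @export
length_spectrum <- function(pop, config) {
  G <- ncol(pop$present)
  len <- rowSums(pop$present)
  cls <- gene_class_index(config)
  out <- data.frame(length = 0:G,
                    count = as.vector(table(factor(len, levels = 0:G))))
  freq <- matrix(NA_real_, G + 1L, 5L,
                 dimnames = list(NULL, c("B", "E", "R", "N", "transposase")))
  for (L in seq_len(G)) {
    rows <- which(len == L)
    if (length(rows) == 0L) next
    pres <- pop$present[rows, , drop = FALSE]
    total <- sum(pres)
    freq[L + 1L, 1:4] <- vapply(c("B", "E", "R", "N"), function(k)
      sum(pres[, cls == k, drop = FALSE]) / total, numeric(1))
    freq[L + 1L, 5L] <- sum(pop$te[rows, , drop = FALSE] > 0L & pres) / total
  }
  out$freq_B <- freq[, "B"]; out$freq_E <- freq[, "E"]
  out$freq_R <- freq[, "R"]; out$freq_N <- freq[, "N"]
  out$freq_transposase <- freq[, "transposase"]
  out
}

#' Mean TE burden per gene class
#'
#' Average number of sustained TE disruptions per genome in each gene class,
#' over all genomes in the population (absent genes contribute zero).
#'
#' @inheritParams classify_prophage
#' @return A named numeric vector `c(B, E, R, N)`.
#' @export
te_burden <- function(pop, config) {
  n <- nrow(pop$te)
  cls <- gene_class_index(config)
  vapply(c("B", "E", "R", "N"), function(k) {
    if (n == 0L) return(0)
    sum(pop$te[, cls == k, drop = FALSE]) / n
  }, numeric(1))
}

#' Per-gene rates of mutational loss and transposition
#'
#' Scales literature point estimates to the per-prophage-gene, per-bacterial
#' generation rates used by the simulator: the mutational loss rate is the
#' substitution rate per nucleotide times the gene length; the genome-wide
#' transposition rate is the per-element rate times the IS copy number; the
#' per-gene transposition rate scales the genome-wide rate by the fraction
#' of the host genome one gene occupies.
#'
#' @param substitution_rate substitutions per nucleotide per generation.
#' @param gene_length_kbp prophage gene length in kbp.
#' @param is_rate transpositions per IS element per generation.
#' @param is_copies IS copies in the host genome.
#' @param genome_mbp host genome size in Mbp.
#' @return A named list: `mutation_per_gene`, `transposition_genome`,
#'   `transposition_per_gene` (components are `NA` when their inputs are
#'   missing).
#' @examples
#' per_gene_rate_estimates(substitution_rate = 2e-10, gene_length_kbp = 1.2,
#'                         is_rate = 1e-5, is_copies = 33, genome_mbp = 4.6)
#' @export
per_gene_rate_estimates <- function(substitution_rate = NA,
                                    gene_length_kbp = NA,
                                    is_rate = NA, is_copies = NA,
                                    genome_mbp = NA) {
  inputs <- c(substitution_rate, gene_length_kbp, is_rate, is_copies,
              genome_mbp)
  if (any(!is.na(inputs) & inputs <= 0))
    stop("all supplied rate inputs must be > 0")
  mut <- substitution_rate * gene_length_kbp * 1000
  tg <- is_rate * is_copies
  tpg <- tg * gene_length_kbp / (genome_mbp * 1000)
  list(mutation_per_gene = mut, transposition_genome = tg,
       transposition_per_gene = tpg)
}
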