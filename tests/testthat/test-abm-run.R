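test_that("runs are bit-reproducible from the seed", {
  cfg <- sim_config(r_D = 0.05, r_I = 1, r_L = 1.5, r_S = 1.5,
                    K = 200, n_steps = 300, seed = 99)
  a <- run_simulation(cfg, record_every = 50)
  b <- run_simulation(cfg, record_every = 50)
  expect_identical(a$summary, b$summary)
  expect_identical(a$population$present, b$population$present)
  expect_identical(a$population$te, b$population$te)
})

test_that("zero-rate dynamics leave the founding population untouched", {
  cfg <- sim_config(r_D = 0, r_I = 0, r_L = 0, r_S = 0, r_T = 0,
                    K = 50, n_steps = 100, seed = 3)
  run <- run_simulation(cfg, record_every = 20)
  expect_true(all(run$summary$pop_size == 50))
  expect_true(all(run$summary$func_R == 8))
  expect_true(all(run$population$present))
})

test_that("pure decay follows the closed-form survival curve", {
  # only deletion active: each gene survives t steps with prob (1 - r_D dt)^t
  cfg <- sim_config(r_D = 2, r_I = 0, r_L = 0, r_S = 0, dt = 0.001,
                    K = 2000, n_steps = 500, seed = 12)
  run <- run_simulation(cfg, record_every = 100)
  p <- (1 - 2 * 0.001)^run$summary$generation
  frac <- (run$summary$func_B + run$summary$func_E + run$summary$func_R) / 10
  se <- sqrt(p * (1 - p) / (2000 * 10))
  expect_true(all(abs(frac - p) <= pmax(3 * se, 1e-12)))
})

test_that("extinction parameters drive all gene means to zero", {
  cfg <- sim_config(r_D = 0.1, r_I = 1, r_L = 0.2, r_S = 0.01,
                    K = 300, n_steps = 8000, seed = 8)
  run <- run_simulation(cfg, record_every = 500)
  last <- run$summary[nrow(run$summary), ]
  expect_lt(last$func_B + last$func_E + last$func_R, 0.05)
  expect_identical(realized_outcome(run), "extinction")
})

test_that("halting on extinction still emits the scheduled records", {
  # certain induction at full excision complement, nothing else: the first
  # generation lyses every host
  cfg <- sim_config(r_D = 0, r_I = 10, r_L = 0, r_S = 0, dt = 0.01,
                    K = 30, n_steps = 200, seed = 2)
  cfg$r_I <- 100  # probability 1 per step
  run <- run_simulation(cfg, record_every = 50, halt_on_extinction = TRUE)
  expect_true(run$halted)
  expect_equal(run$summary$generation, c(0, 50, 100, 150, 200))
  expect_equal(run$summary$pop_size[-1], rep(0, 4))
})

test_that("predicted outcomes follow the generalized loss-gain balance", {
  base <- function(...) sim_config(K = 100, n_steps = 10, ...)
  # 9 excision/re-infection genes: loss 9(0.05)+1 = 1.45 < r_L = 1.5
  expect_identical(predicted_outcome(base(r_D = 0.05, r_I = 1, r_L = 1.5,
                                          r_S = 1.5)), "persistence")
  # TE disruption adds to per-gene loss: 9(0.011)+1 = 1.099 < 1.2, r_S below
  expect_identical(predicted_outcome(base(r_D = 0.001, r_I = 1, r_L = 1.2,
                                          r_S = 0.01, r_T = 0.01, n_N = 1)),
                   "parasitism")
  # 9(0.101)+1 > 1.2 and r_S < r_D + r_T
  expect_identical(predicted_outcome(base(r_D = 0.001, r_I = 1, r_L = 1.2,
                                          r_S = 0.002, r_T = 0.1, n_N = 1)),
                   "extinction")
})

test_that("intactness definitions agree with the strict/threshold semantics", {
  cfg <- sim_config(r_D = 0.1, r_I = 1, r_L = 1, r_S = 1, K = 4,
                    n_steps = 10, theta = 0.8)
  full <- make_pop(matrix(TRUE, 1, 10))
  expect_identical(classify_prophage(full, cfg, mode = "strict"), "intact")
  expect_identical(classify_prophage(full, cfg, mode = "threshold"), "intact")
  # one re-infection gene deleted: strict incomplete, threshold intact (9/10)
  oneR <- matrix(TRUE, 1, 10); oneR[1, 10] <- FALSE
  popR <- make_pop(oneR)
  expect_identical(classify_prophage(popR, cfg, mode = "strict"), "incomplete")
  expect_identical(classify_prophage(popR, cfg, mode = "threshold"), "intact")
  # TE-disrupted excision gene: strict incomplete, threshold intact (present)
  te <- matrix(0L, 1, 10); te[1, 2] <- 1L
  popT <- make_pop(matrix(TRUE, 1, 10), te)
  expect_identical(classify_prophage(popT, cfg, mode = "strict"), "incomplete")
  expect_identical(classify_prophage(popT, cfg, mode = "threshold"), "intact")
})

test_that("repertoire summary computes stratified frequencies and errors on empty strata", {
  cfg <- sim_config(r_D = 0.1, r_I = 1, r_L = 1, r_S = 1, K = 3,
                    n_steps = 10)
  all_full <- make_pop(matrix(TRUE, 3, 10))
  expect_error(repertoire_summary(all_full, cfg), "at least one")
  # one full prophage + one reduced to B only + one with a TE in an R gene
  pres <- matrix(TRUE, 3, 10)
  pres[2, 2:10] <- FALSE
  te <- matrix(0L, 3, 10); te[3, 5] <- 2L
  pop <- make_pop(pres, te)
  rs <- repertoire_summary(pop, cfg, mode = "strict")
  # intact stratum = genome 1 only (10 genes: 1 B, 1 E, 8 R)
  expect_equal(rs$f_intact[rs$class == "B"], 0.1)
  expect_equal(rs$f_intact[rs$class == "R"], 0.8)
  # incomplete stratum = genomes 2 and 3: 11 present genes, 2 B, 1 TE-bearing
  expect_equal(rs$f_incomplete[rs$class == "B"], 2 / 11)
  expect_equal(rs$f_incomplete[rs$class == "transposase"], 1 / 11)
  expect_equal(rs$pct_change[rs$class == "B"],
               100 * (2 / 11 - 0.1) / 0.1)
})

test_that("length spectrum puts an all-full population at maximum length", {
  cfg <- sim_config(r_D = 0.1, r_I = 1, r_L = 1, r_S = 1, K = 5, n_steps = 5)
  pop <- make_pop(matrix(TRUE, 5, 10))
  ls <- length_spectrum(pop, cfg)
  expect_equal(ls$count, c(rep(0, 10), 5))
  expect_equal(ls$freq_B[ls$length == 10], 0.1)
  expect_true(all(is.na(ls$freq_B[ls$count == 0])))
})

test_that("TE burden averages disruption counts over the population", {
  cfg <- sim_config(n_N = 1, r_D = 0.1, r_I = 1, r_L = 1, r_S = 1,
                    K = 1, n_steps = 5)
  te <- matrix(0L, 1, 11); te[1, 11] <- 3L
  pop <- make_pop(matrix(TRUE, 1, 11), te)
  expect_equal(te_burden(pop, cfg), c(B = 0, E = 0, R = 0, N = 3))
  cfg0 <- sim_config(r_D = 0.05, r_I = 1, r_L = 1.2, r_S = 0.5, r_T = 0,
                     K = 100, n_steps = 200, seed = 4)
  run <- run_simulation(cfg0)
  expect_equal(unname(te_burden(run$population, cfg0)), rep(0, 4))
})

test_that("TEs accumulate most in neutral genes, limited elsewhere by selection", {
  cfg <- sim_config(r_D = 0.001, r_I = 1, r_L = 1.2, r_S = 0.52,
                    r_T = 0.009, n_N = 1, K = 1000, n_steps = 5000,
                    seed = 5)
  run <- run_simulation(cfg)
  burden <- te_burden(run$population, cfg)
  expect_gt(burden[["N"]], max(burden[c("B", "E", "R")]))
})

test_that("literature rate inputs scale to the per-gene rates", {
  est <- per_gene_rate_estimates(substitution_rate = 2e-10,
                                 gene_length_kbp = 1.2,
                                 is_rate = 1e-5, is_copies = 33,
                                 genome_mbp = 4.6)
  expect_equal(est$mutation_per_gene, 2.4e-7)
  expect_equal(est$transposition_genome, 3.3e-4)
  expect_equal(signif(est$transposition_per_gene, 2), 8.6e-8)
  expect_error(per_gene_rate_estimates(substitution_rate = -1e-10,
                                       gene_length_kbp = 1.2), "> 0")
})
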