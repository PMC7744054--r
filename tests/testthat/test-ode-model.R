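test_that("mean fitness matches its closed form", {
  r <- rate_set(r_S = 0.52, r_D = 0.01, r_L = 1.2, r_I = 1)
  expect_equal(mean_fitness(genotype_state(P000 = 1), r), 0)
  expect_equal(mean_fitness(genotype_state(P111 = 1), r), 0.72)
  expect_equal(mean_fitness(genotype_state(P111 = 0.5, P100 = 0.5), r),
               0.5 * 0.72 + 0.5 * 0.52)
})

test_that("invalid states and rates are rejected", {
  expect_error(rate_set(-0.1, 0.1, 0.2, 1), "r_S")
  expect_error(genotype_state(P111 = 0.5), "sum to 1")
  expect_error(genotype_state(P111 = 1.5, P000 = -0.5), "non-negative")
  expect_error(mean_fitness(rep(0.2, 8), rate_set(0.1, 0.1, 0.1, 0.1)),
               "sum to 1")
})

test_that("derivative matches closed forms at pure states", {
  r <- rate_set(r_S = 0.52, r_D = 0.01, r_L = 1.2, r_I = 1)
  expect_equal(unname(ode_derivative(genotype_state(P000 = 1), r)),
               rep(0, 8))
  d <- ode_derivative(genotype_state(P111 = 1), r)
  expect_equal(d[["P111"]], -3 * 0.01)
  expect_equal(unname(d[c("P011", "P101", "P110")]), rep(0.01, 3))
  expect_equal(unname(d[c("P001", "P010", "P100", "P000")]), rep(0, 4))
})

test_that("frequency conservation holds for random states and rates", {
  set.seed(421)
  for (i in 1:25) {
    p <- runif(8)
    p <- p / sum(p)
    st <- structure(p, names = prophageContinuum:::GENOTYPES)
    r <- rate_set(runif(1, 0, 2), runif(1, 0, 0.5), runif(1, 0, 3),
                  runif(1, 0, 1.5))
    expect_lt(abs(sum(ode_derivative(st, r))), 1e-12)
  }
})

test_that("the empty-prophage state and the domestication mix are stationary", {
  set.seed(7)
  for (i in 1:10) {
    r <- rate_set(runif(1, 0.1, 1), runif(1, 0.01, 0.09), runif(1, 0, 2), 1)
    expect_equal(unname(ode_derivative(genotype_state(P000 = 1), r)),
                 rep(0, 8))
    # with r_S > r_D, the beneficial-only equilibrium mixes P100 and P000
    eb <- genotype_state(P100 = 1 - r[["r_D"]] / r[["r_S"]],
                         P000 = r[["r_D"]] / r[["r_S"]])
    expect_lt(max(abs(ode_derivative(eb, r))), 1e-12)
  }
})

test_that("integration with zero rates leaves the state constant", {
  tr <- ode_integrate(rate_set(0, 0, 0, 0),
                      genotype_state(P111 = 0.3, P010 = 0.2, P000 = 0.5),
                      duration = 10)
  expect_equal(max(abs(tr$P111 - 0.3)), 0, tolerance = 1e-9)
  expect_equal(max(abs(tr$P010 - 0.2)), 0, tolerance = 1e-9)
})

test_that("integration stays non-negative and conserves total frequency", {
  set.seed(11)
  init <- genotype_state(P111 = 0.3, P011 = 0.1, P101 = 0.1, P110 = 0.1,
                         P001 = 0.1, P010 = 0.1, P100 = 0.1, P000 = 0.1)
  for (r in list(rate_set(0.52, 0.01, 1.2, 1), rate_set(0.01, 0.1, 0.2, 1),
                 rate_set(0.02, 0.1, 1.3, 1))) {
    tr <- ode_integrate(r, init, duration = 500)
    expect_gte(min(as.matrix(tr[prophageContinuum:::GENOTYPES])), -1e-8)
    expect_lt(max(abs(rowSums(tr[prophageContinuum:::GENOTYPES]) - 1)), 1e-6)
  }
})

test_that("mean gene counts sum the carrying genotypes", {
  expect_equal(mean_gene_counts(genotype_state(P111 = 1)),
               c(B = 1, E = 1, R = 1))
  expect_equal(mean_gene_counts(genotype_state(P000 = 1)),
               c(B = 0, E = 0, R = 0))
  expect_equal(mean_gene_counts(genotype_state(P111 = 0.5, P100 = 0.5)),
               c(B = 1, E = 0.5, R = 0.5))
})

test_that("threshold conditions classify the four captioned regimes", {
  expect_identical(classify_regime(rate_set(0.52, 0.01, 1.2, 1)), "persistence")
  expect_identical(classify_regime(rate_set(0.52, 0.01, 0.2, 1)), "domestication")
  expect_identical(classify_regime(rate_set(0.02, 0.1, 1.3, 1)), "parasitism")
  expect_identical(classify_regime(rate_set(0.01, 0.1, 0.2, 1)), "extinction")
})

test_that("condition boundaries classify as non-persistence, with a warning", {
  expect_warning(out <- classify_regime(rate_set(0.1, 0.1, 0.2, 1)),
                 "boundary")
  expect_identical(out, "extinction")
  expect_warning(out2 <- classify_regime(rate_set(0.5, 0.1, 1.2, 1)),
                 "boundary")
  expect_identical(out2, "domestication")
})

test_that("trajectory outcomes match captions, and non-convergence is flagged", {
  expect_identical(infer_outcome(ode_integrate(rate_set(0.52, 0.01, 0.2, 1),
                                               duration = 400)),
                   "domestication")
  expect_identical(infer_outcome(ode_integrate(rate_set(0.52, 0.01, 1.2, 1),
                                               duration = 400)),
                   "persistence")
  expect_identical(infer_outcome(ode_integrate(rate_set(0, 0, 0, 0),
                                               genotype_state(P000 = 1),
                                               duration = 5)),
                   "extinction")
  # coarsely sampled, far from equilibrium: the call must say so, not guess
  short <- ode_integrate(rate_set(0.52, 0.01, 1.2, 1), duration = 5,
                         n_out = 3)
  expect_identical(infer_outcome(short), "undetermined")
})

test_that("rate grid is large enough and respects boundary margins", {
  g <- rate_grid()
  expect_gte(nrow(g), 50)
  expect_true(all(abs(g$r_S - g$r_D) > 0.05))
  expect_true(all(abs(g$r_L - (2 * g$r_D + g$r_I)) > 0.05))
})
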