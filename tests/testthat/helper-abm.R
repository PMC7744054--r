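# Build a sim_config without the rate*dt validity guard, for white-box tests
# of step semantics at extreme probabilities (e.g. certain deletion).
mock_config <- function(n_B = 1L, n_E = 1L, n_R = 8L, n_N = 0L,
                        r_D = 0, r_I = 0, r_L = 0, r_S = 0, r_T = 0,
                        K = 10L, dt = 1, n_steps = 1L, seed = 1L,
                        intact_mode = "strict", theta = 0.8) {
  structure(list(n_B = as.integer(n_B), n_E = as.integer(n_E),
                 n_R = as.integer(n_R), n_N = as.integer(n_N),
                 r_D = r_D, r_I = r_I, r_L = r_L, r_S = r_S, r_T = r_T,
                 K = as.integer(K), dt = dt, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), intact_mode = intact_mode,
                 theta = theta),
            class = "sim_config")
}

make_pop <- function(present, te = NULL) {
  if (is.null(te)) te <- matrix(0L, nrow(present), ncol(present))
  prophageContinuum:::new_population(present, te)
}

# The captioned simulation parameter sets and their long-term outcome classes
# (r_I = 1 throughout; n_B = 1, n_E = 1, n_R = 8; neutral gene only in the
# TE-disruption series).
captioned_param_sets <- function() {
  list(
    list(name = "extinction_noTE",    r_S = 0.01,  r_D = 0.1,   r_L = 0.2,
         r_T = 0,     n_N = 0L, expect = "extinction"),
    list(name = "domestication_noTE", r_S = 0.52,  r_D = 0.01,  r_L = 0.2,
         r_T = 0,     n_N = 0L, expect = "domestication"),
    list(name = "parasitism_noTE",    r_S = 0.02,  r_D = 0.1,   r_L = 2.0,
         r_T = 0,     n_N = 0L, expect = "parasitism"),
    list(name = "persistence_noTE",   r_S = 1.5,   r_D = 0.05,  r_L = 1.5,
         r_T = 0,     n_N = 0L, expect = "persistence"),
    list(name = "persistence_TE",     r_S = 0.52,  r_D = 0.001, r_L = 1.2,
         r_T = 0.009, n_N = 1L, expect = "persistence"),
    list(name = "parasitism_TE",      r_S = 0.01,  r_D = 0.001, r_L = 1.2,
         r_T = 0.01,  n_N = 1L, expect = "parasitism"),
    list(name = "extinction_TE",      r_S = 0.002, r_D = 0.001, r_L = 1.2,
         r_T = 0.1,   n_N = 1L, expect = "extinction")
  )
}

# A small annotation table with hand-countable content.
tiny_records <- function() {
  data.frame(
    prophage_id = c("p1", "p1", "p1", "p2", "p2", "p3"),
    genome_id = "g1",
    completeness = c("intact", "intact", "intact",
                     "incomplete", "incomplete", "questionable"),
    length_bp = c(40000L, 40000L, 40000L, 9000L, 9000L, 15000L),
    cds_index = c(1L, 2L, 3L, 1L, 2L, 1L),
    annotation = c("large terminase subunit", "terminase small subunit",
                   "hypothetical protein", "IS3 transposase B",
                   "baseplate assembly protein", "site-specific integrase"),
    stringsAsFactors = FALSE)
}
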