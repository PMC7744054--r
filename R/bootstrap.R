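#' Proportional bootstrap test of gene-class enrichment
#'
#' Null model: a class's genes carry no information about prophage
#' completeness, so its row total is re-assigned at random to the three
#' completeness labels with probabilities proportional to the column totals
#' (e.g. 82% intact / 11% incomplete for the first bundled data set). Each
#' replicate draws a multinomial re-assignment per class and recomputes the
#' intact-to-incomplete percent change; the observed percent change is then
#' compared with the 2.5 and 97.5 empirical percentiles of the replicate
#' distribution (two-sided 5% level). Replicates with a zero intact draw --
#' possible only for very sparse classes -- leave the percent change
#' undefined and are discarded, with the count reported.
#'
#' Empirical percentiles use linear interpolation; ties with the percentile
#' break toward non-significance (flags require strict inequality).
#'
#' @param table a `gene_class_table`.
#' @param n_reps number of bootstrap replicates.
#' @param seed optional seed (an integer) for reproducible flags; when
#'   `NULL` the current RNG stream is used.
#' @param prevalence_threshold row-prevalence threshold used to mark (not
#'   drop) sparse classes; see [apply_prevalence_filter()].
#' @return A data frame with one row per class: frequencies `f_int`, `f_q`,
#'   `f_inc`; observed `pct_change`; the null percentiles `lower`/`upper`;
#'   `flag` (`"depleted"`, `"enriched"` or `"n.s."`); `excluded` (failed the
#'   prevalence filter); and `discarded` (dropped replicates). Attribute
#'   `"null_probs"` carries the assignment proportions.
#' @examples
#' bootstrap_enrichment(table1_fixture(1), n_reps = 1000, seed = 1)
#' @export
bootstrap_enrichment <- function(table, n_reps = 10000L, seed = NULL,
                                 prevalence_threshold = 0.01) {
  stopifnot(inherits(table, "gene_class_table"))
  col_tot <- colSums(table)
  if (any(col_tot == 0))
    stop("zero column total for: ",
         paste(colnames(table)[col_tot == 0], collapse = ", "))
  probs <- col_tot / sum(col_tot)
  if (!is.null(seed)) set.seed(seed)
  retained <- apply_prevalence_filter(table, prevalence_threshold)
  f <- class_frequencies(table)

  res <- lapply(rownames(table), function(k) {
    row_tot <- sum(table[k, ])
    draws <- rmultinom(n_reps, size = row_tot, prob = probs)
    ok <- draws[1L, ] > 0L
    pct_null <- 100 * ((draws[3L, ok] / col_tot[[3L]]) /
                         (draws[1L, ok] / col_tot[[1L]]) - 1)
    q <- quantile(pct_null, c(0.025, 0.975), names = FALSE, type = 7)
    obs <- if (table[k, 1L] > 0)
      percent_change(f[k, "intact"], f[k, "incomplete"]) else NA_real_
    flag <- if (is.na(obs)) NA_character_
    else if (obs < q[1L]) "depleted"
    else if (obs > q[2L]) "enriched"
    else "n.s."
    data.frame(class = k, f_int = f[k, "intact"], f_q = f[k, "questionable"],
               f_inc = f[k, "incomplete"], pct_change = obs,
               lower = q[1L], upper = q[2L], flag = flag,
               excluded = !(k %in% retained),
               discarded = as.integer(sum(!ok)), row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "null_probs") <- probs
  out
}

#' Null assignment proportions of a count table
#'
#' The per-completeness probabilities used by the proportional bootstrap:
#' column totals over the grand total.
#'
#' @param table a `gene_class_table`.
#' @return Named numeric vector over the three completeness labels.
#' @export
null_assignment_probs <- function(table) {
  stopifnot(inherits(table, "gene_class_table"))
  colSums(table) / sum(table)
}

#' Draw a null gene-class table
#'
#' Generates a count table with the same row totals as `table` but with
#' every class's genes re-assigned multinomially under the null proportions
#' -- the construction the bootstrap calibrates against.
#'
#' @param table a `gene_class_table` supplying row totals and proportions.
#' @return A `gene_class_table`.
#' @export
simulate_null_table <- function(table) {
  stopifnot(inherits(table, "gene_class_table"))
  probs <- null_assignment_probs(table)
  counts <- t(vapply(rownames(table), function(k)
    as.integer(rmultinom(1L, size = sum(table[k, ]), prob = probs)),
    integer(3)))
  colnames(counts) <- COMPLETENESS_LEVELS
  gene_class_table(counts)
}
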