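#' Classify a transposase annotation as IS or non-IS
#'
#' An annotation counts as an insertion-sequence (IS) transposase when it
#' contains an IS-element token: the letters "IS" (case-sensitive)
#' immediately followed by digits, optionally with a family suffix, as in
#' "IS3 transposase B" or "IS630 family transposase". Any other annotation
#' matching the transposase keyword is a non-IS transposase.
#'
#' @param text character vector of annotation strings; each must match the
#'   `transposase` keyword (case-insensitive), otherwise an error.
#' @return Character vector, `"IS"` or `"non-IS"`.
#' @examples
#' classify_transposase("IS3 transposase B")         # "IS"
#' classify_transposase("putative transposase")      # "non-IS"
#' @export
classify_transposase <- function(text) {
  is_tnp <- grepl("transposase", tolower(text), fixed = TRUE)
  if (any(!is_tnp))
    stop("not a transposase annotation: ",
         paste(utils::head(text[!is_tnp], 3L), collapse = "; "))
  ifelse(grepl("IS[0-9]+", text), "IS", "non-IS")
}

#' Per-completeness transposase counts
#'
#' Container for the transposase analysis: IS and non-IS transposase CDS
#' counts per completeness class, together with the total number of phage
#' proteins per class (the frequency denominators).
#'
#' @param is,non_is,total integer vectors of length 3 (intact,
#'   questionable, incomplete).
#' @return An object of class `protein_counts`.
#' @export
protein_counts <- function(is, non_is, total) {
  m <- rbind(IS = as.integer(is), `non-IS` = as.integer(non_is),
             total = as.integer(total))
  colnames(m) <- COMPLETENESS_LEVELS
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(m["IS", ] + m["non-IS", ] > m["total", ]))
    stop("IS + non-IS transposases cannot exceed total phage proteins")
  structure(m, class = c("protein_counts", "matrix"))
}

#' Count IS and non-IS transposases in annotation records
#'
#' Tallies transposase-matching CDS per completeness class and splits them
#' with [classify_transposase()]. The total-protein denominator is the
#' number of CDS rows per class (every recorded CDS is a phage-protein hit).
#'
#' @param records an annotation table (see [read_records()]).
#' @return A [protein_counts()] object.
#' @export
count_transposases <- function(records) {
  records <- validate_records(records)
  comp <- factor(records$completeness, levels = COMPLETENESS_LEVELS)
  tnp <- grepl("transposase", tolower(records$annotation), fixed = TRUE)
  kind <- rep(NA_character_, nrow(records))
  kind[tnp] <- classify_transposase(records$annotation[tnp])
  protein_counts(
    is = table(comp[tnp][kind[tnp] == "IS"]),
    non_is = table(comp[tnp][kind[tnp] == "non-IS"]),
    total = table(comp)
  )
}

#' Transposase frequency summary
#'
#' For each transposase type, the frequency within a completeness class is
#' its count divided by all phage proteins in that class. The relative
#' change from intact to incomplete is `(f_inc - f_int) / f_int`, reported
#' as a fraction (and conventionally quoted as "x-fold" when >= 1). The IS
#' share is the fraction of all transposase CDS, across all three classes,
#' classified as IS.
#'
#' @param counts a [protein_counts()] object (e.g. [table2_fixture()]), or
#'   an annotation table, which is passed through [count_transposases()].
#' @return A list with `is_share` and a data frame `by_type` (per-type
#'   counts, intact/incomplete frequencies, and relative change).
#' @examples
#' transposase_summary(table2_fixture(1))$is_share   # 0.413...
#' @export
transposase_summary <- function(counts) {
  if (!inherits(counts, "protein_counts")) counts <- count_transposases(counts)
  if (any(counts["total", ] == 0))
    stop("zero phage-protein total for: ",
         paste(colnames(counts)[counts["total", ] == 0], collapse = ", "))
  f_int <- counts[c("IS", "non-IS"), "intact"] / counts["total", "intact"]
  f_inc <- counts[c("IS", "non-IS"), "incomplete"] /
    counts["total", "incomplete"]
  if (any(f_int == 0))
    stop("relative change undefined: zero intact transposase count")
  rel <- (f_inc - f_int) / f_int
  list(
    is_share = sum(counts["IS", ]) / sum(counts[c("IS", "non-IS"), ]),
    by_type = data.frame(
      type = c("IS", "non-IS"),
      n_intact = counts[c("IS", "non-IS"), "intact"],
      n_questionable = counts[c("IS", "non-IS"), "questionable"],
      n_incomplete = counts[c("IS", "non-IS"), "incomplete"],
      f_intact = unname(f_int), f_incomplete = unname(f_inc),
      relative_change = unname(rel), row.names = NULL)
  )
}

#' Transposases per kbp, stratified by prophage length
#'
#' Bins prophages by sequence length and reports, per bin and transposase
#' type, the number of transposase CDS per kbp of prophage sequence in the
#' bin (total transposase CDS divided by total prophage length). Bins are
#' left-closed, right-open except the last; they must cover every observed
#' length. Bins containing no prophages have undefined densities, reported
#' as `NA` rather than zero.
#'
#' @param records an annotation table (see [read_records()]).
#' @param bin_edges increasing numeric vector of length-bin edges in bp.
#' @return A data frame with columns `bin_lo`, `bin_hi`, `n_prophages`,
#'   `kbp`, `is_per_kbp`, `non_is_per_kbp`.
#' @export
transposase_density_by_length <- function(records, bin_edges) {
  records <- validate_records(records)
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing with at least two values")
  per_prophage <- records[!duplicated(records$prophage_id),
                          c("prophage_id", "length_bp")]
  if (any(per_prophage$length_bp < bin_edges[1L]) ||
      any(per_prophage$length_bp > bin_edges[length(bin_edges)]))
    stop("bin_edges do not cover the observed prophage lengths")
  bin <- cut(per_prophage$length_bp, bin_edges, right = FALSE,
             include.lowest = TRUE)
  # right-open everywhere except the final bin, which absorbs the maximum
  bin[per_prophage$length_bp == bin_edges[length(bin_edges)]] <-
    levels(bin)[nlevels(bin)]
  tnp <- grepl("transposase", tolower(records$annotation), fixed = TRUE)
  kind <- rep(NA_character_, nrow(records))
  kind[tnp] <- classify_transposase(records$annotation[tnp])
  n_is <- table(factor(records$prophage_id[tnp][kind[tnp] == "IS"],
                       levels = per_prophage$prophage_id))
  n_nis <- table(factor(records$prophage_id[tnp][kind[tnp] == "non-IS"],
                        levels = per_prophage$prophage_id))
  agg <- function(v) as.numeric(tapply(v, bin, sum, default = NA_real_))
  kbp <- agg(per_prophage$length_bp) / 1000
  out <- data.frame(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1L],
    n_prophages = as.integer(table(bin)),
    kbp = ifelse(is.na(kbp), 0, kbp),
    is_per_kbp = agg(as.numeric(n_is)) / kbp,
    non_is_per_kbp = agg(as.numeric(n_nis)) / kbp
  )
  out
}
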