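#' Match an annotation string to gene classes
#'
#' Case-insensitive plain substring search of each class keyword in the
#' annotation text. A string may match several classes (e.g. a fused
#' annotation mentioning both a tail and a plate protein), and substring
#' semantics are deliberate: "baseplate assembly protein" hits the `plate`
#' keyword. "lysis" and "lysin" are distinct, non-overlapping keywords.
#'
#' @param text character vector of annotation strings (one per CDS).
#' @param keywords named character vector mapping class name to keyword;
#'   defaults to the 13 tabulated classes with keyword = class name.
#' @return For a single string, a character vector of matched classes
#'   (possibly empty); for several strings, a list of such vectors.
#' @examples
#' classify_annotation("large terminase subunit")     # "terminase"
#' classify_annotation("baseplate assembly protein")  # "plate"
#' classify_annotation("hypothetical protein")        # character(0)
#' @export
classify_annotation <- function(text, keywords = default_keywords()) {
  m <- keyword_match_matrix(text, keywords)
  hits <- lapply(seq_along(text), function(i) colnames(m)[m[i, ]])
  if (length(text) == 1L) hits[[1L]] else hits
}

#' @rdname classify_annotation
#' @export
default_keywords <- function() setNames(GENE_CLASSES, GENE_CLASSES)

# grepl(fixed=TRUE, ignore.case=TRUE) is rejected by base R; do the
# case-folding ourselves once.
keyword_match_matrix <- function(text, keywords = default_keywords()) {
  lower <- tolower(text)
  m <- vapply(tolower(keywords), function(k) grepl(k, lower, fixed = TRUE),
              logical(length(text)))
  matrix(m, nrow = length(text), dimnames = list(NULL, names(keywords)))
}

#' Tabulate gene classes by prophage completeness
#'
#' Counts, for each gene class and completeness label, the number of
#' prophages containing at least one CDS whose annotation matches the class
#' keyword -- a prophage is counted at most once per class however many of
#' its CDS match.
#'
#' @param records a prophage annotation table as returned by
#'   [read_records()] or [generate_annotation_dataset()]: one row per CDS
#'   with columns `prophage_id`, `completeness`, `length_bp`, `annotation`.
#' @param keywords as in [classify_annotation()].
#' @return A `gene_class_table`: an integer matrix (classes x the three
#'   completeness labels).
#' @export
tabulate_gene_classes <- function(records, keywords = default_keywords()) {
  records <- validate_records(records)
  m <- keyword_match_matrix(records$annotation, keywords)
  counts <- matrix(0L, length(keywords), length(COMPLETENESS_LEVELS),
                   dimnames = list(names(keywords), COMPLETENESS_LEVELS))
  pid <- records$prophage_id
  comp <- records$completeness[!duplicated(pid)]
  names(comp) <- pid[!duplicated(pid)]
  for (k in names(keywords)) {
    hit_prophages <- unique(pid[m[, k]])
    if (length(hit_prophages))
      counts[k, ] <- counts[k, ] +
        as.integer(table(factor(comp[hit_prophages],
                                levels = COMPLETENESS_LEVELS)))
  }
  gene_class_table(counts)
}

#' Construct/validate a gene-class count table
#'
#' @param counts integer matrix of non-negative counts, gene classes in
#'   rows, the three completeness labels in columns.
#' @return The validated matrix with class `gene_class_table`.
#' @export
gene_class_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) ||
      !identical(colnames(counts), COMPLETENESS_LEVELS))
    stop("columns must be exactly: ",
         paste(COMPLETENESS_LEVELS, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  structure(counts, class = c("gene_class_table", "matrix"))
}

#' @export
print.gene_class_table <- function(x, ...) {
  m <- rbind(unclass(x), Total = colSums(x))
  print(m, ...)
  invisible(x)
}

#' Per-completeness gene-class frequencies
#'
#' Frequency of a class within a completeness stratum: its prophage count
#' divided by the stratum's column total.
#'
#' @param table a `gene_class_table`.
#' @return A numeric matrix of the same shape as `table`.
#' @export
class_frequencies <- function(table) {
  stopifnot(inherits(table, "gene_class_table"))
  tot <- colSums(table)
  if (any(tot == 0))
    stop("zero column total for: ",
         paste(colnames(table)[tot == 0], collapse = ", "))
  sweep(unclass(table), 2L, tot, "/")
}

#' Percent change in gene frequency from intact to incomplete prophages
#'
#' \deqn{\%\mathrm{change} = 100\,(f_{inc} - f_{int})/f_{int}.}
#' Positive values indicate classes relatively enriched in incomplete
#' prophages; negative values, classes preferentially lost.
#'
#' @param f_int frequency in intact prophages (must be > 0).
#' @param f_inc frequency in incomplete prophages.
#' @return The percent change (vectorized).
#' @examples
#' percent_change(195 / 2752, 75 / 363)   # transposases: ~ +192%
#' @export
percent_change <- function(f_int, f_inc) {
  if (any(f_int <= 0))
    stop("percent change undefined: intact frequency must be > 0")
  100 * (f_inc - f_int) / f_int
}

#' Prevalence filter on gene classes
#'
#' Classes whose row total is less than `threshold` of the grand total are
#' too sparse for stable frequency comparisons and are excluded from
#' enrichment displays.
#'
#' @param table a `gene_class_table`.
#' @param threshold minimum fraction of the grand total (default 1%).
#' @return Character vector of retained class names.
#' @export
apply_prevalence_filter <- function(table, threshold = 0.01) {
  stopifnot(inherits(table, "gene_class_table"))
  row_tot <- rowSums(table)
  rownames(table)[row_tot / sum(row_tot) >= threshold]
}
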