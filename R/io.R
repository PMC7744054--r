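REQUIRED_COLUMNS <- c("prophage_id", "genome_id", "completeness",
                      "length_bp", "cds_index", "annotation")

#' Validate a prophage annotation table
#'
#' Checks the documented schema (one row per coding sequence), normalizes
#' completeness labels to lowercase, and reports offending rows by number.
#' Every prophage must carry a single completeness label and length.
#'
#' @param records a data frame with columns `prophage_id`, `genome_id`,
#'   `completeness`, `length_bp`, `cds_index`, `annotation`.
#' @return The validated (and label-normalized) data frame.
#' @export
validate_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data frame")
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(records))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  records$completeness <- tolower(trimws(as.character(records$completeness)))
  bad_comp <- which(!records$completeness %in% COMPLETENESS_LEVELS)
  if (length(bad_comp))
    stop("invalid completeness label at row(s) ",
         paste(utils::head(bad_comp, 5L), collapse = ", "),
         " (must be one of ", paste(COMPLETENESS_LEVELS, collapse = "/"), ")")
  records$length_bp <- as.integer(records$length_bp)
  bad_len <- which(is.na(records$length_bp) | records$length_bp <= 0L)
  if (length(bad_len))
    stop("length_bp must be a positive integer; offending row(s): ",
         paste(utils::head(bad_len, 5L), collapse = ", "))
  per <- split(seq_len(nrow(records)), records$prophage_id)
  inconsistent <- names(per)[vapply(per, function(i)
    length(unique(records$completeness[i])) > 1L ||
      length(unique(records$length_bp[i])) > 1L, logical(1))]
  if (length(inconsistent))
    stop("prophage(s) with inconsistent completeness or length: ",
         paste(utils::head(inconsistent, 5L), collapse = ", "))
  records$annotation <- as.character(records$annotation)
  records
}

#' Read prophage annotation records
#'
#' TSV input is the flat schema (tab-separated, UTF-8, header row with the
#' six required columns, one row per CDS). JSON input is an array of
#' prophage objects, each with `prophage_id`, `genome_id`, `completeness`,
#' `length_bp` and a `cds` array of annotation strings; it is flattened to
#' the same table. All input is validated with [validate_records()].
#'
#' @param path file path.
#' @param format `"tsv"` or `"json"`; guessed from the file extension by
#'   default.
#' @return A validated annotation table.
#' @export
read_records <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "tsv") {
    if (file.size(path) == 0L) stop("empty input file: ", path)
    records <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(obj) == 0L) stop("empty input file: ", path)
    records <- do.call(rbind, lapply(obj, function(p) {
      cds <- unlist(p$cds)
      if (is.null(cds)) stop("prophage without cds array: ", p$prophage_id)
      data.frame(prophage_id = p$prophage_id, genome_id = p$genome_id,
                 completeness = p$completeness, length_bp = p$length_bp,
                 cds_index = seq_along(cds), annotation = cds)
    }))
  }
  validate_records(records)
}

#' Write prophage annotation records
#'
#' Inverse of [read_records()] for both supported formats.
#'
#' @param records a validated annotation table.
#' @param path output file path.
#' @param format `"tsv"` or `"json"` (guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  records <- validate_records(records)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "tsv") {
    utils::write.table(records[REQUIRED_COLUMNS], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    split_rows <- split(records, factor(records$prophage_id,
                                        levels = unique(records$prophage_id)))
    obj <- lapply(split_rows, function(d) {
      d <- d[order(d$cds_index), ]
      list(prophage_id = d$prophage_id[1L], genome_id = d$genome_id[1L],
           completeness = d$completeness[1L], length_bp = d$length_bp[1L],
           cds = as.list(d$annotation))
    })
    jsonlite::write_json(unname(obj), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write analysis results with a reproducibility manifest
#'
#' Writes each element of `results` (data frames, matrices, count tables)
#' as a CSV with a stable column order, plus a JSON manifest recording the
#' configuration, seed and package version that produced them, so any
#' result file can be regenerated from its manifest.
#'
#' @param results a named list of tabular objects.
#' @param dir output directory (created if needed).
#' @param config optional list of run parameters stored in the manifest.
#' @param seed optional seed stored in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_results <- function(results, dir, config = NULL, seed = NULL) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, c("gene_class_table", "protein_counts")))
      x <- cbind(data.frame(name = rownames(x)), as.data.frame(unclass(x)))
    else if (is.matrix(x)) x <- as.data.frame(x)
    write.csv(x, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  manifest <- list(
    package = "prophageContinuum",
    version = as.character(packageVersion("prophageContinuum")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config, files = paste0(names(results), ".csv"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
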