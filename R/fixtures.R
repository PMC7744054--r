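#' Bundled prophage gene-repertoire count tables
#'
#' Published counts of prophages containing at least one gene of each of 13
#' classes, by PHASTER completeness label, for two prophage collections:
#' data set 1 (624 prophages from 85 enterobacterial genomes) and data set
#' 2 (760 prophages from 306 phylogenetically diverse genomes).
#'
#' @param dataset `1` or `2`.
#' @return A `gene_class_table`.
#' @examples
#' colSums(table1_fixture(1))   # 2752 240 363
#' @export
table1_fixture <- function(dataset = 1) {
  counts <- switch(as.character(dataset),
    "1" = c(terminase = 317, 25, 14,
            portal = 277, 9, 3,
            head = 299, 16, 25,
            injection = 14, 0, 2,
            tail = 413, 46, 86,
            protease = 82, 3, 5,
            transposase = 195, 32, 75,
            integrase = 346, 54, 85,
            lysis = 226, 19, 11,
            plate = 121, 5, 0,
            capsid = 225, 14, 18,
            lysin = 235, 17, 19,
            flippase = 2, 0, 20),
    "2" = c(terminase = 292, 53, 58,
            portal = 283, 67, 48,
            head = 281, 79, 86,
            injection = 4, 0, 0,
            tail = 419, 116, 141,
            protease = 72, 12, 22,
            transposase = 190, 173, 144,
            integrase = 312, 94, 165,
            lysis = 52, 6, 6,
            plate = 143, 20, 28,
            capsid = 233, 50, 40,
            lysin = 165, 32, 22,
            flippase = 0, 1, 4),
    stop("dataset must be 1 or 2"))
  m <- matrix(as.integer(counts), ncol = 3L, byrow = TRUE,
              dimnames = list(GENE_CLASSES, COMPLETENESS_LEVELS))
  gene_class_table(m)
}

#' Bundled transposase count tables
#'
#' Published counts of IS-transposase and non-IS-transposase coding
#' sequences per completeness class, with the total number of identified
#' phage proteins as denominator, for the same two prophage collections as
#' [table1_fixture()].
#'
#' @param dataset `1` or `2`.
#' @return A [protein_counts()] object.
#' @examples
#' table2_fixture(2)["IS", ]   # 459 90 109
#' @export
table2_fixture <- function(dataset = 1) {
  switch(as.character(dataset),
    "1" = protein_counts(is = c(174, 34, 76),
                         non_is = c(278, 37, 88),
                         total = c(21054, 2271, 1552)),
    "2" = protein_counts(is = c(459, 90, 109),
                         non_is = c(464, 101, 99),
                         total = c(19250, 5097, 4132)),
    stop("dataset must be 1 or 2"))
}
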