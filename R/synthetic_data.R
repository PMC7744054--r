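#' Specification for the synthetic annotation generator
#'
#' Describes a PHASTER-like prophage annotation data set with known ground
#' truth: a completeness mixture, expected CDS counts per gene class and
#' completeness stratum, log-normal prophage lengths per stratum, a rate of
#' distractor (non-phage-keyword) annotations, and the fraction of
#' transposase annotations carrying an IS-element token.
#'
#' The defaults emulate a medium-sized enterobacterial prophage survey:
#' a few hundred prophages, roughly half intact; intact prophages around
#' 35-45 kbp and incomplete ones far shorter; structural and lytic classes
#' concentrated in intact prophages; transposases and integrases relatively
#' enriched in incomplete ones.
#'
#' @param n_prophages number of prophages.
#' @param mixture named probabilities over the completeness labels
#'   (must sum to 1).
#' @param class_means numeric matrix of expected CDS counts per prophage
#'   (gene classes x completeness labels).
#' @param length_meanlog,length_sdlog named per-completeness parameters of
#'   the log-normal length distribution (bp).
#' @param distractor_rate expected number of distractor CDS per prophage.
#' @param is_fraction probability that a transposase annotation is an IS
#'   transposase.
#' @param seed RNG seed used by [generate_annotation_dataset()].
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_prophages = 600L,
                           mixture = c(intact = 0.55, questionable = 0.10,
                                       incomplete = 0.35),
                           class_means = default_class_means(),
                           length_meanlog = c(intact = log(40000),
                                              questionable = log(25000),
                                              incomplete = log(12000)),
                           length_sdlog = c(intact = 0.35,
                                            questionable = 0.40,
                                            incomplete = 0.50),
                           distractor_rate = 20,
                           is_fraction = 0.45,
                           seed = 1L) {
  spec <- list(n_prophages = as.integer(n_prophages), mixture = mixture,
               class_means = class_means, length_meanlog = length_meanlog,
               length_sdlog = length_sdlog, distractor_rate = distractor_rate,
               is_fraction = is_fraction, seed = as.integer(seed))
  if (spec$n_prophages < 1L) stop("n_prophages must be positive")
  if (!identical(sort(names(mixture)), sort(COMPLETENESS_LEVELS)) ||
      abs(sum(mixture) - 1) > 1e-9 || any(mixture < 0))
    stop("mixture must be non-negative probabilities over ",
         paste(COMPLETENESS_LEVELS, collapse = "/"), " summing to 1")
  if (!is.matrix(class_means) || any(class_means < 0) ||
      !identical(colnames(class_means), COMPLETENESS_LEVELS))
    stop("class_means must be a non-negative matrix with columns ",
         paste(COMPLETENESS_LEVELS, collapse = ", "))
  if (distractor_rate < 0 || is_fraction < 0 || is_fraction > 1)
    stop("distractor_rate must be >= 0 and is_fraction in [0, 1]")
  structure(spec, class = "generator_spec")
}

#' @rdname generator_spec
#' @export
default_class_means <- function() {
  intact <- c(terminase = 0.60, portal = 0.50, head = 0.60, injection = 0.03,
              tail = 0.90, protease = 0.15, transposase = 0.40,
              integrase = 0.70, lysis = 0.45, plate = 0.25, capsid = 0.45,
              lysin = 0.45, flippase = 0.01)
  scale_inc <- rep(0.35, 13L); names(scale_inc) <- names(intact)
  scale_inc[c("transposase", "integrase", "tail")] <- c(1.3, 1.0, 0.55)
  cbind(intact = intact, questionable = intact * 0.5,
        incomplete = intact * scale_inc)
}

# Annotation text templates; each phage template contains exactly its class
# keyword, distractors contain none of the 13 keywords and no IS token.
ANNOTATION_TEMPLATES <- list(
  terminase = c("large terminase subunit", "terminase small subunit"),
  portal = c("portal protein", "phage portal vertex protein"),
  head = c("head morphogenesis protein", "major head protein"),
  injection = c("DNA injection protein"),
  tail = c("tail fiber protein", "tail length tape measure protein"),
  protease = c("maturation protease", "scaffolding protease"),
  transposase = c("putative transposase", "transposase, degenerate"),
  integrase = c("site-specific integrase", "tyrosine integrase"),
  lysis = c("lysis protein S", "holin, lysis regulator"),
  plate = c("baseplate assembly protein", "baseplate wedge subunit"),
  capsid = c("major capsid protein", "capsid decoration protein"),
  lysin = c("endolysin", "N-acetylmuramoyl-L-alanine amidase lysin"),
  flippase = c("membrane flippase")
)
DISTRACTOR_TEMPLATES <- c("hypothetical protein", "DNA primase",
                          "phage-associated protein, unknown function",
                          "DNA methyltransferase", "anti-repressor protein",
                          "single-stranded DNA binding protein")
IS_FAMILIES <- c("IS3", "IS5", "IS630", "IS1", "IS110", "IS200")

#' Generate a synthetic prophage annotation data set
#'
#' Draws prophages per the spec: completeness from the mixture, length from
#' the per-completeness log-normal, per-class CDS counts from Poisson
#' distributions with the spec means, plus Poisson distractor CDS.
#' Transposase annotations carry an IS family token ("IS3 transposase")
#' with probability `is_fraction`, otherwise plain transposase text. The
#' per-prophage true class counts are attached as ground truth.
#'
#' @param spec a [generator_spec()].
#' @return A validated annotation table (one row per CDS; columns
#'   `prophage_id`, `genome_id`, `completeness`, `length_bp`, `cds_index`,
#'   `annotation`) with attribute `"ground_truth"`: a data frame of true
#'   per-prophage CDS counts per class.
#' @examples
#' rec <- generate_annotation_dataset(generator_spec(n_prophages = 50))
#' tabulate_gene_classes(rec)
#' @export
generate_annotation_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_prophages
  comp <- sample(COMPLETENESS_LEVELS, n, replace = TRUE,
                 prob = spec$mixture[COMPLETENESS_LEVELS])
  len <- pmax(1000L, as.integer(round(rlnorm(n, spec$length_meanlog[comp],
                                             spec$length_sdlog[comp]))))
  classes <- rownames(spec$class_means)
  truth <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k_counts <- rpois(length(classes), spec$class_means[, comp[i]])
    truth[i, ] <- k_counts
    ann <- character(0)
    for (j in seq_along(classes)) {
      if (k_counts[j] == 0L) next
      cl <- classes[j]
      if (cl == "transposase") {
        is_hit <- runif(k_counts[j]) < spec$is_fraction
        ann <- c(ann, ifelse(is_hit,
                             paste(sample(IS_FAMILIES, k_counts[j],
                                          replace = TRUE), "transposase"),
                             sample(ANNOTATION_TEMPLATES[[cl]], k_counts[j],
                                    replace = TRUE))[seq_len(k_counts[j])])
      } else {
        tmpl <- if (cl %in% names(ANNOTATION_TEMPLATES))
          ANNOTATION_TEMPLATES[[cl]] else paste(cl, "protein")
        ann <- c(ann, sample(tmpl, k_counts[j], replace = TRUE))
      }
    }
    n_dis <- rpois(1L, spec$distractor_rate)
    ann <- c(ann, sample(DISTRACTOR_TEMPLATES, n_dis, replace = TRUE))
    if (length(ann) == 0L) ann <- "hypothetical protein"
    ann <- sample(ann)   # shuffle CDS order within the prophage
    rows[[i]] <- data.frame(
      prophage_id = sprintf("PP%04d", i),
      genome_id = sprintf("G%03d", 1L + (i - 1L) %/% 8L),
      completeness = comp[i], length_bp = len[i],
      cds_index = seq_along(ann), annotation = ann)
  }
  records <- do.call(rbind, rows)
  records <- validate_records(records)
  attr(records, "ground_truth") <-
    data.frame(prophage_id = sprintf("PP%04d", seq_len(n)),
               completeness = comp, length_bp = len, truth)
  records
}
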