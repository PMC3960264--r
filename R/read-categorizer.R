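# Read categorization: every mapped read gets exactly one of six labels.
# Decision order (sense precedence, then residual antisense):
#   1. sense overlap (>= 1 base) with rRNA/tRNA/CDS -> that category,
#      largest overlap first, ties by rRNA > tRNA > mRNA;
#   2. sense overlap with misc_RNA -> misc_rna;
#   3. any opposite-strand overlap with a feature -> antisense;
#   4. nothing -> intergenic.

.CATEGORIES <- c("rRNA", "tRNA", "mRNA", "misc_rna", "intergenic", "antisense")
.ANNOTATED_PANEL <- c("rRNA", "tRNA", "mRNA")
.NONANNOTATED_PANEL <- c("intergenic", "antisense", "misc_rna")

category_of_type <- c(rRNA = "rRNA", tRNA = "tRNA", CDS = "mRNA", misc_RNA = "misc_rna")
.SENSE_PRECEDENCE <- c(rRNA = 1L, tRNA = 2L, mRNA = 3L)

#' Categorize mapped reads against the annotation
#'
#' Assigns each read exactly one of `rRNA`, `tRNA`, `mRNA` (sense overlap
#' with an annotated gene), `misc_rna` (sense overlap with a misc_RNA
#' feature), `antisense` (overlap only with opposite-strand features) or
#' `intergenic` (no overlap at all). A single shared base counts as overlap;
#' when a read sense-overlaps several genes the largest overlap wins, with
#' ties broken by rRNA > tRNA > mRNA.
#'
#' @param reads Tibble of mapped reads (`read_id`, `replicon`, `start`,
#'   `end`, `strand`), e.g. from [read_alignments()].
#' @param ann An `srna_annotation`.
#' @return `reads` with a `category` column added.
#' @export
categorize_reads <- function(reads, ann) {
  stopifnot(inherits(ann, "srna_annotation"))
  if (nrow(reads) == 0) {
    return(dplyr::mutate(reads, category = character(0)))
  }
  if (nrow(ann$features) == 0) {
    return(dplyr::mutate(reads, category = "intergenic"))
  }
  rgr <- intervals_granges(reads)
  fgr <- features_granges(ann)
  hits <- GenomicRanges::findOverlaps(rgr, fgr, minoverlap = 1L, ignore.strand = TRUE)
  ri <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)
  category <- rep("intergenic", nrow(reads))
  if (length(ri)) {
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(rgr)[ri], IRanges::ranges(fgr)[fi]
    ))
    same <- reads$strand[ri] == ann$features$strand[fi]
    ftype <- ann$features$feature_type[fi]
    cand <- tibble(
      read = ri,
      overlap = ov,
      sense = same,
      feature_type = ftype,
      category = unname(category_of_type[ftype])
    )
    # tier 1: sense gene overlap; tier 2: sense misc; tier 3: antisense
    cand$tier <- dplyr::case_when(
      cand$sense & cand$feature_type != "misc_RNA" ~ 1L,
      cand$sense ~ 2L,
      TRUE ~ 3L
    )
    cand$category[cand$tier == 3L] <- "antisense"
    cand$prec <- dplyr::coalesce(.SENSE_PRECEDENCE[cand$category], 9L)
    best <- cand %>%
      dplyr::arrange(
        .data$read, .data$tier,
        dplyr::desc(.data$overlap * (.data$tier == 1L)), .data$prec
      ) %>%
      dplyr::distinct(.data$read, .keep_all = TRUE)
    category[best$read] <- best$category
  }
  dplyr::mutate(reads, category = category)
}

#' Tally read categories into the two reporting panels
#'
#' Counts reads per category and computes the annotated / non-annotated
#' split used in survey-style reporting: the annotated panel holds
#' rRNA/tRNA/mRNA (sense hits to known genes); intergenic, antisense and
#' misc_rna form the non-annotated panel. Panel fractions are relative to
#' the panel, `fraction` to all categorized reads.
#'
#' @param reads Categorized reads (output of [categorize_reads()]), or raw
#'   reads plus `ann` to categorize first.
#' @param ann Optional `srna_annotation`; required when `reads` has no
#'   `category` column.
#' @return An `srna_category_tally`: tibble with one row per category
#'   (`category`, `panel`, `count`, `fraction`, `panel_fraction`) plus a
#'   `panels` attribute with the annotated/non-annotated split. Fractions
#'   are `NA` when their denominator is zero.
#' @export
tally_read_categories <- function(reads, ann = NULL) {
  if (!"category" %in% names(reads)) {
    if (is.null(ann)) stop("reads lack a category column; supply `ann`", call. = FALSE)
    reads <- categorize_reads(reads, ann)
  }
  counts <- table(factor(reads$category, levels = .CATEGORIES))
  out <- tibble(
    category = .CATEGORIES,
    panel = ifelse(.CATEGORIES %in% .ANNOTATED_PANEL, "annotated", "non_annotated"),
    count = as.integer(counts)
  )
  total <- sum(out$count)
  panel_n <- stats::ave(out$count, out$panel, FUN = sum)
  out$fraction <- if (total > 0) out$count / total else NA_real_
  out$panel_fraction <- ifelse(panel_n > 0, out$count / panel_n, NA_real_)
  panels <- tibble(
    panel = c("annotated", "non_annotated"),
    count = c(
      sum(out$count[out$panel == "annotated"]),
      sum(out$count[out$panel == "non_annotated"])
    )
  )
  panels$fraction <- if (total > 0) panels$count / total else NA_real_
  structure(out, panels = panels, class = c("srna_category_tally", class(out)))
}

#' @export
print.srna_category_tally <- function(x, ...) {
  cat("<srna_category_tally> ", sum(x$count), " reads\n", sep = "")
  NextMethod()
}
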