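# Candidate calling: depth/length filtering of clusters, then three-class
# classification. Precedence: sense contamination is excluded first, then
# antisense (the most specific structural signal), then 5'-leader
# containment, then intergenic as the residual class.

.SRNA_CLASSES <- c("I_intergenic", "II_antisense", "III_leader", "excluded_sense")

#' Calling parameters
#'
#' Bundles the tunable thresholds of the candidate caller.
#'
#' @param min_reads Minimum cluster support (default 10 reads).
#' @param min_length Minimum candidate span, nt, inclusive (default 50).
#' @param leader_window Upstream window, nt, within which a candidate can be
#'   a 5'-leader call (default 300).
#' @param depth_statistic Which support statistic the depth filter uses:
#'   `"read_count"` (default; number of member reads) or `"max_coverage"`
#'   (peak per-base depth).
#' @param leader_rule `"contained"` (default: the whole candidate must lie
#'   inside the upstream window) or `"end_within"` (only its gene-proximal
#'   end must).
#' @param include_misc Feed `misc_rna` reads into clustering (default
#'   `FALSE`).
#' @param min_read_overlap Minimum shared bases chaining reads into a
#'   cluster (default 1).
#' @param min_mapq Minimum mapping quality at ingest (default 0).
#' @return A list of class `srna_params`.
#' @export
calling_params <- function(min_reads = 10L, min_length = 50L,
                           leader_window = 300L,
                           depth_statistic = c("read_count", "max_coverage"),
                           leader_rule = c("contained", "end_within"),
                           include_misc = FALSE, min_read_overlap = 1L,
                           min_mapq = 0L) {
  depth_statistic <- match.arg(depth_statistic)
  leader_rule <- match.arg(leader_rule)
  stopifnot(min_reads >= 1, min_length >= 1, leader_window >= 1, min_read_overlap >= 1)
  structure(
    list(
      min_reads = as.integer(min_reads),
      min_length = as.integer(min_length),
      leader_window = as.integer(leader_window),
      depth_statistic = depth_statistic,
      leader_rule = leader_rule,
      include_misc = include_misc,
      min_read_overlap = as.integer(min_read_overlap),
      min_mapq = as.integer(min_mapq)
    ),
    class = "srna_params"
  )
}

#' Filter clusters into candidate sRNAs
#'
#' Keeps clusters whose support statistic is at least `min_reads` and whose
#' span is at least `min_length` nt. Both thresholds are inclusive.
#'
#' @param clusters Cluster tibble from [build_clusters()].
#' @param params An `srna_params` object (see [calling_params()]).
#' @return A list: `candidates` (surviving clusters with a `length` column)
#'   and `rejections` (tibble of counts by reason: depth, length, both).
#' @export
filter_candidates <- function(clusters, params = calling_params()) {
  depth <- clusters[[params$depth_statistic]]
  len <- clusters$end - clusters$start
  too_shallow <- depth < params$min_reads
  too_short <- len < params$min_length
  reason <- dplyr::case_when(
    too_shallow & too_short ~ "both",
    too_shallow ~ "depth",
    too_short ~ "length",
    TRUE ~ "kept"
  )
  rejections <- tibble(
    reason = c("depth", "length", "both"),
    count = c(sum(reason == "depth"), sum(reason == "length"), sum(reason == "both"))
  )
  candidates <- clusters[reason == "kept", , drop = FALSE]
  candidates$length <- candidates$end - candidates$start
  list(candidates = candidates, rejections = rejections)
}

#' Classify candidate sRNAs
#'
#' Applies the three-class scheme with fixed precedence:
#' * `excluded_sense` — any sense overlap (>= 1 base) with an annotated
#'   rRNA/tRNA/CDS gene; reported but not counted among Classes I-III;
#' * `II_antisense` — overlaps a feature on the opposite strand; the
#'   associated gene is the one with the largest overlap;
#' * `III_leader` — lies wholly within the upstream window of a same-strand
#'   gene (nearest gene when several windows contain it);
#' * `I_intergenic` — the residual: inside intergenic space, overlapping no
#'   gene and inside no leader window.
#'
#' @param candidates Candidate tibble from [filter_candidates()].
#' @param ann An `srna_annotation`.
#' @param params An `srna_params`.
#' @return `candidates` with `srna_class`, `associated_gene` and
#'   `replicon_kind` (chromosome/plasmid) columns.
#' @export
classify_candidates <- function(candidates, ann, params = calling_params()) {
  n <- nrow(candidates)
  kind <- ifelse(
    ann$replicons$is_plasmid[match(candidates$replicon, ann$replicons$replicon)],
    "plasmid", "chromosome"
  )
  if (n == 0) {
    return(dplyr::mutate(candidates,
      srna_class = character(0), associated_gene = character(0),
      replicon_kind = character(0)
    ))
  }
  srna_class <- rep("I_intergenic", n)
  associated <- rep(NA_character_, n)

  f <- ann$features
  if (nrow(f) > 0) {
    cgr <- intervals_granges(candidates)
    fgr <- features_granges(ann)
    hits <- GenomicRanges::findOverlaps(cgr, fgr, minoverlap = 1L, ignore.strand = TRUE)
    ci <- S4Vectors::queryHits(hits)
    fi <- S4Vectors::subjectHits(hits)
    if (length(ci)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(cgr)[ci], IRanges::ranges(fgr)[fi]
      ))
      sense <- candidates$strand[ci] == f$strand[fi]
      # rule 0: sense overlap with an annotated gene (misc_RNA exempt)
      sense_gene <- sense & f$feature_type[fi] != "misc_RNA"
      srna_class[unique(ci[sense_gene])] <- "excluded_sense"
      # rule 1: antisense, largest-overlap feature wins
      anti <- !sense & srna_class[ci] != "excluded_sense"
      if (any(anti)) {
        best <- tibble(ci = ci[anti], fi = fi[anti], ov = ov[anti]) %>%
          dplyr::arrange(.data$ci, dplyr::desc(.data$ov), .data$fi) %>%
          dplyr::distinct(.data$ci, .keep_all = TRUE)
        keep <- srna_class[best$ci] != "excluded_sense"
        srna_class[best$ci[keep]] <- "II_antisense"
        associated[best$ci[keep]] <- f$gene_id[best$fi[keep]]
      }
    }
    # rule 2: 5'-leader containment, nearest same-strand gene
    open <- which(srna_class == "I_intergenic")
    if (length(open)) {
      win <- upstream_windows(ann, params$leader_window)
      if (nrow(win)) {
        sub <- candidates[open, , drop = FALSE]
        sgr <- intervals_granges(sub)
        wgr <- intervals_granges(win)
        type <- if (params$leader_rule == "contained") "within" else "any"
        wh <- GenomicRanges::findOverlaps(sgr, wgr,
          type = type, ignore.strand = FALSE
        )
        si <- S4Vectors::queryHits(wh)
        wi <- S4Vectors::subjectHits(wh)
        if (params$leader_rule == "end_within") {
          # the gene-proximal end of the candidate must fall in the window
          prox <- ifelse(sub$strand[si] == "+", sub$end[si] - 1L, sub$start[si])
          ok <- prox >= win$start[wi] & prox < win$end[wi]
          si <- si[ok]
          wi <- wi[ok]
        }
        if (length(si)) {
          gstart <- f$start[match(win$gene_id[wi], f$gene_id)]
          gend <- f$end[match(win$gene_id[wi], f$gene_id)]
          dist <- ifelse(sub$strand[si] == "+",
            gstart - sub$end[si], sub$start[si] - gend
          )
          best <- tibble(si = si, wi = wi, dist = dist) %>%
            dplyr::arrange(.data$si, .data$dist, .data$wi) %>%
            dplyr::distinct(.data$si, .keep_all = TRUE)
          srna_class[open[best$si]] <- "III_leader"
          associated[open[best$si]] <- win$gene_id[best$wi]
        }
      }
    }
  }
  dplyr::mutate(candidates,
    srna_class = srna_class,
    associated_gene = associated,
    replicon_kind = kind
  )
}

#' Call candidate sRNAs end-to-end
#'
#' Runs the full discovery chain: categorize reads, select the
#' non-annotated subset, assemble clusters, filter by depth and length,
#' classify. Deterministic for identical inputs and parameters, and
#' invariant to the order of input reads.
#'
#' @param reads Mapped reads tibble (see [read_alignments()]).
#' @param ann An `srna_annotation`.
#' @param params An `srna_params` (see [calling_params()]).
#' @return An `srna_call` object: list with `candidates` (classified
#'   candidate tibble), `clusters`, `category_tally`, `rejections`,
#'   `n_reads`, and `params`. Use [tidy()]/[glance()]/[autoplot()] or
#'   [summarize_run()] on it.
#' @export
call_srnas <- function(reads, ann, params = calling_params()) {
  categorized <- categorize_reads(reads, ann)
  tally <- tally_read_categories(categorized)
  input <- select_cluster_reads(categorized, include_misc = params$include_misc)
  clusters <- build_clusters(input, min_overlap = params$min_read_overlap)
  flt <- filter_candidates(clusters, params)
  candidates <- classify_candidates(flt$candidates, ann, params)
  structure(
    list(
      candidates = candidates,
      clusters = clusters,
      category_tally = tally,
      rejections = flt$rejections,
      n_reads = nrow(reads),
      params = params
    ),
    class = "srna_call"
  )
}

#' @export
print.srna_call <- function(x, ...) {
  cls <- table(factor(x$candidates$srna_class, levels = .SRNA_CLASSES))
  cat("<srna_call> ", x$n_reads, " reads -> ", nrow(x$clusters), " clusters -> ",
    nrow(x$candidates), " candidates\n", sep = ""
  )
  cat(
    "  Class I (intergenic): ", cls[["I_intergenic"]],
    "; Class II (antisense): ", cls[["II_antisense"]],
    "; Class III (5'-leader): ", cls[["III_leader"]],
    "; excluded (sense): ", cls[["excluded_sense"]], "\n", sep = ""
  )
  invisible(x)
}
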