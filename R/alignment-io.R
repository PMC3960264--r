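# Read ingest: FASTQ-level quality control and SAM/BAM alignment loading.
# Only primary, mapped alignments feed the pipeline; the ingest tally is a
# conservation check (kept + unmapped + non_primary + low_mapq == records).

#' Quality-filter raw reads
#'
#' Applies the two read-level filters used before mapping: discard reads
#' whose mean Phred score is below `min_mean_phred` (default 20) or whose
#' length is below `min_length` (default 18 nt). Both rules are evaluated so
#' the reason code distinguishes `"quality"`, `"length"` and `"both"`;
#' kept reads get `"kept"`. Empty sequences are length failures.
#'
#' @param reads Tibble with columns `read_id`, `sequence` and `phred`
#'   (a list-column of integer vectors, one score per base). See
#'   [read_fastq()].
#' @param min_mean_phred Minimum mean Phred score to keep a read.
#' @param min_length Minimum read length (nt) to keep a read.
#' @return The input with logical `keep` and character `reason` columns.
#' @export
qc_filter_reads <- function(reads, min_mean_phred = 20, min_length = 18) {
  stopifnot(all(c("read_id", "sequence", "phred") %in% names(reads)))
  len <- nchar(reads$sequence)
  qlen <- lengths(reads$phred)
  if (any(len != qlen)) {
    stop("sequence and phred lengths disagree for read(s): ",
      paste(utils::head(reads$read_id[len != qlen], 3), collapse = ", "),
      call. = FALSE
    )
  }
  mean_q <- vapply(
    reads$phred,
    function(q) if (length(q)) mean(q) else NaN, numeric(1)
  )
  short <- len < min_length
  lowq <- !short & is.finite(mean_q) & mean_q < min_mean_phred
  lowq_any <- is.finite(mean_q) & mean_q < min_mean_phred
  reason <- dplyr::case_when(
    short & lowq_any ~ "both",
    short ~ "length",
    lowq ~ "quality",
    TRUE ~ "kept"
  )
  dplyr::mutate(reads, keep = reason == "kept", reason = reason)
}

#' Read a FASTQ file into a QC-ready tibble
#'
#' @param path FASTQ path (uncompressed or gzip).
#' @return Tibble with `read_id`, `sequence`, and `phred` list-column.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- S4Vectors::mcols(seqs)$qualities
  phred <- as(Biostrings::PhredQuality(quals), "IntegerList")
  tibble(
    read_id = sub("\\s.*$", "", names(seqs)),
    sequence = as.character(seqs),
    phred = as.list(phred)
  )
}

#' Load mapped reads from SAM/BAM
#'
#' Ingests a single-end alignment file and keeps primary mapped alignments
#' only, so each read contributes at most once to downstream cluster depth.
#' The aligned span is the reference footprint of the CIGAR (soft-clips
#' excluded); strand comes from the reverse-complement flag. An ingest tally
#' accounts for every input record.
#'
#' @param path SAM or BAM file (extension decides; SAM is converted on the
#'   fly).
#' @param ann An `srna_annotation`; alignment targets must be replicons of
#'   this annotation.
#' @param min_mapq Minimum mapping quality; primary mapped records below it
#'   are tallied as `low_mapq` and dropped (default 0 = no filter).
#' @return A list with `reads` — tibble(`read_id`, `replicon`, `start`,
#'   `end`, `strand`, `mapq`), 0-based half-open — and `tally` — tibble of
#'   `kept`, `unmapped`, `non_primary`, `low_mapq`, `total`.
#' @export
read_alignments <- function(path, ann, min_mapq = 0L) {
  stopifnot(inherits(ann, "srna_annotation"))
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  unknown <- setdiff(names(hdr), ann$replicons$replicon)
  if (length(unknown)) {
    stop("alignment header names replicons absent from the annotation: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mapq")
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  unmapped <- bitwAnd(flag, 0x4L) != 0L
  non_primary <- !unmapped & bitwAnd(flag, bitwOr(0x100L, 0x800L)) != 0L
  primary <- !unmapped & !non_primary
  low_mapq <- primary & !is.na(b$mapq) & b$mapq < min_mapq
  keep <- primary & !low_mapq
  width <- rep(NA_integer_, length(flag))
  if (any(keep)) {
    width[keep] <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[keep])
  }
  reads <- tibble(
    read_id = b$qname[keep],
    replicon = as.character(b$rname[keep]),
    start = b$pos[keep] - 1L,
    end = b$pos[keep] - 1L + width[keep],
    strand = ifelse(bitwAnd(flag[keep], 0x10L) != 0L, "-", "+"),
    mapq = b$mapq[keep]
  )
  tally <- tibble(
    kept = sum(keep),
    unmapped = sum(unmapped),
    non_primary = sum(non_primary),
    low_mapq = sum(low_mapq),
    total = length(flag)
  )
  list(reads = reads, tally = tally)
}

#' Load reads from 6-column BED
#'
#' Alternative ingest for pre-processed read intervals. BED carries no base
#' qualities, so QC cannot be applied; a warning notes this. The score
#' column is ignored.
#'
#' @param path BED6 path.
#' @param ann An `srna_annotation` used to validate replicon names.
#' @return Tibble as in [read_alignments()] (with `mapq = NA`).
#' @export
read_alignments_bed <- function(path, ann) {
  warning("BED input carries no qualities; QC filters are skipped", call. = FALSE)
  gr <- rtracklayer::import(path, format = "bed")
  unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))), ann$replicons$replicon)
  if (length(unknown)) {
    stop("BED names replicons absent from the annotation: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  nm <- gr$name
  if (is.null(nm)) nm <- sprintf("read_%06d", seq_along(gr))
  tibble(
    read_id = nm,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    mapq = NA_integer_
  )
}
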