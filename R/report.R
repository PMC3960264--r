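# Run summary and exports. The count identities (classes partition the
# candidate total; chromosome + plasmids partition it too; per-plasmid
# counts sum to the plasmid total) are hard assertions: a run whose
# bookkeeping does not add up stops with an error naming the identity.

#' Assert that parts partition a total
#'
#' The arithmetic backbone of the run summary: candidate counts broken down
#' one way must re-sum to the total broken down any other way.
#'
#' @param total Integer total.
#' @param parts Integer vector (named parts of the breakdown).
#' @param what Label used in the error message.
#' @return `TRUE` invisibly, or an error naming the identity.
#' @export
check_partition <- function(total, parts, what = "counts") {
  if (sum(parts) != total) {
    stop(
      "bookkeeping identity violated for ", what, ": ",
      paste(parts, collapse = " + "), " = ", sum(parts), " != ", total,
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Summarize a pipeline run with consistency checks
#'
#' Builds the machine-readable run summary and enforces the bookkeeping
#' identities: Class I + II + III + excluded = total candidates;
#' chromosome + plasmid = total; per-plasmid counts sum to the plasmid
#' total. Violations are errors, not warnings.
#'
#' @param call An `srna_call` from [call_srnas()].
#' @param ingest_tally Optional ingest tally from [read_alignments()],
#'   echoed into the summary.
#' @return An `srna_run_summary`: list with `n_reads`, `n_clusters`,
#'   `n_candidates`, `by_class`, `by_replicon_kind`, `by_replicon`,
#'   `category_tally`, `rejections`, `params`, `ingest_tally`.
#' @export
summarize_run <- function(call, ingest_tally = NULL) {
  stopifnot(inherits(call, "srna_call"))
  cand <- call$candidates
  by_class <- table(factor(cand$srna_class, levels = .SRNA_CLASSES))
  by_kind <- table(factor(cand$replicon_kind, levels = c("chromosome", "plasmid")))
  by_replicon <- table(cand$replicon)
  total <- nrow(cand)
  check_partition(total, as.integer(by_class), "candidate classes")
  check_partition(total, as.integer(by_kind), "chromosome/plasmid split")
  plasmids <- cand$replicon[cand$replicon_kind == "plasmid"]
  check_partition(
    as.integer(by_kind[["plasmid"]]),
    as.integer(table(plasmids)), "per-plasmid counts"
  )
  if (!is.null(ingest_tally)) {
    check_partition(
      ingest_tally$total,
      c(
        ingest_tally$kept, ingest_tally$unmapped,
        ingest_tally$non_primary, ingest_tally$low_mapq
      ),
      "ingest tally"
    )
  }
  structure(
    list(
      n_reads = call$n_reads,
      n_clusters = nrow(call$clusters),
      n_candidates = total,
      by_class = as.list(by_class),
      by_replicon_kind = as.list(by_kind),
      by_replicon = as.list(by_replicon),
      category_tally = call$category_tally,
      rejections = call$rejections,
      params = unclass(call$params),
      ingest_tally = ingest_tally
    ),
    class = "srna_run_summary"
  )
}

#' @export
print.srna_run_summary <- function(x, ...) {
  cat("<srna_run_summary>\n")
  cat(
    "  reads: ", x$n_reads, "  clusters: ", x$n_clusters,
    "  candidates: ", x$n_candidates, "\n",
    sep = ""
  )
  cat(
    "  by class: ",
    paste(names(x$by_class), unlist(x$by_class), sep = "=", collapse = ", "), "\n",
    sep = ""
  )
  cat(
    "  by replicon kind: ",
    paste(names(x$by_replicon_kind), unlist(x$by_replicon_kind),
      sep = "=", collapse = ", "
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' Write the run summary as JSON
#'
#' @param summary An `srna_run_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path) {
  x <- unclass(summary)
  x$category_tally <- as.data.frame(x$category_tally)
  x$rejections <- as.data.frame(x$rejections)
  if (!is.null(x$ingest_tally)) x$ingest_tally <- as.data.frame(x$ingest_tally)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export candidates to GFF3, BED6 and TSV
#'
#' The TSV mirrors the survey-style validation tables: columns `name`,
#' `location`, `start`, `end`, `strand` with 1-based inclusive coordinates.
#' BED6 is 0-based half-open with the read count as score; GFF3 records are
#' `ncRNA` features carrying class, support and associated-gene attributes.
#'
#' @param candidates Classified candidate tibble (or an `srna_call`).
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "bed", "gff3")`.
#' @param stem File name stem (default "candidates").
#' @return Named character vector of the files written, invisibly.
#' @export
export_candidates <- function(candidates, dir,
                              formats = c("tsv", "bed", "gff3"),
                              stem = "candidates") {
  if (inherits(candidates, "srna_call")) candidates <- candidates$candidates
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  name <- if ("cluster_id" %in% names(candidates) && nrow(candidates) > 0) {
    candidates$cluster_id
  } else {
    sprintf("srna_%04d", seq_len(nrow(candidates)))
  }
  out <- character(0)
  if ("tsv" %in% formats) {
    path <- file.path(dir, paste0(stem, ".tsv"))
    tab <- tibble(
      name = name,
      location = candidates$replicon,
      start = candidates$start + 1L, # 1-based inclusive
      end = candidates$end,
      strand = candidates$strand
    )
    extra <- intersect(c("srna_class", "associated_gene", "read_count"), names(candidates))
    for (col in extra) tab[[col]] <- candidates[[col]]
    readr::write_tsv(tab, path)
    out["tsv"] <- path
  }
  if ("bed" %in% formats) {
    path <- file.path(dir, paste0(stem, ".bed"))
    score <- if ("read_count" %in% names(candidates)) candidates$read_count else 0L
    bed <- data.frame(
      chrom = candidates$replicon,
      start = candidates$start, # BED is 0-based half-open already
      end = candidates$end,
      name = name,
      score = score,
      strand = candidates$strand
    )
    readr::write_tsv(bed, path, col_names = FALSE)
    out["bed"] <- path
  }
  if ("gff3" %in% formats) {
    path <- file.path(dir, paste0(stem, ".gff3"))
    lines <- "##gff-version 3"
    if (nrow(candidates) > 0) {
      attrs <- sprintf("ID=%s", name)
      for (col in c("srna_class", "read_count", "max_coverage", "associated_gene")) {
        if (col %in% names(candidates)) {
          v <- candidates[[col]]
          add <- sprintf(";%s=%s", sub("srna_", "", col), v)
          add[is.na(v)] <- ""
          attrs <- paste0(attrs, add)
        }
      }
      lines <- c(lines, sprintf(
        "%s\tsrnascan\tncRNA\t%d\t%d\t.\t%s\t.\t%s",
        candidates$replicon, candidates$start + 1L, candidates$end,
        candidates$strand, attrs
      ))
    }
    writeLines(lines, path)
    out["gff3"] <- path
  }
  invisible(out)
}

#' Read a candidate TSV back into internal coordinates
#'
#' Inverse of the TSV writer of [export_candidates()]: converts the 1-based
#' inclusive table back to 0-based half-open intervals, so export/import
#' round-trips are exact.
#'
#' @param path TSV path with columns `name`, `location`, `start`, `end`,
#'   `strand` (extra columns are preserved).
#' @return Tibble with `name`, `replicon`, `start`, `end`, `strand`, ...
#' @export
read_candidate_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("name", "location", "start", "end", "strand") %in% names(tab)))
  dplyr::transmute(tab,
    name = .data$name,
    replicon = .data$location,
    start = as.integer(.data$start) - 1L,
    end = as.integer(.data$end),
    strand = .data$strand,
    dplyr::across(dplyr::any_of(c("srna_class", "associated_gene", "read_count")))
  )
}

#' RT-PCR-validated candidate sRNAs (packaged reference table)
#'
#' The 27 candidates (9 intergenic, 11 antisense, 7 5'-leader) that were
#' validated by RT-PCR in the *Synechocystis* sp. PCC 6803 survey this
#' pipeline models, as printed: name, replicon, 1-based inclusive start/end,
#' strand, class. One antisense row (SYPCC_anti_04) is printed with end <
#' start in the source; it is kept verbatim, flagged `coordinate_valid =
#' FALSE`, and excluded from length computations (but not from row counts).
#'
#' @return Tibble with `name`, `location`, `start`, `end`, `strand`,
#'   `srna_class` (`I`/`II`/`III`), `is_plasmid`, `coordinate_valid`, and
#'   `length` (inclusive span; `NA` for coordinate-invalid rows).
#' @export
validated_srnas <- function() {
  path <- system.file("extdata", "validated_srnas.tsv",
    package = "srnascan", mustWork = TRUE
  )
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab$coordinate_valid <- tab$end >= tab$start
  tab$is_plasmid <- tab$location != "chromosome"
  tab$length <- ifelse(tab$coordinate_valid, tab$end - tab$start + 1L, NA_integer_)
  if (any(!tab$coordinate_valid)) {
    message(
      sum(!tab$coordinate_valid), " row(s) flagged coordinate-invalid (end < start): ",
      paste(tab$name[!tab$coordinate_valid], collapse = ", ")
    )
  }
  as_tibble(tab)
}

#' Run the whole discovery pipeline on files
#'
#' Thin orchestration over the stage functions: load annotation and
#' alignments, call candidates, summarize (with hard consistency checks)
#' and export.
#'
#' @param alignments SAM/BAM path.
#' @param fasta Genome FASTA path.
#' @param gff Annotation GFF3 path.
#' @param out_dir Output directory for exports and the JSON summary
#'   (`NULL` skips writing).
#' @param params An `srna_params`.
#' @return A list: `call` (`srna_call`), `summary` (`srna_run_summary`),
#'   `files` (paths written, if any).
#' @export
run_srna_pipeline <- function(alignments, fasta, gff, out_dir = NULL,
                              params = calling_params()) {
  ann <- read_genome_annotation(gff, fasta)
  aln <- read_alignments(alignments, ann, min_mapq = params$min_mapq)
  call <- call_srnas(aln$reads, ann, params)
  summary <- summarize_run(call, ingest_tally = aln$tally)
  files <- NULL
  if (!is.null(out_dir)) {
    files <- export_candidates(call, out_dir)
    files["summary"] <- write_run_summary(summary, file.path(out_dir, "run_summary.json"))
  }
  list(call = call, summary = summary, files = files)
}
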