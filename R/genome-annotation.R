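# Genome + annotation model: multi-replicon genomes, stranded features, and
# the interval arithmetic every downstream stage leans on. Internal
# coordinates are 0-based half-open; file I/O is 1-based inclusive.

.FEATURE_TYPES <- c("rRNA", "tRNA", "CDS", "misc_RNA")

#' Default GFF3 feature-type mapping
#'
#' Maps GFF3 `type` values onto the closed feature set used for read
#' categorization (`rRNA`, `tRNA`, `CDS`, `misc_RNA`). Bacterial annotations
#' rarely carry UTRs, so `gene`/`mRNA` records stand in for coding regions.
#' Types absent from the map are skipped (with a message) when loading.
#'
#' @return A named character vector: names are GFF3 types, values are the
#'   internal feature types.
#' @export
#' @examples
#' default_feature_type_map()
default_feature_type_map <- function() {
  c(
    CDS = "CDS", gene = "CDS", mRNA = "CDS",
    rRNA = "rRNA", tRNA = "tRNA",
    misc_RNA = "misc_RNA", ncRNA = "misc_RNA", sRNA = "misc_RNA"
  )
}

new_annotation <- function(replicons, features) {
  stopifnot(is.data.frame(replicons), is.data.frame(features))
  structure(
    list(replicons = as_tibble(replicons), features = as_tibble(features)),
    class = "srna_annotation"
  )
}

#' Construct an annotation from replicon and feature tables
#'
#' The in-memory annotation couples a replicon table (name, length,
#' plasmid flag) with a stranded feature table. Both validation and the
#' interval indexes used by [categorize_reads()] and [classify_candidates()]
#' are derived from these two tibbles.
#'
#' @param replicons Tibble with columns `replicon` (unique names), `length`
#'   (positive integer nt) and `is_plasmid` (logical).
#' @param features Tibble with columns `gene_id` (unique), `replicon`,
#'   `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`) and
#'   `feature_type` (one of rRNA, tRNA, CDS, misc_RNA). May have zero rows.
#' @return An object of class `srna_annotation`.
#' @export
annotation <- function(replicons, features = NULL) {
  if (is.null(features)) {
    features <- tibble(
      gene_id = character(), replicon = character(),
      start = integer(), end = integer(),
      strand = character(), feature_type = character()
    )
  }
  replicons <- as_tibble(replicons)
  features <- as_tibble(features)
  stopifnot(all(c("replicon", "length") %in% names(replicons)))
  if (!"is_plasmid" %in% names(replicons)) {
    replicons$is_plasmid <- !grepl("chr", replicons$replicon, ignore.case = TRUE)
  }
  if (anyDuplicated(replicons$replicon)) {
    stop("replicon names must be unique", call. = FALSE)
  }
  if (any(replicons$length < 1)) stop("replicon lengths must be >= 1", call. = FALSE)
  validate_features(features, replicons)
  new_annotation(replicons, features)
}

validate_features <- function(features, replicons) {
  if (nrow(features) == 0) return(invisible(features))
  needed <- c("gene_id", "replicon", "start", "end", "strand", "feature_type")
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(features$feature_type), .FEATURE_TYPES)
  if (length(bad_type)) {
    stop("unknown feature_type(s): ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  bad_rep <- setdiff(unique(features$replicon), replicons$replicon)
  if (length(bad_rep)) {
    stop("features reference unknown replicon(s): ", paste(bad_rep, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'", call. = FALSE)
  }
  len <- replicons$length[match(features$replicon, replicons$replicon)]
  ok <- features$start >= 0 & features$start < features$end & features$end <= len
  if (!all(ok)) {
    bad <- features$gene_id[!ok][1]
    stop("feature '", bad, "' lies outside its replicon bounds (or start >= end)",
      call. = FALSE
    )
  }
  invisible(features)
}

#' @export
print.srna_annotation <- function(x, ...) {
  cat(
    "<srna_annotation> ", nrow(x$replicons), " replicon(s) (",
    sum(x$replicons$is_plasmid), " plasmid), ",
    nrow(x$features), " feature(s)\n",
    sep = ""
  )
  if (nrow(x$features)) {
    print(table(x$features$feature_type))
  }
  invisible(x)
}

#' Load a genome annotation from GFF3 + FASTA
#'
#' Replicon names and lengths come from the FASTA; features come from the
#' GFF3, with types translated through `feature_type_map`. GFF3 records whose
#' type is absent from the map are skipped (a message reports how many).
#'
#' @param gff_path Path to a GFF3 file (1-based inclusive coordinates).
#' @param fasta_path Path to the matching multi-record genome FASTA.
#' @param feature_type_map Named character vector translating GFF3 types to
#'   the internal closed set; see [default_feature_type_map()].
#' @param plasmid_pattern Regular expression applied to replicon names;
#'   non-matching replicons are flagged as plasmids. The default treats any
#'   name containing "chr" as chromosomal.
#' @return An `srna_annotation`.
#' @export
read_genome_annotation <- function(gff_path, fasta_path,
                                   feature_type_map = default_feature_type_map(),
                                   plasmid_pattern = "chr") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  replicons <- tibble(
    replicon = names(seqs),
    length = Biostrings::width(seqs),
    is_plasmid = !grepl(plasmid_pattern, names(seqs), ignore.case = TRUE)
  )
  check_gff_lines(gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  feats <- tibble(
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gff_type = as.character(gr$type),
    gene_id = gff_gene_ids(gr)
  )
  mapped <- feats$gff_type %in% names(feature_type_map)
  if (any(!mapped)) {
    message(sum(!mapped), " GFF record(s) with unmapped feature type skipped: ",
      paste(unique(feats$gff_type[!mapped]), collapse = ", "))
  }
  feats <- feats[mapped, , drop = FALSE]
  feats$feature_type <- unname(feature_type_map[feats$gff_type])
  feats$gff_type <- NULL
  if (any(feats$strand == "*")) {
    stop("GFF features must be stranded (+/-)", call. = FALSE)
  }
  annotation(replicons, feats)
}

# Light structural validation so malformed lines are reported by number
# (rtracklayer's own errors do not carry line context).
check_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield < 8]
  if (length(bad)) {
    stop("malformed GFF line ", bad[1], ": expected >= 8 tab-separated fields",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

gff_gene_ids <- function(gr) {
  md <- S4Vectors::mcols(gr)
  id <- rep(NA_character_, length(gr))
  for (col in c("ID", "locus_tag", "Name", "gene")) {
    if (col %in% names(md)) {
      v <- as.character(md[[col]])
      id[is.na(id) & !is.na(v)] <- v[is.na(id) & !is.na(v)]
    }
  }
  auto <- is.na(id)
  id[auto] <- sprintf("feature_%04d", which(auto))
  make.unique(id)
}

#' Write an annotation back to GFF3 (and optionally FASTA)
#'
#' Inverse of [read_genome_annotation()]: feature intervals are emitted
#' 1-based inclusive, so a write/reload round-trip preserves coordinates
#' and strands exactly.
#'
#' @param ann An `srna_annotation`.
#' @param gff_path Output GFF3 path.
#' @return `gff_path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, gff_path) {
  stopifnot(inherits(ann, "srna_annotation"))
  gr <- features_granges(ann)
  names(gr) <- NULL
  gr$type <- ann$features$feature_type
  gr$ID <- ann$features$gene_id
  gr$phase <- ifelse(ann$features$feature_type == "CDS", 0L, NA_integer_)
  gr$source <- "srnascan"
  sl <- ann$replicons$length
  names(sl) <- ann$replicons$replicon
  GenomeInfoDb_safe_seqlengths(gr) <- sl
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(gff_path)
}

# assigning seqlengths requires seqlevels to be set in matching order
`GenomeInfoDb_safe_seqlengths<-` <- function(x, value) {
  GenomeInfoDb::seqlevels(x) <- names(value)
  GenomeInfoDb::seqlengths(x) <- value
  x
}

# GRanges view of the feature table (1-based closed, as GRanges requires)
features_granges <- function(ann) {
  f <- ann$features
  GenomicRanges::GRanges(
    seqnames = f$replicon,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand
  )
}

intervals_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$replicon,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

#' Overlap length between paired genomic intervals
#'
#' Vectorised over rows: element i of the result is the number of bases
#' shared by `a[i, ]` and `b[i, ]`. Intervals on different replicons or with
#' disjoint spans share 0 bases. Strand is deliberately ignored here —
#' callers (categorization, classification) enforce their own strand rules.
#'
#' @param a,b Data frames with columns `replicon`, `start`, `end`
#'   (0-based half-open). Rows are recycled if one side has a single row.
#' @return Integer vector of shared base counts.
#' @export
#' @examples
#' a <- tibble::tibble(replicon = "chr", start = 100, end = 200)
#' b <- tibble::tibble(replicon = "chr", start = 150, end = 230)
#' overlap_bases(a, b) # 50
overlap_bases <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  stopifnot(nrow(a) == nrow(b))
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  ov[a$replicon != b$replicon] <- 0L
  as.integer(pmax(0L, ov))
}

#' Upstream windows of annotated genes
#'
#' For each gene, the fixed-width window immediately 5' of its start on the
#' gene's own strand: `[start - window, start)` for `+` genes,
#' `[end, end + window)` for `-` genes, truncated at replicon boundaries.
#' Candidates wholly contained in such a window are 5'-leader (Class III)
#' calls.
#'
#' @param ann An `srna_annotation` (windows are computed for every feature;
#'   filter `features` beforehand to restrict, e.g. to CDS).
#' @param window Window width in nt (default 300, the upstream extent within
#'   which leader candidates are accepted).
#' @return Tibble with `gene_id`, `replicon`, `start`, `end`, `strand` and
#'   `truncated` (TRUE when clipped at a replicon edge). Genes whose window
#'   would be empty (gene abutting the boundary) are dropped.
#' @export
upstream_windows <- function(ann, window = 300L) {
  stopifnot(window >= 1)
  f <- ann$features
  L <- ann$replicons$length[match(f$replicon, ann$replicons$replicon)]
  plus <- f$strand == "+"
  w_start <- ifelse(plus, pmax(0L, f$start - window), f$end)
  w_end <- ifelse(plus, f$start, pmin(L, f$end + window))
  out <- tibble(
    gene_id = f$gene_id, replicon = f$replicon,
    start = as.integer(w_start), end = as.integer(w_end),
    strand = f$strand,
    truncated = (w_end - w_start) < window
  )
  out[out$end > out$start, , drop = FALSE]
}
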