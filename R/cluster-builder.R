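# Cluster assembly: transcribed regions are maximal chains of same-strand,
# same-replicon reads where consecutive reads share at least `min_overlap`
# bases. Half-open abutment (read ends exactly where the next begins) does
# NOT join reads. This is the core of the discovery method, so the sweep is
# implemented here directly; tests cross-check it against a quadratic
# union-find oracle and an interval-merge identity.

#' Select the reads that seed cluster assembly
#'
#' Clusters are built from the non-annotated read set: reads categorized
#' `intergenic` or `antisense` (optionally also `misc_rna`). Reads that
#' sense-map to annotated genes never seed sRNA clusters.
#'
#' @param reads Categorized reads (see [categorize_reads()]).
#' @param include_misc Also keep `misc_rna` reads (default `FALSE`,
#'   mirroring reporting that keeps unknown-function RNA as its own slice).
#' @return The selected subset of `reads`.
#' @export
select_cluster_reads <- function(reads, include_misc = FALSE) {
  stopifnot("category" %in% names(reads))
  keep <- c("intergenic", "antisense", if (include_misc) "misc_rna")
  dplyr::filter(reads, .data$category %in% keep)
}

#' Assemble reads into transcribed clusters
#'
#' Two reads belong to the same cluster iff they are connected through a
#' chain of pairwise same-strand overlaps of at least `min_overlap` shared
#' bases on one replicon. Each cluster records its union span, member
#' count, and per-base coverage statistics over the span.
#'
#' @param reads Tibble of mapped reads (`read_id`, `replicon`, `start`,
#'   `end`, `strand`), typically from [select_cluster_reads()].
#' @param min_overlap Minimum shared bases for two reads to chain
#'   (default 1; abutting reads never chain).
#' @return Tibble of clusters sorted by (replicon, strand, start):
#'   `cluster_id`, `replicon`, `start`, `end`, `strand`, `read_count`,
#'   `max_coverage`, `mean_coverage`, and `member_read_ids` (list-column).
#' @export
build_clusters <- function(reads, min_overlap = 1L) {
  stopifnot(min_overlap >= 1)
  empty <- tibble(
    cluster_id = character(), replicon = character(),
    start = integer(), end = integer(), strand = character(),
    read_count = integer(), max_coverage = integer(),
    mean_coverage = double(), member_read_ids = list()
  )
  if (nrow(reads) == 0) return(empty)
  stopifnot(all(reads$strand %in% c("+", "-")), all(reads$end > reads$start))
  out <- reads %>%
    dplyr::group_by(.data$replicon, .data$strand) %>%
    dplyr::group_modify(~ sweep_clusters(.x, min_overlap)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$replicon, .data$strand, .data$start)
  out$cluster_id <- sprintf("cluster_%05d", seq_len(nrow(out)))
  dplyr::select(
    out, "cluster_id", "replicon", "start", "end", "strand",
    "read_count", "max_coverage", "mean_coverage", "member_read_ids"
  )
}

# one replicon+strand group: sorted sweep over read starts
sweep_clusters <- function(g, min_overlap) {
  ord <- order(g$start, g$end)
  s <- g$start[ord]
  e <- g$end[ord]
  ids <- g$read_id[ord]
  reach <- cummax(e)
  new_cluster <- c(TRUE, s[-1] > reach[-length(reach)] - min_overlap)
  cid <- cumsum(new_cluster)
  split_idx <- split(seq_along(cid), cid)
  purrr::map_dfr(split_idx, function(idx) {
    S <- min(s[idx])
    E <- max(e[idx])
    depth <- depth_vector(S, E, s[idx], e[idx])
    tibble(
      start = S, end = E,
      read_count = length(idx),
      max_coverage = max(depth),
      mean_coverage = mean(depth),
      member_read_ids = list(ids[idx])
    )
  })
}

# per-base depth over [S, E) from member read spans, via +1/-1 events
depth_vector <- function(S, E, starts, ends) {
  n <- E - S
  delta <- integer(n + 1L)
  si <- starts - S + 1L
  ei <- ends - S + 1L
  for (k in seq_along(si)) {
    delta[si[k]] <- delta[si[k]] + 1L
    delta[ei[k]] <- delta[ei[k]] - 1L
  }
  cumsum(delta[seq_len(n)])
}

#' Per-base coverage profile of one cluster
#'
#' @param cluster A single-row cluster tibble (from [build_clusters()]).
#' @param reads The read tibble the cluster was built from (only member
#'   reads contribute).
#' @return Integer vector of depth at each base of the cluster span; its
#'   maximum equals `max_coverage` and every value is >= 1.
#' @export
cluster_coverage <- function(cluster, reads) {
  stopifnot(nrow(cluster) == 1)
  members <- reads[reads$read_id %in% cluster$member_read_ids[[1]] &
    reads$replicon == cluster$replicon &
    reads$strand == cluster$strand, , drop = FALSE]
  depth_vector(cluster$start, cluster$end, members$start, members$end)
}
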