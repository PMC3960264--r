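# Fixture builders and independent oracles used across the suite.

# tiny two-replicon annotation built in code
toy_annotation <- function() {
  annotation(
    replicons = tibble::tibble(
      replicon = c("chr", "pA"),
      length = c(10000L, 3000L),
      is_plasmid = c(FALSE, TRUE)
    ),
    features = tibble::tibble(
      gene_id = c("rrn1", "trn1", "cds1", "cds2", "misc1"),
      replicon = c("chr", "chr", "chr", "chr", "pA"),
      start = c(0L, 3100L, 4000L, 7000L, 500L),
      end = c(3000L, 3190L, 5500L, 8200L, 700L),
      strand = c("+", "+", "+", "-", "+"),
      feature_type = c("rRNA", "tRNA", "CDS", "CDS", "misc_RNA")
    )
  )
}

mk_reads <- function(replicon, start, end, strand, id = NULL) {
  n <- max(length(replicon), length(start), length(end), length(strand))
  tibble::tibble(
    read_id = if (is.null(id)) sprintf("r%03d", seq_len(n)) else id,
    replicon = rep_len(replicon, n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    strand = rep_len(strand, n),
    mapq = 60L
  )
}

# random annotation on one or more replicons, features never overlapping
random_annotation <- function(n_features = 20, n_replicons = 2, replicon_len = 5000) {
  reps <- tibble::tibble(
    replicon = paste0("R", seq_len(n_replicons)),
    length = as.integer(replicon_len),
    is_plasmid = c(FALSE, rep(TRUE, n_replicons - 1))
  )
  feats <- lapply(reps$replicon, function(r) {
    k <- max(1L, rpois(1, n_features / n_replicons))
    # sample disjoint intervals by splitting the replicon
    cuts <- sort(sample.int(replicon_len - 1, min(2 * k, replicon_len %/% 3)))
    if (length(cuts) < 2) return(NULL)
    s <- cuts[seq(1, length(cuts) - 1, by = 2)]
    e <- cuts[seq(2, length(cuts), by = 2)]
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    if (!length(s)) return(NULL)
    tibble::tibble(
      gene_id = paste0(r, "_g", seq_along(s)),
      replicon = r,
      start = as.integer(s), end = as.integer(e),
      strand = sample(c("+", "-"), length(s), replace = TRUE),
      feature_type = sample(c("rRNA", "tRNA", "CDS", "misc_RNA"),
        length(s),
        replace = TRUE, prob = c(0.1, 0.2, 0.55, 0.15)
      )
    )
  })
  annotation(reps, dplyr::bind_rows(feats))
}

random_reads <- function(ann, n, read_len = 81) {
  idx <- sample.int(nrow(ann$replicons), n, replace = TRUE, prob = ann$replicons$length)
  L <- ann$replicons$length[idx]
  s <- vapply(L, function(l) sample.int(l - read_len, 1), integer(1))
  mk_reads(ann$replicons$replicon[idx], s, s + read_len,
    sample(c("+", "-"), n, replace = TRUE))
}

# --- linear-scan categorization oracle (checks every feature) -------------
oracle_categorize <- function(read, ann) {
  f <- ann$features
  ov <- pmax(0L, pmin(read$end, f$end) - pmax(read$start, f$start))
  ov[f$replicon != read$replicon] <- 0L
  sense <- f$strand == read$strand
  cat_of <- c(rRNA = "rRNA", tRNA = "tRNA", CDS = "mRNA", misc_RNA = "misc_rna")
  prec <- c(rRNA = 1, tRNA = 2, mRNA = 3)
  sg <- which(ov > 0 & sense & f$feature_type != "misc_RNA")
  if (length(sg)) {
    cats <- cat_of[f$feature_type[sg]]
    best <- sg[order(-ov[sg], prec[cats])][1]
    return(unname(cat_of[f$feature_type[best]]))
  }
  if (any(ov > 0 & sense)) return("misc_rna")
  if (any(ov > 0 & !sense)) return("antisense")
  "intergenic"
}

# --- O(n^2) union-find clustering oracle ----------------------------------
oracle_clusters <- function(reads, min_overlap = 1L) {
  n <- nrow(reads)
  if (n == 0) return(tibble::tibble())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j >= i) next
      same <- reads$replicon[i] == reads$replicon[j] &&
        reads$strand[i] == reads$strand[j]
      ov <- min(reads$end[i], reads$end[j]) - max(reads$start[i], reads$start[j])
      if (same && ov >= min_overlap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- dplyr::group_by(
    dplyr::mutate(reads, .root = root),
    .data$replicon, .data$strand, .data$.root
  )
  out <- dplyr::summarise(out,
    start = min(.data$start), end = max(.data$end),
    read_count = dplyr::n(), .groups = "drop"
  )
  dplyr::arrange(
    dplyr::select(out, -".root"),
    .data$replicon, .data$strand, .data$start
  )
}

# --- brute-force local duplex alignment oracle (tiny sequences only) ------
# Smith-Waterman over srna vs reverse complement of target, linear gaps.
oracle_duplex_score <- function(srna, target, match = 2, gu = 1,
                                mismatch = -1, gap = -3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  t <- strsplit(toupper(gsub("U", "T", target)), "")[[1]]
  rc <- rev(unname(comp[t]))
  p <- strsplit(toupper(gsub("U", "T", srna)), "")[[1]]
  sub_score <- function(a, b) {
    if (a == b) return(match)
    if ((a == "G" && b == "A") || (a == "T" && b == "C")) return(gu)
    mismatch
  }
  n <- length(p); m <- length(rc)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(
        0,
        H[i, j] + sub_score(p[i], rc[j]),
        H[i, j + 1] + gap,
        H[i + 1, j] + gap
      )
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# naive per-position depth recount
oracle_depth <- function(S, E, starts, ends) {
  vapply(seq.int(S, E - 1L), function(p) sum(starts <= p & ends > p), integer(1))
}
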