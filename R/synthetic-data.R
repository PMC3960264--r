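# Synthetic study generator: a multi-replicon genome (1 chromosome + 4
# plasmids) with non-overlapping annotated genes, planted sRNAs of the
# three classes at controlled read depths, optional background noise and a
# category mixture, emitted as pre-aligned SAM records. Everything is
# deterministic under the config seed.

#' Simulation configuration
#'
#' Defaults emulate the study regime at desk scale: an 81-nt strand-specific
#' read library over one chromosome plus the four megaplasmids, with 30
#' planted sRNAs (10 per class) at 20 reads depth and lengths 60-180 nt.
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical outputs.
#' @param replicons Tibble of `replicon`, `length`, `is_plasmid`. Default:
#'   a 100 kb chromosome and four 15-20 kb plasmids named after the
#'   megaplasmids that carry sRNAs in cyanobacteria.
#' @param n_genes Named integer vector, genes per replicon.
#' @param read_length Read length in nt (default 81).
#' @param planted Tibble of `class` (`"I"`, `"II"`, `"III"`), `depth`
#'   (reads) and `length` (nt) for each planted sRNA; `NULL` plants the
#'   default 30.
#' @param background_rate Poisson background reads per kb on random strands
#'   (default 0).
#' @param category_mixture Named fractions over rRNA/tRNA/mRNA/intergenic
#'   for mixture reads (must sum to 1).
#' @param n_mixture_reads Number of mixture reads to emit (default 0).
#' @param min_gap Minimum intergenic gap between simulated genes (default
#'   400 nt, comfortably above the 300-nt leader window).
#' @return A list of class `srna_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              replicons = NULL,
                              n_genes = NULL,
                              read_length = 81L,
                              planted = NULL,
                              background_rate = 0,
                              category_mixture = c(
                                rRNA = 0.4, tRNA = 0.3,
                                mRNA = 0.2, intergenic = 0.1
                              ),
                              n_mixture_reads = 0L,
                              min_gap = 400L) {
  if (is.null(replicons)) {
    replicons <- tibble(
      replicon = c("chromosome", "pSYSX", "pSYSG", "pSYSA", "pSYSM"),
      length = c(100000L, 20000L, 15000L, 20000L, 20000L),
      is_plasmid = c(FALSE, TRUE, TRUE, TRUE, TRUE)
    )
  }
  if (is.null(n_genes)) {
    n_genes <- c(chromosome = 60L, pSYSX = 8L, pSYSG = 6L, pSYSA = 8L, pSYSM = 8L)
    n_genes <- n_genes[replicons$replicon[replicons$replicon %in% names(n_genes)]]
    if (length(n_genes) != nrow(replicons)) {
      stop("supply n_genes for custom replicons", call. = FALSE)
    }
  }
  if (is.null(planted)) {
    planted <- tibble(
      class = rep(c("I", "II", "III"), each = 10),
      depth = 20L,
      length = rep(as.integer(round(seq(60, 180, length.out = 10))), times = 3)
    )
  }
  stopifnot(
    abs(sum(category_mixture) - 1) < 1e-9,
    all(planted$depth >= 0), read_length >= 1,
    all(c("rRNA", "tRNA", "mRNA", "intergenic") %in% names(category_mixture))
  )
  structure(
    list(
      seed = as.integer(seed), replicons = as_tibble(replicons),
      n_genes = n_genes, read_length = as.integer(read_length),
      planted = as_tibble(planted), background_rate = background_rate,
      category_mixture = category_mixture,
      n_mixture_reads = as.integer(n_mixture_reads),
      min_gap = as.integer(min_gap)
    ),
    class = "srna_sim_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of
#'   [simulation_config()] (`replicons` as a list of name/length/is_plasmid
#'   records, `planted` as a list of class/depth/length records).
#' @return An `srna_sim_config`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c(
    "seed", "read_length", "background_rate",
    "n_mixture_reads", "min_gap"
  )) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$replicons)) args$replicons <- dplyr::bind_rows(y$replicons)
  if (!is.null(y$n_genes)) args$n_genes <- unlist(y$n_genes)
  if (!is.null(y$planted)) args$planted <- dplyr::bind_rows(y$planted)
  if (!is.null(y$category_mixture)) args$category_mixture <- unlist(y$category_mixture)
  do.call(simulation_config, args)
}

# gene length by type; tRNA genes stay just above the read length so a
# read can sit fully inside them
sim_gene_length <- function(type) {
  switch(type,
    rRNA = sample(1600:2900, 1),
    tRNA = sample(85:95, 1),
    misc_RNA = sample(150:250, 1),
    CDS = sample(300:1500, 1)
  )
}

#' Simulate a multi-replicon genome with annotation
#'
#' Places non-overlapping genes (mostly CDS with a sprinkling of rRNA, tRNA
#' and misc_RNA) on random strands, separated by gaps of at least
#' `min_gap`, and draws uniform random sequence. Deterministic under the
#' config seed.
#'
#' @param config An `srna_sim_config`.
#' @return A list of class `srna_sim_genome`: `genome` (named
#'   `DNAStringSet`) and `annotation` (`srna_annotation`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "srna_sim_config"))
  set.seed(config$seed)
  feats <- list()
  for (i in seq_len(nrow(config$replicons))) {
    rep_name <- config$replicons$replicon[i]
    L <- config$replicons$length[i]
    n <- config$n_genes[[rep_name]]
    is_chromosome <- !config$replicons$is_plasmid[i]
    if (is_chromosome && n >= 12) {
      # a bacterial chromosome always carries rRNA operons, tRNAs and a few
      # non-coding RNAs; guarantee that complement, fill the rest with CDS
      types <- sample(c(
        rep("rRNA", 2), rep("tRNA", 5), rep("misc_RNA", 2),
        rep("CDS", n - 9)
      ))
    } else {
      types <- sample(c("CDS", "rRNA", "tRNA", "misc_RNA"), n,
        replace = TRUE, prob = c(0.85, 0.03, 0.08, 0.04)
      )
    }
    lens <- vapply(types, sim_gene_length, numeric(1))
    need <- sum(lens) + (n + 1L) * config$min_gap
    if (need > L) {
      stop(
        "cannot fit ", n, " genes (", need, " nt incl. gaps) on ",
        rep_name, " (", L, " nt)",
        call. = FALSE
      )
    }
    extra <- L - need
    # broken-stick allocation of the spare space over the n+1 gaps
    cuts <- sort(sample.int(extra + 1L, n, replace = TRUE) - 1L)
    gaps <- config$min_gap + diff(c(0L, cuts, extra))
    starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0L, lens[-n])) # 0-based
    feats[[rep_name]] <- tibble(
      gene_id = sprintf("%s_g%03d", rep_name, seq_len(n)),
      replicon = rep_name,
      start = as.integer(starts),
      end = as.integer(starts + lens),
      strand = sample(c("+", "-"), n, replace = TRUE),
      feature_type = types
    )
  }
  features <- dplyr::bind_rows(feats)
  ann <- annotation(config$replicons, features)
  genome <- Biostrings::DNAStringSet(vapply(
    config$replicons$length,
    function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)
  ))
  names(genome) <- config$replicons$replicon
  structure(list(genome = genome, annotation = ann), class = "srna_sim_genome")
}

# free gaps between consecutive features (any strand), including the two
# replicon ends; columns: replicon, gap_start, gap_end, prev/next gene info
free_gaps <- function(ann) {
  purrr::map_dfr(ann$replicons$replicon, function(rep_name) {
    L <- ann$replicons$length[ann$replicons$replicon == rep_name]
    f <- dplyr::arrange(
      ann$features[ann$features$replicon == rep_name, , drop = FALSE],
      .data$start
    )
    bounds_start <- c(0L, f$end)
    bounds_end <- c(f$start, L)
    tibble(
      replicon = rep_name,
      gap_start = bounds_start,
      gap_end = bounds_end,
      next_gene = c(f$gene_id, NA),
      next_strand = c(f$strand, NA),
      prev_gene = c(NA, f$gene_id),
      prev_strand = c(NA, f$strand)
    )
  })
}

#' Plant sRNAs and emit strand-specific reads
#'
#' Places each requested sRNA so that it satisfies its class definition by
#' construction: Class I wholly intergenic and clear of every leader
#' window, Class II inside a CDS on the opposite strand, Class III wholly
#' within the 300-nt upstream window of a same-strand gene. Each sRNA
#' emits `depth` reads of `read_length` nt whose starts are uniform within
#' the sRNA span (reads truncate to the span when the sRNA is shorter than
#' a read). Background reads are scattered Poisson per kb; mixture reads
#' are placed inside features (or gaps) according to `category_mixture`.
#'
#' @param config An `srna_sim_config`.
#' @param sim A `srna_sim_genome` from [simulate_genome()]; simulated
#'   fresh from `config` when omitted.
#' @param leader_window Window used for Class III placement (default 300).
#' @return A list of class `srna_sim_reads`: `reads` (mapped-read tibble),
#'   `truth` (planted records: `srna_id`, `class`, `replicon`, `start`,
#'   `end`, `strand`, `depth`, `length`, `associated_gene`), plus the
#'   `genome` and `annotation` carried through.
#' @export
simulate_reads <- function(config, sim = NULL, leader_window = 300L) {
  stopifnot(inherits(config, "srna_sim_config"))
  if (is.null(sim)) sim <- simulate_genome(config)
  ann <- sim$annotation
  set.seed(config$seed + 1L)
  truth <- plant_srnas(config$planted, ann, leader_window)
  rl <- config$read_length

  read_tabs <- list()
  if (nrow(truth)) {
    read_tabs$planted <- purrr::pmap_dfr(
      truth[, c("srna_id", "replicon", "start", "end", "strand", "depth")],
      function(srna_id, replicon, start, end, strand, depth) {
        if (depth == 0) return(NULL)
        len <- end - start
        if (len >= rl) {
          st <- start + sample.int(len - rl + 1L, depth, replace = TRUE) - 1L
          en <- st + rl
        } else {
          st <- rep(start, depth)
          en <- rep(end, depth)
        }
        tibble(
          read_id = sprintf("%s_read%04d", srna_id, seq_len(depth)),
          replicon = replicon, start = st, end = en, strand = strand,
          mapq = 60L
        )
      }
    )
  }

  total_kb <- sum(ann$replicons$length) / 1000
  n_bg <- stats::rpois(1, config$background_rate * total_kb)
  if (n_bg > 0) {
    idx <- sample.int(nrow(ann$replicons), n_bg,
      replace = TRUE,
      prob = ann$replicons$length
    )
    L <- ann$replicons$length[idx]
    st <- vapply(L, function(l) sample.int(max(1L, l - rl + 1L), 1) - 1L, integer(1))
    read_tabs$background <- tibble(
      read_id = sprintf("bg_read%06d", seq_len(n_bg)),
      replicon = ann$replicons$replicon[idx],
      start = st, end = pmin(st + rl, L),
      strand = sample(c("+", "-"), n_bg, replace = TRUE),
      mapq = 60L
    )
  }

  if (config$n_mixture_reads > 0) {
    read_tabs$mixture <- mixture_reads(config, ann)
  }

  reads <- dplyr::bind_rows(read_tabs)
  if (is.null(reads) || nrow(reads) == 0) {
    reads <- tibble(
      read_id = character(), replicon = character(), start = integer(),
      end = integer(), strand = character(), mapq = integer()
    )
  }
  structure(
    list(
      reads = reads, truth = truth,
      genome = sim$genome, annotation = ann
    ),
    class = "srna_sim_reads"
  )
}

# choose positions satisfying each class definition; one planted sRNA per
# free gap / gene so planted intervals never touch each other
plant_srnas <- function(planted, ann, leader_window) {
  empty <- tibble(
    srna_id = character(), class = character(), replicon = character(),
    start = integer(), end = integer(), strand = character(),
    depth = integer(), length = integer(), associated_gene = character()
  )
  if (is.null(planted) || nrow(planted) == 0) return(empty)
  gaps <- free_gaps(ann)
  gaps$len <- gaps$gap_end - gaps$gap_start
  gaps$used <- FALSE
  genes <- ann$features
  genes$used <- FALSE
  # place long sRNAs first so packing never fails for want of ordering
  ord <- order(match(planted$class, c("I", "III", "II")), -planted$length)
  rows <- vector("list", nrow(planted))
  margin <- leader_window + 1L # clearance that keeps Class I out of leader windows
  for (k in ord) {
    cls <- planted$class[k]
    len <- planted$length[k]
    if (cls == "I") {
      ok <- which(!gaps$used & gaps$len >= len + 2L * margin)
      if (!length(ok)) stop("no intergenic gap can host a Class I sRNA of ", len, " nt",
        call. = FALSE
      )
      g <- ok[sample.int(length(ok), 1)]
      lo <- gaps$gap_start[g] + margin
      hi <- gaps$gap_end[g] - margin - len
      s <- lo + sample.int(hi - lo + 1L, 1) - 1L
      rows[[k]] <- tibble(
        class = "I", replicon = gaps$replicon[g],
        start = s, end = s + len,
        strand = sample(c("+", "-"), 1), associated_gene = NA_character_
      )
      gaps$used[g] <- TRUE
    } else if (cls == "II") {
      ok <- which(!genes$used & genes$feature_type == "CDS" &
        (genes$end - genes$start) >= len + 10L)
      if (!length(ok)) stop("no CDS can host a Class II sRNA of ", len, " nt",
        call. = FALSE
      )
      g <- ok[sample.int(length(ok), 1)]
      lo <- genes$start[g] + 5L
      hi <- genes$end[g] - 5L - len
      s <- lo + sample.int(hi - lo + 1L, 1) - 1L
      rows[[k]] <- tibble(
        class = "II", replicon = genes$replicon[g],
        start = s, end = s + len,
        strand = if (genes$strand[g] == "+") "-" else "+",
        associated_gene = genes$gene_id[g]
      )
      genes$used[g] <- TRUE
    } else if (cls == "III") {
      if (len > leader_window) {
        stop("Class III sRNA longer than the leader window", call. = FALSE)
      }
      # upstream gap of a '+' gene precedes it; of a '-' gene follows it
      up <- dplyr::bind_rows(
        dplyr::filter(
          gaps, !gaps$used, !is.na(gaps$next_gene), gaps$next_strand == "+"
        ) %>%
          dplyr::mutate(gene = .data$next_gene, gstrand = "+"),
        dplyr::filter(
          gaps, !gaps$used, !is.na(gaps$prev_gene), gaps$prev_strand == "-"
        ) %>%
          dplyr::mutate(gene = .data$prev_gene, gstrand = "-")
      )
      up <- up[up$len >= len + 5L & !genes$used[match(up$gene, genes$gene_id)], , drop = FALSE]
      if (!nrow(up)) stop("no upstream gap can host a Class III sRNA of ", len, " nt",
        call. = FALSE
      )
      g <- sample.int(nrow(up), 1)
      slack <- min(leader_window - len, up$len[g] - len)
      offset <- sample.int(slack + 1L, 1) - 1L
      if (up$gstrand[g] == "+") {
        e <- up$gap_end[g] - offset
        s <- e - len
      } else {
        s <- up$gap_start[g] + offset
        e <- s + len
      }
      rows[[k]] <- tibble(
        class = "III", replicon = up$replicon[g],
        start = s, end = e, strand = up$gstrand[g],
        associated_gene = up$gene[g]
      )
      gaps$used[gaps$replicon == up$replicon[g] &
        gaps$gap_start == up$gap_start[g]] <- TRUE
      genes$used[genes$gene_id == up$gene[g]] <- TRUE
    } else {
      stop("unknown planted class: ", cls, call. = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$depth <- as.integer(planted$depth)
  out$length <- as.integer(planted$length)
  out$srna_id <- sprintf("planted_%s_%02d", out$class, seq_len(nrow(out)))
  dplyr::select(
    out, "srna_id", "class", "replicon", "start", "end", "strand",
    "depth", "length", "associated_gene"
  )
}

# mixture reads: category drawn from the mixture, read placed fully inside
# a feature of that type (sense) or a free gap
mixture_reads <- function(config, ann) {
  rl <- config$read_length
  mix <- config$category_mixture
  cats <- sample(names(mix), config$n_mixture_reads, replace = TRUE, prob = mix)
  gaps <- free_gaps(ann)
  gaps <- gaps[gaps$gap_end - gaps$gap_start >= rl, , drop = FALSE]
  feat_of <- list(
    rRNA = which(ann$features$feature_type == "rRNA"),
    tRNA = which(ann$features$feature_type == "tRNA"),
    mRNA = which(ann$features$feature_type == "CDS")
  )
  purrr::imap_dfr(cats, function(cat, i) {
    if (cat == "intergenic") {
      g <- sample.int(nrow(gaps), 1)
      lo <- gaps$gap_start[g]
      hi <- gaps$gap_end[g] - rl
      s <- lo + sample.int(hi - lo + 1L, 1) - 1L
      tibble(
        read_id = sprintf("mix_%s_%06d", cat, i),
        replicon = gaps$replicon[g], start = s, end = s + rl,
        strand = sample(c("+", "-"), 1), mapq = 60L
      )
    } else {
      pool <- feat_of[[cat]]
      if (!length(pool)) {
        stop("category mixture requests ", cat,
          " reads but the annotation has no such feature",
          call. = FALSE
        )
      }
      f <- pool[sample.int(length(pool), 1)]
      fs <- ann$features$start[f]
      fe <- ann$features$end[f]
      if (fe - fs >= rl) {
        s <- fs + sample.int(fe - fs - rl + 1L, 1) - 1L
        e <- s + rl
      } else {
        s <- fs
        e <- fe
      }
      tibble(
        read_id = sprintf("mix_%s_%06d", cat, i),
        replicon = ann$features$replicon[f], start = s, end = e,
        strand = ann$features$strand[f], mapq = 60L
      )
    }
  })
}

#' Write simulated reads as SAM
#'
#' Emits one primary single-end record per read; sequences are the genomic
#' substring (error-free simulation) with constant Phred-40 qualities.
#'
#' @param sim An `srna_sim_reads` (or any list with `reads` and `genome`).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path) {
  reads <- sim$reads
  genome <- sim$genome
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome))
  )
  if (nrow(reads) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  seqs <- purrr::pmap_chr(
    reads[, c("replicon", "start", "end")],
    function(replicon, start, end) {
      as.character(Biostrings::subseq(genome[[replicon]], start + 1L, end))
    }
  )
  recs <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
    reads$read_id,
    ifelse(reads$strand == "-", 16L, 0L),
    reads$replicon,
    reads$start + 1L,
    reads$mapq,
    reads$end - reads$start,
    seqs,
    strrep("I", reads$end - reads$start)
  )
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write the simulated genome and annotation to disk
#'
#' @param sim An `srna_sim_genome` or `srna_sim_reads`.
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_simulated_genome <- function(sim, fasta_path, gff_path) {
  ann <- if (!is.null(sim$annotation)) sim$annotation else sim$ann
  Biostrings::writeXStringSet(sim$genome, fasta_path)
  write_annotation_gff3(ann, gff_path)
  invisible(list(fasta = fasta_path, gff = gff_path))
}

#' Score candidate recovery against the planted truth
#'
#' A planted sRNA is recovered when some candidate on the same replicon and
#' strand overlaps it reciprocally by at least `min_reciprocal_overlap`
#' (the shared bases must be at least that fraction of BOTH spans). Class
#' agreement is recorded separately, so the confusion table distinguishes
#' located-but-mislabelled calls.
#'
#' @param candidates Classified candidate tibble (or an `srna_call`).
#' @param truth Planted-truth tibble from [simulate_reads()].
#' @param min_reciprocal_overlap Fraction in (0, 1] (default 0.5).
#' @return An `srna_recovery` object: list with `sensitivity`,
#'   `precision` (NA when there are no candidates), `matches` (planted x
#'   candidate pairs with class columns), and `confusion` (planted class x
#'   called class counts, "missed" column included).
#' @export
evaluate_recovery <- function(candidates, truth, min_reciprocal_overlap = 0.5) {
  if (inherits(candidates, "srna_call")) candidates <- candidates$candidates
  stopifnot(min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  class_map <- c(I_intergenic = "I", II_antisense = "II", III_leader = "III")
  n_truth <- nrow(truth)
  n_cand <- nrow(candidates)
  matched_cand <- logical(n_cand)
  match_rows <- list()
  for (i in seq_len(if (n_cand > 0) n_truth else 0L)) {
    ov <- overlap_bases(candidates, truth[i, , drop = FALSE])
    same <- candidates$strand == truth$strand[i]
    rec <- ov / pmax(1L, candidates$end - candidates$start) >= min_reciprocal_overlap &
      ov / (truth$end[i] - truth$start[i]) >= min_reciprocal_overlap & same
    if (any(rec)) {
      j <- which(rec)[which.max(ov[rec])]
      matched_cand[j] <- TRUE
      match_rows[[length(match_rows) + 1L]] <- tibble(
        srna_id = truth$srna_id[i],
        planted_class = truth$class[i],
        cluster_id = candidates$cluster_id[j],
        called_class = dplyr::coalesce(
          class_map[candidates$srna_class[j]],
          candidates$srna_class[j]
        ),
        reciprocal_overlap = min(
          ov[j] / (candidates$end[j] - candidates$start[j]),
          ov[j] / (truth$end[i] - truth$start[i])
        )
      )
    }
  }
  matches <- dplyr::bind_rows(match_rows)
  recovered <- if (nrow(matches)) nrow(matches) else 0L
  planted_lab <- factor(truth$class, levels = c("I", "II", "III"))
  called_lab <- rep("missed", n_truth)
  if (recovered) {
    called_lab[match(matches$srna_id, truth$srna_id)] <- matches$called_class
  }
  confusion <- table(
    planted = planted_lab,
    called = factor(called_lab, levels = c("I", "II", "III", "excluded_sense", "missed"))
  )
  structure(
    list(
      sensitivity = if (n_truth > 0) recovered / n_truth else NA_real_,
      precision = if (n_cand > 0) sum(matched_cand) / n_cand else NA_real_,
      matches = matches,
      confusion = confusion,
      n_planted = n_truth,
      n_candidates = n_cand
    ),
    class = "srna_recovery"
  )
}

#' @export
print.srna_recovery <- function(x, ...) {
  cat("<srna_recovery> sensitivity ", format(x$sensitivity, digits = 3),
    ", precision ", format(x$precision, digits = 3),
    " (", x$n_planted, " planted, ", x$n_candidates, " candidates)\n",
    sep = ""
  )
  print(x$confusion)
  invisible(x)
}
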