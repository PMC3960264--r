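mk_cluster <- function(replicon = "chr", start = 0L, end = 100L, strand = "+",
                       read_count = 10L, max_coverage = read_count) {
  n <- max(length(start), length(end), length(read_count))
  tibble::tibble(
    cluster_id = sprintf("c%03d", seq_len(n)),
    replicon = rep_len(replicon, n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    strand = rep_len(strand, n),
    read_count = as.integer(rep_len(read_count, n)),
    max_coverage = as.integer(rep_len(max_coverage, n)),
    mean_coverage = 1,
    member_read_ids = replicate(n, character(0), simplify = FALSE)
  )
}

test_that("candidate filter applies inclusive depth and length thresholds", {
  cl <- mk_cluster(
    start = c(0L, 0L, 0L, 0L),
    end = c(120L, 49L, 50L, 40L),
    read_count = c(9L, 10L, 10L, 8L)
  )
  res <- filter_candidates(cl, calling_params())
  expect_equal(res$candidates$cluster_id, "c003") # depth 10, length 50 kept
  expect_equal(res$rejections$count[res$rejections$reason == "depth"], 1)
  expect_equal(res$rejections$count[res$rejections$reason == "length"], 1)
  expect_equal(res$rejections$count[res$rejections$reason == "both"], 1)
  expect_equal(res$candidates$length, 50L)
})

test_that("the depth statistic is switchable to peak coverage", {
  cl <- mk_cluster(end = 200L, read_count = 12L, max_coverage = 4L)
  by_reads <- filter_candidates(cl, calling_params(depth_statistic = "read_count"))
  by_cov <- filter_candidates(cl, calling_params(depth_statistic = "max_coverage"))
  expect_equal(nrow(by_reads$candidates), 1)
  expect_equal(nrow(by_cov$candidates), 0)
})

test_that("classification follows the excluded > antisense > leader > intergenic precedence", {
  reps <- tibble::tibble(replicon = "chr", length = 10000L, is_plasmid = FALSE)
  feats <- tibble::tibble(
    gene_id = c("gminus", "gplus", "gleader"),
    replicon = "chr",
    start = c(150L, 2000L, 5000L), end = c(900L, 2600L, 5700L),
    strand = c("-", "+", "+"),
    feature_type = "CDS"
  )
  ann <- annotation(reps, feats)
  p <- calling_params()

  cand <- mk_cluster(
    start = c(100L, 720L, 4720L, 3500L, 1900L),
    end = c(200L, 980L, 4980L, 3600L, 1990L),
    strand = c("+", "+", "+", "+", "-"),
    read_count = 20L
  )
  cand$length <- cand$end - cand$start
  out <- classify_candidates(cand, ann, p)
  expect_equal(out$srna_class, c(
    "II_antisense", # overlaps gminus on the opposite strand
    "II_antisense", # in gplus's window BUT overlaps gminus antisense: II wins
    "III_leader", # wholly inside gleader's [4700, 5000) window
    "I_intergenic", # overlaps nothing, inside no window
    "I_intergenic" # '-' candidate in a '+' window: strands must match
  ))
  expect_equal(out$associated_gene[1], "gminus")
  expect_equal(out$associated_gene[3], "gleader")
  expect_true(is.na(out$associated_gene[4]))

  # sense overlap with an annotated gene excludes the candidate
  sense <- mk_cluster(start = 2100L, end = 2200L, strand = "+", read_count = 20L)
  sense$length <- 100L
  expect_equal(classify_candidates(sense, ann, p)$srna_class, "excluded_sense")
})

test_that("decision-table enumeration: rule combinations resolve by precedence", {
  reps <- tibble::tibble(replicon = "chr", length = 6000L, is_plasmid = FALSE)
  # gene layouts toggling each rule for a candidate at [1000, 1100) '+'
  cand <- mk_cluster(start = 1000L, end = 1100L, strand = "+", read_count = 20L)
  cand$length <- 100L
  layouts <- list(
    none = NULL,
    sense = tibble::tibble(
      gene_id = "s", replicon = "chr", start = 1050L, end = 1500L,
      strand = "+", feature_type = "CDS"
    ),
    anti = tibble::tibble(
      gene_id = "a", replicon = "chr", start = 1050L, end = 1500L,
      strand = "-", feature_type = "CDS"
    ),
    leader = tibble::tibble(
      gene_id = "l", replicon = "chr", start = 1150L, end = 1800L,
      strand = "+", feature_type = "CDS"
    )
  )
  expected <- c(
    none = "I_intergenic", sense = "excluded_sense",
    anti = "II_antisense", leader = "III_leader",
    sense_anti = "excluded_sense", sense_leader = "excluded_sense",
    anti_leader = "II_antisense", sense_anti_leader = "excluded_sense"
  )
  combos <- list(
    none = "none", sense = "sense", anti = "anti", leader = "leader",
    sense_anti = c("sense", "anti"), sense_leader = c("sense", "leader"),
    anti_leader = c("anti", "leader"),
    sense_anti_leader = c("sense", "anti", "leader")
  )
  for (nm in names(combos)) {
    feats <- dplyr::bind_rows(layouts[combos[[nm]]])
    ann <- annotation(reps, feats)
    got <- classify_candidates(cand, ann, calling_params())$srna_class
    expect_equal(got, unname(expected[nm]), label = paste("layout", nm))
  }
})

test_that("leader calls pick the nearest gene and respect the leader rule", {
  reps <- tibble::tibble(replicon = "chr", length = 10000L, is_plasmid = FALSE)
  feats <- tibble::tibble(
    gene_id = c("near", "far"),
    replicon = "chr",
    start = c(1200L, 1300L), end = c(1250L, 2000L),
    strand = "+", feature_type = "CDS"
  )
  ann <- annotation(reps, feats)
  cand <- mk_cluster(start = 1000L, end = 1150L, strand = "+", read_count = 20L)
  cand$length <- 150L
  out <- classify_candidates(cand, ann, calling_params())
  expect_equal(out$srna_class, "III_leader")
  expect_equal(out$associated_gene, "near")

  # a candidate straddling the window edge: rejected under "contained",
  # accepted under "end_within"
  feats2 <- feats[feats$gene_id == "far", ]
  ann2 <- annotation(reps, feats2)
  straddle <- mk_cluster(start = 900L, end = 1250L, strand = "+", read_count = 20L)
  straddle$length <- 350L
  expect_equal(
    classify_candidates(straddle, ann2, calling_params())$srna_class,
    "I_intergenic"
  )
  expect_equal(
    classify_candidates(straddle, ann2, calling_params(leader_rule = "end_within"))$srna_class,
    "III_leader"
  )
})

test_that("end-to-end call recovers exactly the planted sRNAs and is order-invariant", {
  cfg <- simulation_config(
    seed = 7,
    planted = tibble::tibble(
      class = c("I", "II", "III"),
      depth = 20L,
      length = c(120L, 100L, 90L)
    )
  )
  sim <- simulate_reads(cfg)
  call <- call_srnas(sim$reads, sim$annotation)
  expect_equal(nrow(call$candidates), 3)
  expect_setequal(
    call$candidates$srna_class,
    c("I_intergenic", "II_antisense", "III_leader")
  )
  rec <- evaluate_recovery(call, sim$truth)
  expect_equal(rec$sensitivity, 1.0)
  expect_equal(rec$precision, 1.0)

  # raising min_reads above the planted depth removes everything
  call25 <- call_srnas(sim$reads, sim$annotation, calling_params(min_reads = 25))
  expect_equal(nrow(call25$candidates), 0)

  # shuffling the input reads changes nothing
  set.seed(999)
  shuffled <- sim$reads[sample.int(nrow(sim$reads)), ]
  call_shuf <- call_srnas(shuffled, sim$annotation)
  a <- dplyr::arrange(call$candidates, .data$replicon, .data$start)
  b <- dplyr::arrange(call_shuf$candidates, .data$replicon, .data$start)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$srna_class, b$srna_class)
})

test_that("candidate counts are monotone in both thresholds", {
  cfg <- simulation_config(seed = 19, background_rate = 2)
  sim <- simulate_reads(cfg)
  counts <- sapply(c(5, 10, 15, 21), function(mr) {
    nrow(call_srnas(sim$reads, sim$annotation, calling_params(min_reads = mr))$candidates)
  })
  expect_true(all(diff(counts) <= 0))
  counts_len <- sapply(c(20, 50, 100, 200), function(ml) {
    nrow(call_srnas(sim$reads, sim$annotation, calling_params(min_length = ml))$candidates)
  })
  expect_true(all(diff(counts_len) <= 0))
})

test_that("inclusive span arithmetic matches the validated-table bookkeeping", {
  tab <- suppressMessages(validated_srnas())
  igr02 <- tab[tab$name == "SYPCC_Igr_02", ]
  expect_equal(igr02$length, 68L)
  expect_gte(igr02$length, 50L)
})
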