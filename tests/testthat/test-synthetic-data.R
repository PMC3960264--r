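test_that("genome simulation is deterministic and genes never overlap", {
  cfg <- simulation_config(seed = 7)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation$features, b$annotation$features)
  f <- dplyr::arrange(a$annotation$features, .data$replicon, .data$start)
  by_rep <- split(f, f$replicon)
  for (g in by_rep) {
    if (nrow(g) < 2) next
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_equal(nrow(a$annotation$replicons), 5)
  expect_equal(sum(a$annotation$replicons$is_plasmid), 4)
})

test_that("infeasible gene packing is a configuration error", {
  cfg <- simulation_config(
    seed = 1,
    replicons = tibble::tibble(replicon = "mini", length = 5000L, is_plasmid = FALSE),
    n_genes = c(mini = 50L),
    planted = tibble::tibble(class = character(0), depth = integer(0), length = integer(0))
  )
  expect_error(simulate_genome(cfg), "cannot fit")
})

test_that("planted sRNAs satisfy their class definitions by construction", {
  cfg <- simulation_config(seed = 23)
  sim <- simulate_reads(cfg)
  truth <- sim$truth
  ann <- sim$annotation
  expect_equal(nrow(truth), 30)
  # recompute each planted record's class from first principles
  cand <- tibble::tibble(
    cluster_id = truth$srna_id,
    replicon = truth$replicon, start = truth$start, end = truth$end,
    strand = truth$strand, read_count = truth$depth,
    max_coverage = truth$depth, mean_coverage = 1,
    length = truth$end - truth$start
  )
  got <- classify_candidates(cand, ann, calling_params())
  map <- c(I = "I_intergenic", II = "II_antisense", III = "III_leader")
  expect_equal(got$srna_class, unname(map[truth$class]))
  # class II/III associated genes match the planted ones
  expect_equal(got$associated_gene[truth$class != "I"],
    truth$associated_gene[truth$class != "I"])
})

test_that("read emission respects depth, span and truncation rules", {
  cfg <- simulation_config(
    seed = 3,
    planted = tibble::tibble(class = "I", depth = 20L, length = 120L)
  )
  sim <- simulate_reads(cfg)
  expect_equal(nrow(sim$reads), 20)
  tr <- sim$truth
  expect_true(all(sim$reads$start >= tr$start & sim$reads$end <= tr$end))
  expect_true(all(sim$reads$strand == tr$strand))
  expect_true(all(sim$reads$end - sim$reads$start == 81L))

  # an sRNA shorter than the read length truncates its reads to the span
  cfg_short <- simulation_config(
    seed = 3,
    planted = tibble::tibble(class = "I", depth = 5L, length = 60L)
  )
  sim_short <- simulate_reads(cfg_short)
  expect_true(all(sim_short$reads$end - sim_short$reads$start == 60L))

  # empty plan and zero background gives an empty read set
  cfg0 <- simulation_config(
    seed = 3,
    planted = tibble::tibble(class = character(0), depth = integer(0), length = integer(0))
  )
  expect_equal(nrow(simulate_reads(cfg0)$reads), 0)
})

test_that("SAM output round-trips through the alignment reader", {
  cfg <- simulation_config(
    seed = 13,
    planted = tibble::tibble(class = c("I", "II"), depth = 10L, length = c(100L, 90L))
  )
  sim <- simulate_reads(cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim, sam)
  back <- read_alignments(sam, sim$annotation)
  expect_equal(back$tally$kept, nrow(sim$reads))
  expect_equal(back$tally$total, nrow(sim$reads))
  a <- dplyr::arrange(sim$reads, .data$read_id)
  b <- dplyr::arrange(back$reads, .data$read_id)
  expect_equal(b$replicon, a$replicon)
  expect_equal(b$start, a$start)
  expect_equal(b$end, a$end)
  expect_equal(b$strand, a$strand)
})

test_that("simulation outputs are byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 99, background_rate = 1, n_mixture_reads = 50L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- simulate_reads(cfg)
    write_sam(sim, file.path(d, "reads.sam"))
    write_simulated_genome(sim, file.path(d, "genome.fa"), file.path(d, "genes.gff3"))
    readr::write_tsv(sim$truth, file.path(d, "truth.tsv"))
  }
  for (f in c("reads.sam", "genome.fa", "genes.gff3", "truth.tsv")) {
    expect_identical(
      readLines(file.path(d1, f)),
      readLines(file.path(d2, f)),
      label = f
    )
  }
})

test_that("depth one below the calling threshold is never called", {
  cfg <- simulation_config(
    seed = 37,
    planted = tibble::tibble(class = c("I", "II", "III"), depth = 9L, length = 120L)
  )
  sim <- simulate_reads(cfg)
  call <- call_srnas(sim$reads, sim$annotation)
  expect_equal(nrow(call$candidates), 0)
  rec <- evaluate_recovery(call, sim$truth)
  expect_equal(rec$sensitivity, 0)
  expect_true(is.na(rec$precision)) # no candidates -> precision undefined
})

test_that("planted sRNAs shorter than the length threshold are never called", {
  cfg <- simulation_config(
    seed = 53,
    planted = tibble::tibble(class = c("I", "II", "III"), depth = 20L, length = 49L)
  )
  sim <- simulate_reads(cfg)
  call <- call_srnas(sim$reads, sim$annotation)
  expect_equal(nrow(call$candidates), 0)
})

test_that("heavy sub-threshold noise does not mask planted sRNAs", {
  cfg <- simulation_config(seed = 61, background_rate = 3)
  sim <- simulate_reads(cfg)
  call <- call_srnas(sim$reads, sim$annotation)
  # sparse noise cannot pass the depth filter on its own, so every planted
  # span is still mostly covered by a same-strand candidate (read starts
  # jitter within the span, so its extreme edges need not be sampled) ...
  cand <- call$candidates
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, , drop = FALSE]
    ov <- overlap_bases(cand, tr)
    covered <- ov / (tr$end - tr$start)
    expect_gte(max(covered[cand$strand == tr$strand]), 0.7)
  }
  # ... and no candidate is noise-only: each one overlaps a planted sRNA
  for (j in seq_len(nrow(cand))) {
    ov <- overlap_bases(sim$truth, cand[j, , drop = FALSE])
    expect_gt(max(ov[sim$truth$strand == cand$strand[j]]), 0)
  }
  # noise reads chaining onto a cluster can stretch its span, so strict
  # reciprocal matching is conservative, not exact
  rec <- evaluate_recovery(call, sim$truth)
  expect_gte(rec$sensitivity, 0.9)
})

test_that("recovery matching requires strand agreement and reciprocal overlap", {
  truth <- tibble::tibble(
    srna_id = "t1", class = "I", replicon = "chr",
    start = 1000L, end = 1100L, strand = "+",
    depth = 20L, length = 100L, associated_gene = NA_character_
  )
  cand <- tibble::tibble(
    cluster_id = "c1", replicon = "chr", start = 1000L, end = 1100L,
    strand = "-", srna_class = "I_intergenic"
  )
  rec <- evaluate_recovery(cand, truth)
  expect_equal(rec$sensitivity, 0) # wrong strand
  cand$strand <- "+"
  expect_equal(evaluate_recovery(cand, truth)$sensitivity, 1)
  # a candidate covering only 40% of the planted span fails at 0.5
  cand2 <- dplyr::mutate(cand, end = 1040L)
  expect_equal(evaluate_recovery(cand2, truth)$sensitivity, 0)
  expect_equal(evaluate_recovery(cand2, truth, min_reciprocal_overlap = 0.3)$sensitivity, 1)
})

test_that("YAML configs reproduce in-code configurations", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 5",
    "read_length: 81",
    "background_rate: 0.5",
    "replicons:",
    "  - {replicon: chromosome, length: 50000, is_plasmid: false}",
    "  - {replicon: pX, length: 10000, is_plasmid: true}",
    "n_genes: {chromosome: 20, pX: 5}",
    "planted:",
    "  - {class: I, depth: 15, length: 80}",
    "  - {class: II, depth: 12, length: 70}"
  ), yml)
  cfg <- read_simulation_config(yml)
  expect_s3_class(cfg, "srna_sim_config")
  expect_equal(cfg$seed, 5L)
  expect_equal(nrow(cfg$replicons), 2)
  expect_equal(cfg$planted$depth, c(15L, 12L))
  sim <- simulate_reads(cfg)
  expect_equal(nrow(sim$truth), 2)
})
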