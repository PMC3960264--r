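# Simplified sRNA-target complementarity screen. This is a plain local
# duplex-alignment score between the sRNA and the reverse complement of
# each candidate transcript — deliberately NOT an accessibility-aware
# hybridization energy model; outputs are "screen_score", never "energy".

#' Scoring scheme for the complementarity screen
#'
#' @param match Reward for a Watson-Crick pair (default +2).
#' @param gu Reward for a G:U wobble pair (default +1; set below `mismatch`
#'   to disable wobble pairing rewards).
#' @param mismatch Penalty for a non-pairing alignment column (default -1).
#' @param gap Penalty per gap base (default -3; linear gap model).
#' @return A named list of class `srna_scoring`.
#' @export
screen_scoring <- function(match = 2, gu = 1, mismatch = -1, gap = -3) {
  structure(list(match = match, gu = gu, mismatch = mismatch, gap = gap),
    class = "srna_scoring"
  )
}

# In srna-vs-revcomp(target) space a Watson-Crick duplex pair becomes an
# identity, and a G:U wobble becomes (G,A) or (T,C) (srna base first).
duplex_substitution_matrix <- function(scoring) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(scoring$mismatch, 4, 4, dimnames = list(bases, bases))
  diag(m) <- scoring$match
  m["G", "A"] <- scoring$gu
  m["T", "C"] <- scoring$gu
  m
}

normalize_nt <- function(x, what) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  if (!nzchar(x)) stop(what, " sequence is empty", call. = FALSE)
  if (grepl("[^ACGT]", x)) {
    stop(what, " sequence contains non-nucleotide characters", call. = FALSE)
  }
  x
}

#' Score sRNA/target complementarity
#'
#' Best local alignment score between the sRNA and the reverse complement
#' of the target under a simple match/wobble/mismatch/gap scheme. A perfect
#' duplex of length L scores `2 * L`. The reported spans locate the matched
#' sub-sequences (1-based, within each input sequence).
#'
#' @param srna_seq,target_seq Nucleotide strings (RNA or DNA alphabet).
#' @param scoring A [screen_scoring()] list.
#' @param srna_id,gene_id Optional identifiers carried into the result.
#' @return One-row tibble: `srna_id`, `gene_id`, `score`, `srna_start`,
#'   `srna_end`, `target_start`, `target_end` (0 span when no positive-
#'   scoring duplex exists).
#' @export
#' @examples
#' complementarity_score("AAAAAAAAAA", "TTTTTTTTTT")$score # 20
complementarity_score <- function(srna_seq, target_seq,
                                  scoring = screen_scoring(),
                                  srna_id = NA_character_,
                                  gene_id = NA_character_) {
  srna <- normalize_nt(srna_seq, "sRNA")
  target <- normalize_nt(target_seq, "target")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(target)))
  pa <- Biostrings::pairwiseAlignment(
    srna, rc,
    type = "local",
    substitutionMatrix = duplex_substitution_matrix(scoring),
    gapOpening = 0, gapExtension = -scoring$gap
  )
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(tibble(
      srna_id = srna_id, gene_id = gene_id, score = 0,
      srna_start = 0L, srna_end = 0L, target_start = 0L, target_end = 0L
    ))
  }
  ps <- Biostrings::pattern(pa)
  ss <- Biostrings::subject(pa)
  n <- nchar(target)
  # map the revcomp-space subject span back onto the target sequence
  t_start <- n - Biostrings::end(ss) + 1L
  t_end <- n - Biostrings::start(ss) + 1L
  tibble(
    srna_id = srna_id, gene_id = gene_id, score = sc,
    srna_start = Biostrings::start(ps), srna_end = Biostrings::end(ps),
    target_start = t_start, target_end = t_end
  )
}

#' Rank candidate targets of one sRNA
#'
#' Scores the sRNA against every transcript and returns the top hits in
#' non-increasing score order. Equal scores are ordered by `gene_id`, so
#' the ranking is stable and deterministic.
#'
#' @param srna_seq sRNA sequence.
#' @param transcripts Tibble with `gene_id` and `sequence` columns (e.g.
#'   CDS plus an upstream flank), or a named character vector.
#' @param top_k Number of hits to return (default 10; 0 gives an empty
#'   table).
#' @param scoring A [screen_scoring()] list.
#' @param srna_id Optional identifier carried into the result.
#' @return Tibble of at most `top_k` rows in rank order, columns as in
#'   [complementarity_score()].
#' @export
rank_targets <- function(srna_seq, transcripts, top_k = 10L,
                         scoring = screen_scoring(), srna_id = NA_character_) {
  if (is.character(transcripts)) {
    transcripts <- tibble(gene_id = names(transcripts), sequence = unname(transcripts))
  }
  stopifnot(all(c("gene_id", "sequence") %in% names(transcripts)))
  hits <- purrr::map2_dfr(
    transcripts$gene_id, transcripts$sequence,
    ~ complementarity_score(srna_seq, .y,
      scoring = scoring,
      srna_id = srna_id, gene_id = .x
    )
  )
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$gene_id)
  utils::head(hits, max(0L, top_k))
}

#' Screen all candidate sRNAs against a transcript table
#'
#' Convenience wrapper applying [rank_targets()] to each sRNA sequence.
#'
#' @param srnas Tibble with `srna_id` and `sequence` columns.
#' @param transcripts As in [rank_targets()].
#' @param top_k Hits kept per sRNA.
#' @param scoring A [screen_scoring()] list.
#' @return Tibble of ranked hits for all sRNAs.
#' @export
screen_targets <- function(srnas, transcripts, top_k = 10L,
                           scoring = screen_scoring()) {
  stopifnot(all(c("srna_id", "sequence") %in% names(srnas)))
  purrr::map2_dfr(
    srnas$srna_id, srnas$sequence,
    ~ rank_targets(.y, transcripts, top_k = top_k, scoring = scoring, srna_id = .x)
  )
}

#' Extract candidate sRNA sequences from the genome
#'
#' @param candidates Candidate tibble (needs `replicon`, `start`, `end`,
#'   `strand`; `cluster_id` becomes the sRNA id when present).
#' @param genome A named `DNAStringSet` (or named character vector) of
#'   replicon sequences.
#' @return Tibble with `srna_id` and `sequence` (reverse-complemented for
#'   minus-strand candidates).
#' @export
candidate_sequences <- function(candidates, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  ids <- if ("cluster_id" %in% names(candidates)) {
    candidates$cluster_id
  } else {
    sprintf("srna_%04d", seq_len(nrow(candidates)))
  }
  seqs <- purrr::pmap_chr(
    list(candidates$replicon, candidates$start, candidates$end, candidates$strand),
    function(rep, s, e, strand) {
      x <- Biostrings::subseq(genome[[rep]], start = s + 1L, end = e)
      if (strand == "-") x <- Biostrings::reverseComplement(x)
      as.character(x)
    }
  )
  tibble(srna_id = ids, sequence = seqs)
}
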