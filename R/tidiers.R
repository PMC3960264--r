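# broom-style tidiers so pipeline results drop straight into dplyr chains.

#' Tidy a candidate call
#'
#' @param x An `srna_call`.
#' @param ... Unused.
#' @return The classified candidate tibble (one row per candidate), with
#'   1-based inclusive `start_1based`/`end_1based` convenience columns
#'   alongside the internal 0-based half-open `start`/`end`.
#' @export
tidy.srna_call <- function(x, ...) {
  out <- x$candidates
  dplyr::mutate(out, start_1based = .data$start + 1L, end_1based = .data$end)
}

#' One-row summary of a candidate call
#'
#' @param x An `srna_call`.
#' @param ... Unused.
#' @return A one-row tibble: read, cluster and candidate counts plus the
#'   per-class breakdown.
#' @export
glance.srna_call <- function(x, ...) {
  cls <- table(factor(x$candidates$srna_class, levels = .SRNA_CLASSES))
  tibble(
    n_reads = x$n_reads,
    n_clusters = nrow(x$clusters),
    n_candidates = nrow(x$candidates),
    n_class_I = as.integer(cls[["I_intergenic"]]),
    n_class_II = as.integer(cls[["II_antisense"]]),
    n_class_III = as.integer(cls[["III_leader"]]),
    n_excluded_sense = as.integer(cls[["excluded_sense"]]),
    n_chromosome = sum(x$candidates$replicon_kind == "chromosome"),
    n_plasmid = sum(x$candidates$replicon_kind == "plasmid")
  )
}

#' Tidy a recovery evaluation
#'
#' @param x An `srna_recovery` from [evaluate_recovery()].
#' @param ... Unused.
#' @return The confusion table in long form: `planted`, `called`, `n`.
#' @export
tidy.srna_recovery <- function(x, ...) {
  out <- as.data.frame(x$confusion, stringsAsFactors = FALSE)
  names(out) <- c("planted", "called", "n")
  as_tibble(out)
}

#' One-row summary of a recovery evaluation
#'
#' @param x An `srna_recovery`.
#' @param ... Unused.
#' @return A one-row tibble with `sensitivity`, `precision`, `n_planted`,
#'   `n_candidates` and `n_class_correct` (matched with the right class).
#' @export
glance.srna_recovery <- function(x, ...) {
  correct <- if (nrow(x$matches)) {
    sum(x$matches$planted_class == x$matches$called_class)
  } else {
    0L
  }
  tibble(
    sensitivity = x$sensitivity,
    precision = x$precision,
    n_planted = x$n_planted,
    n_candidates = x$n_candidates,
    n_class_correct = correct
  )
}
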