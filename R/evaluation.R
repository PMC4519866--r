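# Top-k scoring protocol: a substrate is predicted correctly when any
# experimentally known site appears among the top-k ranked sites; results are
# aggregated per reaction type and overall.

#' Score one substrate's prediction against its known sites
#'
#' Match is on carbon identity: a known site is hit when its carbon index is
#' among the top-`k` predicted carbons.  For substrates with several known
#' sites, one hit suffices.  Adjacency-derived predictions count as their own
#' carbon.
#'
#' @param pred a `som_prediction`
#' @param known data.frame with columns `carbon_index` and `reaction_type`
#'   (one row per known site; atom indexing must match the prediction's
#'   substrate)
#' @param k top-rank cutoff (default 3)
#' @param n_atoms_substrate optional atom count for index validation
#' @return a `som_verdict` list: `correct` (logical), `matched_carbon`
#'   (first hit or `NA`), `top_carbons`
#' @export
score_substrate <- function(pred, known, k = 3L, n_atoms_substrate = NULL) {
  stopifnot(is.data.frame(known), "carbon_index" %in% names(known),
            nrow(known) >= 1L)
  if (!is.null(n_atoms_substrate) &&
      any(known$carbon_index < 1L | known$carbon_index > n_atoms_substrate))
    stop("annotation carbon index outside 1..", n_atoms_substrate,
         ": check the atom-label map")
  top <- top_sites(pred, k)
  hit <- intersect(known$carbon_index, top)
  structure(list(correct = length(hit) > 0L,
                 matched_carbon = if (length(hit)) hit[1L] else NA_integer_,
                 top_carbons = top, k = k),
            class = "som_verdict")
}

#' Aggregate per-substrate verdicts into an accuracy table
#'
#' Builds the evaluation report: per reaction type and overall, the number of
#' correctly predicted substrates (Nc), the number of substrates (N) and the
#' ratio 100*Nc/N rounded to two decimals.  A substrate whose known sites
#' span both reaction types contributes to each type row but only once to the
#' overall row (so Nc_total equals the per-type sum only when types partition
#' the substrates).
#'
#' @param verdicts data.frame with columns `substrate_id`, `reaction_type`,
#'   `correct` (logical) and optionally `set_id`; one row per substrate per
#'   known reaction type
#' @return a `som_evaluation`: data.frame `table` (`reaction_type`, `nc`,
#'   `n`, `ratio`) with an "overall" row, plus the input `verdicts`
#' @export
aggregate_verdicts <- function(verdicts) {
  stopifnot(all(c("substrate_id", "reaction_type", "correct") %in%
                names(verdicts)))
  types <- unique(verdicts$reaction_type)
  rows <- lapply(types, function(tt) {
    v <- verdicts[verdicts$reaction_type == tt, , drop = FALSE]
    # one verdict per substrate within a type
    v <- v[!duplicated(v$substrate_id), , drop = FALSE]
    data.frame(reaction_type = tt, nc = sum(v$correct), n = nrow(v))
  })
  ov <- verdicts[!duplicated(verdicts$substrate_id), , drop = FALSE]
  # overall correctness: a substrate is correct when any of its type rows is
  correct_by_sub <- tapply(verdicts$correct, verdicts$substrate_id, any)
  rows[[length(rows) + 1L]] <- data.frame(
    reaction_type = "overall",
    nc = sum(correct_by_sub), n = length(correct_by_sub))
  tab <- do.call(rbind, rows)
  tab$ratio <- round(100 * tab$nc / tab$n, 2)
  structure(list(table = tab, verdicts = verdicts), class = "som_evaluation")
}

#' @export
print.som_evaluation <- function(x, ...) {
  cat("<som_evaluation> top-k prediction accuracy\n")
  t <- x$table
  for (r in seq_len(nrow(t)))
    cat(sprintf("  %-26s Nc = %3d  N = %3d  %.2f%%\n",
                t$reaction_type[r], t$nc[r], t$n[r], t$ratio[r]))
  invisible(x)
}

#' Read a site-annotation table
#'
#' Tab-separated columns: `substrate_id`, `carbon_label`, `reaction_type`,
#' `set_id`.  Carbon labels use positional nomenclature (e.g. "C6") and must
#' be mapped to atom indices once per substrate with
#' [map_annotation_labels()] before scoring.
#'
#' @param path TSV file
#' @return data.frame of annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("substrate_id", "carbon_label", "reaction_type", "set_id")
  if (!all(need %in% names(df)))
    stop("annotation file needs columns ", paste(need, collapse = ", "),
         ": ", path)
  df
}

#' Map positional carbon labels to atom indices
#'
#' @param annotations data.frame from [read_annotations()] (or with a
#'   `carbon_label` column)
#' @param label_map named integer vector, label -> atom index, supplied once
#'   per substrate
#' @return annotations with an added `carbon_index` column
#' @export
map_annotation_labels <- function(annotations, label_map) {
  idx <- unname(label_map[annotations$carbon_label])
  if (anyNA(idx))
    stop("no atom-index mapping for label(s): ",
         paste(unique(annotations$carbon_label[is.na(idx)]), collapse = ", "))
  annotations$carbon_index <- as.integer(idx)
  annotations
}

#' Reported benchmark outcome counts
#'
#' The shipped per-reaction-type outcome counts (correct / total substrates)
#' for the 50-substrate CYP3A4 benchmark: the reactivity-only model and the
#' full mechanism-based model on its training (28 substrates) and test (22
#' substrates) sets.  Used to reproduce the benchmark accuracy tables through
#' [aggregate_verdicts()].
#'
#' @return data.frame: `model`, `set_id`, `reaction_type`, `nc`, `n`
#' @export
reported_accuracy_counts <- function() {
  path <- system.file("extdata", "reported_accuracy_counts.tsv",
                      package = "somcyp", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Expand outcome counts into per-substrate verdicts
#'
#' Turns (Nc, N) counts into Nc correct and N - Nc incorrect synthetic
#' verdicts so count data can drive [aggregate_verdicts()].
#'
#' @param counts data.frame with `reaction_type`, `nc`, `n` (one row per type)
#' @return verdict data.frame suitable for [aggregate_verdicts()]
#' @export
verdicts_from_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(r) {
    n <- counts$n[r]; nc <- counts$nc[r]
    if (nc > n) stop("nc > n in counts row ", r)
    data.frame(
      substrate_id = paste0(counts$reaction_type[r], "_", seq_len(n)),
      reaction_type = counts$reaction_type[r],
      correct = seq_len(n) <= nc)
  })
  do.call(rbind, rows)
}
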