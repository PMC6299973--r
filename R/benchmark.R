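#' Per-tool EC sets for one genome
#'
#' Collapses a normalized annotation table (one genome) to the distinct
#' complete-EC set of each tool — the reaction-level view used for
#' gold-standard benchmarking.
#'
#' @param df Normalized annotation tibble containing a single genome.
#' @param tools Tools to include (default all present).
#' @return Named list of character vectors of canonical EC strings.
#' @export
ec_sets_by_tool <- function(df, tools = NULL) {
  sets <- ec_annotation_sets(df)
  if (length(unique(sets$genome_id)) > 1) {
    stop("ec_sets_by_tool() expects a single genome; got ",
         length(unique(sets$genome_id)), call. = FALSE)
  }
  if (is.null(tools)) tools <- sort(unique(sets$tool))
  out <- lapply(tools, function(t) {
    sort(unique(sets$ec[sets$tool == t]))
  })
  names(out) <- tools
  out
}

#' Combine per-tool EC sets by union or intersection
#'
#' The union is the set of ECs predicted by at least one tool in the
#' combination (coverage-oriented); the intersection the ECs predicted by
#' every tool (confidence-oriented). For a single tool both modes return
#' that tool's own set.
#'
#' @param sets Named list of character vectors (per-tool EC sets).
#' @param tools Tools in the combination (must all be names of `sets`).
#' @param mode `"union"` or `"intersection"`.
#' @return Character vector (sorted, distinct).
#' @export
combine_ec_sets <- function(sets, tools = names(sets),
                            mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (length(tools) == 0) stop("empty tool combination", call. = FALSE)
  unknown <- setdiff(tools, names(sets))
  if (length(unknown) > 0) {
    stop("unknown tool(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  op <- if (mode == "union") union else intersect
  sort(unique(Reduce(op, sets[tools])))
}

#' Precision and recall of a predicted EC set against a gold standard
#'
#' True positives are predicted ECs present in the gold set, false positives
#' predicted ECs absent from it, false negatives gold ECs not predicted.
#' Precision is TP/(TP+FP), reported `NA` (absent) for an empty prediction;
#' recall is TP/(TP+FN). Matching is exact string equality of complete EC
#' numbers.
#'
#' @param predicted Character vector of canonical EC strings.
#' @param gold Non-empty character vector of canonical EC strings.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
precision_recall <- function(predicted, gold) {
  gold <- unique(gold)
  if (length(gold) == 0) {
    stop("precision_recall(): empty gold standard (recall undefined)",
         call. = FALSE)
  }
  predicted <- unique(predicted)
  tp <- length(intersect(predicted, gold))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = tp / (tp + fn)
  )
}

#' Precision/recall sweep over all tool combinations
#'
#' Evaluates every non-empty subset of the tools, in both union and
#' intersection mode (singletons once, since both modes coincide), against a
#' gold-standard EC set. Rows are ordered by subset size, then lexicographic
#' tool labels, with union before intersection.
#'
#' @param sets Named list of per-tool EC sets (see [ec_sets_by_tool()]).
#' @param gold Non-empty character vector of gold-standard ECs.
#' @return Tibble: `combination` ("+"-joined sorted tool labels), `mode`,
#'   `n_tools`, `tp`, `fp`, `fn`, `precision`, `recall`. Four tools give
#'   26 rows (15 subsets x 2 modes - 4 duplicate singletons).
#' @export
pr_sweep <- function(sets, gold) {
  tools <- sort(names(sets))
  if (length(tools) == 0) stop("pr_sweep(): no tools", call. = FALSE)
  subsets <- unlist(lapply(seq_along(tools), function(k) {
    utils::combn(tools, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(s) {
    modes <- if (length(s) == 1) "union" else c("union", "intersection")
    dplyr::bind_rows(lapply(modes, function(m) {
      pr <- precision_recall(combine_ec_sets(sets, s, m), gold)
      dplyr::bind_cols(
        tibble::tibble(combination = paste(s, collapse = "+"),
                       mode = m, n_tools = length(s)),
        pr
      )
    }))
  })
  dplyr::bind_rows(rows)
}

#' Three-way gene-EC confusion regions for two tools and a gold standard
#'
#' Counts the seven Venn regions of gene-EC pairs among tool A, tool B, and
#' the gold standard for one genome — the gene-level companion to the
#' EC-set-level precision/recall sweep.
#'
#' @param df Normalized annotation tibble for one genome containing both
#'   tools.
#' @param tool_a,tool_b Tool labels present in `df`.
#' @param gold Tibble with `genome_id`, `gene_id`, `ec` (one genome, same as
#'   `df`).
#' @return Tibble with `region` (`"a"`, `"b"`, `"gold"`, `"a+b"`,
#'   `"a+gold"`, `"b+gold"`, `"a+b+gold"`) and `n`.
#' @export
gene_ec_confusion <- function(df, tool_a, tool_b, gold) {
  sets <- ec_annotation_sets(df)
  g_df <- unique(sets$genome_id)
  g_gold <- unique(gold$genome_id)
  if (length(g_df) != 1 || length(g_gold) != 1 || g_df != g_gold) {
    stop("gene_ec_confusion(): annotation and gold genomes must match",
         call. = FALSE)
  }
  key <- function(gene, ec) paste(gene, ec, sep = "\r")
  a <- unique(key(sets$gene_id[sets$tool == tool_a], sets$ec[sets$tool == tool_a]))
  b <- unique(key(sets$gene_id[sets$tool == tool_b], sets$ec[sets$tool == tool_b]))
  g <- unique(key(gold$gene_id, gold$ec))
  all_units <- unique(c(a, b, g))
  in_a <- all_units %in% a
  in_b <- all_units %in% b
  in_g <- all_units %in% g
  lab <- c("a", "b", "gold")
  region <- apply(cbind(in_a, in_b, in_g), 1, function(m) {
    paste(lab[m], collapse = "+")
  })
  all_regions <- c("a", "b", "gold", "a+b", "a+gold", "b+gold", "a+b+gold")
  counts <- table(factor(region, levels = all_regions))
  tibble::tibble(region = all_regions, n = as.integer(counts))
}
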