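#' Normalize a transporter substrate string
#'
#' Lowercases, trims, collapses internal whitespace, and strips surrounding
#' punctuation (quotes, brackets, trailing commas); internal separators such
#' as `/` in `"mg/co/ni"` are preserved. Empty or missing input becomes
#' `NA` (no substrate annotated).
#'
#' @param x Character vector of raw substrate strings.
#' @return Character vector of normalized substrates (`NA` when absent).
#' @export
normalize_substrate <- function(x) {
  if (length(x) == 0) return(character())
  out <- tolower(trimws(as.character(x)))
  out <- gsub("[[:space:]]+", " ", out)
  out <- gsub("^[\"'()\\[\\]{},.;:]+|[\"'()\\[\\]{},.;:]+$", "", out, perl = TRUE)
  out <- trimws(out)
  out[is.na(out) | !nzchar(out)] <- NA_character_
  out
}

#' Read a substrate-specificity vocabulary
#'
#' TSV with columns `substrate`, `rank` (1..4), `synonym_group_id`.
#' Rank semantics: 1 = specific metabolite directly usable as a transport
#' reaction in a metabolic model (e.g. lysine, Fe); 2 = substrate(s) mapping
#' to a small number of possible transport reactions (e.g. Mg/Co/Ni,
#' aromatic amino acid); 3 = broader substrate class (e.g. sugar, dipeptide);
#' 4 = very broad class (e.g. multidrug efflux, protein). Rank 5 — no
#' substrate annotated — is never stored in the vocabulary. Synonym groups
#' are flat equivalence classes: substrates that should count as agreeing
#' (e.g. "leucine", "leucine/valine", "branched-chain amino acid") share one
#' `synonym_group_id`.
#'
#' @param path Path to the TSV file.
#' @return Tibble of class `"ecc_vocab"` with normalized `substrate`,
#'   integer `rank`, and `synonym_group_id`.
#' @export
read_substrate_vocabulary <- function(path) {
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("substrate", "rank", "synonym_group_id")
  if (!all(need %in% names(df))) {
    stop("vocabulary format error: need columns substrate, rank, synonym_group_id",
         call. = FALSE)
  }
  substrate_vocabulary(df$substrate, as.integer(df$rank), df$synonym_group_id)
}

#' Construct a substrate vocabulary from vectors
#'
#' @param substrate Substrate strings (normalized internally).
#' @param rank Integer ranks in 1..4.
#' @param synonym_group_id Group labels; substrates sharing a label agree.
#' @return Tibble of class `"ecc_vocab"`.
#' @export
substrate_vocabulary <- function(substrate, rank, synonym_group_id) {
  sub <- normalize_substrate(substrate)
  rank <- as.integer(rank)
  if (any(is.na(sub))) {
    stop("vocabulary error: empty substrate string", call. = FALSE)
  }
  if (any(is.na(rank) | rank < 1L | rank > 4L)) {
    stop("vocabulary error: ranks must be integers in 1..4", call. = FALSE)
  }
  out <- tibble::tibble(substrate = sub, rank = rank,
                        synonym_group_id = as.character(synonym_group_id))
  if (anyDuplicated(out$substrate) > 0) {
    stop("vocabulary error: duplicate substrate '",
         out$substrate[duplicated(out$substrate)][1], "'", call. = FALSE)
  }
  class(out) <- c("ecc_vocab", class(out))
  out
}

#' Built-in starter substrate vocabulary
#'
#' A small curated vocabulary covering the canonical rank examples plus one
#' branched-chain amino-acid synonym class; real analyses should supply a
#' fuller table via [read_substrate_vocabulary()].
#'
#' @return Tibble of class `"ecc_vocab"`.
#' @export
default_substrate_vocabulary <- function() {
  path <- system.file("extdata", "substrate_vocabulary.tsv",
                      package = "ecconsensus", mustWork = TRUE)
  read_substrate_vocabulary(path)
}

#' Assign specificity ranks to transporter annotations
#'
#' Rank 5 is assigned when no substrate is annotated, and also when a
#' non-empty substrate is absent from the vocabulary — such curation gaps are
#' tallied separately (attribute `"n_unranked"`) so they are visible rather
#' than silently inflating the broad-class ranks.
#'
#' @param df Normalized annotation tibble (TRANSPORT records).
#' @param vocab Substrate vocabulary.
#' @return The TRANSPORT records with added `rank` and `synonym_group_id`
#'   columns; attribute `"n_unranked"` counts non-empty substrates unknown to
#'   the vocabulary.
#' @export
rank_substrates <- function(df, vocab = default_substrate_vocabulary()) {
  tr <- dplyr::filter(df, .data$feature_type == "TRANSPORT")
  sub <- normalize_substrate(tr$value)
  idx <- match(sub, vocab$substrate)
  rank <- ifelse(is.na(sub), 5L, ifelse(is.na(idx), 5L, vocab$rank[idx]))
  out <- dplyr::mutate(
    tr,
    rank = as.integer(rank),
    synonym_group_id = vocab$synonym_group_id[idx]
  )
  attr(out, "n_unranked") <- sum(!is.na(sub) & is.na(idx))
  out
}

#' Per-tool distribution of transporter substrate ranks
#'
#' Each transporter gene counts once per tool at its most specific
#' (lowest) rank. Reports counts and fractions per rank 1..5 and the
#' fraction of genes with model-ready substrates (rank 1 or 2).
#'
#' @param ranked Output of [rank_substrates()].
#' @return A list: `per_tool` (tibble `tool`, `rank`, `n`, `fraction`),
#'   `totals` (tibble `tool`, `n_genes`, `rank12_fraction`).
#' @export
rank_distribution <- function(ranked) {
  if (nrow(ranked) == 0) {
    return(list(
      per_tool = tibble::tibble(tool = character(), rank = integer(),
                                n = integer(), fraction = numeric()),
      totals = tibble::tibble(tool = character(), n_genes = integer(),
                              rank12_fraction = numeric())
    ))
  }
  per_gene <- ranked |>
    dplyr::group_by(.data$tool, .data$genome_id, .data$gene_id) |>
    dplyr::summarise(rank = min(.data$rank), .groups = "drop")
  per_tool <- per_gene |>
    dplyr::count(.data$tool, .data$rank, name = "n") |>
    tidyr::complete(tool = unique(per_gene$tool), rank = 1:5,
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$tool) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  totals <- per_tool |>
    dplyr::group_by(.data$tool) |>
    dplyr::summarise(
      n_genes = sum(.data$n),
      rank12_fraction = sum(.data$fraction[.data$rank <= 2]),
      .groups = "drop"
    )
  list(per_tool = per_tool, totals = totals)
}

#' Overlap of transporter gene annotations across tools
#'
#' Pools all (genome, gene, tool) transporter annotation instances across
#' genomes and reports: the pooled total, the number of distinct genes
#' annotated as transporters by *every* tool, how many of those carry a
#' specific (rank 1-2) substrate from every tool, and the agreement
#' percentage (all-tool genes / pooled instances, one decimal).
#'
#' @param ranked Output of [rank_substrates()].
#' @param tools Transporter tools to compare (default: all present; at least
#'   two required).
#' @return A list: `n_pooled`, `n_all_tools`, `n_all_tools_specific`,
#'   `pct_agreement`, plus the underlying `all_tools_genes` tibble so
#'   alternative denominators can be recomputed.
#' @export
three_tool_overlap <- function(ranked, tools = NULL) {
  if (is.null(tools)) tools <- sort(unique(ranked$tool))
  if (length(tools) < 2) {
    stop("three_tool_overlap() needs at least two tools", call. = FALSE)
  }
  tr <- dplyr::filter(ranked, .data$tool %in% tools)
  instances <- dplyr::distinct(tr, .data$genome_id, .data$gene_id, .data$tool)
  per_gene <- instances |>
    dplyr::group_by(.data$genome_id, .data$gene_id) |>
    dplyr::summarise(n_tools = dplyr::n_distinct(.data$tool), .groups = "drop")
  all_tools_genes <- dplyr::filter(per_gene, .data$n_tools == length(tools))
  specific <- tr |>
    dplyr::group_by(.data$genome_id, .data$gene_id, .data$tool) |>
    dplyr::summarise(best_rank = min(.data$rank), .groups = "drop") |>
    dplyr::filter(.data$best_rank <= 2) |>
    dplyr::group_by(.data$genome_id, .data$gene_id) |>
    dplyr::summarise(n_specific_tools = dplyr::n(), .groups = "drop")
  all_specific <- dplyr::semi_join(
    dplyr::filter(specific, .data$n_specific_tools == length(tools)),
    all_tools_genes, by = c("genome_id", "gene_id")
  )
  list(
    tools = tools,
    n_pooled = nrow(instances),
    n_all_tools = nrow(all_tools_genes),
    n_all_tools_specific = nrow(all_specific),
    pct_agreement = agreement_pct(nrow(all_tools_genes), nrow(instances)),
    all_tools_genes = all_tools_genes
  )
}

#' Cross-tool substrate agreement among specific annotations
#'
#' Over genes where at least two tools give a specific (rank 1-2) substrate,
#' the fraction of genes for which all such substrates fall into a single
#' synonym class — counting "leucine", "leucine/valine" and "branched-chain
#' amino acid" as agreeing when the vocabulary groups them. Unknown
#' substrates never qualify (they are rank 5).
#'
#' @param ranked Output of [rank_substrates()].
#' @param tools Tools to consider (default all present).
#' @return A list: `fraction` (`NA` when no gene qualifies), `n_genes`,
#'   `n_agree`, and `per_pair` (tibble `tool_a`, `tool_b`, `n_genes`,
#'   `n_agree`, `fraction`).
#' @export
substrate_agreement <- function(ranked, tools = NULL) {
  if (is.null(tools)) tools <- sort(unique(ranked$tool))
  spec <- ranked |>
    dplyr::filter(.data$tool %in% tools, .data$rank <= 2,
                  !is.na(.data$synonym_group_id)) |>
    dplyr::distinct(.data$genome_id, .data$gene_id, .data$tool,
                    .data$synonym_group_id)
  per_gene <- spec |>
    dplyr::group_by(.data$genome_id, .data$gene_id) |>
    dplyr::summarise(
      n_tools = dplyr::n_distinct(.data$tool),
      n_groups = dplyr::n_distinct(.data$synonym_group_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_tools >= 2)
  pairs <- if (length(tools) >= 2) utils::combn(sort(tools), 2, simplify = FALSE) else list()
  per_pair <- dplyr::bind_rows(lapply(pairs, function(p) {
    a <- dplyr::filter(spec, .data$tool == p[1])
    b <- dplyr::filter(spec, .data$tool == p[2])
    both <- dplyr::inner_join(
      dplyr::distinct(a, .data$genome_id, .data$gene_id),
      dplyr::distinct(b, .data$genome_id, .data$gene_id),
      by = c("genome_id", "gene_id")
    )
    joint <- dplyr::bind_rows(a, b) |>
      dplyr::semi_join(both, by = c("genome_id", "gene_id")) |>
      dplyr::group_by(.data$genome_id, .data$gene_id) |>
      dplyr::summarise(agree = dplyr::n_distinct(.data$synonym_group_id) == 1,
                       .groups = "drop")
    tibble::tibble(
      tool_a = p[1], tool_b = p[2],
      n_genes = nrow(joint), n_agree = sum(joint$agree),
      fraction = if (nrow(joint) > 0) mean(joint$agree) else NA_real_
    )
  }))
  list(
    fraction = if (nrow(per_gene) > 0) mean(per_gene$n_groups == 1) else NA_real_,
    n_genes = nrow(per_gene),
    n_agree = sum(per_gene$n_groups == 1),
    per_pair = per_pair
  )
}
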