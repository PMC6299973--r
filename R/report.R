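#' Assemble the full comparison report for a multi-tool annotation dataset
#'
#' Runs the complete analysis over a normalized annotation table and writes
#' tidy TSV reports plus a machine-readable JSON summary: support partitions
#' of gene-EC pairs / ECs / genes across tools, pairwise gene-level
#' agreement, per-genome EC-region means, per-genome support distributions,
#' gene coverage, the precision/recall sweep of every tool combination when a
#' gold standard is supplied, and the transporter rank distribution, overlap
#' and substrate agreement when transporter records are supplied.
#'
#' Re-running on identical inputs produces identical files.
#'
#' @param annotations Normalized annotation tibble (EC records; may also
#'   contain the TRANSPORT records if `transporter_annotations` is `NULL`).
#' @param out_dir Output directory, created if needed.
#' @param gold Optional gold-standard tibble (`genome_id`, `gene_id`, `ec`).
#' @param transporter_annotations Optional TRANSPORT records (default: taken
#'   from `annotations`).
#' @param vocab Substrate vocabulary used for ranking.
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
assemble_report <- function(annotations, out_dir, gold = NULL,
                            transporter_annotations = NULL,
                            vocab = default_substrate_vocabulary()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  summary <- list()

  ec_df <- dplyr::filter(annotations, .data$feature_type == "EC")
  if (nrow(ec_annotation_sets(ec_df)) > 0 &&
      length(unique(ec_annotation_sets(ec_df)$tool)) >= 2) {
    for (unit in c("gene_ec_pair", "ec", "gene")) {
      part <- support_partition(ec_df, unit = unit)
      readr::write_tsv(part$counts, out(sprintf("support_counts_%s.tsv", unit)),
                       progress = FALSE)
      readr::write_tsv(part$regions, out(sprintf("support_regions_%s.tsv", unit)),
                       progress = FALSE)
      readr::write_tsv(part$per_tool_unique,
                       out(sprintf("per_tool_unique_%s.tsv", unit)),
                       progress = FALSE)
      summary[[paste0("n_units_", unit)]] <- part$n_units
    }
    agree <- pairwise_gene_agreement(ec_df, by_genome = TRUE)
    readr::write_tsv(agree$pooled, out("pairwise_agreement_pooled.tsv"),
                     progress = FALSE)
    readr::write_tsv(agree$per_genome, out("pairwise_agreement_per_genome.tsv"),
                     progress = FALSE)
    readr::write_tsv(region_means_per_genome(ec_df, "ec"),
                     out("ec_region_means_per_genome.tsv"), progress = FALSE)
    genomes <- sort(unique(ec_annotation_sets(ec_df)$genome_id))
    dist <- dplyr::bind_rows(lapply(genomes, function(g) {
      d <- support_distribution(dplyr::filter(ec_df, .data$genome_id == g), "ec")
      dplyr::mutate(d$fractions, genome_id = g, ge3_fraction = d$ge3_fraction)
    }))
    readr::write_tsv(dist, out("support_distribution_per_genome.tsv"),
                     progress = FALSE)
    cov <- gene_coverage(ec_df)
    readr::write_tsv(cov$per_tool, out("gene_coverage_per_tool.tsv"),
                     progress = FALSE)
    summary$gene_union <- cov$n_union
    summary$multi_tool_gene_fraction <- cov$multi_tool_fraction
    summary$mean_gene_ec_per_genome <- mean_units_per_genome(ec_df, "gene_ec_pair")
  }

  if (!is.null(gold) && nrow(gold) > 0) {
    pr_rows <- dplyr::bind_rows(lapply(sort(unique(gold$genome_id)), function(g) {
      sets <- ec_sets_by_tool(dplyr::filter(ec_df, .data$genome_id == g))
      gold_ecs <- unique(gold$ec[gold$genome_id == g])
      dplyr::mutate(pr_sweep(sets, gold_ecs), genome_id = g, .before = 1)
    }))
    readr::write_tsv(pr_rows, out("precision_recall.tsv"), progress = FALSE)
    summary$pr_combinations <- nrow(pr_rows)
    summary$precision_convention <- paste(
      "precision is absent (empty field) for empty predictions,",
      "never 0 or 1 by convention")
  }

  tr <- transporter_annotations
  if (is.null(tr)) {
    tr <- dplyr::filter(annotations, .data$feature_type == "TRANSPORT")
  }
  if (nrow(tr) > 0) {
    ranked <- rank_substrates(tr, vocab)
    rd <- rank_distribution(ranked)
    readr::write_tsv(rd$per_tool, out("transporter_rank_distribution.tsv"),
                     progress = FALSE)
    readr::write_tsv(rd$totals, out("transporter_totals.tsv"), progress = FALSE)
    summary$transporter_unranked_substrates <- attr(ranked, "n_unranked")
    if (length(unique(tr$tool)) >= 2) {
      ov <- three_tool_overlap(ranked)
      ag <- substrate_agreement(ranked)
      readr::write_tsv(ag$per_pair, out("substrate_agreement_per_pair.tsv"),
                       progress = FALSE)
      summary$transporter_overlap <- ov[c("n_pooled", "n_all_tools",
                                          "n_all_tools_specific",
                                          "pct_agreement")]
      summary$substrate_agreement <- ag[c("fraction", "n_genes", "n_agree")]
      summary$substrate_agreement_rule <- paste(
        "agreement = all rank-1..2 substrates of a gene fall in one synonym",
        "class; one formalization of cross-tool substrate concordance")
    }
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}
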