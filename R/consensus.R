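#' Project annotation sets onto comparison units
#'
#' The statistics in this package compare tools on one of three unit kinds:
#' `"gene_ec_pair"` (the atomic gene-EC annotation), `"ec"` (distinct EC
#' numbers, i.e. reactions, ignoring isozymes and multifunctional genes), or
#' `"gene"` (genes carrying at least one complete EC). Units are always
#' qualified by genome, so pooling several genomes never merges units across
#' genomes.
#'
#' @param df Normalized annotation tibble (EC records; partial ECs dropped).
#' @param unit One of `"gene_ec_pair"`, `"ec"`, `"gene"`.
#' @return Tibble with columns `genome_id`, `tool`, `unit_id`, deduplicated.
#' @keywords internal
annotation_units <- function(df, unit = c("gene_ec_pair", "ec", "gene")) {
  unit <- match.arg(unit)
  sets <- ec_annotation_sets(df)
  uid <- switch(unit,
    gene_ec_pair = paste(sets$gene_id, sets$ec, sep = "\r"),
    ec = sets$ec,
    gene = sets$gene_id
  )
  dplyr::distinct(tibble::tibble(
    genome_id = sets$genome_id, tool = sets$tool, unit_id = uid
  ))
}

#' Support partition of annotation units across tools
#'
#' For a collection of per-tool annotation sets, counts how many distinct
#' units (gene-EC pairs, ECs, or genes) are supported by exactly k tools,
#' how many are unique to each single tool, and the full Venn region table
#' (one row per observed tool combination). Multiple genomes are pooled with
#' genome-qualified units.
#'
#' @param df Normalized annotation tibble.
#' @param unit Unit kind; see [annotation_units()].
#' @param tools Tools to include (default: all tools present in `df`).
#' @return A list of class `"ecc_support_partition"`: `unit`, `tools`,
#'   `n_units` (union size), `counts` (tibble `support`, `n`, `pct`),
#'   `per_tool_unique` (tibble `tool`, `n_unique`, `pct_of_union`), and
#'   `regions` (tibble `region` — "+"-joined sorted tool labels — and `n`).
#' @export
support_partition <- function(df, unit = c("gene_ec_pair", "ec", "gene"),
                              tools = NULL) {
  unit <- match.arg(unit)
  units <- annotation_units(df, unit)
  if (!is.null(tools)) {
    units <- dplyr::filter(units, .data$tool %in% tools)
  } else {
    tools <- sort(unique(units$tool))
  }
  if (length(tools) < 2) {
    stop("support_partition() needs at least two tools", call. = FALSE)
  }
  if (length(unique(stats::na.omit(units$genome_id))) == 0 || nrow(units) == 0) {
    stop("support_partition(): no annotation units", call. = FALSE)
  }
  per_unit <- units |>
    dplyr::group_by(.data$genome_id, .data$unit_id) |>
    dplyr::summarise(
      support = dplyr::n_distinct(.data$tool),
      region = paste(sort(unique(.data$tool)), collapse = "+"),
      .groups = "drop"
    )
  n_units <- nrow(per_unit)
  counts <- per_unit |>
    dplyr::count(.data$support, name = "n") |>
    tidyr::complete(support = seq_along(tools), fill = list(n = 0L)) |>
    dplyr::mutate(pct = agreement_pct(.data$n, n_units))
  uniq <- per_unit |>
    dplyr::filter(.data$support == 1L) |>
    dplyr::count(tool = .data$region, name = "n_unique") |>
    tidyr::complete(tool = tools, fill = list(n_unique = 0L)) |>
    dplyr::mutate(pct_of_union = agreement_pct(.data$n_unique, n_units))
  regions <- per_unit |>
    dplyr::count(.data$region, name = "n") |>
    dplyr::arrange(.data$region)
  structure(
    list(unit = unit, tools = tools, n_units = n_units,
         counts = counts, per_tool_unique = uniq, regions = regions),
    class = "ecc_support_partition"
  )
}

#' @export
print.ecc_support_partition <- function(x, ...) {
  cat(sprintf("Support partition over %d distinct %s units (%d tools: %s)\n",
              x$n_units, x$unit, length(x$tools),
              paste(x$tools, collapse = ", ")))
  print(x$counts)
  invisible(x)
}

#' Pairwise gene-level agreement between annotation tools
#'
#' For each pair of tools, the denominator is the number of genes (pooled
#' across genomes) annotated with at least one complete EC by *both* tools,
#' and the numerator the number of those genes for which the two tools share
#' at least one identical EC assignment. The percentage is printed to one
#' decimal (half away from zero); a zero denominator reports `NA`.
#'
#' @param df Normalized annotation tibble.
#' @param tools Tools to compare (default all present).
#' @param by_genome If `TRUE`, also return the per-genome breakdown.
#' @return Tibble with `tool_a`, `tool_b` (lexicographic, `tool_a < tool_b`),
#'   `numerator`, `denominator`, `pct`; with `by_genome = TRUE` a list of
#'   `pooled` and `per_genome` tibbles.
#' @export
pairwise_gene_agreement <- function(df, tools = NULL, by_genome = FALSE) {
  sets <- ec_annotation_sets(df)
  if (is.null(tools)) tools <- sort(unique(sets$tool))
  sets <- dplyr::filter(sets, .data$tool %in% tools)
  pairs <- utils::combn(sort(tools), 2, simplify = FALSE)
  one_pair <- function(ta, tb) {
    a <- dplyr::filter(sets, .data$tool == ta)
    b <- dplyr::filter(sets, .data$tool == tb)
    shared_genes <- dplyr::inner_join(
      dplyr::distinct(a, .data$genome_id, .data$gene_id),
      dplyr::distinct(b, .data$genome_id, .data$gene_id),
      by = c("genome_id", "gene_id")
    )
    agree_genes <- dplyr::inner_join(
      dplyr::distinct(a, .data$genome_id, .data$gene_id, .data$ec),
      dplyr::distinct(b, .data$genome_id, .data$gene_id, .data$ec),
      by = c("genome_id", "gene_id", "ec")
    ) |>
      dplyr::distinct(.data$genome_id, .data$gene_id)
    den <- shared_genes |> dplyr::count(.data$genome_id, name = "denominator")
    num <- agree_genes |> dplyr::count(.data$genome_id, name = "numerator")
    per_genome <- dplyr::full_join(den, num, by = "genome_id") |>
      dplyr::mutate(
        tool_a = ta, tool_b = tb,
        numerator = dplyr::coalesce(.data$numerator, 0L),
        denominator = dplyr::coalesce(.data$denominator, 0L),
        pct = agreement_pct(.data$numerator, .data$denominator)
      )
    per_genome[, c("genome_id", "tool_a", "tool_b", "numerator",
                   "denominator", "pct")]
  }
  per_genome <- dplyr::bind_rows(lapply(pairs, function(p) one_pair(p[1], p[2])))
  pooled <- per_genome |>
    dplyr::group_by(.data$tool_a, .data$tool_b) |>
    dplyr::summarise(numerator = sum(.data$numerator),
                     denominator = sum(.data$denominator), .groups = "drop") |>
    dplyr::mutate(pct = agreement_pct(.data$numerator, .data$denominator))
  # make sure every requested pair appears even with no shared genes
  all_pairs <- tibble::tibble(
    tool_a = vapply(pairs, `[`, "", 1), tool_b = vapply(pairs, `[`, "", 2)
  )
  pooled <- dplyr::left_join(all_pairs, pooled, by = c("tool_a", "tool_b")) |>
    dplyr::mutate(numerator = dplyr::coalesce(.data$numerator, 0L),
                  denominator = dplyr::coalesce(.data$denominator, 0L),
                  pct = agreement_pct(.data$numerator, .data$denominator))
  if (by_genome) list(pooled = pooled, per_genome = per_genome) else pooled
}

#' Distribution of annotation units over support levels
#'
#' Fractions of distinct units (default: EC numbers per genome) supported by
#' exactly k tools, plus the fraction supported by three or more tools —
#' the quantity used to order genomes from consensus-friendly to
#' single-tool-dominated.
#'
#' @param df Normalized annotation tibble.
#' @param unit Unit kind (default `"ec"`).
#' @param tools Tools to include (default all present).
#' @return A list: `fractions` (tibble `support`, `n`, `fraction`),
#'   `ge3_fraction`, and `n_units`. Errors on an empty union.
#' @export
support_distribution <- function(df, unit = "ec", tools = NULL) {
  part <- support_partition(df, unit = unit, tools = tools)
  if (part$n_units == 0) stop("support_distribution(): empty union", call. = FALSE)
  fr <- part$counts |>
    dplyr::transmute(.data$support, .data$n,
                     fraction = .data$n / part$n_units)
  list(
    fractions = fr,
    ge3_fraction = sum(fr$fraction[fr$support >= 3]),
    n_units = part$n_units
  )
}

#' Gene coverage of metabolic annotation per tool
#'
#' Counts, per tool, the genes carrying at least one complete EC annotation,
#' and reports which fraction of the union of such genes is annotated by two
#' or more tools — the headline coverage gain from combining tools.
#'
#' @param df Normalized annotation tibble.
#' @param tools Tools to include (default all present).
#' @return A list: `per_tool` (tibble `tool`, `n_genes`), `n_union`,
#'   `multi_tool_fraction`.
#' @export
gene_coverage <- function(df, tools = NULL) {
  units <- annotation_units(df, "gene")
  if (!is.null(tools)) units <- dplyr::filter(units, .data$tool %in% tools)
  per_tool <- units |>
    dplyr::count(.data$tool, name = "n_genes") |>
    dplyr::arrange(.data$tool)
  per_gene <- units |>
    dplyr::count(.data$genome_id, .data$unit_id, name = "n_tools")
  n_union <- nrow(per_gene)
  list(
    per_tool = per_tool,
    n_union = n_union,
    multi_tool_fraction = if (n_union > 0) mean(per_gene$n_tools >= 2) else NA_real_
  )
}

#' Mean number of annotation units per genome
#'
#' Arithmetic mean across genomes of the per-genome union size (distinct
#' gene-EC pairs by default), e.g. total gene-EC annotations divided by the
#' number of genomes.
#'
#' @param df Normalized annotation tibble.
#' @param unit Unit kind.
#' @param digits Decimal places to round to (half away from zero); `0` gives
#'   integer rounding.
#' @return A single number.
#' @export
mean_units_per_genome <- function(df, unit = "gene_ec_pair", digits = 0) {
  units <- annotation_units(df, unit)
  per_genome <- units |>
    dplyr::distinct(.data$genome_id, .data$unit_id) |>
    dplyr::count(.data$genome_id)
  round_half_away(mean(per_genome$n), digits)
}

#' Average a pooled annotation count over genomes
#'
#' Convenience for the headline "annotations per genome" figure: a pooled
#' total divided by the number of genomes, rounded half away from zero.
#'
#' @param total Pooled count across genomes.
#' @param n_genomes Number of genomes.
#' @param digits Decimal places (default integer rounding).
#' @return A single number.
#' @examples
#' mean_per_genome(47447, 27) # 1757
#' @export
mean_per_genome <- function(total, n_genomes, digits = 0) {
  stopifnot(n_genomes > 0)
  round_half_away(total / n_genomes, digits)
}

#' Per-genome mean of Venn region counts
#'
#' For each tool-combination region, the arithmetic mean across genomes of
#' the per-genome region count (zero when a genome lacks the region),
#' rounded to one decimal — the "average number of EC numbers per genome"
#' presentation of the overlap.
#'
#' @param df Normalized annotation tibble.
#' @param unit Unit kind (default `"ec"`).
#' @param tools Tools to include (default all present).
#' @return Tibble with `region` and `mean_n`.
#' @export
region_means_per_genome <- function(df, unit = "ec", tools = NULL) {
  units <- annotation_units(df, unit)
  if (!is.null(tools)) units <- dplyr::filter(units, .data$tool %in% tools)
  genomes <- unique(units$genome_id)
  regions <- units |>
    dplyr::group_by(.data$genome_id, .data$unit_id) |>
    dplyr::summarise(region = paste(sort(unique(.data$tool)), collapse = "+"),
                     .groups = "drop") |>
    dplyr::count(.data$genome_id, .data$region, name = "n") |>
    tidyr::complete(genome_id = genomes,
                    region = unique(.data$region), fill = list(n = 0L))
  regions |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mean_n = round_half_away(mean(.data$n), 1),
                     .groups = "drop") |>
    dplyr::arrange(.data$region)
}
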