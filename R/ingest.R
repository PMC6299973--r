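#' Ingest RAST-style functional annotations
#'
#' RAST reports one free-text function per gene; any EC tokens embedded as
#' `"(EC x.x.x.x)"` are parsed out, one record per (gene, extracted EC).
#' Genes whose function text carries no EC token contribute no records.
#'
#' @param rows Tibble/data frame with columns `gene_id` and `function_text`,
#'   keyed by locus tag.
#' @param genome_id Genome identifier stamped on every record.
#' @param tool Tool label (default `"rast"`).
#' @param registry Allowed tool labels.
#' @return Normalized annotation tibble (feature_type `"EC"`), with the
#'   originating function string in `raw_function`.
#' @export
ingest_rast <- function(rows, genome_id, tool = "rast", registry = ecc_tools()) {
  stopifnot(is.data.frame(rows), all(c("gene_id", "function_text") %in% names(rows)))
  ecs <- ec_extract(rows$function_text)
  n <- lengths(ecs)
  if (sum(n) == 0) {
    return(empty_annotation_table())
  }
  annotation_record(
    genome_id = genome_id,
    gene_id = rep(rows$gene_id, n),
    tool = tool,
    feature_type = "EC",
    value = unlist(ecs, use.names = FALSE),
    raw_function = rep(rows$function_text, n),
    registry = registry
  )
}

empty_annotation_table <- function() {
  tibble::tibble(
    genome_id = character(), gene_id = character(), tool = character(),
    feature_type = character(), value = character(),
    raw_function = character(), identity_pct = numeric()
  )
}

#' Read a KO-to-EC mapping table
#'
#' TSV with columns `ko_id` and `ec`, one pair per line (a KO may map to
#' zero, one, or many ECs). The mapping is a required local input; it is
#' never fetched at run time.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `ko_id`, `ec` (canonical).
#' @export
read_ko_ec_map <- function(path) {
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("ko_id", "ec") %in% names(df))) {
    stop("KO-EC map format error: need columns ko_id, ec", call. = FALSE)
  }
  validate_ko_ids(df$ko_id)
  df$ec <- ec_canonical(df$ec)
  dplyr::distinct(tibble::as_tibble(df)[, c("ko_id", "ec")])
}

validate_ko_ids <- function(ko) {
  bad <- which(!grepl("^K[0-9]{5}$", ko))
  if (length(bad) > 0) {
    stop(sprintf("format error: malformed KO id '%s' at row %d",
                 ko[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(ko)
}

#' Ingest KAAS-style gene-to-KO assignments
#'
#' Each (gene, KO) row expands to one record per EC mapped to that KO.
#' KOs absent from the map, or mapping to no EC, produce no EC records but
#' are tallied in the ingest report (see [ingest_report()]).
#'
#' @param rows Tibble with columns `gene_id`, `ko_id`.
#' @param ko_map KO-to-EC mapping tibble from [read_ko_ec_map()].
#' @param genome_id Genome identifier.
#' @param tool Tool label (default `"kegg"`).
#' @param registry Allowed tool labels.
#' @return Normalized annotation tibble with an `"ingest_report"` attribute
#'   listing `n_rows`, `n_unmapped_ko` and the unmapped KO ids.
#' @export
ingest_kaas <- function(rows, ko_map, genome_id, tool = "kegg",
                        registry = ecc_tools()) {
  stopifnot(is.data.frame(rows), all(c("gene_id", "ko_id") %in% names(rows)))
  validate_ko_ids(rows$ko_id)
  rows <- dplyr::distinct(tibble::as_tibble(rows)[, c("gene_id", "ko_id")])
  # many genes can share a KO and one KO can map to many ECs
  hits <- dplyr::inner_join(rows, ko_map, by = "ko_id",
                            relationship = "many-to-many")
  unmapped <- sort(unique(setdiff(rows$ko_id, ko_map$ko_id)))
  out <- if (nrow(hits) == 0) {
    empty_annotation_table()
  } else {
    annotation_record(
      genome_id = genome_id, gene_id = hits$gene_id, tool = tool,
      feature_type = "EC", value = hits$ec,
      raw_function = hits$ko_id, registry = registry
    )
  }
  attr(out, "ingest_report") <- list(
    n_rows = nrow(rows),
    n_unmapped_ko = length(unmapped),
    unmapped_ko = unmapped
  )
  out
}

#' Retrieve the ingest report attached to an ingester's output
#'
#' @param x Output of [ingest_kaas()] or [ingest_blast()].
#' @return The report list, or `NULL` if none is attached.
#' @export
ingest_report <- function(x) attr(x, "ingest_report", exact = TRUE)

#' Read BLAST tabular (12-column, outfmt-6 style) hits
#'
#' @param path Path to the tab-separated BLAST output (no header).
#' @return Tibble with the twelve standard columns: `query_gene`,
#'   `subject_id`, `identity_pct`, `align_len`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`.
#' @export
read_blast_tabular <- function(path) {
  cols <- c("query_gene", "subject_id", "identity_pct", "align_len",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bit_score")
  df <- readr::read_tsv(path, comment = "#", col_names = cols,
                        col_types = "ccdiiiiiiidd", progress = FALSE)
  if (any(df$identity_pct < 0 | df$identity_pct > 100)) {
    stop("BLAST format error: identity_pct outside [0, 100]", call. = FALSE)
  }
  if (any(df$evalue < 0)) {
    stop("BLAST format error: negative e-value", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a subject-to-EC index for annotation transfer
#'
#' TSV columns `subject_id`, `ec`; one row per (reference sequence, EC).
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `subject_id`, `ec` (canonical).
#' @export
read_subject_ec_index <- function(path) {
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("subject_id", "ec") %in% names(df))) {
    stop("subject EC index format error: need columns subject_id, ec",
         call. = FALSE)
  }
  df$ec <- ec_canonical(df$ec)
  dplyr::distinct(tibble::as_tibble(df)[, c("subject_id", "ec")])
}

#' Transfer EC annotations from BLAST hits against an EC-labeled reference
#'
#' Hits with percent identity strictly greater than `min_identity` transfer
#' their subject's EC label(s) to the query gene. By default all qualifying
#' hits are used and the resulting (gene, EC) pairs deduplicated, each record
#' keeping the maximum identity among its supporting hits; `best_hit_only`
#' restricts each query to its single best hit (highest bit score, ties
#' broken by lowest e-value, then subject id).
#'
#' @param hits Tibble from [read_blast_tabular()].
#' @param subject_ec_index Tibble from [read_subject_ec_index()]. Subjects
#'   missing from the index are tallied in the ingest report, not fatal.
#' @param genome_id Genome identifier.
#' @param min_identity Percent-identity threshold; strictly-greater-than
#'   comparison (default 60).
#' @param best_hit_only Use only each query's best hit.
#' @param max_evalue Optional e-value cutoff (`<=`); `NULL` disables.
#' @param min_align_len Optional alignment-length cutoff (`>=`); `NULL`
#'   disables.
#' @param tool Tool label (default `"brenda"`).
#' @param registry Allowed tool labels.
#' @return Normalized annotation tibble with `identity_pct` filled and an
#'   `"ingest_report"` attribute (`n_hits`, `n_pass_identity`,
#'   `n_unindexed_subjects`).
#' @export
ingest_blast <- function(hits, subject_ec_index, genome_id, min_identity = 60,
                         best_hit_only = FALSE, max_evalue = NULL,
                         min_align_len = NULL, tool = "brenda",
                         registry = ecc_tools()) {
  stopifnot(is.data.frame(hits),
            all(c("query_gene", "subject_id", "identity_pct") %in% names(hits)))
  keep <- hits$identity_pct > min_identity
  if (!is.null(max_evalue)) keep <- keep & hits$evalue <= max_evalue
  if (!is.null(min_align_len)) keep <- keep & hits$align_len >= min_align_len
  pass <- hits[keep, , drop = FALSE]
  if (best_hit_only && nrow(pass) > 0) {
    pass <- pass |>
      dplyr::arrange(.data$query_gene, dplyr::desc(.data$bit_score),
                     .data$evalue, .data$subject_id) |>
      dplyr::distinct(.data$query_gene, .keep_all = TRUE)
  }
  unindexed <- unique(setdiff(pass$subject_id, subject_ec_index$subject_id))
  labeled <- dplyr::inner_join(pass, subject_ec_index, by = "subject_id",
                               relationship = "many-to-many")
  out <- if (nrow(labeled) == 0) {
    empty_annotation_table()
  } else {
    labeled |>
      dplyr::group_by(.data$query_gene, .data$ec) |>
      dplyr::summarise(identity_pct = max(.data$identity_pct), .groups = "drop") |>
      (\(d) annotation_record(
        genome_id = genome_id, gene_id = d$query_gene, tool = tool,
        feature_type = "EC", value = d$ec, identity_pct = d$identity_pct,
        registry = registry
      ))()
  }
  attr(out, "ingest_report") <- list(
    n_hits = nrow(hits),
    n_pass_identity = nrow(pass),
    n_unindexed_subjects = length(unindexed),
    unindexed_subjects = sort(unindexed)
  )
  out
}

#' Ingest transporter annotations
#'
#' One TRANSPORT record per distinct row; an empty substrate string is
#' preserved as absent (it becomes specificity rank 5 downstream).
#'
#' @param rows Tibble with columns `gene_id`, `tool`, `substrate_text`.
#' @param genome_id Genome identifier.
#' @param registry Allowed tool labels.
#' @return Normalized annotation tibble (feature_type `"TRANSPORT"`); `value`
#'   holds the normalized substrate (`NA` when absent) and `raw_function`
#'   the original text.
#' @export
ingest_transporters <- function(rows, genome_id, registry = ecc_tools()) {
  stopifnot(is.data.frame(rows),
            all(c("gene_id", "tool", "substrate_text") %in% names(rows)))
  if (nrow(rows) == 0) return(empty_annotation_table())
  out <- tibble::tibble(
    genome_id = as.character(genome_id),
    gene_id = as.character(rows$gene_id),
    tool = as.character(rows$tool),
    feature_type = "TRANSPORT",
    value = normalize_substrate(rows$substrate_text),
    raw_function = as.character(rows$substrate_text),
    identity_pct = NA_real_
  )
  validate_annotation_table(out, registry = registry)
  dplyr::distinct(out, dplyr::across(dplyr::all_of(c(
    "genome_id", "gene_id", "tool", "feature_type", "value"
  ))), .keep_all = TRUE)
}
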