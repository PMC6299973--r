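#' Default annotation-tool registry
#'
#' The tool labels the package knows about by default: four enzyme-annotation
#' sources (`rast`, `kegg`, `eficaz`, `brenda`) and the transporter-annotation
#' source `transportdb`. Readers reject records whose tool label is not in the
#' registry; pass an extended vector to register additional tools.
#'
#' @return Character vector of tool labels.
#' @export
ecc_tools <- function() {
  c("rast", "kegg", "eficaz", "brenda", "transportdb")
}

ecc_feature_types <- function() c("EC", "KO", "TRANSPORT")

anno_cols <- c("genome_id", "gene_id", "tool", "feature_type", "value",
               "raw_function", "identity_pct")

#' Build a normalized annotation tibble
#'
#' Internal-ish constructor used by all ingesters: fills optional columns,
#' orders columns, validates labels, and deduplicates identical records.
#'
#' @param genome_id,gene_id,tool,feature_type,value Required record fields
#'   (recycled per tibble rules).
#' @param raw_function,identity_pct Optional provenance fields.
#' @param registry Allowed tool labels.
#' @return A normalized annotation tibble.
#' @export
annotation_record <- function(genome_id, gene_id, tool, feature_type, value,
                              raw_function = NA_character_,
                              identity_pct = NA_real_,
                              registry = ecc_tools()) {
  out <- tibble::tibble(
    genome_id = as.character(genome_id),
    gene_id = as.character(gene_id),
    tool = as.character(tool),
    feature_type = as.character(feature_type),
    value = as.character(value),
    raw_function = as.character(raw_function),
    identity_pct = as.numeric(identity_pct)
  )
  validate_annotation_table(out, registry = registry)
  dplyr::distinct(out, dplyr::across(dplyr::all_of(c(
    "genome_id", "gene_id", "tool", "feature_type", "value"
  ))), .keep_all = TRUE)
}

validate_annotation_table <- function(df, registry = ecc_tools()) {
  missing <- setdiff(setdiff(anno_cols, c("raw_function", "identity_pct")),
                     names(df))
  if (length(missing) > 0) {
    stop(sprintf("annotation table format error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_gene <- which(is.na(df$gene_id) | !nzchar(df$gene_id))
  if (length(bad_gene) > 0) {
    stop(sprintf("annotation table format error: empty gene_id at row %d",
                 bad_gene[1]), call. = FALSE)
  }
  bad_tool <- which(!df$tool %in% registry)
  if (length(bad_tool) > 0) {
    stop(sprintf(
      "annotation table format error: unregistered tool '%s' at row %d",
      df$tool[bad_tool[1]], bad_tool[1]), call. = FALSE)
  }
  bad_type <- which(!df$feature_type %in% ecc_feature_types())
  if (length(bad_type) > 0) {
    stop(sprintf(
      "annotation table format error: unknown feature_type '%s' at row %d",
      df$feature_type[bad_type[1]], bad_type[1]), call. = FALSE)
  }
  ec_rows <- which(df$feature_type == "EC")
  if (length(ec_rows) > 0) {
    msg <- tryCatch({ ec_parse(df$value[ec_rows]); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(msg)) {
      stop(sprintf("annotation table format error: %s", msg), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a normalized annotation table
#'
#' The normalized exchange format every downstream statistic consumes:
#' UTF-8, tab-separated, one header row, `#` comment lines permitted, empty
#' field means absent. Columns: `genome_id`, `gene_id`, `tool`,
#' `feature_type` (`EC` / `KO` / `TRANSPORT`), `value` (canonical EC string,
#' KO id, or substrate string), and optional `raw_function`, `identity_pct`.
#'
#' EC values are canonicalized on read; malformed ECs, missing mandatory
#' columns, duplicated header names, and unregistered tool labels are format
#' errors reporting the offending row.
#'
#' @param path Path to a TSV file.
#' @param registry Allowed tool labels; see [ecc_tools()].
#' @return A normalized annotation tibble.
#' @export
read_annotation_table <- function(path, registry = ecc_tools()) {
  header <- read_tsv_header(path)
  if (anyDuplicated(header) > 0) {
    stop(sprintf("annotation table format error: duplicate header column '%s'",
                 header[duplicated(header)][1]), call. = FALSE)
  }
  col_types <- if ("identity_pct" %in% header) {
    readr::cols(.default = readr::col_character(),
                identity_pct = readr::col_double())
  } else {
    readr::cols(.default = readr::col_character())
  }
  df <- readr::read_tsv(path, comment = "#", col_types = col_types,
                        progress = FALSE)
  for (opt in c("raw_function", "identity_pct")) {
    if (!opt %in% names(df)) {
      df[[opt]] <- if (opt == "identity_pct") NA_real_ else NA_character_
    }
  }
  df <- tibble::as_tibble(df)[, anno_cols[anno_cols %in% names(df)], drop = FALSE]
  validate_annotation_table(df, registry = registry)
  ec_rows <- df$feature_type == "EC"
  if (any(ec_rows)) {
    df$value[ec_rows] <- ec_canonical(df$value[ec_rows])
  }
  dplyr::distinct(df, dplyr::across(dplyr::all_of(c(
    "genome_id", "gene_id", "tool", "feature_type", "value"
  ))), .keep_all = TRUE)
}

read_tsv_header <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) stop("empty file: ", path, call. = FALSE)
    if (!startsWith(line, "#")) break
  }
  strsplit(line, "\t", fixed = TRUE)[[1]]
}

#' Write a normalized annotation table
#'
#' Inverse of [read_annotation_table()]; absent optional fields are written
#' as empty strings so write-then-read round-trips the record set exactly.
#'
#' @param df Normalized annotation tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(df, path) {
  validate_annotation_table(df)
  for (opt in c("raw_function", "identity_pct")) {
    if (!opt %in% names(df)) {
      df[[opt]] <- if (opt == "identity_pct") NA_real_ else NA_character_
    }
  }
  readr::write_tsv(df[, anno_cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a gold-standard gene-EC table
#'
#' A curated reference set of gene-EC pairs (EcoCyc-like) used to define
#' true/false positives. TSV columns: `genome_id`, `gene_id`, `ec`.
#'
#' @param path Path to the TSV file.
#' @return Tibble of distinct `(genome_id, gene_id, ec)` pairs with
#'   canonicalized EC strings.
#' @export
read_gold_standard <- function(path) {
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("genome_id", "gene_id", "ec")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("gold-standard format error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[, need]
  df$ec <- ec_canonical(df$ec)
  dplyr::distinct(df)
}

#' Write a gold-standard gene-EC table
#'
#' @param gold Tibble with `genome_id`, `gene_id`, `ec`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  stopifnot(all(c("genome_id", "gene_id", "ec") %in% names(gold)))
  readr::write_tsv(
    dplyr::distinct(gold[, c("genome_id", "gene_id", "ec")]), path,
    progress = FALSE
  )
  invisible(path)
}

#' Distinct gene-EC pairs per genome and tool
#'
#' Projects a normalized annotation table onto its EC records, drops partial
#' ECs, and deduplicates `(genome_id, tool, gene_id, ec)` — the package's
#' working "annotation set" representation.
#'
#' @param df Normalized annotation tibble.
#' @param keep_partial Keep partial ECs (default drops them).
#' @return Tibble with columns `genome_id`, `tool`, `gene_id`, `ec`.
#' @export
ec_annotation_sets <- function(df, keep_partial = FALSE) {
  stopifnot(is.data.frame(df))
  out <- dplyr::filter(df, .data$feature_type == "EC")
  if (!keep_partial) out <- filter_complete(out)
  out <- dplyr::distinct(out, .data$genome_id, .data$tool, .data$gene_id,
                         ec = .data$value)
  out
}

#' Format an agreement percentage the way comparison tables print it
#'
#' `100 * numerator / denominator`, rounded to one decimal with ties rounded
#' half away from zero. A zero denominator yields `NA` (absent), never 0.
#'
#' @param numerator,denominator Non-negative counts (vectorized).
#' @return Numeric vector of percentages with one-decimal resolution.
#' @examples
#' agreement_pct(16697, 20915) # 79.8
#' @export
agreement_pct <- function(numerator, denominator) {
  ratio <- 100 * numerator / denominator # recycles the shorter argument
  out <- round_half_away(ratio, 1)
  out[rep_len(!(denominator > 0), length(out))] <- NA_real_
  out
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
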