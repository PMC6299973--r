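# Fixture builders and independent brute-force oracles used across tests.

# quick normalized EC annotation tibble: one row per (tool, gene, ec)
make_ec_anno <- function(tool, gene_id, ec, genome_id = "G1") {
  tibble::tibble(
    genome_id = genome_id, gene_id = gene_id, tool = tool,
    feature_type = "EC", value = ec,
    raw_function = NA_character_, identity_pct = NA_real_
  )
}

make_transport_anno <- function(tool, gene_id, substrate, genome_id = "G1") {
  tibble::tibble(
    genome_id = genome_id, gene_id = gene_id, tool = tool,
    feature_type = "TRANSPORT",
    value = ecconsensus::normalize_substrate(substrate),
    raw_function = substrate, identity_pct = NA_real_
  )
}

# independent Venn-region oracle: plain membership loop over the union
oracle_regions <- function(sets) {
  units <- sort(unique(unlist(sets, use.names = FALSE)))
  counts <- list()
  for (u in units) {
    in_tools <- sort(names(sets)[vapply(sets, function(s) u %in% s, logical(1))])
    key <- paste(in_tools, collapse = "+")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small multi-tool instance: per-tool (gene, ec) pair sets
random_instance <- function(n_tools = sample(2:6, 1), n_genes = 12,
                            n_ecs = 8, max_pairs = 50) {
  tools <- paste0("tool", seq_len(n_tools))
  genes <- paste0("g", seq_len(n_genes))
  ecs <- paste0("1.1.1.", seq_len(n_ecs))
  all_pairs <- expand.grid(gene_id = genes, ec = ecs,
                           stringsAsFactors = FALSE)
  df <- dplyr::bind_rows(lapply(tools, function(t) {
    n <- sample.int(min(max_pairs, nrow(all_pairs)), 1)
    idx <- sample.int(nrow(all_pairs), n)
    make_ec_anno(t, all_pairs$gene_id[idx], all_pairs$ec[idx])
  }))
  registry <- tools # not in the default registry; pass explicitly when needed
  list(df = df, tools = tools, registry = registry)
}

# per-tool unit sets (character vectors) from an annotation tibble
unit_sets <- function(df, unit) {
  sets <- ecconsensus::ec_annotation_sets(df)
  tools <- sort(unique(sets$tool))
  out <- lapply(tools, function(t) {
    s <- sets[sets$tool == t, ]
    switch(unit,
      gene_ec_pair = unique(paste(s$gene_id, s$ec, sep = "\r")),
      ec = unique(s$ec),
      gene = unique(s$gene_id)
    )
  })
  names(out) <- tools
  out
}
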