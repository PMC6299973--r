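test_that("normalize_substrate lowercases, squishes and strips edges", {
  expect_equal(normalize_substrate("  Lysine "), "lysine")
  expect_equal(normalize_substrate("Mg/Co/Ni"), "mg/co/ni")
  expect_equal(normalize_substrate("  branched   chain  AA "),
               "branched chain aa")
  expect_equal(normalize_substrate("\"glucose\","), "glucose")
  expect_true(is.na(normalize_substrate("")))
  expect_true(is.na(normalize_substrate("   ")))
  expect_true(is.na(normalize_substrate(NA_character_)))
})

test_that("vocabulary construction enforces rank and uniqueness rules", {
  expect_error(substrate_vocabulary("x", 5, "g"), "ranks must be")
  expect_error(substrate_vocabulary("x", 0, "g"), "ranks must be")
  expect_error(substrate_vocabulary(c("x", "X "), c(1, 2), c("g", "g")),
               "duplicate substrate")
  expect_error(substrate_vocabulary("", 1, "g"), "empty substrate")
  v <- substrate_vocabulary(c("Lysine", "sugar"), c(1, 3), c("lys", "sug"))
  expect_equal(v$substrate, c("lysine", "sugar"))
})

test_that("the shipped vocabulary ranks the canonical examples", {
  vocab <- default_substrate_vocabulary()
  df <- make_transport_anno(
    "transportdb", paste0("g", 1:6),
    c("lysine", "Mg/Co/Ni", "sugar", "multidrug efflux", "", "unobtainium")
  )
  ranked <- rank_substrates(df, vocab)
  get_rank <- function(g) ranked$rank[ranked$gene_id == g]
  expect_equal(get_rank("g1"), 1L) # specific metabolite
  expect_equal(get_rank("g2"), 2L) # small set of possible reactions
  expect_equal(get_rank("g3"), 3L) # broad class
  expect_equal(get_rank("g4"), 4L) # very broad class
  expect_equal(get_rank("g5"), 5L) # no substrate annotated
  # unknown non-empty substrate: rank 5 plus a visible unranked tally
  expect_equal(get_rank("g6"), 5L)
  expect_equal(attr(ranked, "n_unranked"), 1L)
  expect_true(all(ranked$rank %in% 1:5))
})

test_that("rank_distribution counts genes at their most specific rank", {
  vocab <- default_substrate_vocabulary()
  all_specific <- rank_substrates(
    make_transport_anno("transportdb", paste0("g", 1:10), rep("lysine", 10)),
    vocab
  )
  rd <- rank_distribution(all_specific)
  expect_equal(rd$totals$rank12_fraction, 1.0)
  expect_equal(rd$totals$n_genes, 10L)
  # ranks {1:28, 3:20, 5:52} per 100 genes: rank 1-2 fraction 0.28
  df <- rank_substrates(make_transport_anno(
    "rast", paste0("g", 1:100),
    c(rep("lysine", 28), rep("sugar", 20), rep("", 52))
  ), vocab)
  rd <- rank_distribution(df)
  expect_equal(rd$totals$rank12_fraction, 0.28)
  per_rank <- rd$per_tool$n[rd$per_tool$rank %in% c(1, 3, 5)]
  expect_equal(per_rank, c(28L, 20L, 52L))
  # fractions sum to one per tool
  expect_equal(sum(rd$per_tool$fraction), 1, tolerance = 1e-12)
  # empty input: all zeros, no error
  empty <- rank_distribution(rank_substrates(
    make_transport_anno("rast", character(), character()), vocab))
  expect_equal(nrow(empty$totals), 0L)
  # a gene with both a specific and a broad record counts once, specific
  multi <- rank_substrates(make_transport_anno(
    "kegg", c("g1", "g1"), c("lysine", "sugar")), vocab)
  rd <- rank_distribution(multi)
  expect_equal(rd$totals$n_genes, 1L)
  expect_equal(rd$totals$rank12_fraction, 1.0)
})

test_that("three_tool_overlap pools instances and intersects genes", {
  vocab <- default_substrate_vocabulary()
  # identical single-gene sets across 3 tools: 3 pooled, 1 shared = 33.3%
  df <- rank_substrates(dplyr::bind_rows(
    make_transport_anno("transportdb", "g1", "lysine"),
    make_transport_anno("rast", "g1", "lysine"),
    make_transport_anno("kegg", "g1", "lysine")
  ), vocab)
  ov <- three_tool_overlap(df)
  expect_equal(ov$n_pooled, 3L)
  expect_equal(ov$n_all_tools, 1L)
  expect_equal(ov$pct_agreement, 33.3)
  expect_equal(ov$n_all_tools_specific, 1L)
  # pairwise-disjoint gene sets: zero shared genes
  df2 <- rank_substrates(dplyr::bind_rows(
    make_transport_anno("transportdb", "g1", "lysine"),
    make_transport_anno("rast", "g2", "lysine"),
    make_transport_anno("kegg", "g3", "lysine")
  ), vocab)
  ov2 <- three_tool_overlap(df2)
  expect_equal(ov2$n_all_tools, 0L)
  expect_equal(ov2$pct_agreement, 0.0)
  expect_error(three_tool_overlap(df[df$tool == "rast", ]), "at least two")
  # numerator never exceeds the smallest per-tool gene count
  set.seed(55)
  for (i in 1:10) {
    tools <- c("transportdb", "rast", "kegg")
    df3 <- rank_substrates(dplyr::bind_rows(lapply(tools, function(t) {
      genes <- paste0("g", sample(1:15, sample(3:12, 1)))
      make_transport_anno(t, genes, rep("lysine", length(genes)))
    })), vocab)
    ov3 <- three_tool_overlap(df3)
    min_count <- min(table(dplyr::distinct(df3, tool, gene_id)$tool))
    expect_lte(ov3$n_all_tools, min_count)
    # removing some of one tool's records cannot increase the all-tools count
    rast_rows <- which(df3$tool == "rast")
    keep <- sort(sample(rast_rows, ceiling(length(rast_rows) / 2)))
    df_sub <- df3[sort(c(which(df3$tool != "rast"), keep)), ]
    ov_sub <- three_tool_overlap(df_sub, tools = tools)
    expect_lte(ov_sub$n_all_tools, ov3$n_all_tools)
  }
})

test_that("substrate agreement uses synonym classes, not string identity", {
  vocab <- default_substrate_vocabulary()
  # the canonical branched-chain amino-acid example: three spellings, one class
  df <- rank_substrates(dplyr::bind_rows(
    make_transport_anno("transportdb", "g1", "leucine/valine"),
    make_transport_anno("rast", "g1", "leucine"),
    make_transport_anno("kegg", "g1", "branched-chain amino acid")
  ), vocab)
  ag <- substrate_agreement(df)
  expect_equal(ag$n_genes, 1L)
  expect_equal(ag$fraction, 1.0)
  # identical strings agree trivially
  df2 <- rank_substrates(dplyr::bind_rows(
    make_transport_anno("transportdb", "g1", "lysine"),
    make_transport_anno("rast", "g1", "lysine")
  ), vocab)
  expect_equal(substrate_agreement(df2)$fraction, 1.0)
  # substrates in different classes do not agree
  df3 <- rank_substrates(dplyr::bind_rows(
    make_transport_anno("transportdb", "g1", "lysine"),
    make_transport_anno("rast", "g1", "fe")
  ), vocab)
  expect_equal(substrate_agreement(df3)$fraction, 0.0)
  # broad rank-3+ annotations never qualify a gene
  df4 <- rank_substrates(dplyr::bind_rows(
    make_transport_anno("transportdb", "g1", "sugar"),
    make_transport_anno("rast", "g1", "sugar")
  ), vocab)
  expect_equal(substrate_agreement(df4)$n_genes, 0L)
  expect_true(is.na(substrate_agreement(df4)$fraction))
})

test_that("agreement is invariant to record order and group relabeling", {
  vocab <- default_substrate_vocabulary()
  df <- dplyr::bind_rows(
    make_transport_anno("transportdb", c("g1", "g2"), c("leucine/valine", "fe")),
    make_transport_anno("rast", c("g1", "g2"), c("leucine", "lysine")),
    make_transport_anno("kegg", "g1", "branched-chain amino acid")
  )
  base <- substrate_agreement(rank_substrates(df, vocab))
  shuffled <- substrate_agreement(rank_substrates(df[sample(nrow(df)), ], vocab))
  expect_equal(base$fraction, shuffled$fraction)
  expect_equal(base$per_pair, shuffled$per_pair)
  # relabel every synonym group id: fractions unchanged
  relabeled <- vocab
  relabeled$synonym_group_id <- paste0("grp_", vocab$synonym_group_id)
  relab <- substrate_agreement(rank_substrates(df, relabeled))
  expect_equal(base$fraction, relab$fraction)
  expect_equal(base$n_agree, relab$n_agree)
})

test_that("vocabulary TSV reader round-trips the shipped fixture", {
  vocab <- default_substrate_vocabulary()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(vocab, path)
  back <- read_substrate_vocabulary(path)
  expect_equal(as.data.frame(back), as.data.frame(vocab))
})
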