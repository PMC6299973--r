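test_that("support_partition counts hand-enumerated Venn examples", {
  # both tools assign the same single pair: one unit at support 2
  df <- dplyr::bind_rows(
    make_ec_anno("rast", "g1", "1.1.1.1"),
    make_ec_anno("kegg", "g1", "1.1.1.1")
  )
  part <- support_partition(df, "gene_ec_pair")
  expect_equal(part$n_units, 1L)
  expect_equal(part$counts$n[part$counts$support == 2], 1L)
  expect_true(all(part$per_tool_unique$n_unique == 0))

  # A={(g1,e1),(g2,e2)}, B={(g1,e1),(g3,e3)}: counts {1:2, 2:1}, unique 1+1
  df <- dplyr::bind_rows(
    make_ec_anno("rast", c("g1", "g2"), c("1.1.1.1", "2.2.2.2")),
    make_ec_anno("kegg", c("g1", "g3"), c("1.1.1.1", "3.3.3.3"))
  )
  part <- support_partition(df, "gene_ec_pair")
  expect_equal(part$counts$n, c(2L, 1L))
  expect_equal(sum(part$counts$n), part$n_units)
  expect_equal(part$per_tool_unique$n_unique, c(1L, 1L))

  # unit = ec projects away genes: one EC seen by both tools
  df <- dplyr::bind_rows(
    make_ec_anno("rast", c("g1", "g2"), c("1.1.1.1", "1.1.1.1")),
    make_ec_anno("kegg", "g3", "1.1.1.1")
  )
  part <- support_partition(df, "ec")
  expect_equal(part$n_units, 1L)
  expect_equal(part$counts$n[part$counts$support == 2], 1L)
})

test_that("Venn regions match a brute-force membership oracle", {
  set.seed(101)
  for (i in 1:60) {
    inst <- random_instance()
    for (unit in c("gene_ec_pair", "ec", "gene")) {
      sets <- unit_sets(inst$df, unit)
      if (length(sets) < 2) next
      expected <- oracle_regions(sets)
      part <- support_partition(inst$df, unit)
      got <- stats::setNames(as.list(part$regions$n), part$regions$region)
      expect_equal(got[order(names(got))], expected[order(names(expected))],
                   info = sprintf("instance %d unit %s", i, unit))
      # region counts sum to the union size
      expect_equal(sum(part$regions$n), length(unique(unlist(sets))))
      # sum over support levels equals the union size
      expect_equal(sum(part$counts$n), part$n_units)
      # single-tool units split into the per-tool unique counts
      expect_equal(sum(part$per_tool_unique$n_unique),
                   part$counts$n[part$counts$support == 1])
    }
  }
})

test_that("agreement_pct recycles a scalar denominator over many numerators", {
  expect_equal(agreement_pct(c(50, 25, 0), 100), c(50.0, 25.0, 0.0))
  expect_equal(agreement_pct(c(1, 2), c(2, 0)), c(50.0, NA))
  # support-level percentages are per level, not a single recycled value
  df <- dplyr::bind_rows(
    make_ec_anno("rast", c("g1", "g2", "g3"), paste0(1:3, ".1.1.1")),
    make_ec_anno("kegg", "g1", "1.1.1.1")
  )
  part <- support_partition(df, "gene_ec_pair")
  expect_equal(part$counts$pct, c(66.7, 33.3))
})

test_that("pairwise gene agreement matches hand enumeration", {
  # a: g1{e1}, g2{e2}; b: g1{e1,e3}, g2{e4}, g3{e5} -> 1/2 = 50.0%
  df <- dplyr::bind_rows(
    make_ec_anno("rast", c("g1", "g2"), c("1.1.1.1", "2.2.2.2")),
    make_ec_anno("kegg", c("g1", "g1", "g2", "g3"),
                 c("1.1.1.1", "3.3.3.3", "4.4.4.4", "5.5.5.5"))
  )
  out <- pairwise_gene_agreement(df)
  expect_equal(out$numerator, 1L)
  expect_equal(out$denominator, 2L)
  expect_equal(out$pct, 50.0)
  # identical non-empty sets agree on every shared gene
  df2 <- dplyr::bind_rows(
    make_ec_anno("rast", c("g1", "g2"), c("1.1.1.1", "2.2.2.2")),
    make_ec_anno("kegg", c("g1", "g2"), c("1.1.1.1", "2.2.2.2"))
  )
  out2 <- pairwise_gene_agreement(df2)
  expect_equal(out2$numerator, out2$denominator)
  expect_equal(out2$pct, 100.0)
})

test_that("agreement pools numerators and denominators across genomes", {
  g1 <- dplyr::bind_rows(
    make_ec_anno("rast", c("g1", "g2"), c("1.1.1.1", "2.2.2.2"), "GA"),
    make_ec_anno("kegg", c("g1", "g2"), c("1.1.1.1", "9.9.9.9" ), "GA")
  )
  g2 <- dplyr::bind_rows(
    make_ec_anno("rast", "g1", "1.1.1.1", "GB"),
    make_ec_anno("kegg", "g1", "1.1.1.1", "GB")
  )
  res <- pairwise_gene_agreement(dplyr::bind_rows(g1, g2), by_genome = TRUE)
  # pooled: (1+1)/(2+1); per genome 1/2 and 1/1
  expect_equal(res$pooled$numerator, 2L)
  expect_equal(res$pooled$denominator, 3L)
  expect_equal(res$pooled$pct, 66.7)
  expect_equal(sort(res$per_genome$pct), c(50.0, 100.0))
})

test_that("agreement is symmetric, order-invariant, with NA for no overlap", {
  set.seed(57)
  for (i in 1:10) {
    inst <- random_instance(n_tools = 2)
    out <- pairwise_gene_agreement(inst$df)
    shuffled <- pairwise_gene_agreement(inst$df[sample(nrow(inst$df)), ])
    expect_equal(out, shuffled)
    expect_lte(out$numerator, out$denominator)
  }
  disjoint <- dplyr::bind_rows(
    make_ec_anno("rast", "g1", "1.1.1.1"),
    make_ec_anno("kegg", "g2", "1.1.1.1")
  )
  out <- pairwise_gene_agreement(disjoint)
  expect_equal(out$denominator, 0L)
  expect_true(is.na(out$pct))
})

test_that("adding records to one tool never shrinks a pair's denominator", {
  set.seed(77)
  inst <- random_instance(n_tools = 2)
  base <- pairwise_gene_agreement(inst$df)
  for (i in 1:10) {
    extra <- make_ec_anno("tool1", paste0("g", sample(1:12, 3)),
                          sprintf("1.1.1.%d", sample(1:8, 3, TRUE)))
    grown <- pairwise_gene_agreement(dplyr::bind_rows(inst$df, extra))
    expect_gte(grown$denominator, base$denominator)
  }
})

test_that("support_distribution returns fractions summing to one", {
  # counts {1:1, 2:1, 3:1, 4:1}: four ECs at supports 1..4
  df <- dplyr::bind_rows(lapply(1:4, function(k) {
    dplyr::bind_rows(lapply(paste0("tool", 1:k), function(t) {
      make_ec_anno(t, "g1", sprintf("%d.1.1.1", k))
    }))
  }))
  d <- support_distribution(df, "ec")
  expect_equal(d$fractions$fraction, rep(0.25, 4))
  expect_equal(d$ge3_fraction, 0.5)
  expect_equal(sum(d$fractions$fraction), 1, tolerance = 1e-12)
  # everything supported by all four tools
  df_all <- dplyr::bind_rows(lapply(paste0("tool", 1:4), function(t) {
    make_ec_anno(t, c("g1", "g2"), c("1.1.1.1", "2.2.2.2"))
  }))
  expect_equal(support_distribution(df_all, "ec")$ge3_fraction, 1.0)
  # counts {1:48, 2:19, 3:20, 4:13}: single-tool fraction 0.48
  mk <- function(k, n, offset) {
    dplyr::bind_rows(lapply(paste0("tool", 1:k), function(t) {
      make_ec_anno(t, "g1", sprintf("%d.%d.1.1", k, offset + seq_len(n)))
    }))
  }
  df_cd <- dplyr::bind_rows(mk(1, 48, 0), mk(2, 19, 100),
                            mk(3, 20, 200), mk(4, 13, 300))
  d <- support_distribution(df_cd, "ec")
  expect_equal(d$fractions$fraction[d$fractions$support == 1], 0.48)
  expect_equal(d$ge3_fraction, 0.33)
  expect_error(support_distribution(make_ec_anno("rast", "g", "1.2.3.-")[0, ]),
               "at least two tools|no annotation units")
})

test_that("gene_coverage reports the multi-tool fraction of the gene union", {
  disjoint <- dplyr::bind_rows(
    make_ec_anno("rast", "g1", "1.1.1.1"),
    make_ec_anno("kegg", "g2", "2.2.2.2")
  )
  expect_equal(gene_coverage(disjoint)$multi_tool_fraction, 0)
  identical_sets <- dplyr::bind_rows(
    make_ec_anno("rast", c("g1", "g2"), c("1.1.1.1", "2.2.2.2")),
    make_ec_anno("kegg", c("g1", "g2"), c("3.3.3.3", "4.4.4.4"))
  )
  expect_equal(gene_coverage(identical_sets)$multi_tool_fraction, 1)
  # A:{g1,g2}, B:{g2,g3}: union 3 genes, one shared
  partial <- dplyr::bind_rows(
    make_ec_anno("rast", c("g1", "g2"), c("1.1.1.1", "2.2.2.2")),
    make_ec_anno("kegg", c("g2", "g3"), c("2.2.2.2", "3.3.3.3"))
  )
  cov <- gene_coverage(partial)
  expect_equal(cov$n_union, 3L)
  expect_equal(cov$multi_tool_fraction, 1 / 3)
  expect_equal(cov$per_tool$n_genes, c(2L, 2L))
})

test_that("per-genome unit means average the union over genomes", {
  df <- dplyr::bind_rows(
    make_ec_anno("rast", c("g1", "g2"), c("1.1.1.1", "2.2.2.2"), "GA"),
    make_ec_anno("kegg", "g1", "1.1.1.1", "GA"),
    make_ec_anno("rast", "g1", "1.1.1.1", "GB")
  )
  # GA has 2 distinct pairs, GB has 1: mean 1.5 -> 2 at integer rounding
  expect_equal(mean_units_per_genome(df, "gene_ec_pair", digits = 1), 1.5)
  expect_equal(mean_per_genome(47447, 27), 1757)
  expect_equal(mean_per_genome(3, 2), 2) # half away from zero
  # unit=ec regions: GA has {kegg+rast: e1, rast: e2}, GB has {rast: e1};
  # means over the two genomes are 0.5 and (1+1)/2 = 1
  rm <- region_means_per_genome(df, "ec")
  expect_equal(rm$mean_n[rm$region == "kegg+rast"], 0.5)
  expect_equal(rm$mean_n[rm$region == "rast"], 1)
})
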