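#' Per-tool simulation parameters
#'
#' @param sensitivity Probability that a true gene-EC pair of an
#'   average-difficulty gene is detected by the tool (fraction in 0..1).
#' @param false_rate Expected number of false gene-EC pairs per gene in the
#'   genome (false annotations land on real genes, drawn uniformly, with an
#'   EC drawn uniformly from the universe excluding that gene's true ECs).
#' @param partial_ec_prob Probability, per emitted record, of additionally
#'   injecting a partial ("three-digit") EC record for the same gene.
#' @return A named list.
#' @export
sim_tool <- function(sensitivity, false_rate, partial_ec_prob = 0) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            false_rate >= 0,
            partial_ec_prob >= 0, partial_ec_prob <= 1)
  list(sensitivity = sensitivity, false_rate = false_rate,
       partial_ec_prob = partial_ec_prob)
}

#' Per-tool transporter simulation parameters
#'
#' @param coverage Fraction of true transporter genes the tool annotates.
#' @param rank_dist Numeric vector of length 5: probability that an annotated
#'   gene receives a substrate of specificity rank 1..5 (rank 5 = no
#'   substrate). Must sum to 1 within 1e-9.
#' @return A named list.
#' @export
sim_transporter_tool <- function(coverage, rank_dist) {
  stopifnot(coverage >= 0, coverage <= 1, length(rank_dist) == 5,
            all(rank_dist >= 0))
  if (abs(sum(rank_dist) - 1) > 1e-9) {
    stop("rank_dist must sum to 1 (got ", sum(rank_dist), ")", call. = FALSE)
  }
  list(coverage = coverage, rank_dist = rank_dist)
}

#' Simulation configuration
#'
#' Defines a ground-truthed multi-tool annotation scenario: a simulated gene
#' and EC universe, a gold standard of true gene-EC pairs, per-tool
#' sensitivities and false-annotation rates, a shared per-gene detection
#' difficulty inducing cross-tool correlation, and per-tool transporter
#' substrate-rank profiles.
#'
#' Defaults emulate a bacterial genome annotated by four EC tools whose
#' behavior mirrors the published multi-tool comparison: a subsystem-based
#' annotator (`rast`), an ortholog-mapping annotator (`kegg`, highest
#' sensitivity and most over-prediction), an enzyme-function classifier
#' (`eficaz`, conservative, emits some partial ECs), and a reference-database
#' BLAST (`brenda`, lowest sensitivity, highest unique-error fraction); and
#' three transporter annotators with rank profiles shaped like the published
#' per-tool distributions (a dedicated transporter pipeline with mostly
#' specific substrates, and two general annotators dominated by broad or
#' absent substrates).
#'
#' @param seed Integer master seed. Every random draw is derived from it via
#'   a labeled stream-splitting scheme (per genome, tool and stage), so
#'   adding a tool does not perturb the other tools' draws.
#' @param n_genes Genes per genome.
#' @param ec_universe_size Number of distinct complete ECs in the universe.
#' @param frac_metabolic Fraction of genes that truly carry an EC.
#' @param multi_ec_prob Probability a metabolic gene carries a second EC
#'   (multifunctional enzymes).
#' @param difficulty_sd Standard deviation of the per-gene detection
#'   difficulty shared by all tools (0 = independent tool errors).
#' @param tools Named list of [sim_tool()] entries.
#' @param transporters Named list with `n_transporter_genes`, `agree_prob`
#'   (probability a specific substrate annotation matches the gene's true
#'   synonym class), `n_synonym_classes`, and `tools` (named list of
#'   [sim_transporter_tool()]).
#' @return A list of class `"ecc_sim_config"`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_genes = 2000L,
    ec_universe_size = 1500L,
    frac_metabolic = 0.35,
    multi_ec_prob = 0.12,
    difficulty_sd = 1,
    tools = list(
      rast   = sim_tool(sensitivity = 0.75, false_rate = 0.06, partial_ec_prob = 0.01),
      kegg   = sim_tool(sensitivity = 0.80, false_rate = 0.08),
      eficaz = sim_tool(sensitivity = 0.60, false_rate = 0.02, partial_ec_prob = 0.05),
      brenda = sim_tool(sensitivity = 0.35, false_rate = 0.10)
    ),
    transporters = list(
      n_transporter_genes = 500L,
      # per-annotation truth-match probability; two independent specific
      # annotations then share a synonym class ~0.92^2 = 0.85 of the time
      agree_prob = 0.92,
      n_synonym_classes = 60L,
      tools = list(
        transportdb = sim_transporter_tool(0.85, c(0.35, 0.24, 0.21, 0.11, 0.09)),
        kegg        = sim_transporter_tool(0.41, c(0.28, 0.20, 0.17, 0.11, 0.24)),
        rast        = sim_transporter_tool(0.23, c(0.16, 0.12, 0.12, 0.08, 0.52))
      )
    )) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    ec_universe_size = as.integer(ec_universe_size),
    frac_metabolic = frac_metabolic, multi_ec_prob = multi_ec_prob,
    difficulty_sd = difficulty_sd, tools = tools, transporters = transporters
  )
  validate_sim_config(cfg)
  structure(cfg, class = "ecc_sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      is.integer(seed), length(seed) == 1, !is.na(seed),
      n_genes > 0, ec_universe_size > 0,
      frac_metabolic >= 0, frac_metabolic <= 1,
      multi_ec_prob >= 0, multi_ec_prob <= 1,
      difficulty_sd >= 0,
      length(tools) >= 1, !is.null(names(tools)), all(nzchar(names(tools)))
    )
  })
  for (t in cfg$tools) {
    do.call(sim_tool, t) # revalidates field ranges
  }
  tc <- cfg$transporters
  if (!is.null(tc)) {
    stopifnot(tc$n_transporter_genes > 0,
              tc$agree_prob >= 0, tc$agree_prob <= 1,
              tc$n_synonym_classes > 0, length(tc$tools) >= 1)
    for (t in tc$tools) do.call(sim_transporter_tool, t)
  }
  invisible(cfg)
}

# deterministic sub-seed for a labeled random stream
stream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h) %% 2147483646) + 1L
}

# distinct complete canonical ECs drawn from the "universe" stream
sim_ec_universe <- function(cfg) {
  set.seed(stream_seed(cfg$seed, "universe"))
  n <- cfg$ec_universe_size
  ecs <- character(0)
  while (length(ecs) < n) {
    draw <- paste(sample(1:6, 2 * n, replace = TRUE),
                  sample(1:25, 2 * n, replace = TRUE),
                  sample(1:25, 2 * n, replace = TRUE),
                  sample(1:999, 2 * n, replace = TRUE), sep = ".")
    ecs <- unique(c(ecs, draw))
  }
  sort(ecs[seq_len(n)])
}

ec_truncate <- function(ec) {
  sub("\\.[0-9]+$", ".-", ec)
}

#' Simulate multi-tool gene-EC annotations with known ground truth
#'
#' For each genome: a fraction of genes is metabolic and carries one (or,
#' with `multi_ec_prob`, two) true EC(s) drawn uniformly from the universe —
#' the gold standard. Each gene has a detection difficulty shared by all
#' tools, drawn from N(0, `difficulty_sd`); a tool detects a true pair with
#' probability `plogis(qlogis(sensitivity) - difficulty)`, so the marginal
#' detection rate equals `sensitivity` when `difficulty_sd = 0`, and
#' difficulty spread induces the positive cross-tool correlation seen in
#' real genomes. False pairs are added at a Poisson rate of
#' `false_rate * n_genes` per tool, each on a uniformly drawn gene with a
#' uniformly drawn EC outside that gene's true set; partial-EC records are
#' injected at `partial_ec_prob` per emitted record.
#'
#' Identical configuration and seed give identical output.
#'
#' @param config A [simulation_config()].
#' @param genome_ids Character vector of genome identifiers to simulate.
#' @return A list of class `"ecc_sim"`: `gold` (tibble `genome_id`,
#'   `gene_id`, `ec`), `annotations` (normalized annotation tibble including
#'   injected partial-EC records), `provenance` (every generated record
#'   labeled `"tp"`, `"fp"` or `"partial"`), and `config`.
#' @export
simulate_annotations <- function(config, genome_ids = "G1") {
  validate_sim_config(config)
  universe <- sim_ec_universe(config)
  tools <- names(config$tools)
  gold_all <- list(); prov_all <- list()
  for (g in genome_ids) {
    genes <- sprintf("%s_g%05d", g, seq_len(config$n_genes))
    set.seed(stream_seed(config$seed, paste0("gold:", g)))
    n_met <- round(config$frac_metabolic * config$n_genes)
    met_genes <- sort(sample(genes, n_met))
    ec1 <- sample(universe, n_met, replace = TRUE)
    second <- stats::runif(n_met) < config$multi_ec_prob
    ec2 <- sample(universe, n_met, replace = TRUE)
    gold <- tibble::tibble(
      genome_id = g,
      gene_id = c(met_genes, met_genes[second & ec2 != ec1]),
      ec = c(ec1, ec2[second & ec2 != ec1])
    )
    gold <- dplyr::distinct(gold)
    difficulty <- stats::rnorm(config$n_genes, 0, config$difficulty_sd)
    names(difficulty) <- genes
    true_ecs_by_gene <- split(gold$ec, gold$gene_id)

    for (tool in tools) {
      tcfg <- config$tools[[tool]]
      # detection of true pairs
      set.seed(stream_seed(config$seed, paste("detect", tool, g, sep = ":")))
      p <- detection_prob(tcfg$sensitivity, difficulty[gold$gene_id])
      hit <- stats::runif(nrow(gold)) < p
      tp <- gold[hit, , drop = FALSE]
      # false pairs
      set.seed(stream_seed(config$seed, paste("false", tool, g, sep = ":")))
      n_false <- stats::rpois(1, tcfg$false_rate * config$n_genes)
      fp <- tibble::tibble(genome_id = character(), gene_id = character(),
                           ec = character())
      if (n_false > 0) {
        f_gene <- sample(genes, n_false, replace = TRUE)
        f_ec <- sample(universe, n_false, replace = TRUE)
        is_true <- mapply(function(gn, e) {
          e %in% true_ecs_by_gene[[gn]]
        }, f_gene, f_ec, USE.NAMES = FALSE)
        while (any(is_true)) {
          f_ec[is_true] <- sample(universe, sum(is_true), replace = TRUE)
          is_true[is_true] <- mapply(function(gn, e) {
            e %in% true_ecs_by_gene[[gn]]
          }, f_gene[is_true], f_ec[is_true], USE.NAMES = FALSE)
        }
        fp <- dplyr::distinct(tibble::tibble(genome_id = g, gene_id = f_gene,
                                             ec = f_ec))
      }
      emitted <- dplyr::bind_rows(tp, fp)
      # partial-EC injection
      set.seed(stream_seed(config$seed, paste("partial", tool, g, sep = ":")))
      part <- tibble::tibble(genome_id = character(), gene_id = character(),
                             ec = character())
      if (nrow(emitted) > 0 && tcfg$partial_ec_prob > 0) {
        inject <- stats::runif(nrow(emitted)) < tcfg$partial_ec_prob
        if (any(inject)) {
          part <- tibble::tibble(
            genome_id = g,
            gene_id = emitted$gene_id[inject],
            ec = ec_truncate(sample(universe, sum(inject), replace = TRUE))
          )
          part <- dplyr::distinct(part)
        }
      }
      prov_all[[paste(g, tool)]] <- dplyr::bind_rows(
        dplyr::mutate(tp, tool = tool, status = "tp"),
        dplyr::mutate(fp, tool = tool, status = "fp"),
        dplyr::mutate(part, tool = tool, status = "partial")
      )
    }
    gold_all[[g]] <- gold
  }
  prov <- dplyr::bind_rows(prov_all)
  prov <- prov[, c("genome_id", "gene_id", "tool", "ec", "status")]
  anno <- tibble::tibble(
    genome_id = prov$genome_id, gene_id = prov$gene_id, tool = prov$tool,
    feature_type = "EC", value = prov$ec,
    raw_function = NA_character_, identity_pct = NA_real_
  )
  anno <- dplyr::distinct(anno, .data$genome_id, .data$gene_id, .data$tool,
                          .data$feature_type, .data$value, .keep_all = TRUE)
  structure(
    list(gold = dplyr::bind_rows(gold_all), annotations = anno,
         provenance = prov, config = config),
    class = "ecc_sim"
  )
}

# detection probability: sensitivity on the logit scale shifted by the
# gene's shared difficulty; equals sensitivity exactly at difficulty 0 and
# is exact at the 0/1 endpoints
detection_prob <- function(sensitivity, difficulty) {
  if (sensitivity <= 0) return(rep(0, length(difficulty)))
  if (sensitivity >= 1) return(rep(1, length(difficulty)))
  stats::plogis(stats::qlogis(sensitivity) - difficulty)
}

#' Simulate multi-tool transporter annotations and a matched vocabulary
#'
#' Generates `n_synonym_classes` substrate synonym classes, each holding one
#' substrate per specificity rank 1..4, and assigns every simulated
#' transporter gene a true class. Each tool annotates a `coverage` fraction
#' of the transporter genes; each annotation draws a specificity rank from
#' the tool's `rank_dist`, then a substrate of that rank — from the gene's
#' true class with probability `agree_prob` (otherwise a random other class).
#' Rank 5 annotations carry no substrate.
#'
#' @param config A [simulation_config()] (its `transporters` component).
#' @param genome_ids Genomes to simulate.
#' @return A list: `annotations` (normalized TRANSPORT tibble), `vocabulary`
#'   (an `"ecc_vocab"` tibble), and `truth` (tibble `genome_id`, `gene_id`,
#'   `synonym_group_id`).
#' @export
simulate_transporters <- function(config, genome_ids = "G1") {
  validate_sim_config(config)
  tc <- config$transporters
  if (is.null(tc)) stop("config has no transporter component", call. = FALSE)
  n_cls <- tc$n_synonym_classes
  classes <- sprintf("class%03d", seq_len(n_cls))
  vocab <- substrate_vocabulary(
    substrate = paste0("substrate ", rep(classes, each = 4), " r",
                       rep(1:4, n_cls)),
    rank = rep(1:4, n_cls),
    synonym_group_id = rep(classes, each = 4)
  )
  sub_for <- function(cls, rank) paste0("substrate ", cls, " r", rank)
  rows <- list(); truth_all <- list()
  for (g in genome_ids) {
    set.seed(stream_seed(config$seed, paste0("transport-genes:", g)))
    genes <- sprintf("%s_t%05d", g, seq_len(tc$n_transporter_genes))
    true_cls <- sample(classes, length(genes), replace = TRUE)
    names(true_cls) <- genes
    truth_all[[g]] <- tibble::tibble(genome_id = g, gene_id = genes,
                                     synonym_group_id = true_cls)
    for (tool in names(tc$tools)) {
      ttool <- tc$tools[[tool]]
      set.seed(stream_seed(config$seed, paste("transport", tool, g, sep = ":")))
      n_cov <- round(ttool$coverage * length(genes))
      covered <- sort(sample(genes, n_cov))
      if (n_cov == 0) next
      rank <- sample(1:5, n_cov, replace = TRUE, prob = ttool$rank_dist)
      agree <- stats::runif(n_cov) < tc$agree_prob
      cls <- true_cls[covered]
      if (n_cls == 1) agree[] <- TRUE # a single class cannot disagree
      other <- sample(classes, n_cov, replace = TRUE)
      # resample classes colliding with the true class so "disagree" is real
      while (any(!agree & other == cls)) {
        idx <- !agree & other == cls
        other[idx] <- sample(classes, sum(idx), replace = TRUE)
      }
      use_cls <- ifelse(agree, cls, other)
      substrate <- ifelse(rank == 5, NA_character_, sub_for(use_cls, rank))
      rows[[paste(g, tool)]] <- tibble::tibble(
        genome_id = g, gene_id = covered, tool = tool,
        feature_type = "TRANSPORT", value = substrate,
        raw_function = substrate, identity_pct = NA_real_
      )
    }
  }
  anno <- dplyr::bind_rows(rows)
  list(annotations = anno, vocabulary = vocab,
       truth = dplyr::bind_rows(truth_all))
}

#' Write a simulated dataset to disk
#'
#' Writes the normalized annotation TSV, gold-standard TSV, provenance TSV,
#' and (when transporter output is supplied) the transporter TSV and
#' vocabulary TSV into a directory.
#'
#' @param sim Output of [simulate_annotations()].
#' @param dir Output directory (created if needed).
#' @param transporters Optional output of [simulate_transporters()].
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir, transporters = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    annotations = file.path(dir, "annotations.tsv"),
    gold = file.path(dir, "gold_standard.tsv"),
    provenance = file.path(dir, "provenance.tsv")
  )
  write_annotation_table(sim$annotations, paths[["annotations"]])
  write_gold_standard(sim$gold, paths[["gold"]])
  readr::write_tsv(sim$provenance, paths[["provenance"]], progress = FALSE)
  if (!is.null(transporters)) {
    paths <- c(paths,
               transporter_annotations = file.path(dir, "transporters.tsv"),
               vocabulary = file.path(dir, "vocabulary.tsv"))
    write_annotation_table(transporters$annotations,
                           paths[["transporter_annotations"]])
    readr::write_tsv(transporters$vocabulary, paths[["vocabulary"]],
                     progress = FALSE)
  }
  invisible(paths)
}
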