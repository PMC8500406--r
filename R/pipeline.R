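## End-to-end orchestration: simulate (or load) -> Ka/Ks -> screen ->
## distribution -> enrichment -> expression -> methylation, with every
## stage's TSV, a consolidated accounting summary and a parameter log.
## Stages communicate through TSV files so any stage can be rerun alone.

.pipelineDefaults <- function() {
  list(max_ks = 0.3, omega_threshold = 1.2, expressed_threshold = 1.0,
       promoter_length = 2000, kaks_method = "ng86",
       background_n = NULL, distribution_B = 2000, fisher_B = 2000,
       seed = 1)
}

#' Run the full PSG analysis pipeline
#'
#' Accepts a configuration list (or path to a YAML file) with either a
#' `simulation` block (passed to [simulationConfig()]) or an `inputs` block
#' of file paths (`cds_a`, `cds_b`, `pairing`, `gff3`, and optionally
#' `te_bed`, `expression`, `cytosine_report`, `retention`, `annotation`),
#' plus optional threshold overrides (`max_ks`, `omega_threshold`,
#' `expressed_threshold`, `promoter_length`, `kaks_method`, `fisher_B`,
#' `distribution_B`, `seed`). Writes per-stage TSVs, a `summary.tsv`
#' accounting chain and a `log.txt` of parameters and seeds to `outDir`.
#'
#' @param config List or YAML path.
#' @param outDir Report directory (created).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.pipelineDefaults(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  logLines <- c("PSGscreen pipeline log",
                paste0("package_version: ",
                       as.character(utils::packageVersion("PSGscreen"))),
                paste0("seed: ", cfg$seed),
                paste0("max_ks: ", cfg$max_ks),
                paste0("omega_threshold: ", cfg$omega_threshold),
                paste0("expressed_threshold: ", cfg$expressed_threshold),
                paste0("promoter_length: ", cfg$promoter_length),
                paste0("kaks_method: ", cfg$kaks_method))
  summaryRows <- list()
  note <- function(stage, key, value) {
    summaryRows[[length(summaryRows) + 1L]] <<- data.frame(
      stage = stage, key = key, value = value)
  }

  ## ---- stage: inputs -------------------------------------------------
  expression <- retention <- annotation <- NULL
  te <- GenomicRanges::GRanges()
  calls <- NULL
  if (!is.null(cfg$simulation)) {
    simArgs <- cfg$simulation
    simArgs$seed <- if (is.null(simArgs$seed)) cfg$seed else simArgs$seed
    study <- do.call(simulationConfig, simArgs)
    study <- simulateStudy(study)
    pairs <- study$pairs
    models <- study$genome$models
    te <- study$genome$te
    expression <- study$expression$matrix
    retention <- study$retention
    calls <- study$methylation$calls
    .writeTSV(study$estimatesTruth, p("ground_truth.tsv"))
  } else if (!is.null(cfg$inputs)) {
    ip <- cfg$inputs
    need <- c("cds_a", "cds_b", "pairing", "gff3")
    miss <- need[!vapply(need, function(k)
      !is.null(ip[[k]]) && file.exists(ip[[k]]), logical(1))]
    if (length(miss)) {
      stop("stage inputs: missing input file(s): ",
           paste(miss, collapse = ", "))
    }
    pairs <- readOrthologPairs(ip$cds_a, ip$cds_b, ip$pairing)
    models <- readGeneModels(ip$gff3)
    if (!is.null(ip$te_bed)) te <- readTEIntervals(ip$te_bed)
    if (!is.null(ip$expression)) {
      expression <- readExpressionMatrix(ip$expression)
    }
    if (!is.null(ip$cytosine_report)) {
      calls <- readCytosineReport(ip$cytosine_report)
    }
    if (!is.null(ip$retention)) retention <- readRetentionClasses(ip$retention)
    if (!is.null(ip$annotation)) annotation <- readAnnotationMap(ip$annotation)
  } else {
    stop("config needs a 'simulation' or an 'inputs' block")
  }
  note("input", "pairs_in", length(pairs))

  ## ---- stage: kaks ---------------------------------------------------
  est <- switch(tolower(cfg$kaks_method),
                ng86 = kaksNG86(pairs),
                yn00 = kaksYN00(pairs),
                both = rbind(kaksNG86(pairs), kaksYN00(pairs)),
                stop("unknown kaks_method: ", cfg$kaks_method))
  est$gene_a <- geneIdsA(pairs)[match(est$pair_id, pairIds(pairs))]
  .writeTSV(est, p("kaks.tsv"),
            params = list(method = cfg$kaks_method))
  estScreen <- est[est$method == est$method[1], , drop = FALSE]

  ## ---- stage: screen -------------------------------------------------
  retained <- suppressMessages(applyKsFilter(estScreen, cfg$max_ks))
  screen <- classifyPSG(retained, cfg$omega_threshold)
  .writeTSV(screen, p("screen_results.tsv"),
            params = list(max_ks = cfg$max_ks,
                          omega_threshold = cfg$omega_threshold,
                          counts_are = "pairs"))
  note("screen", "ks_removed", attr(retained, "n_removed"))
  note("screen", "ks_undefined", attr(retained, "n_undefined"))
  note("screen", "retained", nrow(retained))
  note("screen", "psg", sum(screen$is_psg))
  psg <- screen$gene_id[screen$is_psg]

  ## ---- stage: distribution -------------------------------------------
  map <- .geneChromMap(models)
  map <- map[map$gene_id %in% screen$gene_id, , drop = FALSE]
  if (length(psg) >= 1 && nrow(map) && all(psg %in% map$gene_id)) {
    cc <- chromosomeCounts(psg, map)
    .writeTSV(cc$distribution, p("chrom_distribution.tsv"))
    tests <- list()
    okMargins <- all(rowSums(cc$table) > 0) && all(colSums(cc$table) > 0)
    if (okMargins) {
      cs <- contingencyChisq(cc$table)
      fi <- contingencyFisher(cc$table, B = cfg$fisher_B,
                              seed = cfg$seed, method = "mc")
      tests <- c(tests, list(
        data.frame(test = "chisq", statistic = cs$statistic, df = cs$df,
                   p = cs$p, B = NA, seed = NA),
        data.frame(test = "fisher_mc", statistic = NA, df = NA, p = fi$p,
                   B = fi$B, seed = fi$seed)))
    }
    pt <- permutationDistributionTest(psg, map, B = cfg$distribution_B,
                                      seed = cfg$seed)
    tests <- c(tests, list(
      data.frame(test = "permutation", statistic = pt$observed_statistic,
                 df = NA, p = pt$empirical_p, B = pt$B, seed = pt$seed)))
    .writeTSV(do.call(rbind, tests), p("distribution_tests.tsv"))
    note("distribution", "psg_placed", length(psg))
  }

  ## ---- stage: enrichment ---------------------------------------------
  if (!is.null(annotation)) {
    enr <- hypergeometricEnrichment(psg, screen$gene_id, annotation)
    .writeTSV(enr, p("enrichment.tsv"),
              params = list(adjustment = "BH",
                            background = "Ks-filtered pairs"))
    note("enrichment", "terms_tested", nrow(enr))
  }

  ## ---- stage: expression ---------------------------------------------
  if (!is.null(expression)) {
    cls <- classifyTissuePattern(expression, cfg$expressed_threshold)
    .writeTSV(cls, p("expression_classes.tsv"),
              params = list(expressed_threshold = cfg$expressed_threshold))
    for (nm in c("specific", "constitutive", "intermediate", "silent")) {
      note("expression", nm, sum(cls$class == nm))
    }
    bgN <- if (is.null(cfg$background_n)) {
      min(length(psg), sum(screen$psg_status == "non-PSG"))
    } else {
      cfg$background_n
    }
    groupTests <- list()
    if (length(psg) >= 2 && bgN >= 2) {
      bg <- sampleBackground(screen, bgN, seed = cfg$seed)
      a <- rowMeans(expression[intersect(psg, rownames(expression)), ,
                               drop = FALSE])
      b <- rowMeans(expression[intersect(bg, rownames(expression)), ,
                               drop = FALSE])
      mw <- compareExpressionGroups(a, b, test = "mann_whitney")
      groupTests[[1]] <- data.frame(comparison = "PSG_vs_background",
                                    test = mw$test, statistic = mw$statistic,
                                    p = mw$p)
      .writeTSV(do.call(rbind, groupTests), p("group_tests.tsv"))
    }
    if (!is.null(retention)) {
      wgt <- wgtRetentionAnalysis(screen, retention, expression)
      .writeTSV(wgt$summary, p("wgt_summary.tsv"),
                params = list(fisher_p = wgt$fisher_p, kw_p = wgt$kw_p))
    }
  }

  ## ---- stage: methylation --------------------------------------------
  if (!is.null(calls)) {
    regions <- suppressWarnings(
      partitionGeneRegions(models, cfg$promoter_length))
    prof <- profileGenes(calls, regions)
    .writeTSV(prof, p("region_methylation.tsv"),
              params = list(promoter_length = cfg$promoter_length,
                            level = "read-weighted"))
    if (length(te)) {
      strat <- teOverlapStratification(prof, regions, te)
      .writeTSV(strat, p("te_stratification.tsv"))
    }
    if (!is.null(expression)) {
      mec <- tryCatch(
        methylationExpressionCorrelation(prof, expression, context = "CG"),
        error = function(e) NULL)
      if (!is.null(mec)) {
        .writeTSV(data.frame(context = "CG", scope = "gene",
                             spearman_rho = mec$rho, p = mec$p, n = mec$n),
                  p("meth_expr_correlation.tsv"))
      }
    }
  }

  summary <- do.call(rbind, summaryRows)
  .writeTSV(summary, p("summary.tsv"))
  writeLines(logLines, p("log.txt"))
  invisible(list(screen = screen, summary = summary, outDir = outDir))
}
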