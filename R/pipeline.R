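.configDefaults <- function() list(
  seed = 1,
  architecture = list(h2_liab_1 = 0.082, h2_liab_2 = 0.23, r_g = 0.143,
                      K_1 = 1 / 400, K_2 = 1 / 100, prop_causal = 0.1),
  cohort = list(n_cases_1 = 300, n_controls_1 = 300, n_cases_2 = 300,
                n_controls_2 = 300, n_shared_controls = 0, n_strata = 1,
                stratum_fst = 0),
  panel = list(n_haplotypes = 200, n_variants = 1000, block_size_mean = 25),
  ldsc = list(window_cm = 1, n_blocks = 50, constrain_intercept_1 = TRUE,
              constrain_components = TRUE),
  prs = list(n_perms = 20),
  cfdr = list(threshold = 0.05, r2_cut = 0.1),
  buhmbox = list(p_cut = 0.01, r2_max = 0.05),
  output_dir = "crosstrait-output")

#' Read and validate a pipeline configuration
#'
#' YAML configuration with blocks `architecture`, `cohort`, `panel`,
#' `ldsc`, `prs`, `cfdr`, `buhmbox` plus `seed` and `output_dir`.  Unknown
#' keys are rejected; omitted keys take their defaults.  The configuration
#' round-trips losslessly through [yaml::as.yaml()].
#'
#' @param path YAML file path, or NULL for the defaults.
#' @param overrides optional named list merged over the file contents.
#' @return a validated config list of class `PipelineConfig`.
#' @export
readPipelineConfig <- function(path = NULL, overrides = NULL) {
  defs <- .configDefaults()
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  bad <- setdiff(names(cfg), names(defs))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in names(defs)) {
    if (is.list(defs[[blk]]) && !is.null(cfg[[blk]])) {
      badk <- setdiff(names(cfg[[blk]]), names(defs[[blk]]))
      if (length(badk))
        stop("unknown key(s) in block '", blk, "': ",
             paste(badk, collapse = ", "))
    }
  }
  cfg <- utils::modifyList(defs, cfg)
  structure(cfg, class = "PipelineConfig")
}

#' Run the full cross-trait pipeline on synthetic data
#'
#' Executes the stages in dependency order: reference panel, effect sizes,
#' shared-control cohorts, summary statistics, LD scores, univariate and
#' bivariate LD score regression, polygenic risk scoring, conditional FDR,
#' the comorbidity model and the heterogeneity test, writing every artifact
#' plus a consolidated JSON report to the output directory.  A stage
#' failure halts with the stage name; artifacts written so far persist.
#'
#' @param config a `PipelineConfig` from [readPipelineConfig()].
#' @param writeFiles write artifacts and the report to
#'   `config$output_dir` (default TRUE).
#' @return the report, an invisible named list.
#' @export
runPipeline <- function(config = readPipelineConfig(), writeFiles = TRUE) {
  stage <- "setup"
  report <- list(config = unclass(config))
  outDir <- config$output_dir
  if (writeFiles) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, writer) if (writeFiles) writer(file.path(outDir, name))
  tryCatch({
    stage <- "simulate"
    arch <- GeneticArchitecture(
      h2Liab1 = config$architecture$h2_liab_1,
      h2Liab2 = config$architecture$h2_liab_2,
      rg = config$architecture$r_g, K1 = config$architecture$K_1,
      K2 = config$architecture$K_2,
      propCausal = config$architecture$prop_causal)
    design <- CohortDesign(
      nCases1 = config$cohort$n_cases_1,
      nControls1 = config$cohort$n_controls_1,
      nCases2 = config$cohort$n_cases_2,
      nControls2 = config$cohort$n_controls_2,
      nSharedControls = config$cohort$n_shared_controls,
      nStrata = config$cohort$n_strata,
      stratumFst = config$cohort$stratum_fst)
    panel <- simulateReferencePanel(config$panel$n_haplotypes,
                                    config$panel$n_variants,
                                    config$panel$block_size_mean,
                                    seed = config$seed)
    emit("panel.bim", function(p) writeBim(panel@variants, p))
    eff <- drawEffectSizes(arch, panel@variants, seed = config$seed + 1)
    cohorts <- simulateSharedCohorts(panel, eff, arch, design,
                                     seed = config$seed + 2)
    emit("cohort1.raw", function(p) writeRaw(cohorts$cohort1, p))
    emit("cohort2.raw", function(p) writeRaw(cohorts$cohort2, p))

    stage <- "sumstats"
    st1 <- computeSummaryStats(cohorts$cohort1)
    st2 <- computeSummaryStats(cohorts$cohort2)
    emit("stats1.tsv", function(p) writeSummaryStats(st1, p,
                                                     seed = config$seed))
    emit("stats2.tsv", function(p) writeSummaryStats(st2, p,
                                                     seed = config$seed))

    stage <- "ldscore"
    scores <- computeLDScores(panel, windowCm = config$ldsc$window_cm)
    emit("ldscores.tsv", function(p) writeLdScores(scores, p))

    stage <- "h2"
    P1 <- mean(phenotype(cohorts$cohort1))
    fit1 <- univariateLdsc(
      st1, scores, constrainedIntercept = config$ldsc$constrain_intercept_1,
      nBlocks = config$ldsc$n_blocks, K = arch@K1, P = P1)
    report$h2 <- jsonlite::fromJSON(fitToJson(fit1))

    stage <- "rg"
    biv <- bivariateLdsc(st1, st2, scores, nBlocks = config$ldsc$n_blocks,
                         constrained1 = config$ldsc$constrain_components,
                         constrained2 = config$ldsc$constrain_components)
    report$rg <- jsonlite::fromJSON(fitToJson(biv))

    stage <- "prs"
    prs <- prsAnalysis(st2, cohorts$cohort1, panel)
    report$prs <- list(per_threshold = prs$perThreshold,
                       best_threshold = prs$bestThreshold)
    if (config$prs$n_perms > 0) {
      pn <- permutationPrs(phenotype(cohorts$cohort1), prs$scores,
                           nPerms = config$prs$n_perms,
                           seed = config$seed + 3)
      report$prs$permutation_mean_delta <- pn$mean
    }

    stage <- "cfdr"
    fit2free <- univariateLdsc(st2, scores, nBlocks = config$ldsc$n_blocks)
    st2r <- residualizeOnLdscore(st2, scores, fit2free)
    al <- .alignStats(st1, st2r)
    nullCorr <- min(abs(biv@crossIntercept), 0.9) * sign(biv@crossIntercept)
    zAdj <- sharedControlAdjust(st1@z[al$i1], st2r@z[al$i2], nullCorr)
    cf <- conditionalFdr(st1@p[al$i1], 2 * pnorm(-abs(zAdj)))
    loci <- clumpLoci(cf, subsetVariants(st1@variants, al$i1), panel,
                      r2Cut = config$cfdr$r2_cut,
                      threshold = config$cfdr$threshold)
    report$cfdr <- list(n_loci = nrow(loci),
                        leads = loci$lead, min_cfdr = loci$minCfdr)

    stage <- "comorbidity"
    com <- comorbidityAnalysis(arch@rg, arch@h2Liab1, arch@h2Liab2,
                               arch@K1, arch@K2,
                               nCases1 = design@nCases1,
                               nCases2 = design@nCases2)
    report$comorbidity <- list(
      rho_liab = com@rhoLiab, p_joint = com@pJoint,
      recip_joint = com@recipJoint, or_comorbid = com@orComorbid,
      n_required = com@nRequired,
      misdiagnosis_rate = com@misdiagnosisRate)

    stage <- "buhmbox"
    rs <- try(selectRiskAlleles(st1, cohorts$cohort1, panel,
                                pCut = config$buhmbox$p_cut,
                                r2Max = config$buhmbox$r2_max),
              silent = TRUE)
    if (!inherits(rs, "try-error")) {
      G2 <- genotypes(cohorts$cohort2)
      colnames(G2) <- variants(cohorts$cohort2)@id
      y2 <- phenotype(cohorts$cohort2)
      bb <- buhmboxStatistic(G2[y2 == 1L, , drop = FALSE],
                             G2[y2 == 0L, , drop = FALSE], rs)
      report$buhmbox <- list(S = bb$S, p = bb$p, n_variants = bb$nVariants)
    } else {
      report$buhmbox <- list(note = "too few associated risk alleles")
    }

    stage <- "report"
    if (writeFiles) {
      jsonlite::write_json(report, file.path(outDir, "report.json"),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
      txt <- c(
        sprintf("crosstrait pipeline report (seed %d)", config$seed),
        sprintf("h2 (liability): %.4f (SE %.4f)", report$h2$h2_liab,
                report$h2$se_h2),
        sprintf("rg: %.4f (SE %.4f, p %.3g)", report$rg$r_g,
                report$rg$se_rg, report$rg$p_rg),
        sprintf("best PRS threshold: %g", report$prs$best_threshold),
        sprintf("cFDR loci: %d", report$cfdr$n_loci),
        sprintf("comorbidity OR: %.3f; 1/P(both): %.0f",
                report$comorbidity$or_comorbid,
                report$comorbidity$recip_joint))
      writeLines(txt, file.path(outDir, "report.txt"))
    }
    invisible(report)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
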