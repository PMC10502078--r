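#' Default pipeline configuration
#'
#' All analysis thresholds appear here as named defaults: the whole-GRS
#' interaction threshold (`alpha_grs` = 0.15), the per-SNP threshold
#' (`alpha_snp` = 0.2), the borderline band upper end triggering the
#' dichotomized follow-up (`borderline` = 0.25), the two covariate sets
#' (screening: sex, LTPA, sleep, PC1, PC2; validation model 2: sex, LTPA,
#' sleep), the rating-to-weekly mapping and the summary-index compositions.
#' When `genotypes`/`cohort` paths are NULL, a synthetic study of
#' `n` individuals with effects `truth` is generated from `seed`.
#'
#' @param ... named overrides of any default field.
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(...) {
  cfg <- list(
    panel = NULL, # path; NULL = packaged default panel
    genotypes = NULL, # path (VCF or dosage TSV); NULL = simulate
    cohort = NULL, # path (CSV); NULL = simulate
    lms_reference = NULL, # path; NULL = synthetic reference
    n = 1142L,
    seed = 1L,
    noise_sd = 1,
    genotype_missing_rate = 0.001,
    ffq_missing_rate = 0.01,
    truth = NULL, # an effectSpec(); NULL = null model
    schemes = c("unweighted", "speliotes", "finhit", "ratio"),
    alpha_grs = 0.15,
    alpha_snp = 0.2,
    borderline = 0.25,
    screening_covariates = c("sex", "ltpa", "sleep", "pc1", "pc2"),
    validation_models = list(
      model1 = "sex",
      model2 = c("sex", "ltpa", "sleep")
    ),
    mapping = defaultFfqMapping(),
    foods = ffqItems(),
    outcome = "bmiz"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  if (cfg$alpha_grs <= 0 || cfg$alpha_grs >= 1) {
    stop("alpha_grs must be in (0, 1)", call. = FALSE)
  }
  if (cfg$alpha_snp < 0 || cfg$alpha_snp >= 1) {
    stop("alpha_snp must be in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "RunConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file path; fields override [runConfig()] defaults.
#' @return A `"RunConfig"` list.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$mapping)) raw$mapping <- setNames(unlist(raw$mapping), as.character(1:7))
  do.call(runConfig, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(
      structure(
        class = c("pipelineError", "error", "condition"),
        list(
          message = sprintf("[stage:%s] %s", name, conditionMessage(e)),
          call = NULL, stage = name
        )
      )
    )
  })
}

#' Run the full gene-diet interaction pipeline
#'
#' Sequences the analysis end-to-end: scoring under all schemes, cohort
#' group comparisons, the whole-GRS screen, the per-SNP screen per flagged
#' food, food-specific GRS construction, two-model validation, stratified
#' effects and the shared-SNP set analysis. Every artifact is written to
#' `outDir` together with the resolved configuration and a structured log
#' recording the sample size used in every model. Identical config + seed
#' reproduce every output byte-identically.
#'
#' @param config a `"RunConfig"` (see [runConfig()] / [readRunConfig()]).
#' @param outDir output directory, created if needed.
#' @return Invisibly, a list of the in-memory results.
#' @export
runPipeline <- function(config = runConfig(), outDir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  panel <- .stage("panel", {
    if (is.null(config$panel)) defaultPanel() else loadPanel(config$panel)
  })
  note("INFO panel: %d SNPs", length(panel))

  simulated <- is.null(config$genotypes) || is.null(config$cohort)
  inputs <- .stage("inputs", {
    if (simulated) {
      truth <- config$truth
      if (is.null(truth)) {
        truth <- effectSpec(noiseSd = config$noise_sd, seed = config$seed)
      }
      study <- simulateStudy(
        n = config$n, panel = panel, spec = truth,
        missingRate = config$genotype_missing_rate,
        ffqMissingRate = config$ffq_missing_rate
      )
      writeDosageTsv(study$genotypes, file.path(outDir, "genotypes.tsv"))
      writeCohortCsv(study$cohort, file.path(outDir, "cohort.csv"))
      writeEffectSpecJson(study$truth, file.path(outDir, "truth.json"))
      study
    } else {
      cohort <- readCohort(config$cohort)
      if (!any(grepl("^weekly_", names(cohort)))) {
        cohort <- addWeeklyFfq(cohort, config$mapping)
      }
      list(
        genotypes = readGenotypes(config$genotypes, panel),
        cohort = cohort, truth = NULL
      )
    }
  })
  cohort <- inputs$cohort
  genotypes <- inputs$genotypes
  note("INFO cohort: %d individuals", nrow(cohort))

  score_tabs <- .stage("scores", {
    lapply(config$schemes, function(s) {
      sv <- grsScore(genotypes, panel, s)
      data.frame(
        id = individualIds(sv), scheme = s, score = unname(scores(sv)),
        n_nonmissing = unname(nNonmissing(sv)), stringsAsFactors = FALSE
      )
    })
  })
  write.csv(do.call(rbind, score_tabs), file.path(outDir, "scores.csv"),
    row.names = FALSE
  )

  comparisons <- .stage("group_comparisons", {
    unw <- grsScore(genotypes, panel, "unweighted")
    grp <- dichotomize(unw)$group[cohort$id]
    keep <- !is.na(grp)
    cont <- intersect(
      c("age", "ltpa", "sleep", config$outcome, paste0("weekly_", config$foods)),
      names(cohort)
    )
    compareGroups(cohort[keep, , drop = FALSE], grp[keep],
      continuous = cont, categorical = intersect("sex", names(cohort))
    )
  })
  write.csv(comparisons, file.path(outDir, "group_comparisons.csv"),
    row.names = FALSE
  )

  screen <- .stage("whole_grs_screen", {
    screenWholeGrs(cohort, genotypes, panel,
      foods = config$foods, schemes = config$schemes,
      alpha = config$alpha_grs, borderline = config$borderline,
      covariates = config$screening_covariates, outcome = config$outcome
    )
  })
  write.csv(screen$report, file.path(outDir, "screen_report.csv"),
    row.names = FALSE
  )
  note(
    "INFO whole-GRS screen: %d food(s) flagged: %s",
    length(screen$flagged), paste(screen$flagged, collapse = ", ")
  )

  fgrs_list <- list()
  snp_screens <- list()
  for (food in screen$flagged) {
    refdir <- screen$referenceDirections[[food]]
    sel <- .stage(paste0("snp_screen:", food), {
      suppressWarnings(screenSnps(cohort, genotypes, panel, food,
        referenceDirection = refdir, alpha = config$alpha_snp,
        covariates = config$screening_covariates, outcome = config$outcome
      ))
    })
    snp_screens[[food]] <- data.frame(food = food, sel$results,
      selected = sel$results$rsid %in% sel$selected
    )
    note(
      "INFO SNP screen %s: %d of %d SNPs selected", food,
      length(sel$selected), length(panel)
    )
    if (length(sel$selected)) {
      fgrs_list[[food]] <- buildFoodGrs(panel, sel$selected, food, refdir)
    }
  }
  if (length(snp_screens)) {
    write.csv(do.call(rbind, snp_screens), file.path(outDir, "snp_screen.csv"),
      row.names = FALSE
    )
  }

  validations <- list()
  stratified <- list()
  if (length(fgrs_list) == 0) {
    note("INFO no food-specific GRS could be built; pipeline ends after screening")
  } else {
    jsonlite::write_json(
      lapply(fgrs_list, function(f) {
        list(
          food = foodItem(f), rsids = rsids(f),
          reference_direction = referenceDirection(f)
        )
      }),
      file.path(outDir, "food_grs.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    val_rows <- list()
    strat_rows <- list()
    for (food in names(fgrs_list)) {
      v <- .stage(paste0("validate:", food), {
        validateFoodGrs(cohort, genotypes, panel, fgrs_list[[food]],
          models = config$validation_models, outcome = config$outcome
        )
      })
      validations[[food]] <- v
      for (mod in names(v)) {
        val_rows[[length(val_rows) + 1L]] <- cbind(
          food = food, model = mod, v[[mod]]
        )
        note(
          "INFO validation %s %s: n = %d", food, mod,
          v[[mod]]$n_used[1]
        )
      }
      s <- .stage(paste0("stratified:", food), {
        stratifiedEffects(cohort, genotypes, panel, fgrs_list[[food]],
          outcome = config$outcome
        )
      })
      stratified[[food]] <- s
      strat_rows[[length(strat_rows) + 1L]] <- cbind(
        food = food, s$by_group,
        interaction_b = s$interaction$b, interaction_p = s$interaction$p
      )
      note(
        "INFO stratified %s: n_low = %d, n_high = %d", food,
        s$by_group$n[1], s$by_group$n[2]
      )
    }
    write.csv(do.call(rbind, val_rows), file.path(outDir, "validation.csv"),
      row.names = FALSE
    )
    write.csv(do.call(rbind, strat_rows), file.path(outDir, "stratified.csv"),
      row.names = FALSE
    )
    shared <- .stage("shared_snps", sharedSnpAnalysis(fgrs_list))
    jsonlite::write_json(
      list(
        union = shared$union,
        union_size = length(shared$union),
        intersection = shared$intersection,
        intersection_size = length(shared$intersection),
        regions = shared$regions
      ),
      file.path(outDir, "shared_snps.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  # resolved config (drop non-serializable truth object gracefully)
  cfg_out <- unclass(config)
  cfg_out$truth <- if (is.null(config$truth)) NULL else unclass(config$truth)
  yaml::write_yaml(cfg_out, file.path(outDir, "resolved_config.yaml"))
  writeLines(log_lines, file.path(outDir, "log.txt"))

  invisible(list(
    panel = panel, genotypes = genotypes, cohort = cohort,
    scores = score_tabs, comparisons = comparisons, screen = screen,
    food_grs = fgrs_list, validations = validations, stratified = stratified,
    shared = if (length(fgrs_list)) sharedSnpAnalysis(fgrs_list) else NULL,
    log = log_lines
  ))
}
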