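#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [runPipeline()], with
#' every stage control at its default. Override entries by passing a named
#' list to \code{runPipeline(config = modifyList(pipelineConfig(), list(...)))}
#' or by editing the returned list.
#'
#' @param outDir output directory for artifacts.
#' @param seed master seed; every stage derives its own seed from it.
#' @return named list of configuration entries.
#' @export
pipelineConfig <- function(outDir = "turbfmri_out", seed = 1L) {
  list(
    outDir = outDir, seed = as.integer(seed),
    # cohort: either a directory with cohort_manifest.json, or synthesis
    cohortDir = NULL,
    nRegions = 60L, groupSizes = c(20L, 20L, 20L),
    groupG = c(1.3, 1.5, 0.9), nVolumes = 300L, tr = 2,
    outcomeCorrelation = 0.4, nLongrange = 40L,
    # measures
    band = c(0.008, 0.08), nTrim = 10L, scales = defaultScales(),
    fitRange = c(10, 75), binWidth = 2,
    # stats
    nPerm = 1000L, fdrQ = 0.05,
    # classifier
    nReps = 100L, trainFrac = 0.9, balanceTo = 32L, nNull = 200L,
    classifierMode = "split",
    # model fit + perturbation (heavier; off by default)
    doFit = FALSE, gGrid = seq(6L, 18L) / 10, nRepsPerG = 3L,
    doPerturb = FALSE, deltaAMax = 0.1, nTrials = 30L,
    perturbDuration = 240)
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::serializeJSON(config), f)
  unname(tools::md5sum(f))
}

.load_cohort_dir <- function(dir, tr) {
  mpath <- file.path(dir, "cohort_manifest.json")
  if (!file.exists(mpath)) stop("cohort manifest not found: ", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  lapply(seq_len(nrow(man$subjects)), function(i) {
    s <- man$subjects[i, ]
    new("SubjectRecord", subjectId = s$subject_id, group = s$group,
      bold = readTimeseries(file.path(dir, s$bold_file), tr = man$spec$tr),
      hamd6Baseline = if (is.null(s$hamd6_baseline) || is.na(s$hamd6_baseline))
        NA_real_ else s$hamd6_baseline,
      hamd6PctChange = if (is.null(s$hamd6_pct_change) || is.na(s$hamd6_pct_change))
        NA_real_ else s$hamd6_pct_change)
  })
}

#' Run the staged whole-brain turbulence analysis end to end
#'
#' Executes, in order: cohort synthesis (or loading), per-subject
#' turbulence measures, group statistics with FDR and outcome
#' correlations, treatment-response classification, and optionally the
#' whole-brain model fit and in-silico perturbation. Every artifact is
#' written under \code{config$outDir} and stamped in a MANIFEST with the
#' configuration hash, package version, seeds, stage timings and warnings.
#' A stage failure leaves partial artifacts on disk, writes the MANIFEST
#' with \code{complete = FALSE}, and signals an error naming the stage.
#'
#' @param config configuration list; see [pipelineConfig()].
#' @return invisibly, a list with the in-memory stage results and the
#'   artifact paths.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  cfg <- utils::modifyList(pipelineConfig(), config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("turbfmri")),
    config = cfg, config_hash = .config_hash(cfg), seed = cfg$seed,
    stages = list(), complete = FALSE)
  results <- list()
  warnings_log <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$stages[[name]] <<- list(status = "failed",
          error = conditionMessage(e))
        jsonlite::write_json(manifest, file.path(cfg$outDir, "MANIFEST.json"),
          auto_unbox = TRUE, digits = NA, na = "null", force = TRUE)
        stop("runPipeline [stage: ", name, "]: ", conditionMessage(e),
          call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
          paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(status = "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    val
  }

  # cohort ---------------------------------------------------------------
  geom <- stage("geometry", {
    g <- generateGeometry(cfg$nRegions, seed = .derive_seed(cfg$seed, 1L))
    writeMatrix(coords(g), file.path(cfg$outDir, "geometry_coords.tsv"))
    g
  })
  cohort <- stage("cohort", {
    if (!is.null(cfg$cohortDir)) .load_cohort_dir(cfg$cohortDir, cfg$tr)
    else {
      conn <- generateConnectome(geom, nLongrange = cfg$nLongrange,
        seed = .derive_seed(cfg$seed, 2L))
      spec <- CohortSpec(cfg$nRegions, groupSizes = cfg$groupSizes,
        groupG = cfg$groupG, nVolumes = cfg$nVolumes, tr = cfg$tr,
        outcomeCorrelation = cfg$outcomeCorrelation,
        seed = .derive_seed(cfg$seed, 3L))
      ch <- generateCohort(spec, geom, connectome = conn)
      writeCohort(ch, spec, file.path(cfg$outDir, "cohort"))
      ch
    }
  })

  # measures -------------------------------------------------------------
  profiles <- stage("measures", {
    pr <- lapply(cohort, function(s) computeProfile(s@bold, geom,
      scales = cfg$scales, lowHz = cfg$band[1L], highHz = cfg$band[2L],
      nTrim = cfg$nTrim, fitRange = cfg$fitRange, binWidth = cfg$binWidth))
    names(pr) <- vapply(cohort, function(s) s@subjectId, "")
    summary <- do.call(rbind, lapply(names(pr), function(id) {
      data.frame(subject_id = id,
        group = cohort[[match(id, names(pr))]]@group,
        t(turbulence(pr[[id]])[c("0.01", "0.03", "0.06")]),
        information_cascade = informationCascade(pr[[id]]),
        check.names = FALSE)
    }))
    utils::write.table(summary, file.path(cfg$outDir, "measures_summary.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    pr
  })

  groups <- vapply(cohort, subjectGroup, "")
  scalar_of <- function(fn) vapply(profiles, fn, 0)

  # stats ----------------------------------------------------------------
  stats_res <- stage("stats", {
    measures <- list(
      `turbulence_0.01` = scalar_of(function(p) turbulence(p)[["0.01"]]),
      `turbulence_0.03` = scalar_of(function(p) turbulence(p)[["0.03"]]),
      `turbulence_0.06` = scalar_of(function(p) turbulence(p)[["0.06"]]),
      `transfer_0.01` = scalar_of(function(p) informationTransfer(p)[["0.01"]]),
      `transfer_0.03` = scalar_of(function(p) informationTransfer(p)[["0.03"]]),
      `transfer_0.06` = scalar_of(function(p) informationTransfer(p)[["0.06"]]),
      information_cascade = scalar_of(informationCascade))
    pairs <- list(c("control", "responder"), c("control", "non_responder"),
      c("responder", "non_responder"))
    rows <- list()
    k <- 0L
    for (pr in pairs) for (mn in names(measures)) {
      k <- k + 1L
      v <- measures[[mn]]
      cmp <- groupComparison(v[groups == pr[1L]], v[groups == pr[2L]],
        nPerm = cfg$nPerm, seed = .derive_seed(cfg$seed, 100L + k))
      rows[[k]] <- data.frame(measure = mn, group_a = pr[1L],
        group_b = pr[2L], cohens_d = cmp$cohensD, p_perm = cmp$pPerm)
    }
    tab <- do.call(rbind, rows)
    tab$p_fdr <- ave(tab$p_perm, paste(tab$group_a, tab$group_b),
      FUN = function(p) fdrBH(p, cfg$fdrQ)$adjusted)
    pat <- groups != "control"
    pct <- vapply(cohort, function(s) s@hamd6PctChange, 0)
    cors <- lapply(measures, function(v)
      outcomeCorrelation(v[pat], pct[pat]))
    utils::write.table(tab, file.path(cfg$outDir, "group_comparisons.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(outcome_correlations = lapply(cors, function(x)
        list(rho = x$rho, p = x$p))),
      file.path(cfg$outDir, "outcome_correlations.json"),
      auto_unbox = TRUE, digits = NA)
    list(comparisons = tab, outcome = cors)
  })

  # classifier -----------------------------------------------------------
  clf <- stage("classifier", {
    pat_ids <- names(profiles)[groups != "control"]
    labels <- stats::setNames(groups[groups != "control"], pat_ids)
    ft <- assembleFeatures(profiles[pat_ids], labels)
    obs <- repeatedSplitEval(ft, nReps = cfg$nReps,
      trainFrac = cfg$trainFrac, balanceTo = cfg$balanceTo,
      seed = .derive_seed(cfg$seed, 200L), mode = cfg$classifierMode)
    sig <- permutationSignificance(ft, obs, nNull = cfg$nNull,
      seed = .derive_seed(cfg$seed, 201L), trainFrac = cfg$trainFrac,
      balanceTo = cfg$balanceTo, mode = cfg$classifierMode,
      nRepsNull = min(cfg$nReps, 10L))
    jsonlite::write_json(list(auc_mean = obs@aucMean, auc_sd = obs@aucSd,
      acc_mean = obs@accMean, acc_sd = obs@accSd, p_auc = sig$pAuc,
      p_acc = sig$pAcc, n_repetitions = obs@nRepetitions),
      file.path(cfg$outDir, "classifier_report.json"),
      auto_unbox = TRUE, digits = NA)
    sig$report
  })

  # optional model-based stages ------------------------------------------
  fits <- NULL
  perturb <- NULL
  if (isTRUE(cfg$doFit)) {
    fits <- stage("model_fit", {
      conn <- generateConnectome(geom, nLongrange = cfg$nLongrange,
        seed = .derive_seed(cfg$seed, 2L))
      coupling <- buildCoupling(geom, conn)
      omegas <- rowMeans(vapply(cohort, function(s)
        estimateFrequencies(s@bold), numeric(nRegions(geom))))
      template <- HopfParams(omegas, G = 1, duration = cfg$nVolumes * cfg$tr,
        seed = .derive_seed(cfg$seed, 300L))
      out <- lapply(unique(groups), function(g) {
        emp <- lapply(cohort[groups == g], function(s) s@bold)
        fitGlobalCoupling(emp, geom, coupling, template, cfg$gGrid,
          nReps = cfg$nRepsPerG)
      })
      names(out) <- unique(groups)
      jsonlite::write_json(lapply(out, function(f) list(g_grid = f@gGrid,
        error_curve = f@errorCurve, g_opt = f@gOpt)),
        file.path(cfg$outDir, "model_fit.json"), auto_unbox = TRUE,
        digits = NA, na = "null")
      out
    })
    if (isTRUE(cfg$doPerturb)) {
      perturb <- stage("perturbation", {
        conn <- generateConnectome(geom, nLongrange = cfg$nLongrange,
          seed = .derive_seed(cfg$seed, 2L))
        coupling <- buildCoupling(geom, conn)
        omegas <- rowMeans(vapply(cohort, function(s)
          estimateFrequencies(s@bold), numeric(nRegions(geom))))
        out <- lapply(names(fits), function(g) {
          params <- HopfParams(omegas, G = fits[[g]]@gOpt,
            duration = cfg$perturbDuration,
            seed = .derive_seed(cfg$seed, 400L))
          perturbAndMeasure(params, coupling, geom,
            deltaAMax = cfg$deltaAMax, nTrials = cfg$nTrials,
            seed = .derive_seed(cfg$seed, 401L))
        })
        names(out) <- names(fits)
        jsonlite::write_json(lapply(out, function(r) list(
          susceptibility = susceptibility(r),
          info_capability = infoCapability(r))),
          file.path(cfg$outDir, "perturbation.json"), auto_unbox = TRUE,
          digits = NA)
        out
      })
    }
  }

  manifest$complete <- TRUE
  manifest$warnings <- warnings_log
  jsonlite::write_json(manifest, file.path(cfg$outDir, "MANIFEST.json"),
    auto_unbox = TRUE, digits = NA, na = "null", force = TRUE)
  invisible(list(geometry = geom, cohort = cohort, profiles = profiles,
    stats = stats_res, classifier = clf, fits = fits, perturbation = perturb,
    outDir = cfg$outDir))
}
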