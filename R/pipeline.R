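# End-to-end orchestration: stream -> JID -> periodograms -> bootstrap ->
# clusters -> NNMF -> population clustering -> coherence.

#' Assemble a pipeline run configuration
#'
#' Two duration profiles mirror the analysis design: \code{"short"}
#' (subjects with >= 90 days; NNMF period slice 2.2-27.7 days) and
#' \code{"long"} (>= 180 days; slice 2.2-70.5 days). Two scales trade
#' resolution for compute: \code{"full"} (50x50 JID grid, 40
#' voices/octave over 2 h - 80 d, ~1000 bootstraps and restarts) and
#' \code{"desk"} (20x20 grid, 8 voices/octave over 1 - 36/72 d multiday
#' grid, 100 bootstraps/restarts), suitable for a single workstation.
#'
#' @param profile \code{"short"} or \code{"long"}.
#' @param scale \code{"desk"} or \code{"full"}.
#' @param seed master seed; every stage seed derives from it.
#' @param ... named overrides of any config entry.
#' @return a list of stage parameters (class \code{"multidienConfig"}).
#' @export
runConfig <- function(profile = c("short", "long"),
                      scale = c("desk", "full"),
                      seed = 1L, ...) {
  profile <- match.arg(profile)
  scale <- match.arg(scale)
  cfg <- list(
    profile = profile,
    scale = scale,
    seed = as.integer(seed),
    minDays = if (profile == "short") 90 else 180,
    sliceDays = if (profile == "short") c(2.2, 27.7) else c(2.2, 70.5),
    bandwidth = 0.1,
    blockHours = 24,
    alpha = 0.05,
    minClusterSize = 5,
    fwProb = 0.975,
    ranks = 3:15,
    maxK = 12
  )
  if (scale == "full") {
    cfg$grid <- jidGrid(nSteps = 50L)
    cfg$pgrid <- periodGrid(voicesPerOctave = 40, periodMin = 2,
                            periodMax = 80 * 24)
    cfg$nBoot <- 1000
    cfg$restarts <- 1000
    cfg$cvReps <- 100
  } else {
    cfg$grid <- jidGrid(nSteps = 20L)
    maxDays <- if (profile == "short") 36 else 72
    cfg$pgrid <- periodGrid(voicesPerOctave = 8, periodMin = 24,
                            periodMax = maxDays * 24)
    cfg$nBoot <- 100
    cfg$restarts <- 100
    cfg$cvReps <- 5
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "multidienConfig"
  cfg
}

# deterministic per-stage child seeds below 2^31
.childSeed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 7919) %% 2147483629 + 1
}

#' Run the per-subject pipeline
#'
#' JID construction, raw periodograms, bootstrap ensemble, aperiodic
#' adjustment, cluster correction, period slicing, optional rank selection
#' and stability-selected NNMF. Subjects below the profile's minimum
#' duration are skipped with a report entry rather than an error.
#'
#' @param stream a [TouchEventStream-class].
#' @param config from [runConfig()].
#' @param rank optional fixed NNMF rank (skips cross-validation).
#' @param keepEnsemble keep the full bootstrap ensemble in the output.
#' @return list of artifacts (jid, raw, ensembleMean, adjusted, clusters,
#'   rhythmMatrix, metaRhythms, seeds, skipped/reason).
#' @export
runSubject <- function(stream, config, rank = NULL, keepEnsemble = FALSE) {
  ev <- events(stream)
  days <- if (nrow(ev)) diff(range(ev$timestampMs)) / 86400e3 else 0
  if (days < config$minDays) {
    return(list(skipped = TRUE, subjectId = subjectId(stream),
                reason = sprintf("recording %.1f days < profile minimum %d",
                                 days, config$minDays)))
  }
  sseed <- .childSeed(config$seed, sum(utf8ToInt(subjectId(stream))))
  jid <- buildJID(stream, config$grid, config$bandwidth)
  raw <- jidPeriodograms(jid, config$pgrid)
  ens <- bootstrapPeriodograms(jid, config$pgrid, nBoot = config$nBoot,
                               blockHours = config$blockHours, seed = sseed)
  adjusted <- aperiodicAdjust(raw, ens)
  clusters <- clusterCorrect(raw, ens, alpha = config$alpha,
                             minSize = config$minClusterSize,
                             fwProb = config$fwProb)
  rm <- sliceReshape(adjusted, config$sliceDays[1], config$sliceDays[2])
  cv <- NULL
  if (is.null(rank)) {
    cv <- selectRank(rm, ranks = config$ranks, reps = config$cvReps,
                     seed = .childSeed(sseed, 1))
    rank <- cv$rank
  }
  mrs <- starNNMF(rm, rank, restarts = config$restarts,
                  seed = .childSeed(sseed, 2),
                  cvCurve = if (is.null(cv)) NULL else cv$cvCurve)
  out <- list(skipped = FALSE, subjectId = subjectId(stream),
              jid = jid, raw = raw,
              ensembleMean = ensembleMean(ens),
              adjusted = adjusted, clusters = clusters,
              rhythmMatrix = rm, metaRhythms = mrs,
              seeds = c(subject = sseed))
  if (keepEnsemble) out$ensemble <- ens
  out
}

#' Run the cohort-level pipeline
#'
#' Runs [runSubject()] on every stream, pools the meta-rhythms on the
#' common period slice, clusters them into rhythm families, tabulates
#' prevalence (confirmed against each subject's significant clusters),
#' and optionally evaluates pairwise coherence for selected families.
#'
#' @param streams list of [TouchEventStream-class].
#' @param config from [runConfig()].
#' @param rank optional fixed rank forwarded to [runSubject()].
#' @param coherenceBands optional list of numeric length-2 day bands; when
#'   NULL, no coherence stage is run.
#' @param coherenceBoot bootstraps per pair in the coherence stage.
#' @param reportDir optional directory for a markdown report + CSVs.
#' @return list: subjects (artifact lists), skipped, rhythmClusters,
#'   prevalence, coherence (named by band).
#' @export
runCohort <- function(streams, config, rank = NULL, coherenceBands = NULL,
                      coherenceBoot = 100, reportDir = NULL) {
  ids <- vapply(streams, subjectId, character(1))
  names(streams) <- ids
  arts <- lapply(streams, runSubject, config = config, rank = rank)
  skipped <- Filter(function(a) isTRUE(a$skipped), arts)
  arts <- Filter(function(a) !isTRUE(a$skipped), arts)
  if (length(arts) < 2)
    stop("fewer than 2 subjects passed the profile preconditions")

  # pool meta-rhythms on the common period slice
  perList <- lapply(arts, function(a) a$rhythmMatrix@periods)
  common <- Reduce(intersect, perList)
  if (!length(common)) stop("no common period slice across subjects")
  curves <- list(); owners <- character(0)
  for (a in arts) {
    sel <- match(common, a$rhythmMatrix@periods)
    W <- metaRhythms(a$metaRhythms)[sel, , drop = FALSE]
    for (j in seq_len(ncol(W))) {
      curves[[length(curves) + 1L]] <- W[, j]
      owners <- c(owners, a$subjectId)
    }
  }
  rcs <- clusterMetaRhythms(do.call(cbind, curves), common,
                            subjectIds = owners, maxK = config$maxK,
                            seed = .childSeed(config$seed, 3))
  genders <- vapply(arts, function(a) {
    g <- streams[[a$subjectId]]@gender
    if (is.null(g)) NA_character_ else g
  }, character(1))
  subjects <- data.frame(subjectId = vapply(arts, `[[`, character(1),
                                            "subjectId"),
                         gender = genders, stringsAsFactors = FALSE)
  clusterSets <- lapply(arts, `[[`, "clusters")
  names(clusterSets) <- subjects$subjectId
  prev <- prevalenceTable(rcs, subjects, clusterSets)

  coh <- NULL
  if (!is.null(coherenceBands)) {
    jids <- lapply(arts, `[[`, "jid")
    names(jids) <- subjects$subjectId
    adj <- lapply(arts, `[[`, "adjusted")
    names(adj) <- subjects$subjectId
    gvec <- genders
    names(gvec) <- subjects$subjectId
    coh <- lapply(coherenceBands, function(band)
      tryCatch(
        cohortCoherence(jids, band, config$pgrid,
                        clusterSets = clusterSets, adjusted = adj,
                        genders = gvec, nBoot = coherenceBoot,
                        blockHours = config$blockHours,
                        seed = .childSeed(config$seed, 4)),
        error = function(e) conditionMessage(e)))
    names(coh) <- vapply(coherenceBands, function(b)
      sprintf("%.1f-%.1f", b[1], b[2]), character(1))
  }
  out <- list(subjects = arts, skipped = skipped, rhythmClusters = rcs,
              prevalence = prev, coherence = coh, config = config)
  if (!is.null(reportDir)) writeCohortReport(out, reportDir)
  out
}

#' Write a markdown cohort report
#'
#' Rhythm-family summary (peak and 95th-percentile range per family),
#' prevalence table, and coherence rates, plus CSV exports of the
#' assignment and prevalence tables.
#'
#' @param cohort result of [runCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the report path.
#' @export
writeCohortReport <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rcs <- cohort$rhythmClusters
  s <- cohort$prevalence$summary
  lines <- c(
    "# Multi-day rhythm cohort report", "",
    sprintf("Subjects analysed: %d (skipped: %d)",
            length(cohort$subjects), length(cohort$skipped)),
    sprintf("Rhythm families: %d (silhouette-selected)", rcs@k), "",
    "## Rhythm families", "",
    "| family | peak (d) | range (d) | incomplete | n meta-rhythms | % present |",
    "|---|---|---|---|---|---|",
    sprintf("| %d | %.1f | %.1f-%.1f | %s | %d | %.0f%% |",
            s$cluster, s$peakDays, s$rangeMinDays, s$rangeMaxDays,
            ifelse(s$incomplete, "yes", "no"), s$nMetaRhythms,
            s$pctPresent))
  if (!is.null(cohort$coherence)) {
    lines <- c(lines, "", "## Pairwise coherence", "")
    for (nm in names(cohort$coherence)) {
      cr <- cohort$coherence[[nm]]
      if (is.character(cr)) {
        lines <- c(lines, sprintf("- band %s d: %s", nm, cr))
      } else {
        lines <- c(lines, sprintf(
          "- band %s d: %d pairs, %.0f%% significant", nm,
          nrow(cr@pairs), 100 * mean(cr@pairs$significant)))
      }
    }
  }
  path <- file.path(dir, "report.md")
  writeLines(lines, path)
  utils::write.csv(rcs@assignments,
                   file.path(dir, "assignments.csv"), row.names = FALSE)
  utils::write.csv(s, file.path(dir, "prevalence.csv"), row.names = FALSE)
  invisible(path)
}
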