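# Plain-text persistence: event tables as CSV, configurations as YAML.

#' Write an event stream to CSV
#'
#' Columns: subject_id, timestamp_ms, event_type.
#'
#' @param stream a [TouchEventStream-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeEventsCSV <- function(stream, path) {
  ev <- events(stream)
  utils::write.csv(
    data.frame(subject_id = rep(subjectId(stream), nrow(ev)),
               timestamp_ms = format(ev$timestampMs, scientific = FALSE,
                                     trim = TRUE),
               event_type = ev$type),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read event streams from CSV
#'
#' @param path CSV with columns subject_id, timestamp_ms, event_type.
#' @param metadata optional data.frame (subject_id, age, gender).
#' @return named list of [TouchEventStream-class], one per subject id.
#' @export
readEventsCSV <- function(path, metadata = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp_ms", "event_type")
  if (!all(need %in% names(d)))
    stop("CSV needs columns ", paste(need, collapse = ", "))
  out <- lapply(split(d, d$subject_id), function(s) {
    s <- s[order(s$timestamp_ms), ]
    age <- NULL; gender <- NULL
    if (!is.null(metadata)) {
      m <- metadata[metadata$subject_id == s$subject_id[1], ]
      if (nrow(m)) {
        if ("age" %in% names(m)) age <- m$age[1]
        if ("gender" %in% names(m)) gender <- m$gender[1]
      }
    }
    new("TouchEventStream", subjectId = s$subject_id[1],
        events = data.frame(timestampMs = as.numeric(s$timestamp_ms),
                            type = s$event_type,
                            stringsAsFactors = FALSE),
        age = age, gender = gender)
  })
  out
}

#' Write a run configuration as YAML
#' @param config from [runConfig()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRunConfig <- function(config, path) {
  plain <- unclass(config)
  plain <- plain[!vapply(plain, isS4, logical(1))]
  plain$gridSteps <- config$grid@nSteps
  plain$gridRange <- c(config$grid@axisMin, config$grid@axisMax)
  plain$voicesPerOctave <- config$pgrid@voicesPerOctave
  plain$periodRangeHours <- c(config$pgrid@periodMin, config$pgrid@periodMax)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML written by [writeRunConfig()].
#' @return a config list as from [runConfig()].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- runConfig(profile = y$profile, scale = y$scale, seed = y$seed)
  for (nm in setdiff(names(y), c("profile", "scale", "seed", "gridSteps",
                                 "gridRange", "voicesPerOctave",
                                 "periodRangeHours")))
    cfg[[nm]] <- y[[nm]]
  cfg$grid <- jidGrid(y$gridRange[1], y$gridRange[2], y$gridSteps)
  cfg$pgrid <- periodGrid(voicesPerOctave = y$voicesPerOctave,
                          periodMin = y$periodRangeHours[1],
                          periodMax = y$periodRangeHours[2])
  cfg
}
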