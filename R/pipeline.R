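# Session I/O, configuration, end-to-end pipeline and the thin CLI.
# The on-disk session container is a documented directory layout of
# delimited text plus JSON metadata (lossless 17-significant-digit
# round-trip); EDF is supported read-only for external EEG.

padStr <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Read a European Data Format (EDF) file
#'
#' Minimal EDF reader for continuous recordings: parses the ASCII
#' header, reads the 16-bit data records and rescales to physical
#' units. All signals must share one sampling rate (the common case for
#' raw electrophysiology); annotation channels are not supported.
#'
#' @param path path to an .edf file.
#' @return a [TimeSeries-class] with channel labels from the header and
#'   units from the first signal's physical dimension.
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    raw <- readBin(con, "raw", nc)
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (!identical(version, "0")) stop("malformed EDF: bad version field")
  rd(80); rd(80); rd(8); rd(8)      # patient, recording, date, time
  rd(8)                             # header bytes
  rd(44)                            # reserved
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(nRec) || nRec < 1 || recDur <= 0)
    stop("malformed EDF header")
  field <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- field(16)
  field(80)                         # transducer
  dims <- field(8)
  physMin <- as.numeric(field(8))
  physMax <- as.numeric(field(8))
  digMin <- as.numeric(field(8))
  digMax <- as.numeric(field(8))
  field(80)                         # prefilter
  spr <- as.integer(field(8))       # samples per record
  field(32)                         # reserved
  if (length(unique(spr)) != 1)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1] / recDur
  gain <- (physMax - physMin) / (digMax - digMin)
  out <- matrix(0, nRec * spr[1], ns)
  for (r in seq_len(nRec)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                   endian = "little")
      if (length(d) < spr[s]) stop("malformed EDF: truncated data record")
      out[((r - 1) * spr[s] + 1):(r * spr[s]), s] <-
        physMin[s] + gain[s] * (d - digMin[s])
    }
  }
  colnames(out) <- labels
  TimeSeries(out, fs, units = dims[1])
}

#' Write a TimeSeries to EDF
#'
#' Minimal EDF writer (16-bit quantization over the observed physical
#' range per channel), primarily for producing test fixtures and
#' interchange files.
#'
#' @param ts a [TimeSeries-class]; its duration must be an integer
#'   number of \code{recordDurS}.
#' @param path output path.
#' @param recordDurS data-record duration in seconds.
#' @return invisibly, \code{path}.
#' @export
writeEDF <- function(ts, path, recordDurS = 1) {
  stopifnot(is(ts, "TimeSeries"))
  x <- ts@samples
  fs <- samplingRate(ts)
  spr <- round(fs * recordDurS)
  if (abs(spr - fs * recordDurS) > 1e-9)
    stop("fs * recordDurS must be an integer")
  nRec <- nrow(x) / spr
  if (abs(nRec - round(nRec)) > 1e-9)
    stop("signal length must be a whole number of records")
  nRec <- as.integer(round(nRec))
  ns <- ncol(x)
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  physMin <- apply(x, 2, min)
  physMax <- apply(x, 2, max)
  same <- physMax - physMin < 1e-12
  physMax[same] <- physMin[same] + 1
  digMin <- rep(-32768, ns)
  digMax <- rep(32767, ns)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(padStr(x, width)), con)
  wr("0", 8)
  wr("synthetic subject", 80)
  wr("synthetic recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + ns)), 8)
  wr("", 44)
  wr(as.character(nRec), 8)
  wr(format(recordDurS), 8)
  wr(as.character(ns), 4)
  wrAll <- function(vals, width) for (v in vals) wr(v, width)
  wrAll(labels, 16)
  wrAll(rep("", ns), 80)
  wrAll(rep(ts@units, ns), 8)
  wrAll(format(physMin, digits = 7), 8)
  wrAll(format(physMax, digits = 7), 8)
  wrAll(format(digMin), 8)
  wrAll(format(digMax), 8)
  wrAll(rep("", ns), 80)
  wrAll(rep(as.character(spr), ns), 8)
  wrAll(rep("", ns), 32)
  gain <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRec)) {
    for (s in seq_len(ns)) {
      seg <- x[((r - 1) * spr + 1):(r * spr), s]
      d <- round(digMin[s] + gain[s] * (seg - physMin[s]))
      writeBin(as.integer(pmax(digMin[s], pmin(digMax[s], d))),
               con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

writeMatrixTSV <- function(m, path) {
  m <- as.matrix(m)
  header <- paste(colnames(m), collapse = "\t")
  body <- do.call(paste, c(lapply(seq_len(ncol(m)), function(j)
    sprintf("%.17g", m[, j])), sep = "\t"))
  writeLines(c(header, body), path)
}

readMatrixTSV <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}

#' Write a synthetic session to a session directory
#'
#' Persists raw channels, the ground-truth state sequence, calcium
#' traces and true event times to a documented directory layout of
#' tab-separated text plus JSON metadata. Numeric values use 17
#' significant digits, so the round trip through [readSession()] is
#' lossless.
#'
#' @param session a [SyntheticSession-class].
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeSession <- function(session, dir) {
  stopifnot(is(session, "SyntheticSession"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  meta <- list(subject = session@subject, seed = session@seed,
               fs = samplingRate(session@eeg),
               units = list(eeg = session@eeg@units,
                            emg = session@emg@units,
                            accel = session@accel@units),
               calciumFs = session@calciumFs,
               windowS = windowSeconds(session@states),
               provenance = session@states@provenance)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  writeMatrixTSV(sampleMatrix(session@eeg), file.path(dir, "eeg.tsv"))
  writeMatrixTSV(sampleMatrix(session@emg), file.path(dir, "emg.tsv"))
  writeMatrixTSV(sampleMatrix(session@accel), file.path(dir, "accel.tsv"))
  writeMatrixTSV(session@calcium, file.path(dir, "calcium.tsv"))
  writeLines(stateLabels(session@states),
             file.path(dir, "truth", "states.txt"))
  utils::write.csv(generatingBouts(session@states),
                   file.path(dir, "truth", "bouts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(session@calciumEvents,
                       file.path(dir, "truth", "calcium_events.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a session directory written by [writeSession()]
#'
#' @param dir session directory.
#' @return a [SyntheticSession-class].
#' @export
readSession <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stop("not a session directory: ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  labels <- readLines(file.path(dir, "truth", "states.txt"))
  bouts <- utils::read.csv(file.path(dir, "truth", "bouts.csv"))
  events <- jsonlite::read_json(file.path(dir, "truth",
                                          "calcium_events.json"),
                                simplifyVector = TRUE)
  if (!is.list(events)) events <- as.list(events)
  events <- lapply(events, as.numeric)
  states <- new("StateSequence", labels = labels, windowS = meta$windowS,
                provenance = meta$provenance, bouts = bouts,
                seed = as.integer(meta$seed))
  new("SyntheticSession",
      eeg = TimeSeries(readMatrixTSV(file.path(dir, "eeg.tsv")), meta$fs,
                       units = meta$units$eeg),
      emg = TimeSeries(readMatrixTSV(file.path(dir, "emg.tsv")), meta$fs,
                       units = meta$units$emg),
      accel = TimeSeries(readMatrixTSV(file.path(dir, "accel.tsv")),
                         meta$fs, units = meta$units$accel),
      states = states,
      calcium = readMatrixTSV(file.path(dir, "calcium.tsv")),
      calciumFs = meta$calciumFs,
      calciumEvents = events,
      subject = meta$subject, seed = as.integer(meta$seed))
}

#' Read and write hypnograms as delimited text
#'
#' Two-column tab-separated format: \code{window_start_s}, \code{label}.
#'
#' @param h a [Hypnogram-class].
#' @param path file path.
#' @return \code{writeHypnogram} returns \code{path} invisibly;
#'   \code{readHypnogram} returns a [Hypnogram-class].
#' @export
writeHypnogram <- function(h, path) {
  stopifnot(is(h, "Hypnogram"))
  d <- data.frame(
    window_start_s = (seq_along(stateLabels(h)) - 1) * windowSeconds(h),
    label = stateLabels(h))
  utils::write.table(d, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeHypnogram
#' @param provenance provenance tag for the hypnogram read back.
#' @export
readHypnogram <- function(path, provenance = "manual") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("window_start_s", "label") %in% names(d)))
    stop("expected columns window_start_s and label")
  winS <- if (nrow(d) > 1) d$window_start_s[2] - d$window_start_s[1]
          else 2.5
  Hypnogram(d$label, windowS = winS, provenance = provenance)
}

#' Write / read a run configuration (JSON, losslessly)
#'
#' @param config a \code{RunConfig}.
#' @param path output path (.json).
#' @return \code{writeRunConfig} returns \code{path} invisibly;
#'   \code{readRunConfig} returns the \code{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$calciumRates <- as.list(cfg$calciumRates)  # keep state names
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$calciumRates <- unlist(cfg$calciumRates)
  structure(cfg, class = "RunConfig")
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end pipeline with their standard
#' settings. Serializes losslessly to JSON (and YAML).
#'
#' @param nSubjects number of synthetic subjects.
#' @param durationS session duration per subject in seconds.
#' @param seed global seed.
#' @param nCells calcium cells per subject.
#' @return a named list of class \code{RunConfig}.
#' @export
defaultRunConfig <- function(nSubjects = 6, durationS = 7200, seed = 1,
                             nCells = 8) {
  structure(list(
    nSubjects = nSubjects, durationS = durationS, seed = seed,
    windowS = 2.5, specWindowS = 5, specStepS = 2.5, nTapers = 35,
    nmfRank = 6, hidden = 32, decay = 1e-3, maxit = 300, minRun = 15,
    dwellWindows = 60, nCells = nCells,
    calciumRates = c(WAKE = 0.0677, NREM = 0.5076, REM = 0.2437),
    calciumNoiseSd = 0.1
  ), class = "RunConfig")
}

#' Run the full synthetic pipeline and report its statistics
#'
#' Generates a synthetic cohort, runs leave-one-subject-out staging
#' cross-validation, recovers the bout-level transition matrix, scores
#' calcium transient detection against ground truth, and computes
#' state-preference summaries. Deterministic for a fixed config and
#' seed.
#'
#' @param config a \code{RunConfig} from [defaultRunConfig()].
#' @return a report list (JSON-serializable) with elements
#'   \code{staging}, \code{transitions}, \code{calcium}, \code{config}.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  seed <- as.integer(config$seed)
  sessions <- lapply(seq_len(config$nSubjects), function(i)
    simulateSession(subject = sprintf("s%02d", i),
                    durationS = config$durationS,
                    windowS = config$windowS,
                    dwellWindows = config$dwellWindows,
                    nCells = if (i == 1) config$nCells else 0,
                    calciumRates = config$calciumRates,
                    calciumNoiseSd = config$calciumNoiseSd,
                    seed = seed + 17L * i))
  subjects <- lapply(sessions, extractStagingFeatures,
                     windowS = config$specWindowS,
                     stepS = config$specStepS, nTapers = config$nTapers)
  cv <- losoCV(subjects, k = config$nmfRank, hidden = config$hidden,
               decay = config$decay, maxit = config$maxit,
               minRun = config$minRun, seed = seed)
  # transition recovery against the generating matrix, pooled over bouts
  boutsAll <- do.call(rbind, lapply(sessions, function(s)
    generatingBouts(s@states)))
  tm <- transitionMatrix(boutsAll$state)
  # calcium detection vs ground truth on subject 1
  s1 <- sessions[[1]]
  calStats <- NULL
  if (ncol(s1@calcium) > 0) {
    prec <- rec <- numeric(ncol(s1@calcium))
    Slist <- matrix(NA_real_, ncol(s1@calcium), 3,
                    dimnames = list(NULL, VIGILANCE_STATES))
    for (ci in seq_len(ncol(s1@calcium))) {
      det <- detectTransients(s1@calcium[, ci], fs = s1@calciumFs)
      m <- matchEvents(det$time, s1@calciumEvents[[ci]],
                       tol = 0.75)
      prec[ci] <- m$precision
      rec[ci] <- m$recall
      sp <- statePreference(stateRates(det, s1@states))
      if (sp$included) Slist[ci, names(sp$S)] <- sp$S
    }
    calStats <- list(meanPrecision = mean(prec, na.rm = TRUE),
                     meanRecall = mean(rec, na.rm = TRUE),
                     meanS = colMeans(Slist, na.rm = TRUE))
  }
  list(
    staging = list(overallAccuracy = cv$overallAccuracy,
                   overallAccuracyRaw = cv$overallAccuracyRaw,
                   perFold = cv$perFold,
                   confusion = cv$confusion,
                   nWindows = cv$nWindows),
    transitions = list(empirical = tm$probabilities,
                       generating = defaultTransitionMatrix(),
                       supNormError = max(abs(
                         tm$probabilities - defaultTransitionMatrix()),
                         na.rm = TRUE),
                       nBouts = nrow(boutsAll)),
    calcium = calStats,
    config = unclass(config)
  )
}

#' Match detected events to ground-truth events
#'
#' Greedy one-to-one matching within a time tolerance; reports
#' precision and recall.
#'
#' @param detected,truth event time vectors in seconds.
#' @param tol matching tolerance in seconds.
#' @return list with \code{precision}, \code{recall}, \code{nMatched}.
#' @export
matchEvents <- function(detected, truth, tol = 0.75) {
  if (!length(truth))
    return(list(precision = if (length(detected)) 0 else 1, recall = 1,
                nMatched = 0L))
  if (!length(detected))
    return(list(precision = 1, recall = 0, nMatched = 0L))
  usedT <- logical(length(truth))
  matched <- 0L
  for (d in sort(detected)) {
    err <- abs(truth - d)
    err[usedT] <- Inf
    j <- which.min(err)
    if (err[j] <= tol) {
      usedT[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(precision = matched / length(detected),
       recall = matched / length(truth), nMatched = matched)
}

#' Write a pipeline report as JSON
#'
#' @param report list from [runPipeline()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Minimal command-line dispatcher
#'
#' Subcommands: \code{simulate --seed S --duration D --out DIR} (write a
#' synthetic session), \code{report DIR --out FILE} (basic
#' ground-truth metrics of a stored session as JSON), \code{--help}.
#' Returns an exit code (0 on success) rather than calling quit(), so
#' it is testable in-process; the installed script
#' \code{inst/scripts/somnostat-cli.R} forwards to it.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
somnostatCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: somnostat-cli.R <command> [options]",
    "  simulate --seed S --duration SECONDS --out DIR",
    "  report <session-dir> [--out FILE]",
    "  --help", sep = "\n")
  getOpt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  if (!length(args) || args[1] %in% c("--help", "-h")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- args[1]
  if (cmd == "simulate") {
    out <- getOpt("--out")
    if (is.null(out)) { message("simulate requires --out\n", usage)
                        return(invisible(2L)) }
    sess <- simulateSession(
      durationS = as.numeric(getOpt("--duration", "600")),
      seed = as.integer(getOpt("--seed", "1")))
    writeSession(sess, out)
    message("wrote session to ", out)
    return(invisible(0L))
  }
  if (cmd == "report") {
    if (length(args) < 2) { message(usage); return(invisible(2L)) }
    sess <- readSession(args[2])
    tis <- timeInState(sess@states)
    rep <- list(subject = sess@subject, seed = sess@seed,
                nWindows = length(stateLabels(sess@states)),
                fractionOfTime = as.list(colMeans(
                  tis[, VIGILANCE_STATES, drop = FALSE])),
                nBouts = nrow(generatingBouts(sess@states)))
    out <- getOpt("--out")
    if (is.null(out)) {
      cat(jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE), "\n")
    } else writeReport(rep, out)
    return(invisible(0L))
  }
  message("unknown command: ", cmd, "\n", usage)
  invisible(2L)
}
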