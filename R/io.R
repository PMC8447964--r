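## Session container I/O. Two dialects:
##  * "csv" — a directory of tidy CSV tables with a JSON manifest; numeric
##    values are written with 17 significant digits so a write -> read
##    round trip is bit-exact. The canonical fixture format.
##  * "nwb-json" — a single structured JSON file mirroring the acquisition /
##    processing group layout of Neurodata Without Borders containers
##    (full-precision numbers via jsonlite).
## All timestamps are stored in seconds relative to injection.

sessionMetaDf <- function(session) {
  data.frame(subjectId = session@subjectId,
             dose = fmtNum(session@dose),
             injectionTime = fmtNum(session@injectionTime),
             stringsAsFactors = FALSE)
}

segmentsMetaDf <- function(session) {
  do.call(rbind, lapply(segments(session), function(s) {
    data.frame(segmentId = s@segmentId,
               startTime = fmtNum(s@startTime),
               samplingRate = fmtNum(s@samplingRate),
               nSamples = nrow(s@channels),
               stringsAsFactors = FALSE)
  }))
}

#' Write a session container
#'
#' @param session a [TremorSession-class].
#' @param path target directory ("csv") or file ("nwb-json").
#' @param format container dialect.
#' @param products optional named list of data.frames (per-segment stats,
#'   MPR tables, ...) stored alongside the acquisition data.
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path, format = c("csv", "nwb-json"),
                         products = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(path)) stop("writeSession: cannot create ", path)
    tables <- c("session", "segments", "acceleration", names(products))
    acc <- do.call(rbind, lapply(segments(session), function(s) {
      data.frame(segmentId = s@segmentId,
                 ax = fmtNum(s@channels[, 1]),
                 ay = fmtNum(s@channels[, 2]),
                 az = fmtNum(s@channels[, 3]),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(sessionMetaDf(session),
                     file.path(path, "session.csv"), row.names = FALSE)
    utils::write.csv(segmentsMetaDf(session),
                     file.path(path, "segments.csv"), row.names = FALSE)
    utils::write.csv(acc, file.path(path, "acceleration.csv"),
                     row.names = FALSE)
    for (nm in names(products)) {
      df <- as.data.frame(products[[nm]])
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], fmtNum)
      utils::write.csv(df, file.path(path, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(format = "tremorquant-csv-bundle", version = 1L,
           tables = as.list(tables)),
      file.path(path, "manifest.json"), auto_unbox = TRUE)
  } else {
    container <- list(
      format = "tremorquant-nwb-json", version = 1L,
      general = list(subject_id = session@subjectId, dose = session@dose,
                     injection_time = session@injectionTime),
      acquisition = lapply(segments(session), function(s)
        list(name = s@segmentId, starting_time = s@startTime,
             rate = s@samplingRate,
             data = list(ax = s@channels[, 1], ay = s@channels[, 2],
                         az = s@channels[, 3]))),
      processing = products)
    ## digits = I(17): full IEEE round-trip precision
    jsonlite::write_json(container, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' Read a session container
#'
#' Reads either dialect written by [writeSession()], validating the schema:
#' a missing table, a non-3-channel acceleration block, or an unknown
#' format raise parse errors naming the defect. Segments are returned
#' sorted by start time regardless of on-disk order.
#'
#' @param path container directory (csv bundle) or file (nwb-json).
#' @return List with `session` (a [TremorSession-class]) and `products`
#'   (named list of data.frames, possibly empty).
#' @export
readSession <- function(path) {
  if (dir.exists(path)) readSessionCsv(path)
  else if (file.exists(path)) readSessionNwbJson(path)
  else stop("readSession: ", path, " does not exist")
}

readSessionCsv <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("parse error: manifest.json missing in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "tremorquant-csv-bundle"))
    stop("parse error: unknown container format '", manifest$format, "'")
  for (tbl in manifest$tables) {
    if (!file.exists(file.path(path, paste0(tbl, ".csv"))))
      stop("parse error: manifest lists table '", tbl,
           "' but ", tbl, ".csv is missing")
  }
  rd <- function(tbl) utils::read.csv(file.path(path, paste0(tbl, ".csv")),
                                      stringsAsFactors = FALSE)
  meta <- rd("session")
  segMeta <- rd("segments")
  acc <- rd("acceleration")
  need <- c("ax", "ay", "az")
  if (!all(need %in% names(acc)))
    stop("parse error: expected 3 acceleration channels (ax, ay, az), ",
         "found: ", paste(intersect(need, names(acc)), collapse = ", "))
  segs <- lapply(seq_len(nrow(segMeta)), function(i) {
    sel <- acc$segmentId == segMeta$segmentId[i]
    if (sum(sel) != segMeta$nSamples[i])
      stop("parse error: segment ", segMeta$segmentId[i], " has ",
           sum(sel), " samples, manifest says ", segMeta$nSamples[i])
    TriaxSegment(cbind(as.numeric(acc$ax[sel]), as.numeric(acc$ay[sel]),
                       as.numeric(acc$az[sel])),
                 samplingRate = as.numeric(segMeta$samplingRate[i]),
                 startTime = as.numeric(segMeta$startTime[i]),
                 subjectId = meta$subjectId,
                 segmentId = segMeta$segmentId[i])
  })
  products <- list()
  for (tbl in setdiff(unlist(manifest$tables),
                      c("session", "segments", "acceleration")))
    products[[tbl]] <- rd(tbl)
  list(session = TremorSession(segs, subjectId = meta$subjectId,
                               dose = as.numeric(meta$dose)),
       products = products)
}

readSessionNwbJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(x$format, "tremorquant-nwb-json"))
    stop("parse error: unknown container format '", x$format, "'")
  segs <- lapply(x$acquisition, function(a) {
    if (!all(c("ax", "ay", "az") %in% names(a$data)))
      stop("parse error: expected 3 acceleration channels in segment ",
           a$name)
    TriaxSegment(cbind(as.numeric(a$data$ax), as.numeric(a$data$ay),
                       as.numeric(a$data$az)),
                 samplingRate = as.numeric(a$rate),
                 startTime = as.numeric(a$starting_time),
                 subjectId = x$general$subject_id, segmentId = a$name)
  })
  products <- lapply(x$processing, function(p) as.data.frame(p))
  list(session = TremorSession(segs, subjectId = x$general$subject_id,
                               dose = as.numeric(x$general$dose)),
       products = products)
}
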