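# File interfaces: EDF and BrainVision EEG, NIfTI volumes, CSV/JSON
# tables. The EDF reader/writer below covers the plain continuous
# 16-bit EDF subset this package produces and consumes.

padField <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as EDF with a JSON event sidecar
#'
#' Plain continuous EDF: one data record per second, 16-bit samples,
#' physical range taken from the data. The sampling rate must be a
#' whole number. Event markers go to \code{<path>.events.json}.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@fs
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate")
  sig <- recording@signal
  ns <- nrow(sig)
  nrec <- floor(ncol(sig) / fs)
  sig <- sig[, seq_len(nrec * fs), drop = FALSE]
  pmin <- floor(apply(sig, 1L, min))
  pmax <- ceiling(apply(sig, 1L, max))
  pmax[pmax <= pmin] <- pmin[pmax <= pmin] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    padField("0", 8L), padField("synthetic", 80L),
    padField("neurodecline export", 80L),
    padField("01.01.00", 8L), padField("00.00.00", 8L),
    padField(256L * (1L + ns), 8L), padField("", 44L),
    padField(nrec, 8L), padField("1", 8L), padField(ns, 4L))
  writeChar(paste(hdr, collapse = ""), con, eos = NULL)
  fields <- list(
    padField(recording@channelNames, 16L), rep(padField("", 80L), ns),
    padField(rep("uV", ns), 8L), padField(pmin, 8L), padField(pmax, 8L),
    padField(rep("-32768", ns), 8L), padField(rep("32767", ns), 8L),
    rep(padField("", 80L), ns), padField(rep(fs, ns), 8L),
    rep(padField("", 32L), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  scale <- 65535 / (pmax - pmin)
  for (r in seq_len(nrec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    for (i in seq_len(ns)) {
      dig <- round((sig[i, idx] - pmin[i]) * scale[i]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2L, endian = "little")
    }
  }
  jsonlite::write_json(
    list(fs = fs, reference = recording@reference,
         events = recording@events),
    paste0(path, ".events.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EDF recording (with optional JSON event sidecar)
#'
#' @param path EDF file written by [writeEDF()] or any plain continuous
#'   EDF with equal per-signal sampling rates.
#' @return an \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  invisible(rd(8L + 80L + 80L + 8L + 8L))
  invisible(rd(8L))                     # header bytes
  invisible(rd(44L))
  nrec <- as.integer(rd(8L))
  recDur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- vapply(seq_len(ns), function(i) rd(16L), "")
  invisible(replicate(ns, rd(80L)))
  invisible(replicate(ns, rd(8L)))      # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), 0)
  invisible(replicate(ns, rd(80L)))
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8L)), 0L)
  invisible(replicate(ns, rd(32L)))
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / recDur
  sig <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    idx <- (r - 1L) * spr[1] + seq_len(spr[1])
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L,
                     endian = "little")
      sig[i, idx] <- pmin[i] +
        (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    }
  }
  events <- NULL
  reference <- "unknown"
  sidecar <- paste0(path, ".events.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    reference <- meta$reference %||% "unknown"
    if (length(meta$events)) events <- as.data.frame(meta$events)
  }
  eegRecording(sig, fs, labels, reference = reference, events = events)
}

parseIniSection <- function(lines, section) {
  starts <- grep("^\\[", lines)
  hit <- grep(paste0("^\\[", section, "\\]$"), lines, ignore.case = TRUE)
  if (!length(hit)) return(character(0))
  end <- starts[starts > hit[1]]
  end <- if (length(end)) end[1] - 1L else length(lines)
  body <- lines[(hit[1] + 1L):end]
  body[grepl("=", body) & !grepl("^;", body)]
}

iniValues <- function(entries) {
  kv <- strsplit(entries, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(p)
    trimws(paste(p[-1], collapse = "=")), ""),
    vapply(kv, function(p) trimws(p[1]), ""))
}

#' Read a BrainVision-style recording (vhdr/eeg/vmrk triplet)
#'
#' Supports multiplexed or vectorized binary IEEE float32 / int16 data
#' and ASCII data files. Marker descriptions matching a task condition
#' name (rest, learning, recall, recognition, case-insensitive) become
#' events; a rest marker's length (points field) becomes the block
#' duration.
#'
#' @param vhdrPath path to the header file.
#' @param session session index attached to the events.
#' @return an \linkS4class{EEGRecording}.
#' @export
readBrainVision <- function(vhdrPath, session = 1L) {
  lines <- readLines(vhdrPath, warn = FALSE)
  common <- iniValues(parseIniSection(lines, "Common Infos"))
  binfo <- iniValues(parseIniSection(lines, "Binary Infos"))
  chan <- iniValues(parseIniSection(lines, "Channel Infos"))
  ns <- as.integer(common[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(common[["SamplingInterval"]])
  fmt <- toupper(common[["DataFormat"]] %||% "BINARY")
  orient <- toupper(common[["DataOrientation"]] %||% "MULTIPLEXED")
  chParts <- strsplit(unname(chan), ",", fixed = TRUE)
  chNames <- vapply(chParts, `[`, "", 1L)
  res <- vapply(chParts, function(p)
    if (length(p) >= 3L && nzchar(p[3])) as.numeric(p[3]) else 1, 0)
  dataPath <- file.path(dirname(vhdrPath), common[["DataFile"]])
  if (fmt == "ASCII") {
    vals <- as.matrix(utils::read.table(dataPath))
    sig <- if (orient == "VECTORIZED") vals else t(vals)
  } else {
    bfmt <- toupper(binfo[["BinaryFormat"]] %||% "IEEE_FLOAT_32")
    sz <- file.info(dataPath)$size
    if (bfmt == "IEEE_FLOAT_32") {
      raw <- readBin(dataPath, "numeric", n = sz / 4L, size = 4L,
                     endian = "little")
    } else if (bfmt == "INT_16") {
      raw <- readBin(dataPath, "integer", n = sz / 2L, size = 2L,
                     endian = "little")
    } else stop("unsupported BinaryFormat: ", bfmt)
    npts <- length(raw) %/% ns
    sig <- if (orient == "VECTORIZED")
      t(matrix(raw, npts, ns)) else matrix(raw, ns, npts)
  }
  sig <- sig * res
  rownames(sig) <- chNames
  events <- data.frame(sample = integer(), condition = character(),
                       session = integer(), duration = integer())
  if (!is.null(common[["MarkerFile"]]) &&
      !is.na(common[["MarkerFile"]])) {
    mpath <- file.path(dirname(vhdrPath), common[["MarkerFile"]])
    if (file.exists(mpath)) {
      mk <- iniValues(parseIniSection(readLines(mpath, warn = FALSE),
                                      "Marker Infos"))
      for (m in mk) {
        p <- trimws(strsplit(m, ",", fixed = TRUE)[[1]])
        cond <- tolower(p[2])
        hit <- c("rest", "learning", "recall", "recognition")
        hit <- hit[vapply(hit, function(h) grepl(h, cond, fixed = TRUE),
                          TRUE)]
        if (!length(hit)) next
        events <- rbind(events, data.frame(
          sample = as.integer(p[3]), condition = hit[1],
          session = as.integer(session),
          duration = if (length(p) >= 4L) as.integer(p[4]) else 0L))
      }
    }
  }
  eegRecording(sig, fs, chNames, reference = "as-recorded",
               events = events)
}

#' Write a recording as an ASCII BrainVision triplet
#'
#' Text-only variant (vhdr + ASCII data + vmrk) used for portable
#' fixtures and interoperability tests.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param basePath path without extension; writes
#'   \code{<basePath>.vhdr/.dat/.vmrk}.
#' @return invisibly, the vhdr path.
#' @export
writeBrainVisionAscii <- function(recording, basePath) {
  stopifnot(is(recording, "EEGRecording"))
  vhdr <- paste0(basePath, ".vhdr")
  dat <- paste0(basePath, ".dat")
  vmrk <- paste0(basePath, ".vmrk")
  ns <- nrow(recording@signal)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(dat)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=ASCII",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", ns),
    paste0("SamplingInterval=", format(1e6 / recording@fs)),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(ns), recording@channelNames))
  writeLines(hdr, vhdr)
  utils::write.table(
    t(recording@signal), dat, row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  ev <- recording@events
  mk <- c("[Marker Infos]",
          if (nrow(ev))
            sprintf("Mk%d=Stimulus,%s,%d,%d,0", seq_len(nrow(ev)),
                    ev$condition, ev$sample, ev$duration))
  writeLines(mk, vmrk)
  invisible(vhdr)
}

#' Write intensity and label volumes as NIfTI
#'
#' Intensity as float32, labels as int16, voxel size in the header.
#'
#' @param volume a \linkS4class{LabeledVolume}.
#' @param intensityPath,labelsPath output paths (.nii or .nii.gz).
#' @return invisibly, the two paths.
#' @export
writeNiftiVolume <- function(volume, intensityPath, labelsPath) {
  stopifnot(is(volume, "LabeledVolume"))
  RNifti::writeNifti(
    RNifti::asNifti(volume@intensity, datatype = "float",
                    pixdim = volume@voxelSize),
    intensityPath)
  RNifti::writeNifti(
    RNifti::asNifti(volume@labels, datatype = "int16",
                    pixdim = volume@voxelSize),
    labelsPath)
  invisible(c(intensityPath, labelsPath))
}

#' Read intensity and label NIfTI volumes into a labeled volume
#'
#' Features downstream are mask-based and orientation-agnostic: the two
#' images are only required to have identical array dimensions.
#'
#' @param intensityPath,labelsPath NIfTI paths.
#' @param labelDict optional named character label dictionary.
#' @return a \linkS4class{LabeledVolume}.
#' @export
readNiftiVolume <- function(intensityPath, labelsPath,
                            labelDict = NULL) {
  int <- RNifti::readNifti(intensityPath)
  lab <- RNifti::readNifti(labelsPath)
  vs <- RNifti::pixdim(int)[1:3]
  labeledVolume(array(as.numeric(int), dim = dim(int)),
                array(as.integer(lab), dim = dim(lab)),
                voxelSize = vs, labelDict = labelDict)
}

#' Write/read a neuropsychological score table as CSV
#'
#' Schema: participant_id, group, subscale, session, raw, norm_mean,
#' norm_sd (norm columns joined from the battery on write).
#'
#' @param table long score table.
#' @param norms battery with norms.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeNeuropsychCSV <- function(table, path, norms = defaultBattery()) {
  i <- match(table$subscale, norms$subscale)
  out <- cbind(table[, c("participant_id", "group", "subscale",
                         "session", "raw")],
               norm_mean = norms$norm_mean[i],
               norm_sd = norms$norm_sd[i])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNeuropsychCSV
#' @export
readNeuropsychCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a feature matrix as a columnar CSV table
#'
#' One row per sample, feature identifiers as the header; participant
#' ids (and any other attached metadata columns) lead the table.
#'
#' @param m feature matrix with optional \code{participant_id}
#'   attribute.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeFeatureTable <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE)
  pid <- attr(m, "participant_id") %||% rownames(m)
  df <- cbind(data.frame(participant_id = pid,
                         check.names = FALSE), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  attr(m, "participant_id") <- df[[1]]
  m
}

#' Write segments as a binary container with a JSON manifest
#'
#' Float32 little-endian samples, one segment after another
#' (channels x samples, column-major); the manifest records shapes,
#' channels and per-segment metadata.
#'
#' @param segments list of \linkS4class{Segment} objects.
#' @param basePath path without extension; writes \code{.bin} and
#'   \code{.json}.
#' @return invisibly, the manifest path.
#' @export
writeSegments <- function(segments, basePath) {
  stopifnot(length(segments) > 0L)
  bin <- paste0(basePath, ".bin")
  con <- file(bin, "wb")
  for (s in segments)
    writeBin(as.numeric(s@data), con, size = 4L, endian = "little")
  close(con)
  s1 <- segments[[1]]
  manifest <- list(
    nChannels = nrow(s1@data), nSamples = ncol(s1@data), fs = s1@fs,
    channelNames = s1@channelNames,
    segments = data.frame(
      participant_id = vapply(segments, function(s) s@participantId, ""),
      condition = vapply(segments, function(s) s@condition, ""),
      session = vapply(segments, function(s) s@session, 1L),
      onsetSample = vapply(segments, function(s) s@onsetSample, 1L)))
  jsonlite::write_json(manifest, paste0(basePath, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(basePath, ".json"))
}

#' @rdname writeSegments
#' @export
readSegments <- function(basePath) {
  manifest <- jsonlite::read_json(paste0(basePath, ".json"),
                                  simplifyVector = TRUE)
  nc <- manifest$nChannels
  np <- manifest$nSamples
  meta <- manifest$segments
  raw <- readBin(paste0(basePath, ".bin"), "numeric",
                 n = nc * np * nrow(meta), size = 4L, endian = "little")
  lapply(seq_len(nrow(meta)), function(k) {
    d <- matrix(raw[(k - 1L) * nc * np + seq_len(nc * np)], nc, np)
    rownames(d) <- manifest$channelNames
    new("Segment", data = d, fs = manifest$fs,
        channelNames = manifest$channelNames,
        condition = meta$condition[k],
        session = as.integer(meta$session[k]),
        participantId = meta$participant_id[k],
        onsetSample = as.integer(meta$onsetSample[k]))
  })
}
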