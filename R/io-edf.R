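## European Data Format (EDF) reader/writer for continuous recordings.
## EDF stores a 256-byte ASCII header, 256 ASCII bytes per signal of
## per-signal metadata, then data records of little-endian int16 samples
## scaled between declared physical and digital ranges.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.edfNum <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edfPad(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a per-channel symmetric
#' physical range, so the read-back differs from the input by at most one
#' quantization step.  A sidecar channel TSV (same path with
#' \code{_channels.tsv} in place of \code{.edf}) carries the channel table
#' columns EDF cannot hold.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param path output file path (conventionally ending in .edf).
#' @param physicalMax optional per-channel physical range half-width
#'   (microvolts); defaults to the per-channel absolute maximum.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, physicalMax = NULL) {
  stopifnot(is(rec, "ContinuousRecording"))
  x <- samples(rec)
  if (!all(is.finite(x))) stop("samples must be finite to write EDF")
  nch <- nrow(x)
  n <- ncol(x)
  rate <- samplingRate(rec)
  ## always write 1 s records; lengths that are not whole seconds are
  ## zero-padded and the true sample count is stored in the reserved
  ## header field (read back by readRecording, ignored by other readers)
  recDur <- 1
  sampPerRec <- rate
  nRec <- ceiling(n / rate)
  nTrue <- n
  if (n %% rate != 0) {
    x <- cbind(x, matrix(0, nch, nRec * rate - n))
    n <- ncol(x)
  }
  if (is.null(physicalMax)) {
    physicalMax <- apply(abs(x), 1, max)
  } else if (length(physicalMax) == 1) {
    physicalMax <- rep(physicalMax, nch)
  }
  physicalMax[physicalMax <= 0] <- 1
  ## symmetric digital range so 0 uV maps to digital 0 exactly
  digMax <- 32767; digMin <- -32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad(sessionId(rec), 80),
    .edfPad("Startdate 01-JAN-2000", 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(256 * (nch + 1), 8),
    .edfPad(if (nTrue != n) paste0("NSAMP=", nTrue) else "", 44),
    .edfPad(nRec, 8), .edfNum(recDur, 8), .edfPad(nch, 4))
  writeChar(hdr, con, eos = NULL)
  labs <- channelTable(rec)$name
  writeChar(paste(vapply(labs, .edfPad, "", width = 16), collapse = ""),
            con, eos = NULL)
  writeChar(strrep(" ", 80 * nch), con, eos = NULL)          # transducer
  writeChar(strrep(.edfPad("uV", 8), nch), con, eos = NULL)  # phys dim
  writeChar(paste(vapply(-physicalMax, .edfNum, "", width = 8),
                  collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(physicalMax, .edfNum, "", width = 8),
                  collapse = ""), con, eos = NULL)
  writeChar(strrep(.edfPad(digMin, 8), nch), con, eos = NULL)
  writeChar(strrep(.edfPad(digMax, 8), nch), con, eos = NULL)
  writeChar(strrep(" ", 80 * nch), con, eos = NULL)          # prefiltering
  writeChar(strrep(.edfPad(sampPerRec, 8), nch), con, eos = NULL)
  writeChar(strrep(" ", 32 * nch), con, eos = NULL)
  physMin <- -physicalMax
  scale <- (digMax - digMin) / (2 * physicalMax)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * sampPerRec + 1):(r * sampPerRec)
    for (ch in seq_len(nch)) {
      dig <- round((x[ch, idx] - physMin[ch]) * scale[ch] + digMin)
      dig <- pmin(pmax(dig, digMin), digMax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  chanPath <- sub("\\.edf$", "_channels.tsv", path, ignore.case = TRUE)
  if (chanPath != path) writeChannels(channelTable(rec), chanPath)
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' All signals must share one sampling rate.  If a sidecar channel TSV
#' (\code{_channels.tsv}) is present its rows are joined to the EDF labels;
#' otherwise a minimal channel table (region OTHER) is derived from the
#' labels.
#'
#' @param path EDF file path.
#' @param sessionId session identifier; defaults to the file name.
#' @return A \linkS4class{ContinuousRecording}.
#' @export
readRecording <- function(path, sessionId = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readStr <- function(nb) {
    trimws(rawToChar(readBin(con, "raw", nb)))
  }
  version <- readStr(8)
  if (!nzchar(version) || substr(version, 1, 1) != "0")
    stop("unreadable EDF header (bad version field)")
  patient <- readStr(80); readStr(80); readStr(8); readStr(8)
  headerBytes <- as.numeric(readStr(8))
  reserved <- readStr(44)
  nRec <- as.numeric(readStr(8))
  recDur <- as.numeric(readStr(8))
  nch <- as.integer(readStr(4))
  if (is.na(nch) || nch < 1 || is.na(nRec) || is.na(recDur))
    stop("unreadable EDF header")
  fld <- function(width) vapply(seq_len(nch), function(i) readStr(width), "")
  labels <- fld(16); fld(80); fld(8)
  physMin <- as.numeric(fld(8)); physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  fld(80)
  sampPerRec <- as.integer(fld(8)); fld(32)
  rates <- sampPerRec / recDur
  if (length(unique(rates)) != 1)
    stop("unsupported EDF: signals have mixed sampling rates (",
         paste(unique(rates), collapse = ", "), " Hz)")
  rate <- rates[1]
  n <- nRec * sampPerRec[1]
  x <- matrix(0, nch, n)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * sampPerRec[1] + 1):(r * sampPerRec[1])
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", sampPerRec[ch], size = 2,
                     signed = TRUE, endian = "little")
      x[ch, idx] <- (dig - digMin[ch]) * scale[ch] + physMin[ch]
    }
  }
  if (grepl("^NSAMP=\\d+$", reserved)) {
    nTrue <- as.integer(sub("NSAMP=", "", reserved))
    if (nTrue <= n) x <- x[, seq_len(nTrue), drop = FALSE]
  }
  chanPath <- sub("\\.edf$", "_channels.tsv", path, ignore.case = TRUE)
  if (chanPath != path && file.exists(chanPath)) {
    channels <- readChannels(chanPath)
    if (!identical(channels$name, labels))
      channels <- channels[match(labels, channels$name), , drop = FALSE]
    if (anyNA(channels$name))
      stop("sidecar channel TSV does not cover all EDF labels")
  } else {
    shaft <- sub("[0-9]+$", "", labels)
    idxs <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", labels)))
    bad <- is.na(idxs)
    if (any(bad)) idxs[bad] <- seq_len(sum(bad))
    channels <- data.frame(
      name = labels, shaft = shaft, contact_index = idxs,
      region = "OTHER", hemisphere = "R", bad = FALSE, soz = FALSE,
      stringsAsFactors = FALSE)
  }
  if (is.null(sessionId))
    sessionId <- if (nzchar(patient)) patient else basename(path)
  new("ContinuousRecording", samples = x, rate = rate,
      channels = channels, sessionId = sessionId)
}
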