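## TSV readers/writers for events and channels (BIDS-iEEG-flavoured
## column names) and the YAML analysis configuration.

JITTER_RANGES <- list(fixation_s = c(1.9, 2.1), delay_s = c(3.9, 4.1))

#' Validate an event table
#'
#' Checks the invariants of the trial schedule: strictly increasing
#' onsets, durations inside the task's jitter ranges (fixation 1.9-2.1 s,
#' delay 3.9-4.1 s; violations warn but do not fail), and question phase
#' present only for "different"-condition trials.
#'
#' @param events data.frame of trial events.
#' @return \code{events}, invisibly, after validation.
#' @export
validateEvents <- function(events) {
  req <- c("onset", "condition", "block_index", "fixation_s", "encoding_s",
           "delay_s", "action_s")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("event table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!all(events$condition %in% CONDITIONS))
    stop("condition must be 'same' or 'different'")
  if (is.unsorted(events$onset, strictly = TRUE))
    stop("trial onsets must be strictly increasing")
  for (col in names(JITTER_RANGES)) {
    rng <- JITTER_RANGES[[col]]
    off <- which(events[[col]] < rng[1] - 1e-9 | events[[col]] > rng[2] + 1e-9)
    if (length(off))
      warning(sprintf("%s outside [%g, %g] s in row(s) %s", col,
                      rng[1], rng[2], paste(off, collapse = ", ")))
  }
  if ("question_s" %in% names(events)) {
    bad <- which(events$condition == "same" & !is.na(events$question_s))
    if (length(bad))
      stop("question_s present for same-condition trial(s) in row(s) ",
           paste(bad, collapse = ", "))
  }
  invisible(events)
}

#' Read / write the events TSV
#'
#' Columns: \code{onset} (s from session start, encoding onset),
#' \code{condition} (same/different), \code{block_index},
#' \code{fixation_s}, \code{encoding_s}, \code{delay_s}, \code{action_s},
#' \code{question_s} (NA for same-condition trials),
#' \code{correct_position}, \code{correct_identity}.
#'
#' @param path TSV file path.
#' @return \code{readEvents}: validated events data.frame.
#' @export
readEvents <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "n/a"))
  validateEvents(ev)
  ev
}

#' @rdname readEvents
#' @param events events data.frame.
#' @export
writeEvents <- function(events, path) {
  validateEvents(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read / write the channels TSV
#'
#' Columns: \code{name}, \code{shaft}, \code{contact_index},
#' \code{region} (IPL/VTC/HIP/OTHER), \code{hemisphere} (L/R),
#' \code{status} (good/bad, BIDS-style) and \code{soz} (seizure-onset-zone
#' flag).  Internally \code{status} maps to the logical \code{bad} column.
#'
#' @param path TSV file path.
#' @return \code{readChannels}: validated channel data.frame with columns
#'   name, shaft, contact_index, region, hemisphere, bad, soz.
#' @export
readChannels <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "shaft", "contact_index", "region", "hemisphere")
  miss <- setdiff(req, names(tb))
  if (length(miss))
    stop("channel table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tb$name)) {
    dup <- which(duplicated(tb$name))
    stop("duplicate channel name(s) in row(s) ", paste(dup, collapse = ", "))
  }
  if ("status" %in% names(tb)) {
    tb$bad <- tb$status != "good"
    tb$status <- NULL
  } else if (!"bad" %in% names(tb)) {
    tb$bad <- FALSE
  }
  if (!"soz" %in% names(tb)) tb$soz <- FALSE
  tb$bad <- as.logical(tb$bad); tb$soz <- as.logical(tb$soz)
  ok <- validChannelTable(tb)
  if (!isTRUE(ok)) stop(paste(ok, collapse = "; "))
  tb
}

#' @rdname readChannels
#' @param channels channel data.frame.
#' @export
writeChannels <- function(channels, path) {
  ok <- validChannelTable(channels)
  if (!isTRUE(ok)) stop(paste(ok, collapse = "; "))
  out <- channels
  out$status <- ifelse(out$bad, "bad", "good")
  out$bad <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

.configDefaults <- function() {
  list(
    version = 1L,
    bands = list(theta = c(2, 7), alpha = c(8, 13)),
    envelope_band = c(2, 13),
    n_perm = 200L,
    alpha_cluster = 0.05,
    alpha_fdr = 0.05,
    notch_order = 2L,
    bandpass_order = 3L,
    envelope_rate = 64,
    gc_rate = 40,
    seed = 1L,
    region_pairs = list(c("IPL", "VTC"), c("IPL", "HIP"))
  )
}

#' Load the analysis configuration
#'
#' Reads a versioned YAML configuration.  Unknown keys are errors;
#' omitted keys take the documented defaults.  All stated frequencies must
#' lie below the Nyquist frequency of the stage they apply to and the
#' permutation count must be at least 1.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return A named list of class \code{AnalysisConfig}.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- .configDefaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    if (!is.null(user$version) && user$version != cfg$version)
      stop("unsupported configuration schema version: ", user$version)
    cfg[names(user)] <- user
  }
  if (cfg$n_perm < 1) stop("permutation count must be >= 1")
  bmax <- max(unlist(cfg$bands))
  if (bmax >= 512 / 2) stop("band frequencies must be below Nyquist")
  structure(cfg, class = "AnalysisConfig")
}
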