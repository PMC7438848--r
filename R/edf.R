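#' Read an EDF recording
#'
#' Minimal reader for continuous 16-bit EDF (European Data Format) files.
#' Signals are returned in their physical units (expected to be microvolts
#' for EEG), and the 19 standard 10-20 channels are matched by name
#' (case- and whitespace-insensitive, ignoring common "EEG " prefixes and
#' reference suffixes such as "-REF"); extra channels are dropped and the
#' result is ordered as [tenTwentyChannels()].
#'
#' @param path path to an EDF file.
#' @param channels required channel names (default the 19 10-20 names);
#'   a missing one is an error naming it.
#' @return A [Recording-class] in microvolts.
#' @export
readEdf <- function(path, channels = tenTwentyChannels()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rdChar <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  rdNum <- function(nc) as.numeric(rdChar(nc))
  rdChar(8)                       # version
  rdChar(80); rdChar(80)          # patient / recording id
  rdChar(8); rdChar(8)            # start date / time
  rdNum(8)                        # header bytes
  rdChar(44)                      # reserved
  nRec <- rdNum(8)
  recDur <- rdNum(8)
  ns <- as.integer(rdNum(4))
  fields <- function(nc) vapply(seq_len(ns), function(i) rdChar(nc), "")
  labels <- fields(16)
  fields(80); fields(8)           # transducer, physical dimension
  physMin <- as.numeric(fields(8))
  physMax <- as.numeric(fields(8))
  digMin <- as.numeric(fields(8))
  digMax <- as.numeric(fields(8))
  fields(80)                      # prefiltering
  nSamp <- as.integer(fields(8))
  fields(32)                      # reserved
  if (nRec < 0) stop("EDF file does not declare its record count")

  raw <- readBin(con, "integer", n = nRec * sum(nSamp), size = 2,
                 signed = TRUE, endian = "little")
  idxEnd <- cumsum(rep(nSamp, nRec))
  idxStart <- idxEnd - rep(nSamp, nRec) + 1L
  gain <- (physMax - physMin) / (digMax - digMin)
  sig <- vector("list", ns)
  for (s in seq_len(ns)) {
    pick <- unlist(lapply(seq_len(nRec), function(r) {
      off <- (r - 1L) * sum(nSamp)
      (off + idxStart[s]):(off + idxEnd[s])
    }))
    sig[[s]] <- physMin[s] + gain[s] * (raw[pick] - digMin[s])
  }

  norm <- normalizeChannelName(labels)
  want <- match(tolower(channels), norm)
  if (anyNA(want)) {
    miss <- channels[is.na(want)]
    stop("required channel(s) missing from EDF file: ",
         paste(miss, collapse = ", "))
  }
  if (length(unique(nSamp[want])) != 1L)
    stop("matched channels have mixed sampling rates")
  fs <- nSamp[want[1]] / recDur
  X <- do.call(rbind, sig[want])
  rownames(X) <- channels
  Recording(X, fs = fs, channelNames = channels, reference = "raw")
}

normalizeChannelName <- function(x) {
  x <- tolower(gsub("[[:space:]]", "", x))
  x <- sub("^eeg", "", x)
  x <- sub("-(ref|le|a1|a2|avg)$", "", x)
  x
}

#' Write a Recording or EegEpoch as a 16-bit EDF file
#'
#' Each channel is scaled to the 16-bit digital range over its own physical
#' range (padded slightly so the extremes are representable), one data
#' record per second. Quantisation error is therefore at most one digital
#' step of `(physMax - physMin) / 65535` per channel.
#'
#' @param x a [Recording-class] or [EegEpoch-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdf <- function(x, path) {
  X <- signals(x)
  fs <- samplingRate(x)
  ch <- channelNames(x)
  ns <- nrow(X)
  nSampRec <- as.integer(round(fs))           # 1 s data records
  if (ncol(X) %% nSampRec != 0)
    stop("signal length must be a whole number of 1 s records")
  nRec <- ncol(X) %/% nSampRec

  # integer physical bounds keep the 8-char EDF header fields exact
  physMin <- floor(apply(X, 1, min)) - 1
  physMax <- ceiling(apply(X, 1, max)) + 1
  digMin <- rep(-32768, ns)
  digMax <- rep(32767, ns)

  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(v, nc) {
    s <- sprintf("%-*s", nc, substr(as.character(v), 1, nc))
    writeChar(paste(s, collapse = ""), con, eos = NULL)
  }
  num <- function(v, nc) pad(formatC(v, format = "d"), nc)
  pad("0", 8)
  pad("synthetic", 80); pad("epidisc", 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  num(256 * (1 + ns), 8)
  pad("", 44)
  num(nRec, 8); num(1, 8); num(ns, 4)
  for (v in ch) pad(v, 16)
  for (v in rep("", ns)) pad(v, 80)
  for (v in rep("uV", ns)) pad(v, 8)
  for (v in physMin) num(v, 8)
  for (v in physMax) num(v, 8)
  for (v in digMin) num(v, 8)
  for (v in digMax) num(v, 8)
  for (v in rep("", ns)) pad(v, 80)
  for (v in rep(nSampRec, ns)) num(v, 8)
  for (v in rep("", ns)) pad(v, 32)

  gain <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * nSampRec + 1L):(r * nSampRec)
    for (s in seq_len(ns)) {
      d <- round(digMin[s] + gain[s] * (X[s, cols] - physMin[s]))
      writeBin(as.integer(pmin(pmax(d, digMin[s]), digMax[s])), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}
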