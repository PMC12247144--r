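#' Write / read a recording in BrainVision format
#'
#' Standard three-file BrainVision set: text header (`.vhdr`), text marker
#' file (`.vmrk`) carrying the event list, and binary data (`.eeg`) as
#' multiplexed IEEE float32 in microvolts (lossless round trip). Electrode
#' positions are not part of the format; pass a montage file alongside
#' (see [write_montage()]).
#'
#' @param rec an [eeg_recording()].
#' @param basename output path without extension.
#' @return `write_recording_brainvision`: the `.vhdr` path, invisibly.
#' @export
write_recording_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  stem <- basename(basename)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$srate, scientific = FALSE)),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$channel_names))
  writeLines(hdr, vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]",
          paste0("DataFile=", stem, ".eeg"),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (!is.null(rec$events) && nrow(rec$events))
    mk <- c(mk, sprintf("Mk%d=Stimulus,S %s,%d,1,0",
                        seq_len(nrow(rec$events)) + 1L,
                        rec$events$label, rec$events$onset + 1L))
  writeLines(mk, vmrk)
  con <- file(eeg, "wb")
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  close(con)
  invisible(vhdr)
}

#' @param vhdr path to the `.vhdr` header file.
#' @param positions optional n x 3 electrode positions to attach.
#' @rdname write_recording_brainvision
#' @return `read_recording_brainvision`: an [eeg_recording()].
#' @export
read_recording_brainvision <- function(vhdr, positions = NULL) {
  ln <- readLines(vhdr, warn = FALSE)
  get1 <- function(key) {
    v <- grep(paste0("^", key, "="), ln, value = TRUE)[1]
    sub(paste0("^", key, "="), "", v)
  }
  if (!identical(get1("DataFormat"), "BINARY") ||
      !identical(get1("DataOrientation"), "MULTIPLEXED") ||
      !identical(get1("BinaryFormat"), "IEEE_FLOAT_32"))
    stop("only multiplexed binary IEEE_FLOAT_32 BrainVision files are supported")
  nch <- as.integer(get1("NumberOfChannels"))
  srate <- 1e6 / as.numeric(get1("SamplingInterval"))
  chl <- grep("^Ch[0-9]+=", ln, value = TRUE)
  names_ <- vapply(strsplit(sub("^Ch[0-9]+=", "", chl), ","),
                   `[`, "", 1)[seq_len(nch)]
  dir <- dirname(vhdr)
  eeg <- file.path(dir, get1("DataFile"))
  con <- file(eeg, "rb")
  raw <- readBin(con, "numeric", n = file.size(eeg) / 4, size = 4,
                 endian = "little")
  close(con)
  data <- matrix(raw, nrow = nch)
  events <- NULL
  vmrk <- file.path(dir, get1("MarkerFile"))
  if (file.exists(vmrk)) {
    ml <- grep("^Mk[0-9]+=Stimulus", readLines(vmrk, warn = FALSE),
               value = TRUE)
    if (length(ml)) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
      events <- data.frame(
        label = sub("^S ?", "", vapply(parts, `[`, "", 2)),
        onset = as.integer(vapply(parts, `[`, "", 3)) - 1L)
    }
  }
  eeg_recording(data, srate, names_, positions, events)
}

#' Write / read a recording as EDF
#'
#' European Data Format with one-second data records and 16-bit samples.
#' Each channel is scaled to its own physical range, so the round trip is
#' lossy at the quantization level (range / 65535). The final partial
#' second, if any, is zero-padded. Events are not stored (use the JSON
#' sidecar, [write_events_json()]).
#'
#' @param rec an [eeg_recording()] with an integer sampling rate.
#' @param path output file path.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"), rec$srate == round(rec$srate))
  nch <- nrow(rec$data)
  spr <- as.integer(rec$srate)
  nrec <- ceiling(ncol(rec$data) / spr)
  pad <- nrec * spr - ncol(rec$data)
  data <- if (pad > 0) cbind(rec$data, matrix(0, nch, pad)) else rec$data
  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  pad8 <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  writeChar(paste0(
    pad8("0", 8), pad8("synthetic subject", 80), pad8("dryclean export", 80),
    "01.01.00", "00.00.00", pad8(256 * (nch + 1), 8), pad8("", 44),
    pad8(nrec, 8), pad8("1", 8), pad8(nch, 4),
    paste(pad8(substr(rec$channel_names, 1, 16), 16), collapse = ""),
    paste(rep(pad8("", 80), nch), collapse = ""),
    paste(rep(pad8("uV", 8), nch), collapse = ""),
    paste(pad8(sprintf("%.8g", pmin_) |> substr(1, 8), 8), collapse = ""),
    paste(pad8(sprintf("%.8g", pmax_) |> substr(1, 8), 8), collapse = ""),
    paste(rep(pad8("-32768", 8), nch), collapse = ""),
    paste(rep(pad8("32767", 8), nch), collapse = ""),
    paste(rep(pad8("", 80), nch), collapse = ""),
    paste(rep(pad8(spr, 8), nch), collapse = ""),
    paste(rep(pad8("", 32), nch), collapse = "")), con, eos = NULL)
  # headers store the *printed* physical range; quantize against the same
  pmin_p <- as.numeric(substr(sprintf("%.8g", pmin_), 1, 8))
  pmax_p <- as.numeric(substr(sprintf("%.8g", pmax_), 1, 8))
  scale <- (pmax_p - pmin_p) / 65535
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(nch)) {
      dig <- round((data[ch, cols] - pmin_p[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2,
               endian = "little")
    }
  }
  close(con)
  invisible(path)
}

#' @param positions optional electrode positions to attach.
#' @rdname write_recording_edf
#' @return `read_recording_edf`: an [eeg_recording()].
#' @export
read_recording_edf <- function(path, positions = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  nrec <- as.integer(rd(8)); recdur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  eeg_recording(data, spr[1] / recdur, labels, positions)
}

#' Event list sidecar (JSON)
#'
#' @param events data frame with `label` and `onset` (0-based samples).
#' @param path file path.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(events, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_events_json
#' @export
read_events_json <- function(path) jsonlite::fromJSON(path)

#' Export a decomposition or ground truth
#'
#' Labels and period tables go to JSON sidecars (text); the array payload
#' (mixing/sources or component matrices) is written at run time as an RDS
#' container next to it.
#'
#' @param dec an `eeg_ica`.
#' @param basename output path without extension.
#' @export
write_decomposition <- function(dec, basename) {
  jsonlite::write_json(list(labels = dec$labels,
                            n_components = dec$n_components,
                            channel_names = dec$channel_names),
                       paste0(basename, "_labels.json"), auto_unbox = FALSE)
  saveRDS(list(mixing = dec$mixing, sources = dec$sources,
               center = dec$center), paste0(basename, "_arrays.rds"))
  invisible(basename)
}

#' @param gt a ground-truth list from [generate_recording()].
#' @rdname write_decomposition
#' @export
write_ground_truth <- function(gt, basename) {
  jsonlite::write_json(gt$jump_periods, paste0(basename, "_periods.json"),
                       auto_unbox = FALSE, digits = NA)
  saveRDS(gt[c("clean", "artifact_components", "jumps")],
          paste0(basename, "_arrays.rds"))
  invisible(basename)
}
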