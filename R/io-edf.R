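# Minimal European Data Format (EDF) reader/writer, sufficient for two-channel
# EEG/EMG telemetry records: fixed-length ASCII header, 16-bit little-endian
# samples, one-second data records. Physical calibration follows the standard
# (digital range -32768..32767 mapped linearly onto the declared physical
# range), so round-trips are exact up to that quantization.

edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a polysomnography recording to an EDF file
#'
#' Channels are written as `EEG` and `EMG` in microvolts with one-second data
#' records. The start zeitgeber time and animal metadata travel in the
#' recording-identification field. The trace is truncated to a whole number of
#' seconds (EDF records are fixed-length).
#'
#' @param psg A [psg_recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polysomnography <- function(psg, path) {
  stopifnot(inherits(psg, "psg_recording"))
  sr <- psg$sampling_rate
  if (sr != round(sr)) stop("EDF writer requires an integer sampling rate")
  n_rec <- floor(length(psg$eeg) / sr)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  sig <- list(EEG = psg$eeg[seq_len(n_rec * sr)], EMG = psg$emg[seq_len(n_rec * sr)])
  ns <- 2L

  phys <- lapply(sig, function(x) {
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-1, 1)
    # pad so extremes stay strictly inside the digital range
    r + c(-1, 1) * diff(r) * 1e-4
  })

  con <- file(path, "wb")
  on.exit(close(con))
  recording_id <- sprintf("animal=%s genotype=%s startzt=%.6g",
                          psg$animal_id, psg$genotype, psg$start_zeitgeber_time)
  header <- paste0(
    edf_pad("0", 8),
    edf_pad("X", 80),
    edf_pad(recording_id, 80),
    edf_pad("01.01.26", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4))
  writeChar(header, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, character(1), width = width), collapse = ""),
              con, eos = NULL)
  }
  field(names(sig), 16)                                   # label
  field(rep("", ns), 80)                                  # transducer
  field(rep("uV", ns), 8)                                 # physical dimension
  field(vapply(phys, function(r) sprintf("%.8g", r[1]), character(1)), 8)
  field(vapply(phys, function(r) sprintf("%.8g", r[2]), character(1)), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                                  # prefiltering
  field(rep(sprintf("%d", as.integer(sr)), ns), 8)        # samples per record
  field(rep("", ns), 32)

  dig <- mapply(function(x, r) {
    as.integer(round((x - r[1]) / (r[2] - r[1]) * 65535 - 32768))
  }, sig, phys, SIMPLIFY = FALSE)
  for (rec in seq_len(n_rec)) {
    idx <- ((rec - 1) * sr + 1):(rec * sr)
    for (ch in seq_len(ns)) writeBin(dig[[ch]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a polysomnography recording from an EDF file
#'
#' Channels are mapped by label: exactly one channel whose label contains
#' `EEG` and one containing `EMG` must be present (case-insensitive).
#'
#' @param path EDF file path.
#' @return A [psg_recording].
#' @export
read_polysomnography <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80)
  recording_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)

  pick <- function(tag) {
    hit <- grep(tag, labels, ignore.case = TRUE)
    if (length(hit) != 1) {
      stop(sprintf("expected exactly one %s channel; labels found: %s",
                   tag, paste(labels, collapse = ", ")))
    }
    hit
  }
  i_eeg <- pick("EEG"); i_emg <- pick("EMG")

  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  chans <- vector("list", ns)
  offsets <- c(0, cumsum(spr))
  per_rec <- sum(spr)
  for (ch in seq_len(ns)) {
    idx <- unlist(lapply(seq_len(n_rec) - 1L, function(r) {
      r * per_rec + offsets[ch] + seq_len(spr[ch])
    }))
    x <- raw[idx]
    chans[[ch]] <- phys_min[ch] +
      (x - dig_min[ch]) / (dig_max[ch] - dig_min[ch]) * (phys_max[ch] - phys_min[ch])
  }
  if (spr[i_eeg] != spr[i_emg]) stop("EEG and EMG sampling rates differ")
  sr <- spr[i_eeg] / rec_dur

  get_tag <- function(tag, default) {
    m <- regmatches(recording_id,
                    regexec(paste0(tag, "=([^ ]+)"), recording_id))[[1]]
    if (length(m) == 2) m[2] else default
  }
  psg_recording(chans[[i_eeg]], chans[[i_emg]], sampling_rate = sr,
                start_zeitgeber_time = as.numeric(get_tag("startzt", "0")),
                animal_id = get_tag("animal", NA_character_),
                genotype = get_tag("genotype", NA_character_))
}
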