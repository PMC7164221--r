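# Minimal European Data Format (EDF) writer/reader: ASCII header plus 16-bit
# little-endian integer data records. One-second records; the true sample
# count is carried in the reserved header field so trailing record padding
# can be stripped on read.

edf_pad <- function(x, width) {
  x <- as.character(x)
  assert_that(nchar(x) <= width, "EDF header field too long: ", x)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(data, fs, channel_labels, path, subject = "X") {
  stopifnot(is.matrix(data))
  assert_that(abs(fs - round(fs)) < 1e-9, "EDF writer requires integer fs")
  fs <- round(fs)
  ns <- nrow(data)
  n <- ncol(data)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  if (pad > 0) data <- cbind(data, matrix(data[, n], nrow = ns, ncol = pad))

  phys_max <- apply(abs(data), 1, max)
  phys_max <- ifelse(phys_max <= 0, 1, phys_max * 1.0001)
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(subject, 80), edf_pad("gaitintent", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad(paste0("NS=", n), 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                     collapse = "")
  writeChar(paste0(
    fld(channel_labels, 16), fld(rep("", ns), 80), fld(rep("uV", ns), 8),
    fld(sprintf("%.6g", -phys_max), 8), fld(sprintf("%.6g", phys_max), 8),
    fld(rep(-dig_max, ns), 8), fld(rep(dig_max, ns), 8),
    fld(rep("", ns), 80), fld(rep(fs, ns), 8), fld(rep("", ns), 32)),
    con, eos = NULL)
  scale <- phys_max / dig_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round(data[, idx, drop = FALSE] / scale)
    block <- pmin(pmax(block, -dig_max), dig_max)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); subject <- rd(80); rec_id <- rd(80)
  rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  assert_that(!is.na(ns) && ns >= 1, "corrupt EDF header in ", path)
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  assert_that(length(unique(spr)) == 1, "mixed per-signal rates unsupported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      matrix(raw, nrow = ns, byrow = TRUE)
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_max - scale * dig_max
  data <- data * scale + offset
  if (grepl("^NS=", reserved)) {
    n_true <- as.integer(sub("^NS=", "", reserved))
    if (!is.na(n_true) && n_true <= ncol(data))
      data <- data[, seq_len(n_true), drop = FALSE]
  }
  list(data = data, fs = fs, channel_labels = labels, subject = subject)
}
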