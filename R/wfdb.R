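# Minimal WFDB support: text .hea headers, format 212 (the packed 12-bit
# format of the MIT-BIH Arrhythmia Database) and format 16 signal files, and
# MIT-format .atr annotation files. Only what the compression pipelines need:
# read one lead + beat annotations, and write a single-lead record for
# roundtrip testing. Annotation writing is out of scope.

# annotation type code -> display symbol (beat and non-beat codes)
.wfdb_symbols <- c("N","L","R","a","V","F","J","A","S","E","j","/","Q","~","",
                   "|","","s","T","*","D","\"","=","p","B","^","t","+","u","?",
                   "!","[","]","e","n","@","x","f","(",")","r")

wfdb_base <- function(path) sub("\\.(hea|dat|atr)$", "", path)

parse_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*", "", top[3] %||% "250"))
  n_samp <- as.integer(top[4])
  sig <- lapply(lines[1 + seq_len(n_sig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    fmt <- sub("x\\d+$|:\\d+$|\\+\\d+$", "", f[2])
    gain_spec <- f[3] %||% "200/mV"
    units <- if (grepl("/", gain_spec)) sub(".*/", "", gain_spec) else "mV"
    g <- sub("/.*", "", gain_spec)
    baseline <- if (grepl("\\(", g)) as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", g)) else NA
    gain <- as.numeric(sub("\\(.*", "", g))
    if (is.na(gain) || gain == 0) gain <- 200
    adc_res <- as.integer(f[4] %||% "12")
    adc_zero <- as.numeric(f[5] %||% "0")
    if (is.na(baseline)) baseline <- adc_zero
    list(file = f[1], format = fmt, gain = gain, baseline = baseline,
         units = units, adc_res = adc_res,
         description = paste(f[-seq_len(min(9, length(f)))], collapse = " "))
  })
  list(record = top[1], n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sig)
}

read_dat_212 <- function(path, n_values) {
  n_bytes <- (as.integer(ceiling(n_values / 2)) ) * 3L
  raw <- readBin(path, "raw", n = n_bytes)
  if (length(raw) < n_bytes)
    stop_cs("signal file %s truncated (%d of %d bytes)", path, length(raw), n_bytes,
            class = "cardiocs_io")
  b <- as.integer(raw)
  b1 <- b[seq(1, n_bytes, 3)]; b2 <- b[seq(2, n_bytes, 3)]; b3 <- b[seq(3, n_bytes, 3)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8)
  s2 <- b3 + bitwShiftL(bitwAnd(b2, 0xF0L), 4)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- integer(2L * length(s1))
  out[c(TRUE, FALSE)] <- s1
  out[c(FALSE, TRUE)] <- s2
  out[seq_len(n_values)]
}

read_dat_16 <- function(path, n_values) {
  v <- readBin(path, "integer", n = n_values, size = 2, signed = TRUE, endian = "little")
  if (length(v) < n_values) stop_cs("signal file %s truncated", path, class = "cardiocs_io")
  v
}

#' Read a WFDB record (header + signal + optional annotations)
#'
#' Supports signal formats 212 and 16. Digital samples are converted to
#' physical units via `(adc - baseline) / gain`. When a `.atr` annotation
#' file sits next to the record it is parsed and beat symbols are mapped to
#' the configured 8-class scheme; annotations whose symbol is absent from the
#' map are dropped (with a message). Annotation sample indices are 0-based
#' and pass through unchanged.
#'
#' @param path record path with or without extension (e.g. `"mitdb/100"`).
#' @param lead 1-based signal index to extract.
#' @param class_map named vector/list mapping annotation symbols to integer
#'   class ids, or a path to a YAML file with one `symbol: id` entry per
#'   line. Defaults to the map shipped in
#'   `system.file("extdata", "mitdb_class_map.yaml", package = "cardiocs")`.
#' @param annotator annotation file extension, default `"atr"`; `NULL` skips
#'   annotation reading.
#' @return an [ecg_record()].
#' @export
read_wfdb <- function(path, lead = 1L,
                      class_map = system.file("extdata", "mitdb_class_map.yaml",
                                              package = "cardiocs"),
                      annotator = "atr") {
  base <- wfdb_base(path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop_cs("no such header: %s", hea, class = "cardiocs_io")
  h <- parse_header(hea)
  if (lead < 1L || lead > h$n_sig)
    stop_cs("lead %d out of range (record has %d signals)", lead, h$n_sig,
            class = "cardiocs_bad_input")
  s <- h$signals[[lead]]
  dat <- file.path(dirname(hea), s$file)
  if (!file.exists(dat)) stop_cs("no such signal file: %s", dat, class = "cardiocs_io")
  n_values <- h$n_samp * h$n_sig
  all_dig <- switch(s$format,
    "212" = read_dat_212(dat, n_values),
    "16"  = read_dat_16(dat, n_values),
    stop_cs("unsupported WFDB format '%s'", s$format, class = "cardiocs_io"))
  dig <- all_dig[seq(lead, n_values, by = h$n_sig)]
  phys <- (dig - s$baseline) / s$gain

  ann <- NULL
  atr <- paste0(base, ".", annotator %||% "")
  if (!is.null(annotator) && file.exists(atr)) {
    a <- read_mit_annotations(atr)
    if (nrow(a)) {
      map <- load_class_map(class_map)
      cls <- unname(map[a$symbol])
      keep <- !is.na(cls)
      if (any(!keep))
        message(sprintf("read_wfdb: dropped %d annotations with unmapped symbols (%s)",
                        sum(!keep), paste(unique(a$symbol[!keep]), collapse = " ")))
      a <- a[keep, , drop = FALSE]
      if (nrow(a)) {
        inb <- a$sample >= 0 & a$sample < h$n_samp
        ann <- data.frame(r_index = a$sample[inb],
                          class_label = as.integer(cls[keep][inb]))
      }
    }
  }
  ecg_record(phys, fs = h$fs, bits_per_sample = s$adc_res,
             record_id = h$record, annotations = ann, units = s$units)
}

load_class_map <- function(class_map) {
  if (is.character(class_map) && length(class_map) == 1L && file.exists(class_map))
    class_map <- yaml::read_yaml(class_map)
  m <- unlist(class_map)
  if (is.null(names(m)) || !length(m))
    stop_cs("class map must be a named symbol -> class-id mapping",
            class = "cardiocs_bad_input")
  storage.mode(m) <- "integer"
  m
}

# MIT annotation format: a stream of 16-bit little-endian words; the high 6
# bits of each word are the type code, the low 10 bits the sample interval
# since the previous annotation. Codes 59-63 are pseudo-annotations (SKIP
# carries a 32-bit interval in the next two words, AUX a byte-counted string,
# NUM/SUB/CHN modify fields); code 0 with interval 0 terminates.
read_mit_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n <- length(raw) %/% 2L
  b1 <- as.integer(raw[seq(1, 2L * n, 2)])
  b2 <- as.integer(raw[seq(2, 2L * n, 2)])
  code <- bitwShiftR(b2, 2)
  interval <- bitwOr(bitwShiftL(bitwAnd(b2, 0x03L), 8), b1)
  time <- 0
  out_t <- integer(0); out_c <- integer(0)
  i <- 1L
  while (i <= n) {
    cd <- code[i]; iv <- interval[i]
    if (cd == 0L && iv == 0L) break
    if (cd == 59L) {            # SKIP: next two words = high then low 16 bits
      if (i + 2L > n) break
      hi <- bitwOr(bitwShiftL(b2[i + 1L], 8), b1[i + 1L])
      lo <- bitwOr(bitwShiftL(b2[i + 2L], 8), b1[i + 2L])
      time <- time + hi * 65536 + lo
      i <- i + 3L
    } else if (cd == 63L) {     # AUX: iv bytes of string, padded to even
      i <- i + 1L + (iv + iv %% 2L) %/% 2L
    } else if (cd %in% 60:62) { # NUM/SUB/CHN
      i <- i + 1L
    } else {
      time <- time + iv
      out_t <- c(out_t, time); out_c <- c(out_c, cd)
      i <- i + 1L
    }
  }
  sym <- ifelse(out_c >= 1L & out_c <= length(.wfdb_symbols),
                .wfdb_symbols[pmax(out_c, 1L)], "")
  data.frame(sample = out_t, code = out_c, symbol = sym,
             stringsAsFactors = FALSE)
}

#' Write a single-lead record in WFDB format 212
#'
#' Quantizes `record$samples` with gain 200 adu/mV and baseline 1024
#' (11-bit range), clamps to `[0, 2047]`, and emits `<id>.hea` / `<id>.dat`.
#' Annotation files are not written.
#'
#' @param record an [ecg_record()].
#' @param dir output directory.
#' @param gain ADC gain, adu per mV.
#' @param baseline ADC value corresponding to 0 mV.
#' @return the header path, invisibly.
#' @export
write_wfdb <- function(record, dir, gain = 200, baseline = 1024) {
  stopifnot(inherits(record, "ecg_record"))
  dig <- as.integer(pmin(2047, pmax(0, round(record$samples * gain + baseline))))
  n <- length(dig)
  id <- record$record_id
  dat_name <- paste0(id, ".dat")
  padded <- if (n %% 2L) c(dig, 0L) else dig
  s1 <- padded[c(TRUE, FALSE)]; s2 <- padded[c(FALSE, TRUE)]
  u1 <- ifelse(s1 < 0L, s1 + 4096L, s1); u2 <- ifelse(s2 < 0L, s2 + 4096L, s2)
  bytes <- as.raw(rbind(bitwAnd(u1, 0xFFL),
                        bitwOr(bitwShiftR(u1, 8), bitwShiftL(bitwShiftR(u2, 8), 4)),
                        bitwAnd(u2, 0xFFL)))
  writeBin(bytes, file.path(dir, dat_name))
  chk <- sum(dig) %% 65536L
  if (chk > 32767L) chk <- chk - 65536L
  hea <- c(sprintf("%s 1 %g %d", id, record$fs, n),
           sprintf("%s 212 %g(%g)/mV %d %g %d %d 0 MLII",
                   dat_name, gain, baseline, record$bits_per_sample,
                   baseline, dig[1], chk))
  writeLines(hea, file.path(dir, paste0(id, ".hea")))
  invisible(file.path(dir, paste0(id, ".hea")))
}
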