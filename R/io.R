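#' Read a mono WAV file
#'
#' Supports IEEE float32 and 8/16/24/32-bit integer PCM at any sampling
#' rate (192 kHz / 24-bit recordings included).  Multi-channel files are
#' refused; truncated or malformed files raise a parse error.
#'
#' @param path WAV file path.
#' @return a [SampledSignal-class] with samples in `[-1, 1]`.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) stop("truncated WAV file: ", path)
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      if (length(raw) < 16) stop("truncated fmt chunk in ", path)
      u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
      u32 <- function(i) sum(as.numeric(raw[i + 0:3]) * 256^(0:3))
      fmt <- list(code = u16(1), channels = u16(3), rate = u32(5),
                  bits = u16(15))
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
      if (length(dat) < sz) stop("truncated data chunk in ", path)
    } else {
      seek(con, sz + sz %% 2, origin = "current")
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat))
    stop("missing fmt or data chunk in ", path)
  if (fmt$channels != 1)
    stop("only mono WAV supported (file has ", fmt$channels, " channels)")
  x <- if (fmt$code == 3 && fmt$bits == 32) {
    readBin(dat, "double", length(dat) / 4, size = 4, endian = "little")
  } else if (fmt$code == 1 && fmt$bits == 16) {
    readBin(dat, "integer", length(dat) / 2, size = 2, signed = TRUE,
            endian = "little") / 2^15
  } else if (fmt$code == 1 && fmt$bits == 24) {
    n <- length(dat) %/% 3
    m <- matrix(as.integer(dat[seq_len(3 * n)]), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else if (fmt$code == 1 && fmt$bits == 32) {
    readBin(dat, "integer", length(dat) / 4, size = 4,
            endian = "little") / 2^31
  } else if (fmt$code == 1 && fmt$bits == 8) {
    (readBin(dat, "integer", length(dat), size = 1, signed = FALSE) -
       128) / 127
  } else stop("unsupported WAV encoding: format ", fmt$code, ", ",
              fmt$bits, " bits")
  sampledSignal(x, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param sig a [SampledSignal-class]; samples outside `[-1, 1]` are
#'   clipped for integer encodings.
#' @param path output path.
#' @param bitDepth `"float32"` (lossless round trip), `"pcm24"` or
#'   `"pcm16"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(sig, path, bitDepth = c("float32", "pcm24", "pcm16")) {
  bitDepth <- match.arg(bitDepth)
  x <- sig@samples
  n <- length(x)
  bytes <- switch(bitDepth, float32 = 4L, pcm24 = 3L, pcm16 = 2L)
  code <- if (bitDepth == "float32") 3L else 1L
  bits <- bytes * 8L
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sig@fs), con, 4, endian = "little")
  writeBin(as.integer(sig@fs * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4, endian = "little")
  if (bitDepth == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else if (bitDepth == "pcm16") {
    v <- as.integer(round(pmax(pmin(x, 1), -1) * (2^15 - 1)))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    v <- round(pmax(pmin(x, 1), -1) * (2^23 - 1))
    v <- ifelse(v < 0, v + 2^24, v)
    m <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(as.integer(m)), con)
  }
  invisible(path)
}

#' Write a signal as CSV (time, value)
#' @param sig a [SampledSignal-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSignalCsv <- function(sig, path) {
  t <- sig@t0 + (seq_along(sig@samples) - 1) / sig@fs
  utils::write.csv(data.frame(time_s = t, value = sig@samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a transfer function as CSV
#'
#' Columns `freq_hz, mag_db` and, for complex spectra, `re, im`.
#' @param tf a [TransferFunction-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTransferFunction <- function(tf, path) {
  df <- data.frame(freq_hz = tf@freq, mag_db = magnitudeDb(tf))
  if (is.complex(tf@values)) {
    df$re <- Re(tf@values); df$im <- Im(tf@values)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a transfer function from CSV
#' @param path CSV with `freq_hz` and either `re`/`im` or `mag_db`.
#' @return a [TransferFunction-class].
#' @export
readTransferFunction <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("re", "im") %in% names(df)))
    new("TransferFunction", freq = df$freq_hz,
        values = complex(real = df$re, imaginary = df$im),
        meta = list(type = "complex", scale = 1, label = basename(path)))
  else
    new("TransferFunction", freq = df$freq_hz, values = df$mag_db,
        meta = list(type = "magnitude_db", label = basename(path)))
}

#' Read an area function from CSV
#' @param path CSV with columns `x_mm`, `area_mm2`.
#' @return an [AreaFunction-class].
#' @export
readAreaFunction <- function(path) {
  df <- utils::read.csv(path)
  areaFunction(df$x_mm, df$area_mm2)
}

#' Read side branches from YAML
#'
#' The file holds a list of branches with fields `attach_x_mm`,
#' `length_mm`, `area_mm2` and optionally `closed_end` (default true).
#' @param path YAML path.
#' @return list of [SideBranch-class] objects.
#' @export
readSideBranches <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$branches)) y <- y$branches
  lapply(y, function(b)
    sideBranch(b$attach_x_mm, b$length_mm, b$area_mm2,
               if (is.null(b$closed_end)) TRUE else isTRUE(b$closed_end)))
}

#' Relative difference in percent, experimental convention
#'
#' `100 * (exp - num) / exp`: the signed relative deviation of a
#' simulated (numerical) value from the measured (experimental) one,
#' with the experimental value as denominator.
#'
#' @param num numerical (simulated) value(s).
#' @param exp experimental (measured) value(s).
#' @return percent difference(s).
#' @examples
#' relativeDifference(264, 283)  # 6.71
#' @export
relativeDifference <- function(num, exp) 100 * (exp - num) / exp

#' Formant comparison table
#'
#' Adds the per-formant relative difference (see [relativeDifference()])
#' to a table of simulated vs measured formant frequencies; the mean
#' absolute difference across all cells is attached as attribute
#' `meanAbsPct`.
#'
#' @param df data frame with columns `num_hz` and `exp_hz` (any id
#'   columns are carried through).
#' @return `df` with an extra `rel_diff_pct` column.
#' @export
formantComparisonTable <- function(df) {
  stopifnot(all(c("num_hz", "exp_hz") %in% names(df)))
  df$rel_diff_pct <- relativeDifference(df$num_hz, df$exp_hz)
  attr(df, "meanAbsPct") <- mean(abs(df$rel_diff_pct))
  df
}

#' Export a measurement/simulation report
#'
#' Writes every transfer function as CSV, the formant and trough tables,
#' and (when both simulated and measured formants are supplied) the
#' comparison table with per-formant relative differences.
#'
#' @param tfs named list of [TransferFunction-class] objects.
#' @param formants data frame of formants (e.g. from [findFormants()]),
#'   or a comparison data frame with `num_hz`/`exp_hz` columns.
#' @param troughs numeric vector of trough frequencies (or NULL).
#' @param dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
exportReport <- function(tfs, formants = NULL, troughs = NULL,
                         dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (nm in names(tfs)) {
    p <- file.path(dir, paste0("tf_", nm, ".csv"))
    writeTransferFunction(tfs[[nm]], p)
    written <- c(written, p)
  }
  if (!is.null(formants)) {
    if (all(c("num_hz", "exp_hz") %in% names(formants)))
      formants <- formantComparisonTable(formants)
    p <- file.path(dir, "formants.csv")
    utils::write.csv(formants, p, row.names = FALSE)
    written <- c(written, p)
  }
  if (!is.null(troughs)) {
    p <- file.path(dir, "troughs.csv")
    utils::write.csv(data.frame(trough_hz = troughs), p,
                     row.names = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}

#' Bundled piriform fossa geometries
#'
#' MRI-derived piriform sinus lengths and volumes for three professional
#' singers (a mezzo-soprano, a bari-tenor and a bass-baritone; five
#' vowels for the bass-baritone), shipped as plain CSV.  The
#' `antires_hz` column lists the published antiresonance frequencies for
#' cross-checking predictions.
#'
#' @return list with `geometries` (list of [PiriformGeometry-class]) and
#'   `table` (the raw data frame).
#' @export
piriformGeometries <- function() {
  p <- system.file("extdata", "piriform_geometries.csv",
                   package = "sweeptract", mustWork = TRUE)
  df <- utils::read.csv(p)
  gs <- lapply(seq_len(nrow(df)), function(i)
    piriformGeometry(df$length_mm[i], df$pv_cm3[i], df$vtv_cm3[i],
                     paste(df$singer[i], df$vowel[i], sep = " - ")))
  list(geometries = gs, table = df)
}

#' Bundled formant comparison data
#'
#' Simulated (FEM) versus measured formant frequencies F1-F5 for three
#' 3-D printed vocal tracts of the bass-baritone subject, shipped as
#' plain CSV.
#'
#' @return data frame with columns `vowel`, `formant`, `num_hz`,
#'   `exp_hz`.
#' @export
formantComparison <- function() {
  p <- system.file("extdata", "formant_comparison.csv",
                   package = "sweeptract", mustWork = TRUE)
  utils::read.csv(p)
}

#' Save / load a run configuration as YAML
#' @param cfg a [RunConfig-class].
#' @param path YAML path.
#' @return `path` (save) or a [RunConfig-class] (load).
#' @export
saveRunConfig <- function(cfg, path) {
  validObject(cfg)
  s <- cfg@sweep
  yaml::write_yaml(list(
    sweep = list(f1 = s@f1, f2 = s@f2, duration = s@duration, fs = s@fs,
                 f_env_lo = s@fEnvLo, f_env_hi = s@fEnvHi,
                 amplitude = s@amplitude),
    repeats = cfg@repeats, temperature_c = cfg@temperatureC,
    window_threshold_db = cfg@windowThresholdDb,
    output_dir = cfg@outputDir, log_level = cfg@logLevel), path)
  invisible(path)
}

#' @rdname saveRunConfig
#' @export
loadRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  s <- y$sweep
  runConfig(sweepSpec(s$f1, s$f2, s$duration, s$fs, s$f_env_lo,
                      s$f_env_hi, s$amplitude),
            repeats = y$repeats, temperatureC = y$temperature_c,
            windowThresholdDb = y$window_threshold_db,
            outputDir = y$output_dir, logLevel = y$log_level)
}
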