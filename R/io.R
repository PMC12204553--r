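fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a phase series to delimited text
#'
#' Single-column text file (header `phase`) of radians in \eqn{[0, 2\pi)},
#' written at full double precision so read/write round-trips to 1e-12.
#' Sampling metadata, when present, is recorded as a `# dt=` comment line.
#'
#' @param theta a [phase_series()] or numeric vector of wrapped angles.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phase_series <- function(theta, path) {
  values <- phase_values(theta)
  if (any(values < 0 | values >= TWO_PI)) stop("phases must lie in [0, 2*pi)")
  dt <- attr(theta, "dt")
  lines <- c(if (!is.null(dt)) sprintf("# dt=%s", fmt_num(dt)),
             "phase", fmt_num(values))
  writeLines(lines, path)
  invisible(path)
}

read_metadata_comment <- function(lines, key) {
  pat <- sprintf("^#\\s*%s=", key)
  hit <- grep(pat, lines)
  if (length(hit) == 0L) return(NULL)
  as.numeric(sub(pat, "", lines[hit[1L]]))
}

#' Read a phase series from delimited text
#'
#' Counterpart of [write_phase_series()]. Every value is validated to lie
#' in \eqn{[0, 2\pi)}; violations are reported with their line number.
#'
#' @param path input file path.
#' @return a [phase_series()].
#' @export
read_phase_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  dt <- read_metadata_comment(lines, "dt")
  body <- grep("^#", lines, invert = TRUE)
  if (length(body) < 2L || lines[body[1L]] != "phase")
    stop("malformed phase file (expected header 'phase'): ", path)
  data_lines <- body[-1L]
  values <- suppressWarnings(as.numeric(lines[data_lines]))
  bad <- which(is.na(values) | values < 0 | values >= TWO_PI)
  if (length(bad) > 0L)
    stop(sprintf("invalid phase (outside [0, 2*pi)) at line %d of %s",
                 data_lines[bad[1L]], path))
  phase_series(values, dt = dt)
}

#' Write a sampled signal to delimited text
#'
#' Single-column text (header `value`) preceded by a `# fs=` comment naming
#' the sampling rate. Missing samples (gap mask) are written as `NA`.
#'
#' @param x a [raw_signal()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path) {
  stopifnot(inherits(x, "raw_signal"))
  vals <- fmt_num(x$samples)
  if (!is.null(x$gap_mask)) vals[x$gap_mask] <- "NA"
  writeLines(c(sprintf("# fs=%s", fmt_num(x$fs)), "value", vals), path)
  invisible(path)
}

#' Read a sampled signal from delimited text
#'
#' Counterpart of [write_signal()]; `NA` entries become the gap mask.
#'
#' @param path input file path.
#' @param fs sampling rate override; required when the file carries no
#'   `# fs=` line.
#' @return a [raw_signal()].
#' @export
read_signal <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  fs <- fs %||% read_metadata_comment(lines, "fs")
  if (is.null(fs)) stop("sampling rate missing: no '# fs=' line in ", path,
                        " and no fs argument")
  body <- grep("^#", lines, invert = TRUE)
  if (length(body) < 2L || lines[body[1L]] != "value")
    stop("malformed signal file (expected header 'value'): ", path)
  data_lines <- body[-1L]
  raw_vals <- lines[data_lines]
  values <- suppressWarnings(as.numeric(raw_vals))
  bad <- which(is.na(values) & raw_vals != "NA")
  if (length(bad) > 0L)
    stop(sprintf("non-numeric sample at line %d of %s", data_lines[bad[1L]],
                 path))
  mask <- raw_vals == "NA"
  raw_signal(values, fs, gap_mask = if (any(mask)) mask else NULL)
}

#' Write per-sample binary labels
#'
#' @param labels 0/1 integer (or logical) vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (is.numeric(labels) && any(labels %% 1 != 0, na.rm = TRUE))
    stop("labels must be binary (0/1)")
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(!labels %in% c(0L, 1L)))
    stop("labels must be binary (0/1)")
  writeLines(c("label", as.character(labels)), path)
  invisible(path)
}

#' Read per-sample binary labels
#'
#' @param path input file path.
#' @return integer 0/1 vector.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L || lines[1L] != "label")
    stop("malformed labels file (expected header 'label'): ", path)
  vals <- lines[-1L]
  bad <- which(!vals %in% c("0", "1"))
  if (length(bad) > 0L)
    stop(sprintf("non-binary label at line %d of %s", bad[1L] + 1L, path))
  as.integer(vals)
}

#' Write an SDE path with its JSON sidecar
#'
#' The wrapped trajectories go to delimited text (one column per rhythm);
#' `dt`, `seed` and the model parameters go to `<path>.json`.
#'
#' @param path_obj an `"sde_path"` from [simulate_sde()].
#' @param path output file path for the trajectory table.
#' @return `path`, invisibly.
#' @export
write_sde_path <- function(path_obj, path) {
  stopifnot(inherits(path_obj, "sde_path"))
  m <- t(path_obj$phases)
  colnames(m) <- paste0("rhythm", seq_len(ncol(m)))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  sidecar <- list(dt = path_obj$dt, seed = path_obj$seed,
                  omega = path_obj$model$omega, sigma = path_obj$model$sigma,
                  coupling = path_obj$model$coupling)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an SDE path written by [write_sde_path()]
#'
#' @param path trajectory table path (its `.json` sidecar must sit beside
#'   it).
#' @return an `"sde_path"`.
#' @export
read_sde_path <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stop("missing sidecar: ", sidecar_path)
  m <- t(as.matrix(utils::read.csv(path)))
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  model <- sde_model(meta$omega, meta$sigma, coupling = meta$coupling)
  structure(list(phases = unname(wrap_matrix(m)), dt = meta$dt,
                 seed = meta$seed, model = model),
            class = "sde_path")
}

# ---- WFDB (read-only, formats 212 and 16) ---------------------------------

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  n_sig <- as.integer(rec[2L])
  fs <- if (length(rec) >= 3L) as.numeric(strsplit(rec[3L], "/")[[1L]][1L]) else 250
  n_samp <- if (length(rec) >= 4L) as.integer(rec[4L]) else NA_integer_
  sig <- lapply(lines[1L + seq_len(n_sig)], function(l) {
    f <- strsplit(trimws(l), "[ \t]+")[[1L]]
    gain_field <- f[3L]
    baseline <- NA_real_
    if (grepl("\\(", gain_field))
      baseline <- as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", gain_field))
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
    if (!is.finite(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5L) as.numeric(f[5L]) else 0
    if (!is.finite(baseline)) baseline <- adc_zero
    list(file = f[1L], format = sub("x.*|:.*|\\+.*", "", f[2L]),
         gain = gain, baseline = baseline,
         description = if (length(f) >= 9L)
           paste(f[9:length(f)], collapse = " ") else "")
  })
  list(record = rec[1L], n_sig = n_sig, fs = fs, n_samp = n_samp,
       signals = sig)
}

read_dat_212 <- function(path, n_sig, n_samp) {
  raw <- readBin(path, "raw", n = file.size(path))
  n_total <- n_sig * n_samp
  n_pairs <- ceiling(n_total / 2)
  b <- as.integer(raw[seq_len(3 * n_pairs)])
  b1 <- b[seq(1, length(b), by = 3)]
  b2 <- b[seq(2, length(b), by = 3)]
  b3 <- b[seq(3, length(b), by = 3)]
  s1 <- b1 + bitwAnd(b2, 15L) * 256L
  s2 <- b3 + bitwAnd(bitwShiftR(b2, 4L), 15L) * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  vals <- as.vector(rbind(s1, s2))[seq_len(n_total)]
  matrix(vals, nrow = n_sig)
}

read_dat_16 <- function(path, n_sig, n_samp) {
  vals <- readBin(path, "integer", n = n_sig * n_samp, size = 2L,
                  signed = TRUE, endian = "little")
  matrix(vals, nrow = n_sig)
}

#' Read a WFDB record (formats 212 and 16)
#'
#' Minimal read-only reader for PhysioNet WFDB records stored locally: the
#' `.hea` header is parsed for the layout and the signal file decoded, with
#' digital values converted to physical units as
#' `(digital - baseline) / gain`. The reader never touches the network; the
#' record files must already exist on disk.
#'
#' @param record path to the record without extension (e.g.
#'   `"data/mitdb/100"`); `<record>.hea` and the signal file it names must
#'   exist.
#' @param channels integer indices of the channels to return; default all.
#' @param n_samples optional truncation to the first `n_samples` samples.
#' @return a list of [raw_signal()] objects, one per requested channel,
#'   named by the header's signal descriptions.
#' @export
read_wfdb_record <- function(record, channels = NULL, n_samples = NULL) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop("no such WFDB header: ", hea)
  h <- parse_wfdb_header(hea)
  channels <- channels %||% seq_len(h$n_sig)
  if (any(channels < 1L | channels > h$n_sig))
    stop(sprintf("channel out of range: record has %d channel(s)", h$n_sig))
  dat_file <- file.path(dirname(hea), h$signals[[1L]]$file)
  if (!file.exists(dat_file)) stop("no such WFDB signal file: ", dat_file)
  fmt <- h$signals[[1L]]$format
  n_samp <- h$n_samp
  if (is.na(n_samp)) { # infer from the file size
    bytes <- file.size(dat_file)
    n_samp <- if (fmt == "212") floor(bytes * 2 / 3 / h$n_sig)
              else floor(bytes / 2 / h$n_sig)
  }
  digital <- switch(fmt,
                    "212" = read_dat_212(dat_file, h$n_sig, n_samp),
                    "16" = read_dat_16(dat_file, h$n_sig, n_samp),
                    stop("unsupported WFDB format: ", fmt))
  if (!is.null(n_samples)) {
    if (n_samples > ncol(digital)) stop("record shorter than n_samples")
    digital <- digital[, seq_len(n_samples), drop = FALSE]
  }
  out <- lapply(channels, function(ch) {
    s <- h$signals[[ch]]
    raw_signal((digital[ch, ] - s$baseline) / s$gain, h$fs)
  })
  names(out) <- vapply(h$signals[channels], function(s)
    if (nzchar(s$description)) s$description else s$file, character(1L))
  out
}

#' Write a JSON provenance/result block
#'
#' Every command-line run records its configuration, seed and package
#' version beside its results, so identical provenance reproduces stochastic
#' outputs bit-identically.
#'
#' @param results named list of results (numbers, vectors, nested lists).
#' @param path output `.json` path.
#' @param config named list of run configuration values.
#' @param seed the run seed (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_result_json <- function(results, path, config = list(), seed = NULL) {
  block <- list(results = results,
                provenance = list(
                  package = "circsde",
                  version = as.character(utils::packageVersion("circsde")),
                  seed = seed, config = config,
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(block, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
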