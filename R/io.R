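#' Multi-lead ECG record
#'
#' A single labelled record: a `[n_leads x T]` signal matrix in millivolts,
#' its sampling rate, ordered lead names, and the coarse/fine label pair.
#'
#' @param signal Numeric matrix `[n_leads x T]`, finite, `n_leads >= 2`.
#' @param fs Sampling rate (Hz).
#' @param lead_names Character vector of length `n_leads`.
#' @param task1,task2 Coarse and fine labels; `task1` must be the family of
#'   `task2` under the taxonomy.
#' @param record_id Identifier string.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, lead_names, task1, task2, record_id) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 2) stopf("a record needs at least 2 leads")
  if (ncol(signal) < 1) stopf("a record needs at least 1 sample")
  if (length(lead_names) != nrow(signal)) {
    stopf("lead_names length must equal the number of signal rows")
  }
  if (!all(is.finite(signal))) stopf("signal contains non-finite values")
  label_pair(task1, task2)
  rownames(signal) <- lead_names
  structure(
    list(signal = signal, fs = fs, lead_names = lead_names,
         labels = list(task1 = task1, task2 = task2),
         record_id = record_id),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d leads x %d samples @ %g Hz, %s/%s>\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              x$labels$task1, x$labels$task2))
  invisible(x)
}

#' Labelled ECG dataset
#'
#' A list of [ecg_record()]s sharing sampling rate and lead set, with a
#' tibble manifest (`record_id`, `task1`, `task2`, `seed`).
#'
#' @param records List of `ecg_record`s.
#' @param manifest Optional manifest tibble; rebuilt from the records when
#'   omitted (the `seed` column is then `NA`).
#' @return An object of class `ecg_dataset`.
#' @export
ecg_dataset <- function(records, manifest = NULL) {
  if (length(records) < 1) stopf("dataset must contain at least one record")
  fs <- unique(vapply(records, function(r) r$fs, numeric(1)))
  if (length(fs) != 1) stopf("all records must share one sampling rate")
  leads <- unique(vapply(records, function(r) paste(r$lead_names, collapse = ","),
                         character(1)))
  if (length(leads) != 1) stopf("all records must share one lead set")
  if (is.null(manifest)) {
    manifest <- tibble::tibble(
      record_id = vapply(records, function(r) r$record_id, character(1)),
      task1 = vapply(records, function(r) r$labels$task1, character(1)),
      task2 = vapply(records, function(r) r$labels$task2, character(1)),
      seed = NA_real_
    )
  }
  structure(
    list(records = records, manifest = tibble::as_tibble(manifest),
         fs = fs, lead_names = records[[1]]$lead_names),
    class = "ecg_dataset"
  )
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset: %d records, %d leads @ %g Hz>\n",
              length(x$records), length(x$lead_names), x$fs))
  print(dplyr::count(x$manifest, .data$task1, .data$task2))
  invisible(x)
}

#' @export
length.ecg_dataset <- function(x) length(x$records)

#' Write a dataset to a plain-text directory container
#'
#' Layout: `meta.json` (sampling rate, lead names, record count),
#' `manifest.csv` (record_id, task1, task2, seed), and one
#' `signals/<record_id>.csv` per record with one column per lead.
#'
#' @param dataset An [ecg_dataset()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "ecg_dataset"))
  dir.create(file.path(path, "signals"), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(fs = dataset$fs, lead_names = dataset$lead_names,
         n_records = length(dataset$records), format = "leadwise-ecg-v1"),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  data.table::fwrite(dataset$manifest, file.path(path, "manifest.csv"))
  for (r in dataset$records) {
    dt <- data.table::as.data.table(t(r$signal))
    data.table::setnames(dt, r$lead_names)
    data.table::fwrite(dt, file.path(path, "signals", paste0(r$record_id, ".csv")))
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates the container schema and the label hierarchy of every manifest
#' row; a coarse label that is not the family of its fine label is a hard
#' error.
#'
#' @param path Container directory.
#' @return An [ecg_dataset()].
#' @export
read_dataset <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stopf("not a dataset container: missing meta.json")
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (!identical(meta$format, "leadwise-ecg-v1")) {
    stopf("unrecognised container format: %s", meta$format %||% "<missing>")
  }
  manifest <- tibble::as_tibble(data.table::fread(
    file.path(path, "manifest.csv"),
    colClasses = list(character = c("record_id", "task1", "task2"))
  ))
  need <- c("record_id", "task1", "task2", "seed")
  if (!all(need %in% names(manifest))) stopf("manifest missing required columns")
  manifest$seed <- as.numeric(manifest$seed)
  for (i in seq_len(nrow(manifest))) {
    label_pair(manifest$task1[i], manifest$task2[i])
  }
  records <- purrr::pmap(
    manifest[, c("record_id", "task1", "task2")],
    function(record_id, task1, task2) {
      f <- file.path(path, "signals", paste0(record_id, ".csv"))
      if (!file.exists(f)) stopf("missing signal file for record %s", record_id)
      dt <- data.table::fread(f)
      if (!identical(names(dt), as.character(meta$lead_names))) {
        stopf("signal columns of %s do not match container lead names", record_id)
      }
      ecg_record(t(as.matrix(dt)), fs = meta$fs, lead_names = meta$lead_names,
                 task1 = task1, task2 = task2, record_id = record_id)
    }
  )
  ecg_dataset(records, manifest = manifest)
}

#' Write one record as a WFDB record (format 16)
#'
#' Emits the standard two-file WFDB layout: a text header
#' (`<record>.hea`) and a little-endian 16-bit signal file
#' (`<record>.dat`, samples interleaved across leads) with a fixed gain of
#' 1000 ADC units per millivolt.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory.
#' @param gain ADC units per millivolt.
#' @return Base path of the written record, invisibly.
#' @export
write_wfdb <- function(record, dir, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_sig <- nrow(record$signal)
  n_samp <- ncol(record$signal)
  base <- record$record_id
  adc <- round(record$signal * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  hea <- c(
    sprintf("%s %d %g %d", base, n_sig, record$fs, n_samp),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
            base, gain, adc[, 1], record$lead_names)
  )
  writeLines(hea, file.path(dir, paste0(base, ".hea")))
  con <- file(file.path(dir, paste0(base, ".dat")), "wb")
  on.exit(close(con))
  # column-major interleave: sample 1 of every lead, then sample 2, ...
  writeBin(as.integer(adc), con, size = 2, endian = "little")
  invisible(file.path(dir, base))
}

#' Read a WFDB format-16 record written by [write_wfdb()]
#'
#' @param base Path to the record without extension.
#' @param task1,task2 Labels to attach (WFDB headers carry none).
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(base, task1 = "N", task2 = "N") {
  hea <- readLines(paste0(base, ".hea"))
  head_fields <- strsplit(hea[1], " +")[[1]]
  n_sig <- as.integer(head_fields[2])
  fs <- as.numeric(head_fields[3])
  n_samp <- as.integer(head_fields[4])
  sig_lines <- strsplit(hea[1 + seq_len(n_sig)], " +")
  gains <- vapply(sig_lines, function(f) as.numeric(sub("\\(.*$", "", f[3])),
                  numeric(1))
  leads <- vapply(sig_lines, function(f) f[length(f)], character(1))
  con <- file(paste0(base, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n_sig * n_samp, size = 2,
                 endian = "little", signed = TRUE)
  adc <- matrix(raw, nrow = n_sig)  # column-major interleave
  signal <- adc / gains
  ecg_record(signal, fs = fs, lead_names = leads,
             task1 = task1, task2 = task2,
             record_id = basename(base))
}

#' Select and reorder leads
#'
#' Returns the record or dataset restricted to `lead_names`, in the
#' requested order; labels are unchanged. Standard presets used for
#' lead-count experiments are the 3-lead limb set I, II, III and the 8-lead
#' basic set II, III, V1-V6.
#'
#' @param x An [ecg_record()] or [ecg_dataset()].
#' @param lead_names At least two names, all present in `x`.
#' @return Object of the same class with the lead subset.
#' @export
select_leads <- function(x, lead_names) UseMethod("select_leads")

#' @export
select_leads.ecg_record <- function(x, lead_names) {
  if (length(lead_names) < 2) stopf("at least 2 leads must be selected")
  missing_leads <- setdiff(lead_names, x$lead_names)
  if (length(missing_leads) > 0) {
    stopf("lead(s) not present: %s", paste(missing_leads, collapse = ", "))
  }
  x$signal <- x$signal[match(lead_names, x$lead_names), , drop = FALSE]
  x$lead_names <- lead_names
  x
}

#' @export
select_leads.ecg_dataset <- function(x, lead_names) {
  records <- purrr::map(x$records, select_leads, lead_names = lead_names)
  ecg_dataset(records, manifest = x$manifest)
}

#' Named lead presets for lead-count experiments
#' @return Named list of lead-name vectors.
#' @export
lead_presets <- function() {
  list(
    `3-lead` = c("I", "II", "III"),
    `8-lead` = c("II", "III", "V1", "V2", "V3", "V4", "V5", "V6"),
    `12-lead` = standard_leads()
  )
}

#' Reduce a record to a fixed-length input window
#'
#' Policy `"crop-center"` keeps the centred `l_win` samples, zero-padding
#' symmetrically when the record is shorter; policy `"decimate"` resamples
#' the full record to `l_win` samples by linear interpolation on a uniform
#' grid. Both are deterministic. Windows use 0-based, half-open sample
#' coordinates: for `T = 5000` and `l_win = 1900`, crop-center keeps
#' columns 1550..3449.
#'
#' @param record An [ecg_record()].
#' @param l_win Target length in samples.
#' @param policy `"decimate"` (default) or `"crop-center"`.
#' @return Numeric matrix `[n_leads x l_win]`.
#' @export
window_record <- function(record, l_win = 1900,
                          policy = c("decimate", "crop-center")) {
  stopifnot(inherits(record, "ecg_record"))
  if (l_win < 1) stopf("l_win must be at least 1")
  policy <- match.arg(policy)
  x <- record$signal
  n <- ncol(x)
  if (policy == "crop-center") {
    if (n == l_win) return(x)
    if (n > l_win) {
      start <- floor((n - l_win) / 2)          # 0-based start
      return(x[, start + seq_len(l_win), drop = FALSE])
    }
    out <- matrix(0, nrow = nrow(x), ncol = l_win,
                  dimnames = list(rownames(x), NULL))
    start <- floor((l_win - n) / 2)
    out[, start + seq_len(n)] <- x
    return(out)
  }
  # decimate: uniform resampling of [0, n-1] onto l_win points
  if (n == l_win) return(x)
  grid <- seq(0, n - 1, length.out = l_win)
  t(apply(x, 1, function(row) stats::approx(0:(n - 1), row, xout = grid)$y))
}

#' Split a dataset into shuffled fixed-size batches
#'
#' Every record appears exactly once per epoch; the final partial batch is
#' kept. Shuffling is deterministic under `seed`.
#'
#' @param dataset An [ecg_dataset()].
#' @param m Batch size, at least 1.
#' @param l_win,policy Windowing passed to [window_record()].
#' @param shuffle Shuffle record order first?
#' @param seed Seed for the shuffle (required when `shuffle = TRUE`).
#' @return List of batches; each batch is a list with `inputs` (array
#'   `[m_b x n_leads x l_win]`), `labels1`, `labels2`, `record_ids`.
#' @export
make_batches <- function(dataset, m = 32, l_win = 1900,
                         policy = "decimate", shuffle = TRUE, seed = NULL) {
  stopifnot(inherits(dataset, "ecg_dataset"))
  if (m < 1) stopf("batch size must be at least 1")
  n <- length(dataset$records)
  if (n == 0) stopf("dataset is empty")
  order_idx <- seq_len(n)
  if (shuffle) {
    if (is.null(seed)) stopf("seed is required when shuffle = TRUE")
    order_idx <- with_seed(seed, sample.int(n))
  }
  windowed <- purrr::map(dataset$records, window_record,
                         l_win = l_win, policy = policy)
  starts <- seq(1, n, by = m)
  purrr::map(starts, function(s) {
    idx <- order_idx[s:min(s + m - 1, n)]
    mb <- length(idx)
    n_leads <- nrow(windowed[[1]])
    inputs <- array(0, dim = c(mb, n_leads, l_win))
    for (j in seq_along(idx)) inputs[j, , ] <- windowed[[idx[j]]]
    list(
      inputs = inputs,
      labels1 = vapply(dataset$records[idx], function(r) r$labels$task1, character(1)),
      labels2 = vapply(dataset$records[idx], function(r) r$labels$task2, character(1)),
      record_ids = vapply(dataset$records[idx], function(r) r$record_id, character(1))
    )
  })
}
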