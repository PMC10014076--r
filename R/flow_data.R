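#' Read a list-mode FCS 3.0/3.1 file
#'
#' Minimal reader for list-mode flow cytometry standard files as written by
#' common acquisition software: parses the HEADER and TEXT segments, then the
#' DATA segment for datatypes F (float), D (double) and I (unsigned integer,
#' 16/32 bit). Log-amplified parameters (keyword `$PnE = "decades,offset"`)
#' are converted back to linear fluorescence via
#' `offset * 10^(decades * x / range)`; linear parameters with a gain
#' (`$PnG`) are divided by the gain. No compensation or gating is applied.
#'
#' @param path path to an FCS 3.0 or 3.1 file.
#' @return an `event_table`: list with `sample_id` (file name), `channels`
#'   (ordered channel names from `$PnN`), `events` (numeric matrix, rows =
#'   cells, columns = channels) and `metadata` (all TEXT-segment keywords).
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header, type = "bytes") < 58L) {
    stop("format error: truncated FCS header at byte offset ",
         nchar(header, type = "bytes"))
  }
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version: '", version, "' (only FCS3.0/FCS3.1)")
  }
  off <- function(a, b) {
    v <- suppressWarnings(as.numeric(trimws(substr(header, a, b))))
    if (is.na(v)) stop("format error: bad offset field at byte offset ", a - 1)
    v
  }
  text_begin <- off(11, 18); text_end <- off(19, 26)
  data_begin <- off(27, 34); data_end <- off(35, 42)

  fsize <- file.size(path)
  if (text_end >= fsize) {
    stop("format error: TEXT segment end ", text_end,
         " beyond file size at byte offset ", fsize)
  }
  seek(con, text_begin)
  raw_text <- readBin(con, "raw", n = text_end - text_begin + 1)
  delim <- rawToChar(raw_text[1])
  body <- rawToChar(raw_text[-1])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  meta <- stats::setNames(as.list(vals), trimws(keys))

  kw <- function(name, required = TRUE) {
    v <- meta[[name]]
    if (is.null(v) && required) stop("format error: missing keyword ", name)
    v
  }
  if (data_begin == 0 || data_end == 0) {
    data_begin <- as.numeric(kw("$BEGINDATA"))
    data_end <- as.numeric(kw("$ENDDATA"))
  }
  n_par <- as.integer(kw("$PAR"))
  n_tot <- as.integer(kw("$TOT"))
  dtype <- toupper(kw("$DATATYPE"))
  byteord <- kw("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  mode <- toupper(kw("$MODE", required = FALSE) %||% "L")
  if (mode != "L") stop("unsupported FCS mode: ", mode, " (list mode only)")

  bits <- vapply(seq_len(n_par),
                 function(i) as.integer(kw(sprintf("$P%dB", i))), integer(1))
  names_pn <- vapply(seq_len(n_par), function(i) {
    v <- kw(sprintf("$P%dN", i), required = FALSE)
    if (is.null(v)) sprintf("P%d", i) else v
  }, character(1))

  if (dtype %in% c("F", "D")) {
    size <- if (dtype == "F") 4L else 8L
    if (any(bits != size * 8L)) stop("format error: $PnB inconsistent with $DATATYPE")
    what <- "double"
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1L || !bits[1] %in% c(16L, 32L)) {
      stop("unsupported integer width: $PnB must be uniformly 16 or 32")
    }
    size <- bits[1] / 8L
    what <- "integer"
  } else {
    stop("unsupported $DATATYPE: ", dtype)
  }

  expected_bytes <- n_par * n_tot * size
  avail <- data_end - data_begin + 1
  if (avail < expected_bytes || fsize < data_begin + expected_bytes) {
    stop("format error: DATA segment holds ", max(avail, 0), " bytes but ",
         expected_bytes, " expected ($TOT x $PAR) at byte offset ", data_begin)
  }
  seek(con, data_begin)
  vals <- readBin(con, what, n = n_par * n_tot, size = size,
                  endian = endian, signed = size > 2)
  if (length(vals) < n_par * n_tot) {
    stop("format error: truncated DATA segment at byte offset ",
         data_begin + length(vals) * size)
  }
  ev <- matrix(as.numeric(vals), nrow = n_tot, ncol = n_par, byrow = TRUE)

  # amplification: $PnE "decades,offset" with decades > 0 means the stored
  # value is log-amplified over $PnR channels; $PnG is a linear gain
  for (i in seq_len(n_par)) {
    pe <- kw(sprintf("$P%dE", i), required = FALSE)
    if (!is.null(pe)) {
      de <- suppressWarnings(as.numeric(strsplit(pe, ",")[[1]]))
      if (length(de) == 2 && !anyNA(de) && de[1] > 0) {
        r <- as.numeric(kw(sprintf("$P%dR", i)))
        o <- if (de[2] == 0) 1 else de[2]
        ev[, i] <- o * 10^(de[1] * ev[, i] / r)
        next
      }
    }
    pg <- kw(sprintf("$P%dG", i), required = FALSE)
    if (!is.null(pg)) {
      g <- suppressWarnings(as.numeric(pg))
      if (!is.na(g) && g > 0 && g != 1) ev[, i] <- ev[, i] / g
    }
  }
  colnames(ev) <- names_pn
  event_table(sample_id = basename(path), channels = names_pn,
              events = ev, metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample event table
#'
#' @param sample_id character identifier.
#' @param channels ordered character vector of channel names.
#' @param events numeric matrix, rows = cells, columns = channels.
#' @param metadata named list of acquisition keywords.
#' @return an object of class `event_table`.
#' @export
event_table <- function(sample_id, channels, events, metadata = list()) {
  events <- as.matrix(events)
  if (ncol(events) != length(channels)) {
    stop("number of event columns (", ncol(events),
         ") must equal number of channel names (", length(channels), ")")
  }
  colnames(events) <- channels
  structure(list(sample_id = as.character(sample_id),
                 channels = as.character(channels),
                 events = events, metadata = metadata),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", x$sample_id, ": ", nrow(x$events), " events x ",
      length(x$channels), " channels (", paste(x$channels, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Read per-cell events from a delimited text file
#'
#' One row per cell, header row naming the channels, comma-delimited.
#'
#' @param path path to the CSV file.
#' @param channel_columns character vector of column names to keep as
#'   channels.
#' @return an `event_table` over the requested columns.
#' @export
read_events_csv <- function(path, channel_columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(channel_columns, names(df))
  if (length(missing) > 0) {
    stop("schema error: missing channel column(s): ",
         paste(missing, collapse = ", "))
  }
  ev <- matrix(NA_real_, nrow = nrow(df), ncol = length(channel_columns))
  for (k in seq_along(channel_columns)) {
    col <- df[[channel_columns[k]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      stop("parse error: non-numeric value in column '", channel_columns[k],
           "' at data row ", bad[1])
    }
    ev[, k] <- num
  }
  event_table(sample_id = basename(path), channels = channel_columns,
              events = ev)
}

#' Transform fluorescence intensities
#'
#' Reporter fluorescence spans decades, so analysis is done on a compressive
#' scale. `log10_floor` replaces values <= 0 by half the smallest positive
#' value in the collection before taking log10 (a deterministic, scale-free
#' floor); `arcsinh` applies `asinh(v / cofactor)`; `identity` returns the
#' values unchanged.
#'
#' @param values numeric vector of finite intensities.
#' @param method one of `"log10_floor"`, `"arcsinh"`, `"identity"`.
#' @param cofactor positive real, required for `arcsinh`.
#' @return numeric vector of the same length.
#' @export
transform_intensity <- function(values,
                                method = c("log10_floor", "arcsinh", "identity"),
                                cofactor = NULL) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  switch(method,
    identity = values,
    arcsinh = {
      if (is.null(cofactor) || !is.finite(cofactor) || cofactor <= 0) {
        stop("arcsinh requires a positive cofactor")
      }
      asinh(values / cofactor)
    },
    log10_floor = {
      pos <- values[values > 0]
      if (length(pos) == 0) {
        stop("degenerate input: no positive values for log10_floor")
      }
      floor_val <- min(pos) / 2
      log10(pmax(values, floor_val))
    }
  )
}

#' Validate a sample sheet
#'
#' A sample sheet maps each acquired sample to its experimental condition:
#' columns `sample_id, receptor, ligand, dose, dose_unit, replicate,
#' stimulation_hours, output_channel`.
#'
#' @param sheet data.frame with the columns above.
#' @return the sheet, with types coerced, invisibly checked.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "receptor", "ligand", "dose", "dose_unit",
                "replicate", "stimulation_hours", "output_channel")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  }
  sheet$dose <- as.numeric(sheet$dose)
  sheet$replicate <- as.integer(sheet$replicate)
  sheet$stimulation_hours <- as.numeric(sheet$stimulation_hours)
  if (any(sheet$dose < 0) || anyNA(sheet$dose)) {
    stop("doses must be non-negative reals")
  }
  if (any(sheet$replicate < 1L) || anyNA(sheet$replicate)) {
    stop("replicate must be an integer >= 1")
  }
  if (any(sheet$stimulation_hours <= 0) || anyNA(sheet$stimulation_hours)) {
    stop("stimulation_hours must be positive")
  }
  key <- paste(sheet$receptor, sheet$ligand, sheet$replicate, sheet$dose,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplication error: repeated (receptor, ligand, replicate, dose)")
  }
  sheet
}

#' Assemble dose-response datasets from event tables and a sample sheet
#'
#' Groups sample-sheet rows by condition (receptor x ligand x replicate),
#' pulls the declared output channel out of each event table, applies the
#' output transform across the condition's pooled events (so the
#' `log10_floor` floor is computed per dataset), and returns one
#' `dose_response_dataset` per condition with doses sorted ascending.
#'
#' @param sheet sample sheet data.frame (see [validate_sample_sheet()]).
#' @param tables named list mapping `sample_id` to `event_table`.
#' @param transform list with `method` and optional `cofactor`; see
#'   [transform_intensity()]. Default log10 with floor.
#' @return named list of `dose_response_dataset`, names
#'   `"receptor/ligand/repN"`.
#' @export
assemble_dataset <- function(sheet, tables,
                             transform = list(method = "log10_floor")) {
  sheet <- validate_sample_sheet(sheet)
  unresolved <- setdiff(unique(sheet$sample_id), names(tables))
  if (length(unresolved) > 0) {
    stop("linkage error: sample sheet references absent sample(s): ",
         paste(unresolved, collapse = ", "))
  }
  cond_key <- paste(sheet$receptor, sheet$ligand, sheet$replicate, sep = "\r")
  out <- list()
  for (key in unique(cond_key)) {
    rows <- sheet[cond_key == key, , drop = FALSE]
    raw <- vector("list", nrow(rows))
    for (r in seq_len(nrow(rows))) {
      tab <- tables[[rows$sample_id[r]]]
      ch <- rows$output_channel[r]
      if (!ch %in% tab$channels) {
        stop("linkage error: output channel '", ch, "' absent from sample ",
             rows$sample_id[r])
      }
      v <- tab$events[, ch]
      if (length(v) == 0) stop("empty event table for sample ",
                               rows$sample_id[r])
      raw[[r]] <- as.numeric(v)
    }
    # transform on the pooled values so the floor is per-dataset
    pooled <- transform_intensity(unlist(raw), method = transform$method,
                                  cofactor = transform$cofactor)
    lens <- vapply(raw, length, integer(1))
    split_idx <- rep(seq_along(raw), lens)
    transformed <- split(pooled, split_idx)
    ds <- dose_response_dataset(
      doses = rows$dose, outputs = unname(transformed),
      receptor = rows$receptor[1], ligand = rows$ligand[1],
      replicate = rows$replicate[1],
      transform_tag = transform$method,
      dose_unit = rows$dose_unit[1]
    )
    out[[paste0(rows$receptor[1], "/", rows$ligand[1], "/rep",
                rows$replicate[1])]] <- ds
  }
  out
}

#' Geometric mean and robust SD of a cell population
#'
#' Populations are summarized as geometric mean with a multiplicative robust
#' SD: `exp(mean(log v))` and `exp(1.4826 * MAD(log v))`, the scaled median
#' absolute deviation on the log scale reported as a fold factor.
#'
#' @param values positive numeric vector (raw fluorescence or molecule
#'   counts).
#' @return list with `geometric_mean` and `robust_sd` (multiplicative
#'   factor, >= 1).
#' @export
summarize_population <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty population")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("domain error: values must be positive for geometric summaries")
  }
  lv <- log(values)
  list(geometric_mean = exp(mean(lv)),
       robust_sd = exp(stats::mad(lv)))  # mad() already scales by 1.4826
}

#' Fit a bead calibration of fluorescence to molecule counts
#'
#' Quantitation beads provide standards of known molecules per bead; a
#' least-squares line on log10(FI) vs log10(molecules) converts arbitrary
#' fluorescence into molecule numbers.
#'
#' @param standards data.frame with columns `measured_fi` and `molecules`,
#'   both positive; at least two standards.
#' @return object of class `bead_calibration` with `slope`, `intercept`
#'   (log10 scale) and the standards.
#' @export
bead_calibration <- function(standards) {
  if (!all(c("measured_fi", "molecules") %in% names(standards))) {
    stop("standards need columns measured_fi and molecules")
  }
  if (nrow(standards) < 2) stop("fit error: at least 2 standards required")
  if (any(standards$measured_fi <= 0) || any(standards$molecules <= 0)) {
    stop("domain error: standards must be positive")
  }
  fit <- stats::lm(log10(molecules) ~ log10(measured_fi), data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope)) stop("fit error: calibration slope not finite")
  structure(list(standards = standards, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 fit_scale = "log-log"),
            class = "bead_calibration")
}

#' Convert fluorescence intensities to molecule counts
#'
#' @param cal a [bead_calibration()].
#' @param values positive numeric vector of fluorescence intensities.
#' @return numeric vector of predicted molecule counts (monotone in the
#'   input for a positive calibration slope).
#' @export
calibrate_fi_to_molecules <- function(cal, values) {
  stopifnot(inherits(cal, "bead_calibration"))
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("domain error: fluorescence values must be positive")
  }
  10^(cal$intercept + cal$slope * log10(values))
}
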