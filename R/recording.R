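# Recording container and delimited-text IO.

#' Construct a recording
#'
#' A uniformly sampled multichannel current-clamp recording: per-neuron
#' membrane voltages and injected currents, optional ground-truth component
#' currents (used for validation only, never for training), and metadata.
#'
#' @param delta sampling period, ms.
#' @param v voltage matrix (N x n), mV.
#' @param u injected-current matrix (N x n), pA.
#' @param components named list of component-current vectors (length N).
#' @param meta named list of metadata (seeds, parameters, split info).
#' @return object of class `rmm_recording`.
#' @export
rmm_recording <- function(delta, v, u, components = list(), meta = list()) {
  v <- as.matrix(v); u <- as.matrix(u)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop_invalid("`delta` must be a single positive sampling period (ms)")
  if (nrow(v) != nrow(u) || ncol(v) != ncol(u))
    stop_invalid("`v` and `u` must have identical dimensions")
  for (nm in names(components))
    if (length(components[[nm]]) != nrow(v))
      stop_invalid("component `", nm, "` length differs from the series")
  colnames(v) <- paste0("v", seq_len(ncol(v)))
  colnames(u) <- paste0("u", seq_len(ncol(u)))
  structure(list(delta = delta, v = v, u = u, components = components,
                 meta = meta),
            class = "rmm_recording")
}

#' @export
print.rmm_recording <- function(x, ...) {
  cat(sprintf("<rmm_recording> %d neurons, %d samples at delta = %g ms (%.3g s)\n",
              ncol(x$v), nrow(x$v), x$delta, nrow(x$v) * x$delta / 1000))
  if (length(x$components))
    cat("  components:", paste(names(x$components), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `rmm_recording`.
#' @export
n_samples <- function(rec) nrow(rec$v)

#' Write / read a recording as delimited text
#'
#' Tab-separated columns `t, v1..vn, u1..un, <components>` preceded by `#`
#' metadata lines (`delta` and the metadata list as JSON); numbers stored at
#' 17 significant digits so the round-trip is lossless.
#'
#' @param rec an `rmm_recording`.
#' @param path file path.
#' @export
write_recording <- function(rec, path) {
  n <- ncol(rec$v)
  tab <- data.table::data.table(t = seq_len(nrow(rec$v)) - 1L)
  for (i in seq_len(n)) tab[[paste0("v", i)]] <- rec$v[, i]
  for (i in seq_len(n)) tab[[paste0("u", i)]] <- rec$u[, i]
  for (nm in names(rec$components)) tab[[nm]] <- rec$components[[nm]]
  hdr <- c(
    paste0("# delta: ", sprintf("%.17g", rec$delta)),
    paste0("# n_neurons: ", n),
    paste0("# meta: ", as.character(jsonlite::toJSON(rec$meta, digits = I(17),
                                                     auto_unbox = TRUE)))
  )
  writeLines(hdr, path)
  suppressWarnings(
    data.table::fwrite(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", append = TRUE, col.names = TRUE,
                       quote = FALSE))
  invisible(path)
}

#' @rdname write_recording
#' @param decimate keep every k-th sample on load, scaling `delta` by k.
#' @export
read_recording <- function(path, decimate = 1L) {
  lines <- readLines(path, n = 20L)
  hdr <- grep("^#", lines, value = TRUE)
  getfield <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop_invalid("malformed recording header: missing `", key, "`")
    sub(paste0("^# ", key, ": "), "", ln[1L])
  }
  delta <- as.numeric(getfield("delta"))
  n <- as.integer(getfield("n_neurons"))
  meta <- jsonlite::fromJSON(getfield("meta"), simplifyVector = TRUE)
  tab <- data.table::fread(path, sep = "\t", skip = length(hdr), header = TRUE)
  need <- c(paste0("v", seq_len(n)), paste0("u", seq_len(n)))
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_invalid("recording is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(tab)) stop_invalid("recording contains missing values (ragged columns?)")
  v <- as.matrix(tab[, paste0("v", seq_len(n)), with = FALSE])
  u <- as.matrix(tab[, paste0("u", seq_len(n)), with = FALSE])
  comp_names <- setdiff(names(tab), c("t", need))
  comps <- lapply(comp_names, function(nm) tab[[nm]])
  names(comps) <- comp_names
  rec <- rmm_recording(delta, v, u, comps, as.list(meta))
  if (decimate > 1L) rec <- decimate_recording(rec, decimate)
  rec
}

#' Decimate a recording by an integer factor
#'
#' Keeps every k-th sample and scales the sampling period to `k * delta`.
#' @param rec an `rmm_recording`.
#' @param k integer factor >= 1.
#' @export
decimate_recording <- function(rec, k) {
  k <- as.integer(k)
  if (k < 1L) stop_invalid("decimation factor must be >= 1")
  if (k == 1L) return(rec)
  keep <- seq(1L, nrow(rec$v), by = k)
  meta <- rec$meta
  meta$decimated_by <- k
  rmm_recording(rec$delta * k, rec$v[keep, , drop = FALSE],
                rec$u[keep, , drop = FALSE],
                lapply(rec$components, function(x) x[keep]), meta)
}

#' Contiguous train/validation split
#'
#' The first `train_frac` of the samples become the training recording and
#' the remainder the validation recording; no shuffling across the
#' boundary.  The boundary index is stored in both recordings' metadata.
#'
#' @param rec an `rmm_recording`.
#' @param train_frac fraction in (0, 1).
#' @return list with `train` and `validation` recordings.
#' @export
make_train_val_split <- function(rec, train_frac = 0.75) {
  N <- nrow(rec$v)
  n_train <- floor(N * train_frac)
  if (n_train < 2L || n_train >= N)
    stop_invalid("split leaves an empty part (N = ", N, ", train_frac = ",
                 train_frac, ")")
  take <- function(idx, part) {
    meta <- rec$meta
    meta$split <- list(part = part, boundary = n_train, total = N,
                       train_frac = train_frac)
    rmm_recording(rec$delta, rec$v[idx, , drop = FALSE],
                  rec$u[idx, , drop = FALSE],
                  lapply(rec$components, function(x) x[idx]), meta)
  }
  list(train = take(seq_len(n_train), "train"),
       validation = take((n_train + 1L):N, "validation"))
}
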