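#' Read and write time-series matrices
#'
#' Time courses travel as tab-delimited text matrices (one row per sample,
#' header row of channel labels) with a JSON sidecar (`<path>.json`)
#' holding the sampling rate, band tag and trial boundaries. Values are
#' written with 12 significant digits, which round-trips doubles to within
#' 1e-9 relative error.
#'
#' @param series a [ts_matrix()].
#' @param path file path for the matrix; the sidecar is written next to it.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns a [ts_matrix()].
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "ts_matrix"))
  header <- paste(series$channel_labels, collapse = "\t")
  body <- apply(series$values, 1, function(r)
    paste(formatC(r, format = "g", digits = 12), collapse = "\t"))
  writeLines(c(header, body), path)
  sidecar <- list(fs_hz = series$fs, band = series$band,
                  trial_boundaries = series$trial_boundaries,
                  n_trials = length(series$trial_boundaries))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop_ncreann("matrix file has no data rows: ", path)
  labs <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (any(lens != length(labs)))
    stop_ncreann("ragged matrix row at line ",
                 which(lens != length(labs))[1] + 1L, " of ", path)
  vals <- matrix(as.numeric(unlist(rows)), length(rows), length(labs),
                 byrow = TRUE)
  if (anyNA(vals)) stop_ncreann("non-numeric value in matrix file ", path)
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path))
    stop_ncreann("missing sidecar file ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(sc$fs_hz))
    stop_ncreann("sidecar ", sc_path, " lacks required field 'fs_hz'")
  ts_matrix(vals, fs = sc$fs_hz, channel_labels = labs,
            band = sc$band,
            trial_boundaries = sc$trial_boundaries %||% 1L)
}

#' Read and write voxel volumes
#'
#' Volumes travel as CSV voxel tables (`i, j, k, x_mm, y_mm, z_mm, value`)
#' with a JSON sidecar recording grid dimensions and spacing.
#'
#' @param volume a [source_volume()].
#' @param path CSV file path.
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   [source_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "source_volume"))
  idx <- which(array(TRUE, volume$dims), arr.ind = TRUE)
  tab <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                    x_mm = (idx[, 1] - 1) * volume$spacing,
                    y_mm = (idx[, 2] - 1) * volume$spacing,
                    z_mm = (idx[, 3] - 1) * volume$spacing,
                    value = formatC(volume$values[idx], format = "g",
                                    digits = 12))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(dims = volume$dims, spacing_mm = volume$spacing),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path)) stop_ncreann("missing sidecar file ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(sc$dims) || is.null(sc$spacing_mm))
    stop_ncreann("volume sidecar lacks 'dims' or 'spacing_mm'")
  tab <- read.csv(path)
  need <- c("i", "j", "k", "value")
  if (!all(need %in% names(tab)))
    stop_ncreann("voxel table needs columns ", paste(need, collapse = ", "))
  vals <- array(NA_real_, sc$dims)
  vals[cbind(tab$i, tab$j, tab$k)] <- tab$value
  if (anyNA(vals)) stop_ncreann("voxel table does not cover the full grid")
  source_volume(vals, spacing = sc$spacing_mm)
}

#' Read and write behavioral trial tables
#'
#' @param table behavioral trial data frame ([generate_behavior()] format).
#' @param path CSV file path.
#' @return `write_behavior` returns `path` invisibly; `read_behavior` the
#'   validated data frame.
#' @export
write_behavior <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  tab <- read.csv(path, na.strings = "")
  need <- c("subject", "response_relation", "overlap", "correct_R1",
            "correct_R2", "rt")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_ncreann("behavior table lacks columns: ", paste(miss, collapse = ", "))
  tab$correct_R1 <- as.logical(tab$correct_R1)
  tab$correct_R2 <- as.logical(tab$correct_R2)
  if (any(!is.na(tab$rt) & tab$rt <= 0))
    stop_ncreann("non-positive reaction times in ", path)
  tab
}

#' Write connectivity results as a long-format CSV
#'
#' One row per directed edge and measure (`lC`/`NC`) with its value and,
#' when a surrogate test was run, its significance flag; values masked as
#' non-significant are left empty.
#'
#' @param x a `connectivity_result` or `surrogate_null`.
#' @param path CSV file path.
#' @param band,condition optional label overrides.
#' @return The written data frame, invisibly.
#' @export
write_connectivity <- function(x, path, band = NULL, condition = NULL) {
  if (inherits(x, "surrogate_null")) {
    tab <- edge_table(x$observed, drop_diagonal = FALSE)
    sig <- c(as.vector(x$sig_lc), as.vector(x$sig_nc))
    pv <- c(as.vector(x$p_lc), as.vector(x$p_nc))
    tab$p_value <- pv
    tab$significant <- sig
    tab$masked_value <- ifelse(sig, tab$value, NA_real_)
    band <- band %||% x$band
    condition <- condition %||% x$condition
  } else {
    stopifnot(inherits(x, "connectivity_result"))
    tab <- edge_table(x, drop_diagonal = FALSE)
    band <- band %||% x$band
    condition <- condition %||% x$condition
  }
  tab$band <- band %||% ""
  tab$condition <- condition %||% ""
  num <- vapply(tab, is.numeric, logical(1))
  for (cn in names(tab)[num])
    tab[[cn]] <- trimws(formatC(tab[[cn]], format = "g", digits = 12))
  tab[tab == "NA"] <- ""
  write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(tab)
}

#' Serialize a fitted network to JSON
#'
#' Writes layer shapes, flat weight arrays (column-major), activation,
#' order and standardization parameters; `read_model_json` reconstructs
#' the model exactly (within float formatting precision).
#'
#' @param model an `nmvar_model`.
#' @param path JSON file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   an `nmvar_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "nmvar_model"))
  obj <- list(shapes = list(W1 = dim(model$W1), W2 = dim(model$W2)),
              W1 = as.vector(model$W1), b1 = model$b1,
              W2 = as.vector(model$W2), b2 = model$b2,
              activation = model$activation, p = model$p, M = model$M,
              channel_labels = model$channel_labels,
              standardization = model$standardization)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    W1 = matrix(obj$W1, obj$shapes$W1[1], obj$shapes$W1[2]),
    b1 = as.numeric(obj$b1),
    W2 = matrix(obj$W2, obj$shapes$W2[1], obj$shapes$W2[2]),
    b2 = as.numeric(obj$b2),
    activation = obj$activation, p = obj$p, M = obj$M,
    channel_labels = obj$channel_labels,
    standardization = obj$standardization), class = "nmvar_model")
}
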