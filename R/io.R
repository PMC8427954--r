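#' Read and write sedation datasets in NONMEM-style CSV
#'
#' The on-disk dialect is comma-separated UTF-8 text with a header and the
#' NONMEM-convention columns `ID`, `TIME` (seconds), `CE` (ug/mL) and `DV`
#' (the UMSS score, 0-4). An optional `MDV` column is honoured: rows with
#' `MDV == 1` are dropped on read. Write followed by read is the identity for
#' values representable in up to 6 significant digits of decimal text.
#'
#' @param path File path.
#' @return `read_dataset()` returns a [sedation_dataset];
#'   `write_dataset()` invisibly returns `path`.
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("ID", "TIME", "CE", "DV")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("dataset file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if ("MDV" %in% names(raw)) raw <- raw[!(raw$MDV %in% 1), , drop = FALSE]
  for (col in c("TIME", "CE", "DV")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at line %d of %s", col, bad[1L] + 1L, path),
           call. = FALSE)
    }
    raw[[col]] <- v
  }
  bad <- which(!(raw$DV %in% 0:4))
  if (length(bad)) {
    stop(sprintf("DV outside 0..4 at line %d of %s", bad[1L] + 1L, path),
         call. = FALSE)
  }
  sedation_dataset(data.frame(id = raw$ID, time = raw$TIME,
                              ce = raw$CE, umss = as.integer(raw$DV)))
}

#' @rdname read_dataset
#' @param dataset A [sedation_dataset].
#' @export
write_dataset <- function(dataset, path) {
  dataset <- sedation_dataset(dataset)
  out <- data.frame(ID = dataset$id, TIME = dataset$time,
                    CE = dataset$ce, DV = dataset$umss)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write infusion logs
#'
#' An infusion log is the piecewise-constant pump record: columns `ID`,
#' `TIME` (seconds, strictly increasing within subject) and `RATE`
#' (mg/min, >= 0). Each rate holds from its time until the next event.
#'
#' @param path File path.
#' @return `read_infusion_log()` returns a data.frame with columns `id`,
#'   `time`, `rate` of class `infusion_log`.
#' @export
read_infusion_log <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("ID", "TIME", "RATE")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("infusion log ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  infusion_log(data.frame(id = raw$ID, time = as.numeric(raw$TIME),
                          rate = as.numeric(raw$RATE)))
}

#' @rdname read_infusion_log
#' @param log An `infusion_log` data.frame.
#' @export
write_infusion_log <- function(log, path) {
  out <- data.frame(ID = log$id, TIME = log$time, RATE = log$rate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an infusion log
#'
#' @param data data.frame with columns `id`, `time` (seconds), `rate`
#'   (mg/min); times strictly increasing within each subject, rates >= 0.
#' @return The validated data.frame with class `infusion_log`.
#' @export
infusion_log <- function(data) {
  data <- as.data.frame(data)
  stopifnot(all(c("id", "time", "rate") %in% names(data)))
  if (any(data$rate < 0)) stop("infusion rates must be >= 0", call. = FALSE)
  for (s in unique(data$id)) {
    t <- data$time[data$id == s]
    if (is.unsorted(t, strictly = TRUE)) {
      stop("infusion times must be strictly increasing within subject ", s,
           call. = FALSE)
    }
  }
  class(data) <- c("infusion_log", "data.frame")
  data
}

#' Read a model/protocol configuration file
#'
#' Configurations are JSON with optional blocks `model`
#' (`{ce50: [4 numbers], gamma}`), `pk` (`{v1, k10, k12, k21, k13, k31,
#' ke0}`), `protocol` (`{targets, hold_after_reach, eval_step}`), `fit`
#' (options passed to [fit_mle()]) and `seed`.
#'
#' @param path Path to a JSON configuration file.
#' @return A named list; `model` is converted to [pd_params], `pk` to
#'   [pk_params] and `protocol` to [study_design] when present.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$model)) {
    cfg$model <- pd_params(cfg$model$ce50, cfg$model$gamma)
  }
  if (!is.null(cfg$pk)) cfg$pk <- do.call(pk_params, as.list(cfg$pk))
  if (!is.null(cfg$protocol)) cfg$protocol <- do.call(study_design, as.list(cfg$protocol))
  cfg
}
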