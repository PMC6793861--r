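#' Read a pattern matrix from disk
#'
#' Supported formats: delimited text (`"csv"`, `"tsv"`, or `"auto"` which
#' sniffs the delimiter from the first line) and an RDS binary container
#' (`"rds"`). The canonical orientation is voxels in rows and stimuli in
#' columns; pass `transpose = TRUE` for files stored the other way round —
#' orientation is never guessed. Every cell must parse as a finite number;
#' offending cells are reported by row and column.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"rds"`.
#' @param header Does the first line hold stimulus identifiers? (delimited
#'   formats only)
#' @param row_ids Does the first column hold voxel identifiers? (delimited
#'   formats only)
#' @param transpose Transpose after reading (file stored stimuli x voxels).
#' @return A [pattern_matrix()] with `normalised = FALSE`.
#' @export
load_pattern_matrix <- function(path, format = c("auto", "csv", "tsv", "rds"),
                                header = TRUE, row_ids = TRUE,
                                transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "rds" || (format == "auto" && grepl("\\.rds$", path,
                                                    ignore.case = TRUE))) {
    vals <- readRDS(path)
    if (!is.matrix(vals)) stop("RDS container does not hold a matrix",
                               call. = FALSE)
  } else {
    sep <- switch(format, csv = ",", tsv = "\t",
                  auto = if (grepl("\t", readLines(path, n = 1L))) "\t" else ",")
    raw <- read.table(path, sep = sep, header = FALSE, colClasses = "character",
                      stringsAsFactors = FALSE, check.names = FALSE)
    stim_ids <- NULL
    vox_ids <- NULL
    if (header) {
      stim_ids <- as.character(raw[1L, ])
      raw <- raw[-1L, , drop = FALSE]
    }
    if (row_ids) {
      vox_ids <- as.character(raw[[1L]])
      raw <- raw[, -1L, drop = FALSE]
      if (header) stim_ids <- stim_ids[-1L]
    }
    vals <- matrix(NA_real_, nrow(raw), ncol(raw))
    for (j in seq_len(ncol(raw))) {
      cell <- trimws(raw[[j]])
      num <- suppressWarnings(as.numeric(cell))
      bad <- which(!is.finite(num))
      if (length(bad)) {
        stop(sprintf("cannot parse cell at voxel row %d, stimulus column %d: '%s'",
                     bad[1L], j, cell[bad[1L]]), call. = FALSE)
      }
      vals[, j] <- num
    }
    dimnames(vals) <- list(vox_ids, stim_ids)
  }
  if (transpose) vals <- t(vals)
  pattern_matrix(vals)
}

#' Write a pattern matrix to disk
#'
#' Round-trips exactly with [load_pattern_matrix()]: delimited text is
#' written with full (17 significant digit) precision.
#'
#' @param m A [pattern_matrix()] or numeric matrix.
#' @param path Output path.
#' @param format One of `"auto"` (from the file extension), `"csv"`, `"tsv"`,
#'   `"rds"`.
#' @return `path`, invisibly.
#' @export
write_pattern_matrix <- function(m, path, format = c("auto", "csv", "tsv", "rds")) {
  format <- match.arg(format)
  m <- as_pattern_matrix(m, normalised = is_normalised(m))
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("csv", "tsv", "rds")) ext else "csv"
  }
  if (format == "rds") {
    vals <- unclass(m)
    attr(vals, "normalised") <- NULL
    saveRDS(vals, path)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    vals <- format(unclass(m), digits = 17, trim = TRUE, scientific = TRUE)
    out <- cbind(rownames(m), vals)
    out <- rbind(c("voxel_id", colnames(m)), out)
    write.table(out, path, sep = sep, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a stimulus annotation table
#'
#' CSV with columns `stimulus_id`, `category` (face/place/object/other) and
#' `animacy` (animate/inanimate/unknown), one row per stimulus.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the three columns as character.
#' @export
read_stimulus_table <- function(path) {
  tab <- read.table(path, sep = ",", header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE)
  required <- c("stimulus_id", "category", "animacy")
  if (!all(required %in% names(tab))) {
    stop("stimulus table must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$stimulus_id)) {
    stop("duplicated stimulus_id in stimulus table", call. = FALSE)
  }
  tibble::as_tibble(tab[required])
}
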