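#' Construct a pattern matrix
#'
#' A pattern matrix holds the multivariate activity patterns of one region of
#' interest: one row per voxel, one column per stimulus, entries typically
#' beta estimates from a first-level general linear model. It is a plain
#' numeric matrix carrying voxel and stimulus identifiers plus a flag
#' recording whether its columns have been z-normalised across voxels.
#'
#' @param values Numeric matrix, voxels in rows and stimuli in columns. All
#'   entries must be finite.
#' @param voxel_ids Character vector of row identifiers (default `v1..vN`).
#' @param stimulus_ids Character vector of column identifiers (default
#'   `s1..sM`).
#' @param normalised Logical; has [znormalise()] been applied? Constructors
#'   other than `znormalise()` should leave this `FALSE`.
#'
#' @return A `pattern_matrix`: a numeric matrix with `dimnames` set from the
#'   identifiers and attribute `normalised`.
#' @examples
#' pm <- pattern_matrix(matrix(rnorm(12), 4, 3))
#' znormalise(pm)
#' @export
pattern_matrix <- function(values, voxel_ids = NULL, stimulus_ids = NULL,
                           normalised = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite entry at voxel row ", bad[1L], ", stimulus column ",
         bad[2L], call. = FALSE)
  }
  if (is.null(voxel_ids)) {
    voxel_ids <- rownames(values) %||% paste0("v", seq_len(nrow(values)))
  }
  if (is.null(stimulus_ids)) {
    stimulus_ids <- colnames(values) %||% paste0("s", seq_len(ncol(values)))
  }
  stopifnot(length(voxel_ids) == nrow(values),
            length(stimulus_ids) == ncol(values))
  dimnames(values) <- list(as.character(voxel_ids), as.character(stimulus_ids))
  structure(values, normalised = isTRUE(normalised),
            class = c("pattern_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_normalised <- function(m) isTRUE(attr(m, "normalised"))

as_pattern_matrix <- function(m, normalised = FALSE) {
  if (inherits(m, "pattern_matrix")) return(m)
  pattern_matrix(m, normalised = normalised)
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat(sprintf("<pattern_matrix> %d voxels x %d stimuli (%s)\n",
              nrow(x), ncol(x),
              if (is_normalised(x)) "z-normalised" else "raw"))
  mat <- unclass(x)
  attr(mat, "normalised") <- NULL
  print(head(mat[, seq_len(min(6L, ncol(mat))), drop = FALSE], 4L), ...)
  invisible(x)
}

#' Z-normalise each stimulus pattern across voxels
#'
#' Centres and scales every column (stimulus) of a pattern matrix across its
#' voxels using the population (divide-by-N) variance, so each column has
#' mean zero and squared Euclidean norm exactly equal to the number of
#' voxels. This convention makes the per-stimulus denominator of the
#' cross-validated goodness-of-fit equal to `N_voxels`, which is what lets
#' the leverage-shortcut objective drop the denominators entirely; sample
#' (divide-by-N-1) scaling would break that identity.
#'
#' @param m A [pattern_matrix()] or plain numeric matrix (voxels x stimuli).
#' @return A `pattern_matrix` with `normalised = TRUE`.
#' @examples
#' znormalise(pattern_matrix(matrix(c(1, 2, 3, 4, 6, 8), 3, 2)))
#' @export
znormalise <- function(m) {
  m <- as_pattern_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 voxels to z-normalise", call. = FALSE)
  vals <- unclass(m)
  centred <- sweep(vals, 2L, colMeans(vals), `-`)
  ss <- colSums(centred^2)
  if (any(ss == 0)) {
    stop("constant column (zero variance): stimulus ",
         paste(colnames(m)[ss == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(centred, 2L, sqrt(ss / nrow(m)), `/`)
  pattern_matrix(out, voxel_ids = rownames(m), stimulus_ids = colnames(m),
                 normalised = TRUE)
}

#' Restrict a pattern matrix to a subset of stimuli
#'
#' Keeps only the columns whose stimulus falls in the requested categories
#' and/or animacy classes, in their original order. The result is flagged as
#' non-normalised: re-run [znormalise()] on the subset so per-stimulus norms
#' are exact for the restricted analysis.
#'
#' @param m A [pattern_matrix()].
#' @param stimuli A stimulus table (see [read_stimulus_table()]) with columns
#'   `stimulus_id`, `category`, `animacy` covering the matrix columns.
#' @param category Optional character vector of categories to keep
#'   (e.g. `"face"`, `"place"`); `NULL` keeps all.
#' @param animacy Optional character vector of animacy classes to keep
#'   (`"animate"`, `"inanimate"`); `NULL` keeps all.
#' @return A `pattern_matrix` with the selected columns, `normalised = FALSE`.
#' @export
subset_stimuli <- function(m, stimuli, category = NULL, animacy = NULL) {
  m <- as_pattern_matrix(m, normalised = is_normalised(m))
  stimuli <- as.data.frame(stimuli)
  stopifnot(all(c("stimulus_id", "category", "animacy") %in% names(stimuli)))
  missing_ids <- setdiff(colnames(m), stimuli$stimulus_id)
  if (length(missing_ids)) {
    stop("stimulus table does not annotate: ",
         paste(head(missing_ids, 3L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(category)) {
    unknown <- setdiff(category, stimuli$category)
    if (length(unknown)) stop("unknown category: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(animacy)) {
    unknown <- setdiff(animacy, stimuli$animacy)
    if (length(unknown)) stop("unknown animacy class: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
  }
  tab <- stimuli[match(colnames(m), stimuli$stimulus_id), ]
  keep <- rep(TRUE, ncol(m))
  if (!is.null(category)) keep <- keep & tab$category %in% category
  if (!is.null(animacy)) keep <- keep & tab$animacy %in% animacy
  if (!any(keep)) stop("selection matches no stimuli", call. = FALSE)
  pattern_matrix(unclass(m)[, keep, drop = FALSE],
                 voxel_ids = rownames(m),
                 stimulus_ids = colnames(m)[keep],
                 normalised = FALSE)
}
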