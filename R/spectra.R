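#' Uniform wavenumber grid
#'
#' Constructs the wavenumber axis shared by all spectra in a study. FT-NIR
#' instruments of the class emulated here record absorbance on a uniform
#' grid in the 4,000--12,000 cm\eqn{^{-1}} region; the default grid spans
#' that full range at 8 cm\eqn{^{-1}} spacing (1,001 points).
#'
#' @param from,to Range endpoints in cm\eqn{^{-1}}.
#' @param by Spacing in cm\eqn{^{-1}}.
#' @param values Optionally, an explicit numeric vector of wavenumbers
#'   (overrides `from`/`to`/`by`). Must be strictly increasing and uniformly
#'   spaced.
#' @return A numeric vector of class `"wavenumber_grid"`.
#' @export
wavenumber_grid <- function(from = 4000, to = 12000, by = 8, values = NULL) {
  v <- if (is.null(values)) seq(from, to, by = by) else as.numeric(values)
  if (length(v) < 2L) stop("a wavenumber grid needs at least 2 points")
  d <- diff(v)
  if (any(d <= 0)) stop("wavenumbers must be strictly increasing")
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
    stop("wavenumber grid must be uniformly spaced")
  structure(v, class = "wavenumber_grid")
}

#' Grid spacing in cm^-1
#' @param grid A [wavenumber_grid()].
#' @return The (uniform) spacing between consecutive grid points.
#' @export
grid_spacing <- function(grid) {
  unclass(grid)[2] - unclass(grid)[1]
}

#' Spectra set container
#'
#' Holds an n-samples-by-n-points absorbance matrix together with its
#' wavenumber grid and unique sample identifiers. This is the `X` object
#' every preprocessing and calibration function consumes.
#'
#' @param matrix Numeric matrix, rows = samples, columns = grid points.
#' @param grid A [wavenumber_grid()] whose length equals `ncol(matrix)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `"S001"`, `"S002"`, ...
#' @return An object of class `"spectra_set"`: a list with elements
#'   `matrix`, `grid`, `sample_ids`.
#' @export
spectra_set <- function(matrix, grid, sample_ids = NULL) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop("absorbance matrix must be numeric")
  if (ncol(matrix) != length(grid))
    stop(sprintf("matrix has %d columns but grid has %d points",
                 ncol(matrix), length(grid)))
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(nrow(matrix)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(matrix))
    stop("one sample_id per spectrum required")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  rownames(matrix) <- sample_ids
  colnames(matrix) <- NULL
  structure(list(matrix = matrix, grid = grid, sample_ids = sample_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  g <- unclass(x$grid)
  cat(sprintf("<spectra_set> %d spectra x %d points, %.0f-%.0f cm^-1 (step %.3g)\n",
              nrow(x$matrix), length(g), min(g), max(g), grid_spacing(x$grid)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$matrix)

#' Subset a spectra set by sample
#' @param x A `spectra_set`.
#' @param i Row index (integer, logical, or sample-id character vector).
#' @param ... Ignored.
#' @return A `spectra_set` with the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  m <- x$matrix[i, , drop = FALSE]
  spectra_set(m, x$grid, sample_ids = rownames(m))
}

as_matrix_x <- function(X) {
  if (inherits(X, "spectra_set")) X$matrix else as.matrix(X)
}
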