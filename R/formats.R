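# Readers/writers for colormap tables (delimited text, 256 x 3) and
# quantitative maps (delimited text matrix or NIfTI). The colormap loader
# is deliberately lenient about dialect — float vs 8-bit values, comma vs
# whitespace, '#' comments — so published tables load regardless of their
# exact export convention.

#' Read a colormap table
#'
#' Accepts 3-column delimited text: floats in `[0, 1]` or integers in
#' 0..255 (dialect auto-detected from the value range), comma- or
#' whitespace-separated, with optional '#' comment/header lines. A
#' recommended-map table has exactly 256 rows; other lengths load with a
#' warning so partial or resampled tables can still be audited.
#'
#' @param path text file path.
#' @param name colormap name; default from the file name.
#' @return a `relax_cmap` with `source = "loaded"`.
#' @export
read_colormap <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty colormap file: ", path, call. = FALSE)
  delim <- if (any(grepl(",", lines, fixed = TRUE))) "," else "[[:space:]]+"
  rows <- strsplit(lines, delim)
  lens <- lengths(rows)
  if (any(lens != 3L)) {
    stop(sprintf("line %d has %d columns, expected 3",
                 which(lens != 3L)[1L], lens[lens != 3L][1L]), call. = FALSE)
  }
  vals <- suppressWarnings(matrix(as.numeric(trimws(unlist(rows))),
                                  ncol = 3L, byrow = TRUE))
  if (anyNA(vals)) {
    stop(sprintf("non-numeric value on line %d", which(rowSums(is.na(vals)) > 0)[1L]),
         call. = FALSE)
  }
  if (any(vals < 0)) stop("negative channel values in colormap table", call. = FALSE)
  if (max(vals) > 1) { # 8-bit dialect
    if (max(vals) > 255) stop("channel values exceed 255", call. = FALSE)
    vals <- vals / 255
  }
  if (nrow(vals) != 256L) {
    warning(sprintf("colormap has %d rows, not the recommended 256", nrow(vals)))
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  colormap(vals, name = name, source = "loaded")
}

#' Write a colormap table
#'
#' @param cmap a `relax_cmap`.
#' @param path output path.
#' @param dialect `"float"` (6 decimals, lossless on round-trip at that
#'   precision) or `"byte"` (8-bit integers 0..255).
#' @param delim column delimiter.
#' @param comment optional comment line(s) written with a '#' prefix.
#' @return `path`, invisibly.
#' @export
write_colormap <- function(cmap, path, dialect = c("float", "byte"),
                           delim = ",", comment = NULL) {
  stopifnot(inherits(cmap, "relax_cmap"))
  dialect <- match.arg(dialect)
  rows <- if (dialect == "float") {
    apply(cmap$entries, 1L, function(r) paste(sprintf("%.6f", r), collapse = delim))
  } else {
    apply(srgb_to_8bit(cmap$entries), 1L, function(r) paste(r, collapse = delim))
  }
  header <- if (is.null(comment)) character(0) else paste0("# ", comment)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a quantitative map
#'
#' Delimited-text matrices or NIfTI volumes (`.nii`, `.nii.gz`; the first
#' slice of a 3D volume is taken with a warning). NaN cells become the
#' sentinel 0; negative values are rejected with their coordinate.
#'
#' @param path file path.
#' @param kind,units as in [quant_map()].
#' @return a [quant_map()].
#' @export
read_quantmap <- function(path, kind = "T1", units = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) > 2L) {
      extra <- prod(dim(arr)[-(1:2)])
      if (extra > 1L) warning("3D volume: using the first slice only")
      arr <- array(arr, dim = dim(arr)[1:2])
    }
    values <- as.matrix(arr)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) stop("empty map file: ", path, call. = FALSE)
    delim <- if (any(grepl(",", lines, fixed = TRUE))) "," else "[[:space:]]+"
    rows <- lapply(strsplit(lines, delim), function(r) {
      suppressWarnings(as.numeric(trimws(r)))
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop(sprintf("inconsistent row lengths (row %d has %d cells, row 1 has %d)",
                   which(lens != lens[1L])[1L], lens[lens != lens[1L]][1L],
                   lens[1L]), call. = FALSE)
    }
    values <- do.call(rbind, rows)
    bad <- which(is.na(values) & !is.nan(values), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric cell at row %d, column %d",
                   bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
    }
  }
  values[is.nan(values)] <- 0
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value at row %d, column %d",
                 neg[1L, 1L], neg[1L, 2L]), call. = FALSE)
  }
  quant_map(values, kind = kind, units = units)
}

#' Write a quantitative map
#'
#' Text matrix (default) or NIfTI, chosen by the file extension.
#'
#' @param qmap a [quant_map()].
#' @param path output path (`.nii`/`.nii.gz` for NIfTI, anything else for
#'   whitespace-delimited text).
#' @return `path`, invisibly.
#' @export
write_quantmap <- function(qmap, path) {
  stopifnot(inherits(qmap, "quant_map"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(qmap$values), path)
  } else {
    utils::write.table(qmap$values, path, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read an anchor-color table
#'
#' 3-column delimited text like a colormap table (any row count >= 2);
#' sRGB rows may be floats in `[0, 1]` or 8-bit integers; `space = "lab"`
#' reads the rows as CIELAB.
#'
#' @param path file path.
#' @param name anchor-set name; default from the file name.
#' @param space `"srgb"` or `"lab"`.
#' @return an [anchor_set()].
#' @export
read_anchors <- function(path, name = NULL, space = c("srgb", "lab")) {
  space <- match.arg(space)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  delim <- if (any(grepl(",", lines, fixed = TRUE))) "," else "[[:space:]]+"
  rows <- strsplit(lines, delim)
  if (any(lengths(rows) != 3L)) stop("anchor table must have 3 columns", call. = FALSE)
  vals <- matrix(as.numeric(trimws(unlist(rows))), ncol = 3L, byrow = TRUE)
  if (anyNA(vals)) stop("non-numeric value in anchor table", call. = FALSE)
  if (space == "srgb" && max(vals) > 1) vals <- vals / 255
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  anchor_set(vals, name = name, space = space)
}
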