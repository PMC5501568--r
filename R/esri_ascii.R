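#' Read an ESRI ASCII grid
#'
#' Parses the 6-line `ncols/nrows/xllcorner|xllcenter/.../NODATA_value`
#' header followed by whitespace-separated rows (north first, as the
#' format stores them) into a [grid_field()].  `xllcorner` headers are
#' converted to cell-center registration by adding half a cell.
#'
#' @param path file path.
#' @param attribute,units labels attached to the result.
#' @return A [grid_field()].
#' @export
read_esri_ascii <- function(path, attribute = "value", units = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ESRI ASCII header (line ", i, "): missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (!is.null(hdr$xllcorner)) {
    ox <- hdr$xllcorner + hdr$cellsize / 2
    oy <- hdr$yllcorner + hdr$cellsize / 2
  } else {
    ox <- hdr$xllcenter; oy <- hdr$yllcenter
  }
  if (is.null(ox) || is.null(oy))
    stop("malformed ESRI ASCII header: no xll/yll origin", call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ESRI ASCII body (from line ", i, "): expected ", nr * nc,
         " values, found ", length(vals), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]           # file is north-first; store south-first
  nodata <- matrix(FALSE, nr, nc)
  if (!is.null(hdr$nodata_value)) {
    nodata <- m == hdr$nodata_value
    m[nodata] <- NA_real_
  }
  nodata <- nodata | !is.finite(m)
  grid_field(m, origin_x = ox, origin_y = oy, cell_size = hdr$cellsize,
             nodata = nodata, attribute = attribute, units = units)
}

#' Write an ESRI ASCII grid
#'
#' @param gf a [grid_field()].
#' @param path output file path.
#' @param nodata_value number written for nodata cells.
#' @param digits significant digits written; `NA` writes full precision
#'   (R's default 15 significant digits), which round-trips exactly at
#'   double precision for typical field data.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(gf, path, nodata_value = -9999, digits = NA) {
  stopifnot(inherits(gf, "grid_field"))
  nr <- nrow(gf$values); nc <- ncol(gf$values)
  m <- gf$values
  m[gf$nodata] <- nodata_value
  fmt <- function(v) {
    if (is.na(digits)) format(v, scientific = FALSE, trim = TRUE, digits = 15)
    else formatC(v, digits = digits, format = "g")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", fmt(gf$origin_x - gf$cell_size / 2)),
    paste("yllcorner", fmt(gf$origin_y - gf$cell_size / 2)),
    paste("cellsize", fmt(gf$cell_size)),
    paste("NODATA_value", fmt(nodata_value))), con)
  for (r in nr:1)                         # north row first
    writeLines(paste(fmt(m[r, ]), collapse = " "), con)
  invisible(path)
}
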