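#' Read and write plain (ASCII) PGM images
#'
#' `P2` portable graymaps are the text image format the package reads and
#' writes: columns of the R matrix map to raster rows, so `image[i, j]` is
#' raster position `(x = i - 1, y = j - 1)`.  Intensities are scaled to
#' \[0, 1\] on read and from \[0, 1\] on write.
#'
#' @param path file path.
#' @return `read_pgm`: numeric matrix in \[0, 1\].
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("only ASCII PGM (P2) is supported")
  w <- as.integer(tok[2])
  h <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("truncated PGM raster")
  matrix(vals / maxval, nrow = w, ncol = h)
}

#' @rdname read_pgm
#' @param image numeric matrix in \[0, 1\] or a [fuzzy_image].
#' @param maxval maximum gray value written.
#' @export
write_pgm <- function(image, path, maxval = 65535) {
  if (inherits(image, "fuzzy_image")) image <- image$mu
  stopifnot(length(dim(image)) == 2)
  vals <- as.integer(round(pmin(pmax(image, 0), 1) * maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(image), ncol(image)), as.character(maxval)),
             con)
  writeLines(vapply(split(vals, rep(seq_len(ncol(image)),
                                    each = nrow(image))),
                    paste, character(1), collapse = " "), con)
  invisible(path)
}

#' Read and write B-spline transform files
#'
#' JSON with a header (dimension, per-dimension control counts, control
#' spacing, support origin, extent, axis-aligned direction) and the flat
#' column-major list of control displacements.
#'
#' @param field a [bspline_field].
#' @param path file path.
#' @export
write_transform_json <- function(field, path) {
  jsonlite::write_json(
    list(dimension = length(field$counts), counts = field$counts,
         spacing = field$delta, origin = field$origin,
         extent = field$extent, direction = "axis-aligned",
         displacements = as.vector(field$phi)),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_transform_json
#' @return `read_transform_json`: a [bspline_field].
#' @export
read_transform_json <- function(path) {
  js <- jsonlite::fromJSON(path)
  bspline_field(js$counts, extent = js$extent,
                phi = matrix(js$displacements, ncol = js$dimension),
                origin = js$origin)
}

#' Landmark tables as CSV
#'
#' One point per row, physical coordinates, columns `x`, `y` (and `z` in
#' 3D).
#'
#' @param path file path.
#' @export
read_landmarks <- function(path) {
  as.matrix(read.csv(path))
}

#' @rdname read_landmarks
#' @param points landmark matrix.
#' @export
write_landmarks <- function(points, path) {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y", "z")[seq_len(ncol(points))]
  write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Export the dense displacement field of a transform as CSV
#'
#' Samples the field at every spel center of the given grid and writes one
#' row per spel: grid indices, physical position, and the displacement
#' components.
#'
#' @param field a [bspline_field] or [warp_stack].
#' @param N grid size per dimension.
#' @param spacing spel spacing per dimension.
#' @param path file path.
#' @export
export_displacement_csv <- function(field, N, spacing = 1, path) {
  spacing <- rep_len(spacing, length(N))
  idx <- as.matrix(expand.grid(lapply(N, seq_len)))
  pos <- spel_position(idx, spacing)
  disp <- transform_points(field, pos) - pos
  n <- length(N)
  axes <- c("x", "y", "z")[seq_len(n)]
  df <- data.frame(idx - 1, pos, disp)
  names(df) <- c(paste0("i_", axes), axes, paste0("d", axes))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
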