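# Image input/output: 8-bit grayscale PNG (via the png package) and binary
# PGM (P5), with silhouette sequences stored as a plain-text manifest (one
# frame file per line, optional "label:" header) next to the frame files.
# Intensities are scaled to [0, 1] on read; masks binarize at 0.5 and
# round-trip losslessly.

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {                 # next whitespace-separated token, '#' comments
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (!length(ch)) stop_format("truncated PGM header: ", path)
      if (ch == "#") { repeat { c2 <- readChar(con, 1, useBytes = TRUE)
        if (!length(c2) || c2 == "\n") break } ; next }
      if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (!length(ch) || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (magic != "P5") stop_format("not a P5 PGM file: ", path)
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (is.na(w) || is.na(h) || is.na(maxval))
    stop_format("malformed PGM header: ", path)
  if (maxval > 255)
    stop_format("unsupported bit depth (maxval ", maxval, "): ", path)
  raw <- readBin(con, "integer", n = w * h, size = 1, signed = FALSE)
  if (length(raw) < w * h) stop_format("truncated PGM pixel data: ", path)
  matrix(raw / maxval, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  v <- round(pmin(pmax(values, 0), 1) * 255)
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(values), nrow(values)), con,
            eos = NULL)
  writeBin(as.integer(t(v)), con, size = 1)
  invisible(path)
}

#' Read a grayscale image (PNG or PGM P5)
#'
#' @param path file path; format chosen by extension (`.png`, `.pgm`).
#' @param range intensity range to attach (default `c(0, 1)`).
#' @return `intensity_image` with values in `[0, 1]`. 16-bit input and
#'   non-grayscale PNGs are rejected with a format error naming the file.
#' @export
read_image <- function(path, range = c(0, 1)) {
  check_that(file.exists(path), "no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  values <- if (ext == "pgm") {
    read_pgm(path)
  } else {
    img <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop_format("unreadable PNG: ", path,
                                                    " (", conditionMessage(e), ")"))
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8)
      stop_format("unsupported bit depth (", info$bit.depth, "-bit): ", path)
    if (length(dim(img)) == 3) {
      if (dim(img)[3] >= 3 &&
          !(all(img[, , 1] == img[, , 2]) && all(img[, , 1] == img[, , 3])))
        stop_format("not a grayscale image: ", path)
      img <- img[, , 1]
    }
    img
  }
  intensity_image(values, range = range)
}

#' Write a grayscale image (PNG or PGM P5)
#'
#' @param values numeric matrix in `[0, 1]` (or logical mask).
#' @param path output path; format chosen by extension.
#' @export
write_image <- function(values, path) {
  v <- pmin(pmax(unclass(values) * 1, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") write_pgm(v, path) else png::writePNG(v, path)
  invisible(path)
}

#' Write a binary mask as a 0/255 image
#' @param mask logical matrix. @param path output path.
#' @export
write_mask <- function(mask, path) write_image(mask * 1, path)

#' Read a silhouette sequence from a manifest
#'
#' The manifest is a text file listing one frame file per line (relative to
#' the manifest's directory), optionally preceded by a `label: <activity>`
#' line. Frame order follows the manifest exactly; frames binarize at 0.5.
#'
#' @param manifest manifest path.
#' @return `silhouette_sequence`.
#' @export
read_silhouette_sequence <- function(manifest) {
  check_that(file.exists(manifest), "no such manifest: ", manifest)
  lines <- trimws(readLines(manifest))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  label <- NULL
  lab_line <- grepl("^label:", lines)
  if (any(lab_line)) {
    label <- trimws(sub("^label:", "", lines[lab_line][1]))
    lines <- lines[!lab_line]
  }
  check_that(length(lines) >= 2, "manifest lists fewer than 2 frames")
  dir <- dirname(manifest)
  frames <- lapply(file.path(dir, lines), function(p) unclass(read_image(p)) > 0.5)
  silhouette_sequence(frames, label = label)
}

#' Write a silhouette sequence with a manifest
#'
#' @param seq `silhouette_sequence`.
#' @param dir output directory (created if needed).
#' @param prefix frame-file prefix.
#' @param format `"png"` or `"pgm"`.
#' @return path of the written manifest.
#' @export
write_silhouette_sequence <- function(seq, dir, prefix = "frame",
                                      format = "png") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%04d.%s", prefix, seq_along(seq$frames), format)
  for (i in seq_along(seq$frames))
    write_mask(seq$frames[[i]], file.path(dir, files[i]))
  manifest <- file.path(dir, paste0(prefix, "_manifest.txt"))
  header <- if (!is.null(seq$label)) paste0("label: ", seq$label) else character()
  writeLines(c(header, files), manifest)
  manifest
}
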