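#' Write a texture to disk
#'
#' Supported formats: plain PBM (`P1`; 1 = black per the format definition)
#' and 8-bit grayscale PNG (white = 255, black = 0). The format is taken
#' from the file extension when not given explicitly.
#'
#' @param tex A `texture` object or 0/1 matrix.
#' @param path Output file path.
#' @param format `"pbm"` or `"png"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @seealso [read_texture()]
#' @export
write_texture <- function(tex, path, format = c("auto", "pbm", "png")) {
  tex <- as_texture(tex)
  format <- match.arg(format)
  if (format == "auto") format <- infer_texture_format(path)
  if (format == "pbm") {
    bits <- 1L - unclass(tex) # PBM: 1 = black
    lines <- c(
      "P1",
      paste(ncol(tex), nrow(tex)),
      apply(bits, 1L, paste, collapse = " ")
    )
    writeLines(lines, path)
  } else {
    png::writePNG(unclass(tex) * 1.0, target = path)
  }
  invisible(path)
}

#' Read a texture from disk
#'
#' Parses a plain PBM (`P1`) or grayscale PNG file written by
#' [write_texture()] (or any conforming file) back into a `texture`.
#' `read_texture(write_texture(tex, path), ...)` is the identity.
#'
#' @param path File path; format inferred from the extension.
#' @param format `"pbm"` or `"png"`; default inferred from `path`.
#' @return A `texture` object.
#' @export
read_texture <- function(path, format = c("auto", "pbm", "png")) {
  format <- match.arg(format)
  if (format == "auto") format <- infer_texture_format(path)
  if (format == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    px <- round(img)
    if (!all(px %in% c(0, 1))) {
      stop(sprintf("'%s': PNG is not binary black/white", path), call. = FALSE)
    }
    return(as_texture(px))
  }
  read_pbm(path)
}

infer_texture_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pbm", "pnm")) return("pbm")
  if (ext == "png") return("png")
  stop(sprintf("cannot infer texture format from path '%s'; pass format=",
               path), call. = FALSE)
}

# Plain (ASCII) PBM parser. Tokens may be separated by arbitrary whitespace;
# '#' starts a comment running to end of line.
read_pbm <- function(path) {
  raw_lines <- tryCatch(readLines(path, warn = FALSE),
                        error = function(e) {
                          stop(sprintf("'%s': cannot read file (%s)",
                                       path, conditionMessage(e)), call. = FALSE)
                        })
  stripped <- sub("#.*$", "", raw_lines)
  tokens <- unlist(strsplit(paste(stripped, collapse = " "), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) < 1L || tokens[1L] != "P1") {
    stop(sprintf("'%s': not a plain PBM file (expected magic 'P1', got '%s')",
                 path, if (length(tokens)) tokens[1L] else "<empty>"),
         call. = FALSE)
  }
  if (length(tokens) < 3L) {
    stop(sprintf("'%s': truncated PBM header (missing width/height)", path),
         call. = FALSE)
  }
  w <- suppressWarnings(as.integer(tokens[2L]))
  h <- suppressWarnings(as.integer(tokens[3L]))
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) {
    stop(sprintf("'%s': invalid PBM dimensions '%s %s'",
                 path, tokens[2L], tokens[3L]), call. = FALSE)
  }
  body <- tokens[-(1:3)]
  # P1 allows digits to be packed without separators
  bits <- suppressWarnings(as.integer(unlist(strsplit(body, ""))))
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop(sprintf("'%s': PBM body contains non-binary tokens", path),
         call. = FALSE)
  }
  if (length(bits) != w * h) {
    stop(sprintf("'%s': PBM body has %d pixels, expected %d (%d x %d)",
                 path, length(bits), w * h, w, h), call. = FALSE)
  }
  px <- matrix(bits, nrow = h, ncol = w, byrow = TRUE)
  as_texture(1L - px) # PBM: 1 = black -> pixel 0
}
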