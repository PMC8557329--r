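# Minimal baseline TIFF codec for the pipeline's image interchange format:
# little-endian, uncompressed, 16-bit grayscale, one page per channel, the
# channel name in each page's ImageDescription. Covers exactly what the
# simulator writes and the quantifier reads; not a general TIFF reader.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               samples = 277L, rows_per_strip = 278L, strip_bytes = 279L)

#' Write a two-channel section image as a multi-page 16-bit TIFF
#'
#' Page 1 carries the dystrophin channel (ImageDescription "DYS"), page 2
#' the laminin channel ("LAMA2"). Pixels are written row-major,
#' little-endian, uncompressed.
#'
#' @param image a `section_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_section_tiff <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  con <- file(path, "wb")
  on.exit(close(con))
  pages <- list(DYS = image$DYS, LAMA2 = image$LAMA2)
  writeBin(charToRaw("II"), con)
  writeBin(as.raw(c(42, 0)), con)         # magic, little-endian
  offset_pos <- 4L                        # where the next-IFD offset lives
  writeBin(as.raw(rep(0, 4)), con)        # patched below
  pos <- 8L
  for (p in seq_along(pages)) {
    mat <- pages[[p]]
    H <- nrow(mat); W <- ncol(mat)
    desc <- c(charToRaw(names(pages)[p]), as.raw(0))
    if (length(desc) %% 2L) desc <- c(desc, as.raw(0))
    vals <- as.integer(t(mat))            # row-major
    data_bytes <- as.raw(rbind(vals %% 256L, vals %/% 256L))
    data_off <- pos
    desc_off <- data_off + length(data_bytes)
    ifd_off <- desc_off + length(desc)
    # patch the pending IFD pointer
    seek(con, offset_pos, origin = "start", rw = "write")
    writeBin(le4(ifd_off), con)
    seek(con, data_off, origin = "start", rw = "write")
    writeBin(data_bytes, con)
    writeBin(desc, con)
    entries <- list(
      tiff_entry(TIFF_TAGS["width"], 4L, W),
      tiff_entry(TIFF_TAGS["height"], 4L, H),
      tiff_entry(TIFF_TAGS["bits"], 3L, 16L),
      tiff_entry(TIFF_TAGS["compression"], 3L, 1L),
      tiff_entry(TIFF_TAGS["photometric"], 3L, 1L),
      tiff_entry(TIFF_TAGS["description"], 2L, desc_off, count = length(desc)),
      tiff_entry(TIFF_TAGS["strip_offsets"], 4L, data_off),
      tiff_entry(TIFF_TAGS["samples"], 3L, 1L),
      tiff_entry(TIFF_TAGS["rows_per_strip"], 4L, H),
      tiff_entry(TIFF_TAGS["strip_bytes"], 4L, length(data_bytes)))
    writeBin(as.raw(c(length(entries) %% 256L, length(entries) %/% 256L)), con)
    for (e in entries) writeBin(e, con)
    offset_pos <- ifd_off + 2L + 12L * length(entries)
    writeBin(as.raw(rep(0, 4)), con)      # next-IFD pointer (0 or patched)
    pos <- offset_pos + 4L
  }
  invisible(path)
}

le4 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

tiff_entry <- function(tag, type, value, count = 1L) {
  # type 2 = ASCII (value is an offset), 3 = SHORT, 4 = LONG
  val <- if (type == 3L) {
    c(as.raw(c(value %% 256L, value %/% 256L)), as.raw(c(0, 0)))
  } else {
    le4(value)
  }
  c(as.raw(c(tag %% 256L, tag %/% 256L)),
    as.raw(c(type %% 256L, type %/% 256L)),
    le4(count), val)
}

#' Read a section image written by [write_section_tiff()]
#'
#' Accepts any uncompressed little-endian 16-bit grayscale multi-page TIFF
#' with per-page descriptions naming the channels; channels may also be
#' assigned by index.
#'
#' @param path TIFF file path.
#' @param dys_channel,lam_channel channel names or 1-based page indices;
#'   defaults "DYS"/"LAMA2".
#' @param pixel_size_um physical pixel size to attach.
#' @return a `section_image`.
#' @export
read_section_tiff <- function(path, dys_channel = "DYS", lam_channel = "LAMA2",
                              pixel_size_um = 0.5) {
  raw <- readBin(path, "raw", file.size(path))
  if (rawToChar(raw[1:2]) != "II" || as.integer(raw[3]) != 42L) {
    stopf("'%s' is not a little-endian TIFF", path)
  }
  rd4 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  rd2 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  pages <- list()
  ifd <- rd4(4L)
  while (ifd != 0) {
    n <- rd2(ifd)
    f <- list(description = "")
    for (i in seq_len(n)) {
      e <- ifd + 2L + 12L * (i - 1L)
      tag <- rd2(e); type <- rd2(e + 2L); count <- rd4(e + 4L)
      value <- if (type == 3L) rd2(e + 8L) else rd4(e + 8L)
      key <- names(TIFF_TAGS)[match(tag, TIFF_TAGS)]
      if (is.na(key)) next
      if (key == "description") {
        chars <- raw[value + seq_len(count)]
        f$description <- rawToChar(chars[chars != as.raw(0)])
      } else {
        f[[key]] <- value
      }
    }
    if (!is.null(f$compression) && f$compression != 1L) {
      stopf("unsupported TIFF compression %d", f$compression)
    }
    if (is.null(f$bits) || f$bits != 16L) stopf("only 16-bit TIFFs supported")
    nv <- f$width * f$height
    vals <- readBin(raw[f$strip_offsets + seq_len(2L * nv)], "integer",
                    n = nv, size = 2L, signed = FALSE, endian = "little")
    pages[[length(pages) + 1L]] <- list(
      mat = matrix(as.integer(vals), f$height, f$width, byrow = TRUE),
      name = f$description)
    ifd <- rd4(ifd + 2L + 12L * n)
  }
  pick <- function(ch) {
    if (is.numeric(ch)) {
      if (ch < 1 || ch > length(pages)) stopf("channel index %d out of range", ch)
      return(pages[[ch]]$mat)
    }
    hit <- which(vapply(pages, function(p) identical(p$name, ch), logical(1)))
    if (length(hit) != 1L) {
      stopf("channel '%s' not found in '%s' (pages: %s)", ch, path,
            paste(vapply(pages, `[[`, "", "name"), collapse = ", "))
    }
    pages[[hit]]$mat
  }
  section_image(pick(dys_channel), pick(lam_channel), pixel_size_um)
}

#' Write a fiber label map as a 16-bit TIFF for audit
#'
#' @param labels a `fiber_label_map`.
#' @param path output path.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(inherits(labels, "fiber_label_map"))
  img <- section_image(labels$labels, labels$labels)
  img$LAMA2 <- NULL
  # single-page variant: reuse the writer with one page
  tmp <- section_image(labels$labels, matrix(0L, nrow(labels$labels),
                                             ncol(labels$labels)))
  write_section_tiff(tmp, path)
  invisible(path)
}
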