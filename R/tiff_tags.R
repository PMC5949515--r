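# Minimal TIFF IFD patching: append XResolution/YResolution/ResolutionUnit
# tags to every image directory of a little-endian TIFF written by
# tiff::writeTIFF (which does pixel encoding but not resolution metadata).
# Existing entries are preserved verbatim (their offsets stay valid because
# rebuilt IFDs are appended at the end of the file).

rd_u16 <- function(raw, off) as.integer(raw[off + 1L]) +
  256L * as.integer(raw[off + 2L])
rd_u32 <- function(raw, off) {
  b <- as.numeric(raw[off + (1:4)])
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}
wr_u16 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
wr_u32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256,
                               x %/% 65536 %% 256, x %/% 16777216 %% 256))

tiff_entry <- function(tag, type, count, value_raw4) {
  c(wr_u16(tag), wr_u16(type), wr_u32(count), value_raw4)
}

#' @keywords internal
tiff_set_resolution <- function(path, pixel_size_um) {
  raw <- readBin(path, "raw", file.size(path))
  if (!(raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49) &&
        rd_u16(raw, 2) == 42L)) {
    stop("not a little-endian TIFF: ", path, call. = FALSE)
  }
  # chain of IFD byte offsets (0-based)
  offs <- integer(0)
  o <- rd_u32(raw, 4)
  while (o != 0) {
    offs <- c(offs, o)
    n <- rd_u16(raw, o)
    o <- rd_u32(raw, o + 2L + 12L * n)
  }
  if (length(offs) == 0L) stop("TIFF has no IFD: ", path, call. = FALSE)

  ppcm <- 10000 / pixel_size_um           # pixels per centimeter
  num <- round(ppcm * 100); den <- 100    # RATIONAL to 0.01 px/cm

  out <- raw
  if (length(out) %% 2L == 1L) out <- c(out, as.raw(0))
  rat_off <- length(out)
  out <- c(out, wr_u32(num), wr_u32(den))  # shared by X and Y resolution

  new_offs <- numeric(length(offs))
  blocks <- vector("list", length(offs))
  pos <- length(out)
  for (i in seq_along(offs)) {
    o <- offs[i]
    n <- rd_u16(raw, o)
    keep <- list()
    for (k in seq_len(n)) {
      eo <- o + 2L + 12L * (k - 1L)
      tag <- rd_u16(raw, eo)
      if (!tag %in% c(282L, 283L, 296L)) {
        keep[[length(keep) + 1L]] <- list(tag = tag,
                                          bytes = raw[eo + (1:12)])
      }
    }
    keep[[length(keep) + 1L]] <- list(
      tag = 282L, bytes = tiff_entry(282L, 5L, 1L, wr_u32(rat_off)))
    keep[[length(keep) + 1L]] <- list(
      tag = 283L, bytes = tiff_entry(283L, 5L, 1L, wr_u32(rat_off)))
    keep[[length(keep) + 1L]] <- list(
      tag = 296L, bytes = tiff_entry(296L, 3L, 1L,
                                     c(wr_u16(3L), wr_u16(0L))))
    keep <- keep[order(vapply(keep, `[[`, integer(1), "tag"))]
    body <- c(wr_u16(length(keep)),
              do.call(c, lapply(keep, `[[`, "bytes")))
    blocks[[i]] <- body
    new_offs[i] <- pos
    pos <- pos + length(body) + 4L  # + next-IFD pointer
  }
  for (i in seq_along(blocks)) {
    nxt <- if (i < length(blocks)) new_offs[i + 1L] else 0
    out <- c(out, blocks[[i]], wr_u32(nxt))
  }
  out[5:8] <- wr_u32(new_offs[1])
  writeBin(out, path)
  invisible(path)
}
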