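## Uncompressed 8-bit grayscale AVI I/O.
##
## Videos are stored as a RIFF/AVI container with a single 'vids' stream using
## the 'DIB ' handler: each frame is a bottom-up, 4-byte-row-aligned 8-bit
## device-independent bitmap indexing a grayscale palette. The format is fully
## lossless, so write -> read round-trips are bit-exact, which the test-fixture
## pipeline relies on.

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
fourcc <- function(s) charToRaw(s)

riff_chunk <- function(id, payload) {
  stopifnot(nchar(id) == 4L)
  body <- c(fourcc(id), u32(length(payload)), payload)
  if (length(payload) %% 2L == 1L) body <- c(body, as.raw(0L))
  body
}

riff_list <- function(type, payload) {
  riff_chunk("LIST", c(fourcc(type), payload))
}

#' Write a video as 8-bit grayscale AVI
#'
#' Frames are rounded to integers and clamped to \[0, 255\]; storage is an
#' uncompressed palettized bitmap stream, so the round-trip through
#' [read_avi()] reproduces integer-valued frames exactly.
#'
#' @param frames H x W x T numeric array with values in \[0, 255\].
#' @param path Output file path.
#' @param fps Frames per second (stored as rate 1000*fps / scale 1000).
#' @return `path`, invisibly.
#' @export
write_avi <- function(frames, path, fps = 30) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  d <- dim(frames)
  H <- d[1L]; W <- d[2L]; TT <- d[3L]
  frames <- round(frames)
  if (min(frames) < 0 || max(frames) > 255) stop("frame intensities must lie in [0, 255]")
  stride <- ((W + 3L) %/% 4L) * 4L
  frame_bytes <- stride * H

  avih <- c(u32(round(1e6 / fps)), u32(0L), u32(0L), u32(0L), u32(TT), u32(0L),
            u32(1L), u32(frame_bytes), u32(W), u32(H), u32(c(0L, 0L, 0L, 0L)))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32(0L), u16(0L), u16(0L), u32(0L),
            u32(1000L), u32(round(fps * 1000)), u32(0L), u32(TT),
            u32(frame_bytes), u32(0L), u32(0L),
            u16(c(0L, 0L, W, H)))
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256L)))  # BGRA quads
  strf <- c(u32(40L), u32(W), u32(H), u16(1L), u16(8L), u32(0L), u32(frame_bytes),
            u32(0L), u32(0L), u32(256L), u32(0L), pal)
  hdrl <- riff_list("hdrl", c(riff_chunk("avih", avih),
                              riff_list("strl", c(riff_chunk("strh", strh),
                                                  riff_chunk("strf", strf)))))

  movi_payload <- vector("list", TT)
  row_sel <- H:1L  # DIB rows are stored bottom-up
  for (t in seq_len(TT)) {
    fr <- frames[row_sel, , t, drop = FALSE]
    dim(fr) <- c(H, W)
    buf <- matrix(as.raw(0L), nrow = stride, ncol = H)
    buf[seq_len(W), ] <- as.raw(t(fr))
    movi_payload[[t]] <- riff_chunk("00db", as.raw(buf))
  }
  movi <- riff_list("movi", do.call(c, movi_payload))

  body <- c(fourcc("AVI "), hdrl, movi)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32(length(body)), body), con)
  invisible(path)
}

read_u32 <- function(raw, off) {
  readBin(raw[(off + 1L):(off + 4L)], "integer", size = 4L, endian = "little")
}

## Walk a RIFF byte vector collecting chunks of interest.
#' Read an 8-bit grayscale AVI written by [write_avi()]
#'
#' @param path File path.
#' @return List with `frames` (H x W x T integer array) and `fps`.
#' @export
read_avi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "AVI ")
    stop("not a RIFF/AVI file: ", path)
  W <- NULL; H <- NULL; fps <- NA_real_
  frames_raw <- list()

  walk <- function(from, to) {
    off <- from
    while (off + 8L <= to) {
      id <- rawToChar(raw[(off + 1L):(off + 4L)])
      sz <- read_u32(raw, off + 4L)
      data_from <- off + 8L
      if (id == "LIST") {
        walk(data_from + 4L, data_from + sz)
      } else if (id == "strh") {
        scale <- read_u32(raw, data_from + 20L)
        rate <- read_u32(raw, data_from + 24L)
        if (scale > 0L) fps <<- rate / scale
      } else if (id == "strf") {
        W <<- read_u32(raw, data_from + 4L)
        H <<- read_u32(raw, data_from + 8L)
      } else if (id %in% c("00db", "00dc")) {
        frames_raw[[length(frames_raw) + 1L]] <<- raw[(data_from + 1L):(data_from + sz)]
      }
      off <- data_from + sz + (sz %% 2L)
    }
  }
  walk(12L, length(raw))
  if (is.null(W) || length(frames_raw) == 0L) stop("no video stream found in ", path)

  stride <- ((W + 3L) %/% 4L) * 4L
  TT <- length(frames_raw)
  frames <- array(0L, dim = c(H, W, TT))
  for (t in seq_len(TT)) {
    buf <- matrix(frames_raw[[t]], nrow = stride, ncol = H)
    fr <- t(matrix(as.integer(buf[seq_len(W), ]), nrow = W, ncol = H))
    frames[, , t] <- fr[H:1L, ]
  }
  list(frames = frames, fps = fps)
}
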