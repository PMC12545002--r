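#' Construct a CEUS cineloop
#'
#' A cineloop is the dynamic recording of a contrast bolus transit: a stack of
#' 2-D intensity frames plus one acquisition time per frame. Intensities are
#' assumed to be linearized echo power (proportional to microbubble
#' concentration); if the source data are log-compressed, set
#' `meta$log_compressed = TRUE` and call [delinearize()] before TIC analysis.
#'
#' @param frames numeric 3-D array indexed `(time, row, column)`; row 1 is the
#'   top of the image. All intensities must be finite and non-negative.
#' @param times numeric vector of acquisition times in seconds since the start
#'   of the recording, one per frame, strictly increasing, `times[1] >= 0`.
#' @param pixel_spacing optional length-2 numeric, mm per pixel `(row, col)`.
#' @param meta named list of free-form acquisition metadata (probe, mechanical
#'   index, agent dose, provenance, ...).
#' @return An object of class `cineloop`.
#' @export
cineloop <- function(frames, times, pixel_spacing = NULL, meta = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array indexed (time, row, column)", call. = FALSE)
  }
  storage.mode(frames) <- "double"
  times <- as.double(times)
  n <- dim(frames)[1L]
  if (n < 2L) stop("cineloop must have at least 2 frames", call. = FALSE)
  if (length(times) != n) {
    stop("`times` must have one entry per frame (", n, "), got ", length(times),
         call. = FALSE)
  }
  if (anyNA(times) || times[1L] < 0) {
    stop("`times` must be non-missing with times[1] >= 0", call. = FALSE)
  }
  bad <- which(diff(times) <= 0)
  if (length(bad)) {
    stop("`times` must be strictly increasing; first violation at frame ",
         bad[1L] + 1L, call. = FALSE)
  }
  if (!all(is.finite(frames))) stop("intensities must be finite", call. = FALSE)
  if (min(frames) < 0) stop("intensities must be >= 0", call. = FALSE)
  if (!is.null(pixel_spacing)) {
    pixel_spacing <- as.double(pixel_spacing)
    stopifnot(length(pixel_spacing) == 2L, all(pixel_spacing > 0))
  }
  structure(
    list(frames = frames, times = times, pixel_spacing = pixel_spacing,
         meta = as.list(meta)),
    class = "cineloop"
  )
}

#' @export
print.cineloop <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cineloop> %d frames of %d x %d px, t = [%.2f, %.2f] s\n",
              d[1], d[2], d[3], x$times[1], x$times[length(x$times)]))
  if (!is.null(x$pixel_spacing)) {
    cat(sprintf("  pixel spacing: %.3f x %.3f mm\n",
                x$pixel_spacing[1], x$pixel_spacing[2]))
  }
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cineloop <- function(x) dim(x$frames)

n_frames <- function(loop) dim(loop$frames)[1L]
frame_dim <- function(loop) dim(loop$frames)[2:3]

#' Undo log compression of cineloop intensities
#'
#' TIC analysis assumes intensities linear in microbubble concentration.
#' Vendor exports are sometimes log-compressed; this maps `I -> 10^(I/k)`.
#'
#' @param loop a [cineloop()].
#' @param k compression constant (intensity units per decade), default 10.
#' @return A `cineloop` with linearized intensities and
#'   `meta$log_compressed = FALSE`.
#' @export
delinearize <- function(loop, k = 10) {
  stopifnot(inherits(loop, "cineloop"), k > 0)
  out <- loop
  out$frames <- 10^(loop$frames / k)
  out$meta$log_compressed <- FALSE
  out$meta$delinearized_k <- k
  out
}

#' Construct a region-of-interest mask
#'
#' The ROI delineates the whole prostate gland on the reference frame; all
#' pixel-wise analysis is restricted to it.
#'
#' @param mask logical (or 0/1 numeric) matrix, same row/column dimensions as
#'   the cineloop frames it accompanies. Must contain at least one `TRUE`.
#' @return An object of class `roi_mask` (a logical matrix with attribute
#'   `n_pixels`).
#' @export
roi_mask <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  m <- matrix(as.logical(mask != 0), nrow(mask), ncol(mask))
  if (anyNA(m)) stop("mask must not contain missing values", call. = FALSE)
  np <- sum(m)
  if (np < 1L) stop("empty ROI: mask has no TRUE pixels", call. = FALSE)
  structure(m, n_pixels = np, class = c("roi_mask", "matrix", "array"))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d in ROI (%.1f%%)\n",
              nrow(x), ncol(x), attr(x, "n_pixels"),
              100 * attr(x, "n_pixels") / length(x)))
  invisible(x)
}

# Every (cineloop, mask) consumer funnels through this check.
check_congruent <- function(loop, mask) {
  fd <- frame_dim(loop)
  if (nrow(mask) != fd[1L] || ncol(mask) != fd[2L]) {
    stop(sprintf("mask dimensions (%d x %d) do not match frames (%d x %d)",
                 nrow(mask), ncol(mask), fd[1L], fd[2L]), call. = FALSE)
  }
  invisible(TRUE)
}

## ---- portable container ----------------------------------------------------
## Single-file archive: 8-byte magic, int32 header length, JSON header
## (dims, spacing flag, metadata), then little-endian float64 arrays
## (times, spacing, frames). Bit-exact round trip for doubles.

CONTAINER_MAGIC <- charToRaw("CEUSARR1")

#' Write a cineloop to the portable container format
#'
#' @param loop a [cineloop()].
#' @param path output file path (conventionally `.ceus`).
#' @return `path`, invisibly.
#' @export
write_cineloop <- function(loop, path) {
  stopifnot(inherits(loop, "cineloop"))
  header <- list(
    format = "ceus-container", version = 1L,
    dims = dim(loop$frames),
    has_spacing = !is.null(loop$pixel_spacing),
    meta = loop$meta
  )
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- tryCatch(suppressWarnings(file(path, "wb")), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeBin(CONTAINER_MAGIC, con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  writeBin(loop$times, con, size = 8L, endian = "little")
  if (header$has_spacing) {
    writeBin(loop$pixel_spacing, con, size = 8L, endian = "little")
  }
  writeBin(as.vector(loop$frames), con, size = 8L, endian = "little")
  invisible(path)
}

read_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic, CONTAINER_MAGIC)) {
    stop("'", path, "' is not a cineloop container (bad magic)", call. = FALSE)
  }
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)),
                               simplifyVector = TRUE, simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
  d <- as.integer(header$dims)
  times <- readBin(con, "double", n = d[1L], size = 8L, endian = "little")
  spacing <- NULL
  if (isTRUE(header$has_spacing)) {
    spacing <- readBin(con, "double", n = 2L, size = 8L, endian = "little")
  }
  frames <- array(readBin(con, "double", n = prod(d), size = 8L,
                          endian = "little"), dim = d)
  cineloop(frames, times, pixel_spacing = spacing, meta = header$meta)
}

#' Read a cineloop from disk
#'
#' Supports the package's portable container format and basic multi-frame
#' DICOM (explicit VR little endian; `NumberOfFrames` with per-frame times
#' from `FrameTimeVector`, `FrameTime`, or `CineRate`). Vendor-private
#' contrast tags are ignored.
#'
#' @param path file path.
#' @param format `"auto"` (sniff the magic bytes), `"container"`, or `"dicom"`.
#' @param frame_rate optional frames/s used to synthesize times when the DICOM
#'   file carries no frame-time information.
#' @return A [cineloop()]; provenance is recorded in `meta$source`.
#' @export
read_cineloop <- function(path, format = c("auto", "container", "dicom"),
                          frame_rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (format == "auto") {
    con <- file(path, "rb")
    head <- readBin(con, "raw", n = 132L)
    close(con)
    format <- if (length(head) >= 8 && identical(head[1:8], CONTAINER_MAGIC)) {
      "container"
    } else if (length(head) >= 132 &&
               identical(head[129:132], charToRaw("DICM"))) {
      "dicom"
    } else {
      stop("unrecognized file format: '", path, "'", call. = FALSE)
    }
  }
  loop <- switch(format,
    container = read_container(path),
    dicom = read_dicom_cineloop(path, frame_rate = frame_rate)
  )
  loop$meta$source <- path
  loop
}

## ---- minimal multi-frame DICOM reader --------------------------------------
## Reads only the basic multi-frame layout from explicit-VR little-endian
## files: Rows/Columns/NumberOfFrames/BitsAllocated + frame timing + PixelData.

dcm_tag <- function(group, element) sprintf("%04x,%04x", group, element)

read_dicom_elements <- function(raw) {
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  out <- list()
  pos <- 1L
  n <- length(raw)
  while (pos + 8L <= n + 1L) {
    grp <- readBin(raw[pos:(pos + 1L)], "integer", size = 2L,
                   endian = "little", signed = FALSE)
    ele <- readBin(raw[(pos + 2L):(pos + 3L)], "integer", size = 2L,
                   endian = "little", signed = FALSE)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported DICOM encoding (implicit VR?) at byte ", pos,
           call. = FALSE)
    }
    if (vr %in% long_vrs) {
      len <- readBin(raw[(pos + 8L):(pos + 11L)], "integer", size = 4L,
                     endian = "little")
      body_at <- pos + 12L
    } else {
      len <- readBin(raw[(pos + 6L):(pos + 7L)], "integer", size = 2L,
                     endian = "little", signed = FALSE)
      body_at <- pos + 8L
    }
    if (len < 0L) {
      stop("undefined-length DICOM element ", dcm_tag(grp, ele),
           " not supported", call. = FALSE)
    }
    body <- if (len > 0L) raw[body_at:(body_at + len - 1L)] else raw(0)
    out[[dcm_tag(grp, ele)]] <- list(vr = vr, body = body)
    pos <- body_at + len
  }
  out
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$body))
}
dcm_numbers <- function(el) {
  s <- dcm_string(el)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.double(strsplit(s, "\\\\")[[1]])
}
dcm_uint16 <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$body, "integer", size = 2L, endian = "little", signed = FALSE)
}

read_dicom_cineloop <- function(path, frame_rate = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 200 || !identical(raw[129:132], charToRaw("DICM"))) {
    stop("'", path, "' is not a DICOM part-10 file", call. = FALSE)
  }
  els <- read_dicom_elements(raw[-(1:132)])
  ts <- dcm_string(els[[dcm_tag(0x0002, 0x0010)]])
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1") {
    stop("unsupported DICOM transfer syntax '", ts,
         "' (only explicit VR little endian)", call. = FALSE)
  }
  rows <- dcm_uint16(els[[dcm_tag(0x0028, 0x0010)]])
  cols <- dcm_uint16(els[[dcm_tag(0x0028, 0x0011)]])
  bits <- dcm_uint16(els[[dcm_tag(0x0028, 0x0100)]])
  nf <- dcm_numbers(els[[dcm_tag(0x0028, 0x0008)]])
  px <- els[[dcm_tag(0x7fe0, 0x0010)]]
  if (is.null(rows) || is.null(cols) || is.null(px)) {
    stop("corrupt DICOM: missing Rows/Columns/PixelData", call. = FALSE)
  }
  nf <- if (is.null(nf)) 1L else as.integer(nf[1])
  if (nf < 2L) {
    stop("single-frame DICOM: a cineloop needs at least 2 frames",
         call. = FALSE)
  }
  if (is.null(bits)) bits <- 8L
  if (!bits %in% c(8L, 16L)) {
    stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  }
  vals <- readBin(px$body, "integer", n = nf * rows * cols,
                  size = bits / 8L, endian = "little", signed = FALSE)
  if (length(vals) < nf * rows * cols) {
    stop("corrupt DICOM: PixelData shorter than Rows*Columns*NumberOfFrames",
         call. = FALSE)
  }
  # DICOM pixel data is row-major within each frame
  frames <- aperm(array(as.double(vals), dim = c(cols, rows, nf)), c(3, 2, 1))

  ftv <- dcm_numbers(els[[dcm_tag(0x0018, 0x1065)]])   # FrameTimeVector, ms
  ft <- dcm_numbers(els[[dcm_tag(0x0018, 0x1063)]])    # FrameTime, ms
  cine <- dcm_numbers(els[[dcm_tag(0x0018, 0x0040)]])  # CineRate, fps
  meta <- list(format = "dicom")
  if (!is.null(ftv) && length(ftv) == nf) {
    times <- cumsum(c(0, ftv[-1])) / 1000
    meta$frame_times_from <- "FrameTimeVector"
  } else if (!is.null(ft)) {
    times <- (seq_len(nf) - 1L) * ft[1] / 1000
    meta$frame_times_from <- "FrameTime"
  } else if (!is.null(cine) && cine[1] > 0) {
    times <- (seq_len(nf) - 1L) / cine[1]
    meta$frame_times_from <- "CineRate"
  } else if (!is.null(frame_rate) && frame_rate > 0) {
    times <- (seq_len(nf) - 1L) / frame_rate
    meta$frame_times_from <- "stated frame_rate"
  } else {
    stop("DICOM carries no frame-time information; supply `frame_rate`",
         call. = FALSE)
  }
  spacing <- dcm_numbers(els[[dcm_tag(0x0028, 0x0030)]])
  cineloop(frames, times, pixel_spacing = spacing, meta = meta)
}

## ---- mask I/O ---------------------------------------------------------------

#' Read an ROI mask from a PNG or CSV file
#'
#' Any nonzero pixel is `TRUE`. For multi-channel PNGs the first channel is
#' used.
#'
#' @param path `.png` (0/255 convention) or `.csv` (0/1 grid, no header).
#' @param loop optional [cineloop()] whose frame dimensions the mask must
#'   match; a mismatch is an error.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, loop = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    m <- img != 0
  } else {
    m <- as.matrix(utils::read.csv(path, header = FALSE)) != 0
    dimnames(m) <- NULL
  }
  mask <- roi_mask(m)
  if (!is.null(loop)) check_congruent(loop, mask)
  mask
}

#' Write an ROI mask to PNG (0/255) or CSV (0/1)
#'
#' @param mask an [roi_mask()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  } else {
    utils::write.table(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                       path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
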