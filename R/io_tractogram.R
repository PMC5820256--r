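#' Tractogram container
#'
#' A tractogram is an ordered list of streamlines, each an n x 3 matrix of
#' points in world millimetres (RAS). Every streamline must have at least
#' two points and finite coordinates. Streamlines carry integer ids that
#' survive selection and filtering so that results can be traced back to the
#' original file.
#'
#' @param streamlines list of n_i x 3 numeric matrices (n_i >= 2).
#' @param ids integer ids, one per streamline (default 1..N).
#' @return an object of class \code{tractogram}.
#' @export
tractogram <- function(streamlines, ids = NULL) {
  stopifnot(is.list(streamlines))
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3) stop("tractogram: streamline must have 3 columns")
    if (nrow(s) < 2) stop("tractogram: streamline with fewer than 2 points")
    if (any(!is.finite(s))) stop("tractogram: non-finite coordinate")
    s
  })
  if (is.null(ids)) ids <- seq_along(streamlines)
  ids <- as.integer(ids)
  if (length(ids) != length(streamlines))
    stop("tractogram: one id per streamline required")
  structure(list(streamlines = streamlines, ids = ids),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- sum(vapply(x$streamlines, nrow, 1L))
  cat("tractogram:", length(x$streamlines), "streamlines,", np, "points\n")
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Read a tractogram (TCK or TRK)
#'
#' Streamline coordinates are always returned in world (scanner RAS)
#' millimetre space regardless of the on-disk convention: TCK files already
#' store world coordinates; TRK files store corner-based voxel-mm
#' coordinates which are mapped through the header's voxel-to-RAS affine
#' (\code{world = A \%*\% (p / voxel_size - 0.5)} in homogeneous form).
#' The streamline count is preserved exactly.
#'
#' @param path file path ending in \code{.tck} or \code{.trk}.
#' @param space_check when \code{TRUE} (default), verify that all
#'   coordinates are finite and within a plausible head-sized range
#'   (|x| < 1000 mm), guarding against voxel-index data mislabeled as mm.
#' @return a \code{\link{tractogram}}.
#' @export
read_tractogram <- function(path, space_check = TRUE) {
  if (!file.exists(path)) stop("read_tractogram: no such file: ", path)
  if (file.info(path)$size == 0)
    stop("read_tractogram: empty tractogram file: ", path)
  ext <- tolower(tools::file_ext(path))
  tg <- switch(ext,
               tck = read_tck(path),
               trk = read_trk(path),
               stop("read_tractogram: unsupported extension '.", ext,
                    "' (expected .tck or .trk)"))
  if (space_check) {
    rng <- range(unlist(lapply(tg$streamlines, range)))
    if (any(!is.finite(rng)) || max(abs(rng)) > 1000)
      stop("read_tractogram: coordinates outside plausible world-mm range; ",
           "is this file really in scanner space?")
  }
  ot_log("read_tractogram: ", length(tg$streamlines),
         " streamlines from ", path)
  tg
}

#' Write a tractogram (TCK or TRK)
#'
#' Coordinates are float32 on disk in both formats. For TRK the world
#' coordinates are converted to the corner-based voxel-mm convention using
#' \code{affine} (voxel-to-RAS) and \code{voxel_size}; pass a non-RAS affine
#' to exercise the convention conversion.
#'
#' @param tg a \code{\link{tractogram}} in world mm.
#' @param path output path ending in \code{.tck} or \code{.trk}.
#' @param affine 4 x 4 voxel-to-RAS matrix (TRK only; default identity).
#' @param voxel_size length-3 voxel size in mm (TRK only; default 1,1,1).
#' @param dim length-3 integer image dimensions recorded in the TRK header.
#' @return \code{path}, invisibly.
#' @export
write_tractogram <- function(tg, path, affine = diag(4),
                             voxel_size = c(1, 1, 1),
                             dim = c(100L, 100L, 100L)) {
  stopifnot(inherits(tg, "tractogram"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = write_tck(tg, path),
         trk = write_trk(tg, path, affine, voxel_size, dim),
         stop("write_tractogram: unsupported extension '.", ext, "'"))
  ot_log("write_tractogram: ", length(tg$streamlines),
         " streamlines to ", path)
  invisible(path)
}

## ---- TCK (MRtrix) ----------------------------------------------------------

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1, warn = FALSE)
  if (!identical(magic, "mrtrix tracks"))
    stop("read_tractogram: malformed TCK header: missing 'mrtrix tracks' ",
         "magic line")
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1, warn = FALSE)
    if (length(ln) == 0)
      stop("read_tractogram: malformed TCK header: no END line")
    if (identical(trimws(ln), "END")) break
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  if (is.null(fields$datatype) || fields$datatype != "Float32LE")
    stop("read_tractogram: malformed TCK header: field 'datatype' must be ",
         "Float32LE")
  if (is.null(fields$file))
    stop("read_tractogram: malformed TCK header: missing field 'file'")
  offset <- as.integer(sub("^\\.\\s+", "", fields$file))
  if (is.na(offset))
    stop("read_tractogram: malformed TCK header: field 'file' has no offset")
  seek(con, offset)
  n_float <- (file.info(path)$size - offset) / 4
  raw <- readBin(con, "double", n = n_float, size = 4, endian = "little")
  if (length(raw) %% 3 != 0)
    stop("read_tractogram: truncated TCK data section")
  pts <- matrix(raw, ncol = 3, byrow = TRUE)
  fin <- which(is.infinite(pts[, 1]))
  if (length(fin) == 0)
    stop("read_tractogram: truncated TCK file (no Inf terminator)")
  pts <- pts[seq_len(fin[1] - 1), , drop = FALSE]
  sep <- is.nan(pts[, 1])
  grp <- cumsum(c(TRUE, head(sep, -1)))
  keep <- !sep
  sl <- split.data.frame(pts[keep, , drop = FALSE], grp[keep])
  sl <- lapply(sl, function(m) { m <- as.matrix(m); dimnames(m) <- NULL; m })
  names(sl) <- NULL
  tractogram(sl)
}

write_tck <- function(tg, path) {
  n <- length(tg$streamlines)
  make_header <- function(offset) {
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           "count: ", n, "\n",
           "file: . ", offset, "\nEND\n")
  }
  offset <- nchar(make_header(0))
  while (nchar(make_header(offset)) != offset)
    offset <- nchar(make_header(offset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(make_header(offset), con, eos = NULL)
  for (s in tg$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

## ---- TRK (TrackVis, version 2) --------------------------------------------

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", n = 6)
  if (!identical(rawToChar(id[1:5]), "TRACK"))
    stop("read_tractogram: malformed TRK header: field 'id_string' is not ",
         "'TRACK'")
  invisible(readBin(con, "integer", n = 3, size = 2,
                    endian = "little"))                          # dim
  voxel_size <- readBin(con, "double", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "double", n = 3, size = 4, endian = "little")) # origin
  n_scalars <- readBin(con, "integer", n = 1, size = 2,
                       endian = "little")
  invisible(readBin(con, "raw", n = 200))                       # scalar names
  n_properties <- readBin(con, "integer", n = 1, size = 2,
                          endian = "little")
  invisible(readBin(con, "raw", n = 200))                       # property names
  affine <- matrix(readBin(con, "double", n = 16, size = 4, endian = "little"),
                   4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", n = 444 + 4 + 4 + 24 + 2 + 6))
  n_count <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  version <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (hdr_size != 1000L)
    stop("read_tractogram: malformed TRK header: field 'hdr_size' is ",
         hdr_size, ", expected 1000")
  if (version >= 2L && affine[4, 4] != 1)
    stop("read_tractogram: malformed TRK header: field 'vox_to_ras' is ",
         "unset (all zero)")
  if (any(voxel_size <= 0))
    stop("read_tractogram: malformed TRK header: field 'voxel_size' is not ",
         "positive")
  sl <- vector("list", max(n_count, 0))
  i <- 0
  repeat {
    np <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (length(np) == 0) break
    vals <- readBin(con, "double",
                    n = np * (3 + n_scalars) + n_properties,
                    size = 4, endian = "little")
    if (length(vals) < np * (3 + n_scalars) + n_properties)
      stop("read_tractogram: truncated TRK streamline record")
    m <- matrix(vals[seq_len(np * (3 + n_scalars))], ncol = 3 + n_scalars,
                byrow = TRUE)[, 1:3, drop = FALSE]
    # corner-based voxmm -> voxel index -> world RAS
    vox <- sweep(m, 2, voxel_size, "/") - 0.5
    world <- cbind(vox, 1) %*% t(affine)
    i <- i + 1
    sl[[i]] <- world[, 1:3, drop = FALSE]
  }
  if (n_count > 0 && i != n_count)
    stop("read_tractogram: truncated TRK file: header count ", n_count,
         " but ", i, " streamlines read")
  tractogram(sl[seq_len(i)])
}

write_trk <- function(tg, path, affine, voxel_size, dim) {
  stopifnot(all(dim(affine) == c(4, 4)), length(voxel_size) == 3)
  inv_aff <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")       # origin
  writeBin(0L, con, size = 2, endian = "little")               # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")               # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                      # reserved
  vo <- affine_orientation(affine)
  writeBin(c(charToRaw(vo), raw(4 - nchar(vo))), con)          # voxel_order
  writeBin(raw(4), con)                                        # pad2
  writeBin(numeric(6), con, size = 4, endian = "little")       # img orient
  writeBin(raw(2 + 6), con)                                    # pad1, inverts
  writeBin(length(tg$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")               # version
  writeBin(1000L, con, size = 4, endian = "little")
  for (s in tg$streamlines) {
    vox <- cbind(s, 1) %*% t(inv_aff)
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, voxel_size, "*")
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.vector(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

# Three-letter orientation code (e.g. "RAS", "LPS") of a voxel-to-world affine.
affine_orientation <- function(affine) {
  letters_pos <- c("R", "A", "S"); letters_neg <- c("L", "P", "I")
  code <- character(3)
  for (j in 1:3) {
    ax <- which.max(abs(affine[1:3, j]))
    code[j] <- if (affine[ax, j] >= 0) letters_pos[ax] else letters_neg[ax]
  }
  paste(code, collapse = "")
}
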