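#' Read and write labeled surfaces
#'
#' Surfaces are stored as a plain-text OFF mesh (the standard ASCII
#' `OFF` polygon format: header line, counts line, vertex coordinates, then
#' triangle rows as `3 i j k` with 0-based indices) plus a label table — a
#' two-column CSV (`vertex`, `label`, 1-based vertex index) sitting next to
#' the mesh with suffix \code{.labels.csv}, or passed explicitly. Vertex
#' normals and areas are recomputed on read; all invariants of
#' \code{\link{labeled_surface}} are enforced.
#'
#' Coordinates are written with full \code{\%.17g} precision so that a
#' write/read round trip is value-exact for doubles.
#'
#' @param path mesh file path.
#' @param labels_path optional label-table path; default
#'   \code{<path>.labels.csv} if it exists, else all labels 0.
#' @param surface a \code{labeled_surface}.
#' @return \code{read_surface}: a \code{labeled_surface};
#'   \code{write_surface}: \code{path}, invisibly.
#' @export
read_surface <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop("read_surface: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2 || !identical(trimws(lines[1]), "OFF"))
    stop("read_surface: not an OFF mesh (missing 'OFF' header): ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- as.integer(counts[1]); nt <- as.integer(counts[2])
  if (length(lines) < 2 + nv + nt)
    stop("read_surface: truncated OFF file (expected ", nv + nt,
         " element rows)")
  vert <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                 nv, 3, byrow = TRUE)
  trows <- matrix(scan(text = lines[(3 + nv):(2 + nv + nt)], quiet = TRUE),
                  nt, 4, byrow = TRUE)
  if (any(trows[, 1] != 3))
    stop("read_surface: non-triangular face in OFF file")
  tri <- trows[, 2:4, drop = FALSE] + 1L

  if (is.null(labels_path)) {
    cand <- paste0(path, ".labels.csv")
    labels_path <- if (file.exists(cand)) cand else NA_character_
  }
  labels <- integer(nv)
  if (!is.na(labels_path)) {
    lt <- read.csv(labels_path)
    if (!all(c("vertex", "label") %in% names(lt)))
      stop("read_surface: label table must have columns 'vertex', 'label'")
    if (nrow(lt) != nv)
      stop("read_surface: label array length (", nrow(lt),
           ") does not match vertex count (", nv, ")")
    labels[lt$vertex] <- as.integer(lt$label)
  }
  surf <- labeled_surface(vert, tri, labels)
  ot_log("read_surface: ", nv, " vertices, ", nt, " triangles from ", path)
  surf
}

#' @rdname read_surface
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "labeled_surface"))
  nv <- nrow(surface$vertices); nt <- nrow(surface$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", paste(nv, nt, 0)), con)
  writeLines(apply(surface$vertices, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(apply(surface$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  write.csv(data.frame(vertex = seq_len(nv), label = surface$labels),
            paste0(path, ".labels.csv"), row.names = FALSE)
  ot_log("write_surface: ", nv, " vertices to ", path)
  invisible(path)
}
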