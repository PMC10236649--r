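# File formats: STL (binary write; binary + ASCII read), landmark CSV,
# NRRD volumes and vector fields. All coordinates are world millimetres.

#' Read an STL surface file
#'
#' Accepts binary and ASCII STL. Duplicate vertices are merged on read with
#' a tolerance of 1e-6 mm so shared triangle corners become true topological
#' neighbours (STL stores each triangle's corners independently).
#'
#' @param path path to an `.stl` file.
#' @return A [triangle_mesh].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (sz < 15) stop("malformed STL (file too short, ", sz, " bytes)")
  con <- file(path, "rb")
  on.exit(close(con))
  head84 <- readBin(con, "raw", n = min(sz, 84))
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    ntri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    body <- readBin(con, "raw", n = 50 * ntri)
    if (length(body) < 50 * ntri) {
      stop("malformed STL: truncated at byte ", 84 + length(body))
    }
    m <- matrix(body, nrow = 50)
    tri <- vapply(seq_len(ntri), function(t) {
      readBin(m[13:48, t], "numeric", n = 9, size = 4, endian = "little")
    }, numeric(9))
    verts <- matrix(as.numeric(tri), ncol = 3, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    if (!grepl("^\\s*solid", txt[1], ignore.case = TRUE)) {
      stop("malformed STL: not binary-sized and no ASCII 'solid' header ",
           "(byte 0)")
    }
    vlines <- grep("^\\s*vertex\\s", txt, ignore.case = TRUE, value = TRUE)
    if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
      stop("malformed ASCII STL: vertex count ", length(vlines),
           " is not a multiple of 3")
    }
    nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(p) {
      as.numeric(p[2:4])
    })
    verts <- do.call(rbind, nums)
    if (any(!is.finite(verts))) stop("malformed ASCII STL: non-numeric vertex")
  }
  merge_mesh_vertices(verts, tol = 1e-6)
}

# fuse duplicated corners into shared vertices (tolerance in mm)
merge_mesh_vertices <- function(corner_matrix, tol = 1e-6) {
  key <- paste(round(corner_matrix[, 1] / tol), round(corner_matrix[, 2] / tol),
               round(corner_matrix[, 3] / tol))
  remap <- as.integer(factor(key, levels = unique(key)))
  vertices <- corner_matrix[!duplicated(key), , drop = FALSE]
  faces <- matrix(remap, ncol = 3, byrow = TRUE)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  triangle_mesh(vertices, faces[keep, , drop = FALSE])
}

#' Write a binary STL surface file
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "bonatlas binary STL"))[1:80]
  writeBin(hdr, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  V <- mesh$vertices
  F <- mesh$faces
  for (t in seq_len(nf)) {
    a <- V[F[t, 1], ]; b <- V[F[t, 2], ]; c <- V[F[t, 3], ]
    n <- pracma::cross(b - a, c - a)
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, a, b, c)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

#' Read landmarks from CSV
#'
#' Expects a header `name,x,y,z` (extra columns are ignored with a warning);
#' coordinates are millimetres.
#'
#' @param path CSV path.
#' @param frame frame identifier to attach.
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path, frame = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns name,x,y,z")
  }
  if (length(setdiff(names(df), need)) > 0) {
    warning("ignoring extra landmark columns: ",
            paste(setdiff(names(df), need), collapse = ", "))
  }
  pts <- as.matrix(df[, c("x", "y", "z")])
  if (!is.numeric(pts) || any(!is.finite(pts))) {
    stop("non-numeric landmark coordinates")
  }
  landmark_set(df$name, pts, frame = frame)
}

#' Write landmarks to CSV
#'
#' @param set a [landmark_set].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(set, path) {
  stopifnot(inherits(set, "landmark_set"))
  df <- data.frame(name = set$names, x = set$points[, 1],
                   y = set$points[, 2], z = set$points[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scalar volume or displacement field as NRRD
#'
#' Raw little-endian encoding with voxel-centre origin and axis-aligned
#' spacing in the header. Fields are written as a 4D NRRD whose slowest
#' axis holds the three vector components.
#'
#' @param x a [scalar_volume] or [displacement_field].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path) {
  if (inherits(x, "scalar_volume")) {
    arr <- x$values
    sizes <- x$dims
    dimn <- 3L
  } else if (inherits(x, "displacement_field")) {
    arr <- x$u
    sizes <- c(x$dims, 3L)
    dimn <- 4L
  } else {
    stop("x must be a scalar_volume or displacement_field")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# bonatlas volume",
           "type: double",
           sprintf("dimension: %d", dimn),
           sprintf("sizes: %s", paste(sizes, collapse = " ")),
           "encoding: raw",
           "endian: little",
           sprintf("spacings: %s", paste(c(x$spacing, if (dimn == 4L) NA),
                                         collapse = " ")),
           sprintf("axis mins: %s", paste(c(x$origin, if (dimn == 4L) NA),
                                          collapse = " ")),
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a NRRD volume or displacement field written by [write_nrrd()]
#'
#' Supports the minimal raw-encoded subset this package writes.
#'
#' @param path NRRD path.
#' @return A [scalar_volume] (3D) or [displacement_field] (4D).
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed NRRD: no data section")
    if (line == "") break
    hdr <- c(hdr, line)
  }
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^", key, ": "), "", ln[1])
  }
  if (!grepl("^NRRD", hdr[1])) stop("malformed NRRD: bad magic")
  if (get_field("encoding") != "raw") stop("only raw NRRD supported")
  sizes <- as.integer(strsplit(get_field("sizes"), " ")[[1]])
  sp <- suppressWarnings(as.numeric(strsplit(get_field("spacings"), " ")[[1]]))
  or <- suppressWarnings(as.numeric(strsplit(get_field("axis mins"), " ")[[1]]))
  n <- prod(sizes)
  vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(vals) < n) stop("malformed NRRD: truncated data")
  if (length(sizes) == 3L) {
    scalar_volume(array(vals, sizes), or[1:3], sp[1:3])
  } else if (length(sizes) == 4L && sizes[4] == 3L) {
    displacement_field(array(vals, sizes), or[1:3], sp[1:3])
  } else {
    stop("unsupported NRRD dimensionality")
  }
}
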