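#' Write a mesh or surface as a VTK XML unstructured grid (VTU)
#'
#' ASCII VTU with full-precision coordinates, cell-data field `region` for
#' tet meshes, and arbitrary per-vertex point-data arrays (e.g.
#' `displacement`, `deviation_mm`). Tet meshes are written as VTK cell type
#' 10, surfaces as triangles (type 5).
#'
#' @param x A `tet_mesh` or `tri_surface`.
#' @param path Output path.
#' @param point_data Named list of per-vertex data (vectors or n x k
#'   matrices).
#' @param cell_data Named list of per-cell data; a tet mesh's `region` is
#'   added automatically.
#' @param provenance Optional character vector written as an XML comment
#'   (config hash, seed, version).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(x, path, point_data = list(), cell_data = list(),
                      provenance = NULL) {
  if (inherits(x, "tet_mesh")) {
    cells <- x$tets; ctype <- 10L
    if (is.null(cell_data$region)) cell_data$region <- x$region
  } else if (inherits(x, "tri_surface")) {
    cells <- x$triangles; ctype <- 5L
  } else stop("write_vtu needs a tet_mesh or tri_surface", call. = FALSE)
  v <- x$vertices
  ncell <- nrow(cells); npt <- nrow(v)
  num <- function(m) paste(sprintf("%.17g", t(m)), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("<?xml version=\"1.0\"?>")
  if (!is.null(provenance))
    w("<!-- ", paste(provenance, collapse = "; "), " -->")
  w("<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" byte_order=\"LittleEndian\">")
  w("  <UnstructuredGrid>")
  w("    <Piece NumberOfPoints=\"", npt, "\" NumberOfCells=\"", ncell, "\">")
  w("      <Points>")
  w("        <DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">")
  w(num(v))
  w("        </DataArray>")
  w("      </Points>")
  w("      <Cells>")
  w("        <DataArray type=\"Int64\" Name=\"connectivity\" format=\"ascii\">")
  w(paste(t(cells) - 1L, collapse = " "))
  w("        </DataArray>")
  w("        <DataArray type=\"Int64\" Name=\"offsets\" format=\"ascii\">")
  w(paste(seq_len(ncell) * ncol(cells), collapse = " "))
  w("        </DataArray>")
  w("        <DataArray type=\"UInt8\" Name=\"types\" format=\"ascii\">")
  w(paste(rep.int(ctype, ncell), collapse = " "))
  w("        </DataArray>")
  w("      </Cells>")
  if (length(point_data)) {
    w("      <PointData>")
    for (nm in names(point_data)) {
      pd <- point_data[[nm]]
      ncomp <- if (is.matrix(pd)) ncol(pd) else 1L
      w("        <DataArray type=\"Float64\" Name=\"", nm,
        "\" NumberOfComponents=\"", ncomp, "\" format=\"ascii\">")
      w(num(if (is.matrix(pd)) pd else matrix(pd, ncol = 1L)))
      w("        </DataArray>")
    }
    w("      </PointData>")
  }
  if (length(cell_data)) {
    w("      <CellData>")
    for (nm in names(cell_data)) {
      cd <- cell_data[[nm]]
      is_int <- is.integer(cd)
      w("        <DataArray type=\"", if (is_int) "Int32" else "Float64",
        "\" Name=\"", nm, "\" format=\"ascii\">")
      w(if (is_int) paste(cd, collapse = " ") else
        paste(sprintf("%.17g", cd), collapse = " "))
      w("        </DataArray>")
    }
    w("      </CellData>")
  }
  w("    </Piece>")
  w("  </UnstructuredGrid>")
  w("</VTKFile>")
  invisible(path)
}

scan_numbers <- function(txt) {
  scan(text = txt, what = numeric(), quiet = TRUE)
}

#' Read a VTU (XML unstructured grid) file
#'
#' Supports ASCII tetrahedral meshes (cell type 10; returned as `tet_mesh`
#' with cell-data `region` if present) and triangle surfaces (type 5;
#' returned as `tri_surface`). Point data arrays are attached as the
#' `point_data` attribute.
#'
#' @param path VTU file path.
#' @return A `tet_mesh` or `tri_surface`.
#' @export
read_vtu <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("failed to parse VTU file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  piece <- xml2::xml_find_first(doc, "//Piece")
  if (is.na(xml2::xml_name(piece)))
    stop("failed to parse VTU file '", path, "': no <Piece> element",
         call. = FALSE)
  get_arr <- function(xpath) {
    node <- xml2::xml_find_first(doc, xpath)
    if (is.na(xml2::xml_name(node))) return(NULL)
    scan_numbers(xml2::xml_text(node))
  }
  pts <- get_arr("//Points/DataArray")
  conn <- get_arr("//Cells/DataArray[@Name='connectivity']")
  types <- get_arr("//Cells/DataArray[@Name='types']")
  if (is.null(pts) || is.null(conn) || is.null(types))
    stop("failed to parse VTU file '", path,
         "': missing points/connectivity/types", call. = FALSE)
  v <- matrix(pts, ncol = 3L, byrow = TRUE)
  ctype <- unique(types)
  if (length(ctype) != 1L || !ctype %in% c(5, 10))
    stop("unsupported VTU cell types in '", path, "': ",
         paste(ctype, collapse = ", "), call. = FALSE)
  k <- if (ctype == 10) 4L else 3L
  cells <- matrix(as.integer(conn), ncol = k, byrow = TRUE) + 1L
  pd <- list()
  for (node in xml2::xml_find_all(doc, "//PointData/DataArray")) {
    nm <- xml2::xml_attr(node, "Name")
    ncomp <- as.integer(xml2::xml_attr(node, "NumberOfComponents"))
    if (is.na(ncomp)) ncomp <- 1L
    vals <- scan_numbers(xml2::xml_text(node))
    pd[[nm]] <- if (ncomp > 1L) matrix(vals, ncol = ncomp, byrow = TRUE) else vals
  }
  if (ctype == 10) {
    region <- rep.int(1L, nrow(cells))
    rnode <- xml2::xml_find_first(doc, "//CellData/DataArray[@Name='region']")
    if (!is.na(xml2::xml_name(rnode)))
      region <- as.integer(scan_numbers(xml2::xml_text(rnode)))
    out <- structure(list(vertices = v, tets = cells,
                          surface_tris = extract_surface(v, cells),
                          region = region,
                          axis = c(0, 0, 1), origin = c(0, 0, 0),
                          spec = NULL),
                     class = "tet_mesh")
  } else {
    out <- tri_surface(v, cells)
  }
  if (length(pd)) attr(out, "point_data") <- pd
  out
}

#' Write / read a legacy-VTK ASCII unstructured grid
#'
#' Minimal legacy (non-XML) VTK dialect for interoperability with older
#' pipelines: POINTS / CELLS / CELL_TYPES plus an optional `region`
#' CELL_DATA field.
#'
#' @param mesh A `tet_mesh`.
#' @param path File path.
#' @return `write_vtk_legacy` returns `path` invisibly; `read_vtk_legacy`
#'   returns a `tet_mesh`.
#' @export
write_vtk_legacy <- function(mesh, path) {
  stopifnot(inherits(mesh, "tet_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; t4 <- mesh$tets
  writeLines(c("# vtk DataFile Version 3.0",
               "bulkybone tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(v), "double")), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  writeLines(paste("CELLS", nrow(t4), nrow(t4) * 5L), con)
  writeLines(apply(t4 - 1L, 1L, function(r) paste(c(4L, r), collapse = " ")), con)
  writeLines(paste("CELL_TYPES", nrow(t4)), con)
  writeLines(as.character(rep.int(10L, nrow(t4))), con)
  writeLines(c(paste("CELL_DATA", nrow(t4)),
               "SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$region), con)
  invisible(path)
}

#' @rdname write_vtk_legacy
#' @export
read_vtk_legacy <- function(path) {
  lines <- readLines(path)
  perr <- function(what, at) stop("failed to parse legacy VTK file '", path,
                                  "': ", what, " (line ", at, ")",
                                  call. = FALSE)
  ip <- grep("^POINTS", lines)
  if (!length(ip)) perr("no POINTS section", 1L)
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
  pts <- scan_numbers(lines[(ip + 1L):(ip + np)])
  if (length(pts) != 3L * np) perr("truncated POINTS", ip)
  ic <- grep("^CELLS", lines)
  if (!length(ic)) perr("no CELLS section", length(lines))
  nc <- as.integer(strsplit(lines[ic], "\\s+")[[1L]][2L])
  if (ic + nc > length(lines)) perr("truncated CELLS", ic)
  cells <- matrix(scan_numbers(lines[(ic + 1L):(ic + nc)]),
                  ncol = 5L, byrow = TRUE)
  if (any(cells[, 1L] != 4L)) perr("non-tetrahedral cell", ic)
  region <- rep.int(1L, nc)
  ir <- grep("^SCALARS region", lines)
  if (length(ir))
    region <- as.integer(scan_numbers(lines[(ir + 2L):(ir + 1L + nc)]))
  v <- matrix(pts, ncol = 3L, byrow = TRUE)
  t4 <- matrix(as.integer(cells[, 2:5]), ncol = 4L) + 1L
  structure(list(vertices = v, tets = t4,
                 surface_tris = extract_surface(v, t4),
                 region = region, axis = c(0, 0, 1), origin = c(0, 0, 0),
                 spec = NULL),
            class = "tet_mesh")
}

#' Write / read STL surfaces (ASCII and binary)
#'
#' Binary STL stores float32 coordinates; the ASCII dialect is written with
#' full double precision. On reading, duplicated facet corners are merged
#' into shared vertices by exact coordinate match, restoring a watertight
#' triangulation for closed surfaces. Zero-area facets are counted and
#' reported as a warning.
#'
#' @param surface A `tri_surface`.
#' @param path File path.
#' @param binary Write the 50-byte-per-facet binary dialect?
#' @param name Solid name (ASCII header).
#' @return `write_stl` returns `path` invisibly; `read_stl` a `tri_surface`.
#' @export
write_stl <- function(surface, path, binary = FALSE, name = "bulkybone") {
  stopifnot(inherits(surface, "tri_surface"))
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 2L], , drop = FALSE]
  c_ <- v[tr[, 3L], , drop = FALSE]
  nrm <- cross_rows(b - a, c_ - a)
  nl <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(nl > 0, nl, 1)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("binary STL", name)))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
    dat <- t(cbind(nrm, a, b, c_))           # 12 floats per facet
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(dat[, i]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("solid", name), con)
    fmt <- function(m) sprintf("%.17g %.17g %.17g", m[, 1L], m[, 2L], m[, 3L])
    body <- paste0("  facet normal ", fmt(nrm), "\n",
                   "    outer loop\n",
                   "      vertex ", fmt(a), "\n",
                   "      vertex ", fmt(b), "\n",
                   "      vertex ", fmt(c_), "\n",
                   "    endloop\n",
                   "  endfacet")
    writeLines(body, con)
    writeLines(paste("endsolid", name), con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head5 <- rawToChar(readBin(con, "raw", 5L))
  close(con)
  tri_xyz <- if (identical(head5, "solid") && is_ascii_stl(path)) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
  n_tri <- nrow(tri_xyz) / 3L
  a <- tri_xyz[3L * seq_len(n_tri) - 2L, , drop = FALSE]
  b <- tri_xyz[3L * seq_len(n_tri) - 1L, , drop = FALSE]
  c_ <- tri_xyz[3L * seq_len(n_tri), , drop = FALSE]
  area2 <- rowSums(cross_rows(b - a, c_ - a)^2)
  if (any(area2 == 0))
    warning(sum(area2 == 0), " zero-area facet(s) in '", path, "'",
            call. = FALSE)
  key <- paste(tri_xyz[, 1L], tri_xyz[, 2L], tri_xyz[, 3L], sep = "|")
  uid <- !duplicated(key)
  vertices <- tri_xyz[uid, , drop = FALSE]
  index <- match(key, key[uid])
  triangles <- matrix(index, ncol = 3L, byrow = TRUE)
  tri_surface(vertices, triangles)
}

# binary files contain NUL or non-UTF8 bytes within the first block
is_ascii_stl <- function(path) {
  n <- min(file.info(path)$size, 4096L)
  raw <- readBin(path, "raw", n)
  !any(raw == as.raw(0)) && any(grepl("facet", rawToChar(raw), fixed = TRUE))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L)
    stop("failed to parse ASCII STL '", path, "': vertex count ",
         length(vl), " not a multiple of 3", call. = FALSE)
  matrix(scan_numbers(sub("^\\s*vertex\\s+", "", vl)), ncol = 3L, byrow = TRUE)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(nt) || nt <= 0)
    stop("failed to parse binary STL '", path, "': bad facet count",
         call. = FALSE)
  out <- matrix(NA_real_, 3L * nt, 3L)
  for (i in seq_len(nt)) {
    vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    if (length(vals) < 12L)
      stop("failed to parse binary STL '", path, "': truncated at facet ", i,
           call. = FALSE)
    readBin(con, "raw", 2L)
    out[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  out
}

#' Write / read labeled volumes as NRRD
#'
#' Minimal NRRD (raw little-endian encoding) with isotropic spacings; enough
#' to exchange segmentation-like volumes with standard viewers.
#'
#' @param volume A [labeled_volume()].
#' @param path File path (`.nrrd`).
#' @return `write_nrrd` returns `path` invisibly; `read_nrrd` a
#'   `labeled_volume`.
#' @export
write_nrrd <- function(volume, path) {
  stopifnot(inherits(volume, "labeled_volume"))
  d <- dim(volume$data)
  header <- c("NRRD0004",
              "# bulkybone labeled volume",
              "type: uint8",
              "dimension: 3",
              paste("sizes:", paste(d, collapse = " ")),
              sprintf("spacings: %.17g %.17g %.17g", volume$voxel_mm,
                      volume$voxel_mm, volume$voxel_mm),
              "encoding: raw",
              "endian: little",
              "")
  con <- file(path, "wb")
  on.exit(close(con))
  # NRRD headers terminate with a blank line before the raw payload
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(as.raw(as.vector(volume$data)), con)
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path))
    stop("cannot open NRRD file '", path, "': no such file", call. = FALSE)
  raw <- readBin(path, "raw", file.info(path)$size)
  # header ends at the first blank line (\n\n)
  sep <- which(raw[-length(raw)] == as.raw(10) & raw[-1L] == as.raw(10))[1L]
  if (is.na(sep)) stop("failed to parse NRRD '", path,
                       "': no header terminator", call. = FALSE)
  header <- strsplit(rawToChar(raw[seq_len(sep)]), "\n")[[1L]]
  fields <- function(key) {
    ln <- grep(paste0("^", key, ":"), header, value = TRUE)
    if (!length(ln)) stop("failed to parse NRRD '", path, "': missing ", key,
                          call. = FALSE)
    trimws(sub(paste0("^", key, ":"), "", ln[1L]))
  }
  if (fields("encoding") != "raw" || fields("type") != "uint8")
    stop("unsupported NRRD encoding/type in '", path, "'", call. = FALSE)
  sizes <- as.integer(strsplit(fields("sizes"), "\\s+")[[1L]])
  spac <- as.numeric(strsplit(fields("spacings"), "\\s+")[[1L]])
  payload <- raw[(sep + 2L):length(raw)]
  if (length(payload) != prod(sizes))
    stop("failed to parse NRRD '", path, "': payload size ", length(payload),
         " != ", prod(sizes), call. = FALSE)
  labeled_volume(array(as.integer(payload), dim = sizes), spac[1L])
}

#' Write / read labeled volumes as multi-page TIFF
#'
#' Each z-slice becomes one 8-bit grayscale page (requires the `tiff`
#' package).
#'
#' @param volume A [labeled_volume()].
#' @param path File path (`.tif`).
#' @return `write_volume_tiff` returns `path` invisibly; `read_volume_tiff`
#'   a `labeled_volume` (`voxel_mm` must be supplied; TIFF does not carry it).
#' @param voxel_mm Voxel size for `read_volume_tiff`.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF volume IO", call. = FALSE)
  pages <- lapply(seq_len(dim(volume$data)[3L]),
                  function(k) volume$data[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path, voxel_mm) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF volume IO", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, dim = c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(round(pages[[k]] * 255))
  labeled_volume(arr, voxel_mm)
}

#' Write / read doublet sets as CSV
#'
#' Column layout `id,ax,ay,az,bx,by,bz,group`; the axis, origin and
#' generator seed are carried in `#`-prefixed header comments.
#'
#' @param doublets A [doublet_set()].
#' @param path CSV path.
#' @return `write_doublets` returns `path` invisibly; `read_doublets` a
#'   `doublet_set`.
#' @export
write_doublets <- function(doublets, path) {
  stopifnot(inherits(doublets, "doublet_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# axis: %.17g %.17g %.17g", attr(doublets, "axis")[1L],
            attr(doublets, "axis")[2L], attr(doublets, "axis")[3L]),
    sprintf("# origin: %.17g %.17g %.17g", attr(doublets, "origin")[1L],
            attr(doublets, "origin")[2L], attr(doublets, "origin")[3L]),
    if (!is.null(attr(doublets, "seed")))
      paste("# seed:", attr(doublets, "seed"))), con)
  df <- as.data.frame(doublets)
  # full-precision coordinates so angles survive the round trip exactly
  for (cl in c("ax", "ay", "az", "bx", "by", "bz"))
    df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_doublets
#' @export
read_doublets <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  parse_vec <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(default)
    as.numeric(strsplit(trimws(sub(paste0("^# ", key, ":"), "", ln[1L])),
                        "\\s+")[[1L]])
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("id", "ax", "ay", "az", "bx", "by", "bz", "group")
  if (!all(need %in% names(df)))
    stop("doublet CSV '", path, "' must have columns ",
         paste(need, collapse = ","), call. = FALSE)
  ds <- doublet_set(as.matrix(df[, c("ax", "ay", "az")]),
                    as.matrix(df[, c("bx", "by", "bz")]),
                    group = df$group,
                    axis = parse_vec("axis", c(0, 0, 1)),
                    origin = parse_vec("origin", c(0, 0, 0)),
                    id = df$id)
  seed <- parse_vec("seed", NULL)
  if (!is.null(seed)) attr(ds, "seed") <- as.integer(seed)
  ds
}
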