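#' Read a binary mask volume from NRRD or NIfTI
#'
#' NRRD is the reference dialect (explicit per-axis spacings or space
#' directions, space origin; raw or ascii encodings). NIfTI is accepted when
#' its transform reduces to an axis-aligned spacing + origin, otherwise it is
#' rejected. An optional JSON sidecar `{"slice_z": [...]}` overrides the
#' uniform z positions derived from the header (non-uniform stacks). A
#' sidecar at `<path>.slices.json` is picked up automatically.
#'
#' @param path NRRD (`.nrrd`) or NIfTI (`.nii`, `.nii.gz`) file with binary
#'   content (at most two distinct values).
#' @param sidecar optional path to the slice-position JSON sidecar.
#' @return A [mask_volume()].
#' @export
read_mask_volume <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  vol <- if (grepl("\\.nrrd$", lower)) {
    read_nrrd_volume(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    read_nifti_volume(path)
  } else {
    stop("unsupported mask format (expected .nrrd, .nii or .nii.gz): ", path)
  }
  if (is.null(sidecar)) {
    auto <- paste0(path, ".slices.json")
    if (file.exists(auto)) sidecar <- auto
  }
  if (!is.null(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(sc$slice_z)) stop("sidecar has no `slice_z` field: ", sidecar)
    if (length(sc$slice_z) != dim(vol$occupancy)[3]) {
      stop("sidecar `slice_z` length does not match the slice count")
    }
    vol$slice_z <- as.numeric(sc$slice_z)
    validate_mask_volume(vol)
  }
  vol
}

binarize_volume <- function(arr, path) {
  vals <- unique(as.vector(arr))
  if (length(vals) > 2L) {
    stop("not a binary mask (", length(vals), " distinct values): ", path)
  }
  arr != 0
}

read_nrrd_volume <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # header ends at the first blank line
  nl <- which(raw == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    # tolerate \r\n line endings
    if (p == prev + 2L && raw[p - 1L] == as.raw(13L)) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("unexpected end of NRRD header: ", path)
  header <- strsplit(rawToChar(raw[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", header[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (line in header[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  payload <- raw[seq.int(hdr_end + 1L, length(raw))]
  if (is.null(fields$sizes)) stop("NRRD header missing `sizes`: ", path)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported: ", path)
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3)))
    off <- m; diag(off) <- 0
    if (any(abs(off) > 1e-9 * max(abs(m)))) {
      stop("NRRD space directions are not axis-aligned: ", path)
    }
    spacing <- abs(diag(m))
  }
  if (is.null(spacing)) stop("NRRD header missing spacing information: ", path)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                  ",")[[1]])
  }
  n <- prod(sizes)
  enc <- tolower(if (is.null(fields$encoding)) "raw" else fields$encoding)
  rtype <- tolower(if (is.null(fields$type)) "unsigned char" else fields$type)
  data <- if (enc %in% c("raw", "gzip", "gz")) {
    bytes <- if (enc == "raw") payload else memDecompress(payload, "gzip")
    endian <- if (identical(fields$endian, "big")) "big" else "little"
    switch(rtype,
      "unsigned char" = , "uchar" = , "uint8" = , "uint8_t" =
        as.integer(readBin(bytes, "integer", n, size = 1, signed = FALSE)),
      "short" = , "int16" = , "signed short" =
        readBin(bytes, "integer", n, size = 2, endian = endian),
      "int" = , "int32" = , "signed int" =
        readBin(bytes, "integer", n, size = 4, endian = endian),
      "float" = readBin(bytes, "numeric", n, size = 4, endian = endian),
      "double" = readBin(bytes, "numeric", n, size = 8, endian = endian),
      stop("unsupported NRRD type: ", rtype)
    )
  } else if (enc %in% c("ascii", "text", "txt")) {
    scan(text = rawToChar(payload), what = numeric(), n = n, quiet = TRUE)
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  if (length(data) != n) stop("truncated NRRD data: ", path)
  arr <- array(data, dim = sizes)
  mask_volume(binarize_volume(arr, path), spacing = spacing, origin = origin)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("only 3D NIfTI volumes are supported: ", path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  off <- rot; diag(off) <- 0
  if (any(abs(off) > 1e-6 * max(abs(rot)))) {
    stop("NIfTI transform is not axis-aligned; reorient the volume first: ", path)
  }
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) stop("NIfTI header missing voxel spacing: ", path)
  # world coordinate of voxel (1,1,1); keep magnitudes, axis-aligned grid
  origin <- as.numeric(xf[1:3, 4])
  mask_volume(binarize_volume(as.array(img), path), spacing = spacing,
              origin = origin)
}

uniform_z_spacing <- function(vol, tol = 1e-9) {
  z <- vol$slice_z
  if (length(z) < 2L) return(NULL)
  gaps <- diff(z)
  if (max(gaps) - min(gaps) <= tol * max(abs(z), 1)) mean(gaps) else NULL
}

#' Write a mask volume as NRRD
#'
#' Unsigned-char raw encoding with axis-aligned space directions. When the
#' slice stack is non-uniform, the header carries the mean slice spacing and
#' the exact positions are written to a JSON sidecar at
#' `<path>.slices.json`, which [read_mask_volume()] picks up automatically.
#'
#' @param vol a [mask_volume()].
#' @param path output `.nrrd` path.
#' @return Invisibly, the path(s) written.
#' @export
write_mask_volume <- function(vol, path) {
  d <- grid_dim(vol)
  sz <- uniform_z_spacing(vol)
  nonuniform <- is.null(sz) && d[3] > 1
  if (is.null(sz)) sz <- if (d[3] > 1) mean_slice_spacing(vol$slice_z) else 1
  con <- file(path, "wb")
  header <- c(
    "NRRD0004",
    "# mask volume written by the safemargin package",
    "type: unsigned char",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            vol$spacing_x, vol$spacing_y, sz),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            vol$origin_x, vol$origin_y, vol$slice_z[1]),
    ""
  )
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.raw(as.integer(vol$occupancy)), con)
  close(con)
  written <- path
  if (nonuniform) {
    sidecar <- paste0(path, ".slices.json")
    jsonlite::write_json(list(slice_z = vol$slice_z), sidecar,
                         auto_unbox = FALSE, digits = NA)
    written <- c(path, sidecar)
  }
  invisible(written)
}

#' Write a point set as ASCII PLY
#'
#' Double-precision world/scanner coordinates in mm; no coordinate flips.
#'
#' @param points point matrix (columns x, y, z).
#' @param path output `.ply` path.
#' @export
write_points_ply <- function(points, path) {
  points <- rbind(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    "comment mm world coordinates, written by the safemargin package",
    sprintf("element vertex %d", nrow(points)),
    "property double x", "property double y", "property double z",
    "end_header"
  ), con)
  if (nrow(points) > 0) {
    utils::write.table(format(points, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Write a point set as CSV (columns x, y, z in mm)
#' @param points point matrix.
#' @param path output `.csv` path.
#' @export
write_points_csv <- function(points, path) {
  points <- rbind(points)
  df <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a point set from CSV written by [write_points_csv()]
#' @param path csv path with columns x, y, z.
#' @return Point matrix.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, c("x", "y", "z")])
}

#' Write a triangle mesh as ASCII STL
#' @param mesh a [reconstruct_surface()] mesh.
#' @param path output `.stl` path.
#' @export
write_mesh_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid safemargin", con)
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; c3 <- v[f[t, 3], ]
    n <- c((b[2]-a[2])*(c3[3]-a[3]) - (b[3]-a[3])*(c3[2]-a[2]),
           (b[3]-a[3])*(c3[1]-a[1]) - (b[1]-a[1])*(c3[3]-a[3]),
           (b[1]-a[1])*(c3[2]-a[2]) - (b[2]-a[2])*(c3[1]-a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
      sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
      sprintf("      vertex %.9g %.9g %.9g", c3[1], c3[2], c3[3]),
      "    endloop",
      "  endfacet"
    ), con)
  }
  writeLines("endsolid safemargin", con)
  invisible(path)
}

#' Write all artifacts of a safe-margin result to a directory
#'
#' Fused point set as PLY and CSV, coarse and ring masks as NRRD, optional
#' hull mesh as STL, and a JSON run manifest with parameters, point counts
#' and md5 checksums of the written files. A degenerate run (empty ring) is
#' flagged in the manifest.
#'
#' @param result a [generate_safe_margin_volume()] result.
#' @param dir output directory (created if missing).
#' @param mesh also write the boundary mesh (`FALSE` by default; hull
#'   construction on large clouds is slow).
#' @return Invisibly, the manifest path.
#' @export
write_outputs <- function(result, dir, mesh = FALSE) {
  stopifnot(inherits(result, "safe_margin_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  files <- c(files, write_points_ply(result$fused_points,
                                     file.path(dir, "fused_points.ply")))
  files <- c(files, write_points_csv(result$fused_points,
                                     file.path(dir, "fused_points.csv")))
  files <- c(files, write_mask_volume(result$coarse,
                                      file.path(dir, "coarse_mask.nrrd")))
  files <- c(files, write_mask_volume(result$ring,
                                      file.path(dir, "ring_mask.nrrd")))
  if (mesh && nrow(result$fused_points) >= 4) {
    m <- reconstruct_surface(result$fused_points)
    files <- c(files, write_mesh_stl(m, file.path(dir, "fused_hull.stl")))
  }
  manifest <- list(
    package = "safemargin",
    version = as.character(utils::packageVersion("safemargin")),
    params = result$params[c("d_s", "target", "xi", "band")],
    replication = result$plan$C,
    n_fused_points = nrow(result$fused_points),
    n_coarse_voxels = sum(result$coarse$occupancy),
    n_ring_voxels = sum(result$ring$occupancy),
    empty_ring = !any(result$ring$occupancy),
    checksums = as.list(tools::md5sum(files))
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
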