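# Readers and writers: NIfTI (via RNifti) and MetaImage (.mha/.mhd + .raw)
# volumes, 4-D displacement fields, plain-text landmark files (1-based voxel
# triples, converted to the package's 0-based convention on read), and YAML
# run configurations.

has_ext <- function(path, exts) {
  low <- tolower(path)
  any(vapply(exts, function(e) endsWith(low, e), logical(1)))
}

#' Read a volume from NIfTI or MetaImage
#'
#' Scalar volumes come back as [image_volume()]; 4-D files as a plain 4-D
#' array with the spacing in attribute `spacing` (displacement fields).
#'
#' @param path file path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return an [image_volume()], or a 4-D array for vector-valued files.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (has_ext(path, c(".nii", ".nii.gz"))) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim(img))
    sp <- rep_len(RNifti::pixdim(img), max(3L, length(dim(img))))[1:3]
  } else if (has_ext(path, c(".mha", ".mhd"))) {
    mi <- read_metaimage(path)
    vals <- mi$values
    sp <- mi$spacing
  } else {
    stop("unknown volume format: ", path, call. = FALSE)
  }
  if (length(dim(vals)) == 4L) {
    attr(vals, "spacing") <- sp
    return(vals)
  }
  image_volume(vals, sp)
}

#' Write a volume to NIfTI or MetaImage
#'
#' @param vol [image_volume()], [label_map()], or a 3-D/4-D array (a 4-D
#'   array is written as a vector-valued volume, e.g. a displacement field).
#' @param path output path; the extension selects the format.
#' @param spacing spacing override for bare arrays (mm per voxel).
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (is.array(vol) && length(dim(vol)) == 4L) {
    vals <- vol
    sp <- if (!is.null(spacing)) spacing else
      if (!is.null(attr(vol, "spacing"))) attr(vol, "spacing") else c(1, 1, 1)
  } else {
    vals <- as_field3d(vol)
    sp <- if (!is.null(spacing)) spacing else spacing_of(vol)
  }
  sp <- rep_len(as.numeric(sp), 3L)
  if (has_ext(path, c(".nii", ".nii.gz"))) {
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- if (length(dim(vals)) == 4L) c(sp, 1) else sp
    RNifti::writeNifti(img, path)
  } else if (has_ext(path, c(".mha", ".mhd"))) {
    write_metaimage(vals, path, sp)
  } else {
    stop("unknown volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

MET_TYPES <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

# Read one LF-terminated header line from a binary connection.
read_raw_line <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) return(if (length(bytes)) rawToChar(bytes) else NULL)
    if (b == as.raw(10L)) return(sub("\r$", "", rawToChar(bytes)))
    bytes <- c(bytes, b)
  }
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- read_raw_line(con)
    if (is.null(line)) stop("corrupt MetaImage header (no ElementDataFile): ",
                            path, call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L) stop(sprintf("corrupt MetaImage header line '%s' in %s",
                                       line, path), call. = FALSE)
    hdr[[kv[2L]]] <- trimws(kv[3L])
    if (kv[2L] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  typ <- MET_TYPES[[hdr$ElementType]]
  if (is.null(typ)) stop("unsupported MetaImage ElementType: ", hdr$ElementType,
                         " in ", path, call. = FALSE)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_vals <- readBin(con, typ$what, n = n, size = typ$size,
                        signed = typ$signed, endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stop("missing MetaImage data file: ", raw_path,
                                     call. = FALSE)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    raw_vals <- readBin(rcon, typ$what, n = n, size = typ$size,
                        signed = typ$signed, endian = "little")
  }
  if (length(raw_vals) < n) stop("truncated MetaImage data in ", path, call. = FALSE)
  sp <- if (!is.null(hdr$ElementSpacing)) {
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1L]])[1:3]
  } else c(1, 1, 1)
  list(values = array(as.numeric(raw_vals), dims), spacing = sp)
}

write_metaimage <- function(vals, path, spacing) {
  dims <- dim(vals)
  is_int <- all(vals == round(vals)) && max(abs(vals)) < 2^31 - 1
  etype <- if (is_int) "MET_INT" else "MET_DOUBLE"
  local_data <- has_ext(path, ".mha")
  data_file <- if (local_data) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                       ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    sprintf("NDims = %d", length(dims)),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %s", paste(dims, collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(format(c(spacing, rep(1, length(dims) - 3L)), trim = TRUE),
                  collapse = " ")),
    sprintf("ElementType = %s", etype),
    sprintf("ElementDataFile = %s", data_file))
  payload <- if (is_int) as.integer(vals) else as.numeric(vals)
  size <- if (is_int) 4L else 8L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (local_data) {
    writeBin(payload, con, size = size, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(payload, rcon, size = size, endian = "little")
  }
  invisible(path)
}

#' Read a plain-text landmark file
#'
#' One landmark per line, three whitespace-delimited 1-based voxel indices
#' (the common lung-CT landmark dialect). Converted to the package's
#' 0-based coordinates. An empty file yields a zero-row matrix.
#'
#' @param path landmark file.
#' @return numeric matrix with columns (x, y, z), 0-based.
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("x", "y", "z"))))
  }
  pts <- matrix(NA_real_, length(lines), 3L)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    v <- suppressWarnings(as.numeric(tok))
    if (length(v) != 3L || anyNA(v)) {
      stop(sprintf("malformed landmark line %d in %s: '%s'", i, path, lines[i]),
           call. = FALSE)
    }
    pts[i, ] <- v
  }
  colnames(pts) <- c("x", "y", "z")
  pts - 1  # file indices are 1-based
}

#' Write a plain-text landmark file
#'
#' Inverse of [read_landmarks()]: internal 0-based coordinates are written
#' as 1-based whitespace-delimited triples, one per line.
#'
#' @param points numeric matrix (n x 3), 0-based coordinates.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_landmarks <- function(points, path) {
  p <- as_points(points) + 1
  writeLines(apply(p, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                            collapse = " ")),
             path)
  invisible(path)
}

RUN_CONFIG_SCHEMA <- 1L

#' Serialize / restore a run configuration
#'
#' Round-trips a [registration_config()] (and optionally a [phantom_spec()])
#' through a schema-versioned YAML file.
#'
#' @param cfg a [registration_config()].
#' @param path YAML file path.
#' @param phantom optional [phantom_spec()] stored alongside.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   a list with `cfg` and (possibly NULL) `phantom`.
#' @export
write_run_config <- function(cfg, path, phantom = NULL) {
  stopifnot(inherits(cfg, "registration_config"))
  obj <- list(schema_version = RUN_CONFIG_SCHEMA, registration = unclass(cfg))
  if (!is.null(phantom)) {
    ph <- unclass(phantom)
    if (!is.null(ph$bumps)) ph$bumps <- as.list(as.data.frame(ph$bumps))
    obj$phantom <- ph
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema_version) || obj$schema_version > RUN_CONFIG_SCHEMA) {
    stop("unsupported run-config schema in ", path, call. = FALSE)
  }
  cfg <- do.call(registration_config,
                 obj$registration[setdiff(names(obj$registration), character(0))])
  phantom <- NULL
  if (!is.null(obj$phantom)) {
    ph <- obj$phantom
    if (!is.null(ph$bumps)) {
      ph$bumps <- as.data.frame(lapply(ph$bumps, as.numeric))
    }
    ph$shape <- as.integer(unlist(ph$shape))
    ph$lung_centers <- lapply(ph$lung_centers, unlist)
    ph$lung_semiaxes <- lapply(ph$lung_semiaxes, unlist)
    ph$body_center <- unlist(ph$body_center)
    ph$body_semiaxes <- unlist(ph$body_semiaxes)
    ph$spacing <- unlist(ph$spacing)
    phantom <- do.call(phantom_spec, ph)
  }
  list(cfg = cfg, phantom = phantom)
}
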