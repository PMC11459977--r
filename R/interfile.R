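## Interfile-dialect I/O.
##
## Pinhole collimators are not covered by standard Interfile, so the package
## fixes a documented dialect: "keyword := value" lines, a tolerated "!"
## prefix, ";" comments, case- and whitespace-insensitive keyword lookup, and
## a raw little-endian binary payload (32-bit float by default, 64-bit double
## supported) stored transaxial-fastest. List values use "{a, b, c}".

norm_key <- function(k) {
  k <- sub("^\\s*!", "", k)
  k <- gsub("\\s+", " ", trimws(tolower(k)))
  k
}

#' Parse an Interfile-like keyword parameter file
#'
#' Lines have the form `keyword := value`; blank lines and `;` comments are
#' allowed and a leading `!` on a keyword is tolerated. Keyword lookup is
#' case-insensitive and whitespace-normalized. A duplicated keyword keeps the
#' last value with a warning; an unparseable line is an error naming its line
#' number.
#'
#' @param path file path.
#' @return object of class `key_value_tree` with fields `entries` (named list
#'   of strings, normalized keys) and `source_path`.
#' @export
parse_parameter_file <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  for (i in seq_along(lines)) {
    ln <- sub(";.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    if (!grepl(":=", ln, fixed = TRUE))
      stop("unparseable line ", i, " in ", path, ": ", trimws(lines[i]))
    kv <- regmatches(ln, regexpr(":=", ln, fixed = TRUE), invert = TRUE)[[1]]
    key <- norm_key(kv[1])
    val <- trimws(kv[2])
    if (!nzchar(key)) next                       # bare "!INTERFILE :=" etc.
    if (key %in% names(entries))
      warning("duplicate keyword '", key, "' in ", path, "; last value wins")
    entries[[key]] <- val
  }
  structure(list(entries = entries, source_path = path),
            class = "key_value_tree")
}

#' Look up a keyword in a parsed parameter file
#'
#' @param tree a `key_value_tree` from [parse_parameter_file()].
#' @param key keyword (case/whitespace-insensitive).
#' @param default value returned when the keyword is absent.
#' @param required error when absent and no default applies.
#' @export
kv_get <- function(tree, key, default = NULL, required = FALSE) {
  v <- tree$entries[[norm_key(key)]]
  if (is.null(v)) {
    if (required) stop("required keyword '", key, "' missing in ",
                       tree$source_path)
    return(default)
  }
  v
}

kv_num <- function(tree, key, default = NULL, required = FALSE) {
  v <- kv_get(tree, key, default = default, required = required)
  if (is.null(v)) return(NULL)
  if (is.character(v)) as.numeric(v) else v
}

kv_vec <- function(tree, key, required = FALSE) {
  v <- kv_get(tree, key, required = required)
  if (is.null(v)) return(NULL)
  as.numeric(strsplit(gsub("[{}]", "", v), ",")[[1]])
}

kv_flag <- function(tree, key, default = FALSE) {
  v <- kv_get(tree, key)
  if (is.null(v)) return(default)
  tolower(v) %in% c("1", "on", "yes", "true")
}

## ---- raw payload helpers ---------------------------------------------------

payload_size <- function(tree) {
  fmt <- tolower(kv_get(tree, "number format", default = "float"))
  nb <- kv_num(tree, "number of bytes per pixel",
               default = if (fmt == "double") 8 else 4)
  if (!(fmt %in% c("float", "double", "short float", "long float")))
    stop("unsupported number format: ", fmt)
  as.integer(nb)
}

read_payload <- function(header_path, tree, n_expected) {
  rel <- kv_get(tree, "name of data file", required = TRUE)
  dpath <- file.path(dirname(header_path), rel)
  if (!file.exists(dpath)) dpath <- rel
  if (!file.exists(dpath)) stop("data file not found: ", rel)
  nb <- payload_size(tree)
  actual <- file.info(dpath)$size
  if (actual != n_expected * nb)
    stop("size mismatch: header declares ", n_expected, " values (",
         n_expected * nb, " bytes) but '", dpath, "' holds ", actual, " bytes")
  con <- file(dpath, "rb")
  on.exit(close(con))
  readBin(con, "double", n = n_expected, size = nb, endian = "little")
}

write_payload <- function(values, data_path, bytes = 4L) {
  con <- file(data_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(values), con, size = bytes, endian = "little")
}

write_header <- function(lines, path) {
  writeLines(c("!INTERFILE :=", lines, "!END OF INTERFILE :="), path)
}

## ---- projection data -------------------------------------------------------

#' Read pinhole SPECT projection data in the package's Interfile dialect
#'
#' @param header_path path to the Interfile header (`.hs`).
#' @return a [projection_data()] object.
#' @export
read_projection_interfile <- function(header_path) {
  tree <- parse_parameter_file(header_path)
  nbt <- kv_num(tree, "matrix size [1]", required = TRUE)
  nba <- kv_num(tree, "matrix size [2]", required = TRUE)
  nv  <- kv_num(tree, "number of projections", required = TRUE)
  bin <- kv_num(tree, "scaling factor (mm/pixel) [1]", required = TRUE)
  rad <- kv_num(tree, "detector radius (mm)", required = TRUE)
  scl <- kv_num(tree, "data scaling factor", default = 1)
  orbit <- orbit_spec(
    n_angles = nv,
    initial_angle = kv_num(tree, "start angle (deg)", default = 180),
    angular_increment = kv_num(tree, "angular increment (deg)", default = 3),
    n_orbits = kv_num(tree, "number of orbits", default = 1),
    axial_position = kv_num(tree, "axial position (mm)", default = 0))
  vals <- read_payload(header_path, tree, nbt * nba * nv) * scl
  a <- array(vals, dim = c(nbt, nba, nv))        # transaxial fastest on disk
  projection_data(aperm(a, c(3, 2, 1)), bin_size = bin,
                  detector_radius = rad, orbit = orbit)
}

#' Write pinhole SPECT projection data in the package's Interfile dialect
#'
#' Exact inverse of [read_projection_interfile()].
#'
#' @param data a [projection_data()] object.
#' @param path header path; the payload goes next to it with extension `.s`.
#' @param bytes 4 (float, default) or 8 (double) bytes per value.
#' @export
write_projection_interfile <- function(data, path, bytes = 4L) {
  stopifnot(inherits(data, "projection_data"))
  d <- dim(data$views)
  dfile <- paste0(sub("\\.[^.]*$", "", basename(path)), ".s")
  o <- data$orbit
  write_header(c(
    "!imaging modality := nucmed",
    "!type of data := tomographic",
    paste0("!name of data file := ", dfile),
    paste0("!number format := ", if (bytes == 8) "double" else "float"),
    paste0("!number of bytes per pixel := ", bytes),
    "imagedata byte order := LITTLEENDIAN",
    paste0("matrix size [1] := ", d[3]),
    paste0("matrix size [2] := ", d[2]),
    paste0("number of projections := ", d[1]),
    paste0("scaling factor (mm/pixel) [1] := ", format(data$bin_size, digits = 17)),
    paste0("scaling factor (mm/pixel) [2] := ", format(data$bin_size, digits = 17)),
    paste0("detector radius (mm) := ", format(data$detector_radius, digits = 17)),
    paste0("number of orbits := ", o$n_orbits),
    paste0("start angle (deg) := ", format(o$initial_angle, digits = 17)),
    paste0("angular increment (deg) := ", format(o$angular_increment, digits = 17)),
    paste0("axial position (mm) := ", format(o$axial_position, digits = 17))),
    path)
  write_payload(aperm(data$views, c(3, 2, 1)),
                file.path(dirname(path), dfile), bytes = bytes)
  invisible(path)
}

## ---- image volumes ---------------------------------------------------------

#' Read an image volume in the package's Interfile dialect
#'
#' @param header_path path to the Interfile image header (`.hv`).
#' @return an [image_volume()] object.
#' @export
read_image_interfile <- function(header_path) {
  tree <- parse_parameter_file(header_path)
  nx <- kv_num(tree, "matrix size [1]", required = TRUE)
  ny <- kv_num(tree, "matrix size [2]", required = TRUE)
  nz <- kv_num(tree, "matrix size [3]", required = TRUE)
  dx <- kv_num(tree, "scaling factor (mm/pixel) [1]", required = TRUE)
  dz <- kv_num(tree, "scaling factor (mm/pixel) [3]", default = dx)
  org <- c(kv_num(tree, "origin (mm) [1]", default = 0),
           kv_num(tree, "origin (mm) [2]", default = 0),
           kv_num(tree, "origin (mm) [3]", default = 0))
  vals <- read_payload(header_path, tree, nx * ny * nz)
  a <- array(vals, dim = c(nx, ny, nz))          # x fastest on disk
  image_volume(aperm(a, c(3, 2, 1)), voxel_size = dx, z_spacing = dz,
               origin = org)
}

#' Write an image volume in the package's Interfile dialect
#'
#' Exact inverse of [read_image_interfile()]; voxel sizes and origin are
#' preserved on round-trip.
#'
#' @param vol an [image_volume()].
#' @param path header path; the payload goes next to it with extension `.v`.
#' @param bytes 4 (float, default) or 8 (double) bytes per value.
#' @export
write_image_interfile <- function(vol, path, bytes = 4L) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$voxels)
  dfile <- paste0(sub("\\.[^.]*$", "", basename(path)), ".v")
  write_header(c(
    "!imaging modality := nucmed",
    "!type of data := Image",
    paste0("!name of data file := ", dfile),
    paste0("!number format := ", if (bytes == 8) "double" else "float"),
    paste0("!number of bytes per pixel := ", bytes),
    "imagedata byte order := LITTLEENDIAN",
    paste0("matrix size [1] := ", d[3]),
    paste0("matrix size [2] := ", d[2]),
    paste0("matrix size [3] := ", d[1]),
    paste0("scaling factor (mm/pixel) [1] := ", format(vol$voxel_size, digits = 17)),
    paste0("scaling factor (mm/pixel) [2] := ", format(vol$voxel_size, digits = 17)),
    paste0("scaling factor (mm/pixel) [3] := ", format(vol$z_spacing, digits = 17)),
    paste0("origin (mm) [1] := ", format(vol$origin[1], digits = 17)),
    paste0("origin (mm) [2] := ", format(vol$origin[2], digits = 17)),
    paste0("origin (mm) [3] := ", format(vol$origin[3], digits = 17))),
    path)
  write_payload(aperm(vol$voxels, c(3, 2, 1)),
                file.path(dirname(path), dfile), bytes = bytes)
  invisible(path)
}

## ---- parameter files: detector, collimator, matrix, reconstruction --------

#' Read a detector parameter file
#'
#' Keywords: `intrinsic resolution (mm)`, `crystal thickness (mm)`,
#' `crystal attenuation (1/mm)` (or `(1/cm)`, converted), `detector radius (mm)`,
#' `number of transaxial bins`, `number of axial bins`, `bin size (mm)`, and the
#' orbit block `number of orbits`, `number of angles`, `initial angle (deg)`,
#' `angular increment (deg)`, `axial position (mm)`.
#'
#' @param path file path.
#' @return a [detector_params()] object.
#' @export
read_detector_params <- function(path) {
  t <- parse_parameter_file(path)
  mu <- kv_num(t, "crystal attenuation (1/mm)")
  if (is.null(mu)) {
    mu <- kv_num(t, "crystal attenuation (1/cm)")
    if (!is.null(mu)) mu <- mu / 10
  }
  if (is.null(mu)) stop("crystal attenuation missing in ", path)
  orbit <- orbit_spec(
    n_angles = kv_num(t, "number of angles", required = TRUE),
    initial_angle = kv_num(t, "initial angle (deg)", default = 180),
    angular_increment = kv_num(t, "angular increment (deg)", default = 3),
    n_orbits = kv_num(t, "number of orbits", default = 1),
    axial_position = kv_num(t, "axial position (mm)", default = 0))
  detector_params(
    intrinsic_resolution = kv_num(t, "intrinsic resolution (mm)", required = TRUE),
    crystal_thickness = kv_num(t, "crystal thickness (mm)", required = TRUE),
    crystal_attenuation = mu,
    detector_radius = kv_num(t, "detector radius (mm)", required = TRUE),
    orbit = orbit,
    n_transaxial = kv_num(t, "number of transaxial bins", required = TRUE),
    n_axial = kv_num(t, "number of axial bins", required = TRUE),
    bin_size = kv_num(t, "bin size (mm)", required = TRUE))
}

#' Read a collimator parameter file
#'
#' Keywords: `radius of rotation (mm)`, `collimator geometry`,
#' `number of holes`, and per hole `hole <i> position (mm)` (`{x, y, z}` in the
#' rotating frame), `hole <i> shape`, `hole <i> diameter (mm)` or
#' `hole <i> width/height (mm)`, `hole <i> tilt (deg)`,
#' `hole <i> acceptance angle (deg)`, `hole <i> detector element`.
#'
#' @param path file path.
#' @return a [collimator_params()] object.
#' @export
read_collimator_params <- function(path) {
  t <- parse_parameter_file(path)
  nh <- kv_num(t, "number of holes", required = TRUE)
  holes <- lapply(seq_len(nh), function(i) {
    p <- function(k, ...) kv_get(t, sprintf("hole %d %s", i, k), ...)
    pn <- function(k, ...) kv_num(t, sprintf("hole %d %s", i, k), ...)
    shape <- tolower(p("shape", default = "round"))
    size <- if (shape == "round") pn("diameter (mm)", required = TRUE) else
      c(pn("width (mm)", required = TRUE), pn("height (mm)", required = TRUE))
    hole_spec(position = kv_vec(t, sprintf("hole %d position (mm)", i),
                                required = TRUE),
              shape = shape, size = size,
              tilt = pn("tilt (deg)", default = 0),
              acceptance_angle = pn("acceptance angle (deg)", default = 45),
              detector_element = pn("detector element", default = 1))
  })
  collimator_params(
    radius_of_rotation = kv_num(t, "radius of rotation (mm)", required = TRUE),
    geometry = tolower(kv_get(t, "collimator geometry", default = "cylindrical")),
    holes = holes)
}

#' Read the system-matrix section of a reconstruction parameter file
#'
#' Keywords: `psf correction`, `doi correction`, `attenuation correction`
#' (`off|simple|full`), `maximum number of sigmas`, `psf subsampling factor`,
#' `spatial sampling interval (mm)`, `mask type`
#' (`cylinder|none|attenuation map|file`), `object radius (mm)`, `mask file`,
#' `attenuation map`, `keep matrix in memory`, `minimum weight`.
#'
#' @param path file path.
#' @return a [matrix_config()]; an `attenuation map` path, when given, is
#'   attached as attribute `atten_map_file`.
#' @export
read_matrix_config <- function(path) {
  t <- parse_parameter_file(path)
  att <- tolower(kv_get(t, "attenuation correction", default = "off"))
  if (att %in% c("0", "no")) att <- "off"
  mask <- tolower(kv_get(t, "mask type", default = "cylinder"))
  mask <- sub("attenuation map", "attenuation_map", mask)
  cfg <- matrix_config(
    psf = kv_flag(t, "psf correction"),
    doi = kv_flag(t, "doi correction"),
    attenuation = att,
    psf_n_sigma = kv_num(t, "maximum number of sigmas", default = 2),
    psf_subsampling = kv_num(t, "psf subsampling factor", default = 1),
    sampling_interval = kv_num(t, "spatial sampling interval (mm)", default = 0.1),
    mask = mask,
    object_radius = kv_num(t, "object radius (mm)"),
    mask_file = kv_get(t, "mask file"),
    keep_in_memory = kv_flag(t, "keep matrix in memory", default = TRUE),
    min_weight = kv_num(t, "minimum weight", default = 0))
  attr(cfg, "atten_map_file") <- kv_get(t, "attenuation map")
  cfg
}

#' Read the reconstruction section of a reconstruction parameter file
#'
#' Keywords: `reconstruction algorithm` (`MLEM|OSEM|OS-OSL-MRP|OS-SPS-QP`),
#' `number of subsets`, `number of subiterations`, `penalisation factor`,
#' `relaxation alpha`, `relaxation gamma`, `save estimates every`,
#' `initial image`.
#'
#' @param path file path.
#' @return a [recon_config()].
#' @export
read_recon_config <- function(path) {
  t <- parse_parameter_file(path)
  alg <- toupper(kv_get(t, "reconstruction algorithm", default = "OSEM"))
  alg <- gsub("-", "_", alg)
  init <- kv_get(t, "initial image")
  recon_config(
    algorithm = alg,
    n_subsets = kv_num(t, "number of subsets", default = 1),
    n_subiterations = kv_num(t, "number of subiterations", required = TRUE),
    penalisation_factor = kv_num(t, "penalisation factor", default = 0),
    alpha = kv_num(t, "relaxation alpha", default = 1),
    gamma = kv_num(t, "relaxation gamma", default = 0.1),
    save_every = kv_num(t, "save estimates every", default = 0),
    initial_image = if (!is.null(init)) read_image_interfile(init))
}
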