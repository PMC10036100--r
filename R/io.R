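#' Write a dose grid or structure mask as NRRD
#'
#' Minimal NRRD0004 writer: raw encoding, little-endian, 3-D, `float` voxels
#' for dose grids and `uchar` (0/1) for masks. The fastest-varying NRRD axis
#' is the first array dimension (R column-major order, LR axis). The carried
#' quantity (`physical`/`bed`/`mask`) and any scalar/character metadata in
#' `$meta` are recorded as `key:=value` pairs.
#'
#' @param x a [dose_grid()], or a logical mask array (with `grid` supplied).
#' @param path output file path.
#' @param grid required when `x` is a bare mask array.
#' @return Invisibly, `path`.
#' @export
write_nrrd <- function(x, path, grid = NULL) {
  if (inherits(x, "dose_grid")) {
    values <- x$values; grid <- x$grid; quantity <- x$quantity
    type <- "float"; meta <- x$meta
  } else {
    stopifnot(is.array(x), is.logical(x), inherits(grid, "grid_spec"),
              identical(dim(x), as.integer(grid$shape)))
    values <- x; quantity <- "mask"; type <- "uchar"; meta <- list()
  }
  sp <- grid$spacing
  hdr <- c(
    "NRRD0004",
    "# dosimargin dose/structure grid",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(values)[1], dim(values)[2], dim(values)[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            sp[1], sp[2], sp[3]),
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("quantity:=%s", quantity))
  for (key in names(meta)) {
    v <- meta[[key]]
    if (length(v) >= 1L && (is.numeric(v) || is.character(v)) && !is.list(v)) {
      hdr <- c(hdr, sprintf("%s:=%s", key,
                            paste(format(v, digits = 10), collapse = " ")))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeLines("", con, sep = "\n")
  if (type == "float") {
    writeBin(as.numeric(values), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(values), con, size = 1L)
  }
  invisible(path)
}

parse_nrrd_vector <- function(s) {
  as.numeric(strsplit(gsub("[()]", "", s), "[,[:space:]]+")[[1]])
}

#' Read an NRRD file written by [write_nrrd()]
#'
#' Supports the subset this package writes: 3-D, raw encoding, little-endian,
#' `float`, `double` or `uchar` sample types, `space directions` given as a
#' diagonal frame (axis-aligned spacing).
#'
#' @param path file path.
#' @return A [dose_grid()] (for `quantity` physical/bed) or a list with
#'   `values` (logical mask array) and `grid` for masks.
#' @export
read_nrrd <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("read_nrrd: unexpected end of header")
    if (line == "") break
    hdr <- c(hdr, line)
  }
  if (!grepl("^NRRD", hdr[1])) stop("read_nrrd: not an NRRD file")
  hdr <- hdr[!grepl("^#", hdr)]
  field <- function(name) {
    hit <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^", name, ": "), "", hit[1])
  }
  kv <- function(name) {
    hit <- grep(paste0("^", name, ":="), hdr, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^", name, ":="), "", hit[1])
  }
  if (!identical(field("encoding"), "raw")) {
    stop("read_nrrd: only raw encoding is supported")
  }
  sizes <- as.integer(strsplit(field("sizes"), "[[:space:]]+")[[1]])
  if (length(sizes) != 3L) stop("read_nrrd: only 3-D grids are supported")
  dirs <- field("space directions")
  spacing <- if (!is.null(dirs)) {
    parts <- strsplit(trimws(dirs), "[[:space:]]+")[[1]]
    vapply(seq_along(parts), function(i) parse_nrrd_vector(parts[i])[i],
           numeric(1))
  } else {
    as.numeric(strsplit(field("spacings"), "[[:space:]]+")[[1]])
  }
  origin <- parse_nrrd_vector(field("space origin"))
  type <- field("type")
  n <- prod(sizes)
  values <- switch(type,
    float = readBin(con, numeric(), n = n, size = 4L, endian = "little"),
    double = readBin(con, numeric(), n = n, size = 8L, endian = "little"),
    uchar = readBin(con, integer(), n = n, size = 1L, signed = FALSE),
    stop(sprintf("read_nrrd: unsupported sample type '%s'", type)))
  if (length(values) != n) stop("read_nrrd: truncated data block")
  arr <- array(values, dim = sizes)
  grid <- grid_spec(sizes, spacing, origin)
  quantity <- kv("quantity")
  if (identical(quantity, "mask")) {
    return(list(values = arr > 0, grid = grid))
  }
  meta <- list()
  for (key in c("style", "prescription_dose", "isodose_level")) {
    v <- kv(key)
    if (!is.null(v)) {
      num <- suppressWarnings(as.numeric(v))
      meta[[key]] <- if (is.na(num)) v else num
    }
  }
  dose_grid(arr, grid, if (is.null(quantity)) "physical" else quantity,
            meta = meta)
}

#' Write a dose grid in the JSON-header + raw fallback format
#'
#' Bit-exact documented fallback: `<basepath>.json` holds the geometry and
#' quantity (`shape`, `spacing`, `origin`, `quantity`, `dtype` = "float32",
#' `byte_order` = "little", `order` = "column-major"); `<basepath>.raw` holds
#' the voxels as IEEE-754 little-endian float32 with the first grid axis
#' fastest.
#'
#' @param dose a [dose_grid()].
#' @param basepath path without extension; `.json` and `.raw` are appended.
#' @return Invisibly, the two paths written.
#' @export
write_dose_raw <- function(dose, basepath) {
  stopifnot(inherits(dose, "dose_grid"))
  hdr <- list(shape = dose$grid$shape, spacing = dose$grid$spacing,
              origin = dose$grid$origin, quantity = dose$quantity,
              dtype = "float32", byte_order = "little",
              order = "column-major")
  jp <- paste0(basepath, ".json")
  rp <- paste0(basepath, ".raw")
  jsonlite::write_json(hdr, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(rp, open = "wb")
  on.exit(close(con))
  writeBin(as.numeric(dose$values), con, size = 4L, endian = "little")
  invisible(c(jp, rp))
}

#' Read a dose grid written by [write_dose_raw()]
#'
#' @param basepath path without extension.
#' @return A [dose_grid()].
#' @export
read_dose_raw <- function(basepath) {
  hdr <- jsonlite::read_json(paste0(basepath, ".json"), simplifyVector = TRUE)
  stopifnot(identical(hdr$dtype, "float32"),
            identical(hdr$byte_order, "little"))
  grid <- grid_spec(hdr$shape, hdr$spacing, hdr$origin)
  n <- prod(grid$shape)
  con <- file(paste0(basepath, ".raw"), open = "rb")
  on.exit(close(con))
  values <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  if (length(values) != n) stop("read_dose_raw: truncated raw block")
  dose_grid(array(values, dim = grid$shape), grid, hdr$quantity)
}
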