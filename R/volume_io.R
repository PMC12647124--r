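# Volume and table I/O.  Two on-disk volume formats are supported:
# - NRRD (detached-header-free, raw little-endian encoding), the primary
#   format for grayscale volumes, label maps and masks;
# - baseline multi-page TIFF (uncompressed, little-endian), used for 8/16-bit
#   integer stacks and for the RGB ratio maps.
# Axis order on disk follows the in-memory convention: z is the fastest axis
# in NRRD raw data; TIFF pages are z-slices with rows = y, columns = x.

nrrd_type <- function(data) {
  if (is.logical(data)) "uint8"
  else if (is.integer(data)) "int32"
  else if (is.double(data)) "double"
  else stop("unsupported array storage mode: ", typeof(data))
}

write_nrrd <- function(data, voxel_size_um, path) {
  dims <- vol_dims(data)
  type <- nrrd_type(data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by airwayplug",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", dims[1], dims[2], dims[3]),
           sprintf("spacings: %.10g %.10g %.10g", voxel_size_um, voxel_size_um, voxel_size_um),
           sprintf("content: %s", typeof(data)),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  v <- as.vector(data)
  if (type == "uint8") writeBin(as.integer(v), con, size = 1L, endian = "little")
  else if (type == "int32") writeBin(as.integer(v), con, size = 4L, endian = "little")
  else writeBin(as.double(v), con, size = 8L, endian = "little")
  invisible(path)
}

read_nrrd <- function(path, voxel_size_um = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of NRRD header")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-D NRRD volumes are supported")
  type <- fields[["type"]]
  enc <- fields[["encoding"]] %||% "raw"
  if (enc != "raw") stop("only raw-encoded NRRD is supported")
  vs <- voxel_size_um
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    if (max(sp) - min(sp) > 1e-9 * max(sp))
      stop("anisotropic voxel spacing is unsupported; volumes must be isotropic")
    vs <- sp[1]
  }
  if (is.null(vs))
    stop("no voxel size in NRRD metadata; supply voxel_size_um explicitly")
  n <- prod(sizes)
  v <- switch(type,
    "uint8"  = readBin(con, "integer", n = n, size = 1L, signed = FALSE, endian = "little"),
    "int16"  = readBin(con, "integer", n = n, size = 2L, endian = "little"),
    "int32"  = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    "float"  = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "double" = readBin(con, "double", n = n, size = 8L, endian = "little"),
    stop("unsupported NRRD type: ", type))
  if (length(v) != n) stop("truncated NRRD data")
  if (identical(fields[["content"]], "logical")) v <- as.logical(v)
  volume3d(array(v, sizes), vs)
}

# --- minimal baseline TIFF (classic, little-endian, uncompressed) ----------

tiff_pack_entry <- function(tag, type, count, value_or_offset) {
  c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4L, endian = "little"),
    value_or_offset)
}

val4 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
val2pad <- function(x) c(writeBin(as.integer(x), raw(), size = 2L, endian = "little"), as.raw(c(0, 0)))

write_tiff <- function(data, voxel_size_um, path, rgb = FALSE, bits = 8L) {
  # data: integer array; gray (nz,ny,nx) or rgb list of three (nz,ny,nx) arrays
  if (rgb) {
    dims <- vol_dims(data[[1]])
    spp <- 3L; bits <- 8L
  } else {
    dims <- vol_dims(data)
    spp <- 1L
    if (!bits %in% c(8L, 16L)) stop("grayscale TIFF supports 8 or 16 bits")
    if (any(data < 0) || any(data >= 2^bits))
      stop(sprintf("values out of range for %d-bit TIFF", bits))
  }
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  desc <- sprintf("airwayplug voxel_size_um=%.10g", voxel_size_um)
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))
  strip_bytes <- ny * nx * spp * (bits %/% 8L)
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(2L * 21L, con, size = 2L, endian = "little")  # magic 42
  writeBin(8L, con, size = 4L, endian = "little")        # first IFD offset
  offset <- 8L
  for (p in seq_len(nz)) {
    ifd_off <- offset
    desc_off <- ifd_off + ifd_size
    strip_off <- desc_off + length(desc_raw)
    next_ifd <- if (p < nz) strip_off + strip_bytes else 0L
    entries <- c(
      tiff_pack_entry(256L, 4L, 1L, val4(nx)),                 # ImageWidth
      tiff_pack_entry(257L, 4L, 1L, val4(ny)),                 # ImageLength
      tiff_pack_entry(258L, 3L, 1L, val2pad(bits)),            # BitsPerSample (single value, same for all samples)
      tiff_pack_entry(259L, 3L, 1L, val2pad(1L)),              # Compression: none
      tiff_pack_entry(262L, 3L, 1L, val2pad(if (rgb) 2L else 1L)), # Photometric
      tiff_pack_entry(270L, 2L, length(desc_raw), val4(desc_off)), # ImageDescription
      tiff_pack_entry(273L, 4L, 1L, val4(strip_off)),          # StripOffsets
      tiff_pack_entry(277L, 3L, 1L, val2pad(spp)),             # SamplesPerPixel
      tiff_pack_entry(278L, 4L, 1L, val4(ny)),                 # RowsPerStrip
      tiff_pack_entry(279L, 4L, 1L, val4(strip_bytes))         # StripByteCounts
    )
    writeBin(n_entries, con, size = 2L, endian = "little")
    writeBin(entries, con)
    writeBin(as.integer(next_ifd), con, size = 4L, endian = "little")
    writeBin(desc_raw, con)
    # pixel data: row-major (y rows of x), samples interleaved for RGB
    if (rgb) {
      r <- data[[1]][p, , ]; g <- data[[2]][p, , ]; b <- data[[3]][p, , ]
      px <- rbind(as.vector(t(r)), as.vector(t(g)), as.vector(t(b)))
      writeBin(as.integer(px), con, size = 1L, endian = "little")
    } else {
      writeBin(as.integer(t(data[p, , ])), con, size = bits %/% 8L, endian = "little")
    }
    offset <- strip_off + strip_bytes
  }
  invisible(path)
}

read_tiff <- function(path, voxel_size_um = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (!identical(rawToChar(raw[1:2]), "II")) stop("only little-endian TIFF is supported")
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2L,
                               signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4L, endian = "little")
  if (u16(2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- u32(4L)
  pages <- list()
  vs <- voxel_size_um
  while (ifd != 0L) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2L + (k - 1L) * 12L
      tag <- u16(e); type <- u16(e + 2L); cnt <- u32(e + 4L)
      val <- if (type == 3L && cnt == 1L) u16(e + 8L) else u32(e + 8L)
      tags[[as.character(tag)]] <- list(type = type, count = cnt, value = val)
    }
    gettag <- function(t, default = NULL) {
      x <- tags[[as.character(t)]]
      if (is.null(x)) default else x$value
    }
    if (gettag(259L, 1L) != 1L) stop("compressed TIFF is not supported")
    w <- gettag(256L); h <- gettag(257L)
    bits <- gettag(258L, 8L)
    if (bits > 255L) bits <- u16(gettag(258L))  # value stored out-of-line
    spp <- gettag(277L, 1L)
    so <- gettag(273L); sb <- gettag(279L)
    if (is.null(w) || is.null(h) || is.null(so)) stop("malformed TIFF IFD")
    dsc <- tags[["270"]]
    if (!is.null(dsc) && is.null(voxel_size_um)) {
      txt <- rawToChar(raw[(dsc$value + 1):(dsc$value + dsc$count)])
      m <- regmatches(txt, regexec("voxel_size_um=([0-9.eE+-]+)", txt))[[1]]
      if (length(m) == 2L) vs <- as.numeric(m[2])
    }
    bytes <- raw[(so + 1):(so + sb)]
    if (spp == 1L) {
      px <- readBin(bytes, "integer", n = w * h, size = bits %/% 8L,
                    signed = FALSE, endian = "little")
      pages[[length(pages) + 1L]] <- list(gray = matrix(px, nrow = h, byrow = TRUE))
    } else if (spp == 3L) {
      px <- as.integer(bytes)
      pages[[length(pages) + 1L]] <- list(
        r = matrix(px[seq(1L, length(px), 3L)], nrow = h, byrow = TRUE),
        g = matrix(px[seq(2L, length(px), 3L)], nrow = h, byrow = TRUE),
        b = matrix(px[seq(3L, length(px), 3L)], nrow = h, byrow = TRUE))
    } else stop("unsupported SamplesPerPixel: ", spp)
    ifd <- u32(ifd + 2L + n * 12L)
  }
  if (is.null(vs))
    stop("TIFF carries no voxel size metadata; supply voxel_size_um explicitly")
  nz <- length(pages)
  if ("gray" %in% names(pages[[1]])) {
    h <- nrow(pages[[1]]$gray); w <- ncol(pages[[1]]$gray)
    out <- array(0L, c(nz, h, w))
    for (p in seq_len(nz)) out[p, , ] <- pages[[p]]$gray
    volume3d(out, vs)
  } else {
    h <- nrow(pages[[1]]$r); w <- ncol(pages[[1]]$r)
    out <- list(r = array(0L, c(nz, h, w)), g = array(0L, c(nz, h, w)),
                b = array(0L, c(nz, h, w)))
    for (p in seq_len(nz)) {
      out$r[p, , ] <- pages[[p]]$r
      out$g[p, , ] <- pages[[p]]$g
      out$b[p, , ] <- pages[[p]]$b
    }
    out$r <- volume3d(out$r, vs)
    out
  }
}

#' Read a 3-D volume (NRRD or multi-page TIFF)
#'
#' @param path file ending in `.nrrd`, `.tif` or `.tiff`.
#' @param voxel_size_um explicit voxel size; required when the file carries
#'   none (never silently defaulted).  Anisotropic spacing is an error.
#' @return a [volume3d()]; for RGB TIFF a list of channel volumes.
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nrrd = read_nrrd(path, voxel_size_um),
         tif = ,
         tiff = read_tiff(path, voxel_size_um),
         stop("unsupported volume format: .", ext, " (use .nrrd or .tif)"))
}

#' Write a 3-D volume (NRRD or multi-page TIFF)
#'
#' NRRD stores logical, integer or double arrays losslessly; TIFF is limited
#' to 8/16-bit non-negative integers.  Integer round-trips are bit-exact.
#'
#' @param volume a [volume3d()] (or plain array with `voxel_size_um` given).
#' @param path output file (`.nrrd`, `.tif`, `.tiff`).
#' @param voxel_size_um voxel size override if `volume` carries none.
#' @param force overwrite an existing file (otherwise an error).
#' @export
write_volume <- function(volume, path, voxel_size_um = NULL, force = FALSE) {
  dims <- vol_dims(volume)
  if (prod(dims) == 0L) stop("refusing to write a 0-voxel volume")
  vs <- voxel_size_um %||% attr(volume, "voxel_size_um")
  if (is.null(vs)) stop("no voxel size available; supply voxel_size_um")
  if (file.exists(path) && !force)
    stop("output exists; use force = TRUE to overwrite: ", path)
  data <- unclass(volume)
  attr(data, "voxel_size_um") <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") write_nrrd(data, vs, path)
  else if (ext %in% c("tif", "tiff")) {
    if (!is.integer(data) && !is.logical(data))
      stop("TIFF output supports integer data only; use .nrrd for doubles")
    data <- array(as.integer(data), dims)
    bits <- if (max(data) > 255L) 16L else 8L
    write_tiff(data, vs, path, rgb = FALSE, bits = bits)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

#' Read and validate a segment score CSV
#'
#' Expected header: `animal_id, genotype, age_group, segment_label, lobe,
#' generation, score`.  Scores must be 0/1/2, generations 1-11 (the trachea,
#' generation 0, is excluded from scoring by design), lobes one of
#' RUL/RML/RLL/RCL/LL, and segment labels must exist in the catalog.
#'
#' @param path CSV file path.
#' @param catalog nomenclature catalog to validate against.
#' @return data.table of validated scores with the catalog attached as an
#'   attribute.
#' @export
read_score_csv <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- as.data.table(read.csv(path, stringsAsFactors = FALSE))
  need <- c("animal_id", "genotype", "age_group", "segment_label", "lobe",
            "generation", "score")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("score CSV is missing columns: ", paste(miss, collapse = ", "))
  rowmsg <- function(i, msg) stop(sprintf("score CSV row %d: %s", i, msg))
  bad <- which(!(d$score %in% c(0L, 1L, 2L)))
  if (length(bad)) rowmsg(bad[1], sprintf("score %s outside {0,1,2}", d$score[bad[1]]))
  bad <- which(d$generation == 0L)
  if (length(bad)) rowmsg(bad[1], "generation 0 is the trachea, which is excluded from visual mucus scoring")
  bad <- which(!(d$generation %in% 1:11))
  if (length(bad)) rowmsg(bad[1], sprintf("generation %s outside 1..11", d$generation[bad[1]]))
  bad <- which(!(d$lobe %in% LOBE_CODES))
  if (length(bad)) rowmsg(bad[1], sprintf("unknown lobe '%s'", d$lobe[bad[1]]))
  cat_dt <- as.data.table(catalog)
  bad <- which(!(d$segment_label %in% cat_dt$segment_label))
  if (length(bad)) rowmsg(bad[1], sprintf("unknown segment label '%s'", d$segment_label[bad[1]]))
  setattr(d, "catalog", cat_dt)
  d[]
}

#' Colour for a ratio value on the green-to-red map scale
#'
#' Linear green (lowest) to red (highest) gradient, clamped at `scale`.
#'
#' @param ratio ratio values in `[0, 1]`.
#' @param scale full-scale ratio (defaults: 0.30 for area, 1.0 for contact).
#' @return integer matrix with columns `r, g, b` in 0-255.
#' @export
ratio_colour <- function(ratio, scale) {
  if (any(ratio < 0 | ratio > 1)) stop("ratio outside [0, 1]")
  s <- clamp(ratio / scale, 0, 1)
  cbind(r = as.integer(round(255 * s)), g = as.integer(round(255 * (1 - s))),
        b = 0L)
}

#' Write a 3-D RGB ratio map (multi-page TIFF)
#'
#' Paints every voxel of each labelled cross-section with the green-to-red
#' colour of its ratio (default full scale 0-30 % for the area ratio and
#' 0-100 % for the contact ratio).  Components excluded from the analysis are
#' rendered blue; background is black.
#'
#' @param station_labels integer array: per-voxel station id (0 = background).
#' @param ratios numeric vector of ratios in `[0, 1]` indexed by station id.
#' @param which `"area"` or `"contact"`; selects the default scale.
#' @param path output `.tif` path.
#' @param excluded_labels station ids to render blue.
#' @param scale override the full-scale ratio.
#' @param voxel_size_um voxel size stored in the TIFF metadata.
#' @param force overwrite existing file.
#' @export
write_ratio_map <- function(station_labels, ratios, which = c("area", "contact"),
                            path, excluded_labels = integer(), scale = NULL,
                            voxel_size_um = 1, force = FALSE) {
  which <- match.arg(which)
  scale <- scale %||% if (which == "area") 0.30 else 1.0
  dims <- vol_dims(station_labels)
  if (file.exists(path) && !force)
    stop("output exists; use force = TRUE to overwrite: ", path)
  cols <- ratio_colour(ratios, scale)
  r <- array(0L, dims); g <- array(0L, dims); b <- array(0L, dims)
  fg <- which(station_labels > 0L)
  lab <- station_labels[fg]
  known <- lab <= nrow(cols)
  li <- fg[known]; lv <- lab[known]
  r[li] <- cols[lv, 1]; g[li] <- cols[lv, 2]; b[li] <- cols[lv, 3]
  if (length(excluded_labels)) {
    ex <- which(array(station_labels %in% excluded_labels, dims))
    r[ex] <- 0L; g[ex] <- 0L; b[ex] <- 255L
  }
  write_tiff(list(r, g, b), voxel_size_um, path, rgb = TRUE)
  invisible(path)
}
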