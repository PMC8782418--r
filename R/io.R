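## Slice input/output. Two dialects:
##  * Single-frame CT DICOM, explicit VR little endian. The writer emits a
##    minimal but standards-shaped file (preamble, file meta group with the
##    explicit-VR transfer syntax, MONOCHROME2 16-bit signed pixels with
##    RescaleSlope/Intercept so stored values map exactly to HU). The
##    reader walks explicit-VR datasets, converts to HU through the rescale
##    tags (their absence is an error, never an assumed identity), and
##    refuses non-CT modalities.
##  * A plain-text raster container (.ctm): '#'-prefixed header lines
##    (rows, cols, spacing, dose, provenance) followed by one image row per
##    line at full double precision; bit-exact round trips.

UID_CT_IMAGE_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_IMPLEMENTATION <- "1.2.826.0.1.3680043.10.1463.1"

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "little")
.u32le <- function(x) {
  ## unsigned 32-bit; values stay far below 2^31 here
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

.evenPad <- function(v, padByte = as.raw(0x20)) {
  if (length(v) %% 2L) c(v, padByte) else v
}

.dcmElement <- function(group, element, vr, value) {
  ## value: raw vector, already even-padded by caller where needed
  head <- c(.u16le(group), .u16le(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .u32le(length(value)), value)
  } else {
    c(head, .u16le(length(value)), value)
  }
}

.dcmString <- function(group, element, vr, s,
                       padByte = if (vr == "UI") as.raw(0) else as.raw(0x20)) {
  .dcmElement(group, element, vr, .evenPad(charToRaw(s), padByte))
}

.dcmUS <- function(group, element, x)
  .dcmElement(group, element, "US", .u16le(x))

#' Write a CT slice
#'
#' Format is chosen by extension: `.dcm` writes single-frame CT DICOM
#' (explicit VR little endian, 16-bit signed stored pixels, slope 1 /
#' intercept -1024 so stored values map exactly to HU); anything else
#' writes the plain-text raster container. HU outside the representable
#' stored range are clipped with a warning reporting the count. The
#' provenance string is recorded (DICOM: Image Comments tag).
#'
#' @param img a [CTImage-class].
#' @param path output path.
#' @param like optional [CTImage-class] whose spatial metadata (pixel
#'   spacing) is copied onto the output.
#' @return `path` invisibly.
#' @export
writeCT <- function(img, path, like = NULL) {
  stopifnot(is(img, "CTImage"))
  if (!is.null(like)) img@pixelSpacing <- pixelSpacing(like)
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) .writeDICOM(img, path)
  else .writeCTText(img, path)
  invisible(path)
}

.writeDICOM <- function(img, path) {
  m <- pixels(img)
  intercept <- -1024
  stored <- round(m - intercept)
  nClip <- sum(stored < -32768 | stored > 32767)
  if (nClip > 0) {
    warning(sprintf("%d pixel(s) outside the storable HU range were clipped",
                    nClip))
    stored <- pmin(pmax(stored, -32768), 32767)
  }
  sp <- pixelSpacing(img)
  sopUID <- paste0(UID_IMPLEMENTATION, ".", format(round(as.numeric(
    Sys.time()) * 1000) %% 1e9, scientific = FALSE), ".",
    sample.int(1e6, 1))

  meta <- c(
    .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dcmString(0x0002, 0x0002, "UI", UID_CT_IMAGE_STORAGE),
    .dcmString(0x0002, 0x0003, "UI", sopUID),
    .dcmString(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
    .dcmString(0x0002, 0x0012, "UI", UID_IMPLEMENTATION))
  metaLen <- .dcmElement(0x0002, 0x0000, "UL", .u32le(length(meta)))

  ## pixel data: column of rows -> DICOM is row-major, so transpose
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  ds <- c(
    .dcmString(0x0008, 0x0016, "UI", UID_CT_IMAGE_STORAGE),
    .dcmString(0x0008, 0x0018, "UI", sopUID),
    .dcmString(0x0008, 0x0060, "CS", "CT"),
    .dcmString(0x0008, 0x103E, "LO", paste0("waveganCT ", doseLabel(img))),
    .dcmString(0x0020, 0x4000, "LT", provenance(img)),
    .dcmUS(0x0028, 0x0002, 1),
    .dcmString(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcmUS(0x0028, 0x0010, nrow(m)),
    .dcmUS(0x0028, 0x0011, ncol(m)),
    .dcmString(0x0028, 0x0030, "DS", sprintf("%g\\%g", sp[1], sp[2])),
    .dcmUS(0x0028, 0x0100, 16),
    .dcmUS(0x0028, 0x0101, 16),
    .dcmUS(0x0028, 0x0102, 15),
    .dcmUS(0x0028, 0x0103, 1),
    .dcmString(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
    .dcmString(0x0028, 0x1053, "DS", "1"),
    .dcmElement(0x7FE0, 0x0010, "OW", pix))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), metaLen, meta, ds), con)
}

.writeCTText <- function(img, path) {
  m <- pixels(img)
  sp <- pixelSpacing(img)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# waveganCT raster v1",
               sprintf("# rows %d", nrow(m)),
               sprintf("# cols %d", ncol(m)),
               sprintf("# spacing %.17g %.17g", sp[1], sp[2]),
               sprintf("# dose %s", doseLabel(img)),
               sprintf("# provenance %s", provenance(img))), con)
  writeLines(apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
}

#' Read a CT slice
#'
#' Dispatches on extension: `.dcm` parses explicit-VR little-endian DICOM
#' (non-CT modality is an error; missing RescaleSlope/Intercept is an
#' error, never an assumed identity); other extensions parse the
#' plain-text raster container.
#'
#' @param path input path.
#' @return A [CTImage-class] in HU.
#' @export
readCT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) .readDICOM(path)
  else .readCTText(path)
}

.readDICOM <- function(path) {
  buf <- readBin(path, raw(), file.size(path))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  tags <- list()
  rd16 <- function(at) readBin(buf[at:(at + 1L)], "integer", size = 2,
                               endian = "little", signed = FALSE)
  rd32 <- function(at) readBin(buf[at:(at + 3L)], "integer", size = 4,
                               endian = "little")
  while (pos + 7L <= length(buf)) {
    group <- rd16(pos); element <- rd16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- rd32(pos + 8L)
      valAt <- pos + 12L
    } else {
      len <- rd16(pos + 6L)
      valAt <- pos + 8L
    }
    if (len < 0 || valAt + len - 1L > length(buf))
      stop("corrupt DICOM element at byte ", pos)
    key <- sprintf("%04x,%04x", group, element)
    tags[[key]] <- list(vr = vr, value = buf[valAt:(valAt + len - 1L)])
    pos <- valAt + len
  }
  getStr <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$value[t$value != as.raw(0)]))
  }
  getUS <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    readBin(t$value, "integer", size = 2, endian = "little", signed = FALSE)
  }
  modality <- getStr("0008,0060")
  if (!is.null(modality) && modality != "CT")
    stop("not a CT image (Modality = ", modality, ")")
  rows <- getUS("0028,0010"); cols <- getUS("0028,0011")
  if (is.null(rows) || is.null(cols)) stop("DICOM lacks Rows/Columns")
  slope <- getStr("0028,1053"); intercept <- getStr("0028,1052")
  if (is.null(slope) || is.null(intercept))
    stop("DICOM lacks RescaleSlope/RescaleIntercept; refusing to assume identity")
  slope <- as.numeric(slope); intercept <- as.numeric(intercept)
  signedPix <- identical(getUS("0028,0103"), 1L)
  pixRaw <- tags[["7fe0,0010"]]
  if (is.null(pixRaw)) stop("DICOM lacks PixelData")
  stored <- readBin(pixRaw$value, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = signedPix)
  hu <- matrix(stored * slope + intercept, rows, cols, byrow = TRUE)
  spStr <- getStr("0028,0030")
  sp <- if (is.null(spStr)) {
    warning("DICOM lacks PixelSpacing; assuming 1 mm")
    c(1, 1)
  } else as.numeric(strsplit(spStr, "\\\\")[[1]][1:2])
  desc <- getStr("0008,103e")
  dose <- if (!is.null(desc) && grepl("virtual", desc)) "virtual"
  else if (!is.null(desc) && grepl("standard", desc)) "standard" else "low"
  CTImage(hu, pixelSpacing = sp, doseLabel = dose,
          provenance = getStr("0020,4000") %||% "")
}

.readCTText <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || !grepl("waveganCT raster", hdr[1]))
    stop("not a waveganCT raster file: ", path)
  field <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, " "), "", ln[1])
  }
  rows <- as.integer(field("rows")); cols <- as.integer(field("cols"))
  sp <- as.numeric(strsplit(field("spacing"), " +")[[1]])
  dose <- field("dose") %||% "low"
  prov <- field("provenance") %||% ""
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) != rows) stop("raster body does not match declared rows")
  m <- do.call(rbind, lapply(body, function(s)
    as.numeric(strsplit(s, " +")[[1]])))
  if (ncol(m) != cols) stop("raster body does not match declared cols")
  CTImage(m, pixelSpacing = sp, doseLabel = dose, provenance = prov)
}

#' Write / read a label mask as plain text
#'
#' Same raster layout as the image container with an integer body and the
#' legend in header lines (`# label <value> <name>`).
#'
#' @param mask a [LabelMask-class].
#' @param path file path.
#' @return `writeMask()` returns `path` invisibly; `readMask()` the
#'   [LabelMask-class].
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  lab <- labelMatrix(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# waveganCT mask v1",
               sprintf("# rows %d", nrow(lab)),
               sprintf("# cols %d", ncol(lab)),
               sprintf("# label %s %s", names(maskLegend(mask)),
                       maskLegend(mask))), con)
  writeLines(apply(lab, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || !grepl("waveganCT mask", hdr[1]))
    stop("not a waveganCT mask file: ", path)
  leg <- hdr[grepl("^# label ", hdr)]
  parts <- strsplit(sub("^# label ", "", leg), " +")
  legend <- setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  lab <- do.call(rbind, lapply(body, function(s)
    as.integer(strsplit(s, " +")[[1]])))
  LabelMask(lab, legend)
}

#' Write / read an image corpus directory
#'
#' Writes every slice plus `manifest.csv` (columns `file`, `dose_label`,
#' `provenance`, and the generating `seed`/config hash when given);
#' `readCorpus()` loads the images listed in the manifest.
#'
#' @param imgs list of [CTImage-class].
#' @param dir directory (created if needed).
#' @param format `"text"` (`.ctm`) or `"dicom"` (`.dcm`).
#' @param seed optional integer recorded in the manifest.
#' @return `writeCorpus()`: the manifest path, invisibly. `readCorpus()`:
#'   list of [CTImage-class].
#' @export
writeCorpus <- function(imgs, dir, format = c("text", "dicom"),
                        seed = NA_integer_) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "text") "ctm" else "dcm"
  files <- sprintf("slice_%04d.%s", seq_along(imgs), ext)
  for (i in seq_along(imgs)) writeCT(imgs[[i]], file.path(dir, files[i]))
  manifest <- data.frame(file = files,
                         dose_label = vapply(imgs, doseLabel, ""),
                         provenance = vapply(imgs, provenance, ""),
                         seed = seed)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  files <- if (file.exists(mf)) read.csv(mf)$file
  else list.files(dir, pattern = "\\.(ctm|dcm)$")
  if (!length(files)) stop("no corpus images found in ", dir)
  lapply(file.path(dir, files), readCT)
}
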