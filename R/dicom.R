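# Minimal DICOM Part-10 support: just enough to write and read the
# image-acquisition header attributes the dose model needs (explicit VR
# little endian, no pixel data, no sequences).  Mammography units store
# kVp, exposure, anode/filter materials and compressed thickness in the
# header; nothing below touches image data.

.DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.DICOM_SOP_MAMMO <- "1.2.840.10008.5.1.4.1.1.1.2"
# VRs carrying a 4-byte length after 2 reserved bytes
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                  endian = "little")

.pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# one explicit-VR element as raw bytes
.dicom_element <- function(group, element, vr, value) {
  body <- switch(vr,
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    OB = as.raw(value),
    # string VRs; UI pads with NUL, the rest with space
    .pad_even(charToRaw(as.character(value)),
              pad = if (vr == "UI") as.raw(0) else as.raw(0x20)))
  if (vr == "OB") body <- .pad_even(body, as.raw(0))
  len <- length(body)
  header <- c(.uint16le(group), .uint16le(element), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    header <- c(header, as.raw(c(0, 0)),
                writeBin(as.integer(len), raw(), size = 4, endian = "little"))
  } else {
    header <- c(header, .uint16le(len))
  }
  c(header, body)
}

# tags: list of list(group, element, vr, value); meta group written with its
# group length, dataset elements in ascending tag order
.dicom_write_file <- function(path, sop_instance_uid, tags) {
  meta_elems <- c(
    .dicom_element(0x0002, 0x0001, "OB", c(0, 1)),
    .dicom_element(0x0002, 0x0002, "UI", .DICOM_SOP_MAMMO),
    .dicom_element(0x0002, 0x0003, "UI", sop_instance_uid),
    .dicom_element(0x0002, 0x0010, "UI", .DICOM_TS_EXPLICIT_LE),
    .dicom_element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.7156.1")
  )
  meta <- c(.dicom_element(0x0002, 0x0000, "UL", length(meta_elems)),
            meta_elems)
  ord <- order(vapply(tags, function(t) t$group * 65536 + t$element, 0))
  body <- unlist(lapply(tags[ord], function(t)
    .dicom_element(t$group, t$element, t$vr, t$value)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# parse a Part-10 file; returns named list "GGGG,EEEE" -> character value
# (string VRs) or raw (binary VRs)
.dicom_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM Part-10 file (no DICM magic)", path),
         call. = FALSE)
  pos <- 133L
  out <- list()
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- u32(pos + 8L); pos <- pos + 12L
    } else {
      len <- u16(pos + 6L); pos <- pos + 8L
    }
    if (group == 0x7FE0 && element == 0x0010) break  # pixel data: done
    val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    out[[key]] <- if (vr %in% c("OB", "OW", "UN", "SQ", "UL", "US"))
      val else trimws(rawToChar(val[val != as.raw(0)]))
    pos <- pos + len
  }
  ts <- out[["0002,0010"]]
  if (!is.null(ts) && !identical(ts, .DICOM_TS_EXPLICIT_LE))
    stop(sprintf("unsupported transfer syntax '%s' (only explicit VR little endian)",
                 ts), call. = FALSE)
  out
}

# reverse map of canonical materials to DICOM defined terms
.material_to_dicom <- c(Mo = "MOLYBDENUM", Rh = "RHODIUM", W = "TUNGSTEN",
                        Ag = "SILVER")

#' Write a header-only DICOM file for an exam
#'
#' Produces a valid Part-10 file (explicit VR little endian, no pixel data)
#' carrying exactly the acquisition attributes the reader consumes: tube
#' voltage (0018,0060), exposure (0018,1152) and exposure-in-uAs
#' (0018,1153), anode target material (0018,1191), filter material
#' (0018,7050), body part thickness in mm (0018,11A0), station name
#' (0008,1010) and patient age (0010,1010).  Used to build test fixtures
#' and interoperability checks; files are deterministic given the exam.
#'
#' @param exam An [exam_record()].
#' @param path Output file path.
#' @param fid_cm Optional FID to record as source-to-detector distance (mm).
#' @return `path`, invisibly.
#' @export
write_exam_dicom <- function(exam, path, fid_cm = NULL) {
  mat <- function(x) {
    m <- .material_to_dicom[x]
    if (is.na(m)) toupper(x) else unname(m)
  }
  uid <- paste0("1.2.826.0.1.3680043.9.7156.2.",
                sum(utf8ToInt(exam$exam_id)) %% 99991, ".",
                round(exam$kvp * 10), ".", round(exam$mas * 1000) %% 999983)
  tags <- list(
    list(group = 0x0008, element = 0x0016, vr = "UI", value = .DICOM_SOP_MAMMO),
    list(group = 0x0008, element = 0x0018, vr = "UI", value = uid),
    list(group = 0x0008, element = 0x0060, vr = "CS", value = "MG"),
    list(group = 0x0008, element = 0x1010, vr = "SH", value = exam$device_id),
    list(group = 0x0018, element = 0x0060, vr = "DS",
         value = format(exam$kvp)),
    list(group = 0x0018, element = 0x1153, vr = "IS",
         value = format(round(exam$mas * 1000))),
    list(group = 0x0018, element = 0x1191, vr = "CS",
         value = mat(exam$combination$anode)),
    list(group = 0x0018, element = 0x7050, vr = "LO",
         value = mat(exam$combination$filter)),
    list(group = 0x0018, element = 0x11A0, vr = "DS",
         value = format(exam$thickness_cm * 10))
  )
  if (abs(exam$mas - round(exam$mas)) < 1e-9)
    tags <- c(tags, list(list(group = 0x0018, element = 0x1152, vr = "IS",
                              value = format(round(exam$mas)))))
  if (!is.null(fid_cm))
    tags <- c(tags, list(list(group = 0x0018, element = 0x1110, vr = "DS",
                              value = format(fid_cm * 10))))
  if (!is.na(exam$age_years))
    tags <- c(tags, list(list(group = 0x0010, element = 0x1010, vr = "AS",
                              value = sprintf("%03dY", round(exam$age_years)))))
  .dicom_write_file(path, uid, tags)
}
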