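# Exam ingestion: DICOM headers or CSV batches -> exam_record objects,
# with unit normalization (DICOM mm -> cm, uAs -> mAs) and per-field
# provenance so audits can trace every number to its source tag/column.

#' Read one exam from a DICOM header
#'
#' Extracts tube voltage (0018,0060), exposure (0018,1152) in mAs with
#' fallback to exposure-in-uAs (0018,1153)/1000, anode target material
#' (0018,1191), filter material (0018,7050) and body part thickness
#' (0018,11A0, mm, converted to cm).  The device is resolved against the
#' registry by station name (0008,1010) unless `device_id` overrides it.
#' Missing mandatory attributes raise an error naming the absent tags;
#' optional ones produce warnings recorded in the extraction log.
#'
#' @param path DICOM file path (header read only; pixel data ignored).
#' @param registry Named list of [device_profile()]s (see
#'   [read_device_registry()]); used to validate the device reference.
#' @param device_id Optional explicit device override.
#' @param exam_id Identifier for the record (defaults to the file name).
#' @return List with `exam` (an [exam_record()]) and `extraction` (raw tag
#'   values, per-field provenance, warnings).
#' @export
read_exam_dicom <- function(path, registry = NULL, device_id = NULL,
                            exam_id = NULL) {
  tags <- .dicom_read_file(path)
  get <- function(key) tags[[key]]
  warnings <- character(0)
  provenance <- list()
  missing_tags <- character(0)

  kvp <- get("0018,0060")
  if (is.null(kvp)) missing_tags <- c(missing_tags, "(0018,0060) KVP")
  else provenance$kvp <- "dicom_tag (0018,0060)"

  exposure_mas <- get("0018,1152")
  exposure_uas <- get("0018,1153")
  mas <- NULL
  if (!is.null(exposure_mas)) {
    mas <- as.numeric(exposure_mas)
    provenance$mas <- "dicom_tag (0018,1152)"
    if (!is.null(exposure_uas)) {
      alt <- as.numeric(exposure_uas) / 1000
      if (abs(alt - mas) > 0.01 * max(mas, 1e-9)) {
        warnings <- c(warnings, sprintf(
          "(0018,1152) Exposure = %g mAs disagrees with (0018,1153)/1000 = %g mAs by > 1%%",
          mas, alt))
      }
    }
  } else if (!is.null(exposure_uas)) {
    mas <- as.numeric(exposure_uas) / 1000
    provenance$mas <- "dicom_tag (0018,1153)/1000"
  } else {
    missing_tags <- c(missing_tags,
                      "(0018,1152) Exposure / (0018,1153) ExposureInuAs")
  }

  anode <- get("0018,1191")
  filt <- get("0018,7050")
  if (is.null(anode)) missing_tags <- c(missing_tags,
                                        "(0018,1191) AnodeTargetMaterial")
  if (is.null(filt)) missing_tags <- c(missing_tags,
                                       "(0018,7050) FilterMaterial")

  thick_mm <- get("0018,11A0")
  if (is.null(thick_mm)) missing_tags <- c(missing_tags,
                                           "(0018,11A0) BodyPartThickness")
  else provenance$thickness_cm <- "dicom_tag (0018,11A0) mm -> cm"

  if (length(missing_tags))
    stop("DICOM header missing mandatory attribute(s): ",
         paste(missing_tags, collapse = "; "), call. = FALSE)

  combination <- map_anode_filter(anode, filt)
  provenance$combination <- "dicom_tag (0018,1191)+(0018,7050)"

  station <- get("0008,1010")
  if (is.null(device_id)) {
    if (is.null(station)) {
      warnings <- c(warnings,
                    "(0008,1010) StationName absent and no device override given")
      device_id <- "unknown"
      provenance$device_id <- "default"
    } else {
      device_id <- station
      provenance$device_id <- "dicom_tag (0008,1010)"
    }
  } else provenance$device_id <- "override"
  if (!is.null(registry) && is.null(registry[[device_id]]))
    warnings <- c(warnings,
                  sprintf("device '%s' not found in registry", device_id))

  age <- NA_real_
  age_raw <- get("0010,1010")
  if (!is.null(age_raw)) {
    age <- suppressWarnings(as.numeric(sub("Y$", "", age_raw)))
    provenance$age_years <- "dicom_tag (0010,1010)"
  }
  # source-to-detector distance is recorded for cross-checking only: the
  # calibrated FID definition can differ from the header value
  sdd <- get("0018,1110")
  if (!is.null(sdd) && !is.null(registry) && !is.null(registry[[device_id]])) {
    fid_hdr <- as.numeric(sdd) / 10
    fid_reg <- registry[[device_id]]$fid_cm
    if (abs(fid_hdr - fid_reg) > 0.5)
      warnings <- c(warnings, sprintf(
        "(0018,1110) source-to-detector %g cm differs from registry FID %g cm",
        fid_hdr, fid_reg))
  }

  exam <- exam_record(exam_id %||% basename(path), combination,
                      kvp = as.numeric(kvp), mas = mas,
                      thickness_cm = as.numeric(thick_mm) / 10,
                      device_id = device_id, age_years = age)
  for (w in warnings) warning(w, call. = FALSE)
  list(exam = exam,
       extraction = list(tags = tags, provenance = provenance,
                         warnings = warnings))
}

#' Read an exam batch CSV
#'
#' Required columns: `exam_id, combination, kvp, mas, thickness_cm,
#' device_id`; optional: `age_years, glandularity_pct, hvl_mmal,
#' thickness_sigma_cm`.  Rows failing validation are reported with their
#' line numbers; by default any bad row aborts the read.
#'
#' @param path CSV file path.
#' @param registry Optional registry; unknown device ids raise warnings.
#' @param on_error `"stop"` (default) or `"collect"`: with `"collect"`,
#'   invalid rows are dropped and returned in an `errors` attribute.
#' @return List of [exam_record()]s (possibly empty), with attribute
#'   `errors` (data.frame of row, message) when `on_error = "collect"`.
#' @export
read_exam_csv <- function(path, registry = NULL,
                          on_error = c("stop", "collect")) {
  on_error <- match.arg(on_error)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("exam_id", "combination", "kvp", "mas", "thickness_cm", "device_id")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("exam CSV missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  opt_num <- function(row, col, default = NA_real_) {
    if (!col %in% names(df)) return(default)
    v <- suppressWarnings(as.numeric(row[[col]]))
    if (is.na(v)) default else v
  }
  exams <- list()
  errors <- data.frame(row = integer(0), message = character(0))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    rec <- tryCatch({
      ex <- exam_record(row$exam_id, row$combination,
                        kvp = suppressWarnings(as.numeric(row$kvp)),
                        mas = suppressWarnings(as.numeric(row$mas)),
                        thickness_cm = suppressWarnings(as.numeric(row$thickness_cm)),
                        device_id = row$device_id,
                        thickness_sigma_cm = opt_num(row, "thickness_sigma_cm", 0.5),
                        age_years = opt_num(row, "age_years"),
                        glandularity_pct = opt_num(row, "glandularity_pct"),
                        hvl_mmal = opt_num(row, "hvl_mmal"))
      if (!is.null(registry) && is.null(registry[[ex$device_id]]))
        warning(sprintf("row %d: device '%s' not in registry", i + 1L,
                        ex$device_id), call. = FALSE)
      ex
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      msg <- sprintf("row %d (line %d): %s", i, i + 1L, conditionMessage(rec))
      if (on_error == "stop") stop(msg, call. = FALSE)
      errors <- rbind(errors, data.frame(row = i, message = msg))
    } else exams[[length(exams) + 1L]] <- rec
  }
  attr(exams, "errors") <- errors
  exams
}

#' Write exams to the normalized CSV schema
#'
#' @param exams List of [exam_record()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exam_csv <- function(exams, path) {
  df <- do.call(rbind, lapply(exams, function(e)
    data.frame(exam_id = e$exam_id, combination = format(e$combination),
               kvp = e$kvp, mas = e$mas, thickness_cm = e$thickness_cm,
               thickness_sigma_cm = e$thickness_sigma_cm,
               device_id = e$device_id, age_years = e$age_years,
               glandularity_pct = e$glandularity_pct,
               hvl_mmal = e$hvl_mmal)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
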