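# Canonical anode-filter vocabulary.  The five calibrated spectra are
# Mo-Mo, Mo-Rh, Rh-Rh (GE Senographe DS reference tube) and W-Rh, W-Ag
# (Hologic Selenia Dimensions reference tube); anything else is
# representable but flagged so downstream code can refuse to pick a
# calibration for it.

.known_materials <- c(Mo = "Mo", Rh = "Rh", W = "W", Ag = "Ag")

.dicom_material_map <- c(
  "MOLYBDENUM" = "Mo", "MO" = "Mo",
  "RHODIUM"    = "Rh", "RH" = "Rh",
  "TUNGSTEN"   = "W",  "W"  = "W", "WOLFRAM" = "W",
  "SILVER"     = "Ag", "AG" = "Ag"
)

.canonical_material <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (!nzchar(x)) stop("empty material label", call. = FALSE)
  hit <- .dicom_material_map[toupper(x)]
  if (!is.na(hit)) unname(hit) else x
}

#' Anode-filter combination
#'
#' Builds the canonical representation of an X-ray target / filtration
#' material pair (e.g. `Mo-Mo`, `W-Rh`).  Comparison and lookup are done on
#' the canonical `"Anode-Filter"` string, case-insensitively.  Materials
#' outside the calibrated vocabulary (Mo, Rh, W, Ag) are accepted but the
#' result carries `known = FALSE` so callers can warn or refuse.
#'
#' @param anode Anode (target) material label, e.g. `"Mo"` or `"TUNGSTEN"`.
#' @param filter Filter material label, e.g. `"Rh"` or `"SILVER"`.
#' @return An object of class `anode_filter` with elements `anode`, `filter`
#'   and `known`.
#' @examples
#' anode_filter("Mo", "Rh")
#' map_anode_filter("TUNGSTEN", "RHODIUM")
#' @export
anode_filter <- function(anode, filter) {
  a <- .canonical_material(anode)
  f <- .canonical_material(filter)
  known <- (a %in% .known_materials) && (f %in% .known_materials)
  structure(list(anode = a, filter = f, known = known),
            class = "anode_filter")
}

#' Map DICOM material spellings to a combination
#'
#' Normalizes the common DICOM spellings of anode/filter materials
#' (`MOLYBDENUM`, `RHODIUM`, `TUNGSTEN`, `SILVER`, and the element symbols)
#' to the canonical combination.  Unknown spellings are kept verbatim and
#' flagged via a warning.
#'
#' @inheritParams anode_filter
#' @return An `anode_filter` object.
#' @export
map_anode_filter <- function(anode, filter) {
  af <- anode_filter(anode, filter)
  if (!af$known) {
    warning(sprintf("unrecognised anode-filter combination '%s' (no bundled calibration)",
                    format(af)), call. = FALSE)
  }
  af
}

#' Parse a combination string
#'
#' @param x A string such as `"Mo-Rh"` or `"TUNGSTEN-SILVER"`.
#' @return An `anode_filter` object.
#' @export
parse_combination <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(trimws(x), "[-/]")[[1]]
  if (length(parts) != 2L)
    stop(sprintf("cannot parse combination '%s' (expected 'Anode-Filter')", x),
         call. = FALSE)
  anode_filter(parts[1], parts[2])
}

#' @export
format.anode_filter <- function(x, ...) paste0(x$anode, "-", x$filter)

#' @export
print.anode_filter <- function(x, ...) {
  cat(format(x), if (!x$known) " [unknown combination]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.anode_filter <- function(x, ...) format(x)

#' @export
`==.anode_filter` <- function(e1, e2) {
  key <- function(e) {
    if (inherits(e, "anode_filter")) toupper(format(e))
    else toupper(format(parse_combination(as.character(e))))
  }
  key(e1) == key(e2)
}

# internal: canonical lookup key for a combination or combination string
combo_key <- function(x) {
  if (inherits(x, "anode_filter")) return(format(x))
  format(parse_combination(as.character(x)))
}
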