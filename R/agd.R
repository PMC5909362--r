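# Reference AGD calculators.  Dance: AGD = k_ai * g * c * s, with g and c
# tabulated against beam quality (HVL, mm Al) and compressed thickness and
# s a per-spectrum scalar.  Wu: AGD = k_ai * DgN with DgN tabulated the
# same way.  The published factor tables come from third-party literature
# and are supplied by the user as CSV grids; this module owns only the
# grid/interpolation contract and the products.

#' Rectangular coefficient lookup grid
#'
#' A Dance `g`/`c` or Wu `DgN` table on a strictly increasing
#' (HVL, thickness) grid, optionally stratified by age group or
#' glandularity bin and by anode-filter combination.
#'
#' @param name One of `"dance_g"`, `"dance_c"`, `"wu_dgn"`.
#' @param hvl_grid Strictly increasing HVL grid (mm Al).
#' @param thickness_grid Strictly increasing thickness grid (cm).
#' @param values Matrix of positive coefficients,
#'   `length(hvl_grid) x length(thickness_grid)`.
#' @param stratum Optional stratifier label (e.g. `"40-49"`, `"50-64"`, a
#'   glandularity bin).
#' @param combination Optional [anode_filter()] the table applies to.
#' @return An object of class `coefficient_table`.
#' @export
coefficient_table <- function(name = c("dance_g", "dance_c", "wu_dgn"),
                              hvl_grid, thickness_grid, values,
                              stratum = NULL, combination = NULL) {
  name <- match.arg(name)
  values <- as.matrix(values)
  if (any(diff(hvl_grid) <= 0) || any(diff(thickness_grid) <= 0))
    stop("grids must be strictly increasing", call. = FALSE)
  if (!all(dim(values) == c(length(hvl_grid), length(thickness_grid))))
    stop("values must be a length(hvl_grid) x length(thickness_grid) matrix",
         call. = FALSE)
  if (any(values <= 0)) stop("coefficients must be > 0", call. = FALSE)
  if (name == "dance_c" && any(values < 0.885 | values > 1.306))
    stop("dance_c values must lie in [0.885, 1.306]", call. = FALSE)
  if (!is.null(combination) && !inherits(combination, "anode_filter"))
    combination <- parse_combination(combination)
  structure(list(name = name, hvl_grid = as.numeric(hvl_grid),
                 thickness_grid = as.numeric(thickness_grid),
                 values = values, stratum = stratum,
                 combination = combination),
            class = "coefficient_table")
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat(sprintf("%s table: HVL [%g, %g] mm Al x thickness [%g, %g] cm (%d x %d)%s\n",
              x$name, min(x$hvl_grid), max(x$hvl_grid),
              min(x$thickness_grid), max(x$thickness_grid),
              nrow(x$values), ncol(x$values),
              if (!is.null(x$stratum)) paste0(", stratum ", x$stratum) else ""))
  invisible(x)
}

#' Bilinear interpolation on a coefficient grid
#'
#' Exact at grid nodes; bilinear between them.  Queries outside the grid
#' raise an error unless `clamp = TRUE`, in which case they are clamped to
#' the nearest edge with a warning.
#'
#' @param table A [coefficient_table()].
#' @param hvl Query half value layer (mm Al).
#' @param d Query thickness (cm).
#' @param clamp Allow (and warn on) out-of-grid queries.
#' @return The interpolated coefficient.
#' @export
interpolate_coefficient <- function(table, hvl, d, clamp = FALSE) {
  hg <- table$hvl_grid; tg <- table$thickness_grid
  out_of_range <- hvl < hg[1] || hvl > hg[length(hg)] ||
    d < tg[1] || d > tg[length(tg)]
  if (out_of_range) {
    if (!clamp)
      stop(sprintf("query (HVL = %g, d = %g) outside %s grid (HVL [%g, %g], d [%g, %g]); set clamp = TRUE to clamp",
                   hvl, d, table$name, hg[1], hg[length(hg)], tg[1],
                   tg[length(tg)]), call. = FALSE)
    warning(sprintf("query (HVL = %g, d = %g) clamped to the %s grid edge",
                    hvl, d, table$name), call. = FALSE)
    hvl <- min(max(hvl, hg[1]), hg[length(hg)])
    d <- min(max(d, tg[1]), tg[length(tg)])
  }
  i <- max(findInterval(hvl, hg, rightmost.closed = TRUE), 1L)
  j <- max(findInterval(d, tg, rightmost.closed = TRUE), 1L)
  i2 <- min(i + 1L, length(hg)); j2 <- min(j + 1L, length(tg))
  th <- if (i2 > i) (hvl - hg[i]) / (hg[i2] - hg[i]) else 0
  tt <- if (j2 > j) (d - tg[j]) / (tg[j2] - tg[j]) else 0
  v <- table$values
  (1 - th) * (1 - tt) * v[i, j] + th * (1 - tt) * v[i2, j] +
    (1 - th) * tt * v[i, j2] + th * tt * v[i2, j2]
}

# extract scalar kerma from a kerma_result or plain number
.k_value <- function(k_ai) {
  if (inherits(k_ai, "kerma_result")) k_ai$k_ai else as.numeric(k_ai)
}

#' Reference AGD, Dance formalism
#'
#' `AGD = k_ai * g * c * s`, with a fixed 20% relative 1-sigma
#' uncertainty (the conventional overall error for table-based AGD).
#'
#' @param k_ai Incident air kerma (mGy) or a `kerma_result`.
#' @param g,c_factor,s Dance conversion factors (all `> 0`).
#' @return List with `value` (mGy) and `sigma`.
#' @export
dance_agd <- function(k_ai, g, c_factor, s) {
  k <- .k_value(k_ai)
  if (any(c(k, g, c_factor, s) <= 0))
    stop("k_ai and all Dance factors must be > 0", call. = FALSE)
  v <- k * g * c_factor * s
  list(value = v, sigma = agd_sigma(v))
}

#' Reference AGD, Wu formalism
#'
#' `AGD = k_ai * DgN`, 20% relative 1-sigma uncertainty.
#'
#' @param k_ai Incident air kerma (mGy) or a `kerma_result`.
#' @param dgn Normalized average glandular dose coefficient (`> 0`).
#' @return List with `value` (mGy) and `sigma`.
#' @export
wu_agd <- function(k_ai, dgn) {
  k <- .k_value(k_ai)
  if (k <= 0 || dgn <= 0) stop("k_ai and DgN must be > 0", call. = FALSE)
  v <- k * dgn
  list(value = v, sigma = agd_sigma(v))
}

#' Pick the c-table stratum for a patient
#'
#' The Dance `c` factor is tabulated separately for the 40-49 and 50-64
#' age groups (a proxy for typical glandularity at that age).  Ages outside
#' both ranges map to the nearest group with a warning.  When the table is
#' binned by glandularity instead and a glandularity is given, it overrides
#' age.
#'
#' @param age_years Patient age (optional when glandularity decides).
#' @param glandularity_pct Breast glandularity in percent (optional).
#' @param glandularity_bins Optional named list of glandularity bins, each
#'   `c(lo, hi)` in percent; when supplied together with
#'   `glandularity_pct`, the matching bin name is returned.
#' @return The stratum key: `"40-49"`, `"50-64"`, or a bin name.
#' @export
select_c_stratum <- function(age_years = NA, glandularity_pct = NA,
                             glandularity_bins = NULL) {
  if (!is.null(glandularity_bins) && !is.na(glandularity_pct)) {
    for (nm in names(glandularity_bins)) {
      b <- glandularity_bins[[nm]]
      if (glandularity_pct >= b[1] && glandularity_pct <= b[2]) return(nm)
    }
    stop(sprintf("glandularity %g%% falls in no declared bin", glandularity_pct),
         call. = FALSE)
  }
  if (is.na(age_years))
    stop("stratified c table: need patient age or glandularity", call. = FALSE)
  if (age_years >= 40 && age_years <= 49) return("40-49")
  if (age_years >= 50 && age_years <= 64) return("50-64")
  nearest <- if (age_years < 40) "40-49" else "50-64"
  warning(sprintf("age %g outside the tabulated 40-49 / 50-64 ranges; using nearest group %s",
                  age_years, nearest), call. = FALSE)
  nearest
}

# ---- CSV grid interface ----------------------------------------------------

#' Read / write a coefficient grid CSV
#'
#' Grid format: first row is the thickness grid (cm) with an empty leading
#' cell, first column the HVL grid (mm Al), body the coefficients.  A
#' sidecar JSON (`<path>.json`) declares `name`, `stratum`, `combination`.
#'
#' @param path CSV path; the sidecar is `paste0(path, ".json")`.
#' @return A [coefficient_table()].
#' @export
read_coefficient_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  thickness <- as.numeric(m[1, -1])
  hvl <- as.numeric(m[-1, 1])
  values <- matrix(as.numeric(m[-1, -1]), nrow = length(hvl))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(name = "wu_dgn")
  coefficient_table(meta$name, hvl, thickness, values,
                    stratum = meta$stratum,
                    combination = meta$combination)
}

#' @param table A [coefficient_table()].
#' @rdname read_coefficient_csv
#' @export
write_coefficient_csv <- function(table, path) {
  m <- rbind(c(NA, table$thickness_grid),
             cbind(table$hvl_grid, table$values))
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "")
  meta <- list(name = table$name)
  if (!is.null(table$stratum)) meta$stratum <- table$stratum
  if (!is.null(table$combination)) meta$combination <- format(table$combination)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an s-factor map
#'
#' JSON object mapping combination strings to the Dance `s` factor, e.g.
#' `{"Mo-Mo": 1.000, "W-Rh": 1.042}`.
#'
#' @param path JSON path.
#' @return Named numeric vector keyed by canonical combination.
#' @export
read_s_factors <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- unlist(raw)
  if (any(s <= 0)) stop("s factors must be > 0", call. = FALSE)
  names(s) <- vapply(names(s), combo_key, character(1))
  s
}
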