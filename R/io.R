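#' Read an SPR curve from a delimited file
#'
#' Expects a header and two numeric columns; columns named `angle_deg` and
#' `reflectance` are used when present, otherwise the first two columns.
#' Errors carry the offending data line number (header = line 1).
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`; default inferred from the extension.
#' @return an [spr_curve()].
#' @export
read_spr_curve <- function(path, format = NULL) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.csv(path, sep = sep, header = TRUE,
                        colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop_input(path, ": need two columns with a header")
  cols <- if (all(c("angle_deg", "reflectance") %in% names(df)))
    c("angle_deg", "reflectance") else names(df)[1:2]
  ang <- suppressWarnings(as.numeric(df[[cols[1]]]))
  val <- suppressWarnings(as.numeric(df[[cols[2]]]))
  bad <- which(is.na(ang) | is.na(val))
  if (length(bad))
    stop_input(path, ": non-numeric cell on line ", bad[1] + 1L)
  nonmono <- which(diff(ang) <= 0)
  if (length(nonmono))
    stop_input(path, ": angle not strictly increasing at line ",
               nonmono[1] + 2L,
               if (ang[nonmono[1] + 1L] == ang[nonmono[1]])
                 " (duplicated angle)" else "")
  spr_curve(ang, val)
}

#' Write an SPR curve as two-column CSV
#'
#' Header `angle_deg,reflectance`, '.' decimal, UTF-8; full double
#' precision so a read/write round trip is value-identical.
#'
#' @param curve an [spr_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spr_curve <- function(curve, path) {
  stopifnot(inherits(curve, "spr_curve"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("angle_deg,reflectance", con)
  writeLines(sprintf("%.17g,%.17g", curve$angles_deg, curve$values), con)
  invisible(path)
}

#' Write a detector image triplet as TIFF files
#'
#' 16-bit grayscale TIFFs `dark.tif`, `te.tif`, `tm.tif` scaled by the
#' detector full scale (65535 counts).
#'
#' @param raw a [raw_image_set()].
#' @param dir output directory (created if missing).
#' @param full_scale count value mapped to the 16-bit maximum.
#' @return character vector of the three paths, invisibly.
#' @export
write_image_set <- function(raw, dir, full_scale = 65535) {
  stopifnot(inherits(raw, "raw_image_set"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_input("the 'tiff' package is required to write TIFF frames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("dark.tif", "te.tif", "tm.tif"))
  frames <- list(raw$dark, raw$te, raw$tm)
  for (i in 1:3)
    tiff::writeTIFF(pmin(pmax(frames[[i]] / full_scale, 0), 1), paths[i],
                    bits.per.sample = 16L)
  invisible(paths)
}

#' Read a detector image triplet from TIFF files
#'
#' @param dir directory holding `dark.tif`, `te.tif`, `tm.tif`.
#' @param full_scale count value of the 16-bit maximum.
#' @return a [raw_image_set()].
#' @export
read_image_set <- function(dir, full_scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_input("the 'tiff' package is required to read TIFF frames")
  get <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop_input("missing frame: ", p)
    m <- tiff::readTIFF(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * full_scale
  }
  raw_image_set(get("dark.tif"), get("te.tif"), get("tm.tif"))
}

#' Write a machine-readable fit report
#'
#' JSON record with the model identity, the parameter record (letters A-I
#' for the nonlinear models, scaled-basis coefficients for the polynomial),
#' convergence metadata, per-region quality when available, the angle
#' estimates, the package version and an MD5 checksum of the input curve.
#'
#' @param fit a [fit_result].
#' @param angles optional [angle_estimates()].
#' @param path output path (`.json`).
#' @param region_stats optional data.frame from [region_quality()].
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, angles = NULL, path,
                             region_stats = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  params <- if (fit$model_id == "polynomial")
    list(order = fit$params$order,
         coefficients = fit$params$coefficients,
         domain = fit$params$domain)
  else as.list(unclass(fit$params))
  rep <- list(
    model = fit$model_id,
    params = params,
    sse = fit$sse,
    converged = fit$converged,
    n_iter = fit$n_iter,
    n_points = length(fit$curve),
    region_stats = region_stats,
    theta_RA_deg = if (!is.null(angles)) angles$theta_RA else NULL,
    theta_CA_deg = if (!is.null(angles)) angles$theta_CA else NULL,
    software_version = as.character(utils::packageVersion("sprfit")),
    input_md5 = curve_checksum(fit$curve))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a fit report
#' @param path a JSON report written by [write_fit_report()].
#' @return named list.
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# MD5 of the canonical CSV serialisation of a curve.
curve_checksum <- function(curve) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_spr_curve(curve, tmp)
  unname(tools::md5sum(tmp))
}
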