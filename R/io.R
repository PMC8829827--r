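#' Read a delimited data table against a required schema
#'
#' Reads a comma- or whitespace-delimited text file with a header row,
#' checks that every required column is present and numeric, and reports
#' malformed cells by row and column. Row numbers in error messages count
#' data rows (header excluded).
#'
#' @param path file path
#' @param columns character vector of required column names
#' @param optional character vector of optional column names kept when
#'   present
#' @return data frame with the requested columns, in file order
#' @export
read_table <- function(path, columns, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl(",", first)) "," else ""
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  missing_cols <- setdiff(columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- c(columns, intersect(optional, names(raw)))
  out <- raw[keep]
  for (col in keep) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & !out[[col]] %in% c("NA", ""))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                   out[[col]][bad[1]], col, bad[1], path), call. = FALSE)
    }
    out[[col]] <- vals
  }
  out
}

#' Read a gradient-series decay table
#'
#' Expects columns `g_G_per_cm`, `integral`, `replicate`; gradients are
#' converted to T/m on read.
#'
#' @param path file path
#' @param params a [pulse_params()] object for the series
#' @return a [decay_series()]
#' @export
read_decay_table <- function(path, params) {
  tab <- read_table(path, c("g_G_per_cm", "integral", "replicate"))
  decay_series(gradient_to_si(tab$g_G_per_cm), tab$integral, params,
               replicate = tab$replicate)
}

#' Read a titration table of apparent diffusion coefficients
#'
#' Expects columns `C_M_mM` (or `KCl_mM` with `xvar = "KCl_mM"`),
#' `D_app_1e5_cm2_s`, and optionally `se_D`; converts to SI on read.
#'
#' @param path file path
#' @param xvar name of the independent-variable column
#' @return data frame with `x` (mol/L), `D_app` (m^2/s), `se_D` (m^2/s or
#'   NA)
#' @export
read_titration_table <- function(path, xvar = "C_M_mM") {
  tab <- read_table(path, c(xvar, "D_app_1e5_cm2_s"), optional = "se_D")
  data.frame(x = conc_to_si(tab[[xvar]]),
             D_app = diffusion_to_si(tab$D_app_1e5_cm2_s),
             se_D = if ("se_D" %in% names(tab)) diffusion_to_si(tab$se_D) else NA_real_)
}

#' Read an ion-quantification table
#'
#' Expects columns `C_M_mM`, `r_sample`, and optionally `replicate`.
#'
#' @param path file path
#' @return data frame with `C_M` (mol/L) and `r_sample`
#' @export
read_quant_table <- function(path) {
  tab <- read_table(path, c("C_M_mM", "r_sample"), optional = "replicate")
  data.frame(C_M = conc_to_si(tab$C_M_mM), r_sample = tab$r_sample)
}

#' Read a sampled 1D spectrum
#'
#' Expects columns `freq_hz`, `intensity`.
#'
#' @param path file path
#' @return a [spectrum1d()]
#' @export
read_spectrum <- function(path) {
  tab <- read_table(path, c("freq_hz", "intensity"))
  spectrum1d(tab$freq_hz, tab$intensity)
}

#' Write a data frame as a comma-delimited table
#'
#' @param x data frame
#' @param path destination
#' @return `path`, invisibly
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
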