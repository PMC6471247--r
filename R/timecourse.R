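#' Construct a fermentation time course
#'
#' A `timecourse` holds one analyte's concentration series for a single
#' donor/matrix/replicate fermenter arm. Concentrations are in mM, times in
#' hours. The default sampling grid used throughout the package is the
#' 9-point batch-fermentation grid 0, 2, 4, 6, 8, 10, 24, 30, 48 h.
#'
#' @param donor Donor identifier (e.g. `"O1"`).
#' @param matrix Matrix identifier (one of the study matrices, or `"control"`
#'   for the blank fermenter with microbiota alone).
#' @param replicate Positive integer replicate index.
#' @param analyte Analyte identifier (e.g. `"acetate"`, `"procyanidins"`).
#' @param times Strictly increasing numeric vector of sampling times (h).
#' @param conc Numeric vector of concentrations (mM), same length as `times`.
#' @param corrected Logical; `TRUE` once the blank-fermenter background has
#'   been subtracted. Uncorrected series must be non-negative.
#' @param clipped_points Integer indices (1-based) of points clipped to zero
#'   during background correction.
#'
#' @return An object of class `timecourse`.
#' @seealso [subtract_background()], [fit_fractional_conversion()]
#' @export
#' @examples
#' tc <- timecourse("O1", "Mno", 1, "acetate",
#'                  times = c(0, 2, 4, 6, 8, 10, 24, 30, 48),
#'                  conc  = c(0, 5, 9, 13, 16, 18, 25, 26, 27))
#' tc
timecourse <- function(donor, matrix, replicate, analyte, times, conc,
                       corrected = FALSE, clipped_points = integer()) {
  stopifnot(is.character(donor) || is.factor(donor),
            is.character(matrix) || is.factor(matrix))
  replicate <- as.integer(replicate)
  if (length(replicate) != 1L || is.na(replicate) || replicate < 1L)
    stop("'replicate' must be a single positive integer", call. = FALSE)
  times <- as.numeric(times)
  conc <- as.numeric(conc)
  if (length(times) != length(conc))
    stop("'times' and 'conc' must have the same length", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(conc)))
    stop("'conc' must be finite", call. = FALSE)
  if (!isTRUE(corrected) && any(conc < 0))
    stop("uncorrected concentrations must be non-negative", call. = FALSE)
  structure(
    list(donor = as.character(donor), matrix = as.character(matrix),
         replicate = replicate, analyte = as.character(analyte),
         times = times, conc = conc, corrected = isTRUE(corrected),
         clipped_points = as.integer(clipped_points)),
    class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %s | %s | rep %d | %s%s\n",
              x$donor, x$matrix, x$replicate, x$analyte,
              if (x$corrected) " (background-corrected)" else ""))
  print(data.frame(time_h = x$times, conc_mM = signif(x$conc, 6)),
        row.names = FALSE)
  if (length(x$clipped_points))
    cat("clipped to 0 at point(s):",
        paste(x$clipped_points, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.timecourse <- function(x, ...) {
  data.frame(donor = x$donor, matrix = x$matrix, replicate = x$replicate,
              analyte = x$analyte, time_h = x$times, conc_mM = x$conc,
              stringsAsFactors = FALSE)
}

# internal: unique key identifying the arm/analyte of a timecourse
tc_key <- function(tc) {
  paste(tc$donor, tc$matrix, tc$replicate, tc$analyte, sep = "|")
}
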