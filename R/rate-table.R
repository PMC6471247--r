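#' Assemble a rate table from kinetic fits
#'
#' Collects per-arm fractional-conversion fits into the standard summary
#' layout: one row per (donor, matrix, analyte) with the rate constant
#' `K_per_h`, the 48-h extent (percent, `NA` where undefined) and a
#' convergence flag. Non-converged fits are flagged, never dropped.
#'
#' @param fits A list of entries, each a list with elements `donor`,
#'   `matrix`, `analyte` and `fit` (an `fc_fit`); entries produced by
#'   [fit_fractional_conversion()] on time courses already carry the key
#'   fields and may be given directly. Optionally an `extent` element
#'   (percent).
#' @return A `data.frame` of class `rate_table` with columns `donor`,
#'   `matrix`, `analyte`, `K_per_h`, `extent_48h_pct`, `converged`.
#' @export
#' @examples
#' t9 <- c(0, 2, 4, 6, 8, 10, 24, 30, 48)
#' tc <- timecourse("O1", "Mnc", 1, "acetate", t9,
#'                  fractional_conversion(0, 60, 0.131, t9))
#' build_rate_table(list(fit_fractional_conversion(tc)))
build_rate_table <- function(fits) {
  if (length(fits) == 0L) {
    out <- data.frame(donor = character(), matrix = character(),
                      analyte = character(), K_per_h = numeric(),
                      extent_48h_pct = numeric(), converged = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("rate_table", "data.frame")
    return(out)
  }
  rows <- lapply(fits, function(f) {
    fit <- if (inherits(f, "fc_fit")) f else f$fit
    if (is.null(f$donor) || is.null(f$matrix) || is.null(f$analyte))
      stop("each entry must carry donor, matrix and analyte", call. = FALSE)
    extent <- if (!inherits(f, "fc_fit") && !is.null(f$extent)) f$extent else NA_real_
    data.frame(donor = f$donor, matrix = f$matrix, analyte = f$analyte,
               K_per_h = fit$K, extent_48h_pct = extent,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- paste(out$donor, out$matrix, out$analyte, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (donor, matrix, analyte) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("Rate table: %d arm(s)\n", nrow(x)))
  NextMethod()
}
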