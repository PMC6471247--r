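#' Subtract the blank-fermenter background from a time course
#'
#' Metabolite production from a fermented matrix is isolated by subtracting,
#' point by point, the concentrations measured when the same donor's fecal
#' microbiota is incubated alone (the `"control"` arm). Negative differences
#' are physically impossible concentrations; by default they are clipped to
#' zero and the affected indices recorded in `clipped_points`.
#'
#' Both arms must share donor and analyte and, by default, an identical
#' sampling grid (both arms of a batch fermentation are sampled on the same
#' schedule). Set `interpolate = TRUE` to linearly interpolate the control
#' onto `tc`'s grid when grids differ; extrapolation outside the control's
#' range is refused.
#'
#' @param tc A [timecourse()] from a matrix arm.
#' @param control The matching [timecourse()] with `matrix == "control"`.
#' @param clip_at_zero Clip negative corrected values to 0 (default `TRUE`).
#' @param interpolate Allow linear interpolation of the control onto `tc`'s
#'   grid (default `FALSE`: grids must be identical).
#' @return A corrected [timecourse()] (`corrected = TRUE`).
#' @export
#' @examples
#' t9 <- c(0, 2, 4, 6, 8, 10, 24, 30, 48)
#' tc <- timecourse("O1", "Mno", 1, "acetate", t9, 1:9 / 2)
#' bg <- timecourse("O1", "control", 1, "acetate", t9, rep(0.2, 9))
#' subtract_background(tc, bg)
subtract_background <- function(tc, control, clip_at_zero = TRUE,
                                interpolate = FALSE) {
  stopifnot(inherits(tc, "timecourse"), inherits(control, "timecourse"))
  if (tc$donor != control$donor || tc$analyte != control$analyte)
    stop(sprintf("cannot pair arms: (%s, %s) vs (%s, %s) differ in donor or analyte",
                 tc$donor, tc$analyte, control$donor, control$analyte),
         call. = FALSE)
  if (control$matrix != "control")
    stop("'control' must be a control arm (matrix == \"control\")",
         call. = FALSE)

  if (length(tc$times) == length(control$times) &&
      all(tc$times == control$times)) {
    bg <- control$conc
  } else if (interpolate) {
    if (min(tc$times) < min(control$times) ||
        max(tc$times) > max(control$times))
      stop("control grid does not cover the sample grid; cannot interpolate",
           call. = FALSE)
    bg <- stats::approx(control$times, control$conc, xout = tc$times)$y
  } else {
    stop("sampling grids differ; pass interpolate = TRUE to align them",
         call. = FALSE)
  }

  diffc <- tc$conc - bg
  clipped <- integer()
  if (clip_at_zero) {
    clipped <- which(diffc < 0)
    diffc[clipped] <- 0
  }
  timecourse(tc$donor, tc$matrix, tc$replicate, tc$analyte,
             tc$times, diffc, corrected = TRUE, clipped_points = clipped)
}

#' Degradation extent after a fixed incubation time
#'
#' Percentage of the initial concentration lost by `t_end`, computed from
#' the observed endpoints (not from fitted parameters):
#' `100 * (C(0) - C(t_end)) / C(0)`.
#'
#' @param tc A [timecourse()] containing observations at `t = 0` and
#'   `t = t_end`, with `C(0) > 0`.
#' @param t_end End time in hours (default 48).
#' @return Extent in percent; 100 means complete disappearance, negative
#'   values indicate net accumulation.
#' @export
#' @examples
#' t9 <- c(0, 2, 4, 6, 8, 10, 24, 30, 48)
#' pc <- timecourse("O1", "Mno", 1, "procyanidins", t9,
#'                  fractional_conversion(0.8, 0.1, 0.2, t9))
#' degradation_extent(pc)
degradation_extent <- function(tc, t_end = 48) {
  stopifnot(inherits(tc, "timecourse"))
  i0 <- match(0, tc$times)
  i1 <- match(t_end, tc$times)
  if (is.na(i0) || is.na(i1))
    stop(sprintf("time course must contain observations at t = 0 and t = %g h",
                 t_end), call. = FALSE)
  c0 <- tc$conc[i0]
  if (c0 <= 0)
    stop("extent undefined: concentration at t = 0 is not positive",
         call. = FALSE)
  100 * (c0 - tc$conc[i1]) / c0
}
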