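#' Matrix composition record
#'
#' Holds one apple matrix's phenolic composition (% w/w of total phenolic
#' compounds) and cell-wall composition (mg per g of alcohol-insoluble
#' solids, AIS), with the methanol content used for the degree of pectin
#' methylation. The average degree of polymerization of procyanidins
#' (`dpn`) is carried as data, never computed.
#'
#' @param matrix_id Matrix identifier.
#' @param phenolics Named numeric, compound code -> % w/w (codes as in the
#'   compound table: CAT, EPI, PCA, PLX, PLZ, `5CQA`, pCQA, TotalFl, EC,
#'   CYA). Shares must total 100 within +/- 1 (rounding of printed values).
#' @param cellwall Named numeric, sugar -> mg/g AIS.
#' @param methanol Methanol, mg/g AIS.
#' @param dpn Average degree of polymerization (optional).
#' @return An object of class `composition_record`.
#' @export
composition_record <- function(matrix_id, phenolics, cellwall = numeric(),
                               methanol = NA_real_, dpn = NA_real_) {
  stopifnot(length(phenolics) >= 1, !is.null(names(phenolics)))
  if (any(phenolics < 0) || any(cellwall < 0, na.rm = TRUE))
    stop("composition values must be non-negative", call. = FALSE)
  tot <- sum(phenolics)
  if (abs(tot - 100) > 1)
    stop(sprintf("phenolic shares sum to %.2f, expected 100 +/- 1", tot),
         call. = FALSE)
  structure(list(matrix_id = as.character(matrix_id),
                 phenolics = phenolics, cellwall = cellwall,
                 methanol = methanol, dpn = dpn),
            class = "composition_record")
}

# molar masses: methanol, and galacturonic acid as the anhydro (polymeric
# pectin residue) unit -- the convention that reproduces the printed DM
MM_METHANOL <- 32.04
MM_ANHYDROGALACTURONIC <- 176.13

#' Degree of pectin methylation
#'
#' Molar ratio of methanol to uronic acid, as a percentage:
#' `100 * (methanol / 32.04) / (galacturonic_acid / 176.13)`, with
#' galacturonic acid counted as the anhydro residue of the pectin backbone
#' (176.13 g/mol). Inputs are mg per g AIS (any common mass unit works,
#' since only the ratio enters).
#'
#' @param methanol Methanol content (mg/g AIS), non-negative.
#' @param galacturonic_acid Galacturonic acid content (mg/g AIS), positive.
#' @return Degree of methylation in percent (unrounded; round to integer
#'   for presentation).
#' @export
#' @examples
#' round(degree_of_methylation(25, 170))  # 81
degree_of_methylation <- function(methanol, galacturonic_acid) {
  if (any(galacturonic_acid <= 0))
    stop("'galacturonic_acid' must be positive", call. = FALSE)
  if (any(methanol < 0))
    stop("'methanol' must be non-negative", call. = FALSE)
  100 * (methanol / MM_METHANOL) /
    (galacturonic_acid / MM_ANHYDROGALACTURONIC)
}

# compound code -> phenolic class
PHENOLIC_CLASSES <- list(
  "flavan-3-ols"        = c("CAT", "EPI", "PCA"),
  "dihydrochalcones"    = c("PLX", "PLZ"),
  "hydroxycinnamic acids" = c("5CQA", "pCQA"),
  "flavonols"           = c("TotalFl"),
  "anthocyanins"        = c("EC", "CYA"))

#' Phenolic class shares
#'
#' Sums individual compound shares (% w/w of total phenolics) into the five
#' phenolic classes: flavan-3-ols (catechin + epicatechin + procyanidins),
#' dihydrochalcones (phloretin-2-xyloglucoside + phloridzin),
#' hydroxycinnamic acids (5-caffeoylquinic + p-coumaroylquinic),
#' flavonols, and anthocyanins. Only classes with at least one compound
#' present are returned; totals are conserved.
#'
#' @param record A [composition_record()], or a named numeric vector of
#'   compound shares.
#' @return Named numeric vector of class shares (percent).
#' @export
#' @examples
#' phenolic_class_shares(c(`5CQA` = 17.39, pCQA = 1.10, PCA = 63.9,
#'                         CAT = 4.16, EPI = 8.9, PLX = 0.68, PLZ = 3.17,
#'                         TotalFl = 0.67))
phenolic_class_shares <- function(record) {
  ph <- if (inherits(record, "composition_record")) record$phenolics
        else record
  stopifnot(is.numeric(ph), !is.null(names(ph)))
  known <- unlist(PHENOLIC_CLASSES, use.names = FALSE)
  bad <- setdiff(names(ph), known)
  if (length(bad))
    stop("unknown phenolic compound code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  shares <- vapply(PHENOLIC_CLASSES, function(codes) {
    hit <- intersect(codes, names(ph))
    if (length(hit)) sum(ph[hit]) else NA_real_
  }, numeric(1))
  shares[!is.na(shares)]
}

#' Read a matrix-composition table
#'
#' Reads a CSV shaped like the published composition table: a `compound`
#' column plus one column per matrix; phenolic compound rows in % w/w,
#' cell-wall rows (`Rha`, `Fuc`, `Ara`, `Xyl`, `Man`, `Gal`, `Glc`,
#' `GalA`, `MeOH`) in mg/g AIS, and an optional `DPn` row.
#'
#' @param path Path to the CSV file.
#' @return A named list of [composition_record()]s, one per matrix column.
#' @export
read_composition <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"compound" %in% names(df))
    stop("composition CSV needs a 'compound' column", call. = FALSE)
  mats <- setdiff(names(df), "compound")
  sugars <- c("Rha", "Fuc", "Ara", "Xyl", "Man", "Gal", "Glc", "GalA")
  phen_rows <- df$compound %in% unlist(PHENOLIC_CLASSES, use.names = FALSE)
  recs <- lapply(mats, function(m) {
    v <- stats::setNames(df[[m]], df$compound)
    ph <- v[df$compound[phen_rows]]
    ph <- ph[!is.na(ph)]  # "nd" cells: compound absent from this matrix
    composition_record(
      m,
      phenolics = ph,
      cellwall = v[intersect(sugars, names(v))],
      methanol = if ("MeOH" %in% names(v)) v[["MeOH"]] else NA_real_,
      dpn = if ("DPn" %in% names(v)) v[["DPn"]] else NA_real_)
  })
  stats::setNames(recs, mats)
}
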