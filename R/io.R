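#' Read fermentation time courses from a long-format CSV
#'
#' Expects the header `donor,matrix,replicate,analyte,time_h,conc_mM`
#' (UTF-8, "." decimal separator). Rows may come in any order; they are
#' grouped by (donor, matrix, replicate, analyte) and sorted by time.
#'
#' @param path Path to the CSV file.
#' @return A list of [timecourse()] objects, ordered by key.
#' @export
read_timecourses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("donor", "matrix", "replicate", "analyte", "time_h", "conc_mM")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("time_h", "conc_mM", "replicate")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data line %d",
                   col, bad[1L] + 1L), call. = FALSE)
    df[[col]] <- v
  }
  if (nrow(df) == 0L) return(list())
  key <- paste(df$donor, df$matrix, df$replicate, df$analyte, sep = "|")
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), ]
    timecourse(g$donor[1L], g$matrix[1L], g$replicate[1L], g$analyte[1L],
               g$time_h, g$conc_mM)
  })
  out[order(names(out))]
}

#' Write time courses to a long-format CSV
#'
#' Inverse of [read_timecourses()]: writes the canonical
#' `donor,matrix,replicate,analyte,time_h,conc_mM` layout, one row per
#' observation, sorted by key then time.
#'
#' @param tcs List of [timecourse()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tcs, path) {
  dfs <- lapply(tcs, as.data.frame)
  df <- if (length(dfs)) do.call(rbind, dfs)
        else data.frame(donor = character(), matrix = character(),
                        replicate = integer(), analyte = character(),
                        time_h = numeric(), conc_mM = numeric())
  key <- paste(df$donor, df$matrix, df$replicate, df$analyte, sep = "|")
  df <- df[order(key, df$time_h), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a rate table to CSV
#'
#' Header: `donor,matrix,analyte,K_per_h,extent_48h_pct,converged`.
#'
#' @param table A `rate_table` from [build_rate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "rate_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# internal: write a stack of ANOVA tables (one per analyte) to CSV
write_anova_csv <- function(results, path) {
  rows <- lapply(names(results), function(a) {
    tab <- results[[a]]$table
    cbind(analyte = a, tab)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(analyte = character(), term = character(),
                        df = integer(), SS = numeric(), MS = numeric(),
                        F = numeric(), p = numeric(), stars = character())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
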