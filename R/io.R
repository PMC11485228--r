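#' Write / read a cohort table
#'
#' Cohort tables are UTF-8 CSV files, one row per patient: `patient_id`,
#' `era` (`comparator` / `primary`), demographics and covariates,
#' `followup_end_years`, and per outcome a `<name>_time` /
#' `<name>_event` column pair, times in years to six decimals.
#' `read_cohort_table(write_cohort_table(x))` is the identity.
#'
#' @param records cohort `data.frame` as from [generate_cohorts()].
#' @param path file path.
#' @return `write_cohort_table` returns `path` invisibly;
#'   `read_cohort_table` returns the validated cohort `data.frame`.
#' @export
write_cohort_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  tcols <- grep("(_time$)|(^followup_end_years$)|(^entry_offset_months$)",
                names(out), value = TRUE)
  for (cl in tcols) out[[cl]] <- sprintf("%.6f", out[[cl]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(dat) == 0L) return(dat)
  if (!all(c("patient_id", "era") %in% names(dat)))
    stop("cohort table must have 'patient_id' and 'era' columns", call. = FALSE)
  bad <- which(!dat$era %in% c("comparator", "primary"))
  if (length(bad))
    stop(sprintf("unknown era label '%s' at row %d", dat$era[bad[1]], bad[1]),
         call. = FALSE)
  tcols <- grep("_time$", names(dat), value = TRUE)
  for (cl in tcols) {
    if (!is.numeric(dat[[cl]]))
      stop(sprintf("malformed non-numeric value in column '%s'", cl),
           call. = FALSE)
    bad <- which(is.na(dat[[cl]]) | dat[[cl]] < 0)
    if (length(bad))
      stop(sprintf("negative or missing time in column '%s' at row %d",
                   cl, bad[1]), call. = FALSE)
    ecl <- sub("_time$", "_event", cl)
    if (ecl %in% names(dat)) {
      bad <- which(!dat[[ecl]] %in% c(0L, 1L))
      if (length(bad))
        stop(sprintf("event flag outside {0,1} in column '%s' at row %d",
                     ecl, bad[1]), call. = FALSE)
    }
  }
  dat
}
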