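#' @keywords internal
"_PACKAGE"

# formatted stop/warning without call noise
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a tab-separated table with '#' comment lines
#'
#' All input tables in this package are UTF-8 TSV files with a header row;
#' lines starting with '#' are ignored.
#'
#' @param path file path
#' @param required character vector of column names that must be present
#' @return data.frame
#' @export
read_tsv_table <- function(path, required = character()) {
  if (!file.exists(path)) stopf("input table not found: %s", path)
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0)
    stopf("table %s is missing column(s): %s", path, paste(miss, collapse = ", "))
  x
}

# check a numeric vector lies in [lo, hi]; used for atom fractions, RIA/LR
check_fraction <- function(x, name, lo = 0, hi = 1) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad))
    stopf("%s outside [%g, %g] (first offending value %g); percent/fraction mix-up?",
          name, lo, hi, x[which(bad)[1]])
  invisible(x)
}
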