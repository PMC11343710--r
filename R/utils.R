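# internal helpers: condition constructors and logging

dk_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "dynastikin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

dk_assert <- function(cond, msg, class = "dk_validation_error") {
  if (!isTRUE(cond)) dk_error(msg, class)
  invisible(TRUE)
}

.dk_env <- new.env(parent = emptyenv())
.dk_env$verbose <- FALSE

#' Toggle progress logging to stderr
#'
#' @param on logical; when `TRUE`, pipeline stages report progress on stderr.
#' @return the previous setting, invisibly.
#' @export
dk_verbose <- function(on = TRUE) {
  old <- .dk_env$verbose
  .dk_env$verbose <- isTRUE(on)
  invisible(old)
}

dk_log <- function(...) {
  if (isTRUE(.dk_env$verbose)) {
    message("[dynastikin] ", ...)
  }
  invisible(NULL)
}

# Parse a calendar year given either as a number already in astronomical
# numbering, or as a string like "616 BCE" / "45 CE".  Astronomical numbering
# makes 1 BCE year 0, so "N BCE" -> -(N - 1).  Applied exactly once, at parse
# time.
parse_year <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  bce <- grepl("BCE?$", x, ignore.case = TRUE)
  ce  <- grepl("(^|[0-9] ?)CE$", x, ignore.case = TRUE) & !bce
  num <- suppressWarnings(as.numeric(sub("\\s*(BCE?|CE)$", "", x, ignore.case = TRUE)))
  out[bce] <- -(num[bce] - 1)
  out[ce] <- num[ce]
  if (anyNA(out)) {
    dk_error(sprintf("cannot parse year value(s): %s",
                     paste(x[is.na(out)], collapse = ", ")),
             "dk_parse_error")
  }
  out
}
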