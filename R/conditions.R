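# Classed conditions: every user-facing failure carries a fedkg_* class so
# the CLI can map it onto its exit-code contract.

stop_fedkg <- function(..., class) {
  stop(structure(
    class = c(class, "fedkg_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

warn_fedkg <- function(..., class = "fedkg_warning") {
  warning(structure(
    class = c(class, "fedkg_warning", "warning", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

fedkg_log <- function(level, ..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
fedkg_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "fedkg"))
  } else {
    system.file("extdata", file, package = "fedkg", mustWork = TRUE)
  }
}
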