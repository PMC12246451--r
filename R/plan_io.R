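#' Read / write an acquisition plan as JSON
#'
#' The JSON mirrors the plan structure: objects `beam`, `scan`, `detector`
#' (field names as in [beam_setting()], [scan_setting()],
#' [detector_model()]) plus `method`.
#'
#' @param path File path.
#' @return An [acquisition_plan()] (read) or `path` invisibly (write).
#' @export
read_plan_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  beam <- do.call(beam_setting, j$beam)
  scan <- do.call(scan_setting, j$scan)
  det <- do.call(detector_model, j$detector)
  acquisition_plan(beam, scan, det, j$method)
}

#' @rdname read_plan_json
#' @param plan An [acquisition_plan()].
#' @export
write_plan_json <- function(plan, path) {
  j <- list(beam = unclass(plan$beam), scan = unclass(plan$scan),
            detector = unclass(plan$detector), method = plan$method)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
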