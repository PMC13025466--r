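# JSON serialization of partition results. Floats are written at full
# precision (digits = NA) so repeated runs with the same inputs are
# byte-identical.

#' Write a partition result as JSON
#'
#' @param result An `sh_partition`.
#' @param path Output path.
#' @param elements Optional element symbols (defaults to those in `result`).
#' @return The path, invisibly.
#' @export
write_partition_json <- function(result, path, elements = NULL) {
  stopifnot(inherits(result, "sh_partition"))
  obj <- list(
    elements = if (is.null(elements)) result$elements else elements,
    coordinates_bohr = unname(apply(result$centers, 1L, as.numeric,
                                    simplify = FALSE)),
    coefficients = result$coefficients,
    populations = result$populations,
    charges = result$charges,
    iterations = result$iterations,
    converged = result$converged,
    objective = result$objective,
    settings = result$settings
  )
  # 17 significant digits: doubles survive the round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
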