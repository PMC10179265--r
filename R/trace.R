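#' Create an empty filter trace
#'
#' A filter trace is the machine-readable audit of a filter cascade: an
#' ordered table of stages with before/after variant counts. Counts never
#' increase within a stage and chain exactly between stages.
#'
#' @return an object of class `filter_trace` (a data frame with columns
#'   `stage`, `count_in`, `count_out`).
#' @export
filter_trace <- function() {
  structure(data.frame(stage = character(0), count_in = integer(0),
                       count_out = integer(0), stringsAsFactors = FALSE),
            class = c("filter_trace", "data.frame"))
}

#' Append a stage to a filter trace
#' @param trace a [filter_trace()].
#' @param stage stage name.
#' @param count_in,count_out variant counts entering/leaving the stage.
#' @return the extended trace.
#' @export
add_stage <- function(trace, stage, count_in, count_out) {
  if (count_out > count_in) stop("count_out exceeds count_in at stage ", stage)
  if (nrow(trace) > 0L && count_in != trace$count_out[nrow(trace)]) {
    stop("stage ", stage, " count_in does not chain from previous stage")
  }
  out <- rbind(as.data.frame(trace),
               data.frame(stage = stage, count_in = as.integer(count_in),
                          count_out = as.integer(count_out)))
  structure(out, class = c("filter_trace", "data.frame"))
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("filter trace:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-40s %8d -> %d\n", x$stage[i], x$count_in[i], x$count_out[i]))
  }
  invisible(x)
}
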