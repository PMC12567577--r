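# Cheap tibble construction for hot per-trial paths: equal-length columns,
# no recycling or name repair needed.
quick_tbl <- function(...) {
  lst <- list(...)
  structure(lst,
    class = c("tbl_df", "tbl", "data.frame"),
    row.names = c(NA_integer_, -length(lst[[1L]]))
  )
}

bind_tbl <- function(lst) {
  out <- data.table::rbindlist(lst)
  data.table::setDF(out)
  structure(out, class = c("tbl_df", "tbl", "data.frame"))
}

# Memoised Butterworth designs: keyed on order / normalised cutoff / type.
.butter_cache <- new.env(parent = emptyenv())
butter_design <- function(order, wc, type) {
  key <- sprintf("%d|%.15g|%s", order, wc, type)
  bt <- .butter_cache[[key]]
  if (is.null(bt)) {
    bt <- signal::butter(order, wc, type = type)
    .butter_cache[[key]] <- bt
  }
  bt
}
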