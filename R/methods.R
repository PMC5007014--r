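# S3 methods for classification results.

#' @export
print.brides <- function(x, ...) {
  cat(sprintf("Path-type classification (%s)\n", x$strategy))
  cat(sprintf("  %d original node(s), %d added node(s), %d pair(s)%s\n",
              x$n_original, x$n_added, nrow(x$records),
              if (x$all_pairs) "" else " (subset)"))
  cat(" ", paste(sprintf("%s=%d", substr(PATH_CLASSES, 1L, 1L), x$counts),
                 collapse = " "), "\n")
  invisible(x)
}

#' Summarize a classification result
#'
#' @param object A `brides` object.
#' @param ... Unused.
#' @return The object, invisibly; prints counts, proportions and witness
#'   length statistics.
#' @export
summary.brides <- function(object, ...) {
  print(object)
  print(object$params)
  tot <- sum(object$counts)
  if (tot > 0L) {
    cat("  proportions:",
        paste(sprintf("%s=%.3f", substr(PATH_CLASSES, 1L, 1L),
                      object$counts / tot), collapse = " "), "\n")
  }
  wl <- object$records$d_y_constrained
  wl <- wl[is.finite(wl)]
  if (length(wl)) {
    cat(sprintf("  constrained path lengths: min %g, median %g, max %g\n",
                min(wl), stats::median(wl), max(wl)))
  }
  invisible(object)
}

#' @export
as.data.frame.brides <- function(x, ...) {
  x$records
}

#' Bar plot of the six path-class counts
#'
#' @param x A `brides` object.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.brides <- function(x, ...) {
  args <- list(height = x$counts,
               names.arg = substr(PATH_CLASSES, 1L, 1L),
               ylab = "node pairs",
               main = sprintf("Path types (%s)", x$strategy),
               col = "steelblue")
  extra <- list(...)
  args[names(extra)] <- extra
  invisible(do.call(graphics::barplot, args))
}

#' Write a per-pair classification table
#'
#' Serializes the per-pair records (`i`, `j`, `d_x`, `d_y_constrained`,
#' `label`, `witness`) as a tab-separated table.
#'
#' @param x A `brides` object.
#' @param file Path or connection.
#' @return Invisibly, the records data frame.
#' @export
write_brides <- function(x, file) {
  stopifnot(inherits(x, "brides"))
  utils::write.table(x$records, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x$records)
}
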