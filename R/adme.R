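#' Read a herb-component table
#'
#' Expects a tab-separated table with columns \code{component_id},
#' \code{name}, \code{herb}, \code{ob} (oral bioavailability, percent),
#' \code{dl} (drug-likeness, 0-1 fraction) and optionally
#' \code{manual_keep} (logical). Blank OB/DL cells are parsed as missing
#' (\code{NA}), not zero, so that components lacking ADME annotations fail
#' the screen rather than passing trivially.
#'
#' @param path File path to the TSV.
#' @return A data frame of component records.
#' @export
read_component_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("component_id", "name", "herb", "ob", "dl")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("component table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$ob <- suppressWarnings(as.numeric(df$ob))
  df$dl <- suppressWarnings(as.numeric(df$dl))
  if (!"manual_keep" %in% names(df)) df$manual_keep <- FALSE
  df$manual_keep <- as.logical(df$manual_keep) %in% TRUE
  if (anyDuplicated(df$component_id)) {
    stop("component_id values must be unique within a table")
  }
  if (any(df$ob < 0, na.rm = TRUE) || any(df$dl < 0, na.rm = TRUE)) {
    stop("ob and dl must be non-negative where present")
  }
  df
}

#' Write a component table
#'
#' @param records Data frame as returned by \code{\link{read_component_table}}.
#' @param path Output path.
#' @return Invisibly \code{path}.
#' @export
write_component_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Screen components for bioactivity by OB/DL thresholds
#'
#' Retains components with oral bioavailability \code{ob >= ob_min} AND
#' drug-likeness \code{dl >= dl_min} (both thresholds inclusive). Records
#' with a missing OB or DL fail the filter. Components flagged
#' \code{manual_keep} are retained regardless of their ADME values when
#' \code{keep_manual} is \code{TRUE}; this models curated retention of
#' pharmacologically established constituents that screening thresholds
#' would otherwise discard. Input order is preserved and per-herb retention
#' counts are reported via \code{message}.
#'
#' The default thresholds (OB >= 20\%, DL >= 0.18) are the usual ADME
#' screening criteria for orally administered herbal formulas.
#'
#' @param records Component data frame (see \code{\link{read_component_table}}).
#' @param ob_min Minimum oral bioavailability in percent (default 20).
#' @param dl_min Minimum drug-likeness fraction (default 0.18).
#' @param keep_manual Honour the \code{manual_keep} flag (default TRUE).
#' @param quiet Suppress the per-herb retention message.
#' @return The retained subset of \code{records}, original order.
#' @examples
#' tab <- data.frame(component_id = c("c1", "c2"), name = c("a", "b"),
#'                   herb = "h", ob = c(46.43, 5), dl = c(0.28, 0.05),
#'                   manual_keep = c(FALSE, FALSE))
#' screen_bioactive(tab, quiet = TRUE)
#' @export
screen_bioactive <- function(records, ob_min = 20, dl_min = 0.18,
                             keep_manual = TRUE, quiet = FALSE) {
  if (ob_min < 0 || dl_min < 0) stop("ob_min and dl_min must be non-negative")
  if (nrow(records) == 0L) return(records)
  pass_adme <- !is.na(records$ob) & !is.na(records$dl) &
    records$ob >= ob_min & records$dl >= dl_min
  manual <- if ("manual_keep" %in% names(records)) {
    records$manual_keep %in% TRUE
  } else rep(FALSE, nrow(records))
  keep <- pass_adme | (keep_manual & manual)
  out <- records[keep, , drop = FALSE]
  if (!quiet && nrow(out) > 0L) {
    counts <- table(out$herb)
    message("screen_bioactive: retained ", nrow(out), "/", nrow(records),
            " components (",
            paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  } else if (!quiet) {
    message("screen_bioactive: retained 0/", nrow(records), " components")
  }
  out
}
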