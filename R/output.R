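## Writers for the basic table, detailed table, run report, HTML and GFF3.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

## Minimal HTML table; identifier cells can be hyperlinked through a URL
## template containing %s (one link per comma-separated identifier).
write_html_table <- function(df, path, title = "snpclassify output",
                             url_template = NULL, link_columns = "ID") {
  fmt_cell <- function(value, col) {
    if (is.na(value)) return("NA")
    value <- as.character(value)
    if (!is.null(url_template) && col %in% link_columns && nzchar(value)) {
      ids <- trimws(strsplit(value, ",", fixed = TRUE)[[1L]])
      return(paste(sprintf('<a href="%s">%s</a>',
                           html_escape(sprintf(url_template, ids)),
                           html_escape(ids)), collapse = ", "))
    }
    html_escape(value)
  }
  rows <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(names(df), function(col) {
      paste0("<td>", fmt_cell(df[i, col], col), "</td>")
    }, "")
    paste0("<tr>", paste(cells, collapse = ""), "</tr>")
  }, "")
  writeLines(c(
    "<!DOCTYPE html>", "<html><head>",
    paste0("<title>", html_escape(title), "</title>"),
    "</head><body>", paste0("<h1>", html_escape(title), "</h1>"),
    "<table border=\"1\">",
    paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                          collapse = ""), "</tr>"),
    rows, "</table></body></html>"), path)
  invisible(path)
}

#' Write the basic (one row per variant) table
#'
#' @param basic Basic data frame from [annotate_variants()] /
#'   [run_annotation()].
#' @param path Output path.
#' @param format `"tsv"` (tab-separated, one header line, NA as literal
#'   `NA`) or `"html"`.
#' @param url_template Optional URL template with `%s` for hyperlinking
#'   identifier cells in HTML output.
#' @return The path, invisibly.
#' @export
write_basic <- function(basic, path, format = c("tsv", "html"),
                        url_template = NULL) {
  format <- match.arg(format)
  if (format == "tsv") write_tsv(basic, path)
  else write_html_table(basic, path, "Basic variant annotation",
                        url_template)
  invisible(path)
}

#' Write the detailed (one row per variant and transcript) table
#'
#' @inheritParams write_basic
#' @param detailed Detailed data frame from [annotate_variants()].
#' @export
write_detailed <- function(detailed, path, format = c("tsv", "html"),
                           url_template = NULL) {
  format <- match.arg(format)
  if (format == "tsv") write_tsv(detailed, path)
  else write_html_table(detailed, path, "Detailed variant annotation",
                        url_template)
  invisible(path)
}

#' Write the run report
#'
#' Key figures of a run: variants processed, reference mismatches, counts
#' per functional class, per variant type and per status, and the
#' configuration used (provenance echo).
#'
#' @param report Report list from [run_annotation()] /
#'   [annotate_variants()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  count_block <- function(title, counts) {
    if (length(counts) == 0L) return(character())
    c(paste0(title, ":"),
      sprintf("  %-30s %d", names(counts), as.integer(counts)))
  }
  lines <- c(
    "snpclassify run report",
    "======================",
    sprintf("variations processed: %d", report$n_processed),
    sprintf("reference mismatches: %d", report$n_ref_mismatch),
    sprintf("records skipped (unparseable): %d", report$n_skipped),
    "",
    count_block("functional classes (variants per class)",
                report$class_counts),
    "",
    count_block("variant types", report$type_counts),
    "",
    count_block("status", report$status_counts),
    "",
    "configuration:",
    sprintf("  %s: %s", names(report$config_echo),
            vapply(report$config_echo, function(v)
              paste(as.character(v), collapse = ","), ""))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Export annotated variants as GFF3
#'
#' One feature line per annotated variant, at chromosomal 1-based
#' coordinates, with name, type, functional class, region and status in
#' column 9.  Insertions (zero-length reference) cannot be encoded as
#' zero-width GFF3 spans; they become width-1 features anchored at the
#' insertion point with an `insertion=true` attribute.
#'
#' @param run An `annotation_run` from [run_annotation()], or the basic
#'   data frame from [annotate_variants()].
#' @param path Output path.
#' @export
export_gff <- function(run, path) {
  basic <- if (inherits(run, "annotation_run")) run$basic else run
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(basic))) {
    r <- basic[i, ]
    if (is.na(r$ChromStart)) next
    attrs <- c(sprintf("ID=%s", r$Name),
               sprintf("variant_type=%s", r$Type),
               sprintf("func_class=%s", r$FuncClass),
               sprintf("region=%s", r$Region),
               sprintf("status=%s", r$Status))
    if (!is.na(r$ID) && nzchar(r$ID)) {
      attrs <- c(attrs, sprintf("known_ids=%s", gsub(", ", ",", r$ID)))
    }
    if (isTRUE(r$Type == "INDEL") && r$ChromEnd == r$ChromStart &&
        !is.na(r$Insertion) && r$Insertion) {
      attrs <- c(attrs, "insertion=true")
    }
    attrs <- attrs[!grepl("=NA$", attrs)]
    lines <- c(lines, paste(
      r$Chr, "snpclassify", "sequence_alteration",
      format(r$ChromStart, scientific = FALSE),
      format(max(r$ChromEnd, r$ChromStart), scientific = FALSE),
      ".", ".", ".", paste(attrs, collapse = ";"), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
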