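# Trimming reports and the HTML rendering of a trimming run.

#' Build a trimming report
#'
#' Records, for every column of the alignment it was computed from, the raw and
#' smoothed entropy-like scores, the gap proportion, and the kept/removed
#' partition, together with the parameters that produced it.
#'
#' @param kept Increasing integer vector of selected (kept) column indices.
#' @param m Total number of columns.
#' @param h,h_smooth,g Optional numeric per-column vectors (length `m`): raw
#'   score, smoothed score and gap proportion.
#' @param regions Optional data frame of regions (`start`, `end`, `kind`).
#' @param params Named list of parameters used.
#' @param method Label of the trimming stage (`"entropy"`, `"stationary"`, ...).
#' @return An object of class `trim_report`.
#' @export
trim_report <- function(kept, m, h = NULL, h_smooth = NULL, g = NULL,
                        regions = NULL, params = list(), method = "entropy") {
  kept <- sort(unique(as.integer(kept)))
  if (length(kept) && (kept[1] < 1L || kept[length(kept)] > m))
    stop("kept column indices out of 1..m")
  for (v in list(h = h, h_smooth = h_smooth, g = g))
    if (!is.null(v) && length(v) != m)
      stop("per-column vectors must have length m = ", m)
  structure(list(kept = kept,
                 removed = setdiff(seq_len(m), kept),
                 m = as.integer(m),
                 h = h, h_smooth = h_smooth, g = g,
                 regions = regions, params = params, method = method),
            class = "trim_report")
}

#' @export
print.trim_report <- function(x, ...) {
  cat(sprintf("trim_report (%s): %d of %d columns selected (%.1f%%)\n",
              x$method, length(x$kept), x$m, 100 * length(x$kept) / max(x$m, 1)))
  if (!is.null(x$params) && length(x$params))
    cat("  parameters:",
        paste(names(x$params), unlist(lapply(x$params, format)),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write an HTML trimming report
#'
#' Renders the per-column smoothed entropy-like scores and gap proportions with
#' the selected columns visually distinguished from the removed ones: a colour
#' map of the columns, bar-style score tracks, and a full per-column table.
#'
#' @param aln The [msa] the report was computed from.
#' @param report A [trim_report] covering every column of `aln`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_html_report <- function(aln, report, file) {
  m <- n_col(aln)
  if (report$m != m)
    stop("consistency error: report covers ", report$m,
         " columns but alignment has ", m)
  kept <- logical(m); kept[report$kept] <- TRUE
  h  <- if (is.null(report$h_smooth)) rep(NA_real_, m) else report$h_smooth
  hr <- if (is.null(report$h)) rep(NA_real_, m) else report$h
  g  <- if (is.null(report$g)) rep(NA_real_, m) else report$g

  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.4f", v))
  bar <- function(v, color) {
    w <- ifelse(is.na(v), 0, round(100 * pmin(pmax(v, 0), 1)))
    sprintf("<div class='bar'><span style='width:%d%%;background:%s'></span></div>",
            w, color)
  }
  rows <- sprintf(
    "<tr class='%s'><td>%d</td><td>%s</td><td>%s%s</td><td>%s%s</td><td>%s</td></tr>",
    ifelse(kept, "kept", "removed"), seq_len(m), fmt(hr),
    fmt(h), bar(h, "#4477aa"), fmt(g), bar(g, "#cc6677"),
    ifelse(kept, "selected", "removed"))

  map <- paste0(sprintf("<i class='%s' title='column %d'></i>",
                        ifelse(kept, "k", "r"), seq_len(m)), collapse = "")
  summary_line <- if (length(report$kept) == 0L)
    "Zero characters selected." else
    sprintf("%d of %d characters selected (%.1f%%), %d removed.",
            length(report$kept), m, 100 * length(report$kept) / m,
            length(report$removed))
  params <- if (length(report$params))
    paste(sprintf("<li><code>%s</code> = %s</li>",
                  html_escape(names(report$params)),
                  html_escape(unlist(lapply(report$params, format)))),
          collapse = "\n") else ""

  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Alignment trimming report</title><style>",
    "body{font-family:sans-serif;margin:2em}",
    "table{border-collapse:collapse;font-size:12px}",
    "td,th{border:1px solid #ccc;padding:2px 6px;text-align:right}",
    "tr.kept{background:#eaf3ea} tr.removed{background:#f7e8e8;color:#777}",
    ".bar{display:inline-block;width:80px;height:8px;background:#eee;margin-left:4px}",
    ".bar span{display:block;height:8px}",
    ".map i{display:inline-block;width:2px;height:14px}",
    ".map i.k{background:#2a7} .map i.r{background:#c44}",
    "</style></head><body>",
    sprintf("<h1>Alignment trimming report (%s)</h1>", html_escape(report$method)),
    sprintf("<p>%d %s sequences, %d columns. %s</p>",
            n_seq(aln), html_escape(aln$seq_type), m, summary_line),
    if (nzchar(params)) c("<h2>Parameters</h2><ul>", params, "</ul>") else NULL,
    "<h2>Column map (green = selected, red = removed)</h2>",
    sprintf("<div class='map'>%s</div>", map),
    "<h2>Per-column scores</h2>",
    "<table><tr><th>column</th><th>h</th><th>smoothed h</th>",
    "<th>gap proportion</th><th>status</th></tr>",
    rows,
    "</table></body></html>")
  writeLines(html, file)
  invisible(file)
}
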