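# Semi-automated trait curation: scan a MediaWiki-style XML article dump for
# a regular expression, render the matches as an interactive HTML review page
# with checkboxes, and parse the compiled comma-separated selection.

#' Scan an XML article dump for a regular expression
#'
#' Reads a MediaWiki-export-style XML dump (`page`/`title`/`revision`/`text`
#' elements; namespaces are ignored) and reports every occurrence of
#' `pattern` in any page's text, with a context window of `window` characters
#' on either side (clipped to the text boundaries). Candidate terms for
#' review are taken from wiki-style link markup (`[[target]]` or
#' `[[target|label]]`, using the displayed label) inside the snippet; if the
#' snippet contains no links, capitalized multi-word spans are used instead.
#'
#' @param xml_path Path to the XML dump.
#' @param pattern A valid regular expression, e.g.
#'   `"[Uu]nicell|[Uu]ni-cell|[Ss]ingle-cell"` for unicellular organisms or
#'   `"arasit"` for parasitism.
#' @param window Context half-width in characters (default 300).
#' @return A list of matches in document order, each a list with
#'   `page_title`, `snippet`, `candidate_terms`.
#' @export
scan_articles <- function(xml_path, pattern, window = 300) {
  ok <- tryCatch({
    grepl(pattern, "probe")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_arg("invalid regular expression: ", pattern)
  doc <- tryCatch(xml2::read_xml(xml_path), error = function(e)
    stop("malformed XML dump: ", conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  pages <- xml2::xml_find_all(doc, "//page")
  out <- list()
  for (pg in pages) {
    title <- xml2::xml_text(xml2::xml_find_first(pg, ".//title"))
    txt_node <- xml2::xml_find_first(pg, ".//revision/text")
    if (inherits(txt_node, "xml_missing"))
      txt_node <- xml2::xml_find_first(pg, ".//text")
    if (inherits(txt_node, "xml_missing")) next
    text <- xml2::xml_text(txt_node)
    hits <- gregexpr(pattern, text)[[1]]
    if (hits[1] == -1) next
    lens <- attr(hits, "match.length")
    for (k in seq_along(hits)) {
      lo <- max(1, hits[k] - window)
      hi <- min(nchar(text), hits[k] + lens[k] - 1 + window)
      snippet <- substr(text, lo, hi)
      out[[length(out) + 1L]] <- list(
        page_title = title,
        snippet = snippet,
        candidate_terms = candidate_terms(snippet)
      )
    }
  }
  out
}

candidate_terms <- function(snippet) {
  links <- regmatches(snippet,
                      gregexpr("\\[\\[([^]|]+)(\\|[^]]*)?\\]\\]", snippet))[[1]]
  if (length(links)) {
    inner <- sub("^\\[\\[", "", sub("\\]\\]$", "", links))
    terms <- vapply(strsplit(inner, "\\|"), function(p) p[length(p)], "")
  } else {
    terms <- regmatches(
      snippet,
      gregexpr("[A-Z][a-z]+(?: [A-Z][a-z]+)+", snippet))[[1]]
  }
  unique(trimws2(terms[terms != ""]))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render scan matches as an interactive HTML review page
#'
#' Produces a single self-contained HTML file (no network dependencies): one
#' block per match showing the page title and snippet, a checkbox per
#' candidate term which, when ticked, appends the term to the selection box
#' on the right; a free-text entry field for manual additions; and a compile
#' button that joins all selected and entered terms into one comma-separated
#' list ready for [parse_selection_list()]. The curation step itself is
#' deliberately manual.
#'
#' @param matches List of matches from [scan_articles()] (may be empty; the
#'   page then states that there were zero matches).
#' @param out_path File path for the HTML output.
#' @return `out_path`, invisibly.
#' @export
render_review_html <- function(matches, out_path) {
  blocks <- character(0)
  for (m in matches) {
    boxes <- vapply(m$candidate_terms, function(term) {
      sprintf(
        '<label><input type="checkbox" class="term" value="%s" onchange="refresh()"> %s</label>',
        html_escape(term), html_escape(term))
    }, "")
    blocks <- c(blocks, sprintf(
      '<div class="match"><h3>%s</h3><p class="snippet">%s</p><div class="terms">%s</div></div>',
      html_escape(m$page_title), html_escape(m$snippet),
      paste(boxes, collapse = "\n")))
  }
  body <- if (length(matches)) paste(blocks, collapse = "\n") else
    "<p>Zero matches.</p>"
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>Trait review</title>\n<style>",
    ".match{border-bottom:1px solid #ccc;padding:0.5em;}",
    "#side{position:fixed;top:1em;right:1em;width:22em;}",
    "body{margin-right:24em;font-family:sans-serif;}",
    "</style>\n<script>\n",
    "function refresh(){var sel=[];",
    "document.querySelectorAll('input.term:checked').forEach(",
    "function(b){sel.push(b.value);});",
    "document.getElementById('selected').value=sel.join(', ');}\n",
    "function compile(){var sel=document.getElementById('selected').value;",
    "var man=document.getElementById('manual').value;",
    "var all=(sel+','+man).split(',').map(function(s){return s.trim();})",
    ".filter(function(s){return s.length>0;});",
    "document.getElementById('compiled').value=all.join(', ');}\n",
    "</script></head>\n<body>\n",
    sprintf("<h1>%d match(es)</h1>\n", length(matches)),
    body,
    "\n<div id=\"side\"><h2>Selection</h2>",
    "<textarea id=\"selected\" rows=\"8\" cols=\"40\" readonly></textarea>",
    "<h2>Manual entries</h2>",
    "<textarea id=\"manual\" rows=\"4\" cols=\"40\"></textarea><br>",
    "<button onclick=\"compile()\">Compile comma-separated list</button><br>",
    "<textarea id=\"compiled\" rows=\"8\" cols=\"40\"></textarea></div>\n",
    "</body></html>\n")
  ok <- tryCatch({
    writeLines(html, out_path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_arg("cannot write HTML review page to ", out_path)
  invisible(out_path)
}

#' Parse a compiled comma-separated selection list
#'
#' Splits on commas, trims whitespace, drops empty entries, and removes
#' duplicates while preserving first-occurrence order.
#'
#' @param text A comma-separated string (possibly empty).
#' @return A character vector of taxon/species names.
#' @export
parse_selection_list <- function(text) {
  if (is.null(text) || !nzchar(text)) return(character(0))
  parts <- trimws2(strsplit(text, ",", fixed = TRUE)[[1]])
  unique(parts[parts != ""])
}
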