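#' Read a weighted edge list
#'
#' Parses a plain-text weighted edge list: one edge per line,
#' `node node weight`, separated by `delimiter` (default: any run of
#' whitespace).  Lines that are empty or start with `#` are ignored.
#' Extra trailing fields are ignored.  A line whose weight does not parse, a
#' self-loop, a non-positive weight, or a duplicate of an earlier pair (in
#' either orientation) is an error naming the offending line.
#'
#' @param path file to read.
#' @param delimiter field separator; `NULL` (default) splits on whitespace.
#' @return A [wgraph()].
#' @export
read_edgelist <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) return(wgraph())
  from <- character(length(keep)); to <- character(length(keep))
  w <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- if (is.null(delimiter)) {
      strsplit(trimws(lines[ln]), "\\s+")[[1]]
    } else {
      strsplit(trimws(lines[ln]), delimiter, fixed = TRUE)[[1]]
    }
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop_arg("line ", ln, ": expected at least 3 fields, got ", length(fields))
    }
    wt <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(wt)) stop_arg("line ", ln, ": weight '", fields[3], "' is not a number")
    if (wt <= 0) stop_arg("line ", ln, ": weight must be > 0")
    if (fields[1] == fields[2]) stop_arg("line ", ln, ": self-loop")
    from[i] <- fields[1]; to[i] <- fields[2]; w[i] <- wt
  }
  dup <- duplicated(edge_key(from, to))
  if (any(dup)) {
    stop_arg("line ", keep[which(dup)[1]], ": duplicate edge ",
             from[which(dup)[1]], " -- ", to[which(dup)[1]])
  }
  wgraph(data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE))
}

#' Write a weighted edge list
#'
#' Writes `graph` as `from to weight` lines in deterministic lexicographic
#' order.  Weights are printed with `%.17g` so that
#' `read_edgelist(write_edgelist(g))` round-trips bit-exactly.  Node labels
#' containing whitespace cannot be represented in this format and are
#' rejected; use the Pajek writer (quoted labels) for those.
#'
#' @param graph a [wgraph()].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_edgelist <- function(graph, path) {
  assert_wgraph(graph)
  if (any(grepl("\\s", graph$nodes))) {
    stop_arg("edge-list format cannot represent labels containing whitespace; ",
             "use write_pajek()")
  }
  ed <- graph$edges
  lines <- sprintf("%s %s %.17g", ed$from, ed$to, ed$weight)
  writeLines(lines, path)
  invisible(path)
}

#' Read a Pajek .net file
#'
#' Supports the subset of Pajek used to distribute weighted networks:
#' a `*Vertices n` section with optional quoted labels, followed by `*Edges`
#' and/or `*Arcs` sections of `i j [weight]` lines (1-based vertex indices,
#' weight defaulting to 1).  Arcs are symmetrised; a pair listed in both
#' directions collapses to one undirected edge when the weights agree and is
#' an error otherwise.  A vertex index outside `1..n` is a parse error.
#' Unlabelled vertices get their stringified index as label.
#'
#' @param path file to read.
#' @return A [wgraph()].
#' @export
read_pajek <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("%.*$", "", lines)         # Pajek comments
  section <- ""
  n_declared <- NA_integer_
  labels <- character()
  ef <- integer(); et <- integer(); ew <- numeric(); arc <- logical()
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt)) next
    low <- tolower(txt)
    if (startsWith(low, "*vertices")) {
      n_declared <- suppressWarnings(as.integer(strsplit(txt, "\\s+")[[1]][2]))
      if (is.na(n_declared)) stop_arg("line ", ln, ": bad *Vertices count")
      labels <- as.character(seq_len(n_declared))
      section <- "vertices"
      next
    }
    if (startsWith(low, "*edges")) { section <- "edges"; next }
    if (startsWith(low, "*arcs")) { section <- "arcs"; next }
    if (startsWith(low, "*")) { section <- "skip"; next }
    if (section == "vertices") {
      m <- regmatches(txt, regexec('^(\\d+)\\s*(?:"([^"]*)")?', txt))[[1]]
      idx <- as.integer(m[2])
      if (is.na(idx) || idx < 1 || idx > n_declared) {
        stop_arg("line ", ln, ": vertex index out of declared range")
      }
      if (length(m) >= 3 && nzchar(m[3])) labels[idx] <- m[3]
    } else if (section %in% c("edges", "arcs")) {
      fields <- strsplit(txt, "\\s+")[[1]]
      if (length(fields) < 2) stop_arg("line ", ln, ": expected 'i j [weight]'")
      i <- suppressWarnings(as.integer(fields[1]))
      j <- suppressWarnings(as.integer(fields[2]))
      if (is.na(i) || is.na(j)) stop_arg("line ", ln, ": bad vertex index")
      if (is.na(n_declared)) stop_arg("line ", ln, ": edge before *Vertices")
      if (i < 1 || i > n_declared || j < 1 || j > n_declared) {
        stop_arg("line ", ln, ": vertex index out of declared range")
      }
      if (i == j) stop_arg("line ", ln, ": self-loop")
      wt <- if (length(fields) >= 3) suppressWarnings(as.numeric(fields[3])) else 1.0
      if (is.na(wt)) stop_arg("line ", ln, ": bad weight")
      if (wt <= 0) stop_arg("line ", ln, ": weight must be > 0")
      ef <- c(ef, i); et <- c(et, j); ew <- c(ew, wt)
      arc <- c(arc, section == "arcs")
    }
  }
  if (is.na(n_declared)) stop_arg("no *Vertices section found")
  if (anyDuplicated(labels)) stop_arg("duplicate vertex labels")
  if (length(ef)) {
    key <- edge_key(ef, et)
    first <- !duplicated(key)
    for (d in which(!first)) {
      orig <- match(key[d], key)
      # duplicate-symmetric arcs collapse when the weights agree
      if (arc[d] && arc[orig] && ew[d] == ew[orig]) next
      stop_arg("duplicate edge between vertices ", ef[d], " and ", et[d],
               if (ew[d] != ew[orig]) " with mismatched weights" else "")
    }
    ef <- ef[first]; et <- et[first]; ew <- ew[first]
  }
  wgraph(data.frame(from = labels[ef], to = labels[et], weight = ew,
                    stringsAsFactors = FALSE),
         nodes = labels)
}

#' Write a Pajek .net file
#'
#' Inverse of [read_pajek()]: vertices in sorted label order with quoted
#' labels, edges in the graph's canonical order under `*Edges`.
#'
#' @param graph a [wgraph()].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_pajek <- function(graph, path) {
  assert_wgraph(graph)
  idx <- stats::setNames(seq_along(graph$nodes), graph$nodes)
  out <- c(
    sprintf("*Vertices %d", length(graph$nodes)),
    sprintf('%d "%s"', idx, graph$nodes),
    "*Edges",
    sprintf("%d %d %.17g", idx[graph$edges$from], idx[graph$edges$to],
            graph$edges$weight)
  )
  writeLines(out, path)
  invisible(path)
}
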