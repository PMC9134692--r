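#' Read a hypergraph from an HGR-TSV file
#'
#' The HGR-TSV dialect is UTF-8 text where comment lines start with `#`
#' and each data line is
#' `edge_id<TAB>tail_csv<TAB>head_csv<TAB>weight`,
#' with `tail_csv`/`head_csv` comma-separated vertex ids (no spaces) and
#' `weight` a decimal number >= 0. An optional header comment `# hgr v1`
#' may appear.
#'
#' @param path Path to an HGR-TSV file.
#' @return A [hypergraph()].
#' @seealso [write_hgr()]
#' @export
read_hgr <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  edges <- list()
  seen <- character()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 4L)
      stop(path, ":", i, ": expected 4 tab-separated fields, got ",
           length(parts))
    id <- parts[[1]]
    if (id %in% seen)
      stop(path, ":", i, ": duplicate edge id '", id, "'")
    tail <- strsplit(parts[[2]], ",", fixed = TRUE)[[1]]
    head <- strsplit(parts[[3]], ",", fixed = TRUE)[[1]]
    tail <- tail[nzchar(tail)]
    head <- head[nzchar(head)]
    if (length(tail) == 0L) stop(path, ":", i, ": empty tail set")
    if (length(head) == 0L) stop(path, ":", i, ": empty head set")
    w <- suppressWarnings(as.numeric(parts[[4]]))
    if (is.na(w)) stop(path, ":", i, ": malformed weight '", parts[[4]], "'")
    if (w < 0) stop(path, ":", i, ": negative weight ", w)
    edges[[length(edges) + 1L]] <- hyperedge(id, tail, head, w)
    seen <- c(seen, id)
  }
  hypergraph(edges)
}

#' Write a hypergraph to an HGR-TSV file
#'
#' Output is deterministic: edges are written sorted by id and set
#' members sorted lexicographically, so writing, re-reading and writing
#' again produces byte-identical files.
#'
#' @param g A [hypergraph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_hgr()]
#' @export
write_hgr <- function(g, path) {
  fmt_w <- function(w) format(w, scientific = FALSE, trim = TRUE, digits = 15)
  lines <- c("# hgr v1", vapply(g$edges, function(e) {
    paste(e$id,
          paste(sort(e$tail, method = "radix"), collapse = ","),
          paste(sort(e$head, method = "radix"), collapse = ","),
          fmt_w(e$weight), sep = "\t")
  }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unname(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Serialize a hyperpath to JSON
#'
#' The interchange format is a JSON object
#' `{"edges": [...], "weight": w, "cyclic": b}` where `edges` lists the
#' hyperedge ids in a witness ordering.
#'
#' @param p A `hyperpath` object (as returned by [shortest_hyperpath()]).
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_hyperpath_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "hyperpath"))
  json <- jsonlite::toJSON(
    list(edges = p$edges, weight = jsonlite::unbox(p$weight),
         cyclic = jsonlite::unbox(p$cyclic)),
    digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(as.character(json))
}

#' Read a hyperpath from its JSON interchange format
#'
#' @param path Path to a JSON file written by [write_hyperpath_json()].
#' @return A `hyperpath` object.
#' @export
read_hyperpath_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  new_hyperpath(as.character(x$edges), as.numeric(x$weight),
                as.logical(x$cyclic))
}

new_hyperpath <- function(edges, weight, cyclic) {
  structure(list(edges = as.character(edges), weight = as.numeric(weight),
                 cyclic = isTRUE(cyclic)),
            class = "hyperpath")
}

#' @export
print.hyperpath <- function(x, ...) {
  if (length(x$edges) == 0L) {
    cat("empty hyperpath (no source-sink hyperpath exists)\n")
    return(invisible(x))
  }
  cat(sprintf("s,t-hyperpath: %d edges, weight %g%s\n  [%s]\n",
              length(x$edges), x$weight,
              if (x$cyclic) ", cyclic" else "",
              paste(x$edges, collapse = " -> ")))
  invisible(x)
}

#' Test whether a hyperpath search returned the empty path
#'
#' The heuristic and the enumeration solvers return the empty path (a
#' zero-length `hyperpath` object) when no source-sink hyperpath exists.
#'
#' @param p A `hyperpath` object or `NULL`.
#' @return Logical scalar.
#' @export
is_empty_path <- function(p) {
  is.null(p) || (inherits(p, "hyperpath") && length(p$edges) == 0L)
}

empty_hyperpath <- function() new_hyperpath(character(), 0, FALSE)
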