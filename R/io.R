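## Per-type edge-list files: one link per line as "start<TAB>end".  Blank
## lines and '#' comments are skipped; node names are kept verbatim so
## protein identifiers survive round trips.

#' Read one per-type edge-list file into a graph
#'
#' @param path file with one `start<TAB>end` pair per line.
#' @param type declared type name the edges belong to.
#' @param directed is the type directed?  Must agree with the graph's
#'   registry.
#' @param g a [typed_graph] whose registry declares `type`; modified in
#'   place.
#' @return `g`, invisibly.  Malformed lines (not exactly two tab-separated
#'   fields, or a self-loop) abort with the offending line numbers.
#' @export
read_link_file <- function(path, type, directed, g) {
  stopifnot(inherits(g, "typed_graph"))
  if (!file.exists(path)) stop("cannot read link file: ", path)
  if (!reg_has_type(g$registry, type)) stop("unknown link type '", type, "'")
  if (!identical(directed, reg_is_directed(g$registry, type)))
    stop("type '", type, "' declared ",
         if (directed) "directed" else "undirected",
         " but registered otherwise")
  lines <- readLines(path, warn = FALSE)
  bad <- character(0)
  edges <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L || any(!nzchar(trimws(fields)))) {
      bad <- c(bad, sprintf("line %d: %s", ln, line))
    } else if (identical(trimws(fields[1]), trimws(fields[2]))) {
      bad <- c(bad, sprintf("line %d: self-loop %s", ln, line))
    } else {
      edges[[length(edges) + 1L]] <- trimws(fields)
    }
  }
  if (length(bad) > 0L)
    stop("malformed lines in ", path, ":\n  ",
         paste(utils::head(bad, 10L), collapse = "\n  "))
  for (e in edges) add_link(g, e[1], e[2], type)
  invisible(g)
}

parse_linkfiles_spec <- function(spec) {
  if (is.data.frame(spec)) {
    stopifnot(all(c("type", "directed", "file") %in% names(spec)))
    return(spec)
  }
  tokens <- strsplit(trimws(spec), "[[:space:]]+")[[1]]
  if (length(tokens) == 0L || length(tokens) %% 3L != 0L)
    stop("linkfiles must be triples \"<type> <d|u> <file>\"; got: ", spec)
  mat <- matrix(tokens, ncol = 3L, byrow = TRUE)
  flags <- tolower(mat[, 2L])
  if (any(!flags %in% c("d", "u")))
    stop("directedness flag must be 'd' or 'u'")
  data.frame(type = mat[, 1L], directed = flags == "d", file = mat[, 3L],
             stringsAsFactors = FALSE)
}

#' Read a whole network from per-type edge-list files
#'
#' @param folder directory holding the files.
#' @param linkfiles either a data.frame with columns `type`, `directed`
#'   (logical), `file`, or a single string of space-separated triples in
#'   the form `"A d linksAtype.txt B d linksBtype.txt C u linksCtype.txt"`.
#' @return a [typed_graph].
#' @export
read_network <- function(folder, linkfiles) {
  lf <- parse_linkfiles_spec(linkfiles)
  if (anyDuplicated(lf$type)) stop("link type names must be unique")
  reg <- link_registry(stats::setNames(ifelse(lf$directed, "d", "u"), lf$type))
  g <- typed_graph(reg)
  for (r in seq_len(nrow(lf)))
    read_link_file(file.path(folder, lf$file[r]), lf$type[r], lf$directed[r], g)
  g
}

#' Write a graph back to per-type edge-list files
#'
#' One `links<type>type.txt` file per declared type, in the same format
#' [read_link_file()] reads.  Undirected edges are written once.
#'
#' @param g a [typed_graph].
#' @param dir output directory (created if missing).
#' @return the linkfiles specification string for the files written.
#' @export
write_link_files <- function(g, dir) {
  stopifnot(inherits(g, "typed_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- graph_edges(g)
  spec <- character(0)
  for (t in g$registry$names) {
    fname <- sprintf("links%stype.txt", t)
    sub <- edges[edges$type == t, , drop = FALSE]
    writeLines(if (nrow(sub) > 0L) paste(sub$from, sub$to, sep = "\t") else character(0),
               file.path(dir, fname))
    spec <- c(spec, t, if (reg_is_directed(g$registry, t)) "d" else "u", fname)
  }
  paste(spec, collapse = " ")
}

#' Write found instances in the standard output line format
#'
#' One line per unique instance, nodes in motif order:
#' `Motif [<specification>]: [<node 1>, <node 2>, ...]`, sorted by node
#' tuple so repeated runs are bit-identical.
#'
#' @param instances matrix of instances (one row each, motif order), e.g.
#'   the `instances` field of a `motif_matches` object.
#' @param m a [parse_motif()] result (provides the specification string).
#' @param path output file path; its directory must exist.
#' @return `path`, invisibly.  A run with zero instances writes an empty
#'   file.
#' @export
write_instances <- function(instances, m, path) {
  stopifnot(inherits(m, "motif_spec"))
  if (!dir.exists(dirname(path)))
    stop("output directory does not exist: ", dirname(path))
  if (is.null(instances) || nrow(instances) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  mat <- instances_matrix(lapply(seq_len(nrow(instances)),
                                 function(r) instances[r, ]), ncol(instances))
  lines <- sprintf("Motif [%s]: [%s]", motif_string(m),
                   apply(mat, 1L, paste, collapse = ", "))
  writeLines(lines, path)
  invisible(path)
}
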