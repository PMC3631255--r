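#' Declare the link types of a network
#'
#' A network carries edges of one or more *link types*; each type has a
#' single upper-case letter as its name and is either directed or
#' undirected.  For a directed type `X` the corresponding lower-case letter
#' `x` denotes the reverse orientation (an edge `u -> v` of type `X` is the
#' same object as `v -> u` of type `x`).  Lower-case letters are therefore
#' reserved and cannot be declared as type names themselves.
#'
#' @param types named character vector mapping type names to directedness,
#'   e.g. `c(A = "directed", B = "d", C = "undirected")`.  Values may be
#'   abbreviated to `"d"` / `"u"`.
#' @return an object of class `link_registry`.
#' @examples
#' reg <- link_registry(c(A = "d", B = "d", C = "u"))
#' reg
#' @export
link_registry <- function(types) {
  if (length(types) == 0L || is.null(names(types)) || any(names(types) == ""))
    stop("'types' must be a named character vector, e.g. c(A = \"d\", C = \"u\")")
  nm <- names(types)
  if (any(!grepl("^[A-Z]$", nm)))
    stop("link type names must be single upper-case letters; got: ",
         paste(nm[!grepl("^[A-Z]$", nm)], collapse = ", "))
  if (anyDuplicated(tolower(nm)))
    stop("link type names must be unique (case-insensitively)")
  dir <- vapply(as.character(types), function(v) {
    v <- tolower(v)
    if (v %in% c("d", "directed")) TRUE
    else if (v %in% c("u", "undirected")) FALSE
    else stop("directedness must be \"d\"/\"directed\" or \"u\"/\"undirected\"; got: ", v)
  }, logical(1))
  names(dir) <- nm
  structure(list(names = nm, directed = dir), class = "link_registry")
}

#' @export
print.link_registry <- function(x, ...) {
  cat("Link type registry:\n")
  for (nm in x$names)
    cat(sprintf("  %s  (%s)\n", nm, if (x$directed[[nm]]) "directed" else "undirected"))
  invisible(x)
}

reg_has_type <- function(reg, name) name %in% reg$names

reg_is_directed <- function(reg, name) isTRUE(reg$directed[[name]])

#' Resolve a (possibly reversed) type key
#'
#' Keys are the alphabet of candidate-set queries: `"X"` for the forward
#' orientation of type `X`, `"x"` for its reverse if `X` is directed.  The
#' lower-case key of an *undirected* type is accepted but aliased to the
#' upper-case key with a warning, since direction is meaningless there.
#'
#' @param reg a [link_registry].
#' @param key single-letter character key.
#' @return the normalised key (upper case for undirected types).
#' @keywords internal
resolve_key <- function(reg, key) {
  if (!is.character(key) || length(key) != 1L || !grepl("^[A-Za-z]$", key))
    stop("type key must be a single letter; got: ", deparse(key))
  base <- toupper(key)
  if (!reg_has_type(reg, base))
    stop("unknown link type '", base, "'")
  if (key != base && !reg_is_directed(reg, base)) {
    warning("key '", key, "' refers to undirected type '", base,
            "'; using '", base, "'")
    return(base)
  }
  key
}

#' Reverse of a type key
#'
#' The reverse of `"X"` is `"x"` and vice versa for directed types; the
#' reverse key of an undirected type is the type itself.
#'
#' @inheritParams resolve_key
#' @return the reversed key.
#' @keywords internal
reverse_key <- function(reg, key) {
  key <- resolve_key(reg, key)
  base <- toupper(key)
  if (!reg_is_directed(reg, base)) return(base)
  if (key == base) tolower(key) else base
}

#' All oriented keys of a registry
#' @keywords internal
all_keys <- function(reg) {
  out <- character(0)
  for (nm in reg$names) {
    out <- c(out, nm)
    if (reg_is_directed(reg, nm)) out <- c(out, tolower(nm))
  }
  out
}
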