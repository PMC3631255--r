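## A motif over k ordered nodes is written as a linear string of
## K = k(k-1)/2 pair codes, one per unordered node pair, in the column-wise
## upper-triangle order (1,2),(1,3),(2,3),(1,4),(2,4),(3,4),...  Each code is
## an upper-case type letter (forward link), the lower-case letter (reversed
## directed link) or '0' (no link).  Motifs never contain (anti-)parallel
## links: exactly one code per pair.

pair_index <- function(i, j) {
  # position of unordered pair (i, j), i < j, in the specification string
  (j - 1L) * (j - 2L) %/% 2L + i
}

k_from_length <- function(K) {
  k <- (1 + sqrt(1 + 8 * K)) / 2
  if (abs(k - round(k)) > 1e-9) NA_integer_ else as.integer(round(k))
}

#' Parse a motif specification string
#'
#' @param spec the specification string, e.g. `"ABC"` or `"AAAB000B0A00BAA"`.
#' @param registry a [link_registry] declaring the types used in `spec`.
#' @return an object of class `motif_spec` with fields `k` (node count),
#'   `entries` (length-`k(k-1)/2` code vector in canonical pair order),
#'   `codes` (a `k x k` matrix giving the code oriented from row to column)
#'   and `string` (the input).
#' @examples
#' reg <- link_registry(c(A = "d", B = "d", C = "u"))
#' m <- parse_motif("ABC", reg)
#' link_code_between(m, 2, 1)  # "a": reverse of the stored (1,2) code
#' @export
parse_motif <- function(spec, registry) {
  if (!inherits(registry, "link_registry"))
    stop("'registry' must be a link_registry")
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec))
    stop("motif specification must be a non-empty string")
  entries <- strsplit(spec, "")[[1]]
  K <- length(entries)
  k <- k_from_length(K)
  if (is.na(k) || k < 2L) {
    lo <- 2L; while (lo * (lo - 1L) %/% 2L < K) lo <- lo + 1L
    stop("specification length ", K, " is not a triangular number; ",
         "nearest valid lengths are ", (lo - 1L) * (lo - 2L) %/% 2L,
         " and ", lo * (lo - 1L) %/% 2L)
  }
  for (code in unique(entries)) {
    if (code == "0") next
    if (!grepl("^[A-Za-z]$", code))
      stop("invalid pair code '", code, "' in motif specification")
    base <- toupper(code)
    if (!reg_has_type(registry, base))
      stop("unknown link type '", base, "'")
    if (code != base && !reg_is_directed(registry, base))
      stop("lower-case code '", code, "' is invalid: type '", base,
           "' is undirected")
  }
  codes <- matrix("0", k, k)
  idx <- 0L
  for (j in 2L:k) for (i in 1L:(j - 1L)) {
    idx <- idx + 1L
    code <- entries[idx]
    codes[i, j] <- code
    codes[j, i] <- if (code == "0") "0" else reverse_key(registry, code)
  }
  structure(list(k = k, entries = entries, codes = codes,
                 registry = registry, string = spec),
            class = "motif_spec")
}

#' Oriented pair code between two motif nodes
#'
#' Returns the code read from `i`'s perspective: if the stored code for the
#' pair is a forward `X` from `i` to `j`, querying `(j, i)` yields `"x"`.
#' Undirected codes and `"0"` are orientation-free.
#'
#' @param m a [parse_motif()] result.
#' @param i,j motif node indexes, `1 <= i, j <= k`, `i != j`.
#' @return a single-character code.
#' @export
link_code_between <- function(m, i, j) {
  stopifnot(inherits(m, "motif_spec"))
  if (i == j) stop("motif node pair must be distinct: i = j = ", i)
  if (i < 1L || j < 1L || i > m$k || j > m$k)
    stop("motif node index out of range 1..", m$k)
  m$codes[i, j]
}

#' Serialise a motif back to its specification string
#' @param m a `motif_spec`.
#' @return the specification string.
#' @export
motif_string <- function(m) {
  stopifnot(inherits(m, "motif_spec"))
  paste(m$entries, collapse = "")
}

## non-'0' oriented codes departing motif node i, named by target node
codes_from <- function(m, i) {
  out <- m$codes[i, ]
  names(out) <- as.character(seq_len(m$k))
  out[out != "0"]
}

## all distinct oriented codes occurring anywhere in the motif (both
## orientations of each directed pair code, once each)
motif_type_keys <- function(m) {
  keys <- character(0)
  for (i in seq_len(m$k)) keys <- c(keys, codes_from(m, i))
  unique(unname(keys))
}

## TRUE iff the motif is connected through its non-'0' pairs
motif_connected <- function(m) {
  k <- m$k
  if (k == 1L) return(TRUE)
  seen <- logical(k); seen[1L] <- TRUE; frontier <- 1L
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (i in frontier) for (j in seq_len(k))
      if (!seen[j] && m$codes[i, j] != "0") { seen[j] <- TRUE; nxt <- c(nxt, j) }
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("motif_spec \"%s\": %d nodes, %d links\n",
              x$string, x$k, sum(x$entries != "0")))
  invisible(x)
}
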