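#' @include AllClasses.R
NULL

## Tokens reserved by the selection grammar.
.selKeywords <- c("chain", "resid", "resname", "name", "elem")
.selReserved <- c(.selKeywords, "and", "or", "not", "all", "none", "(", ")")

.tokenizeSelection <- function(expression) {
  expression <- gsub("([()])", " \\1 ", expression)
  tokens <- strsplit(trimws(expression), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

#' Select atoms by expression
#'
#' Expressions combine the primitives \code{chain <ids>},
#' \code{resid <n | a-b | a:b>}, \code{resname <names>}, \code{name <names>},
#' \code{elem <symbols>}, \code{all} and \code{none} with \code{and},
#' \code{or}, \code{not} and parentheses. Keywords are case-insensitive;
#' values are matched case-insensitively against the topology. Resolution is
#' deterministic: indices are returned sorted. Empty selections (e.g. an
#' empty residue range) are valid.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param expression selection string, e.g. \code{"chain A and name CA"}.
#' @return an \linkS4class{AtomSelection}
#' @export
selectAtoms <- function(traj, expression) {
  stopifnot(is(traj, "Trajectory"))
  tokens <- .tokenizeSelection(expression)
  if (length(tokens) == 0)
    stop("selection parse error: empty expression")
  topo <- traj@topology
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L

  peek <- function() {
    if (state$pos > length(state$tokens)) NULL
    else state$tokens[[state$pos]]
  }
  advance <- function() {
    t <- peek(); state$pos <- state$pos + 1L; t
  }
  fail <- function(msg) {
    stop("selection parse error at token ", state$pos, " ('",
         if (is.null(peek())) "<end>" else peek(), "'): ", msg)
  }

  parseValues <- function() {
    vals <- character(0)
    repeat {
      t <- peek()
      if (is.null(t) || tolower(t) %in% .selReserved) break
      vals <- c(vals, advance())
    }
    if (length(vals) == 0) fail("expected one or more values")
    vals
  }

  evalPrimitive <- function() {
    t <- peek()
    if (is.null(t)) fail("expected a primitive")
    kw <- tolower(t)
    if (kw == "(") {
      advance()
      v <- evalOr()
      if (is.null(peek()) || peek() != ")") fail("expected ')'")
      advance()
      return(v)
    }
    if (kw == "all") { advance(); return(rep(TRUE, nrow(topo))) }
    if (kw == "none") { advance(); return(rep(FALSE, nrow(topo))) }
    if (kw == "not") { advance(); return(!evalPrimitive()) }
    if (!kw %in% .selKeywords) fail("unknown keyword")
    advance()
    vals <- parseValues()
    switch(kw,
      chain = toupper(topo$chain) %in% toupper(vals),
      resname = toupper(topo$resid) %in% toupper(vals),
      name = toupper(topo$elety) %in% toupper(vals),
      elem = toupper(topo$elesy) %in% toupper(vals),
      resid = {
        ids <- integer(0)
        for (v in vals) {
          if (grepl("^-?[0-9]+[-:]-?[0-9]+$", v)) {
            sep <- if (grepl(":", v)) ":" else "-"
            parts <- strsplit(v, sep, fixed = TRUE)[[1]]
            a <- as.integer(parts[1]); b <- as.integer(parts[2])
            if (a <= b) ids <- c(ids, a:b)  # empty when a > b
          } else if (grepl("^-?[0-9]+$", v)) {
            ids <- c(ids, as.integer(v))
          } else fail(paste0("bad residue id '", v, "'"))
        }
        topo$resno %in% ids
      })
  }

  evalAnd <- function() {
    v <- evalPrimitive()
    while (!is.null(peek()) && tolower(peek()) == "and") {
      advance()
      v <- v & evalPrimitive()
    }
    v
  }
  evalOr <- function() {
    v <- evalAnd()
    while (!is.null(peek()) && tolower(peek()) == "or") {
      advance()
      v <- v | evalAnd()
    }
    v
  }

  mask <- evalOr()
  if (!is.null(peek())) fail("unexpected trailing token")
  new("AtomSelection", expression = expression,
      indices = which(mask))
}

#' All-atom selection helper
#' @param traj a \linkS4class{Trajectory}
#' @return an \linkS4class{AtomSelection} covering every atom
#' @export
selectAll <- function(traj) selectAtoms(traj, "all")
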