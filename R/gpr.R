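#' Gene-protein-reaction (GPR) rule trees
#'
#' A GPR rule is a boolean expression over gene identifiers that states which
#' gene products a reaction needs: `AND` joins obligate partners (enzyme
#' subunits, complexes), `OR` joins alternatives (isozymes). Rules are stored
#' as trees with node kinds `"AND"`, `"OR"` and `"GENE"`.
#'
#' Grammar: `OR` has lower precedence than `AND`; parentheses override;
#' operator keywords are case-insensitive; a gene token is any run of
#' characters that is not whitespace, `(` or `)`. The empty string denotes an
#' absent GPR and parses to `NULL`.
#'
#' @param text A GPR rule string, e.g. `"(A OR B) AND C"`.
#' @return `parse_gpr()` returns a `gpr` object (or `NULL` for an empty rule);
#'   `gpr_to_string()` its canonical string form; `gpr_genes()` the sorted
#'   unique gene identifiers at the leaves.
#' @examples
#' tree <- parse_gpr("P4 AND P5")
#' gpr_to_string(tree)
#' gpr_genes(parse_gpr("(A OR B) AND C"))
#' @export
parse_gpr <- function(text) {
  if (is.null(text)) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks$type)) {
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 st$toks$at[st$pos], st$toks$text[st$pos]), call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(text) {
  type <- character(0); txt <- character(0); at <- integer(0)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      type <- c(type, ch); txt <- c(txt, ch); at <- c(at, i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()]$", chars[j], perl = TRUE)) j <- j + 1L
    word <- paste0(chars[i:(j - 1L)], collapse = "")
    up <- toupper(word)
    if (up == "AND" || up == "OR") {
      type <- c(type, up); txt <- c(txt, word)
    } else {
      type <- c(type, "GENE"); txt <- c(txt, word)
    }
    at <- c(at, i)
    i <- j
  }
  list(type = type, text = txt, at = at)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks$type)) NA_character_ else st$toks$type[st$pos]
}

gpr_parse_or <- function(st) {
  kids <- list(gpr_parse_and(st))
  while (identical(gpr_peek(st), "OR")) {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_and(st)))
  }
  if (length(kids) == 1L) kids[[1]] else gpr_node("OR", kids)
}

gpr_parse_and <- function(st) {
  kids <- list(gpr_parse_atom(st))
  while (identical(gpr_peek(st), "AND")) {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_atom(st)))
  }
  if (length(kids) == 1L) kids[[1]] else gpr_node("AND", kids)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) {
    stop("GPR parse error at end of rule: operand expected", call. = FALSE)
  }
  if (tk == "(") {
    open_at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) {
      stop(sprintf("GPR parse error: unbalanced '(' at position %d", open_at),
           call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == "GENE") {
    g <- st$toks$text[st$pos]
    st$pos <- st$pos + 1L
    return(gpr_leaf(g))
  }
  stop(sprintf("GPR parse error at position %d: unexpected '%s'",
               st$toks$at[st$pos], st$toks$text[st$pos]), call. = FALSE)
}

gpr_node <- function(kind, children) {
  stopifnot(kind %in% c("AND", "OR"), length(children) >= 2L)
  structure(list(kind = kind, children = children, gene = NULL),
            class = "gpr")
}

gpr_leaf <- function(gene) {
  structure(list(kind = "GENE", children = list(), gene = gene),
            class = "gpr")
}

#' @rdname parse_gpr
#' @param tree A `gpr` object or `NULL`.
#' @export
gpr_to_string <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$kind == "GENE") return(tree$gene)
  parts <- vapply(tree$children, function(ch) {
    s <- gpr_to_string(ch)
    # parenthesize a child OR under AND so precedence survives the round trip
    if (tree$kind == "AND" && ch$kind == "OR") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tolower(tree$kind), " "))
}

#' @rdname parse_gpr
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$kind == "GENE") return(tree$gene)
  sort(unique(unlist(lapply(tree$children, gpr_genes))))
}

#' Evaluate a GPR tree against per-gene values
#'
#' Implements the standard omics-to-reaction mapping rule: a `GENE` leaf takes
#' the gene's measured value, `AND` takes the minimum of its children and `OR`
#' the maximum. Missing genes are handled by `missing_policy`:
#' `"ignore-or"` drops missing children under `OR` (an isozyme with no data
#' does not veto the others) but makes any `AND` with a missing child
#' unresolved; `"strict"` makes any missing leaf unresolved.
#'
#' @param tree A `gpr` object.
#' @param values Named numeric vector of gene values.
#' @param missing_policy `"ignore-or"` (default) or `"strict"`.
#' @return The reaction value, or `NA_real_` if the rule cannot be resolved.
#' @export
eval_gpr <- function(tree, values, missing_policy = c("ignore-or", "strict")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(tree)) return(NA_real_)
  if (tree$kind == "GENE") {
    v <- values[tree$gene]
    if (length(v) == 0L || is.na(v)) return(NA_real_)
    return(unname(v))
  }
  vals <- vapply(tree$children, eval_gpr, numeric(1),
                 values = values, missing_policy = missing_policy)
  if (tree$kind == "AND") {
    if (anyNA(vals)) return(NA_real_)
    return(min(vals))
  }
  # OR
  if (missing_policy == "strict" && anyNA(vals)) return(NA_real_)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  max(vals)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.gpr <- function(x, ...) gpr_to_string(x)
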