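# Independent LP oracle: scipy.optimize.linprog (HiGHS) through the
# pre-installed python. Used only to cross-check the package's own simplex.
lp_oracle <- function(problems) {
  script <- system.file("oracle", "lp_batch.py", package = "gemctx")
  stopifnot(nzchar(script))
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  payload <- lapply(problems, function(p) {
    list(obj = p$obj,
         A = lapply(seq_len(nrow(p$A)), function(i) as.numeric(p$A[i, ])),
         rhs = p$rhs, lb = p$lb,
         ub = ifelse(is.finite(p$ub), p$ub, 1e30),
         maximize = jsonlite::unbox(isTRUE(p$maximize)))
  })
  jsonlite::write_json(payload, inp, digits = NA)
  status <- system2("python", c(script, inp, outp))
  stopifnot(status == 0)
  jsonlite::fromJSON(outp, simplifyDataFrame = FALSE)
}

# independent GPR evaluator: compiles the tree to an R expression string
# with pmin/pmax and evaluates it (a different code path from eval_gpr)
gpr_eval_oracle <- function(tree, values) {
  expr_of <- function(t) {
    if (t$kind == "GENE") {
      v <- values[t$gene]
      if (length(v) == 0L || is.na(v)) return(NA_character_)
      return(format(unname(v), digits = 17))
    }
    kids <- vapply(t$children, expr_of, character(1))
    if (t$kind == "AND") {
      if (anyNA(kids)) return(NA_character_)
      return(paste0("min(", paste(kids, collapse = ","), ")"))
    }
    kids <- kids[!is.na(kids)]
    if (length(kids) == 0L) return(NA_character_)
    paste0("max(", paste(kids, collapse = ","), ")")
  }
  e <- expr_of(tree)
  if (is.na(e)) return(NA_real_)
  eval(parse(text = e))
}

# random GPR tree of bounded depth over a gene pool
random_gpr_tree <- function(genes, depth = 4) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(gemctx:::gpr_leaf(sample(genes, 1)))
  }
  kind <- sample(c("AND", "OR"), 1)
  nkids <- sample(2:3, 1)
  kids <- lapply(seq_len(nkids), function(i) random_gpr_tree(genes, depth - 1))
  gemctx:::gpr_node(kind, kids)
}
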