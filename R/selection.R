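# Atom selection mini-language.
#
# Grammar (case-insensitive keywords, whitespace-separated):
#   expr    := term ('or' term)*
#   term    := factor ('and' factor)*
#   factor  := 'not' factor | '(' expr ')' | primary
#   primary := 'chain' <id> | 'resid' <a>[-<b>] | 'resname' <name>
#            | 'name' <n1>[,<n2>...] | 'backbone' | 'water'
# 'backbone' matches atom names N, CA, C, O; 'water' matches residues
# HOH/WAT/SOL; resid ranges are inclusive.

.SEL_KEYWORDS <- c("chain", "resid", "resname", "name", "backbone", "water",
                   "and", "or", "not", "(", ")")

.sel_tokenize <- function(expression) {
  m <- gregexpr("[()]|[^()[:space:]]+", expression)[[1L]]
  if (m[1L] == -1L) stop("selection parse error: empty expression")
  list(tok = regmatches(expression, gregexpr("[()]|[^()[:space:]]+",
                                             expression))[[1L]],
       pos = as.integer(m))
}

.sel_error <- function(state, msg) {
  pos <- if (state$i <= length(state$pos)) state$pos[state$i] else
    nchar(state$expr) + 1L
  stop(sprintf("selection parse error at position %d: %s", pos, msg),
       call. = FALSE)
}

.sel_peek <- function(state) {
  if (state$i > length(state$tok)) NULL else tolower(state$tok[state$i])
}

.sel_take <- function(state) {
  t <- state$tok[state$i]
  state$i <- state$i + 1L
  list(t, state)
}

.sel_parse_expr <- function(state, atoms) {
  r <- .sel_parse_term(state, atoms); mask <- r[[1L]]; state <- r[[2L]]
  while (identical(.sel_peek(state), "or")) {
    state$i <- state$i + 1L
    r <- .sel_parse_term(state, atoms)
    mask <- mask | r[[1L]]; state <- r[[2L]]
  }
  list(mask, state)
}

.sel_parse_term <- function(state, atoms) {
  r <- .sel_parse_factor(state, atoms); mask <- r[[1L]]; state <- r[[2L]]
  while (identical(.sel_peek(state), "and")) {
    state$i <- state$i + 1L
    r <- .sel_parse_factor(state, atoms)
    mask <- mask & r[[1L]]; state <- r[[2L]]
  }
  list(mask, state)
}

.sel_parse_factor <- function(state, atoms) {
  tk <- .sel_peek(state)
  if (is.null(tk)) .sel_error(state, "unexpected end of expression")
  if (tk == "not") {
    state$i <- state$i + 1L
    r <- .sel_parse_factor(state, atoms)
    return(list(!r[[1L]], r[[2L]]))
  }
  if (tk == "(") {
    state$i <- state$i + 1L
    r <- .sel_parse_expr(state, atoms); state <- r[[2L]]
    if (!identical(.sel_peek(state), ")")) .sel_error(state, "expected ')'")
    state$i <- state$i + 1L
    return(list(r[[1L]], state))
  }
  .sel_parse_primary(state, atoms)
}

.sel_arg <- function(state, what) {
  tk <- .sel_peek(state)
  if (is.null(tk) || tk %in% .SEL_KEYWORDS) {
    .sel_error(state, paste("expected", what))
  }
  val <- state$tok[state$i]
  state$i <- state$i + 1L
  list(val, state)
}

.sel_parse_primary <- function(state, atoms) {
  tk <- .sel_peek(state)
  state$i <- state$i + 1L
  switch(tk,
    backbone = list(atoms$name %in% BACKBONE_NAMES, state),
    water = list(atoms$res_name %in% WATER_RESNAMES, state),
    chain = {
      r <- .sel_arg(state, "a chain id after 'chain'")
      list(atoms$chain_id == r[[1L]], r[[2L]])
    },
    resname = {
      r <- .sel_arg(state, "a residue name after 'resname'")
      list(atoms$res_name == toupper(r[[1L]]), r[[2L]])
    },
    resid = {
      r <- .sel_arg(state, "a residue id or range after 'resid'")
      spec <- r[[1L]]; state <- r[[2L]]
      if (!grepl("^-?[0-9]+(-[0-9]+)?$", spec)) {
        state$i <- state$i - 1L
        .sel_error(state, paste0("invalid resid specifier '", spec, "'"))
      }
      parts <- regmatches(spec, regexec("^(-?[0-9]+)(?:-([0-9]+))?$",
                                        spec))[[1L]]
      lo <- as.integer(parts[2L])
      hi <- if (parts[3L] == "") lo else as.integer(parts[3L])
      list(atoms$res_id >= lo & atoms$res_id <= hi, state)
    },
    name = {
      r <- .sel_arg(state, "one or more atom names after 'name'")
      names_list <- toupper(strsplit(r[[1L]], ",", fixed = TRUE)[[1L]])
      state <- r[[2L]]
      # further bare tokens (not keywords) extend the name list
      while (!is.null(tk2 <- .sel_peek(state)) &&
             !(tk2 %in% .SEL_KEYWORDS)) {
        names_list <- c(names_list,
                        toupper(strsplit(state$tok[state$i], ",",
                                         fixed = TRUE)[[1L]]))
        state$i <- state$i + 1L
      }
      list(toupper(atoms$name) %in% names_list, state)
    },
    {
      state$i <- state$i - 1L
      .sel_error(state, paste0("unexpected token '", state$tok[state$i], "'"))
    }
  )
}

#' Select atoms by expression
#'
#' Evaluates a selection expression against a topology and returns a sorted,
#' unique index set. See the grammar in the package vignette; examples:
#' `"chain L and backbone"`, `"resid 1-2 or resid 19-20"`,
#' `"water and name O"`, `"not water"`.
#'
#' @param topology a [topology()].
#' @param expression selection string.
#' @return An `AtomSelection`: sorted integer vector of atom indices with the
#'   expression kept as an attribute.
#' @export
select_atoms <- function(topology, expression) {
  stopifnot(inherits(topology, "Topology"), is.character(expression),
            length(expression) == 1L)
  tk <- .sel_tokenize(expression)
  state <- list(tok = tk$tok, pos = tk$pos, i = 1L, expr = expression)
  r <- .sel_parse_expr(state, topology$atoms)
  state <- r[[2L]]
  if (state$i <= length(state$tok)) {
    .sel_error(state, paste0("unexpected trailing token '",
                             state$tok[state$i], "'"))
  }
  atom_selection(which(r[[1L]]), expression = expression)
}

#' Construct an AtomSelection from indices
#'
#' @param indices integer atom indices (1-based); duplicates removed, sorted.
#' @param expression optional originating expression, kept as an attribute.
#' @return An `AtomSelection` integer vector.
#' @export
atom_selection <- function(indices, expression = NULL) {
  idx <- sort(unique(as.integer(indices)))
  if (length(idx) && idx[1L] < 1L) stop("selection indices must be >= 1")
  structure(idx, class = "AtomSelection", expression = expression)
}

#' @export
print.AtomSelection <- function(x, ...) {
  expr <- attr(x, "expression")
  cat(sprintf("AtomSelection: %d atoms%s\n", length(x),
              if (is.null(expr)) "" else paste0(" ('", expr, "')")))
  invisible(x)
}
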