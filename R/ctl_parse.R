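# CTL grammar
#
#   formula  := or_expr ( '->' formula )?          implication, right-assoc
#   or_expr  := and_expr ( '|' and_expr )*
#   and_expr := unary ( ('&' | ',') unary )*       comma == conjunction
#   unary    := '!' unary
#             | ('EX'|'AX'|'EF'|'AF'|'EG'|'AG'|'X') unary
#             | ('E'|'A') '[' formula 'U' formula ']'
#             | '(' formula ')'
#             | 'TRUE' | 'FALSE'
#             | name '=' integer
#
# Commas are accepted as conjunction because published observations write
# AG(OGT=1,OGA=0,...); a bare X is read as AX. Precedence: ! > & > | > ->.

.ctl_tokenize <- function(text) {
  pats <- c(IDENT = "^[A-Za-z_][A-Za-z0-9_.]*", INT = "^[0-9]+",
            IMPLIES = "^->", AND = "^&&?", OR = "^\\|\\|?", NOT = "^!",
            EQ = "^=", COMMA = "^,", LPAREN = "^\\(", RPAREN = "^\\)",
            LBRACK = "^\\[", RBRACK = "^\\]")
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^[[:space:]]+", rest))
    if (length(ws)) {
      pos <- pos + nchar(ws)
      next
    }
    hit <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[ty]], rest))
      if (length(m)) {
        tokens[[length(tokens) + 1L]] <- list(type = ty, value = m, pos = pos)
        pos <- pos + nchar(m)
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      stop("CTL syntax error at position ", pos, ": unexpected character \"",
           substr(text, pos, pos), "\"", call. = FALSE)
    }
  }
  tokens[[length(tokens) + 1L]] <- list(type = "EOF", value = "", pos = n + 1L)
  tokens
}

#' Parse a CTL formula
#'
#' Parses a Computation Tree Logic observation into an abstract syntax tree
#' and validates every atom `entity = level` against the network's declared
#' entities and level ranges. Atoms, boolean connectives (`!`, `&` or `,`,
#' `|`, `->`), the unary temporal operators `EX AX EF AF EG AG`, and the
#' until forms `E[p U q]`, `A[p U q]` are supported.
#'
#' @param text formula source string.
#' @param network a [brn_network()] object used to validate atoms.
#' @return An object of class `ctl_formula` (a nested list of operator
#'   nodes), with the source text attached.
#' @examples
#' net <- pseudomonas_model()$network
#' parse_ctl("(x=0 & y=0) -> AG(!(x=2))", net)
#' @export
parse_ctl <- function(text, network) {
  stopifnot(inherits(network, "brn"))
  tokens <- .ctl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$i <- 1L

  peek <- function() st$tokens[[st$i]]
  advance <- function() {
    tok <- st$tokens[[st$i]]
    st$i <- st$i + 1L
    tok
  }
  expect <- function(type, what) {
    tok <- peek()
    if (tok$type != type) {
      stop("CTL syntax error at position ", tok$pos, ": expected ", what,
           if (tok$type == "EOF") " but reached end of formula"
           else paste0(" before \"", tok$value, "\""), call. = FALSE)
    }
    advance()
  }

  unary_ops <- c(EX = "EX", AX = "AX", EF = "EF", AF = "AF",
                 EG = "EG", AG = "AG", X = "AX")

  parse_formula <- function() {
    lhs <- parse_or()
    if (peek()$type == "IMPLIES") {
      advance()
      list(op = "implies", a = lhs, b = parse_formula())
    } else lhs
  }
  parse_or <- function() {
    lhs <- parse_and()
    while (peek()$type == "OR") {
      advance()
      lhs <- list(op = "or", a = lhs, b = parse_and())
    }
    lhs
  }
  parse_and <- function() {
    lhs <- parse_unary()
    while (peek()$type %in% c("AND", "COMMA")) {
      advance()
      lhs <- list(op = "and", a = lhs, b = parse_unary())
    }
    lhs
  }
  parse_unary <- function() {
    tok <- peek()
    if (tok$type == "NOT") {
      advance()
      return(list(op = "not", a = parse_unary()))
    }
    if (tok$type == "LPAREN") {
      advance()
      inner <- parse_formula()
      expect("RPAREN", "\")\"")
      return(inner)
    }
    if (tok$type == "IDENT") {
      if (tok$value %in% names(unary_ops)) {
        advance()
        return(list(op = unname(unary_ops[tok$value]), a = parse_unary()))
      }
      if (tok$value %in% c("E", "A")) {
        advance()
        expect("LBRACK", "\"[\"")
        a <- parse_formula()
        u <- expect("IDENT", "\"U\"")
        if (u$value != "U") {
          stop("CTL syntax error at position ", u$pos,
               ": expected \"U\" in until form", call. = FALSE)
        }
        b <- parse_formula()
        expect("RBRACK", "\"]\"")
        return(list(op = if (tok$value == "E") "EU" else "AU", a = a, b = b))
      }
      if (tok$value %in% c("TRUE", "FALSE")) {
        advance()
        return(list(op = tolower(tok$value)))
      }
      advance()
      expect("EQ", "\"=\" after entity name")
      lv <- expect("INT", "a level")
      i <- match(tok$value, network$entities$name)
      if (is.na(i)) {
        stop("CTL error at position ", tok$pos, ": unknown entity \"",
             tok$value, "\"", call. = FALSE)
      }
      level <- as.integer(lv$value)
      if (level > network$entities$max_level[i]) {
        stop("CTL error at position ", lv$pos, ": level ", level,
             " outside the declared range 0..",
             network$entities$max_level[i], " of ", tok$value, call. = FALSE)
      }
      return(list(op = "atom", entity = tok$value, level = level))
    }
    stop("CTL syntax error at position ", tok$pos, ": unexpected ",
         if (tok$type == "EOF") "end of formula" else paste0("\"", tok$value, "\""),
         call. = FALSE)
  }

  ast <- parse_formula()
  eof <- peek()
  if (eof$type != "EOF") {
    stop("CTL syntax error at position ", eof$pos, ": unexpected \"",
         eof$value, "\" after complete formula", call. = FALSE)
  }
  structure(ast, class = "ctl_formula", source = text)
}

#' Render a CTL syntax tree back to text
#' @param formula a [parse_ctl()] object (or internal node).
#' @return A single string.
#' @export
format_ctl <- function(formula) {
  node <- formula
  switch(node$op,
    true = "TRUE",
    false = "FALSE",
    atom = paste0(node$entity, "=", node$level),
    not = paste0("!", .fmt_child(node$a)),
    and = paste0(.fmt_child(node$a), " & ", .fmt_child(node$b)),
    or = paste0(.fmt_child(node$a), " | ", .fmt_child(node$b)),
    implies = paste0(.fmt_child(node$a), " -> ", .fmt_child(node$b)),
    EU = paste0("E[", format_ctl(node$a), " U ", format_ctl(node$b), "]"),
    AU = paste0("A[", format_ctl(node$a), " U ", format_ctl(node$b), "]"),
    paste0(node$op, " ", .fmt_child(node$a)))
}

.fmt_child <- function(node) {
  if (node$op %in% c("true", "false", "atom", "EU", "AU")) format_ctl(node)
  else paste0("(", format_ctl(node), ")")
}

#' @export
print.ctl_formula <- function(x, ...) {
  cat("CTL formula: ", format_ctl(x), "\n", sep = "")
  invisible(x)
}
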