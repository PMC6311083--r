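# Four-section model format (SMBioNet-style):
#
#   VAR    entity declarations        name = 0..max ;
#   REG    interactions               source [tau] -> sign target ;
#   PARA   optional K restrictions    K_entity:{r1,r2} = 0..1 ;   or  = 0 ;
#   CTL    observations               one ;-terminated CTL formula per entry
#
# '#' starts a comment; section keywords stand alone on a line; statements
# may span lines and are ';'-terminated. Section order is fixed
# VAR, REG, [PARA], CTL. Every parse error carries a line number and the
# section name.

.SECTION_NAMES <- c("VAR", "REG", "PARA", "CTL")

# split raw lines into sections, then each section into ;-terminated
# statements with the line number where each begins
.split_sections <- function(lines) {
  code <- sub("#.*$", "", lines)
  hdr <- match(trimws(code), .SECTION_NAMES)
  hpos <- which(!is.na(hdr))
  if (!length(hpos) || any(nzchar(trimws(code[seq_len(hpos[1L] - 1L)])))) {
    stop("line ", if (length(hpos)) 1L else 1L,
         ": expected a VAR section header first", call. = FALSE)
  }
  found <- .SECTION_NAMES[hdr[hpos]]
  if (anyDuplicated(found)) {
    stop("duplicate section ", found[duplicated(found)][1L], call. = FALSE)
  }
  if (is.unsorted(match(found, .SECTION_NAMES))) {
    stop("sections must appear in the order VAR, REG, PARA, CTL (got ",
         paste(found, collapse = ", "), ")", call. = FALSE)
  }
  for (need in c("VAR", "REG", "CTL")) {
    if (!need %in% found) {
      stop("missing required section ", need, call. = FALSE)
    }
  }
  sections <- list()
  bounds <- c(hpos, length(code) + 1L)
  for (k in seq_along(hpos)) {
    span <- seq(bounds[k] + 1L, length.out = bounds[k + 1L] - bounds[k] - 1L)
    sections[[found[k]]] <- .split_statements(code[span], span)
  }
  sections
}

.split_statements <- function(code, line_numbers) {
  out <- list()
  buf <- character()
  buf_line <- NA_integer_
  for (j in seq_along(code)) {
    txt <- code[j]
    if (!nzchar(trimws(txt)) && !length(buf)) next
    if (!length(buf)) buf_line <- line_numbers[j]
    while (grepl(";", txt, fixed = TRUE)) {
      cut <- regexpr(";", txt, fixed = TRUE)
      stmt <- trimws(paste(c(buf, substr(txt, 1L, cut - 1L)), collapse = " "))
      if (nzchar(stmt)) {
        out[[length(out) + 1L]] <- list(text = stmt, line = buf_line)
      }
      txt <- substr(txt, cut + 1L, nchar(txt))
      buf <- character()
      buf_line <- line_numbers[j]
    }
    if (nzchar(trimws(txt))) buf <- c(buf, txt)
  }
  if (length(buf)) {
    stop("line ", buf_line, ": statement not terminated by \";\": \"",
         trimws(paste(buf, collapse = " ")), "\"", call. = FALSE)
  }
  out
}

.stmt_stop <- function(section, stmt, ...) {
  stop("section ", section, ", line ", stmt$line, ": ", ..., call. = FALSE)
}

#' Read a four-section model file
#'
#' Parses the VAR/REG/PARA/CTL model format into a validated network,
#' PARA restrictions and parsed CTL observations. See the package format
#' notes: `VAR` entries `name = 0..max ;`, `REG` entries
#' `source [tau] -> sign target ;` with sign `+` or `-`, optional `PARA`
#' entries `K_entity:{r1,r2} = v ;` (single value, `lo..hi` range or comma
#' list; `{}` for the empty resource set), and `;`-terminated CTL formulas.
#' `#` comments anywhere.
#'
#' @param file path to a model file (ignored when `text` is given).
#' @param text model source as a character vector of lines or a single
#'   string with newlines.
#' @param name model name; defaults to the file name.
#' @param compat best-effort mode for externally produced files: statements
#'   that do not match the grammar are collected (with line numbers) into the
#'   `unrecognized` field and reported as a warning instead of an error.
#' @return An object of class `brn_model_document`: list with `network`,
#'   `para` (named list of allowed-value restrictions), `formulas` (parsed),
#'   `formula_sources` and `unrecognized`.
#' @examples
#' doc <- parse_model_file(system.file("extdata", "pseudomonas.smb",
#'                                     package = "brnest"))
#' doc$network
#' @export
parse_model_file <- function(file = NULL, text = NULL, name = NULL,
                             compat = FALSE) {
  if (is.null(text)) {
    if (is.null(file)) stop("give either `file` or `text`", call. = FALSE)
    text <- readLines(file, warn = FALSE)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(file))
  }
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  if (is.null(name)) name <- "model"
  sections <- .split_sections(text)
  unrecognized <- list()
  note_bad <- function(section, stmt, msg) {
    if (!compat) .stmt_stop(section, stmt, msg)
    unrecognized[[length(unrecognized) + 1L]] <<-
      list(section = section, line = stmt$line, text = stmt$text, reason = msg)
  }

  # VAR ------------------------------------------------------------------
  ent_names <- character()
  ent_max <- integer()
  for (stmt in sections$VAR) {
    m <- regmatches(stmt$text,
                    regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*([0-9]+)\\s*\\.\\.\\s*([0-9]+)$",
                            stmt$text))[[1L]]
    if (length(m) != 4L) {
      note_bad("VAR", stmt,
               paste0("expected `name = 0..max` but got \"", stmt$text, "\""))
      next
    }
    if (as.integer(m[3L]) != 0L) {
      .stmt_stop("VAR", stmt, "level ranges must start at 0")
    }
    if (m[2L] %in% ent_names) {
      .stmt_stop("VAR", stmt, "duplicate entity ", m[2L])
    }
    ent_names <- c(ent_names, m[2L])
    ent_max <- c(ent_max, as.integer(m[4L]))
  }
  if (!length(ent_names)) stop("VAR section declares no entities", call. = FALSE)

  # REG ------------------------------------------------------------------
  reg <- data.frame(source = character(), target = character(),
                    threshold = integer(), sign = character())
  for (stmt in sections$REG) {
    m <- regmatches(stmt$text,
                    regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*\\[\\s*([0-9]+)\\s*\\]\\s*->\\s*([+-])\\s*([A-Za-z_][A-Za-z0-9_.]*)$",
                            stmt$text))[[1L]]
    if (length(m) != 5L) {
      note_bad("REG", stmt,
               paste0("expected `source [tau] -> sign target` but got \"",
                      stmt$text, "\""))
      next
    }
    for (who in c(m[2L], m[5L])) {
      if (!who %in% ent_names) {
        .stmt_stop("REG", stmt, "undeclared entity ", who)
      }
    }
    tau <- as.integer(m[3L])
    if (tau < 1L || tau > ent_max[match(m[2L], ent_names)]) {
      .stmt_stop("REG", stmt, "threshold ", tau, " outside 1..",
                 ent_max[match(m[2L], ent_names)], " (max level of ", m[2L], ")")
    }
    reg <- rbind(reg, data.frame(source = m[2L], target = m[5L],
                                 threshold = tau, sign = m[4L]))
  }
  network <- withCallingHandlers(
    brn_network(data.frame(name = ent_names, max_level = ent_max), reg,
                name = name),
    warning = function(w) {
      if (compat) invokeRestart("muffleWarning")
    })

  # PARA -----------------------------------------------------------------
  para <- list()
  for (stmt in if (is.null(sections$PARA)) list() else sections$PARA) {
    m <- regmatches(stmt$text,
                    regexec("^(K_?[A-Za-z_][A-Za-z0-9_.]*\\s*:?\\s*\\{[^{}]*\\})\\s*=\\s*(.+)$",
                            stmt$text))[[1L]]
    if (length(m) != 3L) {
      note_bad("PARA", stmt,
               paste0("expected `K_entity:{r1,r2} = values` but got \"",
                      stmt$text, "\""))
      next
    }
    vals <- trimws(m[3L])
    rng <- regmatches(vals, regexec("^([0-9]+)\\s*\\.\\.\\s*([0-9]+)$", vals))[[1L]]
    values <- if (length(rng) == 3L) {
      as.integer(rng[2L]):as.integer(rng[3L])
    } else {
      parts <- trimws(strsplit(vals, ",", fixed = TRUE)[[1L]])
      if (!all(grepl("^[0-9]+$", parts))) {
        .stmt_stop("PARA", stmt, "allowed values must be `v`, `lo..hi` or ",
                   "a comma list of levels, got \"", vals, "\"")
      }
      as.integer(parts)
    }
    key <- tryCatch(.canon_slot_key(network, m[2L]),
                    error = function(e) .stmt_stop("PARA", stmt, conditionMessage(e)))
    para[[key]] <- values
  }
  if (length(para)) parameter_slots(network, para)  # validate ranges

  # CTL ------------------------------------------------------------------
  formula_sources <- character()
  formulas <- list()
  for (stmt in sections$CTL) {
    f <- tryCatch(parse_ctl(stmt$text, network), error = function(e) e)
    if (inherits(f, "error")) {
      note_bad("CTL", stmt, conditionMessage(f))
      next
    }
    formula_sources <- c(formula_sources, stmt$text)
    formulas[[length(formulas) + 1L]] <- f
  }
  if (!compat && !length(formulas)) {
    stop("CTL section contains no formulas", call. = FALSE)
  }

  if (length(unrecognized)) {
    warning("unrecognized directives in compatibility mode:\n",
            paste0("  section ", vapply(unrecognized, `[[`, "", "section"),
                   ", line ", vapply(unrecognized, `[[`, 1L, "line"), ": ",
                   vapply(unrecognized, `[[`, "", "text"), collapse = "\n"),
            call. = FALSE)
  }
  structure(list(network = network, para = para, formulas = formulas,
                 formula_sources = formula_sources,
                 unrecognized = unrecognized),
            class = "brn_model_document")
}

#' @export
print.brn_model_document <- function(x, ...) {
  print(x$network)
  if (length(x$para)) {
    cat("PARA restrictions:\n")
    for (k in names(x$para)) {
      cat("  ", k, " in {", paste(x$para[[k]], collapse = ","), "}\n", sep = "")
    }
  }
  cat("observations:\n")
  cat(paste0("  ", x$formula_sources), sep = "\n")
  invisible(x)
}

#' Serialize a model document back to the four-section format
#'
#' @param document a [parse_model_file()] object (or a list with `network`,
#'   `para`, `formula_sources`).
#' @param file optional path to write to.
#' @return The lines, invisibly when `file` is given.
#' @export
write_model_file <- function(document, file = NULL) {
  net <- document$network
  lines <- c(
    "VAR",
    paste0(net$entities$name, " = 0..", net$entities$max_level, " ;"),
    "REG",
    if (nrow(net$interactions)) {
      paste0(net$interactions$source, " [", net$interactions$threshold,
             "] -> ", net$interactions$sign, " ", net$interactions$target, " ;")
    },
    if (length(document$para)) c(
      "PARA",
      paste0(names(document$para), " = ",
             vapply(document$para, paste, "", collapse = ","), " ;")),
    "CTL",
    paste0(document$formula_sources, " ;"))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Write an estimation result file
#'
#' Produces the single output file of the master/worker run: a header
#' (model name, parameter-space size, accepted count) followed by one block
#' per accepted model listing every K value in canonical slot order.
#'
#' @param result a [brn_estimate()] fit (must carry its slot table).
#' @param file optional path to write to.
#' @return The lines, invisibly when `file` is given.
#' @export
write_results <- function(result, file = NULL) {
  stopifnot(inherits(result, "brn_estimate"))
  if (is.null(result$slots) || is.null(result$network)) {
    stop("result carries no slot table; estimate with brn_estimate()",
         call. = FALSE)
  }
  lines <- c(
    paste0("model: ", result$network$name),
    paste0("parameter_space: ", format(attr(result$slots, "total"),
                                       scientific = FALSE)),
    paste0("accepted: ", length(result$accepted_indices)))
  for (r in seq_along(result$accepted)) {
    lines <- c(lines,
               paste0("MODEL ", format(result$accepted_indices[r],
                                       scientific = FALSE)),
               format_parametrization(result$accepted[[r]], result$network))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read an estimation result file back
#'
#' @param network the network the results belong to.
#' @param file path to a [write_results()] file (ignored when `text` given).
#' @param text the file content as lines.
#' @return List with `model`, `parameter_space`, `indices` (numeric) and
#'   `parametrizations` (list of `brn_parametrization`).
#' @export
read_results <- function(network, file = NULL, text = NULL) {
  stopifnot(inherits(network, "brn"))
  if (is.null(text)) text <- readLines(file, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ": "), text, value = TRUE)
    if (!length(hit)) stop("result file lacks `", key, ":` header", call. = FALSE)
    sub(paste0("^", key, ": "), "", hit[1L])
  }
  starts <- grep("^MODEL ", text)
  bounds <- c(starts, length(text) + 1L)
  indices <- numeric()
  params <- list()
  for (k in seq_along(starts)) {
    indices <- c(indices, as.numeric(sub("^MODEL ", "", text[starts[k]])))
    block <- text[seq(starts[k] + 1L, length.out = bounds[k + 1L] - starts[k] - 1L)]
    block <- block[nzchar(trimws(block))]
    kv <- regmatches(block, regexec("^(K_[^=]+?)\\s*=\\s*([0-9]+)$", block))
    vals <- lapply(kv, function(m) {
      if (length(m) != 3L) stop("malformed K line in result file", call. = FALSE)
      stats::setNames(as.integer(m[3L]), m[2L])
    })
    params[[k]] <- as_parametrization(network, as.list(unlist(vals)))
  }
  list(model = get_field("model"),
       parameter_space = as.numeric(get_field("parameter_space")),
       accepted = as.integer(get_field("accepted")),
       indices = indices, parametrizations = params)
}

#' Export a state graph as DOT or GraphML text
#'
#' Nodes are labeled with comma-separated level tuples in entity declaration
#' order (the `(1,0,1,...)` notation); stable states carry a `deadlock`
#' attribute. Node and edge order follow the deterministic state-row order.
#'
#' @param graph a [build_state_graph()] object.
#' @param format `"dot"` or `"graphml"`.
#' @param file optional path to write to.
#' @return The text as a character vector of lines, invisibly when `file`
#'   is given.
#' @export
export_state_graph <- function(graph, format = c("dot", "graphml"),
                               file = NULL) {
  stopifnot(inherits(graph, "brn_state_graph"))
  format <- match.arg(tolower(format[1L]), c("dot", "graphml"))
  lab <- apply(graph$levels, 1L, paste, collapse = ",")
  dead <- seq_len(graph$n_states) %in% graph$deadlocks
  lines <- if (format == "dot") {
    c("digraph stategraph {",
      "  node [shape=ellipse];",
      paste0("  \"", lab, "\" [deadlock=", ifelse(dead, "true", "false"),
             ifelse(dead, ", shape=doublecircle", ""), "];"),
      if (length(graph$from)) {
        paste0("  \"", lab[graph$from], "\" -> \"", lab[graph$to], "\";")
      },
      "}")
  } else {
    c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
      "  <key id=\"deadlock\" for=\"node\" attr.name=\"deadlock\" attr.type=\"boolean\"/>",
      "  <graph id=\"stategraph\" edgedefault=\"directed\">",
      paste0("    <node id=\"n", seq_len(graph$n_states), "\">",
             "<data key=\"label\">", lab, "</data>",
             "<data key=\"deadlock\">", ifelse(dead, "true", "false"),
             "</data></node>"),
      if (length(graph$from)) {
        paste0("    <edge source=\"n", format(graph$from, trim = TRUE,
                                              scientific = FALSE),
               "\" target=\"n", format(graph$to, trim = TRUE,
                                       scientific = FALSE), "\"/>")
      },
      "  </graph>",
      "</graphml>")
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
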