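#' Parse a plain-text power-law model
#'
#' Reads the package's PLAS-like dialect: one statement per line (or separated
#' by `;`), `#` starts a comment. Statements:
#' \itemize{
#'   \item Equations: `X1' = 2 X2^0.5 - 1 X1^1`. Each signed term is a rate
#'     constant followed by a juxtaposed product of `name^order` factors
#'     (`^1` may be omitted); an optional `{flux_id}` names the physical flux.
#'   \item Assignments: `X2 = 4` declare a variable's basal value. A name with
#'     an equation is dependent, otherwise independent.
#'   \item Directives: `!unit X1 uM`, `!desc X1 text...` attach metadata.
#' }
#'
#' @param text character: model source (lines or a single string), or use
#'   `file`.
#' @param file path to a model file (used when `text` is missing).
#' @return a [gma_model()].
#' @seealso [write_plas()] for the inverse; round-tripping a model through
#'   write/parse yields an equal model.
#' @export
parse_plas <- function(text, file = NULL) {
  if (missing(text)) text <- readLines(file, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  stmts <- unlist(strsplit(lines, ";", fixed = TRUE))
  lineno <- rep(seq_along(lines), vapply(strsplit(lines, ";", fixed = TRUE),
                                         length, 1L))
  stmts_raw <- stmts
  stmts <- trimws(stmts)
  keep <- nzchar(stmts)
  stmts <- stmts[keep]; lineno <- lineno[keep]

  name_re <- "[A-Za-z][A-Za-z0-9_.]*"
  equations <- list(); values <- c(); units <- c(); descs <- c()
  eq_line <- c()

  for (i in seq_along(stmts)) {
    st <- stmts[i]; ln <- lineno[i]
    if (grepl("^!unit\\s", st)) {
      p <- strsplit(sub("^!unit\\s+", "", st), "\\s+")[[1]]
      units[p[1]] <- paste(p[-1], collapse = " ")
    } else if (grepl("^!desc\\s", st)) {
      p <- sub("^!desc\\s+", "", st)
      nm <- sub("\\s.*$", "", p)
      descs[nm] <- trimws(sub(paste0("^", nm), "", p))
    } else if (grepl(paste0("^(", name_re, ")'\\s*="), st)) {
      nm <- sub("'.*$", "", st)
      if (nm %in% names(equations))
        stop("line ", ln, ": duplicate equation for ", nm, call. = FALSE)
      rhs <- sub("^[^=]*=", "", st)
      equations[[nm]] <- parse_plas_terms(rhs, ln)
      eq_line[nm] <- ln
    } else if (grepl(paste0("^(", name_re, ")\\s*="), st)) {
      nm <- trimws(sub("=.*$", "", st))
      val <- suppressWarnings(as.numeric(trimws(sub("^[^=]*=", "", st))))
      if (is.na(val)) stop("line ", ln, ": bad numeric assignment for ", nm,
                           call. = FALSE)
      values[nm] <- val
    } else {
      stop("line ", ln, ": cannot parse statement: ", st, call. = FALSE)
    }
  }

  referenced <- unique(c(names(equations),
                         unlist(lapply(equations, function(tl)
                           unlist(lapply(tl, function(tm) names(tm$factors)))))))
  undeclared <- setdiff(referenced, names(values))
  if (length(undeclared))
    stop("undeclared variable(s) (referenced but never assigned a value): ",
         paste(sort(undeclared), collapse = ", "), call. = FALSE)

  nms <- names(values)
  vars <- variable_spec(
    name = nms,
    role = ifelse(nms %in% names(equations), "dependent", "independent"),
    value = unname(values),
    unit = ifelse(is.na(units[nms]), "", units[nms]),
    description = ifelse(is.na(descs[nms]), "", descs[nms]))
  gma_model(vars, equations)
}

# Internal: scan the right-hand side of one equation into a term list.
parse_plas_terms <- function(rhs, ln = NA) {
  num_re <- "(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?"
  name_re <- "[A-Za-z][A-Za-z0-9_.]*"
  s <- trimws(rhs)
  terms <- list(); first <- TRUE
  while (nzchar(s)) {
    sign <- 1L
    if (grepl("^[+-]", s)) {
      if (substr(s, 1, 1) == "-") sign <- -1L
      s <- trimws(substr(s, 2, nchar(s)))
    } else if (!first) {
      stop("line ", ln, ": expected '+' or '-' before: ", s, call. = FALSE)
    }
    m <- regmatches(s, regexpr(paste0("^", num_re), s))
    if (!length(m)) stop("line ", ln, ": expected a rate constant at: ", s,
                         call. = FALSE)
    gamma <- as.numeric(m)
    s <- trimws(substr(s, nchar(m) + 1L, nchar(s)))
    factors <- numeric(0)
    repeat {
      fm <- regmatches(s, regexpr(
        paste0("^(", name_re, ")(\\^[+-]?", num_re, ")?"), s))
      if (!length(fm)) break
      piece <- fm
      nm <- sub("\\^.*$", "", piece)
      ord <- if (grepl("\\^", piece)) as.numeric(sub("^.*\\^", "", piece)) else 1
      factors[nm] <- if (nm %in% names(factors)) factors[nm] + ord else ord
      s <- trimws(substr(s, nchar(piece) + 1L, nchar(s)))
    }
    id <- NA_character_; tag <- ""
    bm <- regmatches(s, regexpr("^\\{[^}]*\\}", s))
    if (length(bm)) {
      inner <- substr(bm, 2, nchar(bm) - 1L)
      pieces <- strsplit(inner, "|", fixed = TRUE)[[1]]
      id <- pieces[1]
      if (length(pieces) > 1L) tag <- pieces[2]
      s <- trimws(substr(s, nchar(bm) + 1L, nchar(s)))
    }
    terms[[length(terms) + 1L]] <-
      power_law_term(gamma, factors, sign, flux_id = id, tag = tag)
    first <- FALSE
  }
  if (!length(terms)) stop("line ", ln, ": empty equation", call. = FALSE)
  terms
}

#' Write a model in the plain-text dialect
#'
#' Numbers are written with enough digits that [parse_plas()] recovers the
#' model exactly (write/parse round-trip identity).
#'
#' @param model a [gma_model()].
#' @param file optional path; when NULL the text is returned invisibly only.
#' @param header optional comment lines (without the leading `#`).
#' @return character vector of lines, invisibly.
#' @export
write_plas <- function(model, file = NULL, header = NULL) {
  fmt <- function(x) sprintf("%.17g", x)
  out <- character(0)
  if (!is.null(header)) out <- c(out, paste("#", header))
  v <- model$variables
  for (nm in dependent_names(model)) {
    parts <- vapply(model$equations[[nm]], function(tm) {
      fac <- if (length(tm$factors))
        paste0(" ", paste(sprintf("%s^%s", names(tm$factors),
                                  fmt(tm$factors)), collapse = " ")) else ""
      id <- if (!is.na(tm$flux_id) && nzchar(tm$flux_id))
        paste0(" {", tm$flux_id,
               if (nzchar(tm$tag)) paste0("|", tm$tag) else "", "}") else ""
      paste0(if (tm$sign > 0) "+ " else "- ", fmt(tm$gamma), fac, id)
    }, "")
    rhs <- paste(parts, collapse = " ")
    rhs <- sub("^\\+ ", "", rhs)
    out <- c(out, sprintf("%s' = %s", nm, rhs))
  }
  out <- c(out, "")
  for (i in seq_len(nrow(v)))
    out <- c(out, sprintf("%s = %s", v$name[i], fmt(v$value[i])))
  has_unit <- nzchar(v$unit)
  if (any(has_unit))
    out <- c(out, "", sprintf("!unit %s %s", v$name[has_unit], v$unit[has_unit]))
  has_desc <- nzchar(v$description)
  if (any(has_desc))
    out <- c(out, sprintf("!desc %s %s", v$name[has_desc], v$description[has_desc]))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Test two models for (numerical) equality
#'
#' Compares rosters, roles, basal values, and every equation's terms (rate
#' constants, kinetic orders, signs, flux ids) up to floating-point tolerance.
#'
#' @param a,b `gma_model` objects.
#' @param tol numeric tolerance.
#' @return TRUE/FALSE.
#' @export
gma_equal <- function(a, b, tol = 1e-12) {
  va <- a$variables[order(a$variables$name), ]
  vb <- b$variables[order(b$variables$name), ]
  if (!identical(va$name, vb$name) || !identical(va$role, vb$role)) return(FALSE)
  if (max(abs(va$value - vb$value) / pmax(abs(va$value), 1)) > tol) return(FALSE)
  if (!setequal(names(a$equations), names(b$equations))) return(FALSE)
  for (nm in names(a$equations)) {
    ta <- a$equations[[nm]]; tb <- b$equations[[nm]]
    if (length(ta) != length(tb)) return(FALSE)
    key <- function(tl) order(vapply(tl, function(t)
      paste(t$sign, t$flux_id, t$gamma), ""))
    ta <- ta[key(ta)]; tb <- tb[key(tb)]
    for (k in seq_along(ta)) {
      x <- ta[[k]]; y <- tb[[k]]
      if (x$sign != y$sign) return(FALSE)
      if (!identical(names(x$factors), names(y$factors))) return(FALSE)
      if (abs(x$gamma - y$gamma) > tol * max(abs(x$gamma), 1)) return(FALSE)
      if (length(x$factors) &&
          max(abs(x$factors - y$factors)) > tol) return(FALSE)
    }
  }
  TRUE
}
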