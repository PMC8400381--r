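#' @importFrom stats setNames runif sd rbinom
#' @importFrom utils read.delim write.table head
NULL

# Enumerations shared by the network containers.
RALOGIC_KINDS   <- c("TF", "TARGET_GENE", "PROTEIN", "GENE", "MRNA",
                     "COMPLEX", "SIMPLE_MOLECULE", "PHENOTYPE")
RALOGIC_ORIGINS <- c("COREG", "MAP", "BOTH")
RALOGIC_SIGNS   <- c("ACTIVATION", "INHIBITION", "COREGULATION")

#' Construct a signed interaction network
#'
#' A `signed_network` is the common currency of the integration pipeline: a
#' set of typed nodes plus signed directed edges (activation / inhibition)
#' and undirected TF-TF co-regulation evidence. Co-regulation edges are
#' canonicalised so that `source < target` lexicographically, and duplicate
#' `(source, target, sign)` triples are collapsed.
#'
#' @param nodes data frame with columns `id`, and optionally `label`,
#'   `kind`, `origin`; or a character vector of ids.
#' @param edges data frame with columns `source`, `target`, `sign`, and
#'   optionally `provenance`.
#' @return An object of class `signed_network` with components `nodes` and
#'   `edges`.
#' @export
signed_network <- function(nodes = character(), edges = NULL) {
  if (is.character(nodes)) {
    nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (nrow(nodes) > 0 && is.null(nodes$id)) stop("nodes must have an 'id' column")
  if (is.null(nodes$label))  nodes$label  <- nodes$id
  if (is.null(nodes$kind))   nodes$kind   <- rep("PROTEIN", nrow(nodes))
  if (is.null(nodes$origin)) nodes$origin <- rep("MAP", nrow(nodes))
  nodes <- nodes[, c("id", "label", "kind", "origin")]
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), provenance = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$provenance)) edges$provenance <- rep("", nrow(edges))
    edges <- edges[, c("source", "target", "sign", "provenance")]
  }
  net <- structure(list(nodes = nodes, edges = edges), class = "signed_network")
  canonicalize_network(net)
}

# Enforce container invariants: unique node ids, valid enumerations,
# endpoint referential integrity, undirected storage for co-regulation,
# (source, target, sign) dedup, deterministic row order.
canonicalize_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$id)) {
    nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  }
  if (any(!nzchar(nodes$id))) stop("node ids must be non-empty")
  bad <- setdiff(unique(nodes$kind), RALOGIC_KINDS)
  if (length(bad)) stop("unknown node kind: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(nodes$origin), RALOGIC_ORIGINS)
  if (length(bad)) stop("unknown node origin: ", paste(bad, collapse = ", "))
  if (nrow(edges) > 0) {
    bad <- setdiff(unique(edges$sign), RALOGIC_SIGNS)
    if (length(bad)) stop("unknown edge sign: ", paste(bad, collapse = ", "))
    dangling <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    if (length(dangling)) {
      stop("edge endpoints not in node set: ", paste(dangling, collapse = ", "))
    }
    co <- edges$sign == "COREGULATION"
    if (any(co)) {
      flip <- co & edges$source > edges$target
      tmp <- edges$source[flip]
      edges$source[flip] <- edges$target[flip]
      edges$target[flip] <- tmp
    }
    edges <- edges[!duplicated(edges[, c("source", "target", "sign")]), ,
                   drop = FALSE]
    edges <- edges[order(edges$source, edges$target, edges$sign), ,
                   drop = FALSE]
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  tab <- table(factor(x$edges$sign, levels = RALOGIC_SIGNS))
  cat(sprintf("signed_network: %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              paste(sprintf("%d %s", tab, tolower(names(tab))),
                    collapse = ", ")))
  invisible(x)
}

#' Test two signed networks for equality up to canonical form
#'
#' Node ids/kinds and the edge multiset are compared; labels, origins and
#' provenance tags are ignored unless `strict = TRUE`.
#' @param a,b `signed_network` objects.
#' @param strict compare all columns.
#' @return logical scalar.
#' @export
networks_equal <- function(a, b, strict = FALSE) {
  ea <- a$edges[, c("source", "target", "sign")]
  eb <- b$edges[, c("source", "target", "sign")]
  same_edges <- isTRUE(all.equal(ea, eb, check.attributes = FALSE))
  cols <- if (strict) c("id", "label", "kind", "origin") else c("id", "kind")
  same_nodes <- isTRUE(all.equal(a$nodes[, cols], b$nodes[, cols],
                                 check.attributes = FALSE))
  same_edges && same_nodes
}

sif_sign_map <- c("ACTIVATION" = "ACTIVATION", "POSITIVE" = "ACTIVATION",
                  "->" = "ACTIVATION",
                  "INHIBITION" = "INHIBITION", "NEGATIVE" = "INHIBITION",
                  "-|" = "INHIBITION",
                  "COREGULATION" = "COREGULATION")

#' Parse a SIF (simple interaction format) document
#'
#' Each non-blank line must carry at least three whitespace-separated
#' fields: `source interaction target`. Interaction tokens are mapped
#' case-insensitively: ACTIVATION/POSITIVE/`->` to activation,
#' INHIBITION/NEGATIVE/`-|` to inhibition, COREGULATION to co-regulation.
#' Nodes are auto-created with kind `PROTEIN`.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @param provenance tag recorded on every parsed edge.
#' @return a [signed_network()].
#' @export
parse_sif <- function(text, provenance = "sif") {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  keep <- which(nzchar(trimws(lines)))
  src <- tgt <- sgn <- character(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(fields) < 3) {
      stop(sprintf("SIF parse error at line %d: expected 3 fields, got %d",
                   ln, length(fields)))
    }
    tok <- toupper(fields[2])
    if (!tok %in% names(sif_sign_map)) {
      stop(sprintf("SIF parse error at line %d: unknown interaction '%s'",
                   ln, fields[2]))
    }
    src[i] <- fields[1]
    sgn[i] <- sif_sign_map[[tok]]
    tgt[i] <- fields[3]
  }
  ids <- sort(unique(c(src, tgt)))
  signed_network(
    nodes = data.frame(id = ids, stringsAsFactors = FALSE),
    edges = data.frame(source = src, target = tgt, sign = sgn,
                       provenance = rep(provenance, length(src)),
                       stringsAsFactors = FALSE))
}

#' Serialize a signed network to SIF text
#'
#' Output is deterministic: one tab-separated line per edge, sorted by
#' `(source, target, sign)`.
#' @param net a [signed_network()].
#' @return character scalar (possibly empty).
#' @export
serialize_sif <- function(net) {
  e <- net$edges
  if (nrow(e) == 0) return("")
  paste(paste(e$source, e$sign, e$target, sep = "\t"), collapse = "\n")
}

#' @rdname parse_sif
#' @param path file path.
#' @export
read_sif <- function(path, provenance = basename(path)) {
  parse_sif(readLines(path, warn = FALSE, encoding = "UTF-8"), provenance)
}

#' @rdname serialize_sif
#' @param path file path.
#' @export
write_sif <- function(net, path) {
  txt <- serialize_sif(net)
  writeLines(if (nzchar(txt)) txt else character(), path, useBytes = TRUE)
  invisible(path)
}

## ---- logical models ---------------------------------------------------

#' Construct a Boolean logical model
#'
#' Variables are 0/1; each has an update rule built from `&`, `|`, `!` and
#' parentheses over declared variables (stored as R expression trees). A
#' variable whose rule is itself is an input: both values are
#' self-consistent unless clamped. Clamped variables ignore their rule.
#'
#' @param rules named list mapping each variable to an R language object
#'   (or a string that parses to one).
#' @param clamps named integer/numeric vector of 0/1 forced values.
#' @return object of class `logical_model` with components `variables`
#'   (ordered symbol vector), `rules`, `clamps`.
#' @export
logical_model <- function(rules, clamps = integer()) {
  vars <- names(rules)
  if (is.null(vars) || any(!nzchar(vars))) stop("rules must be a named list")
  if (anyDuplicated(vars)) stop("duplicate variable in rules")
  rules <- lapply(rules, function(r) {
    if (is.character(r)) r <- parse_bool_expr(r)
    r
  })
  for (v in vars) {
    used <- all.vars(rules[[v]])
    undeclared <- setdiff(used, vars)
    if (length(undeclared)) {
      stop(sprintf("rule for %s references undeclared symbol(s): %s",
                   v, paste(undeclared, collapse = ", ")))
    }
    check_bool_expr(rules[[v]], v)
  }
  clamps <- validate_clamps(clamps, vars)
  structure(list(variables = vars, rules = rules, clamps = clamps),
            class = "logical_model")
}

validate_clamps <- function(clamps, vars) {
  if (length(clamps) == 0) return(setNames(integer(), character()))
  if (is.null(names(clamps)) || any(!nzchar(names(clamps)))) {
    stop("clamps must be named")
  }
  unknown <- setdiff(names(clamps), vars)
  if (length(unknown)) {
    stop("clamp on unknown variable: ", paste(unknown, collapse = ", "))
  }
  if (!all(clamps %in% c(0, 1))) stop("clamp values must be 0 or 1")
  storage.mode(clamps) <- "integer"
  clamps[order(names(clamps))]
}

# Parse a Boolean expression in the &, |, ! dialect using the R parser,
# then reject anything that is not pure propositional syntax.
parse_bool_expr <- function(s) {
  ex <- tryCatch(parse(text = s, keep.source = FALSE),
                 error = function(e) stop(sprintf(
                   "malformed Boolean expression '%s': %s",
                   trimws(s), conditionMessage(e)), call. = FALSE))
  if (length(ex) != 1) {
    stop(sprintf("malformed Boolean expression '%s'", trimws(s)))
  }
  ex[[1]]
}

check_bool_expr <- function(e, var) {
  if (is.symbol(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op %in% c("&", "|") && length(e) == 3) {
      check_bool_expr(e[[2]], var); check_bool_expr(e[[3]], var)
      return(invisible(TRUE))
    }
    if (op == "!" && length(e) == 2) {
      check_bool_expr(e[[2]], var)
      return(invisible(TRUE))
    }
    if (op == "(" && length(e) == 2) {
      check_bool_expr(e[[2]], var)
      return(invisible(TRUE))
    }
  }
  stop(sprintf("rule for %s is not a pure &/|/! expression: %s",
               var, deparse1(e)))
}

#' @export
print.logical_model <- function(x, ...) {
  cat(sprintf("logical_model: %d variables (%d inputs, %d clamped)\n",
              length(x$variables), length(model_inputs(x)),
              length(x$clamps)))
  for (v in x$variables) {
    cl <- if (v %in% names(x$clamps)) sprintf("  [clamped %d]", x$clamps[[v]]) else ""
    cat(sprintf("  %s <- %s%s\n", v, deparse1(x$rules[[v]]), cl))
  }
  invisible(x)
}

#' Input variables of a model
#'
#' Inputs are variables whose rule is identical to themselves.
#' @param model a [logical_model()].
#' @return character vector.
#' @export
model_inputs <- function(model) {
  vars <- model$variables
  vars[vapply(vars, function(v) identical(model$rules[[v]], as.symbol(v)),
              logical(1))]
}

#' Parse a bnet-style logical model
#'
#' One line per variable: `VAR, expression` with `&`, `|`, `!` and
#' parentheses. Inputs are written `VAR, VAR`. Lines starting with `#` and
#' the conventional `targets, factors` header are ignored.
#' @param text character vector of lines or a single string.
#' @return a [logical_model()].
#' @export
parse_bnet <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[tolower(gsub("[ ,\t]", "", lines)) != "targets,factors" &
                 tolower(gsub("[ ,\t]", "", lines)) != "targetsfactors"]
  rules <- list()
  for (ln in lines) {
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0) stop("bnet parse error: missing comma in line: ", ln)
    var <- trimws(substr(ln, 1, comma - 1))
    expr <- trimws(substr(ln, comma + 1, nchar(ln)))
    if (!nzchar(var) || !nzchar(expr)) {
      stop("bnet parse error: empty variable or expression in line: ", ln)
    }
    rules[[var]] <- parse_bool_expr(expr)
  }
  logical_model(rules)
}

#' Serialize a logical model to bnet text
#'
#' Deterministic: variables in declaration order, inputs written as
#' `VAR, VAR`. Clamps are not representable in bnet and are dropped with a
#' warning.
#' @param model a [logical_model()].
#' @return character scalar.
#' @export
serialize_bnet <- function(model) {
  if (length(model$clamps)) {
    warning("clamps are not representable in bnet text; dropped")
  }
  paste(vapply(model$variables,
               function(v) paste0(v, ", ", deparse1(model$rules[[v]])),
               character(1)),
        collapse = "\n")
}

#' @rdname parse_bnet
#' @param path file path.
#' @export
read_bnet <- function(path) {
  parse_bnet(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' @rdname serialize_bnet
#' @param path file path.
#' @export
write_bnet <- function(model, path) {
  writeLines(serialize_bnet(model), path, useBytes = TRUE)
  invisible(path)
}

## ---- overlay tables ---------------------------------------------------

#' Read a DEG or variant overlay table
#'
#' Tab-separated with a header row. DEG tables require columns
#' `gene`, `log2fc`, `fdr` (plus optional `dataset`); variant tables
#' require `variant`, `gene`, `vda`, `ei`. Rows with missing required
#' fields or scores outside `[0, 1]` are rejected; the count of rejected
#' rows is attached as attribute `n_rejected`.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param kind `"DEG"` or `"VARIANT"`.
#' @param text alternative to `path`: raw TSV text.
#' @return data frame of class `overlay_table` with attributes `kind` and
#'   `n_rejected`.
#' @export
read_overlay_table <- function(path = NULL, kind = c("DEG", "VARIANT"),
                               text = NULL) {
  kind <- match.arg(kind)
  df <- if (!is.null(text)) {
    read.delim(text = paste(text, collapse = "\n"),
               stringsAsFactors = FALSE)
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
  required <- if (kind == "DEG") c("gene", "log2fc", "fdr")
              else c("variant", "gene", "vda", "ei")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("overlay table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  scores <- if (kind == "DEG") "fdr" else c("vda", "ei")
  for (col in intersect(c("log2fc", scores), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  ok <- rep(TRUE, nrow(df))
  for (col in required) ok <- ok & !is.na(df[[col]])
  ok <- ok & nzchar(trimws(as.character(df$gene)))
  for (col in scores) ok <- ok & !is.na(df[[col]]) &
      df[[col]] >= 0 & df[[col]] <= 1
  n_rejected <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, kind = kind, n_rejected = n_rejected,
            class = c("overlay_table", "data.frame"))
}

#' Write an overlay table as TSV
#' @param table overlay table (any data frame).
#' @param path file path.
#' @export
write_overlay_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## ---- JSON graph export -------------------------------------------------

#' Export a network (plus overlay markers) as a JSON graph
#'
#' Produces a deterministic JSON document with `nodes` (id, kind, origin,
#' markers) and `edges` (source, target, sign) suitable for web viewers.
#'
#' @param net a [signed_network()].
#' @param overlay optional [project_overlay()] result (named list of
#'   marker -> symbol vector); all symbols must be network nodes.
#' @return JSON text (character scalar).
#' @export
export_json_graph <- function(net, overlay = NULL) {
  markers <- rep(list(character()), nrow(net$nodes))
  names(markers) <- net$nodes$id
  if (!is.null(overlay)) {
    sets <- if (inherits(overlay, "network_overlay")) overlay$markers else overlay
    for (m in names(sets)) {
      dangling <- setdiff(sets[[m]], net$nodes$id)
      if (length(dangling)) {
        stop("overlay references unknown node(s): ",
             paste(dangling, collapse = ", "))
      }
      for (id in sets[[m]]) markers[[id]] <- sort(c(markers[[id]], m))
    }
  }
  nodes <- lapply(seq_len(nrow(net$nodes)), function(i) {
    list(id = net$nodes$id[i], kind = net$nodes$kind[i],
         origin = net$nodes$origin[i],
         markers = markers[[net$nodes$id[i]]])
  })
  edges <- lapply(seq_len(nrow(net$edges)), function(i) {
    list(source = net$edges$source[i], target = net$edges$target[i],
         sign = net$edges$sign[i])
  })
  jsonlite::toJSON(list(nodes = nodes, edges = edges), auto_unbox = TRUE,
                   pretty = TRUE)
}

#' Parse a JSON graph produced by [export_json_graph()]
#' @param text JSON text.
#' @return a [signed_network()].
#' @export
parse_json_graph <- function(text) {
  g <- jsonlite::fromJSON(text, simplifyDataFrame = TRUE)
  nodes <- if (NROW(g$nodes)) {
    data.frame(id = g$nodes$id, kind = g$nodes$kind,
               origin = g$nodes$origin, stringsAsFactors = FALSE)
  } else character()
  signed_network(nodes = nodes, edges = g$edges)
}
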