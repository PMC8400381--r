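## Boolean dynamics engine: rule inference from signed topology,
## perturbations, exhaustive fixed-point enumeration, asynchronous
## attractors, variable elimination, and constraint-based rule search.

# Hard engine limits. Exhaustive enumeration is vectorised over all
# 2^n_free states in chunks; the asynchronous state-transition graph is
# materialised in full.
RALOGIC_MAX_EXHAUSTIVE <- 24L
RALOGIC_MAX_ASYNC <- 16L
RALOGIC_CHUNK <- 2^18

or_join <- function(syms) Reduce(function(a, b) call("|", a, b),
                                 lapply(syms, as.symbol))

#' Infer preliminary logical rules from signed topology
#'
#' Standard activity-flow convention: a node with activators `A` and
#' inhibitors `I` gets the rule `(OR over A) AND NOT (OR over I)`; with
#' inhibitors only, `NOT (OR over I)`; with no regulators it becomes an
#' input (`v <- v`). Co-regulation edges carry no direction and must be
#' removed before calling.
#'
#' @param net a [signed_network()] without COREGULATION edges.
#' @return a [logical_model()] over the network's nodes.
#' @export
infer_rules <- function(net) {
  if (any(net$edges$sign == "COREGULATION")) {
    stop("remove COREGULATION edges before rule inference")
  }
  vars <- net$nodes$id
  rules <- lapply(vars, function(v) {
    acts <- sort(net$edges$source[net$edges$target == v &
                                  net$edges$sign == "ACTIVATION"])
    inhs <- sort(net$edges$source[net$edges$target == v &
                                  net$edges$sign == "INHIBITION"])
    if (length(acts) == 0 && length(inhs) == 0) return(as.symbol(v))
    if (length(acts) == 0) return(call("!", call("(", or_join(inhs))))
    if (length(inhs) == 0) return(or_join(acts))
    call("&", call("(", or_join(acts)), call("!", call("(", or_join(inhs))))
  })
  names(rules) <- vars
  logical_model(rules)
}

#' Apply a perturbation (knock-out / ectopic expression) to a model
#'
#' A perturbation forces variables to constants: KO = 0, ectopic = 1.
#' Rules are untouched; existing clamps are overridden.
#'
#' @param model a [logical_model()].
#' @param pert named vector of 0/1 values.
#' @return a [logical_model()] with updated clamps.
#' @export
apply_perturbation <- function(model, pert) {
  if (length(pert) == 0) return(model)
  if (anyDuplicated(names(pert))) {
    dups <- unique(names(pert)[duplicated(names(pert))])
    conflicting <- vapply(dups, function(v)
      length(unique(pert[names(pert) == v])) > 1, logical(1))
    if (any(conflicting)) {
      stop("conflicting clamp for variable(s): ",
           paste(dups[conflicting], collapse = ", "))
    }
    pert <- pert[!duplicated(names(pert))]
  }
  clamps <- model$clamps
  clamps[names(pert)] <- pert
  logical_model(model$rules, clamps)
}

# Bind every variable to a logical vector/scalar and evaluate one rule.
eval_rule <- function(rule, env) {
  as.logical(eval(rule, envir = env, enclos = baseenv()))
}

#' Enumerate all stable states (fixed points) of a Boolean model
#'
#' Exhaustive, vectorised enumeration over the free (unclamped) variables,
#' processed in chunks so memory stays bounded. A state `x` is stable when
#' every unclamped variable satisfies `rule_v(x) == x_v`; clamped
#' variables hold their clamp value.
#'
#' @param model a [logical_model()] with at most 24 free variables.
#' @return data frame with one row per fixed point and one 0/1 column per
#'   model variable, sorted lexicographically in variable order.
#' @export
stable_states <- function(model) {
  vars <- model$variables
  free <- setdiff(vars, names(model$clamps))
  m <- length(free)
  if (m > RALOGIC_MAX_EXHAUSTIVE) {
    stop(sprintf(paste0("model has %d free variables; exhaustive ",
                        "enumeration supports at most %d - use ",
                        "reduce_model() first"), m, RALOGIC_MAX_EXHAUSTIVE))
  }
  n_states <- 2^m
  clamp_env <- lapply(model$clamps, function(x) x == 1L)
  hits <- integer(0)
  start <- 0
  while (start < n_states) {
    len <- min(RALOGIC_CHUNK, n_states - start)
    idx <- start + seq_len(len) - 1
    env <- clamp_env
    for (j in seq_len(m)) {
      # free[1] is the most significant bit so row order is lexicographic
      env[[free[j]]] <- bitwAnd(idx %/% 2^(m - j), 1) == 1L
    }
    ok <- rep(TRUE, len)
    for (v in free) {
      ok <- ok & (eval_rule(model$rules[[v]], env) == env[[v]])
      if (!any(ok)) break
    }
    hits <- c(hits, idx[ok])
    start <- start + len
  }
  out <- matrix(0L, nrow = length(hits), ncol = length(vars),
                dimnames = list(NULL, vars))
  for (j in seq_len(m)) {
    out[, free[j]] <- as.integer(bitwAnd(hits %/% 2^(m - j), 1))
  }
  for (v in names(model$clamps)) out[, v] <- model$clamps[[v]]
  as.data.frame(out)
}

#' Asynchronous attractors of a Boolean model
#'
#' Builds the full asynchronous state-transition graph (one variable
#' updated per transition) and classifies its terminal strongly-connected
#' components: singletons are fixed points, larger components are complex
#' attractors (sustained oscillations).
#'
#' @param model a [logical_model()] with at most 16 free variables.
#' @return list with `fixed_points` (data frame as in [stable_states()])
#'   and `complex_attractors` (list of data frames, one per attractor).
#' @export
async_attractors <- function(model) {
  vars <- model$variables
  free <- setdiff(vars, names(model$clamps))
  m <- length(free)
  if (m > RALOGIC_MAX_ASYNC) {
    stop(sprintf("asynchronous analysis supports at most %d free variables",
                 RALOGIC_MAX_ASYNC))
  }
  n_states <- 2^m
  idx <- seq_len(n_states) - 1
  env <- lapply(model$clamps, function(x) x == 1L)
  cur <- list()
  for (j in seq_len(m)) {
    cur[[free[j]]] <- bitwAnd(idx %/% 2^(m - j), 1) == 1L
    env[[free[j]]] <- cur[[free[j]]]
  }
  from <- to <- vector("list", m)
  for (j in seq_len(m)) {
    v <- free[j]
    fx <- eval_rule(model$rules[[v]], env)
    diff <- which(fx != cur[[v]])
    from[[j]] <- diff - 1L
    to[[j]] <- bitwXor(diff - 1L, as.integer(2^(m - j)))
  }
  from <- unlist(from)
  to <- unlist(to)
  state_df <- function(states) {
    out <- matrix(0L, nrow = length(states), ncol = length(vars),
                  dimnames = list(NULL, vars))
    for (j in seq_len(m)) {
      out[, free[j]] <- as.integer(bitwAnd(states %/% 2^(m - j), 1))
    }
    for (v in names(model$clamps)) out[, v] <- model$clamps[[v]]
    as.data.frame(out)
  }
  has_out <- rep(FALSE, n_states)
  has_out[from + 1] <- TRUE
  fixed <- idx[!has_out]
  complex_attractors <- list()
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from + 1, to + 1), directed = TRUE)
    comp <- igraph::components(g, mode = "strong")
    memb <- comp$membership
    # an SCC is terminal when no edge leaves it
    leaves <- unique(memb[from + 1][memb[from + 1] != memb[to + 1]])
    terminal <- setdiff(which(tabulate(memb, comp$no) > 1), leaves)
    complex_attractors <- lapply(terminal, function(cc) {
      states <- sort(which(memb == cc) - 1L)
      state_df(states)
    })
  }
  list(fixed_points = state_df(sort(fixed)),
       complex_attractors = complex_attractors)
}

subst_expr <- function(e, var, replacement) {
  if (is.symbol(e)) {
    if (identical(as.character(e), var)) return(replacement)
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- subst_expr(e[[i]], var, replacement)
    return(e)
  }
  e
}

#' Reduce a model by eliminating intermediate variables
#'
#' Each eliminated variable's rule is substituted into every rule that
#' references it, then the variable is removed. Eliminated variables must
#' not be autoregulated (rule referencing itself) or clamped; under that
#' condition the fixed points of the reduced model, extended by the
#' eliminated variables' rules, are exactly the fixed points of the
#' original model.
#'
#' @param model a [logical_model()].
#' @param eliminate character vector of variables to remove, processed in
#'   order.
#' @return a [logical_model()] with attribute `eliminated_rules`: a named
#'   list of expressions over the remaining variables that back-substitute
#'   each eliminated variable's value from a reduced fixed point.
#' @export
reduce_model <- function(model, eliminate) {
  if (length(eliminate) == 0) return(model)
  unknown <- setdiff(eliminate, model$variables)
  if (length(unknown)) {
    stop("cannot eliminate unknown variable(s): ",
         paste(unknown, collapse = ", "))
  }
  clamped <- intersect(eliminate, names(model$clamps))
  if (length(clamped)) {
    stop("cannot eliminate clamped variable(s): ",
         paste(clamped, collapse = ", "))
  }
  rules <- model$rules
  elim_rules <- list()
  for (v in eliminate) {
    repl <- rules[[v]]
    if (v %in% all.vars(repl)) {
      stop(sprintf("cannot eliminate autoregulated variable %s", v))
    }
    repl <- call("(", repl)
    rules[[v]] <- NULL
    for (w in names(rules)) rules[[w]] <- subst_expr(rules[[w]], v, repl)
    for (w in names(elim_rules)) {
      elim_rules[[w]] <- subst_expr(elim_rules[[w]], v, repl)
    }
    elim_rules[[v]] <- repl
  }
  out <- logical_model(rules, model$clamps)
  attr(out, "eliminated_rules") <- elim_rules
  out
}

#' Extend fixed points of a reduced model back to the original variables
#'
#' @param states data frame of fixed points of a reduced model.
#' @param reduced the [reduce_model()] output carrying `eliminated_rules`.
#' @param variable_order column order for the result (default: reduced
#'   variables followed by eliminated ones, sorted).
#' @return data frame of extended states.
#' @export
extend_states <- function(states, reduced,
                          variable_order = NULL) {
  elim <- attr(reduced, "eliminated_rules")
  out <- states
  for (v in names(elim)) {
    env <- lapply(as.list(states), function(col) col == 1L)
    out[[v]] <- as.integer(eval_rule(elim[[v]], env))
  }
  if (is.null(variable_order)) variable_order <- sort(names(out))
  out[, variable_order, drop = FALSE]
}

## ---- constraint tables -------------------------------------------------

#' Construct a stable-state constraint table
#'
#' A perturbation context (KOs plus input clamps) together with the
#' stable states required under it. When `exact = TRUE` the required
#' states, projected to the table's variable subset, must be *all* fixed
#' points of the clamped model.
#'
#' @param required data frame of 0/1 assignments; columns name the
#'   variable subset.
#' @param perturbation named 0/1 vector of knock-outs / ectopic values.
#' @param input_clamps named 0/1 vector of clamped input values.
#' @param exact logical flag.
#' @param label optional description used in reports.
#' @return object of class `state_constraint_table`.
#' @export
state_constraint_table <- function(required, perturbation = integer(),
                                   input_clamps = integer(), exact = TRUE,
                                   label = "") {
  required <- as.data.frame(required)
  if (!all(unlist(required) %in% c(0, 1))) {
    stop("required states must be 0/1")
  }
  clamps <- c(perturbation, input_clamps)
  if (anyDuplicated(names(clamps))) {
    dup <- names(clamps)[duplicated(names(clamps))]
    for (v in unique(dup)) {
      if (length(unique(clamps[names(clamps) == v])) > 1) {
        stop("conflicting clamp for variable ", v)
      }
    }
  }
  for (v in intersect(colnames(required), names(clamps))) {
    if (any(required[[v]] != clamps[[v]])) {
      stop(sprintf("required state contradicts clamp on %s", v))
    }
  }
  structure(list(required = required,
                 perturbation = perturbation,
                 input_clamps = input_clamps,
                 exact = isTRUE(exact),
                 label = label),
            class = "state_constraint_table")
}

table_clamps <- function(tab) {
  cl <- c(tab$perturbation, tab$input_clamps)
  cl[!duplicated(names(cl))]
}

# Canonical string form of projected states, for set comparison.
state_keys <- function(df, cols) {
  if (nrow(df) == 0) return(character())
  apply(as.matrix(df[, cols, drop = FALSE]), 1, paste, collapse = "")
}

#' Check a model against constraint tables
#'
#' Enumerates the fixed points of the model under each table's
#' perturbation and clamps and diffs them against the required states.
#'
#' @param model a [logical_model()].
#' @param tables list of [state_constraint_table()] objects.
#' @return data frame report with one row per table: label, number of
#'   required rows, matched rows, extra fixed points, and a `pass` flag.
#' @export
check_constraint_tables <- function(model, tables) {
  rows <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    fps <- stable_states(apply_perturbation(model, table_clamps(tab)))
    cols <- colnames(tab$required)
    got <- unique(state_keys(fps, cols))
    want <- unique(state_keys(tab$required, cols))
    matched <- sum(want %in% got)
    extra <- if (tab$exact) sum(!got %in% want) else 0L
    data.frame(table = if (nzchar(tab$label)) tab$label else as.character(i),
               required = length(want), matched = matched, extra = extra,
               pass = matched == length(want) && extra == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---- constraint-based rule reconstruction ------------------------------

# Candidate rules are monotone DNF formulas over a variable's topology
# regulators: each conjunct is a subset of regulators (activators appear
# positively, inhibitors negated), and the conjunct set is an antichain.

enumerate_antichains <- function(n_regs, max_literals, max_conjuncts) {
  subsets <- list()
  for (size in seq_len(min(n_regs, max_literals))) {
    cmb <- utils::combn(n_regs, size, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  is_subset <- function(a, b) all(a %in% b)
  res <- list()
  grow <- function(chosen, start) {
    if (length(chosen)) res[[length(res) + 1]] <<- chosen
    if (length(chosen) >= max_conjuncts || start > length(subsets)) return()
    for (k in start:length(subsets)) {
      cand <- subsets[[k]]
      comparable <- any(vapply(chosen, function(s)
        is_subset(s, cand) || is_subset(cand, s), logical(1)))
      if (!comparable) grow(c(chosen, list(cand)), k + 1)
    }
  }
  if (length(subsets)) grow(list(), 1)
  res
}

# Evaluate a DNF (list of regulator-index conjuncts) on a 0/1 regulator
# value vector, given per-regulator polarity (+1 activator, -1 inhibitor).
eval_dnf <- function(conjuncts, reg_values, polarity) {
  lit <- ifelse(polarity > 0, reg_values == 1, reg_values == 0)
  for (cj in conjuncts) if (all(lit[cj])) return(1L)
  0L
}

dnf_to_expr <- function(conjuncts, regs, polarity) {
  mk_lit <- function(i) {
    if (polarity[i] > 0) as.symbol(regs[i]) else call("!", as.symbol(regs[i]))
  }
  terms <- lapply(conjuncts, function(cj) {
    Reduce(function(a, b) call("&", a, b), lapply(cj, mk_lit))
  })
  Reduce(function(a, b) call("|", a, b), terms)
}

#' Reconstruct monotone logical rules from stable-state tables
#'
#' Searches, per variable, monotone disjunctive-normal-form rules over the
#' variable's topology regulators (activators used positively, inhibitors
#' negated) such that for every table the fixed points of the resulting
#' model under the table's perturbation and clamps, projected to the
#' table's variables, equal exactly the required states. Rules with fewer
#' literals are preferred; ties break lexicographically on the serialized
#' rule. Nodes without regulators become inputs.
#'
#' The search is counterexample-guided: candidate rules are first filtered
#' by the per-variable point constraints implied by fully-specified
#' required states, then spurious fixed points are eliminated by branching
#' on which variable must reject them.
#'
#' @param topology a [signed_network()] without COREGULATION edges.
#' @param tables list of [state_constraint_table()] objects whose columns
#'   cover all topology nodes (these yield point constraints).
#' @param qualitative optional list of additional
#'   [state_constraint_table()] objects over variable subsets (checked at
#'   the model level only).
#' @param max_conjuncts,max_literals search-space bounds per rule.
#' @param max_nodes search budget.
#' @return a [logical_model()] satisfying every table.
#' @export
solve_rules_from_constraints <- function(topology, tables,
                                         qualitative = list(),
                                         max_conjuncts = 4,
                                         max_literals = 3,
                                         max_nodes = 20000) {
  if (any(topology$edges$sign == "COREGULATION")) {
    stop("remove COREGULATION edges before rule reconstruction")
  }
  vars <- topology$nodes$id
  regulators <- lapply(vars, function(v) {
    e <- topology$edges[topology$edges$target == v, , drop = FALSE]
    regs <- sort(unique(e$source))
    polarity <- vapply(regs, function(r) {
      signs <- unique(e$sign[e$source == r])
      if (length(signs) > 1) {
        stop(sprintf("dual-sign regulation %s -> %s not supported", r, v))
      }
      if (signs == "ACTIVATION") 1L else -1L
    }, integer(1))
    list(regs = regs, polarity = polarity)
  })
  names(regulators) <- vars

  all_tables <- c(tables, qualitative)

  # Point constraints from tables whose required rows (plus clamps)
  # determine a full state.
  points <- setNames(lapply(vars, function(v) list()), vars)
  for (ti in seq_along(all_tables)) {
    tab <- all_tables[[ti]]
    clamps <- table_clamps(tab)
    cols <- colnames(tab$required)
    if (!all(vars %in% union(cols, names(clamps)))) next
    for (ri in seq_len(nrow(tab$required))) {
      state <- setNames(integer(length(vars)), vars)
      state[names(clamps)] <- clamps
      state[cols] <- as.integer(unlist(tab$required[ri, cols]))
      for (v in setdiff(vars, names(clamps))) {
        if (length(regulators[[v]]$regs) == 0) next
        points[[v]][[length(points[[v]]) + 1]] <- list(
          input = state[regulators[[v]]$regs], out = state[[v]],
          table = ti, row = ri)
      }
    }
  }

  # Per-variable candidate lists filtered by point constraints, ordered by
  # (literal count, deparse string).
  cand <- setNames(vector("list", length(vars)), vars)
  for (v in vars) {
    regs <- regulators[[v]]$regs
    pol <- regulators[[v]]$polarity
    if (length(regs) == 0) {
      cand[[v]] <- list(list(conjuncts = NULL, expr = as.symbol(v),
                             nlit = 0L))
      next
    }
    antichains <- enumerate_antichains(length(regs), max_literals,
                                       max_conjuncts)
    keep <- Filter(function(ac) {
      all(vapply(points[[v]], function(p)
        eval_dnf(ac, p$input, pol) == p$out, logical(1)))
    }, antichains)
    if (length(keep) == 0) {
      bad <- points[[v]]
      culprit <- if (length(bad)) bad[[length(bad)]] else NULL
      stop(sprintf(paste0("infeasible constraints: no monotone rule for ",
                          "%s%s"), v,
                   if (!is.null(culprit)) sprintf(
                     " (first violated: table %d, row %d)",
                     culprit$table, culprit$row) else ""))
    }
    entries <- lapply(keep, function(ac) {
      expr <- dnf_to_expr(ac, regs, pol)
      list(conjuncts = ac, expr = expr,
           nlit = sum(lengths(ac)), key = deparse1(expr))
    })
    ord <- order(vapply(entries, `[[`, integer(1), "nlit"),
                 vapply(entries, `[[`, character(1), "key"))
    cand[[v]] <- entries[ord]
  }

  build_model <- function(sel) {
    rules <- lapply(vars, function(v) cand[[v]][[sel[[v]]]]$expr)
    names(rules) <- vars
    logical_model(rules)
  }

  # First violation of `model` across the tables; NULL when all pass.
  find_counterexample <- function(model) {
    for (ti in seq_along(all_tables)) {
      tab <- all_tables[[ti]]
      clamps <- table_clamps(tab)
      fps <- stable_states(apply_perturbation(model, clamps))
      cols <- colnames(tab$required)
      got <- state_keys(fps, cols)
      want <- unique(state_keys(tab$required, cols))
      if (tab$exact) {
        extra <- which(!got %in% want)
        if (length(extra)) {
          return(list(type = "extra", table = ti,
                      state = setNames(as.integer(fps[extra[1], vars]), vars)))
        }
      }
      if (!all(want %in% got)) {
        return(list(type = "missing", table = ti,
                    row = which(!want %in% got)[1]))
      }
    }
    NULL
  }

  nodes_used <- 0L
  search <- function(lists) {
    nodes_used <<- nodes_used + 1L
    if (nodes_used > max_nodes) {
      stop("constraint search exceeded node budget; relax bounds")
    }
    sel <- setNames(as.list(rep(1L, length(vars))), vars)
    # within this branch, selection = first candidate of each list
    rules <- lapply(vars, function(v) lists[[v]][[1]]$expr)
    names(rules) <- vars
    model <- logical_model(rules)
    ce <- find_counterexample(model)
    if (is.null(ce)) return(model)
    if (ce$type == "missing") return(NULL)
    x <- ce$state
    clamps <- table_clamps(all_tables[[ce$table]])
    for (v in vars) {
      if (v %in% names(clamps)) next
      pol <- regulators[[v]]$polarity
      regs <- regulators[[v]]$regs
      if (length(regs) == 0) next
      viol <- Filter(function(entry)
        eval_dnf(entry$conjuncts, x[regs], pol) != x[[v]], lists[[v]])
      if (length(viol) == 0) next
      sub <- lists
      sub[[v]] <- viol
      res <- search(sub)
      if (!is.null(res)) return(res)
    }
    NULL
  }

  model <- search(cand)
  if (is.null(model)) {
    stop("infeasible constraint set: no monotone rule assignment ",
         "satisfies all tables within the search bounds")
  }
  model
}
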