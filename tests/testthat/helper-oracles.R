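# Independent oracles: deliberately naive implementations that share no
# code path with the engine (scalar evaluation, plain loops, igraph for
# graph reachability).

# Naive fixed-point enumeration: loop over all 2^n assignments and check
# each rule by scalar evaluation.
brute_stable_states <- function(model) {
  vars <- model$variables
  n <- length(vars)
  hits <- list()
  for (i in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(i))[seq_len(n)]
    st <- stats::setNames(bits, vars)
    env <- as.list(st == 1L)
    ok <- TRUE
    for (v in vars) {
      want <- if (v %in% names(model$clamps)) model$clamps[[v]]
              else as.integer(eval(model$rules[[v]], envir = env))
      if (want != st[[v]]) { ok <- FALSE; break }
    }
    if (ok) hits[[length(hits) + 1]] <- st
  }
  if (length(hits) == 0) {
    return(as.data.frame(matrix(integer(), 0, n,
                                dimnames = list(NULL, vars))))
  }
  as.data.frame(do.call(rbind, hits))
}

# Canonical row order so fixed-point sets can be compared as data frames.
sort_states <- function(df) {
  df <- df[, sort(colnames(df)), drop = FALSE]
  if (nrow(df) > 1) df <- df[do.call(order, as.list(df)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_same_states <- function(a, b) {
  expect_equal(sort_states(a), sort_states(b))
}

# Scalar truth-table of one rule over given variables (2^n rows).
rule_truth_table <- function(rule, vars) {
  n <- length(vars)
  vapply(0:(2^n - 1), function(i) {
    bits <- as.integer(intToBits(i))[seq_len(n)] == 1L
    as.logical(eval(rule, envir = stats::setNames(as.list(bits), vars)))
  }, logical(1))
}

models_tt_equal <- function(m1, m2) {
  if (!identical(sort(m1$variables), sort(m2$variables))) return(FALSE)
  vars <- sort(m1$variables)
  all(vapply(vars, function(v) {
    identical(rule_truth_table(m1$rules[[v]], vars),
              rule_truth_table(m2$rules[[v]], vars))
  }, logical(1)))
}

as_igraph <- function(net, directed_only = TRUE) {
  e <- net$edges
  if (directed_only) e <- e[e$sign != "COREGULATION", , drop = FALSE]
  igraph::graph_from_data_frame(e[, c("source", "target")], directed = TRUE,
                                vertices = net$nodes$id)
}

# A random signed network where every node touches an edge (so SIF
# round-trips are identity on the node set).
random_connected_network <- function(n_nodes, seed, p_inh = 0.3) {
  withr::with_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n_nodes))
    src <- c(ids[-n_nodes],
             sample(ids, n_nodes, replace = TRUE))
    tgt <- c(ids[-1],
             sample(ids, n_nodes, replace = TRUE))
    sgn <- ifelse(runif(length(src)) < p_inh, "INHIBITION", "ACTIVATION")
    signed_network(ids, data.frame(source = src, target = tgt, sign = sgn,
                                   stringsAsFactors = FALSE))
  })
}
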