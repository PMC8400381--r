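## Seeded generators emulating the processed inputs of the pipeline:
## a TF co-regulatory network (TF-target signed edges plus TF-TF
## co-regulation evidence), a layered signalling map ending in shared TFs,
## DEG tables with planted FDR structure, and variant tables with
## uniform association scores. All generators are pure functions of
## (spec, seed): identical seeds give identical outputs.

#' Specification for the synthetic-data generators
#'
#' Defaults mirror the shapes of the real processed inputs: 19 TFs with 14
#' co-regulatory interactions among them and 373 regulated targets
#' (co-regulatory network); a layered signalling cascade of about 240
#' proteins feeding 6 shared TFs (upstream network); and 2387 candidate
#' disease variants. Score distributions are uniform nulls - the pipeline
#' only thresholds them.
#'
#' @param seed integer seed.
#' @param n_tfs,n_targets co-regulatory network size.
#' @param coreg_density probability that a TF pair is co-regulatory
#'   (default 14 / choose(19, 2)).
#' @param inhibition_rate probability that a directed edge is an
#'   inhibition (the global network is roughly half inhibitions).
#' @param n_layers,layer_width signalling cascade shape.
#' @param complex_rate fraction of signalling nodes that are complexes.
#' @param n_shared_tfs TFs shared between the two networks.
#' @param frac_de fraction of genes planted as differentially expressed.
#' @param n_variants number of variant rows.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_tfs = 19L, n_targets = 373L,
                           coreg_density = 14 / choose(19, 2),
                           inhibition_rate = 0.5, n_layers = 6L,
                           layer_width = 40L, complex_rate = 0.15,
                           n_shared_tfs = 6L, frac_de = 0.1,
                           n_variants = 2387L) {
  rates <- c(coreg_density = coreg_density,
             inhibition_rate = inhibition_rate, complex_rate = complex_rate,
             frac_de = frac_de)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (n_shared_tfs > n_tfs) stop("n_shared_tfs must not exceed n_tfs")
  structure(list(seed = as.integer(seed), n_tfs = as.integer(n_tfs),
                 n_targets = as.integer(n_targets),
                 coreg_density = coreg_density,
                 inhibition_rate = inhibition_rate,
                 n_layers = as.integer(n_layers),
                 layer_width = as.integer(layer_width),
                 complex_rate = complex_rate,
                 n_shared_tfs = as.integer(n_shared_tfs),
                 frac_de = frac_de, n_variants = as.integer(n_variants)),
            class = "synthetic_spec")
}

synth_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Generate a TF co-regulatory network
#'
#' `n_tfs` TF nodes and `n_targets` target genes, each target regulated by
#' one to three TFs with sign drawn by `inhibition_rate`; TF-TF
#' co-regulation edges drawn with probability `coreg_density`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [signed_network()] with node origins `COREG`.
#' @export
gen_coreg_network <- function(spec) {
  withr::with_seed(spec$seed, {
    tfs <- synth_ids("TF", spec$n_tfs)
    targets <- synth_ids("G", spec$n_targets)
    src <- tgt <- sgn <- list()
    for (g in targets) {
      k <- sample(1:3, 1)
      regs <- sample(tfs, min(k, length(tfs)))
      src[[g]] <- regs
      tgt[[g]] <- rep(g, length(regs))
      sgn[[g]] <- ifelse(runif(length(regs)) < spec$inhibition_rate,
                         "INHIBITION", "ACTIVATION")
    }
    co_src <- co_tgt <- character()
    if (spec$n_tfs >= 2) {
      pairs <- utils::combn(tfs, 2)
      pick <- runif(ncol(pairs)) < spec$coreg_density
      co_src <- pairs[1, pick]
      co_tgt <- pairs[2, pick]
    }
    edges <- data.frame(
      source = c(unlist(src), co_src),
      target = c(unlist(tgt), co_tgt),
      sign = c(unlist(sgn), rep("COREGULATION", length(co_src))),
      provenance = "coreg", stringsAsFactors = FALSE)
    nodes <- data.frame(
      id = c(tfs, targets), label = c(tfs, targets),
      kind = c(rep("TF", length(tfs)), rep("TARGET_GENE", length(targets))),
      origin = "COREG", stringsAsFactors = FALSE)
    signed_network(nodes, edges)
  })
}

#' Generate a layered signalling network ending at shared TFs
#'
#' A layered DAG of `n_layers x layer_width` protein nodes: every node in
#' layer `l+1` receives at least one edge from layer `l`, the terminal
#' layer is wired into the shared TF symbols, and a fraction
#' `complex_rate` of protein nodes are complexes with 2-3 members recorded
#' in the membership map. Acyclic by construction.
#'
#' @param spec a [synthetic_spec()].
#' @param shared_tfs character vector of length `n_shared_tfs`.
#' @return list with `network` (a [signed_network()], origins `MAP`) and
#'   `membership` (named list: complex id -> member symbols).
#' @export
gen_signalling_network <- function(spec, shared_tfs) {
  if (length(shared_tfs) != spec$n_shared_tfs) {
    stop("need exactly n_shared_tfs shared TF symbols")
  }
  withr::with_seed(spec$seed + 1L, {
    layers <- lapply(seq_len(spec$n_layers), function(l) {
      sprintf("P%d_%02d", l, seq_len(spec$layer_width))
    })
    prots <- unlist(layers)
    src <- tgt <- character()
    for (l in seq_len(spec$n_layers - 1)) {
      for (node in layers[[l + 1]]) {
        k <- sample(1:2, 1)
        parents <- sample(layers[[l]], min(k, length(layers[[l]])))
        src <- c(src, parents)
        tgt <- c(tgt, rep(node, length(parents)))
      }
    }
    for (tf in shared_tfs) {
      k <- sample(1:2, 1)
      parents <- sample(layers[[spec$n_layers]],
                        min(k, spec$layer_width))
      src <- c(src, parents)
      tgt <- c(tgt, rep(tf, length(parents)))
    }
    sgn <- ifelse(runif(length(src)) < spec$inhibition_rate,
                  "INHIBITION", "ACTIVATION")
    n_complex <- round(spec$complex_rate * length(prots))
    complex_ids <- if (n_complex > 0) sample(prots, n_complex) else character()
    membership <- lapply(complex_ids, function(cx) {
      sprintf("%s_M%d", cx, seq_len(sample(2:3, 1)))
    })
    names(membership) <- complex_ids
    nodes <- data.frame(
      id = c(prots, shared_tfs), label = c(prots, shared_tfs),
      kind = c(rep("PROTEIN", length(prots)),
               rep("TF", length(shared_tfs))),
      origin = "MAP", stringsAsFactors = FALSE)
    nodes$kind[nodes$id %in% complex_ids] <- "COMPLEX"
    net <- signed_network(nodes, data.frame(
      source = src, target = tgt, sign = sgn, provenance = "map",
      stringsAsFactors = FALSE))
    list(network = net, membership = membership)
  })
}

#' Generate a DEG overlay table with a planted DE fraction
#'
#' Exactly `round(frac_de * length(genes))` genes receive an FDR drawn
#' uniformly in `[0, 0.1)` and the rest in `[0.1, 1]`, so selection at the
#' 0.1 threshold recovers the planted set exactly.
#'
#' @param genes character vector of gene symbols.
#' @param frac_de fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param dataset tag recorded on every row.
#' @return an overlay table of kind `DEG`.
#' @export
gen_deg_table <- function(genes, frac_de = 0.1, seed = 1L,
                          dataset = "synthetic") {
  if (frac_de < 0 || frac_de > 1) stop("frac_de must lie in [0, 1]")
  withr::with_seed(as.integer(seed), {
    n <- length(genes)
    n_de <- round(frac_de * n)
    de <- sample(genes, n_de)
    fdr <- setNames(runif(n, 0.1, 1), genes)
    fdr[de] <- runif(n_de, 0, 0.1 - 1e-9)
    log2fc <- stats::rnorm(n, 0, 2)
    df <- data.frame(gene = genes, log2fc = log2fc, fdr = unname(fdr[genes]),
                     dataset = dataset, stringsAsFactors = FALSE)
    structure(df, kind = "DEG", n_rejected = 0L,
              class = c("overlay_table", "data.frame"))
  })
}

#' Generate a variant overlay table with uniform scores
#'
#' `n_variants` rows with VDA and EI drawn independently and uniformly in
#' `[0, 1]`, genes drawn with replacement from `genes`.
#'
#' @param genes character vector of gene symbols.
#' @param n_variants number of rows.
#' @param seed integer seed.
#' @return an overlay table of kind `VARIANT`.
#' @export
gen_variant_table <- function(genes, n_variants = 2387L, seed = 1L) {
  if (n_variants < 0) stop("n_variants must be >= 0")
  withr::with_seed(as.integer(seed), {
    df <- data.frame(
      variant = sprintf("rs%06d", seq_len(n_variants)),
      gene = if (n_variants > 0) sample(genes, n_variants, replace = TRUE)
             else character(),
      vda = runif(n_variants), ei = runif(n_variants),
      stringsAsFactors = FALSE)
    structure(df, kind = "VARIANT", n_rejected = 0L,
              class = c("overlay_table", "data.frame"))
  })
}

#' Generate a random monotone Boolean model
#'
#' Each variable receives 0 to `max_regulators` random regulators and a
#' random monotone DNF rule over them (each regulator used with a fixed
#' polarity, negative with probability `inhibition_rate`). Variables with
#' no regulators become inputs.
#'
#' @param n_vars number of variables (at most 16).
#' @param max_regulators maximum in-degree.
#' @param seed integer seed.
#' @param inhibition_rate probability a regulator is used negated; set to
#'   0 for models whose interaction graph has only positive circuits.
#' @return a [logical_model()].
#' @export
gen_random_model <- function(n_vars, max_regulators = 3, seed = 1L,
                             inhibition_rate = 0.3) {
  if (n_vars > 16) stop("gen_random_model supports at most 16 variables")
  withr::with_seed(as.integer(seed), {
    vars <- sprintf("V%02d", seq_len(n_vars))
    rules <- lapply(seq_len(n_vars), function(i) {
      k <- sample(0:max_regulators, 1)
      if (k == 0) return(as.symbol(vars[i]))
      regs <- sample(vars, min(k, n_vars))
      pol <- ifelse(runif(length(regs)) < inhibition_rate, -1L, 1L)
      # random antichain: sample conjuncts, drop dominated ones
      n_conj <- sample(1:3, 1)
      conjuncts <- unique(lapply(seq_len(n_conj), function(j) {
        sort(sample(seq_along(regs), sample(seq_along(regs), 1)))
      }))
      keep <- rep(TRUE, length(conjuncts))
      for (a in seq_along(conjuncts)) {
        for (b in seq_along(conjuncts)) {
          if (a != b && keep[a] && keep[b] &&
              all(conjuncts[[b]] %in% conjuncts[[a]])) keep[a] <- FALSE
        }
      }
      dnf_to_expr(conjuncts[keep], regs, pol)
    })
    names(rules) <- vars
    logical_model(rules)
  })
}
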