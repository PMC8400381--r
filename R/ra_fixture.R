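## Packaged rheumatoid-arthritis fixture: the 13-variable TNF/IL6/TGFB1
## signalling subnetwork around the AP-1 / NF-kB transcription factors,
## the stable-state tables it must reproduce (wild type plus three virtual
## knock-out settings under TNF blockade), and the reconstructed logical
## model.

RA_VARIABLES <- c("TNF", "IL6", "TGFB1", "JUN", "FOS", "JUND", "NFKBIA",
                  "DAXX", "ILK", "NFKB1", "MAP2K1", "MAPK1", "MAPK14")
RA_TFS <- c("FOS", "JUN", "JUND", "NFKBIA")

ra_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ralogic")
  if (!nzchar(path)) {
    # during development (devtools::load_all) fall back to source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("fixture file not found: ", file)
  path
}

#' The packaged RA signalling subnetwork topology
#'
#' Thirteen species: the three cytokine inputs TNF, IL6 and TGFB1, the
#' kinase cascade ILK / MAP2K1 / MAPK1 / MAPK14, the adaptor DAXX, NFKB1,
#' and the four transcription factors JUN, FOS, JUND and NFKBIA. All
#' interactions are activations (the interaction graph has only positive
#' circuits); IL6 and TGFB1 carry self-loops because they behave as
#' self-sustaining regulated species, which is what makes the wild type
#' have five rather than eight fixed points.
#'
#' @return a [signed_network()].
#' @export
ra_subnetwork <- function() {
  net <- read_sif(ra_extdata("ra_subnetwork.sif"), provenance = "ra_fixture")
  net$nodes$kind[net$nodes$id %in% RA_TFS] <- "TF"
  net$nodes$origin[net$nodes$id %in% RA_TFS] <- "BOTH"
  canonicalize_network(net)
}

# Parse a block file of constraint tables. Blocks start with
# "## table: <label>" followed by "## perturbation:" / "## clamps:" lines
# (comma-separated VAR=0/1 pairs, possibly empty) and a TSV with a
# "state" label column.
parse_constraint_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  starts <- grep("^## table:", lines)
  ends <- c(starts[-1] - 1, length(lines))
  parse_pairs <- function(s) {
    s <- trimws(sub("^[^:]*:", "", s))
    if (!nzchar(s)) return(setNames(integer(), character()))
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    kv <- strsplit(trimws(parts), "=", fixed = TRUE)
    setNames(as.integer(vapply(kv, `[`, character(1), 2)),
             vapply(kv, `[`, character(1), 1))
  }
  lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    label <- trimws(sub("^## table:", "", block[1]))
    pert <- parse_pairs(block[grep("^## perturbation:", block)[1]])
    clamps <- parse_pairs(block[grep("^## clamps:", block)[1]])
    tsv <- block[!startsWith(block, "##") & nzchar(block)]
    df <- read.delim(text = paste(tsv, collapse = "\n"),
                     stringsAsFactors = FALSE)
    rownames(df) <- df$state
    df$state <- NULL
    state_constraint_table(df, perturbation = pert, input_clamps = clamps,
                           exact = TRUE, label = label)
  })
}

#' Stable-state constraint tables of the RA fixture
#'
#' Four tables: the wild type (five fixed points) and three knock-out
#' settings under TNF blockade (MAPK1+MAPK14 KO; DAXX+ILK+MAP2K1 KO;
#' DAXX+NFKB1 KO; three fixed points each), all marked exact.
#'
#' @return list of [state_constraint_table()] objects.
#' @export
ra_constraint_tables <- function() {
  parse_constraint_blocks(ra_extdata("ra_tables.tsv"))
}

#' Qualitative simulation constraints of the RA fixture
#'
#' Nine additional exact constraint tables encoding the real-time
#' simulation outcomes used during rule reconstruction: for each of the
#' three knock-out settings, switching a single input on and requiring
#' the transcription-factor read-out (all four TFs on, except the
#' IL6-only / DAXX+ILK+MAP2K1-KO case where only NFKBIA activates). The
#' IL6-only case additionally clamps TGFB1 to 0 because TGFB1 cannot
#' self-activate from the all-OFF initial state.
#'
#' @return list of [state_constraint_table()] objects over the TF subset.
#' @export
ra_simulation_constraints <- function() {
  parse_constraint_blocks(ra_extdata("ra_sim_constraints.tsv"))
}

#' The packaged RA Boolean model
#'
#' The monotone rule set reconstructed by
#' [solve_rules_from_constraints()] from [ra_constraint_tables()] and
#' [ra_simulation_constraints()] over the [ra_subnetwork()] topology,
#' stored as bnet text for deterministic builds. TNF is the only pure
#' input; IL6 and TGFB1 are self-sustaining regulated species.
#'
#' @return a [logical_model()] over the 13 fixture variables.
#' @export
ra_model <- function() {
  read_bnet(ra_extdata("ra_model.bnet"))
}

#' Re-derive the RA model from its constraints
#'
#' Runs the constraint solver on the packaged topology and tables;
#' the result must be constraint-equivalent to [ra_model()].
#' @return a [logical_model()].
#' @export
ra_solve_model <- function() {
  solve_rules_from_constraints(ra_subnetwork(), ra_constraint_tables(),
                               qualitative = ra_simulation_constraints())
}

#' The full RA fixture
#' @return object of class `ra_fixture`: list with `topology`, `tables`
#'   (stable-state tables), `sim_constraints`, and `model`.
#' @export
ra_fixture <- function() {
  structure(list(topology = ra_subnetwork(),
                 tables = ra_constraint_tables(),
                 sim_constraints = ra_simulation_constraints(),
                 model = ra_model()),
            class = "ra_fixture")
}

#' Verify a fixture against its stable-state tables
#'
#' For each constraint table, enumerates the fixed points of the
#' (perturbed, clamped) model and diffs them against the required states.
#' Failures are reported, not raised.
#'
#' @param fixture an [ra_fixture()] (or any list with `model` and
#'   `tables`).
#' @return data frame with one row per required state: `table`, `state`,
#'   `found`; attributes `extras` (spurious fixed points per table) and
#'   `all_pass`.
#' @export
verify_fixture <- function(fixture = ra_fixture()) {
  model <- fixture$model
  rows <- list()
  extras <- integer()
  for (tab in fixture$tables) {
    fps <- stable_states(apply_perturbation(model, table_clamps(tab)))
    cols <- colnames(tab$required)
    got <- state_keys(fps, cols)
    want <- state_keys(tab$required, cols)
    rows[[length(rows) + 1]] <- data.frame(
      table = tab$label,
      state = rownames(tab$required),
      found = want %in% got,
      stringsAsFactors = FALSE, row.names = NULL)
    extras[tab$label] <- if (tab$exact) sum(!got %in% want) else 0L
  }
  report <- do.call(rbind, rows)
  attr(report, "extras") <- extras
  attr(report, "all_pass") <- all(report$found) && all(extras == 0L)
  report
}
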