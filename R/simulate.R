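## Cell-Collective-style stochastic simulation: dosed inputs are
## resampled ON with probability equal to their dose at every step,
## clamped variables are constant, and all remaining variables update
## synchronously. Activity is the fraction of ON observations after a
## burn-in window, averaged over independent runs.

validate_doses <- function(model, doses) {
  if (length(doses) == 0) return(doses)
  if (is.null(names(doses)) || any(!nzchar(names(doses)))) {
    stop("doses must be named")
  }
  unknown <- setdiff(names(doses), model$variables)
  if (length(unknown)) {
    stop("dose on unknown variable(s): ", paste(unknown, collapse = ", "))
  }
  if (any(doses < 0 | doses > 1)) stop("doses must lie in [0, 1]")
  doses
}

#' Stochastic activity simulation under input dosing
#'
#' Runs `runs` independent synchronous trajectories of `steps` steps from
#' the all-OFF initial state. At every step each dosed variable is
#' resampled ON with probability equal to its dose (overriding its rule);
#' perturbed variables are clamped; every other variable is updated
#' synchronously from the previous state. Activity is the fraction of ON
#' observations over the post-burn-in steps, averaged over runs; the
#' standard error is computed across runs.
#'
#' @param model a [logical_model()].
#' @param doses named numeric vector of doses in `[0, 1]`. Variables not
#'   listed follow their rules (an undosed input keeps its initial 0).
#' @param perturbation named 0/1 vector of clamps (KO = 0).
#' @param steps,runs,burn_in simulation parameters; `steps > burn_in >= 0`.
#' @param seed integer seed; identical arguments give identical estimates.
#' @return object of class `activity_estimate`: list with `activity` and
#'   `stderr` (named numeric vectors) and `meta` (parameters used).
#' @export
run_stochastic <- function(model, doses = numeric(), perturbation = integer(),
                           steps = 2000, runs = 50, burn_in = 500,
                           seed = 1) {
  doses <- validate_doses(model, doses)
  if (!(steps > burn_in && burn_in >= 0)) stop("need steps > burn_in >= 0")
  if (runs < 1) stop("need runs >= 1")
  pmodel <- apply_perturbation(model, perturbation)
  vars <- pmodel$variables
  clamps <- pmodel$clamps
  overlap <- intersect(names(doses), names(clamps))
  if (length(overlap)) {
    stop("variable(s) both dosed and clamped: ",
         paste(overlap, collapse = ", "))
  }
  dosed <- names(doses)
  updated <- setdiff(vars, c(dosed, names(clamps)))

  withr::with_seed(as.integer(seed), {
    state <- matrix(FALSE, nrow = runs, ncol = length(vars),
                    dimnames = list(NULL, vars))
    for (v in names(clamps)) state[, v] <- clamps[[v]] == 1L
    on_count <- matrix(0L, nrow = runs, ncol = length(vars),
                       dimnames = list(NULL, vars))
    for (t in seq_len(steps)) {
      nxt <- state
      for (v in dosed) nxt[, v] <- runif(runs) < doses[[v]]
      if (length(updated)) {
        env <- lapply(setNames(seq_along(vars), vars),
                      function(j) state[, j])
        for (v in updated) nxt[, v] <- eval_rule(pmodel$rules[[v]], env)
      }
      state <- nxt
      if (t > burn_in) on_count <- on_count + state
    }
  })
  per_run <- on_count / (steps - burn_in)
  activity <- colMeans(per_run)
  stderr <- apply(per_run, 2, sd) / sqrt(runs)
  structure(list(activity = activity, stderr = stderr,
                 meta = list(steps = steps, runs = runs, burn_in = burn_in,
                             seed = as.integer(seed), doses = doses,
                             perturbation = perturbation)),
            class = "activity_estimate")
}

#' @export
print.activity_estimate <- function(x, ...) {
  cat(sprintf("activity_estimate (%d runs x %d steps, burn-in %d):\n",
              x$meta$runs, x$meta$steps, x$meta$burn_in))
  for (v in names(x$activity)) {
    cat(sprintf("  %-10s %.3f (se %.3f)\n", v, x$activity[[v]],
                x$stderr[[v]]))
  }
  invisible(x)
}

#' Dose-response curve of a single input
#'
#' Runs [run_stochastic()] at every grid dose of `varied`, on top of the
#' `base` dose condition, deriving one seed per grid point
#' (`seed + grid index`) so points are independent yet reproducible.
#'
#' @param model a [logical_model()].
#' @param varied variable whose dose is swept.
#' @param grid ascending numeric vector of doses in `[0, 1]`.
#' @param base named numeric vector: doses of the other inputs.
#' @param perturbation named 0/1 clamp vector (must not contain `varied`).
#' @param steps,runs,burn_in,seed as in [run_stochastic()].
#' @return object of class `dose_response`: list with `varied`, `grid`,
#'   and `estimates` (one `activity_estimate` per grid point).
#' @export
dose_response <- function(model, varied, grid, base = numeric(),
                          perturbation = integer(), steps = 2000,
                          runs = 50, burn_in = 500, seed = 1) {
  if (varied %in% names(perturbation)) {
    stop("varied input is clamped by the perturbation: ", varied)
  }
  if (is.unsorted(grid)) stop("dose grid must be ascending")
  if (any(grid < 0 | grid > 1)) stop("dose grid must lie in [0, 1]")
  estimates <- lapply(seq_along(grid), function(i) {
    doses <- base
    doses[varied] <- grid[i]
    run_stochastic(model, doses = doses, perturbation = perturbation,
                   steps = steps, runs = runs, burn_in = burn_in,
                   seed = as.integer(seed) + i - 1L)
  })
  structure(list(varied = varied, grid = grid, estimates = estimates),
            class = "dose_response")
}

#' Tidy a dose-response curve
#' @param x a `dose_response` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with columns dose, variable, activity, stderr.
#' @export
as.data.frame.dose_response <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  do.call(rbind, lapply(seq_along(x$grid), function(i) {
    est <- x$estimates[[i]]
    data.frame(dose = x$grid[i], variable = names(est$activity),
               activity = unname(est$activity),
               stderr = unname(est$stderr), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Two-input environment sensitivity grid
#'
#' Estimates activity on the full `|grid| x |grid|` cross of doses for two
#' inputs (rows vary `input_x`, columns `input_y`), with every other
#' condition fixed by `clamped` and `base`. Deterministic under `seed`.
#'
#' @param model a [logical_model()].
#' @param input_x,input_y distinct input variables (absent from `clamped`).
#' @param grid numeric vector of doses in `[0, 1]`.
#' @param clamped named 0/1 clamp vector.
#' @param base named numeric vector of additional doses.
#' @param steps,runs,burn_in,seed as in [run_stochastic()].
#' @return object of class `sensitivity_grid`: list with `grid`, `inputs`,
#'   and `estimates` (matrix-shaped list indexed `[[ix]][[iy]]`).
#' @export
sensitivity_grid <- function(model, input_x, input_y, grid,
                             clamped = integer(), base = numeric(),
                             steps = 2000, runs = 50, burn_in = 500,
                             seed = 1) {
  if (identical(input_x, input_y)) stop("input_x and input_y must differ")
  if (any(c(input_x, input_y) %in% names(clamped))) {
    stop("grid inputs must not be clamped")
  }
  estimates <- lapply(seq_along(grid), function(ix) {
    lapply(seq_along(grid), function(iy) {
      doses <- base
      doses[input_x] <- grid[ix]
      doses[input_y] <- grid[iy]
      run_stochastic(model, doses = doses, perturbation = clamped,
                     steps = steps, runs = runs, burn_in = burn_in,
                     seed = as.integer(seed) +
                       (ix - 1L) * length(grid) + (iy - 1L))
    })
  })
  structure(list(grid = grid, inputs = c(input_x, input_y),
                 estimates = estimates),
            class = "sensitivity_grid")
}

#' Extract one variable's activity from a sensitivity grid
#' @param sens a `sensitivity_grid` object.
#' @param variable variable name.
#' @return numeric matrix (rows: `input_x` doses, cols: `input_y` doses).
#' @export
sensitivity_matrix <- function(sens, variable) {
  n <- length(sens$grid)
  m <- matrix(NA_real_, n, n,
              dimnames = list(as.character(sens$grid),
                              as.character(sens$grid)))
  for (ix in seq_len(n)) {
    for (iy in seq_len(n)) {
      m[ix, iy] <- sens$estimates[[ix]][[iy]]$activity[[variable]]
    }
  }
  m
}
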