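#' Load a scenario configuration
#'
#' Reads and validates a JSON scenario document with blocks \code{params},
#' \code{policy}, \code{init} and (optionally) \code{options},
#' \code{capacity_mode}, \code{name} and \code{assumed} (a list of field names
#' whose values are assumptions, not published facts). Unknown keys are
#' rejected; all violations are reported together with their field paths.
#'
#' @param path path to a JSON file
#' @return An object of class \code{nc_scenario}: list with \code{name},
#'   \code{params}, \code{policy}, \code{init}, \code{options},
#'   \code{capacity_mode}, \code{assumed}.
#' @examples
#' cfg <- load_scenario(system.file("extdata/scenarios/fig1a.json",
#'                                  package = "nomadcolony"))
#' cfg$params
#' @export
load_scenario <- function(path) {
  stop_unless(file.exists(path), paste0("config file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario_from_list(raw, where = path)
}

scenario_from_list <- function(raw, where = "config") {
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  known_top <- c("name", "params", "policy", "init", "options",
                 "capacity_mode", "assumed")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) note(paste0("unknown top-level keys: ",
                                 paste(extra, collapse = ", ")))
  for (blk in c("params", "policy", "init"))
    if (is.null(raw[[blk]])) note(paste0("missing block: ", blk))

  check_keys <- function(blk, allowed) {
    extra <- setdiff(names(raw[[blk]]), allowed)
    if (length(extra))
      note(paste0(blk, ": unknown keys: ", paste(extra, collapse = ", ")))
  }
  if (!is.null(raw$params)) check_keys("params", c("r1", "r2", "rs", "A", "Kmax"))
  if (!is.null(raw$policy))
    check_keys("policy", c("mode", "L1", "L2", "B", "B_margin"))
  if (!is.null(raw$init)) check_keys("init", c("n1", "n2", "K"))
  if (!is.null(raw$options))
    check_keys("options", c("t_end", "rtol", "atol", "max_step",
                            "extinction_floor", "n_out"))

  if (length(errs))
    stop("invalid scenario (", where, "):\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)

  pk <- raw$params
  Kmax <- pk$Kmax %||% Inf
  if (is.null(Kmax) || (is.character(Kmax) && Kmax == "unbounded")) Kmax <- Inf
  capacity_mode <- raw$capacity_mode %||%
    (if (is.finite(Kmax)) "bounded" else "unbounded")
  if (capacity_mode == "bounded" && !is.finite(Kmax))
    stop("invalid scenario (", where,
         "): capacity_mode 'bounded' requires a finite params.Kmax",
         call. = FALSE)
  if (capacity_mode == "unbounded" && is.finite(Kmax))
    stop("invalid scenario (", where,
         "): capacity_mode 'unbounded' conflicts with a finite params.Kmax",
         call. = FALSE)

  params <- tryCatch(
    nc_params(r1 = pk$r1, r2 = pk$r2, rs = pk$rs %||% 0, A = pk$A, Kmax = Kmax),
    error = function(e) stop("invalid scenario (", where, "): params: ",
                             conditionMessage(e), call. = FALSE))
  policy <- tryCatch(
    switch_policy(raw$policy$mode %||% "none", L1 = raw$policy$L1,
                  L2 = raw$policy$L2, B = raw$policy$B,
                  B_margin = raw$policy$B_margin %||% 0.05),
    error = function(e) stop("invalid scenario (", where, "): policy: ",
                             conditionMessage(e), call. = FALSE))
  init <- tryCatch(
    sim_state(n1 = raw$init$n1, n2 = raw$init$n2, K = raw$init$K),
    error = function(e) stop("invalid scenario (", where, "): init: ",
                             conditionMessage(e), call. = FALSE))
  op <- raw$options %||% list()
  options <- tryCatch(
    sim_options(t_end = op$t_end %||% 50,
                rtol = op$rtol %||% 1e-9, atol = op$atol %||% 1e-9,
                max_step = op$max_step,
                extinction_floor = op$extinction_floor %||% 1e-6,
                n_out = op$n_out %||% 2001),
    error = function(e) stop("invalid scenario (", where, "): options: ",
                             conditionMessage(e), call. = FALSE))

  structure(list(name = raw$name %||% "scenario", params = params,
                 policy = policy, init = init, options = options,
                 capacity_mode = capacity_mode,
                 assumed = as.character(raw$assumed %||% character(0))),
            class = "nc_scenario")
}

#' @export
print.nc_scenario <- function(x, ...) {
  cat("<nc_scenario>", x$name, "-", x$policy$mode, "policy,",
      x$capacity_mode, "capacity, t_end =", x$options$t_end, "\n")
  invisible(x)
}

#' Shipped figure scenarios
#'
#' The package ships the parameter sets of the published simulation figures as
#' JSON fixtures under \code{inst/extdata/scenarios}. Values not printed in a
#' caption (the Allee capacity of the fig2 pair, the fig6 initial conditions)
#' are recorded in the fixture's \code{assumed} field.
#'
#' @param name one of \code{"fig1a"}, \code{"fig1b"}, \code{"fig2a"},
#'   \code{"fig2b"}, \code{"fig3"}, \code{"fig4"}, \code{"fig5"},
#'   \code{"fig6a"}, \code{"fig6b"}, \code{"fig7a"}, \code{"fig7b"}
#' @return An \code{nc_scenario}.
#' @examples
#' nc_scenario("fig2b")
#' @export
nc_scenario <- function(name) {
  path <- system.file("extdata", "scenarios", paste0(name, ".json"),
                      package = "nomadcolony")
  if (!nzchar(path))
    stop("unknown scenario '", name, "'; see ?nc_scenario for the list",
         call. = FALSE)
  load_scenario(path)
}

#' Run a scenario end-to-end
#'
#' @param scenario an \code{nc_scenario}, or the name of a shipped fixture
#' @param t_end,rtol,atol optional overrides of the scenario's options
#' @return A list with elements \code{trajectory} (\code{nc_trajectory}) and
#'   \code{regime} (character label from [classify_regime]).
#' @examples
#' \donttest{
#' res <- run_scenario("fig1b")
#' res$regime
#' }
#' @export
run_scenario <- function(scenario, t_end = NULL, rtol = NULL, atol = NULL) {
  if (is.character(scenario)) scenario <- nc_scenario(scenario)
  stopifnot(inherits(scenario, "nc_scenario"))
  op <- scenario$options
  if (!is.null(t_end) || !is.null(rtol) || !is.null(atol))
    op <- sim_options(t_end = t_end %||% op$t_end,
                      rtol = rtol %||% op$rtol, atol = atol %||% op$atol,
                      max_step = op$max_step,
                      extinction_floor = op$extinction_floor,
                      n_out = op$n_out)
  traj <- nc_simulate(scenario$params, scenario$policy, scenario$init, op)
  list(trajectory = traj, regime = classify_regime(traj))
}

#' Sweep a switching level across a scenario
#'
#' Re-runs a fixed-policy scenario over a grid of values of one switching
#' level and classifies each outcome; used to locate the empirical
#' survival/extinction boundary and compare it with the analytic bound.
#'
#' @param scenario an \code{nc_scenario} or fixture name (fixed policy)
#' @param vary which level to vary: \code{"L2"} or \code{"L1"}
#' @param values numeric grid of values
#' @return Data frame with columns \code{L1}, \code{L2}, \code{regime}.
#' @export
sweep_scenario <- function(scenario, vary = c("L2", "L1"), values) {
  if (is.character(scenario)) scenario <- nc_scenario(scenario)
  vary <- match.arg(vary)
  stop_unless(scenario$policy$mode == "fixed",
              "sweeps are defined for fixed-threshold policies")
  rows <- lapply(values, function(v) {
    pol <- scenario$policy
    pol[[vary]] <- v
    pol <- switch_policy("fixed", L1 = pol$L1, L2 = pol$L2)
    traj <- nc_simulate(scenario$params, pol, scenario$init, scenario$options)
    data.frame(L1 = pol$L1, L2 = pol$L2, regime = classify_regime(traj),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ------------------------------------------------------------------------
## trajectory serialisation: full-precision CSV + manifest, exact round-trip

fmt17 <- function(x) sprintf("%.17g", x)

write_csv_precise <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt17)
  tmp <- paste0(path, ".tmp")
  utils::write.table(out, tmp, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  file.rename(tmp, path)
}

#' Write a trajectory to disk
#'
#' Emits \code{trajectory.csv} (columns \code{t, n1, n2, K, phase}),
#' \code{events.csv} (\code{t, event_type, n1, n2, K}) and
#' \code{manifest.json} (scenario echo and solver statistics) into a
#' directory. Numbers are written with 17 significant digits so that
#' [read_trajectory] round-trips exactly; files are written atomically via a
#' temporary name.
#'
#' @param traj an \code{nc_trajectory}
#' @param dir output directory (created if needed)
#' @param name scenario name recorded in the manifest
#' @param assumed character vector of assumed fields for the manifest
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(traj, dir, name = "run",
                             assumed = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- as.data.frame(traj)
  write_csv_precise(tr, file.path(dir, "trajectory.csv"))
  ev <- traj$events
  ev_out <- data.frame(t = ev$time, event_type = ev$type, n1 = ev$n1,
                       n2 = ev$n2, K = ev$K, stringsAsFactors = FALSE)
  write_csv_precise(ev_out, file.path(dir, "events.csv"))

  manifest <- list(
    name = name,
    params = traj$params[c("r1", "r2", "rs", "A")],
    Kmax = if (is.finite(traj$params$Kmax)) traj$params$Kmax else "unbounded",
    policy = Filter(Negate(is.null), unclass(traj$policy)),
    init = unclass(traj$init),
    options = unclass(traj$options)[c("t_end", "rtol", "atol",
                                      "extinction_floor", "n_out")],
    assumed = assumed,
    solver = list(n_segments = traj$n_segments, n_events = nrow(ev),
                  n_samples = length(traj$times))
  )
  mpath <- file.path(dir, "manifest.json")
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, mpath)
  invisible(file.path(dir, c("trajectory.csv", "events.csv", "manifest.json")))
}

#' Read back a written trajectory
#'
#' @param dir directory written by [write_trajectory]
#' @return A list with data frames \code{trajectory}, \code{events} and the
#'   parsed \code{manifest}.
#' @export
read_trajectory <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "trajectory.csv"),
                        stringsAsFactors = FALSE)
  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(t = "numeric", event_type = "character",
                                       n1 = "numeric", n2 = "numeric",
                                       K = "numeric"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  list(trajectory = tr, events = ev, manifest = man)
}
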