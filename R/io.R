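#' Game JSON format
#'
#' Games are serialized as
#' `{"loci": [...], "alleles": {locus: [allele, ...]}, "fitness":
#' {"<allele,allele,...>": number}}` with fitness keys comma-joined in
#' locus order. The loader is strict: every genotype of the product space
#' must appear exactly once, every value must be strictly positive, and no
#' unknown keys are accepted.
#'
#' @name game_json
NULL

#' Read a game from JSON
#'
#' @param path File path.
#' @return A `ci_game`.
#' @seealso [game_json], [write_game()]
#' @export
read_game <- function(path) {
  if (!file.exists(path)) stop(sprintf("game file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.list(x) || is.null(x$loci) || is.null(x$alleles) ||
      is.null(x$fitness))
    stop(sprintf("malformed game file %s: needs 'loci', 'alleles', 'fitness'",
                 path))
  loci <- unlist(x$loci)
  if (!is.character(loci) || !length(loci))
    stop("malformed 'loci': expected a non-empty array of labels")
  if (!setequal(names(x$alleles), loci))
    stop("'alleles' must have exactly one entry per locus")
  al <- lapply(x$alleles[loci], function(a) unlist(a))
  formation <- allelic_formation(stats::setNames(al, loci))
  fit <- x$fitness
  if (is.null(names(fit))) stop("'fitness' must be keyed by genotype")
  vals <- vapply(fit, function(v) {
    if (!is.numeric(v) || length(v) != 1L)
      stop("fitness values must be single numbers")
    as.numeric(v)
  }, numeric(1L))
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad))
    stop(sprintf("non-positive or non-finite fitness for genotype(s): %s",
                 paste(bad, collapse = "; ")))
  # common_interests_game reports missing/extra genotype keys by name
  common_interests_game(formation, vals)
}

#' Write a game to JSON
#'
#' Serializes in the strict format read by [read_game()]; the round trip is
#' bit-identical.
#'
#' @param game A `ci_game`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_game <- function(game, path) {
  stop_if_not_game(game)
  obj <- list(loci = game$formation$loci,
              alleles = game$formation$alleles,
              fitness = as.list(game$fitness))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# short stable digest of a game (polynomial hash of a canonical
# description, modulo a Mersenne prime); identifies the game in trajectory
# headers and run records
game_digest <- function(game) {
  s <- paste(c(game$formation$loci,
               unlist(game$formation$alleles),
               sprintf("%.17g", unname(game$fitness))), collapse = "|")
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a trajectory as CSV
#'
#' Columns: `t`, one frequency column per coordinate (`locus:allele` for
#' sexual mode, genotype key for asexual), and `mean_fitness`. A leading
#' comment line records the game digest and mode.
#'
#' @param traj An `evo_trajectory`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!inherits(traj, "evo_trajectory")) stop("expected an `evo_trajectory`")
  df <- data.frame(t = traj$times, traj$states,
                   mean_fitness = traj$mean_fitness, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# game=%s mode=%s converged=%s",
                     game_digest(traj$game), traj$mode, traj$converged), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path File written by [write_trajectory_csv()].
#' @return Data frame of the trajectory table, with the header metadata in
#'   attribute `"header"`.
#' @export
read_trajectory_csv <- function(path) {
  header <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  attr(df, "header") <- sub("^# ", "", header)
  df
}

#' Write a scenario as a run-config YAML
#'
#' Serializes an [example_scenario()] as a plain run configuration: game
#' parameters, initial weights, scripted mutations and expected outcome
#' labels. Requires the `yaml` package.
#'
#' @param scenario A `scenario`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(scenario, path) {
  if (!inherits(scenario, "scenario")) stop("expected a `scenario`")
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("`write_scenario_yaml` requires the 'yaml' package")
  obj <- list(name = scenario$name,
              order = scenario$order,
              delta = scenario$delta,
              eps = scenario$eps,
              loci = scenario$formation$loci,
              alleles = scenario$formation$alleles,
              initial_weights = as.list(scenario$initial_p),
              script = scenario$script,
              non_novel = if (is.null(scenario$non_novel)) NULL
                          else paste(scenario$non_novel, collapse = ","),
              expected = scenario$expected)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Write a run record as JSON
#'
#' A self-describing record of a PDMP run: rate, injection frequency, game
#' digests, the event table with classifications and pre/post equilibria,
#' and the equilibrium fitness snapshots. With the same seed and
#' configuration the record is byte-identical across runs.
#'
#' @param run A `pdmp_run`.
#' @param path File path.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(run, path, seed = NULL) {
  if (!inherits(run, "pdmp_run")) stop("expected a `pdmp_run`")
  obj <- list(seed = seed,
              lambda = run$lambda,
              eps_mut = run$eps_mut,
              universe_digest = game_digest(run$universe),
              n_events = nrow(run$events),
              events = run$events,
              snapshots = equilibrium_snapshots(run),
              final_equilibrium = run$final$eq,
              final_fitness = run$final$eq_fitness)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
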