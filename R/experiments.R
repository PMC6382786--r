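#' Simulation configuration
#'
#' Bundles and validates the parameters of one simulation cell. Defaults
#' follow the standard study conditions: social capacity `nu = 60`
#' contacts, 100 founders, fertility swept over 2.5-5.0 children per
#' couple, target population sizes 500 or 2000, gossip probability
#' `alpha = 0.1`, forgiving probability `pi = 0.5`, 400 replicates per
#' cell in full runs.
#'
#' @param kappa Mean fertility per pair.
#' @param n_target Final generation size.
#' @param nu Social capacity (must be below `n_target`).
#' @param n_founders Founder count.
#' @param alpha Gossip probability.
#' @param pi Forgiving probability or `NULL` (no forgiving).
#' @param replicates Networks per cell.
#' @param max_rounds Reputation round budget.
#' @param variant Gossip update variant, see [gossip_round()].
#' @param seed Master seed; per-replicate seeds are derived with
#'   [derive_seed()] so any replicate is reproducible in isolation.
#' @param max_restarts Friend-completion restart budget.
#' @param max_generations Pedigree generation budget.
#' @param retries Fresh-seed retries per replicate on population collapse.
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(kappa = 2.5, n_target = 500, nu = 60,
                       n_founders = 100, alpha = 0.1, pi = 0.5,
                       replicates = 400, max_rounds = 100,
                       variant = "shared_acquaintance", seed = 1,
                       max_restarts = 50, max_generations = 60,
                       retries = 20) {
  cfg <- list(kappa = kappa, n_target = as.integer(n_target),
              nu = as.integer(nu), n_founders = as.integer(n_founders),
              alpha = alpha, pi = pi,
              replicates = as.integer(replicates),
              max_rounds = as.integer(max_rounds), variant = variant,
              seed = as.integer(seed),
              max_restarts = as.integer(max_restarts),
              max_generations = as.integer(max_generations),
              retries = as.integer(retries))
  if (cfg$kappa <= 0) stop_kinnet("kappa must be positive",
                                  "kinnet_invalid_argument")
  if (cfg$nu >= cfg$n_target)
    stop_kinnet("nu must be below n_target", "kinnet_invalid_argument")
  if (cfg$alpha < 0 || cfg$alpha > 1)
    stop_kinnet("alpha must be in [0, 1]", "kinnet_invalid_argument")
  if (!is.null(cfg$pi) && (cfg$pi < 0 || cfg$pi > 1))
    stop_kinnet("pi must be in [0, 1] or NULL", "kinnet_invalid_argument")
  if (cfg$replicates < 0)
    stop_kinnet("replicates must be non-negative", "kinnet_invalid_argument")
  if (cfg$n_founders < 2 || cfg$max_rounds < 1 || cfg$retries < 1)
    stop_kinnet("sizes must be positive", "kinnet_invalid_argument")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config: kappa = %g, n = %d, nu = %d, alpha = %g, pi = %s, %d reps, seed %d>\n",
    x$kappa, x$n_target, x$nu, x$alpha,
    if (is.null(x$pi)) "none" else format(x$pi), x$replicates, x$seed))
  invisible(x)
}

#' Build a library of simulated populations and networks
#'
#' For each replicate: simulate a pedigree to the target size, build the
#' kin graph, truncate to capacity, complete with random friends to a
#' uniform-degree social network, and (optionally) summarise its
#' structure. Each replicate runs under its own seed derived from the
#' master seed; a replicate whose population collapses is retried with a
#' fresh derived seed (up to `config$retries` attempts, attempts logged).
#'
#' @param config A `sim_config`.
#' @param metrics Compute a [network_summary()] per replicate?
#' @param max_steps Step-count horizon for the summaries.
#' @param keep_networks Keep the `social_network` objects (set `FALSE` to
#'   save memory when only the summary table is needed).
#' @return An object of class `sim_library`: a list of replicate records,
#'   each with `replicate`, `seed`, `attempts`, `n_generations`,
#'   `dg_pre`, `dg_post`, `fertility`, and (as requested) `network` and
#'   `summary`; the `config` is attached as an attribute.
#' @section Errors: if more than half of the replicates fail despite
#'   retries, a `kinnet_configuration_error` is raised.
#' @export
build_library <- function(config, metrics = TRUE, max_steps = 6,
                          keep_networks = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  out <- vector("list", config$replicates)
  failed <- 0L
  for (r in seq_len(config$replicates)) {
    rec <- NULL
    for (attempt in seq_len(config$retries)) {
      s <- derive_seed(config$seed,
                       (r - 1L) * (config$retries + 1L) + attempt)
      rec <- tryCatch(
        build_one_replicate(config, s, metrics, max_steps, keep_networks),
        kinnet_extinction_error = function(e) NULL,
        kinnet_convergence_error = function(e) NULL,
        kinnet_completion_error = function(e) NULL)
      if (!is.null(rec)) {
        rec$replicate <- r
        rec$attempts <- attempt
        break
      }
    }
    if (is.null(rec)) failed <- failed + 1L
    out[[r]] <- rec
  }
  if (config$replicates > 0L && failed / config$replicates > 0.5)
    stop_kinnet(sprintf("%d of %d replicates failed; configuration unviable",
                        failed, config$replicates),
                "kinnet_configuration_error")
  out <- out[!vapply(out, is.null, logical(1L))]
  structure(out, class = "sim_library", config = config, failed = failed)
}

build_one_replicate <- function(config, seed, metrics, max_steps,
                                keep_networks) {
  set.seed(seed)
  gen <- simulate_pedigree(config$kappa, config$n_target,
                           n_founders = config$n_founders,
                           max_generations = config$max_generations)
  kin <- build_kin_adjacency(gen)
  dg_pre <- mean_kin_degree(kin)
  kin <- truncate_kin_degree(kin, config$nu)
  dg_post <- mean_kin_degree(kin)
  sn <- add_random_friends(kin, config$nu,
                           max_restarts = config$max_restarts)
  summ <- if (metrics) network_summary(sn, max_steps = max_steps) else NULL
  list(seed = seed, n_generations = attr(gen, "n_generations"),
       dg_pre = dg_pre, dg_post = dg_post,
       fertility = classify_fertility_regime(dg_post, config$nu),
       network = if (keep_networks) sn else NULL,
       summary = summ)
}

#' @export
print.sim_library <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<sim_library: %d replicates (kappa = %g, n = %d, nu = %d), %d failed>\n",
    length(x), cfg$kappa, cfg$n_target, cfg$nu, attr(x, "failed")))
  invisible(x)
}

#' Tabulate the structural summaries of a library
#'
#' One row per replicate: seed, cell parameters, mean kin degree before
#' and after truncation, fertility class, mean clustering, mean graph
#' distance, connectedness, and the mean step counts `step0`, `step1`,
#' ... as far as the summaries carry them.
#'
#' @param library A `sim_library` built with `metrics = TRUE`.
#' @return A data frame in long (replicate-per-row) format.
#' @export
structure_table <- function(library) {
  stopifnot(inherits(library, "sim_library"))
  cfg <- attr(library, "config")
  if (length(library) == 0L) {
    return(data.frame(kappa = numeric(0), n = integer(0), nu = integer(0),
                      replicate = integer(0), seed = integer(0)))
  }
  rows <- lapply(library, function(rec) {
    if (is.null(rec$summary))
      stop_kinnet("library built without metrics", "kinnet_invalid_argument")
    steps <- rec$summary$step_counts
    names(steps) <- paste0("step", names(steps))
    cbind(data.frame(kappa = cfg$kappa, n = cfg$n_target, nu = cfg$nu,
                     replicate = rec$replicate, seed = rec$seed,
                     attempts = rec$attempts,
                     n_generations = rec$n_generations,
                     dg_pre = rec$dg_pre, dg_post = rec$dg_post,
                     fertility = rec$fertility,
                     chi = rec$summary$mean_clustering,
                     delta = rec$summary$mean_distance,
                     connected = rec$summary$connected),
          as.data.frame(as.list(steps)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run reputation dynamics over a library
#'
#' Runs `runs` reputation trajectories on every network of the library
#' and tabulates their summaries: time to inform half of the focal's
#' contacts (censored at `max_rounds` when never reached, with a
#' `reached_half` flag), final extent as a fraction of the focal's
#' contacts and of all agents, and the extinction round for forgiving
#' runs.
#'
#' @param library A `sim_library` built with `keep_networks = TRUE`.
#' @param alpha Gossip probability (default from the library config).
#' @param pi Forgiving probability or `NULL`; default from the config.
#' @param max_rounds,variant Overrides of the config values.
#' @param runs Trajectories per network (default 2).
#' @param seed Master seed for trajectory seeds (default config seed).
#' @return A data frame, one row per trajectory.
#' @export
reputation_table <- function(library, alpha = NULL, pi = NULL,
                             max_rounds = NULL, variant = NULL, runs = 2,
                             seed = NULL) {
  stopifnot(inherits(library, "sim_library"))
  cfg <- attr(library, "config")
  if (is.null(alpha)) alpha <- cfg$alpha
  if (missing(pi)) pi <- cfg$pi
  if (is.null(max_rounds)) max_rounds <- cfg$max_rounds
  if (is.null(variant)) variant <- cfg$variant
  if (is.null(seed)) seed <- cfg$seed
  rows <- list()
  for (rec in library) {
    if (is.null(rec$network))
      stop_kinnet("library built without networks", "kinnet_invalid_argument")
    for (run in seq_len(runs)) {
      s <- derive_seed(seed, rec$replicate * 1000L + run)
      traj <- run_reputation(rec$network, alpha = alpha, pi = pi,
                             max_rounds = max_rounds, variant = variant,
                             seed = s)
      final <- traj$counts[nrow(traj$counts), ]
      rows[[length(rows) + 1L]] <- data.frame(
        kappa = cfg$kappa, n = cfg$n_target, nu = cfg$nu,
        replicate = rec$replicate, run = run, seed = s,
        dg_post = rec$dg_post, fertility = rec$fertility,
        alpha = alpha, pi = if (is.null(pi)) NA_real_ else pi,
        variant = variant,
        reached_half = !is.na(traj$time_to_half),
        time_to_half = if (is.na(traj$time_to_half)) max_rounds
                       else traj$time_to_half,
        final_contact_fraction = final$informed_contacts / traj$n_contacts,
        final_total_fraction = final$informed_total /
          (length(rec$network$agent_ids) - 1L),
        extinct = !is.na(traj$extinction_round),
        extinction_round = traj$extinction_round)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep network structure over a fertility-by-size grid
#'
#' Builds one library per `(kappa, n_target)` cell and stacks their
#' [structure_table()] rows — the replicate-level data behind the
#' clustering, distance and step-count comparisons.
#'
#' @param config Base `sim_config` (its `kappa`/`n_target` are replaced
#'   cell by cell; each cell gets its own seed derived from the master).
#' @param kappas Fertility grid.
#' @param n_targets Group size grid.
#' @param max_steps Step-count horizon.
#' @return A long-format data frame.
#' @export
sweep_structure <- function(config, kappas = c(2.5, 5),
                            n_targets = c(500, 2000), max_steps = 6) {
  stopifnot(inherits(config, "sim_config"))
  cells <- expand.grid(kappa = kappas, n = n_targets)
  tabs <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- config
    cfg$kappa <- cells$kappa[i]
    cfg$n_target <- as.integer(cells$n[i])
    cfg$seed <- derive_seed(config$seed, 100000L + i)
    lib <- build_library(cfg, metrics = TRUE, max_steps = max_steps,
                         keep_networks = FALSE)
    structure_table(lib)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Sweep reputation dynamics over a fertility-by-size grid
#'
#' Builds one library per cell and runs reputation trajectories on every
#' network, returning the stacked [reputation_table()] rows. Fertility
#' class per replicate comes from its post-truncation mean kin degree.
#'
#' @inheritParams sweep_structure
#' @param runs Trajectories per network.
#' @return A long-format data frame.
#' @export
sweep_reputation <- function(config, kappas = c(2.5, 5),
                             n_targets = c(500, 2000), runs = 2) {
  stopifnot(inherits(config, "sim_config"))
  cells <- expand.grid(kappa = kappas, n = n_targets)
  tabs <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- config
    cfg$kappa <- cells$kappa[i]
    cfg$n_target <- as.integer(cells$n[i])
    cfg$seed <- derive_seed(config$seed, 200000L + i)
    lib <- build_library(cfg, metrics = FALSE, keep_networks = TRUE)
    reputation_table(lib, runs = runs)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
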