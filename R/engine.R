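#' Simulation configuration
#'
#' Bundles the grid, the strain specifications, the per-molecule diffusion
#' parameters and the run settings. Any molecule produced or sensed by a
#' strain that has no explicit entry in `diffusion` gets AHL defaults
#' (D = 8e-10 m^2/s) for QSMM strains or the metabolite diffusivity
#' (D = 5e-10 m^2/s) for molecules produced by MMM strains, with the grid's
#' square length and the configured time step.
#'
#' @param grid A [create_grid()] grid (its occupancy is ignored; seeding is
#'   described by `pattern`).
#' @param strains List of [strain_spec()] objects (e.g. from
#'   [make_consortium()]).
#' @param pattern A [seed_patterns] object describing the initial
#'   configuration.
#' @param n_steps Number of simulation steps (>= 0); each step is
#'   `dt_min` minutes.
#' @param seed Integer RNG seed; the whole trajectory is reproducible from it.
#' @param diffusion Optional named list of [diffusion_params()] keyed by
#'   molecule id, overriding the defaults.
#' @param dt_min Time step in minutes (default 10).
#' @param snapshot_every Record grid snapshots every this many steps
#'   (0 = never).
#' @param update_order `"shuffled"` (asynchronous: occupied squares divide in
#'   a freshly shuffled order, each division taking effect immediately) or
#'   `"synchronous_lottery"` (all parents draw against start-of-step occupancy
#'   and conflicting claims on one empty square are resolved by lottery).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(grid, strains, pattern, n_steps, seed = 1L,
                              diffusion = list(), dt_min = 10,
                              snapshot_every = 0,
                              update_order = c("shuffled", "synchronous_lottery")) {
  update_order <- match.arg(update_order)
  stopifnot(inherits(grid, "ca_grid"), inherits(pattern, "seed_pattern"))
  if (n_steps < 0 || n_steps != floor(n_steps))
    stop("n_steps must be a non-negative integer", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer", call. = FALSE)
  if (!all(vapply(strains, inherits, TRUE, "strain_spec")))
    stop("`strains` must be a list of strain_spec objects", call. = FALSE)
  ids <- vapply(strains, `[[`, "", "strain_id")
  if (anyDuplicated(ids)) stop("duplicate strain ids", call. = FALSE)
  names(strains) <- ids

  produced <- vapply(strains, `[[`, "", "produced")
  sensed <- vapply(strains, `[[`, "", "sensed")
  molecules <- unique(c(produced, sensed))
  for (m in molecules) {
    if (is.null(diffusion[[m]])) {
      mmm <- any(vapply(strains, function(s)
        s$produced == m && s$model_kind == "MMM", TRUE))
      diffusion[[m]] <- diffusion_params(
        D_m2_per_s = if (mmm) 5e-10 else 8e-10,
        dt_min = dt_min, dL_mm = grid$square_length)
    }
    st <- check_stability(diffusion[[m]])
    if (!st$pass)
      stop(sprintf("diffusion of '%s' violates the FTCS stability criterion: s = %.4g > 0.25",
                   m, st$s), call. = FALSE)
  }
  structure(list(grid = grid, strains = strains, pattern = pattern,
                 molecules = molecules, diffusion = diffusion,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 dt_min = dt_min, snapshot_every = as.integer(snapshot_every),
                 update_order = update_order),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %dx%d grid, %d strains (%s), %d steps of %g min, seed %d\n",
              x$grid$width, x$grid$height, length(x$strains),
              paste(names(x$strains), collapse = ", "),
              x$n_steps, x$dt_min, x$seed))
  for (m in x$molecules)
    cat(sprintf("  %s: s = %.4g\n", m, x$diffusion[[m]]$s))
  invisible(x)
}

#' Initial simulation state
#'
#' Seeds the configured pattern onto the grid and creates one zero
#' concentration field per molecule.
#'
#' @param config A [simulation_config()].
#' @return A `ca_state` list with elements `grid`, `fields` (named list of
#'   [ahl_field()]) and `step` (0).
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- seed_grid(config$grid, config$pattern)
  # register all configured strains even if the pattern seeds only a subset
  for (id in names(config$strains))
    if (!id %in% grid$strain_ids) grid$strain_ids <- c(grid$strain_ids, id)
  fields <- stats::setNames(
    lapply(config$molecules, function(m) ahl_field(grid, m)), config$molecules)
  structure(list(grid = grid, fields = fields, step = 0L), class = "ca_state")
}

# per-strain parameter tables aligned to grid$strain_ids codes
strain_tables <- function(config, grid) {
  ids <- grid$strain_ids
  sp <- config$strains[ids]
  list(ids = ids,
       produced = vapply(sp, `[[`, "", "produced"),
       sensed = vapply(sp, `[[`, "", "sensed"),
       rate = vapply(sp, `[[`, 0, "secretion_rate"),
       threshold = vapply(sp, `[[`, 0, "threshold"),
       base = vapply(sp, `[[`, 0, "base_fitness"),
       gain = vapply(sp, `[[`, 0, "fitness_gain"))
}

#' Advance the simulation by one step
#'
#' Per step: every molecule field is updated (secretion by producing blocks,
#' one FTCS diffusion step, one decay step); then each occupied square,
#' visited in a freshly shuffled order, divides with probability equal to its
#' current fitness into an empty von Neumann neighbour chosen uniformly at the
#' moment of division. Fitness reads the freshly updated fields. Blocks
#' created within a step do not divide in that step; blocks with no empty
#' neighbour cannot divide. No block is ever removed or overwritten.
#'
#' Uses the current R RNG stream: seed it (or use [run_simulation()], which
#' seeds from the config) for reproducibility.
#'
#' @param state A `ca_state` from [init_state()] or a previous step.
#' @param config The [simulation_config()].
#' @return The updated state; attribute `"events"` holds a data.frame of the
#'   step's division events (`strain`, `parent_x`, `parent_y`, `child_x`,
#'   `child_y`, 0-based).
#' @export
ca_step <- function(state, config) {
  stopifnot(inherits(state, "ca_state"))
  tab <- strain_tables(config, state$grid)
  occ <- state$grid$occupancy
  h <- nrow(occ); w <- ncol(occ)

  # --- field updates: secretion -> diffusion -> decay ---
  for (m in config$molecules) {
    U <- state$fields[[m]]$conc
    pars <- config$diffusion[[m]]
    prod_codes <- which(tab$produced == m & tab$rate > 0)
    for (k in prod_codes) {
      sel <- occ == k
      U[sel] <- U[sel] + tab$rate[k] * pars$dt_min
    }
    U <- U + pars$s * stencil_sum(U, pars$boundary)
    U <- U * (1 - pars$decay_k_per_min * pars$dt_min)
    state$fields[[m]]$conc <- U
  }

  # --- division phase ---
  idx <- which(occ != 0L)            # linear indices, column-major: (x-1)*h + y
  n0 <- length(idx)
  ev <- NULL
  if (n0 > 0L) {
    ks <- occ[idx]
    conc <- numeric(n0)
    for (m in unique(tab$sensed)) {
      sel <- tab$sensed[ks] == m
      if (any(sel)) conc[sel] <- state$fields[[m]]$conc[idx[sel]]
    }
    fit <- pmin(1, tab$base[ks] + tab$gain[ks] * (conc > tab$threshold[ks]))

    ord <- sample.int(n0)
    draws <- stats::runif(n0) < fit[ord]
    parents <- integer(n0); children <- integer(n0); strains <- integer(n0); ne <- 0L

    if (config$update_order == "shuffled") {
      for (i in seq_len(n0)) {
        if (!draws[i]) next
        b <- ord[i]
        p <- idx[b]
        y <- (p - 1L) %% h + 1L; x <- (p - 1L) %/% h + 1L
        cand <- c(if (y > 1L) p - 1L, if (y < h) p + 1L,
                  if (x > 1L) p - h, if (x < w) p + h)
        emp <- cand[occ[cand] == 0L]
        if (length(emp) == 0L) next
        child <- if (length(emp) == 1L) emp else emp[sample.int(length(emp), 1L)]
        occ[child] <- ks[b]
        ne <- ne + 1L
        parents[ne] <- p; children[ne] <- child; strains[ne] <- ks[b]
      }
    } else {
      # synchronous lottery: claims against start-of-step occupancy,
      # one winner per contested empty square (processed in shuffled order)
      claims_p <- integer(0); claims_c <- integer(0); claims_k <- integer(0)
      for (i in seq_len(n0)) {
        if (!draws[i]) next
        b <- ord[i]
        p <- idx[b]
        y <- (p - 1L) %% h + 1L; x <- (p - 1L) %/% h + 1L
        cand <- c(if (y > 1L) p - 1L, if (y < h) p + 1L,
                  if (x > 1L) p - h, if (x < w) p + h)
        emp <- cand[occ[cand] == 0L]
        if (length(emp) == 0L) next
        child <- if (length(emp) == 1L) emp else emp[sample.int(length(emp), 1L)]
        claims_p <- c(claims_p, p); claims_c <- c(claims_c, child)
        claims_k <- c(claims_k, ks[b])
      }
      keep <- !duplicated(claims_c)    # first claim in shuffled order wins
      for (j in which(keep)) {
        occ[claims_c[j]] <- claims_k[j]
        ne <- ne + 1L
        parents[ne] <- claims_p[j]; children[ne] <- claims_c[j]
        strains[ne] <- claims_k[j]
      }
    }
    if (ne > 0L) {
      pp <- parents[seq_len(ne)]; cc <- children[seq_len(ne)]
      ev <- data.frame(
        strain = state$grid$strain_ids[strains[seq_len(ne)]],
        parent_x = (pp - 1L) %/% h, parent_y = (pp - 1L) %% h,
        child_x = (cc - 1L) %/% h, child_y = (cc - 1L) %% h)
    }
  }
  state$grid$occupancy <- occ
  state$step <- state$step + 1L
  attr(state, "events") <- ev
  state
}

#' Run a simulation
#'
#' Applies [ca_step()] `n_steps` times from the seeded initial state, under
#' `set.seed(config$seed)`: identical seeds give bit-identical trajectories.
#'
#' @param config A [simulation_config()].
#' @return A `ca_trajectory` with elements:
#'   * `counts`: data.frame (`step`, `strain`, `count`), step 0 = seeding;
#'   * `events`: data.frame of all division events with their step;
#'   * `final`: the final `ca_state`;
#'   * `snapshots`: list of occupancy matrices (if requested);
#'   * `seed`, `n_steps`, `dt_min`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  state <- init_state(config)
  ids <- state$grid$strain_ids
  count_of <- function(g) vapply(seq_along(ids), function(k) sum(g$occupancy == k), 0L)
  counts <- matrix(0L, config$n_steps + 1L, length(ids),
                   dimnames = list(NULL, ids))
  counts[1L, ] <- count_of(state$grid)
  events <- vector("list", config$n_steps)
  snapshots <- list()
  with_local_seed(config$seed, {
    for (t in seq_len(config$n_steps)) {
      state <- ca_step(state, config)
      counts[t + 1L, ] <- count_of(state$grid)
      ev <- attr(state, "events")
      if (!is.null(ev)) { ev$step <- t; events[[t]] <- ev }
      if (config$snapshot_every > 0L && t %% config$snapshot_every == 0L)
        snapshots[[as.character(t)]] <- state$grid$occupancy
    }
  })
  events <- do.call(rbind, events[!vapply(events, is.null, TRUE)])
  if (is.null(events))
    events <- data.frame(strain = character(0), parent_x = integer(0),
                         parent_y = integer(0), child_x = integer(0),
                         child_y = integer(0), step = integer(0))
  counts_df <- data.frame(
    step = rep(0:config$n_steps, times = length(ids)),
    strain = rep(ids, each = config$n_steps + 1L),
    count = as.vector(counts))
  structure(list(counts = counts_df, events = events, final = state,
                 snapshots = snapshots, seed = config$seed,
                 n_steps = config$n_steps, dt_min = config$dt_min),
            class = "ca_trajectory")
}

#' @export
print.ca_trajectory <- function(x, ...) {
  fin <- x$counts[x$counts$step == x$n_steps, ]
  cat(sprintf("<ca_trajectory> %d steps (%g min), seed %d\n",
              x$n_steps, x$n_steps * x$dt_min, x$seed))
  cat("  final counts:",
      paste(sprintf("%s = %d", fin$strain, fin$count), collapse = ", "), "\n")
  invisible(x)
}

#' Final population counts of a trajectory
#'
#' @param traj A `ca_trajectory`.
#' @return Named integer vector of final cell-block counts per strain.
#' @export
final_counts <- function(traj) {
  fin <- traj$counts[traj$counts$step == traj$n_steps, ]
  stats::setNames(fin$count, fin$strain)
}

# derive a per-run seed from a root seed (kept below 2^31)
derive_seed <- function(root, i) {
  as.integer((as.double(root) * 48271 + i * 16807) %% 2147483647)
}
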