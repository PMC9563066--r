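#' Sender/receiver band-pass patterning assay
#'
#' Deterministic reaction-diffusion assay: sender cell-blocks at the grid
#' centre secrete a signal into a static lawn of receiver blocks filling every
#' other square; receivers express a fluorescent reporter only while the local
#' concentration lies inside the band-pass window. No growth occurs (the lawn
#' is full and receivers have fitness 0), so the run is fully deterministic:
#' each step is secretion, one FTCS diffusion step and one decay step, after
#' which the fluorescence mask is recorded.
#'
#' The pattern is called stable at the first step of a run of
#' `stability_window` consecutive identical masks; iteration stops there. If
#' no such run occurs within `max_steps` the result is flagged unstable and
#' extents are reported for the final mask.
#'
#' Ring extents are measured as the Euclidean distance from each fluorescing
#' receiver's centre to the nearest sender centre, rounded down to whole
#' blocks; `mm_per_block` (default 3, the model's nominal resolution) converts
#' blocks to mm.
#'
#' @param grid_size Lawn size in squares (default 21; square grid).
#' @param senders `"2x2"` (four central sender blocks, default), `"single"`,
#'   or a data.frame with 0-based columns `x`, `y`.
#' @param window Band-pass window `c(low, high)` in nM (default `c(10, 200)`,
#'   i.e. 0.01-0.2 uM).
#' @param secretion_rate Sender secretion rate in nM/cell-block/min.
#' @param params [diffusion_params()] for the signal.
#' @param max_steps Iteration cap.
#' @param stability_window Consecutive identical masks required (default 6,
#'   one hour at the 10-min step).
#' @param block_area Square area in mm^2.
#' @param mm_per_block Reporting scale for mm extents.
#' @return A `bandpass_result` with `steps_to_stability`, `stable`,
#'   `mask` (logical matrix), `conc` (nM), `inner_extent_blocks`,
#'   `outer_extent_blocks`, `inner_extent_mm`, `outer_extent_mm`,
#'   `n_fluorescing`, and the sender coordinates. Extents are `NA` when no
#'   receiver fluoresces.
#' @export
bandpass_assay <- function(grid_size = 21, senders = "2x2",
                           window = c(10, 200), secretion_rate = 1.6e-2,
                           params = diffusion_params(),
                           max_steps = 1000, stability_window = 6,
                           block_area = 10, mm_per_block = 3) {
  stopifnot(inherits(params, "diffusion_params"))
  if (!check_stability(params)$pass)
    stop("unstable diffusion parameters", call. = FALSE)
  w <- as.integer(grid_size); h <- w
  if (is.character(senders)) {
    senders <- switch(match.arg(senders, c("2x2", "single")),
      "2x2" = {
        x0 <- (w - 2L) %/% 2L; y0 <- (h - 2L) %/% 2L
        expand.grid(x = x0 + 0:1, y = y0 + 0:1)
      },
      "single" = data.frame(x = (w - 1L) %/% 2L, y = (h - 1L) %/% 2L))
  }
  stopifnot(all(c("x", "y") %in% names(senders)))
  sender_mask <- matrix(FALSE, h, w)
  sender_mask[cbind(senders$y + 1L, senders$x + 1L)] <- TRUE

  # distance of every square to the nearest sender centre, in blocks
  dgrid <- outer(seq_len(h), seq_len(w), function(r, c) {
    dd <- Inf
    for (i in seq_len(nrow(senders)))
      dd <- pmin(dd, sqrt((r - 1L - senders$y[i])^2 + (c - 1L - senders$x[i])^2))
    dd
  })

  U <- matrix(0, h, w)
  add <- secretion_rate * params$dt_min
  kdt <- params$decay_k_per_min * params$dt_min
  prev <- NULL; run_len <- 0L; stable <- FALSE; t_stable <- NA_integer_
  n_fluor <- integer(0)
  for (t in seq_len(max_steps)) {
    U[sender_mask] <- U[sender_mask] + add
    U <- U + params$s * stencil_sum(U, params$boundary)
    U <- U * (1 - kdt)
    mask <- bandpass_expression(U, window[1], window[2]) & !sender_mask
    n_fluor[t] <- sum(mask)
    if (!is.null(prev) && identical(mask, prev)) {
      run_len <- run_len + 1L
      if (run_len == stability_window - 1L) {
        stable <- TRUE
        t_stable <- t - (stability_window - 1L)
        break
      }
    } else run_len <- 0L
    prev <- mask
  }
  d <- dgrid[mask]
  inner <- if (length(d)) floor(min(d)) else NA_real_
  outer_ <- if (length(d)) floor(max(d)) else NA_real_
  structure(list(
    steps_to_stability = if (stable) t_stable else NA_integer_,
    stable = stable, last_step = t,
    mask = mask, conc = U, senders = senders,
    inner_extent_blocks = inner, outer_extent_blocks = outer_,
    inner_extent_mm = inner * mm_per_block, outer_extent_mm = outer_ * mm_per_block,
    n_fluorescing = n_fluor, window = window,
    secretion_rate = secretion_rate, params = params
  ), class = "bandpass_result")
}

#' @export
print.bandpass_result <- function(x, ...) {
  if (x$stable)
    cat(sprintf("<bandpass_result> stable at step %d\n", x$steps_to_stability))
  else
    cat(sprintf("<bandpass_result> NOT stable within %d steps\n", x$last_step))
  if (is.na(x$inner_extent_blocks))
    cat("  no fluorescing receivers\n")
  else
    cat(sprintf("  ring: %g-%g blocks (%g-%g mm) from the sender colony, %d blocks fluorescing\n",
                x$inner_extent_blocks, x$outer_extent_blocks,
                x$inner_extent_mm, x$outer_extent_mm, sum(x$mask)))
  invisible(x)
}

## ---- preferential growth ---------------------------------------------------

#' Preferential growth assay
#'
#' Seeds two (or more) coupled strains in parallel lines and classifies every
#' division event of the two outer strains by the sign of the child-minus-
#' parent displacement along the axis joining the lines: *toward* the partner
#' line, *away* from it, or *neutral* (lateral). Reports per-run counts, run
#' means, the toward/away count ratio, and a one-sided Welch test of
#' toward > away across runs for each strain.
#'
#' The default geometry places the two lines 10 rows apart, 5 rows from their
#' respective rims of a 21 x 21 grid, with a 14-step horizon, so that no
#' growth front (at most `max fitness` rows per step) can reach a rim or the
#' opposing front within the assay: directional counts then measure growth
#' rates rather than space exhaustion, and toward/away counts are symmetric
#' in distribution when coupling is absent.
#'
#' @param n_runs Number of replicate runs (>= 2).
#' @param n_steps Steps per run.
#' @param grid_size Grid side in squares.
#' @param line_length Blocks per seed line.
#' @param separation Rows between the two lines.
#' @param model_kind `"QSMM"` or `"MMM"`.
#' @param seed Root RNG seed; per-run seeds are derived from it.
#' @param overrides Optional named list of per-strain parameter overrides,
#'   e.g. `list(S1 = list(secretion_rate = 1e-3))` — the varied-parameter hook
#'   of the assay.
#' @param pattern Optional [seed_patterns] object; must be of kind
#'   `parallel_lines`.
#' @param ... Passed to [make_consortium()] (shared strain parameters).
#' @return A `pref_growth_result` with `per_run` (run x strain counts) and
#'   `summary` (per strain: mean toward/away/neutral, toward/away ratio,
#'   one-sided p-value).
#' @export
preferential_growth_assay <- function(n_runs = 100, n_steps = 14,
                                      grid_size = 21, line_length = 8,
                                      separation = 10,
                                      model_kind = c("QSMM", "MMM"),
                                      seed = 1L, overrides = list(),
                                      pattern = NULL, ...) {
  model_kind <- match.arg(model_kind)
  if (n_runs < 2) stop("need at least two runs", call. = FALSE)
  cons <- make_consortium(2, model_kind = model_kind, ...)
  for (id in names(overrides)) {
    k <- match(id, vapply(cons$strains, `[[`, "", "strain_id"))
    if (is.na(k)) stop(sprintf("override for unknown strain '%s'", id), call. = FALSE)
    for (p in names(overrides[[id]])) cons$strains[[k]][[p]] <- overrides[[id]][[p]]
  }
  ids <- vapply(cons$strains, `[[`, "", "strain_id")
  if (is.null(pattern))
    pattern <- seed_parallel_lines(ids, length = line_length, separation = separation)
  if (pattern$kind != "parallel_lines")
    stop("the preferential growth assay requires a parallel_lines seeding", call. = FALSE)

  grid <- create_grid(grid_size, grid_size)
  pos0 <- resolve_positions(pattern, grid)
  line_y <- vapply(ids, function(s) unique(pos0$y[pos0$strain == s])[1], 0L)
  # toward = displacement sign pointing at the other strain's line
  toward_sign <- vapply(seq_along(ids), function(i) {
    other <- line_y[-i]
    sign(other[which.min(abs(other - line_y[i]))] - line_y[i])
  }, 0)

  per_run <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- simulation_config(grid, cons$strains, pattern, n_steps = n_steps,
                             seed = derive_seed(seed, r))
    traj <- run_simulation(cfg)
    ev <- traj$events
    per_run[[r]] <- do.call(rbind, lapply(seq_along(ids), function(i) {
      e <- ev[ev$strain == ids[i], , drop = FALSE]
      dy <- e$child_y - e$parent_y
      data.frame(run = r, strain = ids[i],
                 toward = sum(dy * toward_sign[i] > 0),
                 away = sum(dy * toward_sign[i] < 0),
                 neutral = sum(dy == 0))
    }))
  }
  per_run <- do.call(rbind, per_run)

  summ <- do.call(rbind, lapply(ids, function(s) {
    d <- per_run[per_run$strain == s, ]
    p <- if (stats::sd(d$toward) == 0 && stats::sd(d$away) == 0) {
      if (mean(d$toward) > mean(d$away)) 0 else 1    # degenerate: no variance
    } else stats::t.test(d$toward, d$away, alternative = "greater")$p.value
    data.frame(strain = s,
               mean_toward = mean(d$toward), mean_away = mean(d$away),
               mean_neutral = mean(d$neutral),
               toward_away_ratio = sum(d$toward) / sum(d$away),
               p_value = p)
  }))
  structure(list(per_run = per_run, summary = summ, n_runs = n_runs,
                 n_steps = n_steps, model_kind = model_kind, seed = seed),
            class = "pref_growth_result")
}

#' @export
print.pref_growth_result <- function(x, ...) {
  cat(sprintf("<pref_growth_result> %s, %d runs x %d steps\n",
              x$model_kind, x$n_runs, x$n_steps))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

## ---- parameter sweeps ------------------------------------------------------

# shared runner: n_iter seeded runs of an n-strain consortium with strain 1's
# parameters overridden; random seeding of n_seed_blocks per strain
run_batch <- function(values_df, n_strains, n_iter, n_steps, n_seed_blocks,
                      grid_size, seed, model_kind = "QSMM") {
  out <- vector("list", nrow(values_df) * n_iter)
  z <- 0L
  for (v in seq_len(nrow(values_df))) {
    cons <- make_consortium(n_strains, model_kind = model_kind)
    for (p in names(values_df)) cons$strains[[1]][[p]] <- values_df[[p]][v]
    ids <- vapply(cons$strains, `[[`, "", "strain_id")
    for (r in seq_len(n_iter)) {
      rs <- derive_seed(seed, (v - 1L) * n_iter + r)
      grid <- create_grid(grid_size, grid_size)
      pattern <- seed_random(ids, n_per_strain = n_seed_blocks, seed = rs)
      cfg <- simulation_config(grid, cons$strains, pattern,
                               n_steps = n_steps, seed = rs)
      fc <- final_counts(run_simulation(cfg))
      z <- z + 1L
      out[[z]] <- data.frame(point = v, run = r, strain = names(fc),
                             count = as.integer(fc), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

summarize_batch <- function(runs, values_df) {
  pts <- unique(runs$point)
  do.call(rbind, lapply(pts, function(v) {
    d <- runs[runs$point == v, ]
    agg <- stats::aggregate(count ~ strain, d, function(x) c(mean(x), stats::sd(x)))
    cbind(values_df[rep(v, nrow(agg)), , drop = FALSE],
          data.frame(strain = agg$strain, mean_count = agg$count[, 1],
                     sd_count = agg$count[, 2], row.names = NULL))
  }))
}

#' Single-parameter sweep
#'
#' Varies one parameter of Strain 1 over a set of values, holding the other
#' strain(s) at defaults, with `n_seed_blocks` blocks per strain seeded
#' randomly and `n_iter` seeded replicate runs per value. Two- and
#' three-strain consortia are supported (the three-strain model uses the
#' orthogonal ring topology).
#'
#' @param parameter One of `"secretion_rate"`, `"threshold"`,
#'   `"fitness_gain"`.
#' @param values Numeric vector of parameter values for Strain 1.
#' @param n_strains 2 or 3.
#' @param n_iter Replicate runs per value (default 100).
#' @param n_steps Steps per run (default 100).
#' @param n_seed_blocks Random seed blocks per strain (default 4).
#' @param grid_size Grid side (default 21).
#' @param seed Root seed; all per-run seeds derive from it.
#' @return A `sweep_result` with `runs` (per-run final counts) and `summary`
#'   (per value and strain: mean and sd of the final population).
#' @export
single_parameter_sweep <- function(parameter, values, n_strains = 2,
                                   n_iter = 100, n_steps = 100,
                                   n_seed_blocks = 4, grid_size = 21,
                                   seed = 1L) {
  parameter <- match.arg(parameter, c("secretion_rate", "threshold", "fitness_gain"))
  if (length(values) < 1) stop("need at least one value", call. = FALSE)
  values_df <- stats::setNames(data.frame(values), parameter)
  runs <- run_batch(values_df, n_strains, n_iter, n_steps, n_seed_blocks,
                    grid_size, seed)
  structure(list(parameter = parameter, runs = runs, values = values_df,
                 summary = summarize_batch(runs, values_df),
                 n_iter = n_iter, n_steps = n_steps, seed = seed),
            class = "sweep_result")
}

#' Grid search over Strain 1's coupling parameters
#'
#' Simultaneously varies Strain 1's secretion rate, induction threshold and
#' fitness gain over a Cartesian grid (Strain 2 fixed at defaults), with 4 + 4
#' randomly seeded blocks and `n_iter` replicate runs per grid point. Default
#' axes: secretion 1e-4..1e-1 nM/cell-block/min and threshold 0.1..1e4 nM
#' sampled log-uniformly, fitness gain 0.01..0.1 linearly, 4 points each.
#'
#' @param secretion_values,threshold_values,gain_values Axis values.
#' @param n_iter Replicate runs per grid point (default 100).
#' @param n_steps Steps per run (default 50).
#' @param n_seed_blocks,grid_size,seed As in [single_parameter_sweep()].
#' @return A `sweep_result`; its `summary` additionally allows the dominant
#'   strain and population difference per point to be derived.
#' @export
grid_search <- function(secretion_values = 10^seq(-4, -1, length.out = 4),
                        threshold_values = 10^seq(-1, 4, length.out = 4),
                        gain_values = seq(0.01, 0.1, length.out = 4),
                        n_iter = 100, n_steps = 50, n_seed_blocks = 4,
                        grid_size = 21, seed = 1L) {
  if (!length(secretion_values) || !length(threshold_values) || !length(gain_values))
    stop("empty parameter grid", call. = FALSE)
  values_df <- expand.grid(secretion_rate = secretion_values,
                           threshold = threshold_values,
                           fitness_gain = gain_values)
  runs <- run_batch(values_df, 2, n_iter, n_steps, n_seed_blocks, grid_size, seed)
  structure(list(parameter = c("secretion_rate", "threshold", "fitness_gain"),
                 runs = runs, values = values_df,
                 summary = summarize_batch(runs, values_df),
                 n_iter = n_iter, n_steps = n_steps, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s: %d point(s) x %d runs x %d steps\n",
              paste(x$parameter, collapse = " x "), nrow(x$values),
              x$n_iter, x$n_steps))
  print(utils::head(x$summary, 12), row.names = FALSE)
  if (nrow(x$summary) > 12) cat("  ...\n")
  invisible(x)
}
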