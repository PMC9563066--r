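# shared fixtures and independent oracles

# independent per-square implementation of the five-point FTCS stencil with
# zero-flux boundaries, written as an explicit loop (oracle for ftcs_step)
ftcs_loop_oracle <- function(U, s) {
  nr <- nrow(U); nc <- ncol(U)
  out <- U
  at <- function(r, c) {            # reflective out-of-bounds lookup
    r <- min(max(r, 1L), nr); c <- min(max(c, 1L), nc)
    U[r, c]
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    out[r, c] <- U[r, c] + s * (at(r - 1L, c) + at(r + 1L, c) +
                                at(r, c - 1L) + at(r, c + 1L) - 4 * U[r, c])
  }
  out
}

# two-strain config on a small grid with an explicit seeding
small_config <- function(n_steps = 5, seed = 1L, grid_size = 9,
                         pattern = NULL, ...) {
  cons <- make_consortium(2, ...)
  if (is.null(pattern))
    pattern <- seed_random(c("S1", "S2"), n_per_strain = 2, seed = seed)
  simulation_config(create_grid(grid_size, grid_size), cons$strains, pattern,
                    n_steps = n_steps, seed = seed)
}

# single static block of strain `S1` with a given base fitness, sensing a
# molecule that is never produced (so fitness is exactly the base fitness)
lone_block_config <- function(base_fitness, n_steps = 1, seed = 1L,
                              grid_size = 3) {
  s1 <- strain_spec("S1", produced = "molA", sensed = "molB",
                    base_fitness = base_fitness, secretion_rate = 0)
  pos <- (grid_size - 1L) %/% 2L
  simulation_config(create_grid(grid_size, grid_size), list(s1),
                    seed_custom(data.frame(x = pos, y = pos, strain = "S1")),
                    n_steps = n_steps, seed = seed)
}
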