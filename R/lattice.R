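#' Create an empty cellular-automaton grid
#'
#' The simulation arena is a 2D lattice of square patches. Each patch either is
#' empty or holds exactly one *cell-block*: a dense patch of cells of a single
#' strain that acts as the replicating unit of the automaton. The default patch
#' area of 10 mm^2 corresponds to roughly 1e8 *E. coli* cells per block, so the
#' square side length is `sqrt(10)` ~ 3.162 mm.
#'
#' Coordinates throughout the package are 0-based, with `x` the column index
#' (0 .. width-1) and `y` the row index (0 .. height-1). Snapshot files use the
#' same convention: row `y`, column `x`.
#'
#' @param width,height Grid dimensions in squares (>= 1).
#' @param block_area Area of one square in mm^2 (> 0); the square side length
#'   is `sqrt(block_area)` mm.
#' @param cells_per_block Number of cells represented by one cell-block
#'   (default 1e8).
#' @return An object of class `ca_grid` with fields `width`, `height`,
#'   `square_length` (mm), `block_area` (mm^2), `cells_per_block`,
#'   `strain_ids` (character vector of registered strains) and `occupancy`
#'   (integer `height x width` matrix; 0 = empty, k = k-th strain).
#' @examples
#' g <- create_grid(21, 21, block_area = 10)
#' g$square_length  # sqrt(10) mm
#' @export
create_grid <- function(width, height, block_area = 10, cells_per_block = 1e8) {
  if (!is.numeric(width) || !is.numeric(height) ||
      length(width) != 1L || length(height) != 1L ||
      width < 1 || height < 1 || width != floor(width) || height != floor(height))
    stop("`width` and `height` must be integers >= 1", call. = FALSE)
  if (!is.numeric(block_area) || length(block_area) != 1L || block_area <= 0)
    stop("`block_area` must be a positive scalar (mm^2)", call. = FALSE)
  if (!is.numeric(cells_per_block) || cells_per_block <= 0)
    stop("`cells_per_block` must be positive", call. = FALSE)
  structure(list(
    width = as.integer(width),
    height = as.integer(height),
    block_area = block_area,
    square_length = sqrt(block_area),
    cells_per_block = cells_per_block,
    strain_ids = character(0),
    occupancy = matrix(0L, nrow = as.integer(height), ncol = as.integer(width))
  ), class = "ca_grid")
}

#' @export
print.ca_grid <- function(x, ...) {
  cat(sprintf("<ca_grid> %d x %d squares, dL = %.3f mm (%.3g mm^2/block, %.3g cells/block)\n",
              x$width, x$height, x$square_length, x$block_area, x$cells_per_block))
  occ <- sum(x$occupancy > 0L)
  cat(sprintf("  occupied: %d/%d", occ, x$width * x$height))
  if (length(x$strain_ids))
    cat(" | strains:", paste(x$strain_ids, collapse = ", "))
  cat("\n")
  invisible(x)
}

stopifnot_inbounds <- function(grid, pos) {
  if (length(pos) != 2L || any(!is.finite(pos)))
    stop("`pos` must be a length-2 vector c(x, y)", call. = FALSE)
  x <- pos[[1]]; y <- pos[[2]]
  if (x < 0 || x >= grid$width || y < 0 || y >= grid$height)
    stop(sprintf("position (%s, %s) is outside the %d x %d grid",
                 format(x), format(y), grid$width, grid$height), call. = FALSE)
  c(as.integer(x), as.integer(y))
}

#' Von Neumann neighbourhood of a square
#'
#' Nearest neighbours are the four non-diagonally adjacent squares; squares on
#' the grid boundary have fewer (2 at corners, 3 on edges).
#'
#' @param grid A [create_grid()] object.
#' @param pos Length-2 vector `c(x, y)`, 0-based.
#' @return Integer matrix with columns `x`, `y`, one row per in-bounds
#'   neighbour (2 to 4 rows).
#' @export
von_neumann_neighbors <- function(grid, pos) {
  p <- stopifnot_inbounds(grid, pos)
  nb <- cbind(x = p[1] + c(0L, 0L, -1L, 1L), y = p[2] + c(-1L, 1L, 0L, 0L))
  nb[nb[, "x"] >= 0L & nb[, "x"] < grid$width &
     nb[, "y"] >= 0L & nb[, "y"] < grid$height, , drop = FALSE]
}

#' Empty von Neumann neighbours of a square
#'
#' The subset of [von_neumann_neighbors()] whose squares hold no cell-block;
#' these are the sites available for cell division.
#'
#' @inheritParams von_neumann_neighbors
#' @return Integer matrix with columns `x`, `y` (possibly 0 rows).
#' @export
empty_neighbors <- function(grid, pos) {
  nb <- von_neumann_neighbors(grid, pos)
  nb[grid$occupancy[cbind(nb[, "y"] + 1L, nb[, "x"] + 1L)] == 0L, , drop = FALSE]
}

#' Strain occupying a square
#'
#' @inheritParams von_neumann_neighbors
#' @return The strain id (character) or `NA` if the square is empty.
#' @export
occupant <- function(grid, pos) {
  p <- stopifnot_inbounds(grid, pos)
  k <- grid$occupancy[p[2] + 1L, p[1] + 1L]
  if (k == 0L) NA_character_ else grid$strain_ids[[k]]
}

# register a strain id, returning its integer code
strain_code <- function(grid, strain_id) {
  k <- match(strain_id, grid$strain_ids)
  if (is.na(k)) stop(sprintf("unknown strain id '%s'", strain_id), call. = FALSE)
  k
}

## ---- seed patterns ---------------------------------------------------------

new_seed_pattern <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "seed_pattern")
}

#' @export
print.seed_pattern <- function(x, ...) {
  cat(sprintf("<seed_pattern> kind = %s, strains = %s\n",
              x$kind, paste(x$strains, collapse = ", ")))
  invisible(x)
}

#' Seed patterns
#'
#' Constructors for the predefined initial configurations: parallel lines,
#' a single file, diagonally opposite corners, concentric circles, random
#' placements, and fully custom position lists. A pattern is resolved against a
#' concrete grid by [seed_grid()].
#'
#' * `seed_parallel_lines()`: one horizontal line of blocks per strain,
#'   centred, consecutive lines `separation` rows apart.
#' * `seed_single_file()`: all strains interleaved along one centred row.
#' * `seed_diagonal_corners()`: `n_per_strain` blocks per strain packed into
#'   diagonally opposite corners (two strains).
#' * `seed_concentric_circles()`: one circle per strain; a square belongs to
#'   the circle of radius `r` if its centre-to-centre Euclidean distance from
#'   the grid centre rounds to `r`.
#' * `seed_random()`: `n_per_strain` blocks per strain on distinct uniformly
#'   drawn empty squares, reproducible from `seed`.
#' * `seed_custom()`: explicit `data.frame(x, y, strain)`.
#'
#' @param strains Character vector of strain ids.
#' @param length Line length in blocks (parallel lines).
#' @param separation Rows between consecutive lines (default 4).
#' @param row Optional 0-based row of the first line; default centres the
#'   stack of lines vertically.
#' @param n_per_strain Blocks per strain (random / corners patterns).
#' @param radii Integer radii, one per strain (concentric circles).
#' @param seed Integer RNG seed (random pattern); required for
#'   reproducibility.
#' @param positions A `data.frame` with columns `x`, `y` (0-based) and
#'   `strain` (custom pattern).
#' @return A `seed_pattern` object.
#' @name seed_patterns
NULL

#' @rdname seed_patterns
#' @export
seed_parallel_lines <- function(strains, length = 8, separation = 4, row = NULL) {
  stopifnot(length >= 1, separation >= 1)
  new_seed_pattern("parallel_lines", strains = strains, length = as.integer(length),
                   separation = as.integer(separation),
                   row = if (is.null(row)) NULL else as.integer(row))
}

#' @rdname seed_patterns
#' @export
seed_single_file <- function(strains, n_per_strain = 4, row = NULL) {
  new_seed_pattern("single_file", strains = strains,
                   n_per_strain = as.integer(n_per_strain),
                   row = if (is.null(row)) NULL else as.integer(row))
}

#' @rdname seed_patterns
#' @export
seed_diagonal_corners <- function(strains, n_per_strain = 4) {
  if (length(strains) != 2L)
    stop("diagonal_corners expects exactly two strains", call. = FALSE)
  new_seed_pattern("diagonal_corners", strains = strains,
                   n_per_strain = as.integer(n_per_strain))
}

#' @rdname seed_patterns
#' @export
seed_concentric_circles <- function(strains, radii) {
  if (length(radii) != length(strains))
    stop("need one radius per strain", call. = FALSE)
  new_seed_pattern("concentric_circles", strains = strains, radii = radii)
}

#' @rdname seed_patterns
#' @export
seed_random <- function(strains, n_per_strain = 4, seed = 1L) {
  new_seed_pattern("random", strains = strains,
                   n_per_strain = as.integer(n_per_strain), seed = as.integer(seed))
}

#' @rdname seed_patterns
#' @export
seed_custom <- function(positions) {
  stopifnot(is.data.frame(positions), all(c("x", "y", "strain") %in% names(positions)))
  new_seed_pattern("custom", strains = unique(as.character(positions$strain)),
                   positions = positions)
}

# evaluate RNG-consuming code under a local seed, restoring global RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Resolve a seed pattern to explicit block positions
#'
#' @param pattern A [seed_patterns] object.
#' @param grid The target [create_grid()] grid.
#' @return A `data.frame` with columns `x`, `y` (0-based) and `strain`.
#' @export
resolve_positions <- function(pattern, grid) {
  stopifnot(inherits(pattern, "seed_pattern"), inherits(grid, "ca_grid"))
  w <- grid$width; h <- grid$height
  ns <- length(pattern$strains)
  out <- switch(pattern$kind,
    parallel_lines = {
      len <- pattern$length; sep <- pattern$separation
      if (len > w) stop("line length exceeds grid width", call. = FALSE)
      span <- (ns - 1L) * sep
      y0 <- if (is.null(pattern$row)) (h - 1L - span) %/% 2L else pattern$row
      x0 <- (w - len) %/% 2L
      do.call(rbind, lapply(seq_len(ns), function(i)
        data.frame(x = x0 + seq_len(len) - 1L, y = y0 + (i - 1L) * sep,
                   strain = pattern$strains[[i]])))
    },
    single_file = {
      n <- pattern$n_per_strain
      total <- n * ns
      if (total > w) stop("single file does not fit the grid width", call. = FALSE)
      y <- if (is.null(pattern$row)) (h - 1L) %/% 2L else pattern$row
      x0 <- (w - total) %/% 2L
      data.frame(x = x0 + seq_len(total) - 1L, y = y,
                 strain = rep(pattern$strains, times = n))
    },
    diagonal_corners = {
      n <- pattern$n_per_strain
      side <- ceiling(sqrt(n))
      corner <- function(xs, ys, strain) {
        cells <- expand.grid(x = xs, y = ys)[seq_len(n), ]
        data.frame(x = cells$x, y = cells$y, strain = strain)
      }
      rbind(corner(0:(side - 1L), 0:(side - 1L), pattern$strains[[1]]),
            corner((w - side):(w - 1L), (h - side):(h - 1L), pattern$strains[[2]]))
    },
    concentric_circles = {
      cx <- (w - 1) / 2; cy <- (h - 1) / 2
      cells <- expand.grid(x = 0:(w - 1L), y = 0:(h - 1L))
      r <- round(sqrt((cells$x - cx)^2 + (cells$y - cy)^2))
      do.call(rbind, lapply(seq_len(ns), function(i) {
        sel <- cells[r == pattern$radii[[i]], ]
        if (nrow(sel) == 0L)
          stop(sprintf("radius %s selects no squares", pattern$radii[[i]]), call. = FALSE)
        data.frame(x = sel$x, y = sel$y, strain = pattern$strains[[i]])
      }))
    },
    random = {
      n <- pattern$n_per_strain
      free <- which(grid$occupancy == 0L)
      if (length(free) < n * ns)
        stop("not enough empty squares for random seeding", call. = FALSE)
      idx <- with_local_seed(pattern$seed, sample(free, n * ns))
      data.frame(x = (idx - 1L) %/% h, y = (idx - 1L) %% h,
                 strain = rep(pattern$strains, each = n))
    },
    custom = {
      data.frame(x = as.integer(pattern$positions$x),
                 y = as.integer(pattern$positions$y),
                 strain = as.character(pattern$positions$strain))
    },
    stop(sprintf("unknown pattern kind '%s'", pattern$kind), call. = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Seed cell-blocks onto a grid
#'
#' Places the blocks described by a seed pattern. Placement fails (with no
#' partial effect) if any target square is out of bounds, already occupied, or
#' requested twice.
#'
#' @param grid A [create_grid()] grid.
#' @param pattern A [seed_patterns] object.
#' @return The grid with updated occupancy and strain registry.
#' @examples
#' g <- create_grid(21, 21)
#' g <- seed_grid(g, seed_parallel_lines(c("S1", "S2"), length = 8, separation = 4))
#' sum(g$occupancy > 0)  # 16
#' @export
seed_grid <- function(grid, pattern) {
  pos <- resolve_positions(pattern, grid)
  if (any(pos$x < 0 | pos$x >= grid$width | pos$y < 0 | pos$y >= grid$height))
    stop("seeding error: pattern places blocks outside the grid", call. = FALSE)
  idx <- cbind(pos$y + 1L, pos$x + 1L)
  if (anyDuplicated(idx))
    stop("seeding error: pattern places two blocks on the same square", call. = FALSE)
  if (any(grid$occupancy[idx] != 0L))
    stop("seeding error: target square already occupied", call. = FALSE)
  for (s in unique(pos$strain))
    if (!s %in% grid$strain_ids) grid$strain_ids <- c(grid$strain_ids, s)
  grid$occupancy[idx] <- match(pos$strain, grid$strain_ids)
  grid
}

#' Write / read a grid occupancy snapshot
#'
#' Snapshots are plain-text CSV integer matrices (0 = empty, k = k-th strain in
#' `grid$strain_ids`), laid out row = y, column = x.
#'
#' @param grid A `ca_grid`.
#' @param file Path to write to / read from.
#' @return `write_grid_snapshot()` returns `file` invisibly;
#'   `read_grid_snapshot()` returns an integer matrix.
#' @export
write_grid_snapshot <- function(grid, file) {
  utils::write.table(grid$occupancy, file, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_grid_snapshot
#' @export
read_grid_snapshot <- function(file) {
  as.matrix(utils::read.table(file, sep = ",", header = FALSE))
}
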