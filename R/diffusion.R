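#' Diffusion and decay parameters for a signalling molecule
#'
#' Concentrations are carried in nM throughout. The diffusivity is supplied in
#' m^2/s (the unit in which measured values are tabulated) and converted once
#' to mm^2/min internally; the time step is in minutes and the square length in
#' mm, so the dimensionless stability number is `s = D * dt / dL^2`.
#'
#' Defaults are those of acyl homoserine lactones in agar: D = 8e-10 m^2/s
#' (0.048 mm^2/min), first-order decay 4.6e-4/min, a 10-min step and
#' dL = sqrt(10) mm, giving s = 0.048. A representative small-metabolite
#' diffusivity (maltose) is 5e-10 m^2/s.
#'
#' @param D_m2_per_s Diffusivity in m^2/s (> 0).
#' @param dt_min Time step in minutes (> 0).
#' @param dL_mm Square side length in mm (> 0).
#' @param decay_k_per_min First-order decay rate constant in /min (>= 0).
#' @param boundary `"zero_flux"` (reflective, mass-conserving; default) or
#'   `"absorbing"` (concentration clamped to 0 outside the rim).
#' @return A `diffusion_params` object; element `s` is the stability number.
#' @examples
#' p <- diffusion_params()           # AHL defaults
#' p$s                               # 0.048
#' check_stability(p)$pass           # TRUE
#' @export
diffusion_params <- function(D_m2_per_s = 8e-10, dt_min = 10, dL_mm = sqrt(10),
                             decay_k_per_min = 4.6e-4,
                             boundary = c("zero_flux", "absorbing")) {
  boundary <- match.arg(boundary)
  if (D_m2_per_s <= 0 || dt_min <= 0 || dL_mm <= 0)
    stop("D, dt and dL must be positive", call. = FALSE)
  if (decay_k_per_min < 0)
    stop("decay_k_per_min must be >= 0", call. = FALSE)
  D_mm2_min <- convert_diffusivity(D_m2_per_s)
  structure(list(
    D_m2_per_s = D_m2_per_s,
    D_mm2_per_min = D_mm2_min,
    dt_min = dt_min,
    dL_mm = dL_mm,
    decay_k_per_min = decay_k_per_min,
    boundary = boundary,
    s = D_mm2_min * dt_min / dL_mm^2
  ), class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf(paste0("<diffusion_params> D = %.3g m^2/s (%.4g mm^2/min), dt = %g min, ",
                     "dL = %.4g mm, k = %.3g/min, %s boundary, s = %.4g (%s)\n"),
              x$D_m2_per_s, x$D_mm2_per_min, x$dt_min, x$dL_mm, x$decay_k_per_min,
              x$boundary, x$s, if (x$s <= 0.25) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Convert a diffusivity from m^2/s to mm^2/min
#'
#' The single unit-conversion routine used by the package:
#' 1 m^2/s = 1e6 mm^2/m^2 * 60 s/min = 6e7 mm^2/min.
#'
#' @param D_m2_per_s Diffusivity in m^2/s.
#' @return Diffusivity in mm^2/min.
#' @export
convert_diffusivity <- function(D_m2_per_s) D_m2_per_s * 6e7

#' Per-block secretion rate from a per-cell rate
#'
#' A cell-block aggregates `cells_per_block` cells, so a per-cell secretion
#' rate of 1.6e-10 nM/cell/min with 1e8 cells/block gives the per-block default
#' 1.6e-2 nM/cell-block/min.
#'
#' @param per_cell_rate Secretion rate in nM/cell/min.
#' @param cells_per_block Cells per block (default 1e8).
#' @return Rate in nM/cell-block/min.
#' @export
per_block_rate <- function(per_cell_rate, cells_per_block = 1e8)
  per_cell_rate * cells_per_block

#' FTCS stability report
#'
#' The explicit forward-time central-space scheme on a 2D von Neumann stencil
#' is stable iff `s = D*dt/dL^2 <= 1/4`.
#'
#' @param params A [diffusion_params()] object.
#' @return A list with elements `s` and `pass`.
#' @export
check_stability <- function(params) {
  stopifnot(inherits(params, "diffusion_params"))
  list(s = params$s, pass = params$s <= 0.25)
}

#' Create a concentration field
#'
#' A per-molecule 2D concentration field (nM) co-registered with a grid.
#'
#' @param grid A [create_grid()] grid (used for dimensions).
#' @param molecule Molecule identifier.
#' @param conc Optional initial matrix (defaults to 0 everywhere).
#' @return An `ahl_field` object with elements `molecule` and `conc`.
#' @export
ahl_field <- function(grid, molecule, conc = NULL) {
  if (is.null(conc)) conc <- matrix(0, grid$height, grid$width)
  conc <- as.matrix(conc)
  if (nrow(conc) != grid$height || ncol(conc) != grid$width)
    stop("field dimensions do not match the grid", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(list(molecule = molecule, conc = conc), class = "ahl_field")
}

# five-point Laplacian sum with the requested boundary handling, on a raw matrix
stencil_sum <- function(U, boundary) {
  nr <- nrow(U); nc <- ncol(U)
  if (boundary == "zero_flux") {
    # reflective: out-of-bounds neighbour mirrors the centre cell, so the
    # boundary face carries no flux and total mass is conserved
    up <- rbind(U[1, , drop = FALSE], U[-nr, , drop = FALSE])
    dn <- rbind(U[-1, , drop = FALSE], U[nr, , drop = FALSE])
    lf <- cbind(U[, 1, drop = FALSE], U[, -nc, drop = FALSE])
    rt <- cbind(U[, -1, drop = FALSE], U[, nc, drop = FALSE])
  } else {
    z <- function(n) matrix(0, n[1], n[2])
    up <- rbind(z(c(1, nc)), U[-nr, , drop = FALSE])
    dn <- rbind(U[-1, , drop = FALSE], z(c(1, nc)))
    lf <- cbind(z(c(nr, 1)), U[, -nc, drop = FALSE])
    rt <- cbind(U[, -1, drop = FALSE], z(c(nr, 1)))
  }
  up + dn + lf + rt - 4 * U
}

#' One forward-time central-space diffusion step
#'
#' Applies the explicit FTCS update
#' `U[x,y] <- U[x,y] + s * (U[x-1,y] + U[x+1,y] + U[x,y-1] + U[x,y+1] - 4 U[x,y])`
#' with `s = D*dt/dL^2`. Under zero-flux boundaries the total amount is
#' conserved to machine precision; with `s <= 1/4` non-negativity is preserved.
#'
#' @param field An [ahl_field()] object.
#' @param params A [diffusion_params()] object (must be stable).
#' @return The updated field.
#' @export
ftcs_step <- function(field, params) {
  stopifnot(inherits(field, "ahl_field"), inherits(params, "diffusion_params"))
  if (params$s > 0.25)
    stop(sprintf("unstable FTCS parameters: s = %.4g > 0.25", params$s), call. = FALSE)
  field$conc <- field$conc + params$s * stencil_sum(field$conc, params$boundary)
  field
}

#' One first-order decay step
#'
#' Forward-Euler discretisation of first-order decay: `U <- U * (1 - k*dt)`,
#' consistent with the explicit diffusion scheme. Requires `k*dt < 1` so the
#' field stays non-negative; for the AHL defaults `k*dt = 0.0046` and the
#' error relative to the exact exponential is below 0.002 %.
#'
#' @inheritParams ftcs_step
#' @return The updated field.
#' @export
decay_step <- function(field, params) {
  stopifnot(inherits(field, "ahl_field"), inherits(params, "diffusion_params"))
  kdt <- params$decay_k_per_min * params$dt_min
  if (kdt >= 1)
    stop(sprintf("decay_k * dt = %.3g >= 1: decrease the time step", kdt), call. = FALSE)
  field$conc <- field$conc * (1 - kdt)
  field
}

#' Secretion of a molecule by occupied squares
#'
#' Every square occupied by a producing strain gains `rate * dt` nM of the
#' field's molecule; secretion deposits into the producer's own square only.
#'
#' @param field An [ahl_field()] object.
#' @param grid The co-registered [create_grid()] grid.
#' @param producers Character vector of strain ids that secrete this molecule.
#' @param rate_per_block Secretion rate(s) in nM/cell-block/min; either a
#'   scalar or a named vector keyed by strain id.
#' @param params A [diffusion_params()] object (supplies `dt`).
#' @return The updated field.
#' @export
secrete <- function(field, grid, producers, rate_per_block, params) {
  stopifnot(inherits(field, "ahl_field"), inherits(grid, "ca_grid"),
            inherits(params, "diffusion_params"))
  if (any(rate_per_block < 0)) stop("secretion rate must be >= 0", call. = FALSE)
  for (s in producers) {
    k <- strain_code(grid, s)   # errors on unknown strain id
    r <- if (length(rate_per_block) == 1L && is.null(names(rate_per_block)))
      rate_per_block else rate_per_block[[s]]
    if (is.null(r) || is.na(r))
      stop(sprintf("no secretion rate given for strain '%s'", s), call. = FALSE)
    field$conc[grid$occupancy == k] <-
      field$conc[grid$occupancy == k] + r * params$dt_min
  }
  field
}

#' Write a concentration field snapshot
#'
#' CSV matrix of concentrations in nM, row = y, column = x.
#'
#' @param field An [ahl_field()].
#' @param file Output path.
#' @export
write_field_snapshot <- function(field, file) {
  utils::write.table(field$conc, file, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
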