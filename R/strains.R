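#' Registry of common acyl homoserine lactones
#'
#' Convenience labels for six experimentally characterised, mutually orthogonal
#' AHL quorum-sensing signals. The simulator treats molecule identities as
#' opaque labels; only the per-molecule diffusion/decay parameters matter.
#'
#' @return Character vector of molecule names.
#' @export
ahl_registry <- function() {
  c("C4-HSL", "3OC6-HSL", "3OC8-HSL", "3OC12-HSL", "3OHC14-HSL", "pC-HSL")
}

#' Define a strain phenotype
#'
#' A strain is characterised by the signal molecule it secretes, the molecule
#' it senses, its secretion rate, the Boolean induction threshold, its base
#' fitness (per-step division probability) and the fitness gain added when the
#' sensed concentration exceeds the threshold.
#'
#' Two model kinds are supported. In the quorum-sensing-mediated model
#' (`"QSMM"`) strains have a non-zero base fitness (a reduced-growth knockout
#' background) and gain fitness when the partner's AHL exceeds the threshold;
#' a QSMM strain never senses its own product. In the metabolite-mediated
#' model (`"MMM"`) strains are auxotrophs with base fitness 0: they cannot
#' divide unless the partner-secreted essential metabolite is present above
#' threshold.
#'
#' The default base fitness 0.25 corresponds to a 10-min step, a 20-min
#' generation time and a knockout growth ratio of 0.5 (see [base_fitness()]).
#'
#' @param strain_id Strain identifier.
#' @param produced Molecule id secreted by this strain.
#' @param sensed Molecule id whose local concentration gates the fitness gain.
#' @param secretion_rate nM/cell-block/min (default 1.6e-2).
#' @param threshold Induction threshold in nM (default 5).
#' @param base_fitness Per-step division probability below threshold.
#' @param fitness_gain Additive probability increment above threshold
#'   (default 0.05); the total is clamped to 1.
#' @param model_kind `"QSMM"` or `"MMM"`.
#' @return A `strain_spec` object.
#' @examples
#' s <- strain_spec("S1", produced = "3OC8-HSL", sensed = "pC-HSL")
#' compute_fitness(s, c(2, 10))  # 0.25 below, 0.30 above the 5 nM threshold
#' @export
strain_spec <- function(strain_id, produced, sensed,
                        secretion_rate = 1.6e-2, threshold = 5,
                        base_fitness = 0.25, fitness_gain = 0.05,
                        model_kind = c("QSMM", "MMM")) {
  model_kind <- match.arg(model_kind)
  if (secretion_rate < 0) stop("secretion_rate must be >= 0", call. = FALSE)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (base_fitness < 0 || base_fitness > 1)
    stop("base_fitness must be a probability in [0, 1]", call. = FALSE)
  if (fitness_gain < 0) stop("fitness_gain must be >= 0", call. = FALSE)
  if (model_kind == "MMM" && base_fitness != 0)
    stop("MMM strains are auxotrophs: base_fitness must be 0", call. = FALSE)
  if (model_kind == "QSMM" && identical(produced, sensed))
    stop("a QSMM strain must not sense its own produced molecule", call. = FALSE)
  structure(list(
    strain_id = strain_id, produced = produced, sensed = sensed,
    secretion_rate = secretion_rate, threshold = threshold,
    base_fitness = base_fitness, fitness_gain = fitness_gain,
    model_kind = model_kind
  ), class = "strain_spec")
}

#' @export
print.strain_spec <- function(x, ...) {
  cat(sprintf(paste0("<strain_spec> %s (%s): produces %s @ %.3g nM/block/min, ",
                     "senses %s (threshold %.3g nM), fitness %.3g (+%.3g above threshold)\n"),
              x$strain_id, x$model_kind, x$produced, x$secretion_rate,
              x$sensed, x$threshold, x$base_fitness, x$fitness_gain))
  invisible(x)
}

#' Orthogonal coupling topology
#'
#' Assigns each strain's secreted molecule to a *different* strain's sensor (a
#' fixed-point-free permutation, so no strain responds to its own product).
#' Two strains are mutually coupled (1 <-> 2). Three strains use the ring in
#' which the signal of strain 1 is sensed by strain 3, that of strain 2 by
#' strain 1, and that of strain 3 by strain 2. For n > 3 the cyclic shift
#' i -> i + 1 (mod n) is used.
#'
#' @param n_strains Number of strains (>= 2).
#' @return A `coupling_topology` object whose element `sensed_by` is an
#'   integer vector: `sensed_by[i]` is the index of the strain that senses the
#'   molecule produced by strain `i`.
#' @examples
#' make_topology(2)$sensed_by  # c(2, 1)
#' make_topology(3)$sensed_by  # c(3, 1, 2)
#' @export
make_topology <- function(n_strains) {
  if (!is.numeric(n_strains) || n_strains < 2 || n_strains != floor(n_strains))
    stop("n_strains must be an integer >= 2", call. = FALSE)
  n <- as.integer(n_strains)
  sensed_by <- if (n == 2L) c(2L, 1L)
    else if (n == 3L) c(3L, 1L, 2L)
    else c(seq_len(n)[-1L], 1L)          # cyclic shift i -> i + 1
  structure(list(n_strains = n, sensed_by = sensed_by), class = "coupling_topology")
}

#' @export
print.coupling_topology <- function(x, ...) {
  cat("<coupling_topology>",
      paste(sprintf("%d->%d", seq_len(x$n_strains), x$sensed_by), collapse = ", "), "\n")
  invisible(x)
}

#' Threshold-gated fitness of a cell-block
#'
#' Gene expression downstream of the quorum-sensing promoter is a Boolean
#' process gated by the signal concentration: at or below the threshold the
#' fitness is the strain's base fitness; strictly above it, the fitness gain is
#' added (and the sum clamped to 1). There is no graded response.
#'
#' @param strain A [strain_spec()].
#' @param conc Local concentration(s) of the strain's sensed molecule, in nM
#'   (vectorised).
#' @return Division probability (same length as `conc`).
#' @export
compute_fitness <- function(strain, conc) {
  stopifnot(inherits(strain, "strain_spec"))
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  pmin(1, strain$base_fitness + strain$fitness_gain * (conc > strain$threshold))
}

#' Band-pass reporter expression
#'
#' A band-pass genetic filter expresses its reporter only when the local signal
#' concentration lies within a window; both boundaries are inclusive.
#'
#' @param conc Concentration(s) in nM (vectorised).
#' @param low,high Window boundaries in nM, `0 <= low < high` (`high` may be
#'   `Inf`).
#' @return Logical vector.
#' @examples
#' bandpass_expression(c(5, 10, 50, 200, 201), 10, 200)
#' @export
bandpass_expression <- function(conc, low, high) {
  if (length(low) != 1L || length(high) != 1L || low < 0 || low >= high)
    stop("need 0 <= low < high", call. = FALSE)
  conc >= low & conc <= high
}

#' Build a coupled consortium of strains
#'
#' Convenience constructor wiring `n_strains` strains through
#' [make_topology()]. Strain `i` produces the i-th molecule (AHL registry names
#' for QSMM, `"metabolite_i"` for MMM) and senses the molecule of the strain
#' designated by the topology. All strains share the supplied parameter
#' defaults; MMM strains get base fitness 0 and the metabolite diffusivity
#' 5e-10 m^2/s is used by [simulation_config()] for their molecules.
#'
#' @param n_strains Number of strains (>= 2).
#' @param model_kind `"QSMM"` or `"MMM"`.
#' @param secretion_rate,threshold,fitness_gain Shared strain parameters.
#' @param base_fitness Base fitness for QSMM strains (MMM strains always 0).
#' @return A list with elements `strains` (list of [strain_spec()]) and
#'   `topology`.
#' @export
make_consortium <- function(n_strains = 2, model_kind = c("QSMM", "MMM"),
                            secretion_rate = 1.6e-2, threshold = 5,
                            base_fitness = 0.25, fitness_gain = 0.05) {
  model_kind <- match.arg(model_kind)
  topo <- make_topology(n_strains)
  mols <- if (model_kind == "QSMM" && n_strains <= length(ahl_registry()))
    ahl_registry()[seq_len(topo$n_strains)]
  else paste0(if (model_kind == "MMM") "metabolite_" else "AHL_", seq_len(topo$n_strains))
  # strain i senses the molecule of the producer p with sensed_by[p] == i
  producer_for <- match(seq_len(topo$n_strains), topo$sensed_by)
  strains <- lapply(seq_len(topo$n_strains), function(i)
    strain_spec(paste0("S", i), produced = mols[[i]], sensed = mols[[producer_for[i]]],
                secretion_rate = secretion_rate, threshold = threshold,
                base_fitness = if (model_kind == "MMM") 0 else base_fitness,
                fitness_gain = fitness_gain, model_kind = model_kind))
  list(strains = strains, topology = topo)
}
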