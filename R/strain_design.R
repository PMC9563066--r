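#' Constraint-based metabolic model
#'
#' A compact stoichiometric model for flux balance analysis: `S` (metabolites x
#' reactions), flux bounds `lb`/`ub`, an objective (biomass) reaction, a gene
#' list and per-reaction gene-reaction rules (boolean expressions over gene
#' identifiers with `and`, `or` and parentheses; `NA`/`""` means
#' unconditionally available).
#'
#' @param S Stoichiometric matrix (metabolites x reactions).
#' @param lb,ub Lower/upper flux bounds, length `ncol(S)`; `lb <= ub`.
#' @param objective Index or reaction id of the single biomass reaction.
#' @param reaction_ids,metabolite_ids Optional identifier vectors.
#' @param genes Character vector of gene identifiers.
#' @param rules Character vector of gene-reaction rules, length `ncol(S)`.
#' @return A `metabolic_model` object.
#' @export
metabolic_model <- function(S, lb, ub, objective,
                            reaction_ids = NULL, metabolite_ids = NULL,
                            genes = character(0), rules = NULL) {
  S <- as.matrix(S)
  n <- ncol(S)
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(n))
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(nrow(S)))
  if (is.null(rules)) rules <- rep(NA_character_, n)
  if (length(lb) != n || length(ub) != n || length(rules) != n ||
      length(reaction_ids) != n || length(metabolite_ids) != nrow(S))
    stop("inconsistent model dimensions", call. = FALSE)
  if (any(lb > ub)) stop("lb must be <= ub", call. = FALSE)
  if (is.character(objective)) objective <- match(objective, reaction_ids)
  if (length(objective) != 1L || is.na(objective) || objective < 1 || objective > n)
    stop("objective must designate exactly one reaction", call. = FALSE)
  structure(list(S = S, lb = as.numeric(lb), ub = as.numeric(ub),
                 objective = as.integer(objective),
                 reaction_ids = reaction_ids, metabolite_ids = metabolite_ids,
                 genes = genes, rules = rules),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites x %d reactions, %d genes, objective: %s\n",
              nrow(x$S), ncol(x$S), length(x$genes), x$reaction_ids[x$objective]))
  invisible(x)
}

#' Maximal growth rate by flux balance analysis
#'
#' Solves the linear programme `max c'v` subject to steady-state mass balance
#' `S v = 0` and `lb <= v <= ub`, where `c` selects the biomass reaction. The
#' optimum is the predicted growth rate (1/h for genome-scale models). The LP
#' is solved by the package's two-phase simplex with Bland's rule, which
#' remains exact on the degenerate programmes produced by gene knockouts.
#'
#' @param model A [metabolic_model()].
#' @return The optimal biomass flux (scalar).
#' @export
fba_growth <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  n <- ncol(model$S)
  cc <- numeric(n); cc[model$objective] <- 1
  fin_lb <- ifelse(is.finite(model$lb), model$lb, -1e6)
  fin_ub <- ifelse(is.finite(model$ub), model$ub, 1e6)
  res <- lp_solve_bounded(cc, model$S, numeric(nrow(model$S)), fin_lb, fin_ub)
  if (res$status != "optimal")
    stop(sprintf("FBA LP did not solve: %s", res$status), call. = FALSE)
  res$value
}

# --- gene-reaction rule evaluation -----------------------------------------

# tokenize a GPR rule into gene ids, and/or operators and parentheses
gpr_tokens <- function(rule) {
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  toks
}

#' Evaluate a gene-reaction rule
#'
#' Boolean evaluation with `and`/`or` (case-insensitive) and parentheses, the
#' dialect used by standard genome-scale models. A gene identifier evaluates
#' to `TRUE` iff it is in `present`.
#'
#' @param rule Rule string (`NA` or `""` means always active).
#' @param present Character vector of present genes.
#' @return Logical scalar: is the reaction available?
#' @export
eval_gpr <- function(rule, present) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(TRUE)
  toks <- gpr_tokens(rule)
  mapped <- vapply(toks, function(tk) {
    lt <- tolower(tk)
    if (tk == "(" || tk == ")") tk
    else if (lt == "and" || tk == "&&" || tk == "&") "&&"
    else if (lt == "or" || tk == "||" || tk == "|") "||"
    else if (grepl("^[A-Za-z0-9_.:-]+$", tk)) as.character(tk %in% present)
    else stop(sprintf("malformed gene-reaction rule token '%s'", tk), call. = FALSE)
  }, character(1))
  expr <- paste(mapped, collapse = " ")
  out <- tryCatch(eval(parse(text = expr)[[1]], envir = baseenv()),
                  error = function(e)
                    stop(sprintf("malformed gene-reaction rule '%s'", rule), call. = FALSE))
  isTRUE(out)
}

#' Simulate a single-gene deletion
#'
#' Every reaction whose gene-reaction rule evaluates to `FALSE` with the gene
#' removed is disabled (`lb = ub = 0`); all other reactions are untouched.
#'
#' @param model A [metabolic_model()].
#' @param gene Gene identifier (must be in `model$genes`).
#' @return The knockout model.
#' @export
delete_gene <- function(model, gene) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!gene %in% model$genes)
    stop(sprintf("unknown gene '%s'", gene), call. = FALSE)
  present <- setdiff(model$genes, gene)
  off <- vapply(model$rules, function(r) !eval_gpr(r, present), logical(1))
  model$lb[off] <- 0
  model$ub[off] <- 0
  model
}

#' Screen single-gene knockouts for reduced-growth candidates
#'
#' Computes the knockout/wild-type growth ratio for every gene and flags as
#' candidates the non-lethal knockouts whose growth ratio lies in
#' `[lo, hi]` (default 30-90 % of wild type). Ratios below `1e-6` are treated
#' as lethal.
#'
#' @param model A [metabolic_model()] with `fba_growth(model) > 0`.
#' @param lo,hi Candidate growth-ratio window (defaults 0.30 and 0.90).
#' @return A `data.frame` with columns `gene`, `growth`, `ratio`, `lethal`,
#'   `candidate`, one row per gene.
#' @export
screen_candidates <- function(model, lo = 0.30, hi = 0.90) {
  stopifnot(inherits(model, "metabolic_model"))
  wt <- fba_growth(model)
  if (wt <= 0) stop("wild-type growth is zero: nothing to screen against", call. = FALSE)
  growth <- vapply(model$genes, function(g) fba_growth(delete_gene(model, g)), numeric(1))
  ratio <- growth / wt
  lethal <- ratio < 1e-6
  data.frame(gene = model$genes, growth = unname(growth), ratio = unname(ratio),
             lethal = unname(lethal),
             candidate = unname(!lethal & ratio >= lo & ratio <= hi),
             row.names = NULL)
}

#' Base fitness of a designed strain
#'
#' The wild-type fitness is the simulation time step divided by the generation
#' time, so a wild-type block divides once per generation time on average. A
#' knockout strain's base fitness is the wild-type fitness multiplied by its
#' FBA growth ratio.
#'
#' @param dt_min Time step in minutes.
#' @param generation_time_min Generation time in minutes (>= `dt_min`).
#' @param growth_ratio Knockout/wild-type growth ratio in `[0, 1]`.
#' @return Per-step division probability.
#' @examples
#' base_fitness(10, 20, 0.5)  # 0.25
#' @export
base_fitness <- function(dt_min, generation_time_min, growth_ratio) {
  if (generation_time_min < dt_min)
    stop("generation time must be >= the time step (fitness would exceed 1)",
         call. = FALSE)
  if (growth_ratio < 0 || growth_ratio > 1)
    stop("growth_ratio must be in [0, 1]", call. = FALSE)
  (dt_min / generation_time_min) * growth_ratio
}

#' Generation time implied by an FBA growth rate
#'
#' `ln(2) / mu`, converted to minutes, for a growth rate `mu` in 1/h.
#'
#' @param mu_per_h Specific growth rate in 1/h (> 0).
#' @return Generation (doubling) time in minutes.
#' @export
generation_time_from_growth <- function(mu_per_h) {
  if (mu_per_h <= 0) stop("growth rate must be positive", call. = FALSE)
  log(2) / mu_per_h * 60
}
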