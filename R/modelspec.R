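#' Parameter sets
#'
#' A `param_set` is an ordered table of named, strictly positive parameter
#' values belonging to the three identifiable classes of the surrogate cell:
#' promoter binding probabilities (`binding_probability`, dimensionless, in
#' (0, 1]), RNA half-lives (`rna_half_life`, time units) and reaction turnover
#' numbers (`turnover_number`, per unit time).
#'
#' @param name character vector of unique parameter names.
#' @param class character vector, one of `"binding_probability"`,
#'   `"rna_half_life"`, `"turnover_number"`.
#' @param value strictly positive numeric vector.
#' @return A data frame of class `param_set` with columns `name`, `class`,
#'   `value`.
#' @export
param_set <- function(name, class, value) {
  x <- data.frame(name = as.character(name), class = as.character(class),
                  value = as.numeric(value), stringsAsFactors = FALSE)
  class(x) <- c("param_set", "data.frame")
  validate_param_set(x)
  x
}

PARAM_CLASSES <- c("binding_probability", "rna_half_life", "turnover_number")

validate_param_set <- function(x) {
  stopifnot(is.data.frame(x), all(c("name", "class", "value") %in% names(x)))
  if (anyDuplicated(x$name)) stop("parameter names must be unique")
  if (!all(x$class %in% PARAM_CLASSES))
    stop("unknown parameter class: ", paste(setdiff(x$class, PARAM_CLASSES), collapse = ", "))
  if (any(!is.finite(x$value)) || any(x$value <= 0))
    stop("invalid parameter: all values must be finite and > 0")
  bp <- x$value[x$class == "binding_probability"]
  if (any(bp > 1)) stop("invalid parameter: binding probabilities must be <= 1")
  invisible(x)
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("<param_set> %d parameters (%s)\n", nrow(x),
              paste(sprintf("%s: %d", PARAM_CLASSES,
                            tabulate(factor(x$class, PARAM_CLASSES), 3)),
                    collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Extract parameter values as a named vector
#'
#' @param params a [param_set].
#' @param class optional class filter.
#' @return named numeric vector.
#' @export
param_values <- function(params, class = NULL) {
  if (!is.null(class)) params <- params[params$class %in% class, ]
  stats::setNames(params$value, params$name)
}

#' Apply multiplicative fold changes to a parameter set
#'
#' Binding probabilities are capped at 1 after the change; values must remain
#' positive.
#'
#' @param params a [param_set].
#' @param folds named numeric vector of fold changes (names must exist in
#'   `params`).
#' @return the modified `param_set`.
#' @export
apply_folds <- function(params, folds) {
  stopifnot(all(names(folds) %in% params$name), all(folds > 0))
  i <- match(names(folds), params$name)
  params$value[i] <- params$value[i] * folds
  bp <- params$class == "binding_probability"
  params$value[bp] <- pmin(params$value[bp], 1)
  validate_param_set(params)
  params
}

#' Surrogate whole-cell model specification
#'
#' Defines the wiring of the toy cell: genes with chromosome positions
#' (fractions of the chromosome from the origin of replication, oriC at 0,
#' terminus terC at 0.5, symmetric bidirectional forks), a gene-to-reaction
#' map for the metabolic genes (one enzyme per reaction), the wild-type
#' parameter table and the kinetic/growth constants.
#'
#' @param n_genes number of genes (>= 2).
#' @param metabolic_genes indices of genes acting as enzymes; gene
#'   `metabolic_genes[r]` catalyses reaction `r`.
#' @param gene_positions chromosome positions in `[0, 1)`, unique; defaults to
#'   an even spread.
#' @param wildtype a [param_set] with one binding probability and one half-life
#'   per gene and one turnover number per reaction, or `NULL` for the built-in
#'   wild type.
#' @param n_metabolites number of metabolite pools; reactions are assigned
#'   round-robin.
#' @param constants named list overriding the default constants, see Details.
#'
#' @details The constants are: `initial_mass` (arbitrary units), `repl_mass`
#' (replication-initiation mass threshold), `fork_speed` (chromosome fraction
#' per unit time per fork), `k_txn` (transcription events per unit time per
#' gene copy per unit binding probability), `k_tl` (protein synthesis per RNA
#' per unit time), `K` (metabolite saturation constant), `S_star` (homeostatic
#' metabolite set point), `k_relax` (metabolite relaxation rate), `gamma_met`
#' (exponent coupling specific flux to the metabolite target), `mu0` (baseline
#' growth rate per unit time), `ratio_floor`/`ratio_cap` (clamp on normalized
#' fluxes entering the growth law), `tau_p` (protein initial-condition time
#' scale), `dt` (time step, about 1% of the wild-type doubling time),
#' `max_time` (simulation horizon).
#'
#' @return an object of class `cell_model_spec`.
#' @export
cell_model_spec <- function(n_genes = 12,
                            metabolic_genes = seq_len(9),
                            gene_positions = NULL,
                            wildtype = NULL,
                            n_metabolites = 3,
                            constants = list()) {
  stopifnot(n_genes >= 2, length(metabolic_genes) >= 1,
            all(metabolic_genes %in% seq_len(n_genes)),
            !anyDuplicated(metabolic_genes))
  n_rxn <- length(metabolic_genes)
  if (is.null(gene_positions)) {
    # spread loci over the chromosome, avoiding oriC/terC exactly
    gene_positions <- ((seq_len(n_genes) - 1) / n_genes + 0.037) %% 1
  }
  stopifnot(length(gene_positions) == n_genes,
            all(gene_positions >= 0 & gene_positions < 1),
            !anyDuplicated(gene_positions))

  cst <- list(
    initial_mass = 1.0,
    repl_mass    = 1.25,
    fork_speed   = 1.0,
    k_txn        = 1000,
    k_tl         = 10,
    K            = 1.0,
    S_star       = 2.0,
    k_relax      = 30,
    gamma_met    = 0.3,
    mu0          = 0.48,
    ratio_floor  = 0.02,
    ratio_cap    = 3.0,
    tau_p        = 1.3,
    dt           = 0.01,
    max_time     = 4.0
  )
  cst[names(constants)] <- constants
  if (any(!vapply(cst, function(z) is.numeric(z) && z > 0, TRUE)))
    stop("all model constants must be strictly positive")

  gene_names <- sprintf("g%02d", seq_len(n_genes))
  rxn_names  <- sprintf("r%02d", seq_len(n_rxn))
  if (is.null(wildtype)) wildtype <- default_wildtype(n_genes, n_rxn, gene_names, rxn_names)

  spec <- structure(list(
    n_genes = n_genes,
    gene_names = gene_names,
    gene_positions = gene_positions,
    metabolic_genes = as.integer(metabolic_genes),
    n_reactions = n_rxn,
    reaction_names = rxn_names,
    met_of_reaction = ((seq_len(n_rxn) - 1L) %% n_metabolites) + 1L,
    n_metabolites = as.integer(n_metabolites),
    wildtype = wildtype,
    constants = cst
  ), class = "cell_model_spec")
  validate_model_spec(spec)
  # reference fluxes (birth-state wild-type fluxes) close the growth law
  spec$constants$ref_flux <- reference_fluxes(spec, wildtype)
  spec
}

default_wildtype <- function(n_genes, n_rxn, gene_names, rxn_names) {
  # fixed, deterministic wild type: values vary across genes but are not random
  p  <- 0.2 + 0.6 * (seq_len(n_genes) %% 5) / 4          # 0.2 .. 0.8
  th <- 0.03 + 0.05 * (seq_len(n_genes) %% 4) / 3        # 0.03 .. 0.08
  kc <- 5 * (1 + (seq_len(n_rxn) %% 3)) / 1.5            # ~6.7 .. 10
  param_set(
    name  = c(paste0("p_", gene_names), paste0("thalf_", gene_names),
              paste0("kcat_", rxn_names)),
    class = rep(PARAM_CLASSES, c(n_genes, n_genes, n_rxn)),
    value = c(p, th, kc)
  )
}

validate_model_spec <- function(spec) {
  wt <- spec$wildtype
  validate_param_set(wt)
  cnt <- tabulate(factor(wt$class, PARAM_CLASSES), 3)
  if (cnt[1] != spec$n_genes || cnt[2] != spec$n_genes || cnt[3] != spec$n_reactions)
    stop("wildtype class counts must match the model layout")
  invisible(spec)
}

# Wild-type fluxes at the birth state; the growth law normalizes by these.
reference_fluxes <- function(spec, params) {
  cst <- spec$constants
  st <- init_state(spec, params, deterministic = TRUE)
  sat <- cst$S_star / (cst$K + cst$S_star)
  kcat <- param_values(params, "turnover_number")
  unname(kcat * st$protein[spec$metabolic_genes] * sat)
}

#' @export
print.cell_model_spec <- function(x, ...) {
  cat(sprintf(
    "<cell_model_spec> %d genes (%d metabolic), %d reactions, %d metabolites, %d parameters\n",
    x$n_genes, length(x$metabolic_genes), x$n_reactions, x$n_metabolites,
    nrow(x$wildtype)))
  invisible(x)
}

# ---- serialization -----------------------------------------------------------

#' Read and write parameter sets as TSV
#'
#' The layout is a three-column table with header `name  class  value`.
#'
#' @param params a [param_set].
#' @param path file path.
#' @return `read_param_set` returns a [param_set]; `write_param_set` returns
#'   `path` invisibly.
#' @export
write_param_set <- function(params, path) {
  utils::write.table(as.data.frame(params)[, c("name", "class", "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_param_set
#' @export
read_param_set <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  param_set(x$name, x$class, x$value)
}

#' Read and write a model specification
#'
#' The layout constants go to a JSON document and the wild-type parameter
#' table to a TSV file next to it.
#'
#' @param spec a [cell_model_spec].
#' @param dir directory to hold `spec.json` and `wildtype.tsv`.
#' @return `read_model_spec` returns a [cell_model_spec]; `write_model_spec`
#'   returns `dir` invisibly.
#' @export
write_model_spec <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  doc <- spec[setdiff(names(spec), "wildtype")]
  jsonlite::write_json(doc, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  write_param_set(spec$wildtype, file.path(dir, "wildtype.tsv"))
  invisible(dir)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(dir) {
  doc <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  wt <- read_param_set(file.path(dir, "wildtype.tsv"))
  spec <- cell_model_spec(
    n_genes = doc$n_genes,
    metabolic_genes = doc$metabolic_genes,
    gene_positions = doc$gene_positions,
    wildtype = wt,
    n_metabolites = doc$n_metabolites,
    constants = doc$constants[setdiff(names(doc$constants), "ref_flux")]
  )
  spec
}

# deterministic integer substreams below 2^31, derived from a master seed
# (rolling polynomial hash mod the Mersenne prime 2^31 - 1; intermediate
# products stay far below 2^53 so double arithmetic is exact)
derive_seed <- function(master, tag) {
  m <- 2147483647
  a <- (as.numeric(master) %% m) * 48271 %% m
  for (v in utf8ToInt(as.character(tag))) a <- (a * 131 + v) %% m
  as.integer((a * 16807) %% m + 1)
}
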