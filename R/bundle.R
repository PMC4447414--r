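# Population data bundles: the eight in silico "experimental" data classes.
#
# single_cell            growth/mass/volume time courses + event times
# metabolite_concentrations  time-averaged metabolite pools
# dnaseq                 time-averaged copy number per chromosome bin
# chipseq                lifetime transcription-initiation counts per gene
# rnaseq                 count-sampled time-averaged RNA abundance
# rna_array              time-averaged RNA abundance, multiplicative noise
# protein_array          time-averaged protein abundance, multiplicative noise
# reaction_fluxes        time-averaged reaction fluxes

DATA_CLASSES <- c("single_cell", "metabolite_concentrations", "dnaseq",
                  "rnaseq", "chipseq", "rna_array", "protein_array",
                  "reaction_fluxes")

# fixed measurement layout; depends only on the spec
bundle_registry <- function(spec, tc_grid = seq(0.1, 0.5, by = 0.1),
                            n_bins = 8) {
  mids <- (seq_len(n_bins) - 0.5) / n_bins * 0.5   # bin midpoints, oriC -> terC
  rows <- rbind(
    data.frame(data_class = "single_cell",
               entity = rep(c("mass", "volume", "growth_rate"),
                            each = length(tc_grid)),
               time = rep(tc_grid, 3)),
    data.frame(data_class = "single_cell",
               entity = c("t_initiation", "t_completion", "t_cytokinesis"),
               time = NA_real_),
    data.frame(data_class = "metabolite_concentrations",
               entity = sprintf("m%02d", seq_len(spec$n_metabolites)),
               time = NA_real_),
    data.frame(data_class = "dnaseq",
               entity = sprintf("bin_%0.4f", mids), time = NA_real_),
    data.frame(data_class = "rnaseq", entity = spec$gene_names, time = NA_real_),
    data.frame(data_class = "chipseq", entity = spec$gene_names, time = NA_real_),
    data.frame(data_class = "rna_array", entity = spec$gene_names, time = NA_real_),
    data.frame(data_class = "protein_array", entity = spec$gene_names,
               time = NA_real_),
    data.frame(data_class = "reaction_fluxes", entity = spec$reaction_names,
               time = NA_real_)
  )
  rows$index <- seq_len(nrow(rows))
  attr(rows, "bin_mids") <- mids
  rows[, c("index", "data_class", "entity", "time")]
}

# one cell's full measurement vector; measurement layers (sequencing counts,
# array noise) are sampled from the current RNG stream in stochastic mode
cell_measurements <- function(spec, traj, registry, stochastic,
                              seq_depth = 20, array_sd = 0.1) {
  cst <- spec$constants
  tt <- traj$time
  t_end <- tt[length(tt)]
  grid <- registry$time[registry$data_class == "single_cell" &
                          registry$entity == "mass"]

  at <- function(y) stats::approx(tt, y, xout = grid, rule = 2)$y
  sc <- c(at(traj$mass), at(traj$volume), at(traj$growth_rate),
          traj$events$t_initiation, traj$events$t_completion,
          traj$events$t_cytokinesis)

  met <- time_average(tt, traj$metabolites)

  mids <- as.numeric(sub("bin_", "", grep("^bin_", registry$entity, value = TRUE)))
  t_init <- traj$events$t_initiation
  if (is.na(t_init)) {
    dna <- rep(1, length(mids))
  } else {
    t_pass <- t_init + mids / cst$fork_speed
    dna <- 1 + pmax(0, t_end - t_pass) / t_end
  }

  rna_bar <- time_average(tt, traj$rna)
  prot_bar <- time_average(tt, traj$protein)
  flux_bar <- time_average(tt, traj$flux)

  if (stochastic) {
    rnaseq <- stats::rpois(length(rna_bar), rna_bar * seq_depth) / seq_depth
    lg <- function(n) exp(stats::rnorm(n, -array_sd^2 / 2, array_sd))
    rna_arr <- rna_bar * lg(length(rna_bar))
    prot_arr <- prot_bar * lg(length(prot_bar))
  } else {
    rnaseq <- rna_bar; rna_arr <- rna_bar; prot_arr <- prot_bar
  }

  c(sc, met, dna, rnaseq, traj$chip, rna_arr, prot_arr, flux_bar)
}

#' Simulate a cell population and assemble its data bundle
#'
#' Runs `n_cells` independent cells (per-cell seeds derived from `seed`) and
#' returns per-measurement means and unbiased variances across cells for the
#' eight data classes. In deterministic mode all cells are identical and every
#' variance is zero.
#'
#' @param spec a [cell_model_spec].
#' @param params a [param_set].
#' @param n_cells number of cells (>= 2 so the variance is defined).
#' @param seed integer master seed for the population.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return an object of class `data_bundle`: `registry` (flat measurement
#'   index), `mean`, `var`, `cells` (cells x measurements matrix), `n_cells`,
#'   `n_undivided`, `seed`, `mode`.
#' @export
simulate_population <- function(spec, params, n_cells = 32, seed = 1,
                                mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  if (n_cells < 2) stop("n_cells must be >= 2 for the variance to be defined")
  registry <- bundle_registry(spec)
  det <- mode == "deterministic"
  if (det) {
    traj <- simulate_cell(spec, params, mode = "deterministic")
    row <- cell_measurements(spec, traj, registry, stochastic = FALSE)
    cells <- matrix(rep(row, each = n_cells), nrow = n_cells)
    n_undiv <- if (traj$divided) 0L else n_cells
  } else {
    cells <- matrix(NA_real_, n_cells, nrow(registry))
    n_undiv <- 0L
    for (i in seq_len(n_cells)) {
      set.seed(derive_seed(seed, paste0("cell", i)))
      traj <- simulate_cell(spec, params, mode = "stochastic")
      if (!traj$divided) n_undiv <- n_undiv + 1L
      cells[i, ] <- cell_measurements(spec, traj, registry, stochastic = TRUE)
    }
  }
  mu <- colMeans(cells, na.rm = TRUE)
  va <- apply(cells, 2, stats::var, na.rm = TRUE)
  va[!is.finite(va)] <- NA_real_
  mu[is.nan(mu)] <- NA_real_
  structure(list(registry = registry, mean = unname(mu), var = unname(va),
                 cells = cells, n_cells = n_cells, n_undivided = n_undiv,
                 seed = seed, mode = mode),
            class = "data_bundle")
}

#' @export
print.data_bundle <- function(x, ...) {
  cat(sprintf("<data_bundle> M = %d measurements, 8 data classes, %d cells (%s)\n",
              nrow(x$registry), x$n_cells, x$mode))
  invisible(x)
}

#' Extract measurements of one data class from a bundle
#'
#' @param bundle a [data_bundle].
#' @param data_class one of the eight data-class names.
#' @return data frame `index`, `entity`, `time`, `mean`, `variance`.
#' @export
bundle_slice <- function(bundle, data_class) {
  stopifnot(data_class %in% DATA_CLASSES)
  i <- bundle$registry$data_class == data_class
  out <- bundle$registry[i, ]
  out$mean <- bundle$mean[i]
  out$variance <- bundle$var[i]
  out
}

# small rolling checksum over the registry (no external digest dependency)
registry_checksum <- function(registry) {
  s <- paste(registry$data_class, registry$entity, registry$time,
             collapse = ";")
  h <- 2166136261
  for (v in utf8ToInt(s)) h <- ((h %% 2^19) * 16777619 + v) %% 2^32
  sprintf("%08x", h)
}

#' Read and write data bundles
#'
#' One TSV per data class (`index  entity  time  mean  variance`) plus a JSON
#' manifest recording `n_cells`, `seed`, `M` and a registry checksum. The
#' per-cell matrix is not serialized.
#'
#' @param bundle a [data_bundle].
#' @param dir directory for the TSV files and `manifest.json`.
#' @return `read_bundle` returns a [data_bundle] (without `cells`);
#'   `write_bundle` returns `dir` invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (dc in DATA_CLASSES) {
    utils::write.table(bundle_slice(bundle, dc),
                       file.path(dir, paste0(dc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(n_cells = bundle$n_cells, seed = bundle$seed,
                   mode = bundle$mode, M = nrow(bundle$registry),
                   n_undivided = bundle$n_undivided,
                   registry_checksum = registry_checksum(bundle$registry))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  parts <- lapply(DATA_CLASSES, function(dc) {
    x <- utils::read.table(file.path(dir, paste0(dc, ".tsv")), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
    x$data_class <- dc
    x
  })
  tab <- do.call(rbind, parts)
  tab <- tab[order(tab$index), ]
  registry <- tab[, c("index", "data_class", "entity", "time")]
  rownames(registry) <- NULL
  stopifnot(identical(registry_checksum(registry), manifest$registry_checksum))
  structure(list(registry = registry, mean = tab$mean, var = tab$variance,
                 cells = NULL, n_cells = manifest$n_cells,
                 n_undivided = manifest$n_undivided,
                 seed = manifest$seed, mode = manifest$mode),
            class = "data_bundle")
}
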