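# Challenge package directory layout:
#   wildtype.tsv                 disclosed wild-type parameters
#   unknowns.tsv                 name, class of the 30 unknowns
#   mutant/                      32-cell mutant data bundle
#   perturbations/<name>_<dir>/  8-cell perturbation bundles
#   manifest.json                seed, budget, released keys, checksums
#   spec/                        model specification
#   truth.tsv.sealed             mutant truth; scoring only

#' Read and write challenge packages
#'
#' Serializes a `challenge_package` to the on-disk layout above. The sealed
#' truth lives in `truth.tsv.sealed`, outside the estimator-facing files.
#'
#' @param pkg a `challenge_package`.
#' @param dir target directory.
#' @return `read_challenge` returns a `challenge_package`; `write_challenge`
#'   returns `dir` invisibly.
#' @export
write_challenge <- function(pkg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_model_spec(pkg$spec, file.path(dir, "spec"))
  write_param_set(pkg$wildtype, file.path(dir, "wildtype.tsv"))
  utils::write.table(as.data.frame(pkg$unknowns), file.path(dir, "unknowns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bundle(pkg$mutant_bundle, file.path(dir, "mutant"))
  for (key in names(pkg$perturbations))
    write_bundle(pkg$perturbations[[key]], file.path(dir, "perturbations", key))
  manifest <- list(
    master_seed = pkg$master_seed,
    budget = pkg$ledger$budget,
    released = as.list(pkg$ledger$released),
    n_perturbation_datasets = perturbation_dataset_count(pkg),
    n_mutant_datasets = mutant_dataset_count(pkg),
    registry_checksum = registry_checksum(pkg$mutant_bundle$registry))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  truth <- challenge_truth(pkg)
  tt <- as.data.frame(truth$mutant)
  tt$modified <- as.integer(tt$name %in% truth$modifications$name)
  tt$wildtype_value <- pkg$wildtype$value[match(tt$name, pkg$wildtype$name)]
  utils::write.table(tt, file.path(dir, "truth.tsv.sealed"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_challenge
#' @export
read_challenge <- function(dir) {
  spec <- read_model_spec(file.path(dir, "spec"))
  wildtype <- read_param_set(file.path(dir, "wildtype.tsv"))
  unknowns <- utils::read.table(file.path(dir, "unknowns.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  class(unknowns) <- c("unknown_set", "data.frame")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  mutant_bundle <- read_bundle(file.path(dir, "mutant"))
  keys <- list.dirs(file.path(dir, "perturbations"), recursive = FALSE,
                    full.names = FALSE)
  perturbations <- lapply(keys, function(k)
    read_bundle(file.path(dir, "perturbations", k)))
  names(perturbations) <- keys

  ledger <- new.env(parent = emptyenv())
  ledger$budget <- as.integer(manifest$budget)
  ledger$released <- as.character(unlist(manifest$released))

  tt <- utils::read.table(file.path(dir, "truth.tsv.sealed"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  mutant <- param_set(tt$name, tt$class, tt$value)
  mods <- tt[tt$modified == 1, ]
  truth <- structure(list(
    mutant = mutant, wildtype = wildtype,
    modifications = data.frame(name = mods$name, wildtype = mods$wildtype_value,
                               mutant = mods$value,
                               fold = mods$value / mods$wildtype_value,
                               stringsAsFactors = FALSE),
    step_log = NULL, achieved_ratio = NA_real_), class = "mutant_strain")

  parts <- strsplit(keys, "_(?=up$|down$)", perl = TRUE)
  conditions <- data.frame(name = vapply(parts, `[`, "", 1),
                           direction = vapply(parts, `[`, "", 2),
                           stringsAsFactors = FALSE)
  pkg <- structure(list(spec = spec, wildtype = wildtype,
                        mutant_bundle = mutant_bundle, unknowns = unknowns,
                        perturbations = perturbations, conditions = conditions,
                        ledger = ledger, master_seed = manifest$master_seed),
                   class = "challenge_package")
  attr(pkg, "sealed_truth") <- truth
  pkg
}
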