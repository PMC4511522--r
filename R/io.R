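#' Read and write long-format phenotype tables
#'
#' The on-disk format is a strict tidy CSV with header
#' `assay_id,genotype,allele_id,block_id,timepoint,arm,replicate,value,unit`,
#' `NA` as the missing token, UTF-8 encoding and decimal points.  Reading
#' validates the schema and rejects duplicated measurement keys
#' (assay, genotype, allele, block, timepoint, arm, replicate), listing the
#' offending line numbers.
#'
#' @param table a `phenotype_table` data frame.
#' @param path file path.
#' @return `read_phenotype_csv()` returns a `phenotype_table`;
#'   `write_phenotype_csv()` returns `path` invisibly.
#' @name phenotype-io
NULL

.PHENO_COLS <- c("assay_id", "genotype", "allele_id", "block_id", "timepoint",
                 "arm", "replicate", "value", "unit")

#' @rdname phenotype-io
#' @export
write_phenotype_csv <- function(table, path) {
  .assert(all(.PHENO_COLS %in% names(table)),
          paste("table must have columns:", paste(.PHENO_COLS, collapse = ", ")))
  write.csv(table[, .PHENO_COLS], path, row.names = FALSE, na = "NA",
            fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname phenotype-io
#' @export
read_phenotype_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                  fileEncoding = "UTF-8")
  missing_cols <- setdiff(.PHENO_COLS, names(tab))
  if (length(missing_cols)) {
    stop("phenotype CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(tab$value) || any(!is.finite(tab$value))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab$value)))) + 1L
    stop("non-finite or non-numeric value(s) at line(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(tab[setdiff(.PHENO_COLS, c("value", "unit"))], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicated measurement key(s) at line(s): ",
         paste(head(which(dup) + 1L, 10), collapse = ", "), call. = FALSE)
  }
  class(tab) <- c("phenotype_table", class(tab))
  tab
}

#' Read and write lines-by-assays matrices as TSV
#'
#' Matrices are written lines-as-rows / assays-as-columns with the row
#' identifier in a leading `id` column and the literal token `NA` for
#' unmeasured cells; the round trip is exact.
#'
#' @param m numeric or character matrix with dimnames.
#' @param path file path.
#' @return `read_matrix_tsv()` returns a matrix; `write_matrix_tsv()`
#'   returns `path` invisibly.
#' @name matrix-io
NULL

#' @rdname matrix-io
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "NA",
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname matrix-io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                   check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# (de)serialize a sim_config through plain YAML lists
.config_to_list <- function(cfg) {
  list(
    assays = lapply(cfg$assays, function(a) a[setdiff(names(a), "unit")]),
    allele_map = as.list(cfg$allele_map),
    effect_matrix = list(genes = rownames(cfg$effect_matrix),
                         assays = colnames(cfg$effect_matrix),
                         values = as.vector(cfg$effect_matrix)),
    block_sd = cfg$block_sd, n_per_cell = cfg$n_per_cell,
    reference = cfg$reference, seed = cfg$seed)
}

.list_to_config <- function(x) {
  assays <- lapply(x$assays, function(a) do.call(assay_design, a))
  em <- matrix(as.numeric(x$effect_matrix$values),
               length(x$effect_matrix$genes), length(x$effect_matrix$assays),
               dimnames = list(x$effect_matrix$genes, x$effect_matrix$assays))
  sim_config(assays, allele_map = unlist(x$allele_map), effect_matrix = em,
             block_sd = x$block_sd, n_per_cell = x$n_per_cell,
             reference = x$reference, seed = x$seed)
}

#' Read or write a pipeline configuration as YAML
#'
#' A pipeline configuration bundles either a simulation configuration
#' (`sim:`) or a path to an input phenotype CSV (`input_csv:` plus assay
#' declarations), the harmonization parameters (`B`, `n_boot`,
#' `family_scope`, `z_cap`, `tier_cuts`), the clustering recipe
#' (`"ward_euclidean"` or `"complete_pearson"`), and the global `seed`.
#' Validation happens before any computation: unknown assay families or
#' inconsistent tier cutpoints fail at read time.
#'
#' @param path YAML file path.
#' @param config a `pipeline_config` list (from [pipeline_config()]).
#' @return `read_pipeline_config()` returns a validated `pipeline_config`.
#' @name pipeline-io
NULL

#' Build a validated pipeline configuration
#'
#' @param sim a [sim_config()] (or `NULL` when reading from CSV).
#' @param input_csv path to a phenotype CSV (used when `sim` is `NULL`).
#' @param assays assay designs for CSV input (ignored when `sim` given).
#' @param B,n_boot,family_scope,z_cap,tier_cuts harmonization parameters,
#'   see [harmonize_z()].
#' @param clustering `"ward_euclidean"` (default) or `"complete_pearson"`.
#' @param seed global pipeline seed.
#' @param heatmap also render a PNG heatmap (default FALSE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, input_csv = NULL, assays = NULL,
                            B = 200, n_boot = 15,
                            family_scope = "per_experiment",
                            z_cap = 8,
                            tier_cuts = c(fdr10 = 1.67, fdr5 = 2, fdr1 = 2.6),
                            clustering = c("ward_euclidean", "complete_pearson"),
                            seed = 1, heatmap = FALSE) {
  clustering <- match.arg(clustering)
  .assert(!is.null(sim) || !is.null(input_csv),
          "provide either a simulation configuration or an input CSV path")
  .assert(B >= 1, "B must be at least 1")
  .assert(n_boot >= 2, "n_boot must be at least 2")
  .assert(length(tier_cuts) == 3L && !is.unsorted(tier_cuts, strictly = TRUE),
          "tier cutpoints must be strictly increasing")
  .assert(family_scope %in% c("per_experiment", "global"), "invalid family_scope")
  structure(list(sim = sim, input_csv = input_csv, assays = assays,
                 B = as.integer(B), n_boot = as.integer(n_boot),
                 family_scope = family_scope, z_cap = z_cap,
                 tier_cuts = tier_cuts, clustering = clustering,
                 seed = as.integer(seed), heatmap = isTRUE(heatmap)),
            class = "pipeline_config")
}

#' @rdname pipeline-io
#' @export
write_pipeline_config <- function(config, path) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  x <- list(
    sim = if (!is.null(config$sim)) .config_to_list(config$sim),
    input_csv = config$input_csv,
    assays = if (!is.null(config$assays))
      lapply(config$assays, function(a) a[setdiff(names(a), "unit")]),
    B = config$B, n_boot = config$n_boot, family_scope = config$family_scope,
    z_cap = config$z_cap, tier_cuts = as.list(config$tier_cuts),
    clustering = config$clustering, seed = config$seed, heatmap = config$heatmap)
  yaml::write_yaml(x[!vapply(x, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    sim = if (!is.null(x$sim)) .list_to_config(x$sim),
    input_csv = x$input_csv,
    assays = if (!is.null(x$assays)) lapply(x$assays, function(a) do.call(assay_design, a)),
    B = x$B %||% 200, n_boot = x$n_boot %||% 15,
    family_scope = x$family_scope %||% "per_experiment",
    z_cap = x$z_cap %||% 8,
    tier_cuts = if (!is.null(x$tier_cuts)) unlist(x$tier_cuts) else
      c(fdr10 = 1.67, fdr5 = 2, fdr1 = 2.6),
    clustering = x$clustering %||% "ward_euclidean",
    seed = x$seed %||% 1, heatmap = x$heatmap %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full harmonization pipeline
#'
#' Simulates (or reads) the phenotype table, computes the harmonized fit
#' ([harmonize_z()]), clusters the adjusted matrix and writes the report
#' bundle to `out_dir`: `phenotypes.csv`, `contrasts.tsv` (long per-cell
#' results), `z_raw.tsv`, `z_adj.tsv`, `tiers.tsv`, `dendrogram.nwk`,
#' `leaf_order.txt`, `manifest.json` and optionally `heatmap.png`.  All text
#' outputs are byte-identical across reruns of the same configuration.
#'
#' @param config a `pipeline_config`, or the path to its YAML file.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the configuration's seed.
#' @return the `phenoz` fit, invisibly, with attribute `"files"` listing the
#'   written paths.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- substream_seed(config$seed, "simulate")
    tab <- simulate_phenotypes(sim)
    assays <- sim$assays
  } else {
    tab <- read_phenotype_csv(config$input_csv)
    assays <- config$assays
    .assert(!is.null(assays), "CSV input requires assay declarations")
  }
  fit <- harmonize_z(tab, assays = assays, B = config$B, n_boot = config$n_boot,
                     seed = substream_seed(config$seed, "bootstrap"),
                     family_scope = config$family_scope,
                     tier_cuts = config$tier_cuts, z_cap = config$z_cap)
  hc <- if (config$clustering == "ward_euclidean") {
    cluster_ward_euclidean(fit$z_adj)
  } else {
    cluster_complete_pearson(fit$z_adj)
  }
  files <- c(
    phenotypes = file.path(out_dir, "phenotypes.csv"),
    contrasts = file.path(out_dir, "contrasts.tsv"),
    z_raw = file.path(out_dir, "z_raw.tsv"),
    z_adj = file.path(out_dir, "z_adj.tsv"),
    tiers = file.path(out_dir, "tiers.tsv"),
    dendrogram = file.path(out_dir, "dendrogram.nwk"),
    leaf_order = file.path(out_dir, "leaf_order.txt"),
    manifest = file.path(out_dir, "manifest.json"))
  write_phenotype_csv(tab, files[["phenotypes"]])
  long <- data.frame(
    line = rep(rownames(fit$z), ncol(fit$z)),
    assay_id = rep(colnames(fit$z), each = nrow(fit$z)),
    z = as.vector(fit$z), p = as.vector(fit$p),
    z_adj = as.vector(fit$z_adj), p_adj = as.vector(fit$p_adj),
    tier = as.vector(fit$tier), stringsAsFactors = FALSE)
  write.table(long, files[["contrasts"]], sep = "\t", row.names = FALSE,
              quote = FALSE, na = "NA", fileEncoding = "UTF-8")
  write_matrix_tsv(fit$z, files[["z_raw"]])
  write_matrix_tsv(fit$z_adj, files[["z_adj"]])
  write_matrix_tsv(fit$tier, files[["tiers"]])
  writeLines(export_newick(hc), files[["dendrogram"]])
  writeLines(rownames(fit$z_adj)[hc$order], files[["leaf_order"]])
  if (config$heatmap) {
    png_path <- file.path(out_dir, "heatmap.png")
    grDevices::png(png_path, width = 1200, height = 900, res = 150)
    plot(fit)
    grDevices::dev.off()
    files <- c(files, heatmap = png_path)
  }
  manifest <- list(
    package = "phenoz", version = as.character(packageVersion("phenoz")),
    seed = config$seed,
    parameters = list(B = config$B, n_boot = config$n_boot,
                      family_scope = config$family_scope, z_cap = config$z_cap,
                      tier_cuts = as.list(config$tier_cuts),
                      clustering = config$clustering),
    n_lines = nrow(fit$z), n_assays = ncol(fit$z),
    outputs = as.list(setNames(basename(files), names(files))),
    checksums = as.list(tools::md5sum(files[setdiff(names(files),
                                                    c("manifest", "heatmap"))])))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  attr(fit, "files") <- files
  invisible(fit)
}
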