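#' Declare a synthetic assay design
#'
#' Describes one assay of a synthetic phenotyping screen: its measurement
#' family, observation times, treatment arms, residual noise and number of
#' independent experiment blocks.  Families mirror the assay catalogue of a
#' typical mutant-collection screen:
#'
#' * `endpoint_continuous` - one continuous measurement per plant, with
#'   experiment blocks (e.g. root length, bolting time).
#' * `timecourse_continuous` - continuous measurements at several timepoints
#'   (e.g. relative electrolyte leakage after ozone exposure).
#' * `ordinal_score` - 0-3 severity scores (e.g. bacterial disease symptoms),
#'   generated by thresholding a latent Gaussian at fixed quartile cutpoints.
#' * `germination_curve` - percent germinated per dish assessed every 5 hours,
#'   logistic in time with genotype shifting the half-time; monotone
#'   nondecreasing within a dish by construction.
#' * `burst_total` - a single positive total (e.g. summed ROS luminescence).
#'
#' @param assay_id character identifier, unique within a configuration.
#' @param family one of the five families above.
#' @param timepoints ordered numeric observation times; defaults: none for
#'   endpoint families, `c(0, 8, 24, 48)` hours for time courses,
#'   `seq(0, 50, by = 5)` hours for germination curves.
#' @param arms treatment-arm labels (default a single `"trt"` arm).
#' @param noise_sd residual standard deviation in assay units (latent units
#'   for ordinal scores, half-time shift units for germination curves).
#' @param n_blocks number of independent experiment replicates (blocks).
#' @param baseline wild-type cell mean (latent baseline 0 for ordinal scores;
#'   half-time in hours, default 24, for germination curves).
#' @param endpoint_timepoint the timepoint contributing this assay's column to
#'   the effect matrix; defaults to the last timepoint (for germination
#'   curves, the timepoint nearest the baseline half-time, where dishes
#'   discriminate best).
#' @return an `assay_design` list.
#' @examples
#' assay_design("rosette_area", "endpoint_continuous", noise_sd = 2)
#' @export
assay_design <- function(assay_id, family, timepoints = NULL, arms = "trt",
                         noise_sd = 1, n_blocks = 3, baseline = NULL,
                         endpoint_timepoint = NULL) {
  families <- c("endpoint_continuous", "timecourse_continuous", "ordinal_score",
                "germination_curve", "burst_total")
  if (!(is.character(family) && length(family) == 1L && family %in% families)) {
    stop(sprintf("unknown assay family '%s'; must be one of: %s",
                 paste(family, collapse = ","), paste(families, collapse = ", ")),
         call. = FALSE)
  }
  .assert(is.character(assay_id) && length(assay_id) == 1L && nzchar(assay_id),
          "assay_id must be a nonempty string")
  .assert(is.numeric(noise_sd) && noise_sd > 0, "noise_sd must be positive")
  .assert(n_blocks >= 1, "n_blocks must be at least 1")
  if (is.null(timepoints)) {
    timepoints <- switch(family,
      timecourse_continuous = c(0, 8, 24, 48),
      germination_curve = seq(0, 50, by = 5),
      numeric(0))
  }
  .assert(!is.unsorted(timepoints, strictly = TRUE) || length(timepoints) <= 1L,
          "timepoints must be strictly increasing")
  if (family %in% c("timecourse_continuous", "germination_curve")) {
    .assert(length(timepoints) >= 2L, "time-structured families need >= 2 timepoints")
  }
  if (is.null(baseline)) {
    baseline <- switch(family,
      endpoint_continuous = 10, timecourse_continuous = 10,
      ordinal_score = 0, germination_curve = 24, burst_total = 100)
  }
  if (is.null(endpoint_timepoint)) {
    endpoint_timepoint <- if (length(timepoints) == 0L) NA_real_
      else if (family == "germination_curve") timepoints[which.min(abs(timepoints - baseline))]
      else timepoints[length(timepoints)]
  }
  if (length(timepoints) > 0L) {
    .assert(endpoint_timepoint %in% timepoints,
            "endpoint_timepoint must be one of the assay's timepoints")
  }
  unit <- switch(family,
    endpoint_continuous = "au", timecourse_continuous = "au",
    ordinal_score = "score", germination_curve = "percent", burst_total = "RLU")
  structure(list(assay_id = assay_id, family = family, timepoints = timepoints,
                 arms = arms, noise_sd = noise_sd, n_blocks = as.integer(n_blocks),
                 baseline = baseline, endpoint_timepoint = endpoint_timepoint,
                 unit = unit),
            class = "assay_design")
}

#' Configure a synthetic phenotyping screen
#'
#' Bundles the mutant collection (lines mapped to genes, some genes with two
#' independent insertion alleles), the assay catalogue and the planted
#' gene-by-assay effect matrix into a validated simulation configuration.
#'
#' @param assays list of [assay_design()] objects with unique ids.
#' @param n_lines number of mutant lines (ignored when `allele_map` given).
#' @param allele_map named character vector mapping line (allele) id to gene
#'   id.  Default: `n_lines` lines where the first gene carries two alleles
#'   and every other gene one, mimicking a T-DNA collection.
#' @param effect_matrix numeric gene-by-assay matrix of planted effects in
#'   units of each assay's residual SD; rownames must cover every gene and
#'   colnames every assay id.  Default: all zero (a null screen).
#' @param block_sd between-experiment random-intercept SD, in residual-SD
#'   units (default 0.5).
#' @param n_per_cell replicates per genotype x arm x timepoint cell
#'   (default 15, matching the common-n the harmonization bootstraps to).
#' @param reference wild-type reference genotype label (default `"Col-0"`).
#' @param seed RNG seed; the generator is byte-reproducible given the
#'   configuration.
#' @return a `sim_config` list.
#' @seealso [simulate_phenotypes()], [crk_collection_config()]
#' @export
sim_config <- function(assays, n_lines = 10, allele_map = NULL,
                       effect_matrix = NULL, block_sd = 0.5, n_per_cell = 15,
                       reference = "Col-0", seed = 1) {
  .assert(is.list(assays) && length(assays) >= 1L &&
            all(vapply(assays, inherits, logical(1), "assay_design")),
          "assays must be a nonempty list of assay_design objects")
  ids <- vapply(assays, `[[`, character(1), "assay_id")
  .assert(!anyDuplicated(ids), "assay ids must be unique")
  .assert(n_per_cell >= 2, "n_per_cell must be at least 2")
  .assert(block_sd >= 0, "block_sd cannot be negative")
  if (is.null(allele_map)) {
    .assert(n_lines >= 2, "need at least 2 mutant lines")
    genes <- sprintf("gene%02d", c(1L, seq_len(n_lines - 1L)))
    allele_map <- setNames(sprintf("%s-%d", genes, c(1L, 2L, rep(1L, n_lines - 2L))), NULL)
    allele_map <- setNames(genes, allele_map)
  }
  .assert(!is.null(names(allele_map)) && all(nzchar(names(allele_map))),
          "allele_map must be a named vector: names are line ids, values gene ids")
  .assert(!anyDuplicated(names(allele_map)), "every line must map to exactly one gene")
  .assert(!(reference %in% names(allele_map)), "the reference genotype is not a mutant line")
  genes <- unique(unname(allele_map))
  if (is.null(effect_matrix)) {
    effect_matrix <- matrix(0, length(genes), length(ids), dimnames = list(genes, ids))
  }
  .assert(is.matrix(effect_matrix) && all(genes %in% rownames(effect_matrix)) &&
            all(ids %in% colnames(effect_matrix)),
          "effect_matrix rows must cover every gene and columns every assay")
  .assert(all(is.finite(effect_matrix)), "planted effects must be finite")
  structure(list(assays = assays, allele_map = allele_map,
                 effect_matrix = effect_matrix, block_sd = block_sd,
                 n_per_cell = as.integer(n_per_cell), reference = reference,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' A study-scale example configuration
#'
#' Emulates the shape of a receptor-like-kinase T-DNA collection screen:
#' 39 mutant lines over 35 genes (four genes with two independent alleles), a
#' wild-type Col-0 reference, and five assays covering every measurement
#' family.  Planted effects default to zero; pass `effect_matrix` to plant
#' signal.
#'
#' @param seed RNG seed.
#' @param effect_matrix optional gene-by-assay planted effects (residual-SD
#'   units); defaults to all zero.
#' @return a `sim_config`.
#' @export
crk_collection_config <- function(seed = 1, effect_matrix = NULL) {
  genes <- sprintf("crk%02d", 1:35)
  two_allele <- genes[c(2, 5, 10, 28)]
  lines <- c(sprintf("%s-1", genes), sprintf("%s-2", two_allele))
  map <- setNames(sub("-[12]$", "", lines), lines)
  assays <- list(
    assay_design("root_length", "endpoint_continuous", noise_sd = 1.5, n_blocks = 3),
    assay_design("o3_leakage", "timecourse_continuous", timepoints = c(0, 8, 24, 48),
                 noise_sd = 1, n_blocks = 3),
    assay_design("pto_score", "ordinal_score", n_blocks = 3),
    assay_design("nacl_germination", "germination_curve", n_blocks = 3),
    assay_design("flg22_ros", "burst_total", noise_sd = 20, n_blocks = 3)
  )
  sim_config(assays, allele_map = map, effect_matrix = effect_matrix, seed = seed)
}

# rows for one assay; called under that assay's RNG substream.
# Fully vectorized: one RNG call per draw stage, in a fixed documented order
# (block effects, then cell-level noise), so output is byte-reproducible.
.simulate_assay <- function(a, cfg) {
  lines <- names(cfg$allele_map)
  genos <- c(cfg$reference, lines)
  eff <- c(0, unname(cfg$effect_matrix[cfg$allele_map[lines], a$assay_id]))
  n <- cfg$n_per_cell
  nb <- a$n_blocks; ng <- length(genos); na_ <- length(arms <- a$arms)
  block_ids <- sprintf("block%d", seq_len(nb))
  block_eff <- rnorm(nb, 0, cfg$block_sd)  # residual-SD units, shared by all cells
  tps <- if (a$family == "timecourse_continuous") a$timepoints else NA_real_
  nt <- length(tps)

  if (a$family == "germination_curve") {
    # one dish per replicate; half-time shifts by 2 h per residual-SD unit,
    # so a positive planted effect means faster germination (higher percent
    # mid-curve); 50 seeds per dish with logistic germination times
    ndish <- nb * ng * na_ * n
    b_i <- rep(seq_len(nb), each = ng * na_ * n)
    g_i <- rep(rep(seq_len(ng), each = na_ * n), nb)
    a_i <- rep(rep(rep(seq_len(na_), each = n), ng), nb)
    d_i <- rep(seq_len(n), nb * ng * na_)
    t50 <- a$baseline - 2 * (eff[g_i] + block_eff[b_i] + rnorm(ndish, 0, a$noise_sd))
    germ_t <- matrix(rlogis(50 * ndish, 0, 3), nrow = 50) +
      rep(t50, each = 50)
    ntp <- length(a$timepoints)
    pct <- vapply(a$timepoints, function(tp) 100 * colMeans(germ_t <= tp),
                  numeric(ndish))                      # ndish x ntp, monotone in tp
    idx <- rep(seq_len(ndish), each = ntp)
    value <- as.numeric(t(pct))
    tp_col <- rep(a$timepoints, times = ndish)
    out <- data.frame(
      assay_id = a$assay_id,
      genotype = ifelse(genos[g_i][idx] == cfg$reference, cfg$reference,
                        unname(cfg$allele_map[genos[g_i][idx]])),
      allele_id = genos[g_i][idx], block_id = block_ids[b_i][idx],
      timepoint = tp_col, arm = arms[a_i][idx], replicate = d_i[idx],
      value = value, unit = a$unit, stringsAsFactors = FALSE)
    return(out)
  }

  total <- nb * ng * na_ * nt * n
  b_i <- rep(seq_len(nb), each = ng * na_ * nt * n)
  g_i <- rep(rep(seq_len(ng), each = na_ * nt * n), nb)
  a_i <- rep(rep(rep(seq_len(na_), each = nt * n), ng), nb)
  t_i <- rep(rep(rep(seq_len(nt), each = n), ng * na_), nb)
  r_i <- rep(seq_len(n), nb * ng * na_ * nt)
  shift <- (eff[g_i] + block_eff[b_i]) * a$noise_sd
  noise <- rnorm(total, 0, a$noise_sd)
  value <- if (a$family == "ordinal_score") {
    cuts <- a$noise_sd * qnorm(c(0.25, 0.5, 0.75))  # fixed quartile cutpoints
    as.numeric(findInterval(shift + noise, cuts))   # latent-Gaussian threshold
  } else if (a$family == "timecourse_continuous") {
    a$baseline + 0.05 * a$noise_sd * tps[t_i] + shift + noise
  } else {  # endpoint_continuous, burst_total
    a$baseline + shift + noise
  }
  data.frame(
    assay_id = a$assay_id,
    genotype = ifelse(genos[g_i] == cfg$reference, cfg$reference,
                      unname(cfg$allele_map[genos[g_i]])),
    allele_id = genos[g_i], block_id = block_ids[b_i],
    timepoint = tps[t_i], arm = arms[a_i], replicate = r_i,
    value = value, unit = a$unit, stringsAsFactors = FALSE)
}

#' Simulate a multi-assay phenotyping screen
#'
#' Generates a long-format phenotype table under the configuration's planted
#' effects: each wild-type cell mean equals the assay baseline; each mutant
#' cell mean is shifted by `effect * noise_sd` plus a shared per-block random
#' intercept.  Ordinal scores threshold a latent Gaussian at fixed quartile
#' cutpoints; germination curves are logistic in time with the genotype
#' shifting the half-time, computed per dish so curves are monotone
#' nondecreasing.
#'
#' Each assay is generated under its own RNG substream derived by stable
#' hashing of the assay id ([substream_seed()]), so adding an assay to a
#' configuration leaves every other assay's draws untouched, and identical
#' configurations yield byte-identical tables.
#'
#' @param config a [sim_config()].
#' @return a `phenotype_table` data frame with columns `assay_id`, `genotype`
#'   (gene, or the reference), `allele_id` (line), `block_id`, `timepoint`,
#'   `arm`, `replicate`, `value`, `unit`, carrying the configuration as
#'   attribute `"config"`.
#' @examples
#' tab <- simulate_phenotypes(sim_config(list(
#'   assay_design("a", "endpoint_continuous")), n_lines = 3, seed = 7))
#' head(tab)
#' @export
simulate_phenotypes <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config object")
  parts <- lapply(config$assays, function(a) {
    with_seed(substream_seed(config$seed, paste0("assay/", a$assay_id)),
              .simulate_assay(a, config))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("phenotype_table", class(out))
  out
}

#' Remove (line, assay) cells to emulate unmeasured combinations
#'
#' Integrated screens rarely measure every line in every assay; this drops the
#' listed line-by-assay cells so downstream matrices carry a missingness mask
#' ("not measured") in those positions.
#'
#' @param table a `phenotype_table`.
#' @param mask data frame with columns `allele_id` and `assay_id` naming the
#'   cells to drop, or `NULL`/empty for no-op.
#' @return the table without the masked cells (attributes preserved).
#' @export
mask_cells <- function(table, mask) {
  if (is.null(mask) || NROW(mask) == 0L) return(table)
  .assert(all(c("allele_id", "assay_id") %in% names(mask)),
          "mask must have columns allele_id and assay_id")
  cfg <- attr(table, "config")
  ref <- if (!is.null(cfg)) cfg$reference else "Col-0"
  if (any(mask$allele_id == ref)) {
    stop("cannot mask the reference genotype: no comparison would be possible",
         call. = FALSE)
  }
  key <- paste(table$allele_id, table$assay_id, sep = "\r")
  drop <- key %in% paste(mask$allele_id, mask$assay_id, sep = "\r")
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$config <- attr(table, "config")
  class(out) <- class(table)
  out
}
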