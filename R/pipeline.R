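# End-to-end study runners: ingest -> normalize -> class stats ->
# species models -> ratios (mouse) / covariate-adjusted arm (human),
# writing every result table as CSV plus a JSON run manifest. All numeric
# output is written with 10 significant digits so reruns are comparable
# byte for byte.

.write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) signif(col, 10))
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

.matrix_to_df <- function(m, id_col = "sample") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  df
}

.write_manifest <- function(path, entries) {
  entries$package <- as.character(utils::packageVersion("lipidlens"))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
}

.ingest_stage <- function(input, annotation, mode, max_missing_fraction) {
  tab <- if (inherits(input, "abundance_table")) input
         else read_abundance_csv(input)
  ann <- if (is.data.frame(annotation)) validate_annotation(annotation, mode)
         else read_annotation_csv(annotation, mode)
  filtered <- filter_species_by_missingness(tab, ann, max_missing_fraction)
  mole <- to_mole_percent(filtered)
  list(raw = tab, filtered = filtered, mole = mole, annotation = ann)
}

#' Run the full mouse 2x2 study pipeline
#'
#' Ingest (CSV path or `abundance_table`) -> within-group missingness
#' filter -> mole percent -> class totals (after imputation) with
#' Mann-Whitney comparisons per genotype -> log2 -> per-species factorial
#' models with three BH families -> regulation-group clustering ->
#' per-genotype fold-change classification -> matched PC/PE ratio tests.
#' All tables are written to `out_dir` together with a JSON manifest.
#'
#' @param input wide pmol CSV path or an `abundance_table`.
#' @param annotation mouse annotation CSV path or data frame.
#' @param out_dir output directory (created if absent); `NULL` skips
#'   writing.
#' @param max_missing_fraction missingness filter threshold, default 0.5.
#' @param impute_method `"group_median"` or `"regression"`.
#' @param p_backing fold-change p backing, see
#'   [per_genotype_fold_changes()].
#' @param k regulation-group count, default 4.
#' @param fdr,lfc discovery thresholds (defaults 0.1, 0.5).
#' @param include_ether also pair ether PC/PE species among themselves.
#' @return Invisibly, a list with every stage result (`class_tests`,
#'   `fit`, `clusters`, `fold_changes`, `ratio_tests`, ...).
#' @export
run_mouse_study <- function(input, annotation, out_dir = NULL,
                            max_missing_fraction = 0.5,
                            impute_method = "group_median",
                            p_backing = "factorial", k = 4,
                            fdr = 0.1, lfc = 0.5, include_ether = FALSE) {
  st <- .ingest_stage(input, annotation, "mouse", max_missing_fraction)
  imputed <- impute_for_class_totals(st$mole, st$annotation, impute_method)
  totals <- class_totals(imputed)
  class_tests <- compare_classes(totals, st$annotation,
                                 "mouse_within_genotype", fdr)
  log2tab <- log2_transform(st$mole)
  fit <- fit_lipid_factorial(log2tab, st$annotation, fdr)
  clusters <- if (sum(fit$table$retained) >= k)
    cluster_regulation_groups(fit, k) else NULL
  fold_changes <- per_genotype_fold_changes(st$mole, log2tab, st$annotation,
                                            p_backing, fit, fdr, lfc)
  spp <- attr(st$mole$catalog, "species")
  pcs <- Filter(function(s) s$class_code %in% c("PC", "PC O-"), spp)
  pes <- Filter(function(s) s$class_code %in% c("PE", "PE O-"), spp)
  pairs <- find_matched_pairs(pcs, pes, include_ether)
  ratios <- if (nrow(pairs)) compute_matched_ratios(st$mole, pairs) else NULL
  ratio_tests <- if (!is.null(ratios))
    test_ratios(ratios, st$annotation, discovery_fdr = fdr) else NULL

  res <- list(mode = "mouse", filtered = st$filtered, mole = st$mole,
              log2 = log2tab, annotation = st$annotation, totals = totals,
              class_tests = class_tests, fit = fit, clusters = clusters,
              fold_changes = fold_changes, pairs = pairs,
              ratios = ratios, ratio_tests = ratio_tests)
  if (!is.null(out_dir)) .write_mouse_bundle(res, out_dir, st,
                                             max_missing_fraction, fdr, lfc,
                                             p_backing, impute_method, k)
  invisible(res)
}

.write_mouse_bundle <- function(res, out_dir, st, max_missing_fraction,
                                fdr, lfc, p_backing, impute_method, k) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  .write_num_csv(res$mole$catalog, fp("species_catalog.csv"))
  .write_num_csv(.matrix_to_df(res$mole$values), fp("mole_percent.csv"))
  .write_num_csv(as.data.frame(res$class_tests), fp("class_tests.csv"))
  .write_num_csv(res$fit$table, fp("species_models.csv"))
  if (!is.null(res$clusters)) {
    zm <- .matrix_to_df(res$clusters$zscores, "species")
    zm$cluster <- res$clusters$labels[zm$species]
    .write_num_csv(zm, fp("heatmap_zscores.csv"))
  }
  .write_num_csv(as.data.frame(res$fold_changes), fp("fold_changes.csv"))
  if (!is.null(res$ratio_tests)) {
    .write_num_csv(as.data.frame(res$ratio_tests), fp("pcpe_ratio_tests.csv"))
    .write_num_csv(.matrix_to_df(res$ratios$values), fp("pcpe_ratios.csv"))
  }
  .write_manifest(fp("manifest.json"), list(
    mode = "mouse",
    config = list(max_missing_fraction = max_missing_fraction, fdr = fdr,
                  lfc = lfc, p_backing = p_backing,
                  impute_method = impute_method, k = k),
    n_samples = nrow(res$mole$values),
    species_raw = ncol(st$raw$values),
    species_retained = ncol(res$mole$values),
    species_removed = nrow(res$filtered$filter$removed),
    n_classes = ncol(res$totals$values),
    retained_any_family = sum(res$fit$table$retained),
    matched_pairs = nrow(res$pairs)))
}

#' Run the human case/control pipeline
#'
#' Ingest -> missingness filter -> mole percent -> imputed class totals,
#' corrected for age and BMI, compared by Mann-Whitney -> log2 ->
#' per-species robust covariate-adjusted models with BH across species and
#' dual-threshold classification.
#'
#' @inheritParams run_mouse_study
#' @param annotation human annotation CSV path or data frame (`sample`,
#'   `group`, `age`, `bmi`).
#' @param engine `"robust"` or `"ls"`, see [fit_lipid_cohort()].
#' @return Invisibly, a list with stage results (`class_tests`, `cohort`,
#'   ...).
#' @export
run_human_study <- function(input, annotation, out_dir = NULL,
                            max_missing_fraction = 0.5,
                            impute_method = "group_median",
                            engine = "robust", fdr = 0.1, lfc = 0.5) {
  st <- .ingest_stage(input, annotation, "human", max_missing_fraction)
  imputed <- impute_for_class_totals(st$mole, st$annotation, impute_method)
  totals <- class_totals(imputed)
  corrected <- correct_class_totals(totals, st$annotation)
  class_tests <- compare_classes(corrected, st$annotation,
                                 "human_two_group", fdr)
  log2tab <- log2_transform(st$mole)
  cohort <- fit_lipid_cohort(log2tab, st$annotation, engine, fdr, lfc)

  res <- list(mode = "human", filtered = st$filtered, mole = st$mole,
              log2 = log2tab, annotation = st$annotation, totals = totals,
              corrected = corrected, class_tests = class_tests,
              cohort = cohort)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(out_dir, f)
    .write_num_csv(res$mole$catalog, fp("species_catalog.csv"))
    .write_num_csv(.matrix_to_df(res$mole$values), fp("mole_percent.csv"))
    .write_num_csv(.matrix_to_df(corrected$values),
                   fp("corrected_class_totals.csv"))
    .write_num_csv(as.data.frame(class_tests), fp("class_tests.csv"))
    .write_num_csv(cohort$table, fp("species_models.csv"))
    .write_manifest(fp("manifest.json"), list(
      mode = "human",
      config = list(max_missing_fraction = max_missing_fraction,
                    engine = engine, fdr = fdr, lfc = lfc,
                    impute_method = impute_method),
      n_samples = nrow(res$mole$values),
      species_raw = ncol(st$raw$values),
      species_retained = ncol(res$mole$values),
      n_classes = ncol(totals$values),
      significant_species = sum(cohort$table$significant, na.rm = TRUE)))
  }
  invisible(res)
}

#' Write a simulated study to disk
#'
#' Emits the wide pmol abundance CSV that [read_abundance_csv()] reads
#' (missing entries as empty cells), the annotation CSV, the ground-truth
#' effect ledger CSV, and a manifest.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory.
#' @return Invisibly, the `sim_study`.
#' @export
run_simulation <- function(config, out_dir) {
  study <- simulate_study(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  .write_num_csv(.matrix_to_df(study$table$values), fp("abundance_pmol.csv"))
  .write_num_csv(study$annotation, fp("annotation.csv"))
  .write_num_csv(study$truth$effects, fp("truth_effects.csv"))
  .write_manifest(fp("manifest.json"), list(
    mode = config$mode, seed = config$seed,
    n_species = nrow(config$catalog),
    n_classes = length(unique(config$catalog$class_code)),
    n_samples = nrow(study$annotation),
    residual_sd = config$residual_sd,
    missingness = as.list(config$missingness),
    planted_effects = nrow(config$effects)))
  invisible(study)
}
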