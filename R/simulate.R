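# Seeded synthetic lipidome studies with known ground truth. Heart mode
# emulates a 2x2 mouse design (genotype x intervention), plasma mode a
# case/control cohort with age/BMI confounding. Species-level log2 mole
# fractions are baseline + planted effects + covariate terms + Gaussian
# noise, renormalized to a composition, scaled to a pmol total, and
# censored by an abundance-dependent logistic detection model.

.fa_pool <- c("14:0", "15:0", "16:0", "16:1", "17:0", "17:1", "18:0",
              "18:1", "18:2", "18:3", "19:0", "20:0", "20:1", "20:3",
              "20:4", "20:5", "21:0", "22:0", "22:1", "22:4", "22:5",
              "22:6", "24:0", "24:1")

.mode_classes <- function(mode) {
  if (mode == "heart") {
    data.frame(
      class_code = c("PC", "PE", "CL", "TAG", "PC O-", "PE O-", "PI", "PS",
                     "DAG", "SM", "Cer", "PG", "LPC", "LPE", "LPI", "LPS",
                     "LPE O-", "Chol"),
      count = c(40, 35, 25, 20, 15, 12, 12, 10, 10, 10, 8, 8, 6, 4, 3, 3,
                3, 1),
      share = c(35, 28, 12, 6, 3, 2, 4, 3, 1.5, 2.5, 0.6, 1.2, 0.3, 0.15,
                0.1, 0.1, 0.05, 0.5),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      class_code = c("PC", "TAG", "SE", "PE", "PC O-", "SM", "LPC", "PI",
                     "Cer", "DAG", "PE O-", "LPE", "ST"),
      count = c(35, 30, 20, 12, 10, 10, 8, 6, 6, 4, 3, 2, 1),
      share = c(32, 22, 18, 2.5, 1.2, 6, 5, 3, 1.5, 0.5, 0.2, 0.1, 8),
      stringsAsFactors = FALSE)
  }
}

.allocate_counts <- function(base, n_species) {
  # scale base counts to n_species by largest remainder, keeping every
  # class present and chain-free sterol classes at a single species
  q <- base$count * n_species / sum(base$count)
  n <- pmax(1L, floor(q))
  sterol <- base$class_code %in% c("Chol", "ST")
  n[sterol] <- 1L
  rem <- q - floor(q)
  rem[sterol] <- -Inf
  while (sum(n) < n_species) {
    i <- which.max(rem)
    n[i] <- n[i] + 1L
    rem[i] <- rem[i] - 1
  }
  while (sum(n) > n_species) {
    i <- which.max(n)
    n[i] <- n[i] - 1L
  }
  n
}

.chain_pairs <- function(n) {
  idx <- utils::combn(length(.fa_pool), 2)
  idx <- cbind(idx, rbind(seq_along(.fa_pool), seq_along(.fa_pool)))
  ord <- order(colSums(idx), idx[1, ])
  idx <- idx[, ord, drop = FALSE][, seq_len(n), drop = FALSE]
  paste0(.fa_pool[idx[1, ]], "-", .fa_pool[idx[2, ]])
}

.sum_comp_names <- function(class_code, n, carbons, dbs) {
  grid <- expand.grid(d = dbs, c = carbons)[seq_len(n), ]
  paste0(class_code, " ", grid$c, ":", grid$d)
}

.class_species_names <- function(class_code, n) {
  switch(class_code,
    "Chol" = "Chol",
    "ST" = "ST",
    "CL" = .sum_comp_names("CL", n, seq(68, 80, 2), 4:12),
    "TAG" = .sum_comp_names("TAG", n, seq(44, 58, 2), 0:9),
    "SM" = .sum_comp_names("SM", n, seq(32, 44, 2), 1:2),
    "Cer" = .sum_comp_names("Cer", n, seq(34, 44, 2), 1:3),
    {
      nc <- .chain_counts[[class_code]]
      if (nc == 1) paste(class_code, .fa_pool[seq_len(n)])
      else paste(class_code, .chain_pairs(n))
    })
}

#' Synthetic species catalog for a simulation mode
#'
#' Deterministic catalog (no randomness): heart mode yields 225 species in
#' 18 classes with PC, PE and CL carrying the largest mole-percent shares;
#' plasma mode 147 species in 13 classes dominated by PC, TAG, SE and ST.
#' Within a class, species baseline shares decay geometrically (ratio
#' 0.9), giving the right-skewed abundance profile typical of shotgun
#' lipidomics. Other catalog sizes rescale the per-class species counts by
#' largest remainder.
#'
#' @param mode `"heart"` or `"plasma"`.
#' @param n_species total species count (defaults: 225 heart, 147 plasma).
#' @return Data frame: `canonical_name`, `class_code`, `share` (baseline
#'   mole percent, sums to 100).
#' @export
sim_catalog <- function(mode = c("heart", "plasma"), n_species = NULL) {
  mode <- match.arg(mode)
  base <- .mode_classes(mode)
  if (is.null(n_species)) n_species <- sum(base$count)
  stopifnot(n_species >= nrow(base))
  base$n <- .allocate_counts(base, n_species)
  rows <- lapply(seq_len(nrow(base)), function(i) {
    nm <- .class_species_names(base$class_code[i], base$n[i])
    w <- 0.9^(seq_along(nm) - 1)
    data.frame(canonical_name = nm, class_code = base$class_code[i],
               share = base$share[i] * w / sum(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default planted-effect ledger
#'
#' Heart mode plants a +1 log2 induction, confined to the wt x TAC cell
#' (`factor = "interaction"`), on the 10 lowest-abundance diacyl PE
#' species: the headline pattern of pressure-overload PE induction that is
#' present in wild-type and absent in knockout hearts, placed on species
#' carrying little total mass so that compositional closure barely
#' distorts the remaining species. Plasma mode plants 10 group effects
#' (HFrEF vs control) echoing the cohort pattern: three PE and two DAG
#' species up (the strongest at +2.5 log2), two PC and one Cer up, two
#' ether PC down.
#'
#' @param catalog a [sim_catalog()] data frame.
#' @param mode `"heart"` or `"plasma"`.
#' @return Data frame `species`, `factor`, `log2_effect`.
#' @export
default_effect_ledger <- function(catalog, mode = c("heart", "plasma")) {
  mode <- match.arg(mode)
  pick_low <- function(class_code, k) {
    sub <- catalog[catalog$class_code == class_code, ]
    sub <- sub[order(sub$share), ]
    sub$canonical_name[seq_len(min(k, nrow(sub)))]
  }
  if (mode == "heart") {
    data.frame(species = pick_low("PE", 10), factor = "interaction",
               log2_effect = 1, stringsAsFactors = FALSE)
  } else {
    data.frame(
      species = c(pick_low("PE", 3), pick_low("DAG", 2), pick_low("PC", 2),
                  pick_low("Cer", 1), pick_low("PC O-", 2)),
      factor = "group",
      log2_effect = c(2.5, 1.5, 1, 1, 1, 1, 1, 1, -1, -1),
      stringsAsFactors = FALSE)
  }
}

#' Build a simulation configuration
#'
#' @param mode `"heart"` (mouse 2x2) or `"plasma"` (human case/control).
#' @param n_per_group samples per cell (heart; default 7) or a length-2
#'   vector `c(control, case)` (plasma; default `c(10, 13)`).
#' @param n_species catalog size (defaults 225 / 147).
#' @param residual_sd Gaussian noise SD on the log2 scale, default 0.5.
#' @param effects planted-effect data frame (`species`, `factor` in
#'   genotype/intervention/interaction/group, `log2_effect`);
#'   `NULL` uses [default_effect_ledger()], `"none"` plants nothing.
#'   `"interaction"` effects act only in the wt x TAC cell (induction
#'   present in wild type, absent in knockout).
#' @param covariates plasma-mode covariate model: list with `age_mean`
#'   (per group; defaults 43.3 control / 59.2 case years), `age_sd`,
#'   `bmi_mean` (25.5 / 27.3 kg/m2), `bmi_sd`, `frac_affected` (fraction
#'   of species with covariate slopes, default 0.2), `age_slope_sd` (log2
#'   per year, default 0.01), `bmi_slope_sd` (log2 per kg/m2, 0.02).
#' @param missingness logistic detection-failure model on log2 mole
#'   percent: `c(intercept, slope)`; negative slope makes low-abundance
#'   species drop out more often. Default `c(-7, -1)`.
#' @param total_pmol total lipid amount per sample, default 1e6.
#' @param seed RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(mode = c("heart", "plasma"),
                              n_per_group = NULL, n_species = NULL,
                              residual_sd = 0.5, effects = NULL,
                              covariates = list(),
                              missingness = c(intercept = -7, slope = -1),
                              total_pmol = 1e6, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(n_per_group))
    n_per_group <- if (mode == "heart") 7 else c(control = 10, case = 13)
  stopifnot(all(n_per_group >= 2), residual_sd >= 0, total_pmol > 0)
  catalog <- sim_catalog(mode, n_species)
  if (is.null(effects)) effects <- default_effect_ledger(catalog, mode)
  else if (identical(effects, "none"))
    effects <- data.frame(species = character(), factor = character(),
                          log2_effect = numeric())
  bad <- setdiff(effects$species, catalog$canonical_name)
  if (length(bad))
    stop("effect ledger references absent species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  ok_factors <- if (mode == "heart")
    c("genotype", "intervention", "interaction") else "group"
  if (!all(effects$factor %in% ok_factors))
    stop("effect factors for ", mode, " mode must be in: ",
         paste(ok_factors, collapse = ", "), call. = FALSE)
  cov_default <- list(age_mean = c(control = 43.3, HFrEF = 59.2),
                      age_sd = 12, bmi_mean = c(control = 25.5,
                                                HFrEF = 27.3),
                      bmi_sd = c(control = 2.7, HFrEF = 3.6),
                      frac_affected = 0.2, age_slope_sd = 0.01,
                      bmi_slope_sd = 0.02)
  covariates <- utils::modifyList(cov_default, covariates)
  structure(list(mode = mode, n_per_group = n_per_group,
                 catalog = catalog, residual_sd = residual_sd,
                 effects = effects, covariates = covariates,
                 missingness = c(intercept = unname(missingness[1]),
                                 slope = unname(missingness[2])),
                 total_pmol = total_pmol, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> mode ", x$mode, ": ", nrow(x$catalog), " species / ",
      length(unique(x$catalog$class_code)), " classes, ",
      nrow(x$effects), " planted effect(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

.sim_annotation <- function(config) {
  if (config$mode == "heart") {
    n <- config$n_per_group
    grid <- expand.grid(rep = seq_len(n),
                        intervention = c("sham", "TAC"),
                        genotype = c("wt", "atATGL-KO"),
                        stringsAsFactors = FALSE)
    data.frame(sample = paste(sub("atATGL-KO", "ko", grid$genotype),
                              tolower(grid$intervention), grid$rep,
                              sep = "_"),
               genotype = grid$genotype, intervention = grid$intervention,
               stringsAsFactors = FALSE)
  } else {
    n <- config$n_per_group
    cv <- config$covariates
    grp <- rep(c("control", "HFrEF"), n)
    bmi_sd <- rep(unname(cv$bmi_sd), length.out = 2)
    data.frame(sample = c(paste0("ctrl_", seq_len(n[1])),
                          paste0("case_", seq_len(n[2]))),
               group = grp,
               age = stats::rnorm(sum(n), unname(cv$age_mean[grp]),
                                  cv$age_sd),
               bmi = stats::rnorm(sum(n), unname(cv$bmi_mean[grp]),
                                  bmi_sd[match(grp, c("control", "HFrEF"))]),
               stringsAsFactors = FALSE)
  }
}

.effect_matrix <- function(config, ann) {
  # samples x species planted log2 shifts
  cat_names <- config$catalog$canonical_name
  E <- matrix(0, nrow(ann), length(cat_names),
              dimnames = list(ann$sample, cat_names))
  for (r in seq_len(nrow(config$effects))) {
    ef <- config$effects[r, ]
    active <- switch(ef$factor,
                     genotype = ann$genotype == "atATGL-KO",
                     intervention = ann$intervention == "TAC",
                     interaction = ann$genotype == "wt" &
                       ann$intervention == "TAC",
                     group = ann$group == "HFrEF")
    E[active, ef$species] <- E[active, ef$species] + ef$log2_effect
  }
  E
}

#' Simulate a synthetic lipidomics study
#'
#' Draws one study from a [simulation_config()]: a raw pmol abundance
#' table (with abundance-dependent missingness), the matching sample
#' annotation, and a ground-truth ledger for recovery scoring. Fully
#' reproducible: the same configuration (including seed) yields a
#' bit-identical study.
#'
#' @param config a `sim_config`.
#' @return List of class `sim_study`: `table` (an `abundance_table`,
#'   pmol), `annotation`, `truth` (class `synthetic_truth`: the effect
#'   ledger, baseline shares, covariate slopes, realized missingness),
#'   `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ann <- .sim_annotation(config)
  cat_df <- config$catalog
  m <- nrow(cat_df); n <- nrow(ann)
  baseline <- log2(cat_df$share / 100)
  E <- .effect_matrix(config, ann)

  slopes <- NULL
  C <- 0
  if (config$mode == "plasma") {
    cv <- config$covariates
    n_aff <- ceiling(cv$frac_affected * m)
    aff <- sample.int(m, n_aff)
    age_slope <- bmi_slope <- numeric(m)
    age_slope[aff] <- stats::rnorm(n_aff, 0, cv$age_slope_sd)
    bmi_slope[aff] <- stats::rnorm(n_aff, 0, cv$bmi_slope_sd)
    slopes <- data.frame(species = cat_df$canonical_name,
                         age_slope = age_slope, bmi_slope = bmi_slope,
                         stringsAsFactors = FALSE)
    C <- outer(ann$age - mean(ann$age), age_slope) +
      outer(ann$bmi - mean(ann$bmi), bmi_slope)
  }

  X <- matrix(rep(baseline, each = n), n, m) + E + C +
    matrix(stats::rnorm(n * m, 0, config$residual_sd), n, m)
  # closure: renormalize to a composition, scale to the sample total
  P <- 2^X
  P <- P / rowSums(P)
  mole_pct <- 100 * P
  pmol <- P * config$total_pmol

  p_miss <- stats::plogis(config$missingness["intercept"] +
                          config$missingness["slope"] * log2(mole_pct))
  drop <- matrix(stats::runif(n * m) < p_miss, n, m)
  pmol[drop] <- NA_real_
  dimnames(pmol) <- list(ann$sample, cat_df$canonical_name)

  truth <- structure(list(
    effects = config$effects,
    baseline = data.frame(species = cat_df$canonical_name,
                          class_code = cat_df$class_code,
                          share = cat_df$share, stringsAsFactors = FALSE),
    covariate_slopes = slopes,
    missing_per_species = stats::setNames(colSums(drop),
                                          cat_df$canonical_name),
    mode = config$mode), class = "synthetic_truth")

  structure(list(table = abundance_table(pmol, "pmol"), annotation = ann,
                 truth = truth, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study> ", x$config$mode, " mode, seed ", x$config$seed, "\n",
      sep = "")
  print(x$table)
  invisible(x)
}

#' Score pipeline recovery against planted truth
#'
#' Compares discoveries with the planted-effect ledger. For a
#' [per_genotype_fold_changes()] table, detection is dual-threshold
#' significance in the wild-type family (where interaction-planted effects
#' live), and the knockout family is scored for the expected absence of
#' signal; for a [fit_lipid_cohort()] object, detection is the cohort
#' dual-threshold flag.
#'
#' @param results a `fold_change_table` or a `lipid_cohort_fit`.
#' @param truth a `synthetic_truth`.
#' @return List of class `recovery_report`: `sensitivity`, `fdp`
#'   (observed false-discovery proportion), `bias` and `rmse` of the
#'   estimated log2 fold change on planted species, `n_detected`,
#'   `n_planted`, and (mouse) `wt_log2fc_mean` / `ko_log2fc_mean` over
#'   planted species.
#' @export
evaluate_recovery <- function(results, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  planted <- truth$effects$species
  magnitude <- stats::setNames(truth$effects$log2_effect, planted)
  if (inherits(results, "fold_change_table")) {
    wt <- results[results$genotype == "wt", ]
    ko <- results[results$genotype == "atATGL-KO", ]
    if (!all(planted %in% wt$species))
      stop("results and truth refer to different species catalogs",
           call. = FALSE)
    detected <- wt$species[wt$significant %in% TRUE]
    est <- stats::setNames(wt$log2fc, wt$species)[planted]
    extra <- list(
      wt_log2fc_mean = mean(est),
      ko_log2fc_mean = mean(stats::setNames(ko$log2fc,
                                            ko$species)[planted]))
  } else if (inherits(results, "lipid_cohort_fit")) {
    tab <- results$table
    if (!all(planted %in% tab$species))
      stop("results and truth refer to different species catalogs",
           call. = FALSE)
    detected <- tab$species[tab$significant %in% TRUE]
    est <- stats::setNames(tab$log2fc, tab$species)[planted]
    extra <- list()
  } else stop("unsupported results object", call. = FALSE)
  err <- est - magnitude
  out <- c(list(
    n_planted = length(planted),
    n_detected = length(detected),
    sensitivity = if (length(planted)) mean(planted %in% detected) else NA,
    fdp = if (length(detected)) mean(!detected %in% planted) else 0,
    bias = if (length(planted)) mean(err) else NA,
    rmse = if (length(planted)) sqrt(mean(err^2)) else NA), extra)
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  planted: %d  detected: %d  sensitivity: %.3f  FDP: %.3f\n",
              x$n_planted, x$n_detected, x$sensitivity, x$fdp))
  cat(sprintf("  log2FC bias: %+.3f  rmse: %.3f\n", x$bias, x$rmse))
  if (!is.null(x$wt_log2fc_mean))
    cat(sprintf("  mean log2FC on planted species: wt %+.3f  ko %+.3f\n",
                x$wt_log2fc_mean, x$ko_log2fc_mean))
  invisible(x)
}
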