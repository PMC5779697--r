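cells_y <- function(wt_sham, wt_tac, ko_sham, ko_tac, reps = 2) {
  y <- rep(c(wt_sham, wt_tac, ko_sham, ko_tac), each = reps)
  g <- rep(c("wt", "wt", "atATGL-KO", "atATGL-KO"), each = reps)
  iv <- rep(c("sham", "TAC", "sham", "TAC"), each = reps)
  list(y = y, g = g, iv = iv)
}

test_that("coefficients reproduce cell means under treatment coding", {
  d <- cells_y(1, 2, 1, 1)
  f <- fit_species_linear_model(d$y, d$g, d$iv)
  expect_true(f$estimable)
  expect_equal(unname(f$coef), c(1, 0, 1, -1))   # b0, b1, b2, b3
  # noise-free: tests inestimable rather than p = 0
  expect_true(all(is.na(f$p)))

  allsame <- cells_y(3, 3, 3, 3)
  f0 <- fit_species_linear_model(allsame$y, allsame$g, allsame$iv)
  expect_equal(unname(f0$coef), c(3, 0, 0, 0))
  expect_true(is.na(f0$F) || is.na(f0$p_F))
})

test_that("model statistics match a normal-equations oracle", {
  set.seed(12)
  for (i in 1:20) {
    reps <- sample(2:5, 1)
    d <- cells_y(0, 0, 0, 0, reps = reps)
    y <- rnorm(length(d$y))
    f <- fit_species_linear_model(y, d$g, d$iv)
    G <- as.numeric(d$g == "atATGL-KO"); I <- as.numeric(d$iv == "TAC")
    o <- oracle_ols(cbind(1, G, I, G * I), y)
    expect_equal(unname(f$coef), unname(o$beta), tolerance = 1e-10)
    expect_equal(unname(f$t), unname(o$t[2:4]), tolerance = 1e-10)
    expect_equal(unname(f$p), unname(o$p_t[2:4]), tolerance = 1e-10)
    expect_equal(f$F, o$F, tolerance = 1e-10)
    expect_equal(f$p_F, o$p_F, tolerance = 1e-10)
    # knockout intervention contrast b2 + b3 via the oracle's vcov
    expect_equal(f$ko_contrast[["estimate"]], o$beta[3] + o$beta[4],
                 tolerance = 1e-10)
  }
})

test_that("degenerate designs are flagged inestimable, not fatal", {
  # only two cells populated
  y <- c(1, 2, 3, 4, 5, 6)
  g <- rep("wt", 6)
  iv <- rep(c("sham", "TAC"), 3)
  f <- fit_species_linear_model(y, g, iv)
  expect_false(f$estimable)

  # fewer than 5 observations
  d <- cells_y(1, 2, 3, 4, reps = 1)
  expect_false(fit_species_linear_model(d$y, d$g, d$iv)$estimable)
})

test_that("three BH families retain planted intervention effects", {
  set.seed(31)
  cat60 <- sim_catalog("heart", 60)
  low_mass <- cat60$canonical_name[order(cat60$share)][1:8]
  cfg <- simulation_config(
    "heart", n_species = 60, seed = 31,
    effects = data.frame(species = low_mass,
                         factor = "intervention", log2_effect = 1.5),
    missingness = c(-30, -1))
  st <- simulate_study(cfg)
  l2 <- log2_transform(to_mole_percent(
    filter_species_by_missingness(st$table, st$annotation)))
  fit <- fit_lipid_factorial(l2, st$annotation)
  planted <- cfg$effects$species
  tab <- fit$table
  expect_true(all(tab$retained[tab$species %in% planted]))
  expect_true(all(tab$p_adj_intervention[tab$species %in% planted] < 0.1))
  expect_lt(mean(tab$retained[!tab$species %in% planted]), 0.2)
})

test_that("retained set ignores species order", {
  cfg <- simulation_config("heart", n_species = 40, seed = 13)
  st <- simulate_study(cfg)
  l2 <- log2_transform(to_mole_percent(
    filter_species_by_missingness(st$table, st$annotation)))
  fit1 <- fit_lipid_factorial(l2, st$annotation)
  perm <- sample(ncol(l2$values))
  l2p <- l2
  l2p$values <- l2$values[, perm, drop = FALSE]
  l2p$catalog <- l2$catalog[perm, , drop = FALSE]
  attr(l2p$catalog, "species") <- attr(l2$catalog, "species")[perm]
  fit2 <- fit_lipid_factorial(l2p, st$annotation)
  r1 <- fit1$table$species[fit1$table$retained]
  r2 <- fit2$table$species[fit2$table$retained]
  expect_setequal(r1, r2)
})

test_that("regulation clustering separates planted statistic profiles", {
  set.seed(17)
  cat40 <- sim_catalog("heart", 40)
  # every species carries one of two strong, orthogonal statistic
  # profiles, so a k = 2 cut must recover exactly those two groups
  genotype_hits <- cat40$canonical_name[seq(1, 40, 2)]
  intervention_hits <- cat40$canonical_name[seq(2, 40, 2)]
  cfg <- simulation_config(
    "heart", n_species = 40, residual_sd = 0.2, seed = 17,
    effects = rbind(
      data.frame(species = genotype_hits, factor = "genotype",
                 log2_effect = 2),
      data.frame(species = intervention_hits, factor = "intervention",
                 log2_effect = 2)),
    missingness = c(-30, -1))
  st <- simulate_study(cfg)
  l2 <- log2_transform(to_mole_percent(
    filter_species_by_missingness(st$table, st$annotation)))
  fit <- fit_lipid_factorial(l2, st$annotation)
  cl <- cluster_regulation_groups(fit, k = 2)
  lab_g <- cl$labels[genotype_hits]
  lab_i <- cl$labels[intervention_hits]
  expect_equal(length(unique(lab_g)), 1L)
  expect_equal(length(unique(lab_i)), 1L)
  expect_true(unique(lab_g) != unique(lab_i))
  expect_error(cluster_regulation_groups(fit, k = 1000), "exceeds")
})

test_that("cluster labels do not depend on species order", {
  cfg <- simulation_config("heart", n_species = 50, seed = 19)
  st <- simulate_study(cfg)
  l2 <- log2_transform(to_mole_percent(
    filter_species_by_missingness(st$table, st$annotation)))
  fit <- fit_lipid_factorial(l2, st$annotation)
  if (sum(fit$table$retained) >= 4) {
    cl1 <- cluster_regulation_groups(fit)
    fit2 <- fit
    perm <- sample(nrow(fit$table))
    fit2$table <- fit$table[perm, , drop = FALSE]
    cl2 <- cluster_regulation_groups(fit2)
    expect_identical(cl1$labels, cl2$labels)
    expect_identical(cl1$zscores, cl2$zscores)
  }
})

test_that("heatmap rows are z-scores with mean 0 and unit population SD", {
  cfg <- simulation_config("heart", n_species = 60, seed = 23)
  st <- simulate_study(cfg)
  l2 <- log2_transform(to_mole_percent(
    filter_species_by_missingness(st$table, st$annotation)))
  fit <- fit_lipid_factorial(l2, st$annotation)
  cl <- cluster_regulation_groups(fit,
                                  k = min(4, sum(fit$table$retained)))
  z <- cl$zscores
  expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-12)
  pop_sd <- apply(z, 1, function(r) sqrt(mean((r - mean(r))^2)))
  expect_equal(unname(pop_sd), rep(1, nrow(z)), tolerance = 1e-12)
})

test_that("dual-threshold rule needs both small adjusted p and large shift", {
  expect_true(classify_significant(0.05, 0.6))
  expect_false(classify_significant(0.05, 0.4))
  expect_false(classify_significant(0.2, 1.0))
  expect_false(classify_significant(NA, 1.0))
})

test_that("fold changes are per-genotype log2 mean differences", {
  ann <- mouse_annotation(paste0("s", 1:12),
                          rep(c("wt", "atATGL-KO"), each = 6),
                          rep(rep(c("sham", "TAC"), each = 3), 2))
  mole_vals <- c(rep(1, 3), rep(2, 3),    # wt: sham 1 -> TAC 2 mole%
                 rep(4, 3), rep(4, 3))    # ko: flat
  other <- 100 - mole_vals
  m <- cbind("PE 16:0-18:2" = mole_vals, "PC 16:0-18:1" = other)
  rownames(m) <- ann$sample
  mole <- abundance_table(m, "mole_percent")
  l2 <- log2_transform(mole)
  fc <- per_genotype_fold_changes(mole, l2, ann, p_backing = "ttest")
  pe_wt <- fc[fc$species == "PE 16:0-18:2" & fc$genotype == "wt", ]
  expect_equal(pe_wt$log2fc, 1)
  expect_equal(pe_wt$mean_mole_pct, 1.5)
  pe_ko <- fc[fc$species == "PE 16:0-18:2" & fc$genotype == "atATGL-KO", ]
  expect_equal(pe_ko$log2fc, 0)
})

test_that("two-sample t backing reproduces the classical statistic", {
  set.seed(5)
  ann <- mouse_annotation(paste0("s", 1:28),
                          rep(c("wt", "atATGL-KO"), each = 14),
                          rep(rep(c("sham", "TAC"), each = 7), 2))
  cat20 <- sim_catalog("heart", 20)
  m <- matrix(abs(rnorm(28 * 20, 10, 2)), 28, 20,
              dimnames = list(ann$sample, cat20$canonical_name))
  mole <- to_mole_percent(abundance_table(m, "pmol"))
  l2 <- log2_transform(mole)
  fc <- per_genotype_fold_changes(mole, l2, ann, p_backing = "ttest")
  sp <- colnames(l2$values)[4]
  wt_tac <- l2$values[ann$genotype == "wt" & ann$intervention == "TAC", sp]
  wt_sham <- l2$values[ann$genotype == "wt" & ann$intervention == "sham", sp]
  direct <- t.test(wt_tac, wt_sham, var.equal = TRUE)$p.value
  expect_equal(fc$p[fc$species == sp & fc$genotype == "wt"], direct)
})
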