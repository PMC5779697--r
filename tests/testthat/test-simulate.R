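test_that("default catalogs match the emulated study dimensions", {
  heart <- sim_catalog("heart")
  expect_equal(nrow(heart), 225L)
  expect_equal(length(unique(heart$class_code)), 18L)
  expect_equal(sum(heart$share), 100, tolerance = 1e-9)
  top_heart <- names(sort(tapply(heart$share, heart$class_code, sum),
                          decreasing = TRUE))[1:3]
  expect_setequal(top_heart, c("PC", "PE", "CL"))

  plasma <- sim_catalog("plasma")
  expect_equal(nrow(plasma), 147L)
  expect_equal(length(unique(plasma$class_code)), 13L)
  top_plasma <- names(sort(tapply(plasma$share, plasma$class_code, sum),
                           decreasing = TRUE))[1:3]
  expect_true(all(c("PC", "TAG") %in% top_plasma))
  expect_true(any(c("SE", "ST") %in% top_plasma))

  # all catalog names parse
  expect_silent(species_catalog(heart$canonical_name))
  expect_silent(species_catalog(plasma$canonical_name))

  # rescaled catalogs keep every class and hit the requested size
  small <- sim_catalog("heart", 200)
  expect_equal(nrow(small), 200L)
  expect_equal(length(unique(small$class_code)), 18L)
})

test_that("identical seeds reproduce a study bit for bit", {
  cfg <- simulation_config("heart", n_species = 40, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$table$values, s2$table$values)
  expect_identical(s1$annotation, s2$annotation)
  s3 <- simulate_study(simulation_config("heart", n_species = 40,
                                         seed = 100))
  expect_false(identical(s1$table$values, s3$table$values))
})

test_that("the zero-noise, no-effect limit is a constant composition", {
  cfg <- simulation_config("heart", n_species = 30, residual_sd = 0,
                           effects = "none", missingness = c(-50, -1),
                           seed = 1)
  st <- simulate_study(cfg)
  mp <- to_mole_percent(st$table)
  expect_true(all(!is.na(mp$values)))
  for (i in 2:nrow(mp$values))
    expect_equal(unname(mp$values[i, ]), unname(mp$values[1, ]),
                 tolerance = 1e-12)
  # and the composition is the catalog's baseline shares
  expect_equal(unname(mp$values[1, ]),
               cfg$catalog$share[match(colnames(mp$values),
                                       cfg$catalog$canonical_name)],
               tolerance = 1e-9)
})

test_that("interaction effects appear in wt and stay absent in knockout", {
  cat30 <- sim_catalog("heart", 30)
  planted <- cat30$canonical_name[order(cat30$share)][1:3]
  contrasts <- replicate(60, {
    seed <- sample.int(1e6, 1)
    cfg <- simulation_config(
      "heart", n_species = 30, n_per_group = 3, seed = seed,
      effects = data.frame(species = planted, factor = "interaction",
                           log2_effect = 1),
      missingness = c(-30, -1))
    st <- simulate_study(cfg)
    l2 <- log2(to_mole_percent(st$table)$values)
    ann <- st$annotation
    cm <- function(gt, iv) colMeans(l2[ann$genotype == gt &
                                       ann$intervention == iv, planted,
                                       drop = FALSE])
    c(wt = mean(cm("wt", "TAC") - cm("wt", "sham")),
      ko = mean(cm("atATGL-KO", "TAC") - cm("atATGL-KO", "sham")))
  })
  avg <- rowMeans(contrasts)
  # planted mass is ~1% so closure shrinks the realized contrast slightly
  expect_equal(unname(avg["wt"]), 1, tolerance = 0.12)
  expect_equal(unname(avg["ko"]), 0, tolerance = 0.1)
})

test_that("detection rates rise with abundance under negative missingness slope", {
  cfg <- simulation_config("heart", n_per_group = 25, seed = 55,
                           missingness = c(-4, -1))
  st <- simulate_study(cfg)
  share <- cfg$catalog$share
  obs_rate <- colMeans(!is.na(st$table$values))
  deciles <- cut(rank(share, ties.method = "first"),
                 breaks = 10, labels = FALSE)
  rate_by_decile <- tapply(obs_rate, deciles, mean)
  expect_gt(rate_by_decile[[10]], rate_by_decile[[1]])
  expect_gt(cor(seq_len(10), as.vector(rate_by_decile), method = "spearman"),
            0.8)
})

test_that("the effect ledger rejects unknown species and foreign factors", {
  expect_error(simulation_config(
    "heart", effects = data.frame(species = "PE 99:9-99:9",
                                  factor = "interaction",
                                  log2_effect = 1)), "absent species")
  expect_error(simulation_config(
    "heart", effects = data.frame(species = sim_catalog("heart")$
                                    canonical_name[1],
                                  factor = "group", log2_effect = 1)),
    "must be in")
})

test_that("recovery scoring matches an independent scorer", {
  cfg <- simulation_config("heart", n_species = 200, seed = 77)
  st <- simulate_study(cfg)
  l2 <- log2_transform(to_mole_percent(
    filter_species_by_missingness(st$table, st$annotation)))
  mp <- to_mole_percent(filter_species_by_missingness(st$table,
                                                      st$annotation))
  fit <- fit_lipid_factorial(l2, st$annotation)
  fc <- per_genotype_fold_changes(mp, l2, st$annotation, fit = fit)
  rec <- evaluate_recovery(fc, st$truth)

  # second, set-based implementation of the same score
  wt <- fc[fc$genotype == "wt", ]
  det <- wt$species[wt$significant %in% TRUE]
  planted <- st$truth$effects$species
  expect_equal(rec$sensitivity, length(intersect(det, planted)) /
                 length(planted))
  expect_equal(rec$fdp,
               if (length(det)) length(setdiff(det, planted)) / length(det)
               else 0)
  est <- wt$log2fc[match(planted, wt$species)]
  expect_equal(rec$bias, mean(est - st$truth$effects$log2_effect))
  expect_equal(rec$rmse, sqrt(mean((est - st$truth$effects$log2_effect)^2)))

  # degenerate cases
  fake <- fc
  fake$significant <- fake$species %in% planted
  perfect <- evaluate_recovery(fake, st$truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdp, 0)
  none <- fc
  none$significant <- FALSE
  expect_equal(evaluate_recovery(none, st$truth)$sensitivity, 0)
  expect_equal(evaluate_recovery(none, st$truth)$fdp, 0)
})
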