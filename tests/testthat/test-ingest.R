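write_csv_lines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("wide CSVs read with zeros and blanks as below-detection missing", {
  f <- write_csv_lines(c("sample,PE 16:0-18:2,PC 16:0-18:1",
                         "s1,50,50", "s2,30,", "s3,0,10"))
  tab <- read_abundance_csv(f, "wide")
  expect_equal(dim(tab), c(3L, 2L))
  expect_true(is.na(tab$values["s2", "PC 16:0-18:1"]))
  expect_true(is.na(tab$values["s3", "PE 16:0-18:2"]))  # zero == missing
  expect_equal(tab$values["s1", "PE 16:0-18:2"], 50)
  expect_equal(tab$unit_state, "pmol")
})

test_that("long CSVs read and duplicate cells are rejected", {
  f <- write_csv_lines(c("sample,species,pmol",
                         "s1,PE 16:0-18:2,50", "s1,PC 16:0-18:1,30",
                         "s2,PE 16:0-18:2,20"))
  tab <- read_abundance_csv(f, "long")
  expect_equal(dim(tab), c(2L, 2L))
  expect_true(is.na(tab$values["s2", "PC 16:0-18:1"]))

  fdup <- write_csv_lines(c("sample,species,pmol",
                            "s1,PE 16:0-18:2,50", "s1,PE 16:0-18:2,51"))
  expect_error(read_abundance_csv(fdup, "long"), "duplicate")
})

test_that("two spellings of one species collide at ingest", {
  f <- write_csv_lines(c("sample,PE 16:0-18:2,PE16:0–18:2",
                         "s1,1,2", "s2,3,4"))
  expect_error(read_abundance_csv(f, "wide"), "collide")
})

test_that("unparseable header names are reported together", {
  f <- write_csv_lines(c("sample,PE 16:0-18:2,QQ 1:2,ZZ 3:4",
                         "s1,1,2,3"))
  expect_error(read_abundance_csv(f, "wide"), "QQ.*ZZ")
})

test_that("missingness filter keeps species observed well in any one group", {
  # species A: full in the TAC-wt group only; B: 1 observation per group
  g <- rep(c("wt:sham", "wt:TAC", "ko:sham", "ko:TAC"), each = 6)
  a <- ifelse(g == "wt:TAC", 5, NA)
  b <- ifelse(duplicated(g) == FALSE, 5, NA)   # first sample of each group
  m <- cbind("PE 16:0-18:2" = a, "PC 16:0-18:1" = b,
             "PI 18:0-20:4" = 5)
  rownames(m) <- paste0("s", seq_len(24))
  tab <- abundance_table(m, "pmol")
  filt <- filter_species_by_missingness(tab, g, max_missing_fraction = 0.5)
  expect_equal(colnames(filt$values), c("PE 16:0-18:2", "PI 18:0-20:4"))
  expect_equal(filt$filter$removed$canonical_name, "PC 16:0-18:1")
})

test_that("raising the missingness tolerance never drops a retained species", {
  set.seed(1)
  m <- matrix(rexp(30 * 40), 30, 40)
  m[runif(length(m)) < 0.4] <- NA
  colnames(m) <- sim_catalog("heart", 40)$canonical_name
  rownames(m) <- paste0("s", 1:30)
  g <- rep(c("a", "b", "c"), each = 10)
  tab <- abundance_table(m, "pmol")
  prev <- character()
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    kept <- colnames(filter_species_by_missingness(tab, g, th)$values)
    expect_true(all(prev %in% kept), info = paste("threshold", th))
    prev <- kept
  }
})

test_that("mole-percent rows sum to 100 over observed values", {
  tab <- make_table(c(25, 75,
                      10, 10), c("PE 16:0-18:2", "PC 16:0-18:1"))
  mp <- to_mole_percent(tab)
  expect_equal(unname(mp$values["s1", ]), c(25, 75))
  expect_equal(unname(mp$values["s2", ]), c(50, 50))

  m <- matrix(c(10, 10, NA), 1, dimnames = list("s1", c("PE 16:0-18:2",
                                                        "PC 16:0-18:1",
                                                        "PI 18:0-20:4")))
  mp2 <- to_mole_percent(abundance_table(m, "pmol"))
  expect_equal(unname(mp2$values[1, ]), c(50, 50, NA))

  set.seed(7)
  big <- matrix(rexp(20 * 50), 20, 50)
  big[sample(length(big), 100)] <- NA
  colnames(big) <- sim_catalog("heart", 50)$canonical_name
  rownames(big) <- paste0("s", 1:20)
  bt <- to_mole_percent(abundance_table(big, "pmol"))
  expect_equal(unname(rowSums(bt$values, na.rm = TRUE)), rep(100, 20))
})

test_that("normalization is invariant to per-sample scale", {
  set.seed(8)
  m <- matrix(rexp(5 * 20), 5, 20,
              dimnames = list(paste0("s", 1:5),
                              sim_catalog("heart", 20)$canonical_name))
  t1 <- to_mole_percent(abundance_table(m, "pmol"))
  m2 <- m; m2[3, ] <- m2[3, ] * 17.3
  t2 <- to_mole_percent(abundance_table(m2, "pmol"))
  expect_equal(t1$values, t2$values)
})

test_that("all-missing samples are named in the normalization error", {
  m <- matrix(c(1, NA, 2, NA), 2, 2,
              dimnames = list(c("good", "bad"),
                              c("PE 16:0-18:2", "PC 16:0-18:1")))
  expect_error(to_mole_percent(abundance_table(m, "pmol")), "bad")
})

test_that("log2 transform round-trips and refuses surviving zeros", {
  tab <- make_table(c(4, 1, 0.25, 8), c("PE 16:0-18:2", "PC 16:0-18:1"),
                    unit_state = "mole_percent")
  lt <- log2_transform(tab)
  expect_equal(unname(lt$values["s1", ]), c(2, 0))
  expect_equal(2^lt$values, tab$values, tolerance = 1e-12)

  zero <- make_table(c(0, 4), c("PE 16:0-18:2", "PC 16:0-18:1"),
                     unit_state = "mole_percent")
  expect_error(log2_transform(zero), "missing at ingest")
})

test_that("imputation fills from group medians or group-mean regression", {
  g <- c("a", "a", "a", "b", "b", "b")
  m <- matrix(c(2, 4, NA, 7, 9, 8), 6, 1,
              dimnames = list(paste0("s", 1:6), "PE 16:0-18:2"))
  tab <- abundance_table(m, "mole_percent")
  gm <- impute_for_class_totals(tab, g, "group_median")
  expect_equal(unname(gm$values[3, 1]), 3)        # median of {2, 4}
  expect_true(gm$imputed[3, 1])
  expect_equal(sum(gm$imputed), 1L)

  # regression imputation equals the least-squares fit on group indicators
  rg <- impute_for_class_totals(tab, g, "regression")
  fit <- lm(v ~ g2, data = data.frame(v = m[-3, 1], g2 = g[-3]))
  expect_equal(unname(rg$values[3, 1]),
               unname(predict(fit, data.frame(g2 = "a"))))

  # fully observed tables pass through unchanged
  full <- abundance_table(matrix(1:6, 6, 1,
                                 dimnames = list(paste0("s", 1:6),
                                                 "PE 16:0-18:2")) * 1.0,
                          "mole_percent")
  expect_equal(impute_for_class_totals(full, g)$values, full$values)
})

test_that("species and sample order survive the whole transform chain", {
  cfg <- simulation_config("heart", n_species = 30, seed = 5)
  st <- simulate_study(cfg)
  f <- filter_species_by_missingness(st$table, st$annotation)
  mp <- to_mole_percent(f)
  lt <- log2_transform(mp)
  expect_equal(rownames(lt$values), rownames(st$table$values))
  expect_true(all(colnames(lt$values) ==
                  colnames(st$table$values)[colnames(st$table$values) %in%
                                            colnames(lt$values)]))
})
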