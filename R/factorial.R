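# Per-species 2x2 factorial linear models (genotype x intervention,
# treatment coding, wt/sham reference), three test families under BH
# control, regulation-group clustering and fold-change classification.

#' Fit the 2x2 factorial linear model for one species
#'
#' Ordinary least squares of log2 mole percent on
#' `1 + genotype + intervention + genotype:intervention` with treatment
#' (dummy) coding and wt / sham reference levels; missing observations are
#' dropped casewise. Three hypotheses are read off the single fit: the
#' genotype coefficient t-test, the intervention coefficient t-test, and
#' the joint F-test of all three terms against the intercept-only model.
#' The intervention effect within the knockout (`b2 + b3`) is also tested
#' as a linear contrast, used by per-genotype fold-change classification.
#'
#' @param y numeric vector of log2 values (may contain `NA`).
#' @param genotype,intervention factors (or coercible) with levels
#'   `wt`/`atATGL-KO` and `sham`/`TAC`.
#' @return List with `coef` (`b0`..`b3`), per-test `t` and `p`, `F` and
#'   `p_F`, the knockout intervention contrast, `df_residual`, `n`,
#'   `cells` (non-empty cell count) and `estimable`.
#' @export
fit_species_linear_model <- function(y, genotype, intervention) {
  genotype <- factor(genotype, levels = c("wt", "atATGL-KO"))
  intervention <- factor(intervention, levels = c("sham", "TAC"))
  ok <- !is.na(y) & !is.na(genotype) & !is.na(intervention)
  y <- y[ok]; g <- genotype[ok]; iv <- intervention[ok]
  cells <- interaction(g, iv, drop = TRUE)
  out <- list(coef = stats::setNames(rep(NA_real_, 4),
                                     c("b0", "b1", "b2", "b3")),
              t = c(genotype = NA_real_, intervention = NA_real_,
                    interaction = NA_real_),
              p = c(genotype = NA_real_, intervention = NA_real_,
                    interaction = NA_real_),
              F = NA_real_, p_F = NA_real_,
              ko_contrast = c(estimate = NA_real_, se = NA_real_,
                              t = NA_real_, p = NA_real_),
              df_residual = NA_integer_, n = length(y),
              cells = nlevels(cells), estimable = FALSE)
  if (length(y) < 5 || nlevels(cells) < 3) return(out)
  fit <- stats::lm(y ~ g * iv)
  if (anyNA(stats::coef(fit))) return(out)   # rank-deficient after missingness
  # noise-free cells trigger the "essentially perfect fit" warning; the
  # zero-variance branch below handles that case explicitly
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  out$coef[] <- stats::coef(fit)[seq_len(nrow(cf))]
  out$df_residual <- fit$df.residual
  out$estimable <- TRUE
  sigma_zero <- sm$sigma < sqrt(.Machine$double.eps) * max(1, abs(mean(y)))
  if (sigma_zero) {
    # zero residual variance: slopes are exact, tests are inestimable
    out$t[] <- NA_real_; out$p[] <- NA_real_
    return(out)
  }
  rn <- rownames(cf)
  pick <- function(term) {
    i <- grep(term, rn)
    c(t = cf[i, "t value"], p = cf[i, "Pr(>|t|)"])
  }
  gi <- pick("^gatATGL-KO$"); ii <- pick("^ivTAC$")
  xi <- pick("^gatATGL-KO:ivTAC$")
  out$t[] <- c(gi["t"], ii["t"], xi["t"])
  out$p[] <- c(gi["p"], ii["p"], xi["p"])
  fs <- unname(sm$fstatistic)
  out$F <- fs[1]
  out$p_F <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  # intervention effect within the knockout: b2 + b3
  V <- stats::vcov(fit)
  est <- sum(stats::coef(fit)[c("ivTAC", "gatATGL-KO:ivTAC")])
  se <- sqrt(V["ivTAC", "ivTAC"] + V["gatATGL-KO:ivTAC", "gatATGL-KO:ivTAC"] +
             2 * V["ivTAC", "gatATGL-KO:ivTAC"])
  tt <- est / se
  out$ko_contrast[] <- c(est, se, tt,
                         2 * stats::pt(-abs(tt), fit$df.residual))
  out
}

#' Fit factorial models for every species
#'
#' Runs [fit_species_linear_model()] per species and applies
#' Benjamini-Hochberg adjustment separately within three test families
#' across species: the genotype t-tests, the intervention t-tests, and the
#' joint F-tests. A species is retained when any family's adjusted p falls
#' below `fdr`. Inestimable species are carried through with `NA`
#' statistics and excluded from the BH families.
#'
#' @param x an `abundance_table` in log2 mole percent.
#' @param annotation mouse annotation data frame.
#' @param fdr retention threshold on adjusted p, default 0.1.
#' @return An object of class `lipid_factorial_fit` whose `table` holds one
#'   row per species: coefficients, cell means, t/F statistics, raw and
#'   adjusted p per family, knockout contrast, and the `retained` flag.
#' @export
fit_lipid_factorial <- function(x, annotation, fdr = 0.1) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$unit_state != "log2_mole_percent")
    stop("factorial models are fitted on log2 mole-percent tables",
         call. = FALSE)
  ann <- validate_annotation(.match_annotation(x, annotation), "mouse")
  v <- x$values
  rows <- lapply(colnames(v), function(sp) {
    f <- fit_species_linear_model(v[, sp], ann$genotype, ann$intervention)
    cell_mean <- function(gt, iv) {
      sel <- ann$genotype == gt & ann$intervention == iv & !is.na(v[, sp])
      if (any(sel)) mean(v[sel, sp]) else NA_real_
    }
    data.frame(
      species = sp,
      class = x$catalog$class_code[x$catalog$canonical_name == sp][1],
      n = f$n, cells = f$cells, estimable = f$estimable,
      b0 = f$coef[1], b1 = f$coef[2], b2 = f$coef[3], b3 = f$coef[4],
      mean_wt_sham = cell_mean("wt", "sham"),
      mean_wt_tac = cell_mean("wt", "TAC"),
      mean_ko_sham = cell_mean("atATGL-KO", "sham"),
      mean_ko_tac = cell_mean("atATGL-KO", "TAC"),
      t_genotype = f$t[["genotype"]], p_genotype = f$p[["genotype"]],
      t_intervention = f$t[["intervention"]],
      p_intervention = f$p[["intervention"]],
      t_interaction = f$t[["interaction"]],
      p_interaction = f$p[["interaction"]],
      F_joint = f$F, p_joint = f$p_F,
      ko_int_estimate = f$ko_contrast[["estimate"]],
      ko_int_t = f$ko_contrast[["t"]], ko_int_p = f$ko_contrast[["p"]],
      df_residual = f$df_residual,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adj_genotype <- bh_adjust(tab$p_genotype)
  tab$p_adj_intervention <- bh_adjust(tab$p_intervention)
  tab$p_adj_joint <- bh_adjust(tab$p_joint)
  adj <- cbind(tab$p_adj_genotype, tab$p_adj_intervention, tab$p_adj_joint)
  tab$retained <- apply(adj < fdr, 1, any, na.rm = TRUE) &
    rowSums(!is.na(adj)) > 0
  structure(list(table = tab, fdr = fdr,
                 n_samples = nrow(v), n_species = ncol(v)),
            class = "lipid_factorial_fit")
}

#' @export
print.lipid_factorial_fit <- function(x, ...) {
  cat("<lipid_factorial_fit> ", x$n_species, " species, ", x$n_samples,
      " samples\n", sep = "")
  cat("  retained (any family adjusted p < ", x$fdr, "): ",
      sum(x$table$retained), "\n", sep = "")
  invisible(x)
}

#' @export
summary.lipid_factorial_fit <- function(object, ...) {
  tab <- object$table
  fam <- c(genotype = sum(tab$p_adj_genotype < object$fdr, na.rm = TRUE),
           intervention = sum(tab$p_adj_intervention < object$fdr,
                              na.rm = TRUE),
           joint = sum(tab$p_adj_joint < object$fdr, na.rm = TRUE))
  out <- list(fdr = object$fdr, per_family = fam,
              retained = sum(tab$retained),
              inestimable = sum(!tab$estimable), n_species = nrow(tab))
  class(out) <- "summary.lipid_factorial_fit"
  out
}

#' @export
print.summary.lipid_factorial_fit <- function(x, ...) {
  cat("2x2 factorial lipidome fit:", x$n_species, "species\n")
  cat("  discoveries at adjusted p <", x$fdr, "\n")
  cat(sprintf("    genotype: %d   intervention: %d   joint F: %d\n",
              x$per_family[["genotype"]], x$per_family[["intervention"]],
              x$per_family[["joint"]]))
  cat("  retained in >=1 family:", x$retained, "\n")
  if (x$inestimable) cat("  inestimable species:", x$inestimable, "\n")
  invisible(x)
}

#' @export
coef.lipid_factorial_fit <- function(object, ...) {
  m <- as.matrix(object$table[, c("b0", "b1", "b2", "b3")])
  rownames(m) <- object$table$species
  m
}

.row_zscore <- function(m) {
  # population SD over the row entries; all-equal rows map to zeros
  t(apply(m, 1, function(r) {
    mu <- mean(r)
    s <- sqrt(mean((r - mu)^2))
    if (s == 0) rep(0, length(r)) else (r - mu) / s
  }))
}

#' Cluster retained species into regulation groups
#'
#' Agglomerative hierarchical clustering (default Ward linkage on Euclidean
#' distance) of the per-species statistic vector (genotype t, intervention
#' t, signed square root of the joint F, the sign taken from the
#' coefficient with the largest absolute t). Columns are standardized
#' before clustering; species are processed in canonical-name order so the
#' labels do not depend on input order. Also returns the display matrix of
#' row-scaled z-scores of the four cell means.
#'
#' @param fit a `lipid_factorial_fit`.
#' @param k number of regulation groups, default 4.
#' @param linkage,metric passed to [stats::hclust()] / [stats::dist()].
#' @return An object of class `regulation_groups`: `labels` (named integer
#'   vector), `statistics` (the clustered matrix), `zscores` (species x 4
#'   cell-mean z-scores, ordered by cluster then dendrogram order),
#'   `hclust`.
#' @export
cluster_regulation_groups <- function(fit, k = 4, linkage = "ward.D2",
                                      metric = "euclidean") {
  stopifnot(inherits(fit, "lipid_factorial_fit"))
  tab <- fit$table[fit$table$retained & fit$table$estimable, , drop = FALSE]
  tab <- tab[!is.na(tab$F_joint), , drop = FALSE]
  if (nrow(tab) < k)
    stop("k = ", k, " exceeds the ", nrow(tab), " retained species",
         call. = FALSE)
  tab <- tab[order(tab$species), , drop = FALSE]
  dom <- cbind(tab$b1, tab$b2, tab$b3)[
    cbind(seq_len(nrow(tab)),
          max.col(abs(cbind(tab$t_genotype, tab$t_intervention,
                            tab$t_interaction)), ties.method = "first"))]
  stat <- cbind(t_genotype = tab$t_genotype,
                t_intervention = tab$t_intervention,
                signed_sqrt_F = sign(dom) * sqrt(tab$F_joint))
  rownames(stat) <- tab$species
  std <- apply(stat, 2, function(col) {
    s <- stats::sd(col)
    if (is.na(s) || s == 0) col - mean(col) else (col - mean(col)) / s
  })
  hc <- stats::hclust(stats::dist(std, method = metric), method = linkage)
  labels <- stats::cutree(hc, k = k)
  cm <- as.matrix(tab[, c("mean_wt_sham", "mean_wt_tac",
                          "mean_ko_sham", "mean_ko_tac")])
  rownames(cm) <- tab$species
  z <- .row_zscore(cm)
  ord <- hc$order
  z <- z[ord, , drop = FALSE][order(labels[ord]), , drop = FALSE]
  structure(list(labels = labels, statistics = stat, zscores = z,
                 hclust = hc, k = k),
            class = "regulation_groups")
}

#' @export
print.regulation_groups <- function(x, ...) {
  cat("<regulation_groups> ", length(x$labels), " species in ", x$k,
      " groups: ", paste(tabulate(x$labels, x$k), collapse = "/"), "\n",
      sep = "")
  invisible(x)
}

#' Dual-threshold significance rule
#'
#' The discovery rule for fold-change classification: BH-adjusted p below
#' `fdr` (default 0.1) together with an absolute log2 fold change of at
#' least `lfc` (default 0.5).
#'
#' @param p_adj adjusted p-values.
#' @param log2fc log2 fold changes.
#' @param fdr,lfc thresholds.
#' @return Logical vector (`NA`-safe: `NA` statistics are never
#'   significant).
#' @export
classify_significant <- function(p_adj, log2fc, fdr = 0.1, lfc = 0.5) {
  sig <- !is.na(p_adj) & !is.na(log2fc) & p_adj < fdr & abs(log2fc) >= lfc
  sig
}

#' Per-genotype fold changes with dual-threshold classification
#'
#' For each genotype separately: the species' mean mole percent over that
#' genotype's samples, the log2 fold change (mean log2 TAC minus mean log2
#' sham), and an intervention p-value BH-adjusted across species within
#' the genotype. The default p backing is the factorial model's
#' intervention test evaluated in the genotype (wt: the intervention
#' coefficient; knockout: the `b2 + b3` contrast), which pools the
#' residual variance over all four cells; two-group alternatives are
#' available.
#'
#' @param mole an `abundance_table` in mole percent (the log2 table's
#'   parent).
#' @param log2tab the matching `abundance_table` in log2 mole percent.
#' @param annotation mouse annotation data frame.
#' @param p_backing `"factorial"` (default), `"ttest"` (equal-variance
#'   two-sample t), `"welch"` or `"mw"` (Mann-Whitney).
#' @param fit a `lipid_factorial_fit` for the factorial backing (computed
#'   on the fly when omitted).
#' @param fdr,lfc dual-threshold parameters (defaults 0.1 and 0.5).
#' @return A data frame of class `fold_change_table`: species, class,
#'   genotype, mean mole percent, log2fc, raw and adjusted p, significance.
#' @export
per_genotype_fold_changes <- function(mole, log2tab, annotation,
                                      p_backing = c("factorial", "ttest",
                                                    "welch", "mw"),
                                      fit = NULL, fdr = 0.1, lfc = 0.5) {
  p_backing <- match.arg(p_backing)
  stopifnot(inherits(mole, "abundance_table"),
            inherits(log2tab, "abundance_table"))
  if (mole$unit_state != "mole_percent" ||
      log2tab$unit_state != "log2_mole_percent")
    stop("need the mole-percent table and its log2 transform", call. = FALSE)
  if (!identical(colnames(mole$values), colnames(log2tab$values)))
    stop("mole-percent and log2 tables disagree on species", call. = FALSE)
  ann <- validate_annotation(.match_annotation(log2tab, annotation), "mouse")
  if (p_backing == "factorial" && is.null(fit))
    fit <- fit_lipid_factorial(log2tab, annotation, fdr = fdr)
  out <- list()
  for (gt in levels(ann$genotype)) {
    sel <- ann$genotype == gt
    if (!any(sel & ann$intervention == "sham") ||
        !any(sel & ann$intervention == "TAC"))
      stop("genotype ", gt, " lacks a sham or TAC group", call. = FALSE)
    lv <- log2tab$values[sel, , drop = FALSE]
    mv <- mole$values[sel, , drop = FALSE]
    tac <- ann$intervention[sel] == "TAC"
    res <- data.frame(
      species = colnames(lv),
      class = log2tab$catalog$class_code,
      genotype = gt,
      mean_mole_pct = colMeans(mv, na.rm = TRUE),
      log2fc = colMeans(lv[tac, , drop = FALSE], na.rm = TRUE) -
        colMeans(lv[!tac, , drop = FALSE], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
    res$p <- vapply(seq_len(ncol(lv)), function(j) {
      ys <- lv[!tac, j]; yt <- lv[tac, j]
      ys <- ys[!is.na(ys)]; yt <- yt[!is.na(yt)]
      if (length(ys) < 2 || length(yt) < 2) return(NA_real_)
      switch(p_backing,
             factorial = {
               row <- fit$table[fit$table$species == colnames(lv)[j], ]
               if (gt == "wt") row$p_intervention else row$ko_int_p
             },
             ttest = tryCatch(stats::t.test(yt, ys,
                                            var.equal = TRUE)$p.value,
                              error = function(e) NA_real_),
             welch = tryCatch(stats::t.test(yt, ys)$p.value,
                              error = function(e) NA_real_),
             mw = mann_whitney_two_sided(yt, ys)$p)
    }, 0)
    res$p_adj <- bh_adjust(res$p)
    res$significant <- classify_significant(res$p_adj, res$log2fc, fdr, lfc)
    out[[gt]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  attr(out, "p_backing") <- p_backing
  attr(out, "thresholds") <- c(fdr = fdr, lfc = lfc)
  out
}

#' @export
print.fold_change_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("<fold_change_table> ", length(unique(x$species)), " species x ",
      length(unique(x$genotype)), " genotypes (p backing: ",
      attr(x, "p_backing"), ")\n", sep = "")
  for (gt in unique(x$genotype)) {
    sub <- x[x$genotype == gt, ]
    cat(sprintf("  %s: %d significant (adjusted p < %g & |log2FC| >= %g)\n",
                gt, sum(sub$significant, na.rm = TRUE), th["fdr"],
                th["lfc"]))
  }
  invisible(x)
}
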