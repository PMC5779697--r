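# Human case/control arm: age- and BMI-corrected class totals and
# per-species robust (Huber) regression with the group coefficient read
# as an estimated log2 fold change.

#' Correct class totals for age and BMI
#'
#' Per class, a pooled (both groups together) least-squares fit of the
#' class total on age and BMI; the corrected value is the residual plus
#' the grand mean, so group differences survive the correction while the
#' corrected values are exactly uncorrelated with both covariates.
#'
#' @param totals a `class_totals` object.
#' @param annotation human annotation data frame (`sample`, `group`,
#'   `age`, `bmi`).
#' @return A `class_totals` object of corrected values (same class order).
#' @export
correct_class_totals <- function(totals, annotation) {
  stopifnot(inherits(totals, "class_totals"))
  v <- totals$values
  i <- match(rownames(v), annotation$sample)
  if (anyNA(i)) stop("samples without annotation", call. = FALSE)
  ann <- validate_annotation(annotation[i, , drop = FALSE], "human")
  if (stats::sd(ann$age) == 0 || stats::sd(ann$bmi) == 0)
    stop("age and BMI must vary across samples to be corrected for",
         call. = FALSE)
  corrected <- apply(v, 2, function(col) {
    ok <- !is.na(col)
    fit <- stats::lm(col[ok] ~ ann$age[ok] + ann$bmi[ok])
    out <- col
    out[ok] <- stats::residuals(fit) + mean(col[ok])
    out
  })
  rownames(corrected) <- rownames(v)
  structure(list(values = corrected, unit_state = "corrected_mole_percent"),
            class = "class_totals")
}

#' Robust covariate-adjusted model for one species
#'
#' Huber M-estimation (tuning constant 1.345, 95% efficiency at the
#' normal) of `log2 value ~ group + age + bmi`. With no outliers every
#' Huber weight is 1 and the fit coincides with ordinary least squares.
#' The group coefficient is the estimated log2 fold change (HFrEF vs
#' control) at fixed age and BMI; its standard error comes from the
#' robust asymptotic covariance of the M-estimator, and p from a t
#' reference with `n - 4` degrees of freedom. The estimated control-group
#' mean mole percent is the back-transformed model prediction for a
#' control subject at the cohort-mean age and BMI.
#'
#' @param y numeric vector of log2 values (may contain `NA`).
#' @param group factor `control` / `HFrEF`.
#' @param age,bmi numeric covariates.
#' @param engine `"robust"` (Huber, default) or `"ls"` (plain least
#'   squares).
#' @return List with `log2fc`, `se`, `t`, `p`, `est_control_mole_pct`,
#'   `n`, `estimable`, `converged`.
#' @export
fit_species_robust_model <- function(y, group, age, bmi,
                                     engine = c("robust", "ls")) {
  engine <- match.arg(engine)
  group <- factor(group, levels = c("control", "HFrEF"))
  ok <- !is.na(y) & !is.na(group) & is.finite(age) & is.finite(bmi)
  out <- list(log2fc = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
              est_control_mole_pct = NA_real_, n = sum(ok),
              estimable = FALSE, converged = NA)
  y <- y[ok]; g <- group[ok]; a <- age[ok]; b <- bmi[ok]
  if (sum(ok) < 6 || length(unique(g)) < 2) return(out)
  fit <- tryCatch({
    if (engine == "robust")
      MASS::rlm(y ~ g + a + b, psi = MASS::psi.huber, k = 1.345,
                maxit = 50, acc = 1e-8)
    else stats::lm(y ~ g + a + b)
  }, error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit))) return(out)
  cf <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients["gHFrEF", "Std. Error"]
  tt <- cf[["gHFrEF"]] / se
  df <- length(y) - length(cf)
  out$log2fc <- cf[["gHFrEF"]]
  out$se <- se
  out$t <- tt
  out$p <- 2 * stats::pt(-abs(tt), df)
  out$est_control_mole_pct <-
    2^(cf[[1]] + cf[["a"]] * mean(a) + cf[["b"]] * mean(b))
  out$estimable <- TRUE
  out$converged <- if (engine == "robust") fit$converged else TRUE
  out
}

#' Covariate-adjusted differential analysis of a plasma lipidome
#'
#' Fits [fit_species_robust_model()] for every species of a log2
#' mole-percent table, adjusts the raw p-values by Benjamini-Hochberg
#' across all species, and applies the dual-threshold discovery rule
#' (adjusted p < `fdr` and |estimated log2FC| >= `lfc`).
#'
#' @param x an `abundance_table` in log2 mole percent.
#' @param annotation human annotation data frame.
#' @param engine `"robust"` (default) or `"ls"`.
#' @param fdr,lfc dual-threshold parameters (defaults 0.1, 0.5).
#' @return An object of class `lipid_cohort_fit` whose `table` has one row
#'   per species: estimated log2 fold change (HFrEF vs control), robust
#'   standard error, raw and adjusted p, estimated control-group mean mole
#'   percent, linear fold change and the `significant` flag.
#' @export
fit_lipid_cohort <- function(x, annotation, engine = c("robust", "ls"),
                             fdr = 0.1, lfc = 0.5) {
  stopifnot(inherits(x, "abundance_table"))
  engine <- match.arg(engine)
  if (x$unit_state != "log2_mole_percent")
    stop("cohort models are fitted on log2 mole-percent tables",
         call. = FALSE)
  ann <- validate_annotation(.match_annotation(x, annotation), "human")
  v <- x$values
  rows <- lapply(colnames(v), function(sp) {
    f <- fit_species_robust_model(v[, sp], ann$group, ann$age, ann$bmi,
                                  engine = engine)
    data.frame(species = sp,
               class = x$catalog$class_code[x$catalog$canonical_name == sp][1],
               n = f$n, estimable = f$estimable,
               log2fc = f$log2fc, se = f$se, t = f$t, p = f$p,
               est_control_mole_pct = f$est_control_mole_pct,
               fold_change = 2^f$log2fc,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adj <- bh_adjust(tab$p)
  tab$significant <- classify_significant(tab$p_adj, tab$log2fc, fdr, lfc)
  structure(list(table = tab, engine = engine, fdr = fdr, lfc = lfc,
                 n_samples = nrow(v), n_species = ncol(v)),
            class = "lipid_cohort_fit")
}

#' @export
print.lipid_cohort_fit <- function(x, ...) {
  cat("<lipid_cohort_fit> ", x$n_species, " species, ", x$n_samples,
      " samples (", x$engine, " fit)\n", sep = "")
  cat("  significant (adjusted p < ", x$fdr, " & |log2FC| >= ", x$lfc, "): ",
      sum(x$table$significant, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}

#' @export
summary.lipid_cohort_fit <- function(object, ...) {
  tab <- object$table
  sig <- tab[tab$significant %in% TRUE, , drop = FALSE]
  sig <- sig[order(sig$p_adj), , drop = FALSE]
  out <- list(engine = object$engine, fdr = object$fdr, lfc = object$lfc,
              n_species = nrow(tab), significant = sig,
              inestimable = sum(!tab$estimable))
  class(out) <- "summary.lipid_cohort_fit"
  out
}

#' @export
print.summary.lipid_cohort_fit <- function(x, ...) {
  cat("Covariate-adjusted cohort fit (", x$engine, "): ", x$n_species,
      " species\n", sep = "")
  cat(sprintf("  %d significant at adjusted p < %g & |log2FC| >= %g\n",
              nrow(x$significant), x$fdr, x$lfc))
  if (nrow(x$significant)) {
    show <- utils::head(x$significant[, c("species", "log2fc",
                                          "fold_change", "p_adj")], 15)
    print(format(show, digits = 3), row.names = FALSE)
  }
  if (x$inestimable) cat("  inestimable species:", x$inestimable, "\n")
  invisible(x)
}

#' @export
coef.lipid_cohort_fit <- function(object, ...) {
  stats::setNames(object$table$log2fc, object$table$species)
}
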