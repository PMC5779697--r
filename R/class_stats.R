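# Class-level analysis: totals per lipid class, Mann-Whitney comparisons
# per family, Benjamini-Hochberg control across classes.

#' Aggregate species to lipid-class totals
#'
#' @param x an `abundance_table` in mole percent (imputation already
#'   applied for class-level work, see [impute_for_class_totals()]).
#' @return An object of class `class_totals`: list with `values` (samples x
#'   classes matrix, classes ordered by mean abundance, descending) and
#'   `unit_state`.
#' @export
class_totals <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$unit_state != "mole_percent")
    stop("class totals are computed on mole-percent tables", call. = FALSE)
  cls <- x$catalog$class_code
  tot <- t(rowsum(t(x$values), cls, na.rm = TRUE))
  # rowsum over t() treats NA as 0; restore NA where a class is fully missing
  n_obs <- t(rowsum(t(!is.na(x$values)) + 0, cls))
  tot[n_obs == 0] <- NA_real_
  tot <- tot[, order(colMeans(tot, na.rm = TRUE), decreasing = TRUE),
             drop = FALSE]
  structure(list(values = tot, unit_state = "mole_percent"),
            class = "class_totals")
}

#' @export
print.class_totals <- function(x, ...) {
  cat("<class_totals> ", nrow(x$values), " samples x ", ncol(x$values),
      " classes\n", sep = "")
  m <- sort(colMeans(x$values, na.rm = TRUE), decreasing = TRUE)
  cat("  mean mole%:", paste(sprintf("%s %.2f", names(m), m), collapse = ", "),
      "\n")
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' In `auto` mode the exact null distribution of U is used when
#' `n1 + n2 <= 20` and the data are tie-free; otherwise the normal
#' approximation with tie and continuity correction. Ties always force the
#' approximation (the exact enumeration assumes continuous data).
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return List with `U` (number of (a, b) pairs with a > b), `p`
#'   (two-sided, in (0, 1]) and `method`.
#' @export
mann_whitney_two_sided <- function(a, b, mode = c("auto", "exact",
                                                  "normal_approx")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode,
                  auto = length(a) + length(b) <= 20 && !ties,
                  exact = !ties,
                  normal_approx = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  p <- min(max(wt$p.value, .Machine$double.xmin), 1)
  list(U = unname(wt$statistic), p = p,
       method = if (exact) "exact" else "normal_approx")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; input order preserved, output
#' monotone in the input and never smaller than it.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

.sig_tier <- function(p_adj) {
  ifelse(is.na(p_adj), "",
         ifelse(p_adj < 0.001, "***",
                ifelse(p_adj < 0.01, "**", ifelse(p_adj < 0.05, "*", ""))))
}

.sem <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))

.compare_family <- function(values, sel1, sel2, family, label1, label2,
                            discovery_fdr) {
  res <- lapply(colnames(values), function(cl) {
    v1 <- values[sel1, cl]; v2 <- values[sel2, cl]
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2 || length(v2) < 2)
      stop("family ", family, " has fewer than 2 samples per group",
           call. = FALSE)
    mw <- mann_whitney_two_sided(v1, v2)
    data.frame(class = cl, family = family,
               n1 = length(v1), n2 = length(v2),
               mean1 = mean(v1), sem1 = .sem(v1),
               mean2 = mean(v2), sem2 = .sem(v2),
               direction = ifelse(mean(v2) > mean(v1), "up", "down"),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out$tier <- .sig_tier(out$p_adj)
  out$significant <- out$p_adj < discovery_fdr
  names(out)[names(out) %in% c("mean1", "sem1", "mean2", "sem2")] <-
    c(paste0("mean_", label1), paste0("sem_", label1),
      paste0("mean_", label2), paste0("sem_", label2))
  out
}

#' Compare lipid-class totals between groups
#'
#' Mouse design: sham vs TAC tested separately within each genotype
#' (two BH families, one per genotype, adjusted across classes). Human
#' design: control vs HFrEF in one family (typically on covariate-corrected
#' totals, see [correct_class_totals()]). Display tiers use adjusted
#' p < 0.05 / 0.01 / 0.001; the pipeline-wide discovery rule (adjusted
#' p < `discovery_fdr`, default 0.1) is reported alongside.
#'
#' @param totals a `class_totals` object.
#' @param annotation mouse or human annotation data frame.
#' @param design `"mouse_within_genotype"` or `"human_two_group"`.
#' @param discovery_fdr adjusted-p discovery threshold, default 0.1.
#' @return A data frame of class `lipid_class_tests`: one row per class per
#'   family with group means and SEM, U, raw and adjusted p, display tier
#'   and discovery flag.
#' @export
compare_classes <- function(totals, annotation,
                            design = c("mouse_within_genotype",
                                       "human_two_group"),
                            discovery_fdr = 0.1) {
  stopifnot(inherits(totals, "class_totals"))
  design <- match.arg(design)
  v <- totals$values
  i <- match(rownames(v), annotation$sample)
  if (anyNA(i)) stop("samples without annotation", call. = FALSE)
  ann <- annotation[i, , drop = FALSE]
  if (design == "mouse_within_genotype") {
    ann <- validate_annotation(ann, "mouse")
    fam <- lapply(levels(ann$genotype), function(gt) {
      sel <- ann$genotype == gt
      .compare_family(v[sel, , drop = FALSE],
                      ann$intervention[sel] == "sham",
                      ann$intervention[sel] == "TAC",
                      family = gt, "sham", "TAC", discovery_fdr)
    })
    out <- do.call(rbind, fam)
  } else {
    ann <- validate_annotation(ann, "human")
    out <- .compare_family(v, ann$group == "control", ann$group == "HFrEF",
                           family = "control_vs_HFrEF", "control", "HFrEF",
                           discovery_fdr)
  }
  class(out) <- c("lipid_class_tests", "data.frame")
  out
}

#' @export
print.lipid_class_tests <- function(x, ...) {
  cat("<lipid_class_tests> ", nrow(x), " class comparisons in ",
      length(unique(x$family)), " family(ies)\n", sep = "")
  sig <- x[x$significant %in% TRUE, ]
  if (nrow(sig))
    cat("  discoveries (adjusted p < 0.1): ",
        paste(sprintf("%s [%s, %s]", sig$class, sig$family, sig$direction),
              collapse = "; "), "\n", sep = "")
  else cat("  no discoveries at adjusted p < 0.1\n")
  invisible(x)
}
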