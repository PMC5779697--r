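# PC/PE ratios of acyl-chain-matched species pairs: per-sample ratios on
# the mole-percent scale and Mann-Whitney intervention tests per genotype.

#' Per-sample ratios for matched species pairs
#'
#' Computes, for every matched pair, the per-sample ratio of the first
#' member's mole percent to the second's. The ratio is missing wherever
#' either member is missing; no imputation is used. Because both members
#' share the sample's normalization denominator, the ratio is invariant to
#' the per-sample total.
#'
#' @param mole an `abundance_table` in mole percent.
#' @param pairs data frame from [find_matched_pairs()] (columns `a`, `b`);
#'   both members must be retained species of the table.
#' @return An object of class `ratio_table`: `values` (samples x pairs
#'   matrix, columns named `"a / b"`) and `pairs`.
#' @export
compute_matched_ratios <- function(mole, pairs) {
  stopifnot(inherits(mole, "abundance_table"))
  if (mole$unit_state != "mole_percent")
    stop("ratios are computed on mole-percent tables", call. = FALSE)
  missing_sp <- setdiff(unique(c(pairs$a, pairs$b)), colnames(mole$values))
  if (length(missing_sp))
    stop("pair member(s) not in the table (filtered out?): ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  v <- mole$values
  ratios <- v[, pairs$a, drop = FALSE] / v[, pairs$b, drop = FALSE]
  colnames(ratios) <- paste(pairs$a, "/", pairs$b)
  structure(list(values = ratios, pairs = pairs), class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat("<ratio_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " matched pairs\n", sep = "")
  invisible(x)
}

#' Test matched ratios for an intervention response
#'
#' Sham vs TAC Mann-Whitney test per pair within each genotype, BH-adjusted
#' across the testable pairs of that genotype. Pairs with fewer than
#' `min_observed` of their ratios observed within a genotype, or fewer
#' than 2 observed ratios in either group, are flagged untestable and
#' excluded from that genotype's BH family. Group means of the ratio are
#' reported with SEM (display convention: log-scaled axis).
#'
#' @param ratios a `ratio_table`.
#' @param annotation mouse annotation data frame.
#' @param min_observed minimum observed fraction of ratios per genotype
#'   family, default 0.5.
#' @param discovery_fdr adjusted-p threshold for flagging, default 0.1.
#' @return Data frame of class `ratio_tests`: pair, genotype, group means
#'   and SEM, U, raw and adjusted p, direction, display tier, `tested`.
#' @export
test_ratios <- function(ratios, annotation, min_observed = 0.5,
                        discovery_fdr = 0.1) {
  stopifnot(inherits(ratios, "ratio_table"))
  v <- ratios$values
  i <- match(rownames(v), annotation$sample)
  if (anyNA(i)) stop("samples without annotation", call. = FALSE)
  ann <- validate_annotation(annotation[i, , drop = FALSE], "mouse")
  out <- list()
  for (gt in levels(ann$genotype)) {
    sel <- ann$genotype == gt
    vv <- v[sel, , drop = FALSE]
    tac <- ann$intervention[sel] == "TAC"
    res <- lapply(colnames(vv), function(pr) {
      rs <- vv[!tac, pr]; rt <- vv[tac, pr]
      rs <- rs[!is.na(rs)]; rt <- rt[!is.na(rt)]
      observed_frac <- (length(rs) + length(rt)) / nrow(vv)
      testable <- observed_frac >= min_observed &&
        length(rs) >= 2 && length(rt) >= 2
      if (testable) {
        mw <- mann_whitney_two_sided(rs, rt)
        U <- mw$U; p <- mw$p
      } else {
        U <- NA_real_; p <- NA_real_
      }
      data.frame(pair = pr, genotype = gt,
                 mean_sham = if (length(rs)) mean(rs) else NA_real_,
                 sem_sham = if (length(rs) > 1) .sem(rs) else NA_real_,
                 mean_tac = if (length(rt)) mean(rt) else NA_real_,
                 sem_tac = if (length(rt) > 1) .sem(rt) else NA_real_,
                 U = U, p = p, tested = testable,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adj <- NA_real_
    res$p_adj[res$tested] <- bh_adjust(res$p[res$tested])
    res$direction <- ifelse(res$mean_tac > res$mean_sham, "up", "down")
    res$tier <- .sig_tier(res$p_adj)
    res$significant <- !is.na(res$p_adj) & res$p_adj < discovery_fdr
    out[[gt]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ratio_tests", "data.frame")
  out
}

#' @export
print.ratio_tests <- function(x, ...) {
  cat("<ratio_tests> ", length(unique(x$pair)), " pairs x ",
      length(unique(x$genotype)), " genotypes\n", sep = "")
  for (gt in unique(x$genotype)) {
    sub <- x[x$genotype == gt & x$significant %in% TRUE, ]
    cat("  ", gt, ": ", nrow(sub), " significantly changed ratio(s)",
        if (nrow(sub)) paste0(" (", paste(sub$direction, collapse = ", "),
                              ")"), "\n", sep = "")
  }
  invisible(x)
}
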