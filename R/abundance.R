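# Abundance tables: samples x species matrices in pmol, mole percent, or
# log2 mole percent. Zeros and blanks in raw input are below-detection
# missing values, never true zeros.

.unit_states <- c("pmol", "mole_percent", "log2_mole_percent")

#' Construct an abundance table
#'
#' @param values numeric matrix, samples in rows, species in columns;
#'   `NA` marks missing (below-detection) entries. Row names are sample
#'   identifiers, column names species names (parsed and canonicalised).
#' @param unit_state one of `"pmol"`, `"mole_percent"`,
#'   `"log2_mole_percent"`.
#' @return An object of class `abundance_table`: list with `values` (matrix
#'   with canonical species column names), `catalog` (see
#'   [species_catalog()]) and `unit_state`.
#' @export
abundance_table <- function(values, unit_state = "pmol") {
  stopifnot(is.matrix(values), is.numeric(values))
  unit_state <- match.arg(unit_state, .unit_states)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample row names and species column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample identifiers", call. = FALSE)
  cat_df <- species_catalog(colnames(values))
  dup <- duplicated(cat_df$canonical_name)
  if (any(dup))
    stop("species names collide after canonicalisation: ",
         paste(sQuote(unique(cat_df$canonical_name[dup])), collapse = ", "),
         call. = FALSE)
  colnames(values) <- cat_df$canonical_name
  if (unit_state != "log2_mole_percent" && any(values < 0, na.rm = TRUE))
    stop("negative amounts are not allowed", call. = FALSE)
  structure(list(values = values, catalog = cat_df, unit_state = unit_state,
                 filter = NULL, imputed = NULL),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  v <- x$values
  cat("<abundance_table> ", nrow(v), " samples x ", ncol(v), " species [",
      x$unit_state, "]\n", sep = "")
  cat("  classes: ", paste(sort(unique(x$catalog$class_code)), collapse = ", "),
      "\n", sep = "")
  miss <- mean(is.na(v))
  cat(sprintf("  missing: %.1f%%", 100 * miss))
  if (!is.null(x$filter))
    cat("  (", nrow(x$filter$removed), " species removed by filter)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read a raw pmol abundance CSV
#'
#' Wide orientation: first column holds sample identifiers, remaining
#' column headers are species names. Long orientation: columns `sample`,
#' `species`, `pmol`. Empty cells and zeros are both recorded as missing
#' (below detection).
#'
#' @param path CSV file path.
#' @param orientation `"wide"` or `"long"`.
#' @return An `abundance_table` with `unit_state = "pmol"`.
#' @export
read_abundance_csv <- function(path, orientation = c("wide", "long")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (orientation == "wide") {
    if (ncol(df) < 2) stop("wide table needs a sample column plus species",
                           call. = FALSE)
    samples <- as.character(df[[1]])
    if (anyDuplicated(samples))
      stop("duplicated sample identifiers in ", path, call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- samples
  } else {
    need <- c("sample", "species", "pmol")
    if (!all(need %in% names(df)))
      stop("long table must have columns sample, species, pmol", call. = FALSE)
    key <- paste(df$sample, df$species, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE]
      stop("duplicate (sample, species) rows, e.g. ", d$sample[1], " / ",
           d$species[1], call. = FALSE)
    }
    samples <- unique(df$sample)
    spp <- unique(df$species)
    m <- matrix(NA_real_, length(samples), length(spp),
                dimnames = list(samples, spp))
    m[cbind(match(df$sample, samples), match(df$species, spp))] <-
      as.numeric(df$pmol)
  }
  m[!is.na(m) & m == 0] <- NA_real_   # zero = below detection
  abundance_table(m, "pmol")
}

#' Read a sample annotation CSV
#'
#' Mouse mode expects columns `sample`, `genotype` (`wt` / `atATGL-KO`),
#' `intervention` (`sham` / `TAC`); human mode expects `sample`, `group`
#' (`control` / `HFrEF`), `age`, `bmi`.
#'
#' @param path CSV file path.
#' @param mode `"mouse"` or `"human"`.
#' @return A validated data frame; factor columns use the reference levels
#'   wt, sham and control.
#' @export
read_annotation_csv <- function(path, mode = c("mouse", "human")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotation(df, mode)
}

#' Validate a sample annotation data frame
#' @param annotation data frame as described in [read_annotation_csv()].
#' @param mode `"mouse"` or `"human"`.
#' @return The annotation with factor levels fixed (wt/sham/control first).
#' @export
validate_annotation <- function(annotation, mode = c("mouse", "human")) {
  mode <- match.arg(mode)
  need <- if (mode == "mouse") c("sample", "genotype", "intervention")
          else c("sample", "group", "age", "bmi")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(annotation$sample))
    stop("duplicated samples in annotation", call. = FALSE)
  if (mode == "mouse") {
    annotation$genotype <- factor(annotation$genotype,
                                  levels = c("wt", "atATGL-KO"))
    annotation$intervention <- factor(annotation$intervention,
                                      levels = c("sham", "TAC"))
    if (anyNA(annotation$genotype) || anyNA(annotation$intervention))
      stop("genotype must be wt/atATGL-KO and intervention sham/TAC",
           call. = FALSE)
  } else {
    annotation$group <- factor(annotation$group, levels = c("control", "HFrEF"))
    if (anyNA(annotation$group))
      stop("group must be control/HFrEF", call. = FALSE)
    if (!all(is.finite(annotation$age)) || !all(is.finite(annotation$bmi)))
      stop("age and bmi must be finite for every sample", call. = FALSE)
  }
  annotation
}

.match_annotation <- function(x, annotation) {
  i <- match(rownames(x$values), annotation$sample)
  if (anyNA(i))
    stop("samples without annotation: ",
         paste(rownames(x$values)[is.na(i)], collapse = ", "), call. = FALSE)
  annotation[i, , drop = FALSE]
}

.grouping_factor <- function(x, grouping) {
  # grouping: factor/character per sample, or a mouse/human annotation df
  if (is.data.frame(grouping)) {
    ann <- .match_annotation(x, grouping)
    if (all(c("genotype", "intervention") %in% names(ann)))
      return(interaction(ann$genotype, ann$intervention, drop = FALSE,
                         sep = ":"))
    if ("group" %in% names(ann)) return(factor(ann$group))
    stop("cannot derive a grouping from this annotation", call. = FALSE)
  }
  if (length(grouping) != nrow(x$values))
    stop("grouping length must equal the number of samples", call. = FALSE)
  factor(grouping)
}

#' Filter species by within-group missingness
#'
#' A species is retained iff in at least one experimental group the
#' fraction of samples in which it was observed is at least
#' `1 - max_missing_fraction`. Species observed reliably in any single
#' group survive, so group-confined lipids are not discarded.
#'
#' @param x an `abundance_table` in pmol.
#' @param grouping per-sample group labels, or an annotation data frame
#'   (mouse annotations group by genotype x intervention cell).
#' @param max_missing_fraction maximum tolerated missing fraction, default
#'   0.5.
#' @return The filtered table; the removal report (data frame of removed
#'   species and their best observed fraction) is kept in `$filter`.
#' @export
filter_species_by_missingness <- function(x, grouping,
                                          max_missing_fraction = 0.5) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$unit_state != "pmol")
    stop("filtering operates on raw pmol tables", call. = FALSE)
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  g <- .grouping_factor(x, grouping)
  obs <- !is.na(x$values)
  by_group <- rowsum(obs + 0, g)                     # groups x species counts
  n_group <- as.vector(table(g)[rownames(by_group)])
  frac <- sweep(by_group, 1, n_group, "/")
  best <- apply(frac, 2, max)
  keep <- best >= 1 - max_missing_fraction
  if (!any(keep)) stop("all species removed by missingness filter",
                       call. = FALSE)
  removed <- data.frame(canonical_name = colnames(x$values)[!keep],
                        best_observed_fraction = unname(best[!keep]),
                        stringsAsFactors = FALSE)
  x$values <- x$values[, keep, drop = FALSE]
  x$catalog <- x$catalog[keep, , drop = FALSE]
  attr(x$catalog, "species") <- attr(x$catalog, "species")[keep]
  x$filter <- list(max_missing_fraction = max_missing_fraction,
                   removed = removed)
  x
}

#' Convert pmol amounts to mole percent
#'
#' Each sample's values are expressed as a percentage of that sample's
#' total observed amount over the retained species (the normalization
#' denominator is computed after filtering).
#'
#' @param x an `abundance_table` in pmol.
#' @return The table with `unit_state = "mole_percent"`; each sample's
#'   observed values sum to 100.
#' @export
to_mole_percent <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$unit_state != "pmol")
    stop("input must be in pmol", call. = FALSE)
  totals <- rowSums(x$values, na.rm = TRUE)
  empty <- rowSums(!is.na(x$values)) == 0
  if (any(empty))
    stop("sample(s) with no observed species: ",
         paste(rownames(x$values)[empty], collapse = ", "), call. = FALSE)
  x$values <- sweep(x$values, 1, totals, "/") * 100
  x$unit_state <- "mole_percent"
  x
}

#' Log2-transform a mole-percent table
#'
#' @param x an `abundance_table` in mole percent with strictly positive
#'   observed values (zeros must have been declared missing at ingest).
#' @return The table with `unit_state = "log2_mole_percent"`.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$unit_state != "mole_percent")
    stop("input must be in mole percent", call. = FALSE)
  if (any(x$values <= 0, na.rm = TRUE))
    stop("non-missing zero or negative value encountered; zeros must be ",
         "declared missing at ingest", call. = FALSE)
  x$values <- log2(x$values)
  x$unit_state <- "log2_mole_percent"
  x
}

#' Impute missing mole-percent values for class-level totals
#'
#' Used only upstream of class-level comparisons; species-level models use
#' casewise deletion instead. `group_median` replaces a missing value by
#' the median of the species' observed values within the sample's group
#' (falling back to the overall species median when the group has none);
#' `regression` uses fitted values of a least-squares fit of the species
#' on group indicators, which on a balanced design equals group means.
#'
#' @param x an `abundance_table` in mole percent.
#' @param grouping as in [filter_species_by_missingness()].
#' @param method `"group_median"` or `"regression"`.
#' @return The table with missing entries filled; the logical matrix of
#'   imputed positions is kept in `$imputed`.
#' @export
impute_for_class_totals <- function(x, grouping,
                                    method = c("group_median", "regression")) {
  stopifnot(inherits(x, "abundance_table"))
  method <- match.arg(method)
  if (x$unit_state != "mole_percent")
    stop("imputation operates on mole-percent tables", call. = FALSE)
  g <- .grouping_factor(x, grouping)
  v <- x$values
  all_missing <- colSums(!is.na(v)) == 0
  if (any(all_missing))
    stop("species missing in all samples (should have been filtered): ",
         paste(colnames(v)[all_missing], collapse = ", "), call. = FALSE)
  imputed <- is.na(v)
  for (j in seq_len(ncol(v))) {
    miss <- which(is.na(v[, j]))
    if (!length(miss)) next
    if (method == "group_median") {
      med_all <- stats::median(v[, j], na.rm = TRUE)
      for (i in miss) {
        sel <- g == g[i]
        med <- stats::median(v[sel, j], na.rm = TRUE)
        v[i, j] <- if (is.na(med)) med_all else med
      }
    } else {
      obs <- !is.na(v[, j])
      fit_means <- tapply(v[obs, j], g[obs], mean)
      overall <- mean(v[obs, j])
      for (i in miss) {
        m <- fit_means[as.character(g[i])]
        v[i, j] <- if (is.na(m)) overall else m
      }
    }
  }
  x$values <- v
  x$imputed <- imputed
  x
}
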