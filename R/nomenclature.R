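# Shorthand lipid nomenclature: "CLASS [O-] C:D[;H] [sep C:D[;H] ...]"
# where sep is "-", an en-dash, or "/". A single composition token on a
# multi-chain class is a sum composition (e.g. "SM 34:1", "CL 76:12").

# class code -> number of radyl chains; ether variants listed explicitly
.chain_counts <- c(
  CL = 4L, TAG = 3L,
  PA = 2L, PC = 2L, PE = 2L, PG = 2L, PI = 2L, PS = 2L, DAG = 2L,
  Cer = 2L, HexCer = 2L, SM = 2L,
  "PC O-" = 2L, "PE O-" = 2L,
  LPA = 1L, LPC = 1L, LPE = 1L, LPG = 1L, LPI = 1L, LPS = 1L,
  "LPC O-" = 1L, "LPE O-" = 1L,
  SE = 1L, CE = 1L,
  Chol = 0L, ST = 0L
)

.known_classes <- names(.chain_counts)

#' Lipid class catalog
#'
#' Class codes understood by the parser together with the number of radyl
#' (acyl/alkyl) chains each class carries and whether it is an ether class.
#'
#' @return A data frame with columns `class_code`, `n_chains`, `ether`.
#' @export
#' @examples
#' lipid_classes()
lipid_classes <- function() {
  data.frame(
    class_code = .known_classes,
    n_chains = unname(.chain_counts),
    ether = grepl("O-$", .known_classes),
    stringsAsFactors = FALSE
  )
}

.format_chain <- function(carbons, double_bonds, hydroxylations) {
  s <- paste0(carbons, ":", double_bonds)
  ifelse(hydroxylations > 0, paste0(s, ";", hydroxylations), s)
}

.parse_chain_token <- function(token, name) {
  m <- regmatches(token, regexec("^([0-9]+):([0-9]+)(;([0-9]+))?$", token))[[1]]
  if (length(m) == 0)
    stop("cannot parse chain token '", token, "' in species name '", name, "'",
         call. = FALSE)
  c(carbons = as.integer(m[2]), double_bonds = as.integer(m[3]),
    hydroxylations = if (m[5] == "") 0L else as.integer(m[5]))
}

#' Parse a shorthand lipid species name
#'
#' Accepts chain-resolved names (`"PE 16:0-18:2"`, `"Cer 18:1;2/17:0"`),
#' sum-composition names (`"SM34:1"`, `"CL 76:12"`) and chain-free sterol
#' names (`"Chol"`). Hyphen, en-dash and `/` are equivalent chain
#' separators; whitespace between class and composition is optional; the
#' ether marker may be written `O-` or `O`.
#'
#' @param name a single species name.
#' @return An object of class `lipid_species`: a list with elements
#'   `class_code`, `chains` (data frame with `carbons`, `double_bonds`,
#'   `hydroxylations`, `ether_linked`; zero rows when only the sum
#'   composition is known), `sum_carbons`, `sum_double_bonds`,
#'   `sum_hydroxylations`, `resolution` (`"chain_resolved"` or
#'   `"sum_composition"`), `ether` and `canonical_name`.
#' @export
#' @examples
#' parse_species_name("PE 16:0-18:2")
#' parse_species_name("SM34:1")
#' parse_species_name("PC O- 16:0/20:4")
parse_species_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  raw <- name
  x <- gsub("\u2013", "-", trimws(name))
  m <- regmatches(x, regexec("^([A-Za-z]+)[ ]*(O-?(?=$|[ 0-9]))?[ ]*(.*)$", x,
                             perl = TRUE))[[1]]
  if (length(m) == 0) stop("cannot parse species name '", raw, "'", call. = FALSE)
  base <- m[2]
  ether <- m[3] != ""
  class_code <- if (ether) paste(base, "O-") else base
  if (!class_code %in% .known_classes)
    stop("unknown lipid class code '", class_code, "' in '", raw, "'",
         call. = FALSE)
  n_expected <- .chain_counts[[class_code]]
  comp <- trimws(m[4])

  if (comp == "") {
    if (n_expected != 0L)
      stop("species '", raw, "' of class ", class_code,
           " lacks a chain composition", call. = FALSE)
    return(.new_species(class_code, chains = .empty_chains(), 0L, 0L, 0L,
                        "chain_resolved", ether))
  }
  if (n_expected == 0L)
    stop("class ", class_code, " carries no chains but '", raw,
         "' has composition '", comp, "'", call. = FALSE)

  tokens <- strsplit(comp, "[-/]")[[1]]
  tokens <- tokens[tokens != ""]
  parsed <- lapply(tokens, .parse_chain_token, name = raw)

  if (length(tokens) == n_expected) {
    chains <- do.call(rbind, lapply(parsed, function(p)
      data.frame(carbons = p[["carbons"]], double_bonds = p[["double_bonds"]],
                 hydroxylations = p[["hydroxylations"]])))
    chains$ether_linked <- FALSE
    if (ether) chains$ether_linked[1] <- TRUE
    .new_species(class_code, chains,
                 sum(chains$carbons), sum(chains$double_bonds),
                 sum(chains$hydroxylations), "chain_resolved", ether)
  } else if (length(tokens) == 1L && n_expected > 1L) {
    p <- parsed[[1]]
    .new_species(class_code, .empty_chains(), p[["carbons"]],
                 p[["double_bonds"]], p[["hydroxylations"]],
                 "sum_composition", ether)
  } else {
    stop("species '", raw, "' has ", length(tokens), " chains but class ",
         class_code, " expects ", n_expected, call. = FALSE)
  }
}

.empty_chains <- function() {
  data.frame(carbons = integer(), double_bonds = integer(),
             hydroxylations = integer(), ether_linked = logical())
}

.new_species <- function(class_code, chains, sum_c, sum_db, sum_oh,
                         resolution, ether) {
  stopifnot(all(chains$carbons > 0), all(chains$double_bonds >= 0),
            all(chains$hydroxylations >= 0))
  obj <- list(class_code = class_code, chains = chains,
              sum_carbons = as.integer(sum_c),
              sum_double_bonds = as.integer(sum_db),
              sum_hydroxylations = as.integer(sum_oh),
              resolution = resolution, ether = ether,
              canonical_name = NA_character_)
  obj$canonical_name <- .format_species(obj)
  class(obj) <- "lipid_species"
  obj
}

.format_species <- function(x) {
  if (nrow(x$chains) == 0 && x$resolution == "chain_resolved")
    return(x$class_code)
  comp <- if (x$resolution == "chain_resolved")
    paste(.format_chain(x$chains$carbons, x$chains$double_bonds,
                        x$chains$hydroxylations), collapse = "-")
  else
    .format_chain(x$sum_carbons, x$sum_double_bonds, x$sum_hydroxylations)
  paste(x$class_code, comp)
}

#' Canonical name of a parsed lipid species
#' @param x a `lipid_species` object.
#' @param ... unused.
#' @return The canonical shorthand name, a single string.
#' @export
format.lipid_species <- function(x, ...) x$canonical_name

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", x$canonical_name, "\n", sep = "")
  cat("  class: ", x$class_code, "  resolution: ", x$resolution,
      if (x$ether) "  (ether)" else "", "\n", sep = "")
  cat("  sum composition: ", x$sum_carbons, ":", x$sum_double_bonds,
      if (x$sum_hydroxylations > 0) paste0(";", x$sum_hydroxylations) else "",
      "\n", sep = "")
  if (nrow(x$chains) > 0)
    cat("  chains: ", paste(.format_chain(x$chains$carbons,
                                          x$chains$double_bonds,
                                          x$chains$hydroxylations),
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Parse many species names into a catalog
#'
#' @param names character vector of shorthand names (e.g. CSV column
#'   headers). Parse failures are collected and reported together.
#' @return A data frame (one row per input, input order preserved) with
#'   columns `name`, `canonical_name`, `class_code`, `sum_carbons`,
#'   `sum_double_bonds`, `n_chains`, `chains` (collapsed `C:D;H` string),
#'   `ether`, `resolution`, plus the parsed objects in attribute `"species"`.
#' @export
species_catalog <- function(names) {
  parsed <- vector("list", length(names))
  bad <- character()
  for (i in seq_along(names)) {
    parsed[[i]] <- tryCatch(parse_species_name(names[i]), error = function(e) e)
    if (inherits(parsed[[i]], "error")) bad <- c(bad, names[i])
  }
  if (length(bad))
    stop("unparseable species names: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  cat_df <- data.frame(
    name = names,
    canonical_name = vapply(parsed, function(s) s$canonical_name, ""),
    class_code = vapply(parsed, function(s) s$class_code, ""),
    sum_carbons = vapply(parsed, function(s) s$sum_carbons, 0L),
    sum_double_bonds = vapply(parsed, function(s) s$sum_double_bonds, 0L),
    n_chains = vapply(parsed, function(s) nrow(s$chains), 0L),
    chains = vapply(parsed, function(s)
      paste(.format_chain(s$chains$carbons, s$chains$double_bonds,
                          s$chains$hydroxylations), collapse = "-"), ""),
    ether = vapply(parsed, function(s) s$ether, TRUE),
    resolution = vapply(parsed, function(s) s$resolution, ""),
    stringsAsFactors = FALSE
  )
  attr(cat_df, "species") <- parsed
  cat_df
}

#' Order-insensitive chain composition of a species
#'
#' Returns the multiset of chain compositions as a sorted character vector
#' of `"C:D;H"` entries (hydroxylation suffix always present so that
#' multiplicity and hydroxylation state both participate in equality);
#' sn-position is deliberately discarded.
#'
#' @param species a `lipid_species` object (chain-resolved).
#' @return Sorted character vector, one entry per chain.
#' @export
#' @examples
#' chain_multiset(parse_species_name("PE 18:1-18:1"))
chain_multiset <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (species$resolution != "chain_resolved")
    stop("chains unresolved for '", species$canonical_name, "'", call. = FALSE)
  ch <- species$chains
  sort(paste0(ch$carbons, ":", ch$double_bonds, ";", ch$hydroxylations))
}

.multiset_key <- function(species) paste(chain_multiset(species), collapse = "|")

#' Match species across two classes by acyl-chain composition
#'
#' Pairs species whose chain multisets are identical (sn-position ignored,
#' hydroxylations included). Ether species are excluded by default; with
#' `include_ether = TRUE` ether species are matched among themselves
#' (an ether never pairs with a diacyl species). Each species joins at most
#' one pair; candidates are taken in lexicographic canonical-name order so
#' the result is deterministic.
#'
#' @param class_a_species,class_b_species lists of `lipid_species` (or
#'   character vectors of names, which are parsed).
#' @param include_ether logical; match ether species among themselves.
#' @return A data frame with columns `a`, `b` (canonical names) and
#'   `chains` (the shared multiset key), ordered by `a`.
#' @export
find_matched_pairs <- function(class_a_species, class_b_species,
                               include_ether = FALSE) {
  norm <- function(lst) {
    if (is.character(lst)) lst <- lapply(lst, parse_species_name)
    if (inherits(lst, "lipid_species")) lst <- list(lst)
    lst <- Filter(function(s) s$resolution == "chain_resolved", lst)
    if (!include_ether) lst <- Filter(function(s) !s$ether, lst)
    lst[order(vapply(lst, function(s) s$canonical_name, ""))]
  }
  a <- norm(class_a_species)
  b <- norm(class_b_species)
  key_b <- vapply(b, .multiset_key, "")
  ether_b <- vapply(b, function(s) s$ether, TRUE)
  used <- rep(FALSE, length(b))
  out_a <- out_b <- out_k <- character()
  for (sa in a) {
    k <- .multiset_key(sa)
    j <- which(!used & key_b == k & ether_b == sa$ether)
    if (length(j)) {
      j <- j[1]
      used[j] <- TRUE
      out_a <- c(out_a, sa$canonical_name)
      out_b <- c(out_b, b[[j]]$canonical_name)
      out_k <- c(out_k, k)
    }
  }
  data.frame(a = out_a, b = out_b, chains = out_k, stringsAsFactors = FALSE)
}
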