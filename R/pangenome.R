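#' Build a family-by-lineage presence matrix
#'
#' @param family_sets named list, one character vector of family names per
#'   lineage (e.g. from [mirnome_families()] applied to each lineage's
#'   locus table). Lineage names must be unique; a lineage may be empty.
#' @return object of class `presence_matrix`: list with `present` (logical
#'   families x lineages matrix, families natural-sorted, lineages in
#'   input order), `families`, `lineages` and `counts` (lineages per
#'   family). Families observed in zero lineages cannot occur by
#'   construction.
#' @export
build_presence_matrix <- function(family_sets) {
  if (length(family_sets) == 0) stop("need at least one lineage")
  lineages <- names(family_sets)
  if (is.null(lineages) || any(!nzchar(lineages))) {
    stop("family sets must be named by lineage")
  }
  if (anyDuplicated(lineages)) stop("duplicate lineage names")
  families <- sort_families(unique(unlist(family_sets, use.names = FALSE)))
  present <- matrix(FALSE, nrow = length(families), ncol = length(lineages),
                    dimnames = list(families, lineages))
  for (l in lineages) present[, l] <- families %in% family_sets[[l]]
  res <- list(present = present, families = families, lineages = lineages,
              counts = rowSums(present))
  class(res) <- "presence_matrix"
  res
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("Presence matrix:", length(x$families), "families x",
      length(x$lineages), "lineages\n")
  grp <- classify_conservation(x$counts, n_lineages = length(x$lineages))
  print(table(group = grp))
  invisible(x)
}

#' Conservation group boundaries
#'
#' For a 54-lineage panel the groups are: rare (1-9 lineages), moderately
#' conserved (10-44), highly conserved (45-52) and common (53-54). The
#' intervals are inclusive and partition the full range of counts. For
#' other panel sizes the three upper boundaries scale by the same
#' fractions (9/54, 44/54, 52/54), rounded down.
#'
#' @param n_lineages panel size.
#' @return named integer vector `c(rare_max, moderate_max, high_max)`.
#' @export
conservation_thresholds <- function(n_lineages = 54L) {
  n_lineages <- as.integer(n_lineages)
  if (n_lineages < 1) stop("n_lineages must be positive")
  if (n_lineages == 54L) {
    th <- c(9L, 44L, 52L)
  } else {
    th <- as.integer(floor(c(9, 44, 52) / 54 * n_lineages))
  }
  names(th) <- c("rare_max", "moderate_max", "high_max")
  th
}

#' Classify a family's conservation level
#'
#' @param lineage_count integer vector: number of lineages the family was
#'   identified in (1 .. `n_lineages`).
#' @param n_lineages panel size (default 54).
#' @return factor with levels `rare`, `moderately_conserved`,
#'   `highly_conserved`, `common`.
#' @examples
#' classify_conservation(c(9, 44, 45, 54))
#' @export
classify_conservation <- function(lineage_count, n_lineages = 54L) {
  lineage_count <- as.integer(lineage_count)
  if (any(lineage_count < 1 | lineage_count > n_lineages)) {
    stop("lineage_count must be in [1, n_lineages]")
  }
  th <- conservation_thresholds(n_lineages)
  lv <- c("rare", "moderately_conserved", "highly_conserved", "common")
  g <- ifelse(lineage_count <= th["rare_max"], lv[1],
       ifelse(lineage_count <= th["moderate_max"], lv[2],
       ifelse(lineage_count <= th["high_max"], lv[3], lv[4])))
  factor(g, levels = lv)
}

#' Directional pairwise conservation matrix
#'
#' The extent of miRNA conservation of lineage A with lineage B is the
#' number of families shared by A and B divided by the number of families
#' in A. The matrix is generally asymmetric and should be read row-first:
#' `C["Arn1", "Mon3"]` is conservation of Arn1 with Mon3.
#'
#' @param pm a `presence_matrix`.
#' @return numeric lineages x lineages matrix with entries in `[0, 1]`;
#'   diagonal 1 for every lineage with at least one family.
#' @export
pairwise_conservation <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  P <- pm$present * 1L
  totals <- colSums(P)
  if (any(totals == 0)) {
    stop("lineage(s) with zero families: ",
         paste(pm$lineages[totals == 0], collapse = ", "))
  }
  shared <- crossprod(P)            # lineages x lineages, |A intersect B|
  sweep(shared, 1, totals, "/")
}

#' Per-family summary table
#'
#' Joins presence counts, conservation group, precursor counts and
#' repeat-content flags into one table, the per-family bookkeeping behind
#' precursor-distribution figures.
#'
#' @param pm a `presence_matrix`.
#' @param loci combined locus table (rows of [discover_mirnome()] results
#'   across lineages), optionally carrying a logical `repetitive` column
#'   from [annotate_repetitive()].
#' @return data.frame: `family`, `lineage_count`, `group`,
#'   `n_precursors`, `n_repetitive`. Families without any locus are
#'   dropped.
#' @export
family_summary <- function(pm, loci) {
  stopifnot(inherits(pm, "presence_matrix"))
  fams <- pm$families[pm$families %in% loci$family]
  n_pre <- vapply(fams, function(f) sum(loci$family == f), integer(1))
  n_rep <- if ("repetitive" %in% names(loci)) {
    vapply(fams, function(f) sum(loci$repetitive[loci$family == f]),
           integer(1))
  } else {
    rep(NA_integer_, length(fams))
  }
  data.frame(family = fams,
             lineage_count = unname(pm$counts[fams]),
             group = classify_conservation(pm$counts[fams],
                                           n_lineages = length(pm$lineages)),
             n_precursors = unname(n_pre),
             n_repetitive = unname(n_rep),
             stringsAsFactors = FALSE)
}

#' Curated conservation-group catalogue for Brachypodium miRNA families
#'
#' Loads the bundled catalogue of miRNA families identified across the
#' 54-lineage *Brachypodium distachyon* pan-genome, with each family's
#' conservation group. The catalogue names 20 rare, 10 moderately
#' conserved, 18 highly conserved and 66 common families (114 named
#' families in total); the survey's summary tallies count 115 families
#' with 67 in the common group, i.e. one common family is not named in
#' the catalogue. The rare/moderate/high counts match the tallies.
#'
#' @return data.frame with columns `family` and `group` (factor with the
#'   levels of [classify_conservation()]).
#' @export
family_conservation_catalogue <- function() {
  path <- system.file("extdata", "brachypodium_family_groups.tsv",
                      package = "panmirnome", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = c("rare", "moderately_conserved",
                                          "highly_conserved", "common"))
  df
}
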