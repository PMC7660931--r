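#' Per-gene score profile
#'
#' A score profile holds one gene's observed bitscores across species
#' together with each species' evolutionary distance from the focal
#' species. The focal species itself must be present at distance 0 with
#' the gene's self-comparison score.
#'
#' @param species character vector of species identifiers (unique).
#' @param t numeric vector of evolutionary distances from the focal
#'   species, in substitutions/site; all non-negative.
#' @param score numeric vector of bitscores; all non-negative.
#' @param gene_id single string naming the gene.
#' @param focal_species single string; must appear in `species` with
#'   `t == 0`.
#' @return A data frame of class `score_profile` with columns `species`,
#'   `t`, `score` and attributes `gene_id` and `focal_species`.
#' @examples
#' score_profile(c("Scer", "Spar", "Smik"), c(0, 0.02, 0.09),
#'               c(200, 180, 150), "YAL001C", "Scer")
#' @export
score_profile <- function(species, t, score, gene_id = "gene",
                          focal_species = species[which.min(t)]) {
  species <- as.character(species)
  t <- as.numeric(t)
  score <- as.numeric(score)
  n <- length(species)
  stopifnot(length(t) == n, length(score) == n,
            length(gene_id) == 1, length(focal_species) == 1)
  if (anyNA(t) || anyNA(score))
    stop("missing values in 't' or 'score' for gene ", gene_id)
  if (any(t < 0))
    stop("negative evolutionary distance for gene ", gene_id)
  if (any(score < 0))
    stop("negative bitscore for gene ", gene_id)
  if (anyDuplicated(species))
    stop("duplicated species in profile for gene ", gene_id)
  i <- match(focal_species, species)
  if (is.na(i))
    stop("focal species '", focal_species, "' absent from profile for gene ",
         gene_id)
  if (t[i] != 0)
    stop("focal species must be at distance 0 (gene ", gene_id, ")")
  out <- data.frame(species = species, t = t, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "gene_id") <- as.character(gene_id)
  attr(out, "focal_species") <- as.character(focal_species)
  class(out) <- c("score_profile", "data.frame")
  out
}

#' @export
print.score_profile <- function(x, ...) {
  cat("Score profile for gene '", attr(x, "gene_id"), "' (focal: ",
      attr(x, "focal_species"), ", ", nrow(x), " species)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Species-to-distance map
#'
#' @param distances named numeric vector: species -> distance from the
#'   focal species in substitutions/site.
#' @param focal_species focal species name; its distance must be 0. If it
#'   is missing from `distances` it is added with distance 0.
#' @param source `"computed"` or `"supplied"`.
#' @return named numeric vector of class `species_distances`.
#' @export
species_distances <- function(distances, focal_species,
                              source = c("supplied", "computed")) {
  source <- match.arg(source)
  stopifnot(is.numeric(distances), !is.null(names(distances)))
  if (!focal_species %in% names(distances))
    distances <- c(setNames(0, focal_species), distances)
  if (anyNA(distances) || any(distances < 0))
    stop("distances must be non-negative and non-missing")
  if (distances[[focal_species]] != 0)
    stop("focal species must have distance 0")
  if (anyDuplicated(names(distances)))
    stop("duplicated species names in distance set")
  structure(distances, focal_species = focal_species, source = source,
            class = "species_distances")
}

#' @export
print.species_distances <- function(x, ...) {
  cat("Distances from focal species '", attr(x, "focal_species"),
      "' (", attr(x, "source"), "):\n", sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Read and write two-column species/distance tables
#'
#' The distance table is a TSV with a header and two columns,
#' `species` and `distance` (substitutions/site from the focal species).
#'
#' @param path file path.
#' @param focal_species focal species; defaults to the species at
#'   distance 0.
#' @return [read_distance_table()] returns a [species_distances] object.
#' @export
read_distance_table <- function(path, focal_species = NULL) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) < 2)
    stop("distance table must have two columns (species, distance): ", path)
  v <- setNames(as.numeric(d[[2]]), as.character(d[[1]]))
  if (is.null(focal_species)) {
    i <- which(v == 0)
    if (length(i) != 1)
      stop("cannot infer focal species: expected exactly one distance of 0")
    focal_species <- names(v)[i]
  }
  species_distances(v, focal_species, source = "supplied")
}

#' @param x a [species_distances] object.
#' @rdname read_distance_table
#' @export
write_distance_table <- function(x, path) {
  df <- data.frame(species = names(x), distance = as.numeric(x))
  write.table(format(df, digits = 6, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-species bitscore table
#'
#' Rows are genes, columns species; the first column holds gene ids.
#' Empty cells (or NA) mean no ortholog was assigned in that species.
#'
#' @param path TSV file path.
#' @return numeric matrix (genes x species) with NA for missing
#'   orthologs; row names are gene ids.
#' @export
read_score_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(d) < 2) stop("score table needs a gene column plus species columns")
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  m
}

#' Assemble score profiles from a score matrix and a distance set
#'
#' Species present in the score table but absent from the distance set are
#' an error; genes keep whatever subset of species has an observed score.
#' Genes with fewer than 3 observations are kept (the fit will flag them
#' as `insufficient_data`), never dropped.
#'
#' @param scores numeric matrix as from [read_score_table()].
#' @param distances a [species_distances] object.
#' @return named list of [score_profile] objects, in input row order.
#' @export
profiles_from_table <- function(scores, distances) {
  focal <- attr(distances, "focal_species")
  missing_sp <- setdiff(colnames(scores), names(distances))
  if (length(missing_sp))
    stop("species in score table without a distance: ",
         paste(missing_sp, collapse = ", "))
  if (!focal %in% colnames(scores))
    stop("focal species '", focal, "' has no score column (self-scores required)")
  out <- lapply(rownames(scores), function(g) {
    s <- scores[g, ]
    keep <- !is.na(s)
    if (!keep[[focal]])
      stop("gene ", g, " lacks a self-score in focal species ", focal)
    sp <- colnames(scores)[keep]
    score_profile(sp, as.numeric(distances[sp]), as.numeric(s[keep]),
                  gene_id = g, focal_species = focal)
  })
  setNames(out, rownames(scores))
}
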