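#' Aligned amino-acid block
#'
#' A light container for one locus' multiple sequence alignment: a named
#' character vector (species -> aligned sequence), all rows the same
#' length, alphabet restricted to the 20 amino acids plus gap `-` and
#' ambiguity `X`. Alignments are consumed, not built, here; distances
#' derived from them are relative, which is all the decay model needs
#' (each gene's decay rate rescales them).
#'
#' @param rows named character vector of aligned sequences.
#' @param locus_id optional locus label.
#' @return object of class `aa_alignment`.
#' @export
alignment <- function(rows, locus_id = "locus") {
  stopifnot(is.character(rows), !is.null(names(rows)))
  rows <- toupper(rows)
  if (anyDuplicated(names(rows))) stop("duplicated species ids in alignment")
  w <- unique(nchar(rows))
  if (length(w) != 1)
    stop("unequal row lengths in alignment '", locus_id, "'")
  bad <- grepl("[^ARNDCQEGHILKMFPSTWYVX-]", rows)
  if (any(bad))
    stop("invalid characters in alignment '", locus_id, "' (species: ",
         paste(names(rows)[bad], collapse = ", "), ")")
  structure(rows, locus_id = locus_id, class = "aa_alignment")
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment '", attr(x, "locus_id"), "': ",
      length(x), " species x ", nchar(x[[1]]), " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Record ids are taken as species ids (first whitespace-delimited
#' token).
#'
#' @param path aligned FASTA file.
#' @param locus_id label; defaults to the file name.
#' @return an [alignment] object.
#' @export
read_alignment <- function(path, locus_id = basename(path)) {
  ss <- Biostrings::readAAStringSet(path)
  rows <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  alignment(rows, locus_id = locus_id)
}

#' Concatenate per-locus alignments
#'
#' Joins blocks species-wise in the given order. Every species present in
#' any block must be present in all blocks (single-copy marker sets such
#' as BUSCO genes with orthologs in all species satisfy this).
#'
#' @param blocks list of [alignment] objects.
#' @param locus_id label for the concatenated block.
#' @return an [alignment] spanning the summed length.
#' @export
concat_alignments <- function(blocks, locus_id = "concatenated") {
  stopifnot(length(blocks) >= 1)
  blocks <- lapply(blocks, function(b)
    if (inherits(b, "aa_alignment")) b else alignment(b))
  all_sp <- sort(unique(unlist(lapply(blocks, names))))
  for (b in blocks) {
    miss <- setdiff(all_sp, names(b))
    if (length(miss))
      stop("species missing from block '", attr(b, "locus_id"), "': ",
           paste(miss, collapse = ", "))
  }
  rows <- vapply(all_sp, function(sp)
    paste(vapply(blocks, function(b) b[[sp]], character(1)), collapse = ""),
    character(1))
  alignment(rows, locus_id = locus_id)
}

#' Pairwise evolutionary distance between two aligned sequences
#'
#' Distances are in substitutions/site. Columns with a gap or ambiguity
#' in either row are excluded for that pair (complete-pair deletion,
#' maximising usable sites). Two estimators:
#' * `"ml_empirical"` (default): maximum-likelihood distance under an
#'   amino-acid replacement model, maximising the pairwise likelihood
#'   \eqn{\sum_{xy} N_{xy} \log(\pi_x P_{xy}(d))} by one-dimensional
#'   search over \eqn{d \in [10^{-6}, 20]}. `submodel` selects the
#'   exchangeability matrix: `"JTT"` (default, the classic protdist
#'   choice), `"WAG"`, `"LG"`, `"Dayhoff"`, or `"uniform"` (all
#'   exchangeabilities and frequencies equal, the 20-state
#'   Poisson-family model).
#' * `"poisson"`: the analytic correction \eqn{d = -\ln(1 - p)} with
#'   \eqn{p} the fraction of differing comparable columns; fast fallback.
#'
#' Rate matrices are normalised to one expected substitution per site
#' per unit distance. Poisson saturation (\eqn{p \ge 1 - 10^{-9}})
#' returns the search cap of 20 substitutions/site with a warning.
#'
#' @param aln an [alignment].
#' @param sp1,sp2 species ids present in `aln`.
#' @param model `"ml_empirical"` or `"poisson"`.
#' @param submodel exchangeability matrix for the ML estimator.
#' @return single non-negative distance.
#' @export
pairwise_distance <- function(aln, sp1, sp2,
                              model = c("ml_empirical", "poisson"),
                              submodel = "JTT") {
  model <- match.arg(model)
  stopifnot(inherits(aln, "aa_alignment"))
  miss <- setdiff(c(sp1, sp2), names(aln))
  if (length(miss))
    stop("species not in alignment: ", paste(miss, collapse = ", "))
  x <- strsplit(aln[[sp1]], "")[[1]]
  y <- strsplit(aln[[sp2]], "")[[1]]
  keep <- x %in% .AA20 & y %in% .AA20
  if (!any(keep))
    stop("no comparable columns between ", sp1, " and ", sp2)
  x <- x[keep]; y <- y[keep]

  if (model == "poisson") {
    p <- mean(x != y)
    if (p >= 1 - 1e-9) {
      warning("saturated pair (", sp1, ", ", sp2, "): distance capped at 20")
      return(20)
    }
    return(-log(1 - p))
  }

  if (all(x == y)) return(0)
  .ml_pairwise(match(x, .AA20), match(y, .AA20), .aa_model(submodel))
}

# exchangeability matrix (lower triangle, 190 values) and equilibrium
# frequencies for a named empirical model, or the uniform model
.aa_model <- function(submodel) {
  if (identical(submodel, "uniform"))
    return(list(Q = rep(1, 190), bf = rep(1 / 20, 20)))
  obj <- paste0(".", submodel)
  ns <- asNamespace("phangorn")
  if (!exists(obj, envir = ns))
    stop("unknown substitution model: ", submodel)
  m <- get(obj, envir = ns)
  list(Q = m$Q, bf = unname(m$bf))  # frequencies in ARNDCQEGHILKMFPSTWYV order
}

# ML distance for one pair: spectral decomposition of the reversible
# rate matrix, then a coarse scan plus golden-section refinement of the
# log-likelihood over d in [1e-6, 20]
.ml_pairwise <- function(ix, iy, mod, d_max = 20) {
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- mod$Q
  S <- S + t(S)
  bf <- mod$bf
  Q <- S %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(bf * diag(Q))  # one substitution/site per unit distance
  rb <- sqrt(bf)
  B <- diag(rb) %*% Q %*% diag(1 / rb)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / rb) %*% eg$vectors
  W <- t(eg$vectors) %*% diag(rb)
  N <- matrix(0, 20, 20)
  for (k in seq_along(ix)) N[ix[k], iy[k]] <- N[ix[k], iy[k]] + 1
  nz <- which(N > 0, arr.ind = TRUE)
  cnt <- N[nz]
  ll <- function(d) {
    P <- U %*% (exp(eg$values * d) * W)
    sum(cnt * log(pmax(bf[nz[, 1]] * P[nz], 1e-300)))
  }
  ds <- exp(seq(log(1e-6), log(d_max), length.out = 60))
  lls <- vapply(ds, ll, numeric(1))
  i <- which.max(lls)
  lo <- ds[max(i - 1, 1)]; hi <- ds[min(i + 1, length(ds))]
  optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)$maximum
}

#' Distances from a focal species to every other species
#'
#' Applies [pairwise_distance()] between the focal species and each other
#' species in the (typically concatenated) alignment. Species whose
#' distance cannot be computed (e.g. no comparable columns) are dropped
#' with a warning naming them.
#'
#' @param aln an [alignment] containing the focal species.
#' @param focal focal species id.
#' @inheritParams pairwise_distance
#' @return a [species_distances] object (focal at 0), `source =
#'   "computed"`.
#' @export
distances_from_focal <- function(aln, focal,
                                 model = c("ml_empirical", "poisson"),
                                 submodel = "JTT") {
  model <- match.arg(model)
  stopifnot(inherits(aln, "aa_alignment"))
  if (!focal %in% names(aln))
    stop("focal species '", focal, "' not in alignment")
  others <- setdiff(names(aln), focal)
  vals <- lapply(others, function(sp)
    tryCatch(pairwise_distance(aln, focal, sp, model = model,
                               submodel = submodel),
             error = function(e) NA_real_))
  vals <- setNames(unlist(vals), others)
  if (anyNA(vals)) {
    warning("dropping species with uncomputable distances: ",
            paste(names(vals)[is.na(vals)], collapse = ", "))
    vals <- vals[!is.na(vals)]
  }
  species_distances(c(setNames(0, focal), vals), focal,
                    source = "computed")
}

#' Gap density of an alignment
#'
#' Total gap characters divided by (columns x sequences) - the gaps per
#' column per sequence.
#'
#' @param aln an [alignment].
#' @return real in \[0, 1\].
#' @export
gap_density <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (length(aln) == 0 || nchar(aln[[1]]) == 0) stop("empty alignment")
  gaps <- sum(vapply(aln, function(s)
    sum(strsplit(s, "")[[1]] == "-"), numeric(1)))
  gaps / (nchar(aln[[1]]) * length(aln))
}
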