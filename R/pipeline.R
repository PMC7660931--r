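#' Genome-wide detectability analysis
#'
#' The end-to-end null-model test: for every gene in a score table, fit
#' the exponential decay model to its observed bitscores, then
#' extrapolate to each target (outgroup) species and compute the
#' probability that a homolog there would still be detected. Ineligible
#' genes (fewer than 3 observations) and non-decaying genes are retained
#' with their status flags, never dropped; output rows follow input
#' order, so repeated runs are identical.
#'
#' The detectability threshold is either an explicit `bitscore_cutoff`
#' (recommended when matching a specific search program's accounting) or
#' derived per gene and target as \eqn{\log_2(m n / E)} from `evalue`,
#' the gene's query length `query_len` and the target proteome size
#' `db_len`.
#'
#' @param scores gene-by-species bitscore matrix ([read_score_table()])
#'   or a path to one. Must contain a focal-species column of
#'   self-scores.
#' @param distances a [species_distances] object or path to a distance
#'   TSV.
#' @param targets character vector of target species (must have
#'   distances); they may also appear in the score table, in which case
#'   their scores are excluded from each gene's fit (the test's
#'   protocol: fit inside the lineage, extrapolate out).
#' @param bitscore_cutoff explicit threshold in bits (scalar or named
#'   per target); overrides the E-value formula.
#' @param evalue E-value threshold (default 0.001).
#' @param query_len residues per gene: named vector, scalar, or `NULL`
#'   to approximate from the self-score (self-score / 2 bits per
#'   residue).
#' @param db_len database size in residues per target (named or scalar).
#' @param pi_level prediction-interval level (default 0.99).
#' @param param_uncertainty include delta-method parameter variance.
#' @param weighted passed to [fit_decay()].
#' @return data frame, one row per gene: `gene`, `a`, `b`, `r2_log`,
#'   `n_points`, `status`, then for each target species `<sp>.mean`,
#'   `<sp>.pi_low`, `<sp>.pi_high`, `<sp>.p_detected`, `<sp>.flags`.
#' @export
run_detectability_analysis <- function(scores, distances, targets,
                                       bitscore_cutoff = NULL,
                                       evalue = 0.001, query_len = NULL,
                                       db_len = NULL, pi_level = 0.99,
                                       param_uncertainty = TRUE,
                                       weighted = FALSE) {
  if (is.character(scores) && length(scores) == 1)
    scores <- read_score_table(scores)
  if (is.character(distances) && length(distances) == 1)
    distances <- read_distance_table(distances)
  stopifnot(inherits(distances, "species_distances"))
  miss <- setdiff(targets, names(distances))
  if (length(miss))
    stop("target species without a distance: ", paste(miss, collapse = ", "))

  fit_scores <- scores[, !colnames(scores) %in% targets, drop = FALSE]
  profs <- profiles_from_table(fit_scores, distances)
  genes <- rownames(scores)

  # per-gene, per-target threshold in bits
  cutoff_for <- function(gene, target, self_score) {
    if (!is.null(bitscore_cutoff)) {
      if (!is.null(names(bitscore_cutoff))) {
        if (!target %in% names(bitscore_cutoff))
          stop("no bitscore_cutoff for target ", target)
        return(bitscore_cutoff[[target]])
      }
      return(bitscore_cutoff[[1]])
    }
    if (is.null(db_len))
      stop("either bitscore_cutoff or db_len must be supplied")
    n <- if (!is.null(names(db_len))) {
      if (!target %in% names(db_len))
        stop("no db_len for target ", target)
      db_len[[target]]
    } else db_len[[1]]
    m <- if (is.null(query_len)) {
      max(round(self_score / 2), 1)  # ~2 bits per residue of self-score
    } else if (!is.null(names(query_len))) {
      if (!gene %in% names(query_len))
        stop("no query_len for gene ", gene)
      query_len[[gene]]
    } else query_len[[1]]
    bitscore_threshold(evalue, m = m, n = n)$bits
  }

  rows <- lapply(genes, function(g) {
    pr <- profs[[g]]
    fit <- fit_decay(pr, weighted = weighted)
    self_score <- pr$score[pr$t == 0][1]
    base <- data.frame(gene = g, a = fit$a, b = fit$b, r2_log = fit$r2_log,
                       n_points = fit$n_points, status = fit$status,
                       stringsAsFactors = FALSE)
    for (sp in targets) {
      tt <- distances[[sp]]
      cut <- cutoff_for(g, sp, self_score)
      det <- p_detected(fit, tt, cut, param_uncertainty = param_uncertainty,
                        target_species = sp)
      if (fit$status %in% c("ok", "degenerate")) {
        pi <- prediction_interval(fit, tt, level = pi_level,
                                  param_uncertainty = param_uncertainty)
        lo <- pi$pi_low; hi <- pi$pi_high; mu <- pi$mean
      } else {
        lo <- hi <- mu <- NA_real_
      }
      add <- data.frame(mu, lo, hi, det$p_detected, det$flags,
                        stringsAsFactors = FALSE)
      names(add) <- paste(sp, c("mean", "pi_low", "pi_high", "p_detected",
                                "flags"), sep = ".")
      base <- cbind(base, add)
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write and read the per-gene result table
#'
#' Numbers are serialised with 6 significant digits so that re-running
#' with identical inputs produces byte-identical files, and writing then
#' re-reading reproduces the values to printed precision.
#'
#' @param x result data frame from [run_detectability_analysis()].
#' @param path output TSV path.
#' @export
write_result_table <- function(x, path) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = 6)
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = "NA")
}

#' Write a gene-by-species score table
#'
#' @param profiles list of [score_profile] objects sharing a focal
#'   species.
#' @param path output TSV path.
#' @export
write_score_table <- function(profiles, path) {
  sp <- unique(unlist(lapply(profiles, function(p) p$species)))
  m <- matrix(NA_real_, length(profiles), length(sp),
              dimnames = list(vapply(profiles, attr, character(1), "gene_id"),
                              sp))
  for (p in profiles) m[attr(p, "gene_id"), p$species] <- p$score
  df <- data.frame(gene = rownames(m), signif(m, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
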