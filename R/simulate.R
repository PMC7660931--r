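#' A fungal-like 12-taxon distance ladder
#'
#' Default study conditions for the simulators: one focal species plus 11
#' relatives at distances (substitutions/site) spanning the range typical
#' of a yeast-to-distant-fungus comparison - nearest relatives at 0.02
#' and 0.09 and the most distant outgroup at 0.92, with the rest spread
#' between.
#'
#' @return a [species_distances] object with 12 species (`sp00` focal).
#' @export
fungi_like_distances <- function() {
  d <- c(sp00 = 0, sp01 = 0.02, sp02 = 0.09, sp03 = 0.12, sp04 = 0.16,
         sp05 = 0.28, sp06 = 0.40, sp07 = 0.48, sp08 = 0.56, sp09 = 0.64,
         sp10 = 0.78, sp11 = 0.92)
  species_distances(d, "sp00", source = "supplied")
}

#' Simulate score profiles from the decay null model
#'
#' For each gene and species at distance \eqn{t}, draws a bitscore from
#' \eqn{N(a e^{-bt},\, a(1-e^{-bt})e^{-bt})}, left-censored at 0. At
#' \eqn{t = 0} the score is exactly \eqn{a}. `a` and `b` may be vectors
#' (recycled over genes) to emulate a genome's spread of lengths and
#' rates.
#'
#' @param n_genes number of genes.
#' @param a score at distance 0, bits (roughly 2 x protein length).
#' @param b decay rate per substitution/site.
#' @param distances a [species_distances] object; default
#'   [fungi_like_distances()].
#' @param seed optional seed; identical seeds give identical output.
#' @param gene_prefix prefix for generated gene ids.
#' @return named list of [score_profile] objects.
#' @export
simulate_scores <- function(n_genes = 1, a = 300, b = 2,
                            distances = fungi_like_distances(),
                            seed = NULL, gene_prefix = "gene") {
  stopifnot(inherits(distances, "species_distances"), n_genes >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- rep_len(a, n_genes)
  b <- rep_len(b, n_genes)
  sp <- names(distances)
  t <- as.numeric(distances)
  focal <- attr(distances, "focal_species")
  out <- lapply(seq_len(n_genes), function(i) {
    mu <- a[i] * exp(-b[i] * t)
    sdv <- sqrt(pmax(a[i] * (1 - exp(-b[i] * t)) * exp(-b[i] * t), 0))
    s <- pmax(rnorm(length(t), mu, sdv), 0)
    s[t == 0] <- a[i]
    score_profile(sp, t, s, gene_id = sprintf("%s%04d", gene_prefix, i),
                  focal_species = focal)
  })
  setNames(out, vapply(out, attr, character(1), "gene_id"))
}

#' Simulate constant-rate protein evolution on a star topology
#'
#' Draws a random ancestral sequence from the background frequencies and
#' evolves an independent copy toward each species: every site receives a
#' Poisson number of substitution events with mean `rate * t` (times an
#' optional gamma-distributed per-site rate multiplier, shared across
#' species), and each event replaces the residue with a draw from the
#' background frequencies - which may coincide with the current residue,
#' giving the closed-form identity probability
#' \eqn{e^{-rt} + (1 - e^{-rt})\sum_i f_i^2}. The focal species keeps the
#' ancestral sequence, so pairwise focal-species distances equal the
#' input distances. No indels are simulated (the empirical decay rate
#' subsumes them in real data).
#'
#' @param L sequence length, sites.
#' @param distances a [species_distances] object.
#' @param rate substitutions per site per unit distance (default 1, so
#'   distances are in substitutions/site).
#' @param freqs background amino-acid frequencies (20-vector, summing to
#'   1; default uniform).
#' @param gamma_shape optional shape of a mean-1 gamma distribution of
#'   per-site rate multipliers.
#' @param seed optional seed.
#' @return list with elements `sequences` (an [alignment]) and
#'   `distances` (the true input distances).
#' @export
simulate_sequences <- function(L, distances = fungi_like_distances(),
                               rate = 1, freqs = rep(1 / 20, 20),
                               gamma_shape = NULL, seed = NULL) {
  stopifnot(L >= 1, inherits(distances, "species_distances"),
            length(freqs) == 20)
  freqs <- freqs / sum(freqs)
  if (!is.null(seed)) set.seed(seed)
  focal <- attr(distances, "focal_species")
  anc <- sample(.AA20, L, replace = TRUE, prob = freqs)
  mult <- if (is.null(gamma_shape)) rep(1, L)
          else rgamma(L, shape = gamma_shape, rate = gamma_shape)
  rows <- lapply(names(distances), function(sp) {
    t <- distances[[sp]]
    if (t == 0) return(paste(anc, collapse = ""))
    hit <- rpois(L, rate * t * mult) > 0
    s <- anc
    if (any(hit))
      s[hit] <- sample(.AA20, sum(hit), replace = TRUE, prob = freqs)
    paste(s, collapse = "")
  })
  seqs <- alignment(setNames(unlist(rows), names(distances)),
                    locus_id = "simulated")
  list(sequences = seqs, distances = distances)
}

#' Identity-count score profile from simulated sequences
#'
#' Scores each species against the focal species as `lambda` bits per
#' identical position - the score model underlying the decay curve (a
#' similarity score proportional to percent identity).
#'
#' @param sim output of [simulate_sequences()] (or a list with
#'   `sequences` and `distances`).
#' @param lambda bits per identity; default 2, the order of the average
#'   BLOSUM62 diagonal element. Only the relative scale matters.
#' @param gene_id label for the resulting profile.
#' @return a [score_profile].
#' @export
score_identity <- function(sim, lambda = 2, gene_id = "simulated") {
  seqs <- sim$sequences
  distances <- sim$distances
  focal <- attr(distances, "focal_species")
  f <- strsplit(seqs[[focal]], "")[[1]]
  sc <- vapply(names(distances), function(sp)
    lambda * sum(strsplit(seqs[[sp]], "")[[1]] == f), numeric(1))
  score_profile(names(distances), as.numeric(distances), sc,
                gene_id = gene_id, focal_species = focal)
}

#' Simulate-and-refit parameter recovery report
#'
#' Simulates `n_genes` score profiles from known `(a, b)`, refits each
#' with [fit_decay()], and summarises estimation quality: bias, RMSE and
#' median relative error per parameter, plus empirical coverage of
#' nominal Wald confidence intervals. With `two_taxa = TRUE`, each gene
#' is additionally refit using only the focal species and the two
#' closest relatives - the worst-case scenario of a gene confined to a
#' very young lineage - and the report includes the correlation between
#' full-taxa and two-taxa estimates.
#'
#' @param n_genes number of simulated genes.
#' @param a,b true parameters (recycled over genes).
#' @param distances a [species_distances] object.
#' @param noise if `FALSE`, scores lie exactly on the curve (refits must
#'   recover the truth to numerical tolerance).
#' @param two_taxa also fit with only the two closest relatives.
#' @param conf_level nominal level of the Wald intervals (default 0.95).
#' @param seed optional seed; fixed seeds give identical reports.
#' @return object of class `recovery_report`: list with `per_gene` (data
#'   frame) and `summary` (list of bias/rmse/median relative error/
#'   coverage per parameter; `concordance` when `two_taxa`).
#' @export
parameter_recovery <- function(n_genes = 100, a = 300, b = 2,
                               distances = fungi_like_distances(),
                               noise = TRUE, two_taxa = FALSE,
                               conf_level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- rep_len(a, n_genes)
  b <- rep_len(b, n_genes)
  profs <- if (noise) {
    simulate_scores(n_genes, a, b, distances)
  } else {
    t <- as.numeric(distances)
    lapply(seq_len(n_genes), function(i)
      score_profile(names(distances), t, a[i] * exp(-b[i] * t),
                    gene_id = sprintf("gene%04d", i),
                    focal_species = attr(distances, "focal_species")))
  }
  zc <- qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(seq_len(n_genes), function(i) {
    f <- fit_decay(profs[[i]])
    se <- sqrt(pmax(diag(f$cov), 0))
    data.frame(gene_id = f$gene_id, a_true = a[i], b_true = b[i],
               a_hat = f$a, b_hat = f$b, status = f$status,
               covered_a = is.finite(se[1]) &&
                 abs(f$a - a[i]) <= zc * se[1],
               covered_b = is.finite(se[2]) &&
                 abs(f$b - b[i]) <= zc * se[2],
               stringsAsFactors = FALSE)
  })
  pg <- do.call(rbind, rows)
  if (two_taxa) {
    t <- as.numeric(distances)
    keep <- order(t)[1:3]  # focal + two closest relatives
    two <- vapply(profs, function(p) {
      sel <- p$species %in% names(distances)[keep]
      f2 <- fit_decay(p$t[sel], p$score[sel], gene_id = attr(p, "gene_id"))
      c(f2$a, f2$b)
    }, numeric(2))
    pg$a_hat2 <- two[1, ]
    pg$b_hat2 <- two[2, ]
  }
  ok <- pg$status %in% c("ok", "degenerate")
  rel <- function(est, tr) abs(est - tr) / tr
  summ <- list(
    n_ok = sum(ok),
    bias = c(a = mean(pg$a_hat[ok] - pg$a_true[ok]),
             b = mean(pg$b_hat[ok] - pg$b_true[ok])),
    rmse = c(a = sqrt(mean((pg$a_hat[ok] - pg$a_true[ok])^2)),
             b = sqrt(mean((pg$b_hat[ok] - pg$b_true[ok])^2))),
    median_rel_err = c(a = median(rel(pg$a_hat[ok], pg$a_true[ok])),
                       b = median(rel(pg$b_hat[ok], pg$b_true[ok]))),
    coverage = c(a = mean(pg$covered_a[ok]), b = mean(pg$covered_b[ok])),
    conf_level = conf_level)
  if (two_taxa) {
    ok2 <- ok & is.finite(pg$a_hat2) & is.finite(pg$b_hat2)
    summ$concordance <- c(r2_a = cor(pg$a_hat[ok2], pg$a_hat2[ok2])^2,
                          r2_b = cor(pg$b_hat[ok2], pg$b_hat2[ok2])^2)
  }
  structure(list(per_gene = pg, summary = summ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  s <- x$summary
  cat("Parameter recovery over", nrow(x$per_gene), "simulated genes (",
      s$n_ok, "usable fits)\n")
  m <- rbind(bias = s$bias, rmse = s$rmse,
             `median rel. error` = s$median_rel_err,
             `CI coverage` = s$coverage)
  print(round(m, digits))
  if (!is.null(s$concordance))
    cat("full vs two-taxa concordance: r2(a) =",
        format(s$concordance[["r2_a"]], digits = digits),
        " r2(b) =", format(s$concordance[["r2_b"]], digits = digits), "\n")
  invisible(x)
}
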