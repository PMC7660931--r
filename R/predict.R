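#' Predicted mean score and model variance at a distance
#'
#' Under the null model the expected bitscore at evolutionary distance
#' \eqn{t} is \eqn{a e^{-bt}}, with sampling variance
#' \eqn{\sigma^2(t) = a(1-e^{-bt})e^{-bt}} (the binomial scatter of the
#' number of identical positions, expressed in score units). The variance
#' is 0 at \eqn{t = 0}, tends to 0 as \eqn{t \to \infty}, and peaks at
#' \eqn{a/4} where \eqn{e^{-bt} = 1/2}.
#'
#' @param fit a `decay_fit` with status `ok` or `degenerate`.
#' @param t non-negative distance(s), substitutions/site.
#' @return numeric vector: bits ([predict_mean]) or bits^2
#'   ([predict_variance]).
#' @export
predict_mean <- function(fit, t) {
  .check_usable(fit, allow = c("ok", "degenerate"))
  .check_t(t)
  fit$a * exp(-fit$b * t)
}

#' @rdname predict_mean
#' @export
predict_variance <- function(fit, t) {
  .check_usable(fit, allow = c("ok", "degenerate"))
  .check_t(t)
  pmax(fit$a * (1 - exp(-fit$b * t)) * exp(-fit$b * t), 0)
}

.check_t <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("distances must be finite and non-negative")
  invisible(t)
}

# total predictive variance: model variance plus, optionally, parameter
# uncertainty propagated from the fit covariance by the delta method
# (gradient of a*exp(-b*t) w.r.t. (a, b)).
.total_variance <- function(fit, t, param_uncertainty = TRUE) {
  v <- predict_variance(fit, t)
  if (param_uncertainty && all(is.finite(fit$cov))) {
    e <- exp(-fit$b * t)
    g1 <- e
    g2 <- -fit$a * t * e
    vp <- g1^2 * fit$cov[1, 1] + 2 * g1 * g2 * fit$cov[1, 2] +
      g2^2 * fit$cov[2, 2]
    v <- v + pmax(vp, 0)
  }
  v
}

#' Prediction interval for a future homolog's score
#'
#' Normal-quantile interval around the predicted mean. By default the
#' width combines the model variance with parameter uncertainty
#' propagated from the fit covariance by the delta method; set
#' `param_uncertainty = FALSE` for a model-variance-only interval. The
#' lower bound is clamped at 0 (bitscores cannot be negative).
#'
#' @param fit a `decay_fit` (status `ok` or `degenerate`).
#' @param t non-negative distance(s).
#' @param level coverage level in (0, 1); default 0.99.
#' @param param_uncertainty include delta-method parameter variance.
#' @return data frame with columns `t`, `mean`, `variance` (total),
#'   `pi_low`, `pi_high`; attribute `level`.
#' @export
prediction_interval <- function(fit, t, level = 0.99,
                                param_uncertainty = TRUE) {
  stopifnot(length(level) == 1, level > 0, level < 1)
  mu <- predict_mean(fit, t)
  v <- .total_variance(fit, t, param_uncertainty)
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(t = t, mean = mu, variance = v,
                    pi_low = pmax(mu - z * sqrt(v), 0),
                    pi_high = mu + z * sqrt(v))
  attr(out, "level") <- level
  out
}

#' Bitscore detectability threshold from an E-value
#'
#' The expected number of chance hits at bitscore \eqn{S} in a search of
#' a query of \eqn{m} residues against a database of \eqn{n} residues is
#' \eqn{E = mn\,2^{-S}}, so the score needed to reach a given E-value is
#' \eqn{S_{min} = \log_2(mn/E)}. No effective-length correction is
#' applied (BLAST's internal edge adjustment is search-specific); pass an
#' explicit cutoff to downstream functions if exact agreement with a
#' particular search is needed.
#'
#' @param evalue significance threshold (e.g. 0.001); must be positive.
#' @param m query length, residues.
#' @param n database length, residues.
#' @return object of class `detection_threshold` with elements `evalue`,
#'   `m`, `n`, `bits`.
#' @examples
#' bitscore_threshold(0.001, m = 400, n = 3e6)
#' @export
bitscore_threshold <- function(evalue, m, n) {
  stopifnot(length(evalue) == 1, length(m) == 1, length(n) == 1)
  if (!is.finite(evalue) || evalue <= 0) stop("evalue must be positive")
  if (m < 1 || n < 1) stop("m and n must be at least 1 residue")
  structure(list(evalue = evalue, m = m, n = n,
                 bits = log2(m) + log2(n) - log2(evalue)),
            class = "detection_threshold")
}

#' @export
print.detection_threshold <- function(x, ...) {
  cat("Detectability threshold:", format(x$bits, digits = 5), "bits",
      "(E <", format(x$evalue), ", m =", format(x$m), ", n =",
      format(x$n), ")\n")
  invisible(x)
}

.threshold_bits <- function(threshold) {
  if (inherits(threshold, "detection_threshold")) return(threshold$bits)
  if (is.numeric(threshold) && length(threshold) == 1) return(threshold)
  stop("'threshold' must be a detection_threshold or a single bitscore")
}

#' Probability that a homolog would be detected at a distance
#'
#' The central quantity of the null-model test: the probability mass of
#' the predicted score distribution above the detectability threshold at
#' distance \eqn{t}, P(detected | null model, t). The score distribution
#' is normal with the extrapolated mean and the total variance of
#' [prediction_interval()]; it is not truncated at 0, but probabilities
#' are clamped to \[0, 1\]. A gene with a small P(detected) at the
#' outgroup distance is well explained by homology detection failure; a
#' gene with P(detected) near 1 is not, making it a candidate for genuine
#' novelty.
#'
#' Flag semantics: `extrapolation_beyond_data` when `t` exceeds the
#' largest fitted distance; `model_violation` (score not decaying) forces
#' a conservative `p_detected = 1`; `insufficient_data` yields `NA`.
#' With zero total variance the normal collapses to a step function.
#'
#' @param fit a `decay_fit` (any status; flags propagate).
#' @param t non-negative distance(s) of the target species.
#' @param threshold a [bitscore_threshold()] object or a bitscore.
#' @param param_uncertainty include delta-method parameter variance in
#'   the score distribution (default TRUE).
#' @param target_species optional character vector naming the targets.
#' @return data frame with columns `gene_id`, `target_species`, `t`,
#'   `threshold_bits`, `mean`, `sd`, `p_detected`, `flags`
#'   (comma-separated, `""` when clean).
#' @examples
#' pr <- score_profile(c("A", "B", "C"), c(0, 0.1, 0.4),
#'                     300 * exp(-2 * c(0, 0.1, 0.4)), "g1", "A")
#' p_detected(fit_decay(pr), t = 1.2, threshold = 37)
#' @export
p_detected <- function(fit, t, threshold, param_uncertainty = TRUE,
                       target_species = NA_character_) {
  stopifnot(inherits(fit, "decay_fit"))
  .check_t(t)
  cutoff <- .threshold_bits(threshold)
  k <- length(t)
  target_species <- rep_len(target_species, k)
  flags <- vector("list", k)

  if (fit$status == "insufficient_data") {
    return(data.frame(gene_id = fit$gene_id, target_species = target_species,
                      t = t, threshold_bits = cutoff, mean = NA_real_,
                      sd = NA_real_, p_detected = NA_real_,
                      flags = "insufficient_data",
                      stringsAsFactors = FALSE))
  }
  if (fit$status == "model_violation") {
    return(data.frame(gene_id = fit$gene_id, target_species = target_species,
                      t = t, threshold_bits = cutoff, mean = NA_real_,
                      sd = NA_real_, p_detected = 1,
                      flags = "model_violation",
                      stringsAsFactors = FALSE))
  }

  mu <- predict_mean(fit, t)
  v <- .total_variance(fit, t, param_uncertainty)
  s <- sqrt(v)
  p <- ifelse(s > 0, 1 - pnorm((cutoff - mu) / s),
              as.numeric(mu >= cutoff))
  p <- pmin(pmax(p, 0), 1)

  t_max <- max(fit$data$t)
  fl <- ifelse(t > t_max, "extrapolation_beyond_data", "")
  data.frame(gene_id = fit$gene_id, target_species = target_species,
             t = t, threshold_bits = cutoff, mean = mu, sd = s,
             p_detected = p, flags = fl, stringsAsFactors = FALSE)
}

#' Z-score of an observed score against the model prediction
#'
#' Expresses the gap between an observed bitscore and the model's
#' expectation as a multiple of the predicted standard deviation,
#' \eqn{z = (S_{obs} - ae^{-bt})/\sqrt{a(1-e^{-bt})e^{-bt}}} (model
#' variance only - the scatter the model itself predicts). Used as a
#' genome-wide diagnostic of the variance model: if the variance is
#' right, Z-scores are roughly standard normal.
#'
#' @param fit a `decay_fit` (status `ok` or `degenerate`).
#' @param t distance(s) of the observation(s).
#' @param observed observed bitscore(s).
#' @param species_id optional species label(s).
#' @return data frame with `gene_id`, `species_id`, `t`, `observed`,
#'   `expected`, `sd`, `z` (`NA` with a flag where the model variance is
#'   0, i.e. at `t = 0` or `b = 0`).
#' @export
zscore <- function(fit, t, observed, species_id = NA_character_) {
  .check_usable(fit, allow = c("ok", "degenerate"))
  .check_t(t)
  stopifnot(length(observed) == length(t))
  mu <- predict_mean(fit, t)
  v <- predict_variance(fit, t)
  z <- ifelse(v > 0, (observed - mu) / sqrt(v), NA_real_)
  data.frame(gene_id = fit$gene_id,
             species_id = rep_len(species_id, length(t)),
             t = t, observed = observed, expected = mu, sd = sqrt(v),
             z = z,
             flags = ifelse(v > 0, "", "zero_variance"),
             stringsAsFactors = FALSE)
}

#' Predict method for decay fits
#'
#' Convenience wrapper returning the mean and, optionally, the
#' prediction interval at new distances.
#'
#' @param object a `decay_fit`.
#' @param t distances; defaults to the fitted ones.
#' @param interval `"none"` or `"prediction"`.
#' @param level interval coverage.
#' @param param_uncertainty include parameter uncertainty in the interval.
#' @param ... unused.
#' @return numeric vector of means (`interval = "none"`) or the data
#'   frame of [prediction_interval()].
#' @export
predict.decay_fit <- function(object, t = object$data$t,
                              interval = c("none", "prediction"),
                              level = 0.99, param_uncertainty = TRUE, ...) {
  interval <- match.arg(interval)
  if (interval == "none") return(predict_mean(object, t))
  prediction_interval(object, t, level = level,
                      param_uncertainty = param_uncertainty)
}
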