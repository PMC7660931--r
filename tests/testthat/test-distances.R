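test_that("alignment blocks validate and concatenate", {
  b1 <- alignment(c(A = "ACDE", B = "ACDF", C = "AC-E"), "l1")
  b2 <- alignment(c(A = "GHIKLM", B = "GHIKLM", C = "GXIKLM"), "l2")
  cc <- concat_alignments(list(b1, b2))
  expect_equal(nchar(cc[["A"]]), 10)
  expect_equal(cc[["C"]], "AC-EGXIKLM")

  one <- concat_alignments(list(b1))
  expect_equal(unname(one[names(b1)]), unname(b1[names(b1)]))

  b3 <- alignment(c(A = "WW", B = "WW"), "l3")  # C missing
  expect_error(concat_alignments(list(b1, b3)), "missing from block 'l3'")
  expect_error(alignment(c(A = "ACD", B = "AC")), "unequal")
  expect_error(alignment(c(A = "AJZ", B = "ACD")), "invalid characters")
})

test_that("poisson distance is the analytic -ln(1 - p)", {
  aln <- alignment(c(A = "ACDEFGHIKL", B = "ACDEFGHIKL"))
  expect_equal(pairwise_distance(aln, "A", "B", model = "poisson"), 0)

  # exactly half of the comparable columns differ
  aln2 <- alignment(c(A = "AAAACCCC", B = "AAAADDDD"))
  expect_equal(pairwise_distance(aln2, "A", "B", model = "poisson"), log(2))

  # strictly increasing in the difference fraction
  d <- vapply(1:7, function(k) {
    x <- rep("A", 8); y <- rep("A", 8); y[seq_len(k)] <- "C"
    pairwise_distance(alignment(c(A = paste(x, collapse = ""),
                                  B = paste(y, collapse = ""))),
                      "A", "B", model = "poisson")
  }, numeric(1))
  expect_true(all(diff(d) > 0))

  # saturation is capped with a warning
  sat <- alignment(c(A = "AAAA", B = "CCCC"))
  expect_warning(ds <- pairwise_distance(sat, "A", "B", model = "poisson"),
                 "saturated")
  expect_equal(ds, 20)

  # gap/ambiguity columns are excluded pairwise
  g <- alignment(c(A = "AC-EX", B = "ADPEF"))
  # comparable columns: 1 (A/A), 2 (C/D), 4 (E/E) -> p = 1/3
  expect_equal(pairwise_distance(g, "A", "B", model = "poisson"),
               -log(1 - 1 / 3))
  expect_error(pairwise_distance(alignment(c(A = "--", B = "AC")), "A", "B",
                                 model = "poisson"), "no comparable")
})

test_that("ML distance agrees with a grid-search likelihood oracle", {
  jtt <- jtt_params()
  set.seed(31)
  for (d_true in c(0.15, 0.7, 1.6)) {
    pair <- sim_jtt_pair(400, d_true, jtt$Q, jtt$bf)
    aln <- alignment(c(A = paste(AA20[pair$x], collapse = ""),
                       B = paste(AA20[pair$y], collapse = "")))
    d_hat <- pairwise_distance(aln, "A", "B", model = "ml_empirical")
    d_oracle <- grid_ml_oracle(pair$x, pair$y, jtt$Q, jtt$bf)
    expect_equal(d_hat, d_oracle, tolerance = 1e-3)
    # cross-check against an independent ML implementation
    pd <- phangorn::phyDat(rbind(A = AA20[pair$x], B = AA20[pair$y]),
                           type = "AA")
    expect_equal(d_hat, as.numeric(phangorn::dist.ml(pd, model = "JTT")),
                 tolerance = 1e-3)
  }
  # identical sequences have distance zero; distances are symmetric
  same <- alignment(c(A = "ACDEFGHIKLMNPQRSTVWY", B = "ACDEFGHIKLMNPQRSTVWY"))
  expect_equal(pairwise_distance(same, "A", "B"), 0)
  pair <- sim_jtt_pair(200, 0.5, jtt$Q, jtt$bf)
  aln <- alignment(c(A = paste(AA20[pair$x], collapse = ""),
                     B = paste(AA20[pair$y], collapse = "")))
  expect_equal(pairwise_distance(aln, "A", "B"),
               pairwise_distance(aln, "B", "A"))
})

test_that("uniform-exchangeability ML matches the analytic 20-state correction", {
  set.seed(12)
  sim <- simulate_sequences(L = 2000,
                            distances = species_distances(
                              c(F = 0, S = 0.6), "F"),
                            rate = 1, seed = 12)
  aln <- sim$sequences
  d_ml <- pairwise_distance(aln, "F", "S", model = "ml_empirical",
                            submodel = "uniform")
  x <- strsplit(aln[["F"]], "")[[1]]
  y <- strsplit(aln[["S"]], "")[[1]]
  p <- mean(x != y)
  d_analytic <- -(19 / 20) * log(1 - (20 / 19) * p)
  expect_equal(d_ml, d_analytic, tolerance = 0.01)
})

test_that("distances recover the truth on simulated sequences", {
  dist_true <- species_distances(c(F = 0, A = 0.1, B = 0.4, C = 0.9), "F")
  sim <- simulate_sequences(L = 10000, distances = dist_true, rate = 1,
                            seed = 77)
  got <- distances_from_focal(sim$sequences, "F", model = "ml_empirical",
                              submodel = "uniform")
  for (sp in c("A", "B", "C")) {
    t_ev <- dist_true[[sp]]
    # under replacement-from-frequencies, the expected number of
    # observable state changes per site is (19/20) * rate * t
    d_exp <- (19 / 20) * t_ev
    p <- (19 / 20) * (1 - exp(-t_ev))
    se <- sqrt(p * (1 - p) / 10000) / (1 - (20 / 19) * p)
    expect_lt(abs(got[[sp]] - d_exp), 3 * se)
  }
  expect_equal(got[["F"]], 0)
})

test_that("distances are stable across marker-gene subsets", {
  dist_true <- fungi_like_distances()
  set.seed(55)
  loci <- lapply(1:30, function(i)
    simulate_sequences(L = 150, distances = dist_true, rate = 1)$sequences)
  all_cc <- concat_alignments(loci)
  sub_cc <- concat_alignments(loci[sample(30, 15)])
  d_all <- distances_from_focal(all_cc, "sp00", submodel = "uniform")
  d_sub <- distances_from_focal(sub_cc, "sp00", submodel = "uniform")
  sp <- setdiff(names(dist_true), "sp00")
  expect_gt(cor(as.numeric(d_all[sp]), as.numeric(d_sub[sp]))^2, 0.95)

  # permuting block order leaves distances unchanged
  d_perm <- distances_from_focal(concat_alignments(rev(loci)), "sp00",
                                 submodel = "uniform")
  expect_equal(as.numeric(d_perm[sp]), as.numeric(d_all[sp]))
})

test_that("gap density counts gaps per column per sequence", {
  expect_equal(gap_density(alignment(c(A = "ACDE", B = "ACDE"))), 0)
  expect_equal(gap_density(alignment(c(A = "AC-E", B = "A-DE"))), 0.25)
  set.seed(3)
  rows <- vapply(1:5, function(i)
    paste(sample(c(AA20, "-"), 40, replace = TRUE), collapse = ""),
    character(1))
  names(rows) <- paste0("s", 1:5)
  aln <- alignment(rows)
  direct <- sum(vapply(rows, function(s)
    sum(strsplit(s, "")[[1]] == "-"), numeric(1))) / (40 * 5)
  expect_equal(gap_density(aln), direct)
})

test_that("alignment FASTA round-trips through the reader", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">spA some description", "ACDE-GHIK",
               ">spB", "ACDEFGHIK"), path)
  aln <- read_alignment(path)
  expect_s3_class(aln, "aa_alignment")
  expect_equal(names(aln), c("spA", "spB"))
  expect_equal(aln[["spA"]], "ACDE-GHIK")
})
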