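test_that("tabular hit parsing is typed, strict, and line-aware", {
  empty <- tempfile(); writeLines(character(0), empty)
  tab <- read_blast_tab(empty)
  expect_s3_class(tab, "hit_table")
  expect_equal(nrow(tab), 0)

  p <- write_hits(data.frame(qseqid = c("q1", "q1", "q2"),
                             sseqid = c("s1", "s2", "s1"),
                             evalue = c(1e-10, 1e-3, 0.5),
                             bitscore = c(120, 45, 20)))
  tab <- read_blast_tab(p)
  expect_equal(nrow(tab), 3)
  expect_type(tab$evalue, "double")
  expect_equal(tab$bitscore, c(120, 45, 20))

  # comment lines are skipped; malformed lines are named by line number
  bad <- tempfile()
  writeLines(c("# BLASTP 2.x", readLines(p)[1], "q9\ts9\tgarbage"), bad)
  expect_error(read_blast_tab(bad), "line\\(s\\) 3")
  expect_warning(tab2 <- read_blast_tab(bad, strict = FALSE), "line\\(s\\) 3")
  expect_equal(nrow(tab2), 1)

  nonnum <- tempfile()
  l <- strsplit(readLines(p)[1], "\t")[[1]]; l[11] <- "abc"
  writeLines(paste(l, collapse = "\t"), nonnum)
  expect_error(read_blast_tab(nonnum), "line\\(s\\) 1")
})

test_that("best hits use the E-value with deterministic tie-breaking", {
  tab <- hit_tab(q = c("q1"), s = c("s1"), e = 1e-5, b = 50)
  expect_equal(best_hits(tab)$sseqid, "s1")

  # equal E-values: larger bitscore wins
  tie <- hit_tab(q = c("q1", "q1"), s = c("sA", "sB"),
                 e = c(1e-6, 1e-6), b = c(40, 50))
  expect_equal(best_hits(tie)$sseqid, "sB")

  # equal E-value and bitscore: lexicographically smaller subject
  tie2 <- hit_tab(q = c("q1", "q1"), s = c("sB", "sA"),
                  e = c(1e-6, 1e-6), b = c(40, 40))
  expect_equal(best_hits(tie2)$sseqid, "sA")

  # hits at or above the cutoff are ignored entirely
  over <- hit_tab(q = "q1", s = "s1", e = 0.001, b = 30)
  expect_equal(nrow(best_hits(over, evalue_max = 0.001)), 0)

  # random table agrees with an exhaustive per-query scan
  set.seed(19)
  n <- 300
  tab <- hit_tab(q = sample(paste0("q", 1:30), n, TRUE),
                 s = sample(paste0("s", 1:40), n, TRUE),
                 e = 10^runif(n, -20, 0), b = round(runif(n, 20, 300)))
  got <- best_hits(tab, 0.001)
  for (q in unique(tab$qseqid)) {
    h <- tab[tab$qseqid == q & tab$evalue < 0.001, ]
    if (!nrow(h)) {
      expect_false(q %in% got$qseqid)
    } else {
      h <- h[order(h$evalue, -h$bitscore, h$sseqid), ]
      expect_equal(got$sseqid[got$qseqid == q], h$sseqid[1])
    }
  }
})

test_that("reciprocal best hits form a matching and respect direction", {
  ab <- hit_tab(q = c("a1", "a2"), s = c("b1", "b2"),
                e = c(1e-10, 1e-8), b = c(100, 80), qp = "A", sp = "B")
  ba <- hit_tab(q = c("b1", "b2"), s = c("a1", "a2"),
                e = c(1e-10, 1e-8), b = c(100, 80), qp = "B", sp = "A")
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(rbh$gene_a, c("a1", "a2"))
  expect_equal(rbh$gene_b, c("b1", "b2"))

  # a1's best is b1, but b1 prefers a9: no pair for a1
  ba2 <- hit_tab(q = "b1", s = "a9", e = 1e-12, b = 150, qp = "B", sp = "A")
  expect_equal(nrow(reciprocal_best_hits(ab, ba2)), 0)

  # swapping the two searches yields the same pairs reversed
  rev <- reciprocal_best_hits(ba, ab)
  expect_equal(rev$gene_a, rbh$gene_b)
  expect_equal(rev$gene_b, rbh$gene_a)

  # direction bookkeeping is enforced
  expect_error(reciprocal_best_hits(ab, ab), "reciprocal")

  # a pair with several HSP lines contributes its best line's score
  ab3 <- hit_tab(q = c("a1", "a1"), s = c("b1", "b1"),
                 e = c(1e-10, 1e-9), b = c(60, 90))
  ba3 <- hit_tab(q = "b1", s = "a1", e = 1e-10, b = 95)
  expect_equal(reciprocal_best_hits(ab3, ba3)$bitscore, 90)
})

test_that("planted one-to-one orthologs are recovered amid decoy paralogs", {
  set.seed(4)
  genes <- paste0("g", 1:25)
  ab <- data.frame(qseqid = genes, sseqid = paste0("h", 1:25),
                   evalue = 10^runif(25, -50, -10),
                   bitscore = round(runif(25, 100, 400)))
  # decoys: strictly worse E-values to shuffled partners
  decoy_ab <- data.frame(qseqid = sample(genes, 40, TRUE),
                         sseqid = paste0("h", sample(25, 40, TRUE)),
                         evalue = 10^runif(40, -8, -4),
                         bitscore = round(runif(40, 30, 90)))
  ba <- data.frame(qseqid = ab$sseqid, sseqid = ab$qseqid,
                   evalue = ab$evalue, bitscore = ab$bitscore)
  decoy_ba <- data.frame(qseqid = decoy_ab$sseqid, sseqid = decoy_ab$qseqid,
                         evalue = decoy_ab$evalue, bitscore = decoy_ab$bitscore)
  tab_ab <- read_blast_tab(write_hits(rbind(ab, decoy_ab)), "A", "B")
  tab_ba <- read_blast_tab(write_hits(rbind(ba, decoy_ba)), "B", "A")
  rbh <- reciprocal_best_hits(tab_ab, tab_ba)
  expect_equal(nrow(rbh), 25)
  expect_equal(rbh$gene_b, paste0("h", sub("g", "", rbh$gene_a)))
  # partial matching: no gene repeats on either side
  expect_false(anyDuplicated(rbh$gene_a) > 0)
  expect_false(anyDuplicated(rbh$gene_b) > 0)
})

test_that("lineage specificity means no sub-threshold hit in any outgroup", {
  genes <- c("g1", "g2", "g3")
  out1 <- hit_tab(q = "g2", s = "x1", e = 1e-6, b = 60)   # real outgroup hit
  out2 <- hit_tab(q = "g3", s = "y1", e = 0.5, b = 22)    # insignificant
  tabs <- list(out_sp1 = out1, out_sp2 = out2)
  ls <- find_lineage_specific(genes, tabs, lineage = c("in_sp1", "in_sp2"))
  expect_equal(ls, c("g1", "g3"))

  # monotone: raising the cutoff can only shrink the set
  for (e_hi in c(0.01, 0.1, 1)) {
    ls_hi <- find_lineage_specific(genes, tabs, c("in_sp1", "in_sp2"),
                                   evalue_max = e_hi)
    expect_true(all(ls_hi %in% ls))
  }
  expect_error(find_lineage_specific(genes, tabs, lineage = c("out_sp1")),
               "also given as outgroups")
})

test_that("score profiles assemble from orthology with eligibility flags", {
  dists <- species_distances(c(focal = 0, s1 = 0.1, s2 = 0.3, s3 = 0.7),
                             "focal")
  orth <- data.frame(gene_id = c("gA", "gA", "gB"),
                     species_id = c("s1", "s2", "s1"),
                     ortholog_id = c("o1", "o2", "o3"),
                     bitscore = c(90, 60, 40), stringsAsFactors = FALSE)
  selfs <- c(gA = 120, gB = 55, gC = 80)
  profs <- build_score_profiles(orth, dists, selfs)
  expect_equal(length(profs), 3)
  expect_equal(nrow(profs$gA), 3)  # self + 2 orthologs: eligible
  expect_equal(fit_decay(profs$gA)$status, "ok")
  expect_equal(fit_decay(profs$gB)$status, "insufficient_data")
  expect_equal(fit_decay(profs$gC)$status, "insufficient_data")

  # counting oracle: eligible-profile count equals direct enumeration
  eligible <- sum(table(orth$gene_id)[names(selfs)] >= 2, na.rm = TRUE)
  n_ok <- sum(vapply(profs, function(p) nrow(p) >= 3, logical(1)))
  expect_equal(n_ok, eligible)

  expect_error(build_score_profiles(
    data.frame(gene_id = "gA", species_id = "unknown", ortholog_id = "o",
               bitscore = 10), dists, selfs), "without a distance")
})
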