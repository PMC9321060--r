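# ROC/AUC, detection matrices, resampling stability, GSZ correlation
# clustering and PAT assignment.

test_that("AUC equals exhaustive pair counting, with ties counted 1/2", {
  pair_auc <- function(scores, labels, positive) {
    pos <- scores[labels == positive]
    neg <- scores[labels != positive]
    total <- 0
    for (p in pos) for (n in neg)
      total <- total + (p > n) + 0.5 * (p == n)
    total / (length(pos) * length(neg))
  }
  # worked instance: positives {0.9, 0.4}, negatives {0.5, 0.1}
  r <- roc(c(0.9, 0.4, 0.5, 0.1), c("p", "p", "n", "n"), positive = "p")
  expect_equal(r$auc, 3 / 4)

  set.seed(8)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    labels <- c("p", "n", sample(c("p", "n"), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)           # coarse rounding forces ties
    r <- roc(scores, labels, positive = "p")
    expect_equal(r$auc, pair_auc(scores, labels, "p"))
    # curve endpoints and monotonicity
    expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
    expect_equal(utils::tail(r$tpr, 1), 1)
    expect_equal(utils::tail(r$fpr, 1), 1)
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  }
  expect_equal(roc(c(3, 4, 1, 2), c("p", "p", "n", "n"), "p")$auc, 1)
  expect_equal(roc(rep(1, 6), rep(c("p", "n"), 3), "p")$auc, 0.5)
  expect_error(roc(1:3, rep("p", 3), "p"), "both classes")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(40)
  labels <- sample(c("p", "n"), 40, replace = TRUE, prob = c(0.4, 0.6))
  ours <- roc(scores, labels, positive = "p")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref)
})

test_that("signature evaluation is invariant to sample and gene order", {
  pl <- small_pipeline()
  E <- pl$expression
  labs <- pl$labels
  sig <- signature("modA", truth_module_genes(pl$truth)[["A"]][1:15])
  base <- evaluate_signatures(E, list(sig), labs, "X", "Y")
  perm <- expression_matrix(
    E$values[sample(nrow(E$values)), sample(ncol(E$values))])
  expect_equal(evaluate_signatures(perm, list(sig), labs, "X", "Y")$auc,
               base$auc)
  # unmatched signatures are flagged, not dropped
  tab <- evaluate_signatures(E, list(sig, signature("none", "zzz")),
                             labs, "X", "Y")
  expect_identical(tab$flagged, c(FALSE, TRUE))
  expect_true(is.na(tab$auc[2]))

  # noise-free planted module classifies its subtype perfectly
  act0 <- matrix(c(1, -1, 0, 1), 2, 2,
                 dimnames = list(c("X", "Y"), c("A", "B")))
  ch0 <- generate_cohort(cohort_spec(
    strata_counts = c(X = 8L, Y = 8L), activation = act0,
    module_sizes = c(A = 20L, B = 20L), sigma_act = 0, sigma_eps = 0,
    background_genes = 100L, seed = 2))
  E0 <- preprocess(ch0$expression)
  sig0 <- signature("A", truth_module_genes(ch0$truth)[["A"]])
  expect_equal(evaluate_signatures(E0, list(sig0), ch0$truth$labels,
                                   "X", "Y")$auc, 1)
})

test_that("joint detection is a Jaccard over detected samples", {
  prof <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1), c = c(1, 1, 1, -1))
  jd <- joint_detection(prof)
  expect_equal(unname(diag(jd)), rep(1, 3))
  expect_equal(unname(jd["a", "b"]), 1 / 3)
  disjoint <- cbind(a = c(1, -1), b = c(-1, 1))
  expect_equal(unname(joint_detection(disjoint)["a", "b"]), 0)

  sigs <- list(signature("s1", c("g1", "g2", "g3")),
               signature("s2", c("g2", "g3", "g4")))
  ov <- gene_overlap(sigs)
  expect_identical(unname(diag(ov)), c(3L, 3L))
  expect_identical(unname(ov["s1", "s2"]), 2L)
})

test_that("subtype detection rates behave like the planted activation", {
  pl <- small_pipeline()
  sigs <- make_reference_signatures(
    pl$truth, sizes = c(x_up = 20L), sources = c(x_up = "A"),
    decoy_fraction = 0.1, seed = 2)
  prof <- gsz(pl$expression, sigs$x_up)
  dr <- detection_rate(prof, pl$labels,
                       list(X = "X", Y = "Y"))
  expect_equal(unname(dr["X"]), 1)
  expect_lt(unname(dr["Y"]), 0.1)
})

test_that("resampling stability is seeded and converges to the full set", {
  pl <- small_pipeline()
  genes <- truth_module_genes(pl$truth)[["A"]]
  full <- evaluate_signatures(pl$expression, list(signature("A", genes)),
                              pl$labels, "X", "Y")$auc
  rs <- resample_stability(genes, pl$expression, pl$labels, "X", "Y",
                           fractions = c(0.2, 1), reps = 10, seed = 9)
  expect_true(all(rs$auc["1", ] == full))
  expect_lt(abs(rs$summary$median[rs$summary$fraction == 0.2] - full), 0.02)
  rs2 <- resample_stability(genes, pl$expression, pl$labels, "X", "Y",
                            fractions = c(0.2, 1), reps = 10, seed = 9)
  expect_identical(rs$auc, rs2$auc)
  expect_error(resample_stability(genes[1:4], pl$expression, pl$labels,
                                  "X", "Y", fractions = 0.2, reps = 2),
               "subset size")
})

test_that("GSZ profile correlations recover the planted two-cluster split", {
  pl <- small_pipeline()
  sigs <- make_reference_signatures(
    pl$truth,
    sizes = c(x1_up = 15L, x2_up = 15L, y1_up = 15L, y2_up = 15L),
    sources = c(x1_up = "A", x2_up = "A", y1_up = "B", y2_up = "B"),
    decoy_fraction = 0.1, seed = 4)
  prof <- gsz_matrix(pl$expression, sigs)
  cc <- gsz_correlation_clusters(prof)
  expect_equal(unname(diag(cc$correlation)), rep(1, 4))
  expect_lt(cc$correlation["x1_up", "y1_up"], 0)
  expect_identical(cc$clusters[["x1_up"]], cc$clusters[["x2_up"]])
  expect_identical(cc$clusters[["y1_up"]], cc$clusters[["y2_up"]])
  expect_false(cc$clusters[["x1_up"]] == cc$clusters[["y1_up"]])
})

test_that("PAT labels follow the activation rules and their invariances", {
  pl <- small_pipeline()
  P <- pl$portraits
  ss <- pl$spots
  pats <- pat_assign(P, ss, q = 0.9)
  expect_identical(names(pats$labels), colnames(P))

  # all-negative portrait gets the empty label
  neg <- matrix(-abs(P[, 1]) - 1, ncol = 1,
                dimnames = list(NULL, "neg"))
  expect_identical(unname(pat_assign(neg, ss, q = 0.9)$labels), "∅")

  # scale invariance and monotone sparsification in q
  expect_identical(pat_assign(P * 7, ss, q = 0.9)$labels, pats$labels)
  tighter <- pat_assign(P, ss, q = 0.95)$labels
  for (s in names(pats$labels)) {
    a <- strsplit(pats$labels[[s]], "")[[1]]
    b <- strsplit(tighter[[s]], "")[[1]]
    expect_true(all(setdiff(b, "∅") %in% a))
  }

  # letters are sorted alphabetically
  multi <- pats$labels[nchar(pats$labels) > 1 & pats$labels != "∅"]
  if (length(multi)) {
    chars <- strsplit(multi[[1]], "")[[1]]
    expect_identical(chars, sort(chars))
  }
})

test_that("subtype concentration differs between focused and mixed groups", {
  # X-like samples concentrate in one dominant PAT; a stratum built as a
  # mixture spreads over more groups
  pl <- small_pipeline()
  pats <- pat_assign(pl$portraits, pl$spots, q = 0.9)
  x_tab <- table(pats$labels[names(pl$labels)[pl$labels == "X"]])
  expect_gte(max(x_tab) / sum(x_tab), 0.6)
})

test_that("literature-style and spot classifiers perform nearly equally", {
  pl <- default_run(1)
  con <- mmml_contrasts()
  sigs <- make_reference_signatures(pl$truth, seed = 1)
  spotB <- matched_spot_signature(pl, "B")
  tab <- evaluate_signatures(
    pl$expression,
    c(sigs[c("hummel_BL_up", "sha_BL_up", "masque_BL_up")], list(spotB)),
    pl$labels, con$BL, con$DLBCL)
  expect_lt(max(tab$auc) - min(tab$auc), 0.02)

  # the proliferation module D is less specific than B for BL-vs-DLBCL:
  # it also flags DLBCL samples as detected (GSZ > 0)
  mg <- truth_module_genes(pl$truth)
  detD <- detection_rate(gsz(pl$expression, signature("modD", mg$D)),
                         pl$labels, list(DLBCL = con$DLBCL))
  detB <- detection_rate(gsz(pl$expression, signature("modB", mg$B)),
                         pl$labels, list(DLBCL = con$DLBCL))
  expect_gt(detD[["DLBCL"]], detB[["DLBCL"]])

  # GSZ-profile correlation clustering splits the signature families by
  # their dark-zone vs light-zone resemblance
  fam <- sigs[c("hummel_BL_up", "masque_GCB_up", "ennishi_DHL_up",
                "hummel_DLBCL_up", "masque_ABC_up")]
  cc <- gsz_correlation_clusters(gsz_matrix(pl$expression, fam))
  cl <- cc$clusters
  expect_identical(cl[["hummel_BL_up"]], cl[["masque_GCB_up"]])
  expect_identical(cl[["hummel_BL_up"]], cl[["ennishi_DHL_up"]])
  expect_identical(cl[["hummel_DLBCL_up"]], cl[["masque_ABC_up"]])
  expect_false(cl[["hummel_BL_up"]] == cl[["hummel_DLBCL_up"]])
})

test_that("PATs concentrate BL but spread DLBCL over several groups", {
  pl <- default_run(1)
  con <- mmml_contrasts()
  pats <- pat_assign(pl$portraits, pl$spots)
  bl <- table(pats$labels[names(pl$labels)[pl$labels %in% con$BL]])
  dlbcl <- table(pats$labels[names(pl$labels)[pl$labels %in% con$DLBCL]])
  expect_gte(max(bl) / sum(bl), 0.5)
  expect_gte(length(dlbcl), 3)
})
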