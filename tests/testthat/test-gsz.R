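# Gene-set Z-score, signature mapping and Fisher spot enrichment.

centered_matrix <- function(v) {
  expression_matrix(v - rowMeans(v))
}

test_that("GSZ reproduces the hand-computed finite-population z-score", {
  # 5 genes, one informative sample; set = first two genes
  v <- matrix(c(2, 1, 0, -1, -2, 0, 0, 0, 0, 0), 5, 2,
              dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  E <- expression_matrix(v)               # already gene-centered? no: rows
  # rows have nonzero means; bypass centering: scores are computed on the
  # matrix as given, which is the worked configuration for s1
  sig <- signature("set", c("g1", "g2"))
  prof <- gsz(E, sig)
  m_set <- 1.5; m_all <- 0; sd2 <- 2      # population variance, N divisor
  expected <- (m_set - m_all) / sqrt((sd2 / 2) * (5 - 2) / (5 - 1))
  expect_equal(unname(prof$scores["s1"]), expected)
  expect_equal(expected, sqrt(3), tolerance = 1e-12)

  # independent oracle: the denominator must be the exact standard deviation
  # of the mean of a size-2 sample drawn without replacement from s1
  combos <- utils::combn(v[, "s1"], 2)
  exact_var <- mean(colMeans(combos)^2) - mean(colMeans(combos))^2
  expect_equal(unname(prof$scores["s1"]), m_set / sqrt(exact_var))

  # constant sample column: sd_all = 0 rule
  expect_equal(unname(prof$scores["s2"]), 0)
})

test_that("GSZ degeneracies and invariances hold", {
  pl <- small_pipeline()
  E <- pl$expression
  # whole-universe set: m_set = m_all and zero variance term
  whole <- signature("all", gene_ids(E))
  expect_true(all(gsz(E, whole)$scores == 0))

  sig <- signature("mod", truth_module_genes(pl$truth)[["A"]][1:10])
  base <- gsz(E, sig)$scores
  # scaling all values by c > 0 leaves GSZ unchanged
  scaled <- expression_matrix(E$values * 3.7)
  expect_equal(gsz(scaled, sig)$scores, base)
  # adding a constant before centering changes nothing
  shifted <- preprocess(expression_matrix(E$values + 2))
  expect_equal(gsz(shifted, sig)$scores, base)

  expect_error(gsz(E, signature("tiny", c("g00001"))), "matched")
  expect_warning(gsz(E, signature("half", c(sig$genes, paste0("nope", 1:20)))),
                 "found in the matrix")
})

test_that("GSZ of random gene sets is calibrated to mean 0, variance 1", {
  set.seed(10)
  v <- matrix(rnorm(2000 * 3), 2000, 3,
              dimnames = list(sprintf("g%04d", 1:2000), c("s1", "s2", "s3")))
  E <- centered_matrix(v)
  draws <- replicate(1000, {
    sig <- signature("r", sample(rownames(v), 20))
    gsz(E, sig)$scores[["s1"]]
  })
  expect_lt(abs(mean(draws)), 0.1)
  expect_lt(abs(var(draws) - 1), 0.1)
})

test_that("emulated subtype signatures score their subtype, not the rest", {
  pl <- small_pipeline()
  sigs <- make_reference_signatures(
    pl$truth, sizes = c(x_up = 20L), sources = c(x_up = "A"),
    decoy_fraction = 0.1, seed = 2)
  prof <- gsz(pl$expression, sigs$x_up)
  labs <- pl$labels
  expect_gt(mean(prof$scores[labs == "X"]), 0)
  expect_lt(mean(prof$scores[labs == "Y"]), 0)
})

test_that("signature maps count BMUs and accumulate in the source spot", {
  pl <- small_pipeline()
  g1 <- gene_ids(pl$expression)[1]
  m1 <- map_signature(signature("one", g1), pl$model)
  expect_identical(sum(m1$counts), 1L)
  expect_identical(which(m1$counts == 1L), unname(pl$model$bmu[g1]))

  sigs <- make_reference_signatures(
    pl$truth, sizes = c(x_up = 20L), sources = c(x_up = "A"),
    decoy_fraction = 0.1, seed = 2)
  ms <- map_signature(sigs$x_up, pl$model, spotset = pl$spots)
  expect_identical(sum(ms$counts), ms$n_matched)

  # >= 80% of matched genes fall inside the module-A spot or its 1-pixel
  # dilation
  spA <- pl$spots$spots[[pl$match$spot[pl$match$module == "A"]]]
  co <- pixel_coords(seq_len(pl$model$rows * pl$model$cols),
                     pl$model$rows, pl$model$cols)
  spot_co <- pixel_coords(spA$pixels, pl$model$rows, pl$model$cols)
  near <- vapply(seq_len(nrow(co)), function(p) {
    any(abs(co[p, 1] - spot_co[, 1]) <= 1 & abs(co[p, 2] - spot_co[, 2]) <= 1)
  }, TRUE)
  expect_gte(sum(ms$counts[near]) / ms$n_matched, 0.8)

  expect_error(map_signature(signature("alien", "zz"), pl$model),
               "no gene in the mapped universe")
})

test_that("Fisher enrichment matches closed forms and exhaustive enumeration", {
  # spot set scaffold with two hand-made spots
  mk_spotset <- function(spots, rows = 5, cols = 5) {
    structure(list(spots = spots, threshold = 0, q = 0.5, min_size = 1L,
                   rows = rows, cols = cols), class = "SpotSet")
  }
  universe <- sprintf("u%03d", 1:100)
  spot <- list(letter = "A", pixels = 1:3, genes = universe[1:5],
               seed_pixel = 1L, peak = 1)
  ss <- mk_spotset(list(A = spot))
  # signature identical to the spot genes: p = 1 / C(100, 5)
  res <- spot_enrichment(list(signature("same", universe[1:5])), ss, universe)
  expect_equal(res$p, 1 / choose(100, 5))
  # disjoint signature in a tiny universe: upper-tail p at overlap 0 is 1
  res0 <- spot_enrichment(list(signature("disj", universe[6:8])),
                          mk_spotset(list(A = modifyList(spot, list(
                            genes = universe[1:3])))), universe[1:10])
  expect_equal(res0$p, 1)

  # exhaustive enumeration oracle on all instances with N <= 30
  enum_p <- function(k, n_sig, n_spot, N) {
    ks <- max(0, n_sig + n_spot - N):min(n_sig, n_spot)
    probs <- choose(n_sig, ks) * choose(N - n_sig, n_spot - ks) /
      choose(N, n_spot)
    sum(probs[ks >= k])
  }
  set.seed(4)
  for (i in 1:20) {
    N <- sample(5:30, 1)
    n_sig <- sample(1:(N - 1), 1)
    n_spot <- sample(1:(N - 1), 1)
    uni <- sprintf("x%02d", 1:N)
    sig_genes <- sample(uni, n_sig)
    spot_genes <- sample(uni, n_spot)
    res <- spot_enrichment(
      list(signature("s", sig_genes)),
      mk_spotset(list(A = modifyList(spot, list(genes = spot_genes)))), uni)
    k <- length(intersect(sig_genes, spot_genes))
    expect_equal(res$overlap, k)
    expect_equal(res$p, enum_p(k, n_sig, n_spot, N))
  }
})

test_that("each planted signature is most enriched in its source spot", {
  pl <- small_pipeline()
  sigs <- make_reference_signatures(
    pl$truth, sizes = c(a_up = 20L, b_up = 20L, c_up = 15L),
    sources = c(a_up = "A", b_up = "B", c_up = "C"),
    decoy_fraction = 0.1, seed = 3)
  res <- spot_enrichment(sigs, pl$spots, names(pl$model$bmu))
  for (nm in c("a_up", "b_up", "c_up")) {
    src <- switch(nm, a_up = "A", b_up = "B", c_up = "C")
    sub <- res[res$signature == nm, ]
    expect_identical(sub$spot[which.min(sub$p)],
                     pl$match$spot[pl$match$module == src])
  }
})
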