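test_that("Cohen's kappa handles the canonical fixed points", {
  cats <- c("a", "b", "c", "d")
  expect_equal(cohenKappa(c("a", "b", "a", "c"), c("a", "b", "a", "c"),
                          cats), 1.0)
  # independence: pairs (a,a),(a,b),(b,a),(b,b) give p_o = p_e = 0.5
  expect_equal(cohenKappa(c("a", "a", "b", "b"), c("a", "b", "a", "b"),
                          cats), 0.0)
  expect_error(cohenKappa(c("a", "b"), c("a"), cats), "length")
  expect_error(cohenKappa(c("a", "x"), c("a", "a"), cats), "unknown label")
  # constant identical sequences: p_e = 1 with perfect agreement -> 1
  expect_equal(cohenKappa(rep("a", 5), rep("a", 5), cats), 1)
})

test_that("Cohen's kappa matches a brute-force tally on a random table", {
  set.seed(41)
  cats <- annotationLabels()
  for (rep in 1:5) {
    a <- sample(cats, 20, TRUE)
    b <- sample(cats, 20, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    # direct hand evaluation by exhaustive tallying
    po <- sum(a == b) / 20
    pe <- 0
    for (cat in cats) pe <- pe + (sum(a == cat) / 20) * (sum(b == cat) / 20)
    expect_equal(cohenKappa(a, b, cats), (po - pe) / (1 - pe),
                 tolerance = 1e-12)
  }
})

test_that("Cohen's kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  cats <- annotationLabels()
  a <- sample(cats, 60, TRUE)
  b <- ifelse(runif(60) < 0.6, a, sample(cats, 60, TRUE))
  tab <- table(factor(a, cats), factor(b, cats))
  expect_equal(cohenKappa(a, b, cats),
               e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
})

test_that("Fleiss' kappa reproduces a scalar hand computation", {
  # 6 items, 3 raters over 4 categories
  counts <- rbind(c(3, 0, 0, 0),
                  c(0, 3, 0, 0),
                  c(2, 1, 0, 0),
                  c(1, 1, 1, 0),
                  c(0, 0, 2, 1),
                  c(1, 0, 0, 2))
  n <- 3; N <- 6
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  pj <- colSums(counts) / (N * n)
  Pe <- sum(pj^2)
  expect_equal(fleissKappa(counts), (Pbar - Pe) / (1 - Pe), tolerance = 1e-12)
  # unanimity across two or more categories: kappa = 1
  expect_equal(fleissKappa(rbind(c(3, 0), c(0, 3), c(3, 0))), 1.0)
  # single-category degenerate table: flagged undefined
  und <- fleissKappa(rbind(c(3, 0), c(3, 0)))
  expect_true(is.nan(und))
  expect_true(attr(und, "undefined"))
  expect_error(fleissKappa(rbind(c(2, 1), c(1, 0))), "ragged")
})

test_that("Fleiss' kappa on uniform random votes concentrates near zero", {
  # for n raters and uniform categories the asymptotic null s.e. is
  # 1 / (3 sqrt(N)) at n = 3, K = 4 (Fleiss' large-sample variance)
  N <- 10000L
  set.seed(43)
  votes <- t(stats::rmultinom(N, 3, rep(0.25, 4)))
  k <- fleissKappa(votes)
  expect_lt(abs(k), 3 / (3 * sqrt(N)))
})

test_that("kappa interpretation bands follow Landis-Koch", {
  expect_equal(interpretKappa(0.529), "moderate")
  expect_equal(interpretKappa(0.598), "moderate")
  expect_equal(interpretKappa(1.0), "almost perfect")
  expect_equal(interpretKappa(0.0), "slight")
  expect_equal(interpretKappa(0.205), "fair")
  expect_equal(interpretKappa(0.605), "substantial")
  expect_equal(interpretKappa(-0.2), "poor")
  expect_error(interpretKappa(1.2), "-1, 1")
})

test_that("percent agreement counts unanimous rows at one decimal", {
  m <- cbind(rep("a", 4), rep("a", 4), c("a", "a", "b", "a"))
  expect_equal(percentAgreement(m), 75.0)
  expect_equal(percentAgreement(cbind(c("a", "b"), c("a", "b"))), 100.0)
  expect_error(percentAgreement(cbind(c("a", NA), c("a", "b"))), "missing")
  # 2554 unanimous of 3131 -> 81.6
  lab <- c(rep("x", 2554), rep("y", 577))
  other <- c(rep("x", 2554), rep("z", 577))
  expect_equal(percentAgreement(cbind(lab, lab, other)), 81.6)
})

test_that("kappas are invariant under consistent label renaming and symmetric", {
  set.seed(44)
  cats <- annotationLabels()
  a <- sample(cats, 80, TRUE)
  b <- ifelse(runif(80) < 0.5, a, sample(cats, 80, TRUE))
  k1 <- cohenKappa(a, b, cats)
  expect_equal(cohenKappa(b, a, cats), k1, tolerance = 1e-12)
  perm <- setNames(cats[c(3, 1, 4, 2)], cats)
  expect_equal(cohenKappa(unname(perm[a]), unname(perm[b]), cats), k1,
               tolerance = 1e-12)
  m <- cbind(a, b, sample(cats, 80, TRUE))
  k3 <- fleissKappa(SonoCAM:::voteCounts(m))
  mP <- apply(m, 2, function(col) unname(perm[col]))
  expect_equal(fleissKappa(SonoCAM:::voteCounts(mP)), k3, tolerance = 1e-12)
})

test_that("estimated kappa decreases as simulated rater noise grows", {
  set.seed(45)
  labs <- annotationLabels()
  n <- 5000
  truth <- sample(labs, n, TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  kappaAt <- function(p) {
    m <- sapply(1:3, function(i)
      simulateRater(truth, raterModel(paste0("r", i), flipProbability = p)))
    fleissKappa(SonoCAM:::voteCounts(m))
  }
  ks <- vapply(c(0.05, 0.15, 0.30), kappaAt, numeric(1))
  expect_true(all(diff(ks) < 0))
  # noiseless raters agree perfectly
  m0 <- sapply(1:3, function(i)
    simulateRater(truth, raterModel(paste0("r", i), flipProbability = 0)))
  expect_equal(fleissKappa(SonoCAM:::voteCounts(m0)), 1.0)
})

test_that("the agreement report assembles all statistics coherently", {
  set.seed(46)
  labs <- annotationLabels()
  truth <- sample(labs, 400, TRUE, prob = c(0.5, 0.25, 0.15, 0.1))
  m <- sapply(1:3, function(i)
    simulateRater(truth, raterModel(paste0("r", i), flipProbability = 0.15)))
  colnames(m) <- paste0("r", 1:3)
  rownames(m) <- sprintf("i%04d", 1:400)
  ann <- annotationsFrom(m)
  rep <- agreementReport(ann)
  expect_s4_class(rep, "AgreementReport")
  expect_equal(rep@nItems, 400L)
  expect_equal(rep@nRaters, 3L)
  expect_named(rep@cohen, c("r1-r2", "r1-r3", "r2-r3"))
  expect_equal(unname(rep@cohen[["r1-r2"]]),
               cohenKappa(m[, "r1"], m[, "r2"]), tolerance = 1e-12)
  expect_equal(rep@fleiss, as.numeric(fleissKappa(SonoCAM:::voteCounts(m))),
               tolerance = 1e-12)
  expect_equal(rep@percentAgreement, percentAgreement(m))
  expect_equal(unname(rep@interpretations["fleiss"]),
               interpretKappa(rep@fleiss))
  # serialization carries three-decimal kappas and one-decimal percentages
  path <- tempfile(fileext = ".json")
  writeAgreementReport(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$fleiss, round(rep@fleiss, 3), tolerance = 5e-4)
  expect_equal(back$n_raters, 3L)
})

test_that("two raters yield both a Cohen and a Fleiss statistic", {
  set.seed(47)
  labs <- annotationLabels()
  a <- sample(labs, 200, TRUE)
  b <- ifelse(runif(200) < 0.7, a, sample(labs, 200, TRUE))
  m <- cbind(r1 = a, r2 = b)
  rownames(m) <- sprintf("i%03d", 1:200)
  rep <- agreementReport(annotationsFrom(m))
  expect_length(rep@cohen, 1L)
  expect_false(is.na(rep@fleiss))
  # the two chance models genuinely differ on this data
  expect_false(isTRUE(all.equal(unname(rep@cohen[[1]]), rep@fleiss)))
})
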