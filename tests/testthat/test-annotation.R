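test_that("the oracle follows the quality floor and precedence order", {
  # cell (1,1) fully inside the vessel mask, quality 1 -> lymph_node_vessel
  fr <- handFrame(vesselCells = rbind(c(1, 1)))
  r <- regionFrom(c(1, 1))
  expect_equal(oracleLabel(r, fr), "lymph_node_vessel")
  # quality 0 overrides any overlap
  fr0 <- handFrame(vesselCells = rbind(c(1, 1)), quality = 0)
  expect_equal(oracleLabel(r, fr0), "not_interpretable")
  # region over pure background: other_structure
  expect_equal(oracleLabel(regionFrom(c(5, 5)), fr), "other_structure")
  # artifact overlap without node/vessel overlap: artifact
  fra <- handFrame(artifactCells = rbind(c(2, 2)))
  expect_equal(oracleLabel(regionFrom(c(2, 2)), fra), "artifact")
  # node/vessel outranks artifact when both overlap
  frb <- handFrame(nodeCells = rbind(c(3, 3)), artifactCells = rbind(c(3, 3)))
  expect_equal(oracleLabel(regionFrom(c(3, 3)), frb), "lymph_node_vessel")
  # empty/degenerate region: not interpretable
  dg <- methods::new("ActivationRegion", cells = matrix(integer(), 0, 2),
                     maxCell = c(NA_integer_, NA_integer_), threshold = 0.9,
                     degenerate = TRUE)
  expect_equal(oracleLabel(dg, fr), "not_interpretable")
})

test_that("the oracle respects the minimum overlap fraction", {
  S <- 70L
  fr <- handFrame(imageSize = S)
  # paint 20% of cell (4,4)'s footprint with lymph node
  fp <- SonoCAM:::cellFootprint(4, 4, S)
  nr <- length(fp$rows)
  sub <- fp$rows[seq_len(ceiling(0.2 * nr))]
  fr@masks$lymph_node[sub, fp$cols] <- 1
  r <- regionFrom(c(4, 4))
  expect_equal(oracleLabel(r, fr, overlapRules(minFraction = 0.25)),
               "other_structure")
  expect_equal(oracleLabel(r, fr, overlapRules(minFraction = 0.15)),
               "lymph_node_vessel")
})

test_that("the oracle is deterministic", {
  fr <- handFrame(nodeCells = rbind(c(2, 3)))
  r <- regionFrom(rbind(c(2, 3), c(5, 5)))
  labs <- replicate(5, oracleLabel(r, fr))
  expect_true(all(labs == labs[1]))
})

test_that("simulated raters honour the flip probability limits", {
  truth <- rep(annotationLabels(), each = 25)
  set.seed(31)
  faithful <- simulateRater(truth, raterModel("r1", flipProbability = 0))
  expect_identical(faithful, truth)
  always <- simulateRater(truth, raterModel("r2", flipProbability = 1))
  expect_true(all(always != truth)) # default kernel excludes the truth
})

test_that("complete-agreement rate of 3 raters matches the closed form", {
  # P(all three agree) = sum_t pi_t * sum_j P(r = j | t)^3 with
  # P(r = j | t) = (1 - p) 1[j = t] + p K[t, j]
  p <- 0.2
  labs <- annotationLabels()
  K <- matrix(1 / 3, 4, 4, dimnames = list(labs, labs))
  diag(K) <- 0
  cond <- (1 - p) * diag(4) + p * K
  pTruth <- c(0.55, 0.25, 0.12, 0.08)
  analytic <- sum(vapply(1:4, function(t)
    pTruth[t] * sum(cond[t, ]^3), numeric(1)))
  n <- 5000
  set.seed(32)
  truth <- sample(labs, n, TRUE, prob = pTruth)
  rater <- raterModel("r", flipProbability = p)
  l1 <- simulateRater(truth, rater)
  l2 <- simulateRater(truth, rater)
  l3 <- simulateRater(truth, rater)
  obs <- mean(l1 == l2 & l2 == l3)
  se <- sqrt(analytic * (1 - analytic) / n)
  expect_lt(abs(obs - analytic), 3 * se)
})

test_that("consensus classifies the three canonical cases", {
  mk <- function(labels) data.frame(image_id = "i1",
                                    rater_id = c("r1", "r2", "r3"),
                                    label = labels)
  cc <- consensus(mk(c("artifact", "artifact", "artifact")))
  expect_equal(cc$agreement_level, "complete")
  expect_equal(cc$final_label, "artifact")
  cm <- consensus(mk(c("artifact", "artifact", "other_structure")))
  expect_equal(cm$agreement_level, "majority")
  expect_equal(cm$final_label, "artifact")
  cd <- consensus(mk(c("artifact", "other_structure", "not_interpretable")))
  expect_equal(cd$agreement_level, "disagreement")
  expect_true(is.na(cd$final_label))
})

test_that("consensus rejects malformed input", {
  expect_error(consensus(data.frame(image_id = "i1", rater_id = c("r1", "r2"),
                                    label = c("artifact", "artifact"))),
               "exactly 3")
  expect_error(consensus(data.frame(image_id = "i1",
                                    rater_id = c("r1", "r1", "r2"),
                                    label = rep("artifact", 3))),
               "duplicate rater")
  expect_error(consensus(data.frame(image_id = "i1",
                                    rater_id = c("r1", "r2", "r3"),
                                    label = c("bogus", "artifact", "artifact"))),
               "unknown label")
})

test_that("every 3-rater tuple lands in exactly one agreement level", {
  # exhaustive property over all 4^3 = 64 tuples against a brute-force
  # classifier of tuples
  labs <- annotationLabels()
  bruteClassify <- function(tr) {
    u <- length(unique(tr))
    if (u == 1) "complete" else if (u == 2) "majority" else "disagreement"
  }
  for (a in labs) for (b in labs) for (c in labs) {
    tup <- c(a, b, c)
    got <- consensus(data.frame(image_id = "i", rater_id = c("r1", "r2", "r3"),
                                label = tup))
    expect_equal(got$agreement_level, bruteClassify(tup))
    if (got$agreement_level == "complete")
      expect_equal(got$final_label, a)
    if (got$agreement_level == "majority")
      expect_equal(got$final_label,
                   names(which.max(table(tup))))
  }
})

test_that("adjudication resolves pending items and validates labels", {
  ann <- rbind(
    data.frame(image_id = "i1", rater_id = c("r1", "r2", "r3"),
               label = c("artifact", "other_structure", "not_interpretable")),
    data.frame(image_id = "i2", rater_id = c("r1", "r2", "r3"),
               label = rep("lymph_node_vessel", 3)))
  cc <- consensus(ann)
  expect_error(adjudicate(cc, data.frame(image_id = "zz",
                                         final_label = "artifact")),
               "no adjudication")
  done <- adjudicate(cc, data.frame(image_id = "i1",
                                    final_label = "artifact"))
  expect_false(anyNA(done$final_label))
  expect_equal(done$final_label[done$image_id == "i1"], "artifact")
})

test_that("agreement distribution reproduces printed percentages", {
  mk <- function(n, lvl) if (n > 0)
    data.frame(image_id = sprintf("%s%05d", lvl, seq_len(n)),
               final_label = "lymph_node_vessel", agreement_level = lvl)
  cr <- rbind(mk(2554, "complete"), mk(474, "majority"),
              mk(103, "disagreement"))
  d <- agreementDistribution(cr)
  expect_equal(d$count, c(2554L, 474L, 103L))
  expect_equal(d$percentage, c(81.6, 15.1, 3.3))
  expect_lt(abs(sum(d$percentage) - 100), 0.2)
  allc <- agreementDistribution(mk(50, "complete"))
  expect_equal(allc$percentage, c(100.0, 0.0, 0.0))
})
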