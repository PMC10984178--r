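# Shared toy data: a cleanly separable 2-covariate problem and a noisy
# logistic one.
makeToyData <- function(n, beta = c(2, -1.5), intercept = 0, noise = TRUE,
                        seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- intercept + beta[1] * x1 + beta[2] * x2
  p <- plogis(eta)
  label <- if (noise) rbinom(n, 1, p) else as.integer(eta > 0)
  data.frame(label = label, x1 = x1, x2 = x2)
}

test_that("replicate splits have the right size and stratification", {
  labels <- c(rep(1, 300), rep(0, 600))
  splits <- splitReplicates(labels, nReplicates = 10, seed = 2)
  expect_length(splits, 10)
  for (tr in splits) {
    expect_equal(length(tr), round(0.8 * 300) + round(0.8 * 600))
    expect_equal(mean(labels[tr]), mean(labels), tolerance = 0.01)
    te <- setdiff(seq_along(labels), tr)
    expect_equal(mean(labels[te]), mean(labels), tolerance = 0.01)
  }
  # union of test sets covers close to 1 - 0.8^10 of the points
  covered <- unique(unlist(lapply(splits, function(tr)
    setdiff(seq_along(labels), tr))))
  expect_gt(length(covered) / length(labels), 0.85)
})

test_that("all six families separate a linearly separable problem", {
  dat <- makeToyData(400, noise = FALSE, seed = 5)
  for (alg in c("GLM", "GAM", "GBM", "MARS", "RF", "MAXENT")) {
    m <- fitMember(alg, dat, seed = 7)
    auc <- aucRank(predictMember(m, dat), dat$label)
    expect_gt(auc, 0.95)
    p <- predictMember(m, dat)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("GLM recovers coefficient signs from a known logistic model", {
  dat <- makeToyData(5000, beta = c(1.2, -0.8), seed = 9)
  m <- fitMember("GLM", dat)
  co <- coef(m@fit)
  expect_gt(co[["x1"]], 0)
  expect_lt(co[["x2"]], 0)
})

test_that("degenerate training data is refused or flagged", {
  dat <- makeToyData(100, seed = 3)
  dat$label <- 1L
  expect_error(fitMember("GLM", dat), "single-class")
  dat2 <- makeToyData(100, seed = 3)
  dat2$x2 <- 5
  expect_warning(m <- fitMember("GLM", dat2), "constant")
  expect_true(all(is.finite(predictMember(m, dat2))))
})

test_that("AUC equals brute-force concordant-pair counting", {
  expect_equal(aucRank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucRank(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  # 6-point toy set with a tie
  pred <- c(0.9, 0.6, 0.6, 0.4, 0.3, 0.1)
  lab <- c(1, 1, 0, 1, 0, 0)
  pairs <- expand.grid(p = which(lab == 1), n = which(lab == 0))
  conc <- mean(ifelse(pred[pairs$p] > pred[pairs$n], 1,
                      ifelse(pred[pairs$p] == pred[pairs$n], 0.5, 0)))
  expect_equal(aucRank(pred, lab), conc)
  # random data against pROC as an independent oracle
  set.seed(12)
  for (k in 1:5) {
    p <- runif(200); l <- rbinom(200, 1, 0.4)
    expect_equal(aucRank(p, l),
                 as.numeric(pROC::auc(pROC::roc(l, p, quiet = TRUE, direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("TSS and kappa at the reported optimum dominate the sweep", {
  set.seed(4)
  p <- runif(300); l <- rbinom(300, 1, plogis(3 * (p - 0.5)))
  met <- evalMetrics(p, l)
  sw <- thresholdSweep(p, l)
  expect_equal(met$tss, max(sw$tss))
  expect_equal(met$kappa, max(sw$kappa))
  expect_gte(met$tss, sw$tss[which(sw$threshold == met$threshold_star)] - 1e-12)
  expect_equal(evalMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0))$tss, 1)
})

test_that("member selection and AUC-proportional weights follow the rule", {
  tab <- data.frame(algorithm = "GLM", replicate = 1:2,
                    auc = c(0.85, 0.85))
  w <- selectAndWeight(tab)
  expect_equal(w$weight, c(0.5, 0.5))
  tab2 <- data.frame(auc = c(0.75, 0.80, 0.90))
  w2 <- selectAndWeight(tab2)
  expect_false(w2$selected[1])
  expect_equal(w2$weight, c(0, 8 / 17, 9 / 17))
  expect_error(selectAndWeight(data.frame(auc = c(0.5, 0.6))),
               "no member exceeds")
})

test_that("ensemble prediction is the weighted member mean, inside the envelope", {
  dat <- makeToyData(600, seed = 15)
  ens <- fitEnsemble(dat, algorithms = c("GLM", "GBM", "RF"),
                     nReplicates = 2, aucThreshold = 0.5, seed = 15)
  newdata <- makeToyData(50, seed = 16)[, -1]
  pred <- predictEnsemble(ens, newdata)
  sel <- which(ens@memberTable$selected)
  manual <- rep(0, nrow(newdata))
  for (i in sel) {
    manual <- manual + ens@memberTable$weight[i] *
      predictMember(ens@members[[i]], newdata)
  }
  expect_equal(pred, 100 * manual, tolerance = 1e-10)
  allp <- vapply(sel, function(i)
    predictMember(ens@members[[i]], newdata), numeric(nrow(newdata)))
  expect_true(all(pred >= 100 * apply(allp, 1, min) - 1e-9))
  expect_true(all(pred <= 100 * apply(allp, 1, max) + 1e-9))
  expect_equal(sum(ens@memberTable$weight), 1, tolerance = 1e-12)
})

test_that("a single selected member predicts exactly 100 x its probability", {
  dat <- makeToyData(400, seed = 21)
  ens <- fitEnsemble(dat, algorithms = "GLM", nReplicates = 1,
                     aucThreshold = 0.5, seed = 21)
  newdata <- dat[1:30, -1]
  expect_equal(predictEnsemble(ens, newdata),
               100 * predictMember(ens@members[[1]], newdata),
               tolerance = 1e-12)
})

test_that("permutation importance: single-variable model takes the full share", {
  set.seed(30)
  dat <- data.frame(label = rbinom(400, 1, 0.5), x1 = rnorm(400))
  dat$label <- as.integer(plogis(2 * dat$x1) > runif(400))
  dat$x2 <- rnorm(400)  # pure noise variable
  ens <- fitEnsemble(dat, algorithms = "GLM", nReplicates = 2,
                     aucThreshold = 0.5, seed = 30)
  imp <- variableImportance(ens, dat, nPermutations = 5, seed = 31)
  expect_equal(sum(imp$importance), 100, tolerance = 1e-9)
  expect_gt(imp$importance[imp$variable == "x1"], 90)
})

test_that("response curves agree with direct predictions at the sweep ends", {
  dat <- makeToyData(500, seed = 33)
  ens <- fitEnsemble(dat, algorithms = c("GLM", "MARS"), nReplicates = 2,
                     aucThreshold = 0.5, seed = 33)
  curves <- responseCurves(ens, dat, nGrid = 21)
  for (v in c("x1", "x2")) {
    cv <- curves[[v]]
    nd <- data.frame(x1 = mean(dat$x1), x2 = mean(dat$x2))
    for (endIdx in c(1, 21)) {
      nd[[v]] <- cv$value[endIdx]
      expect_equal(cv$response[endIdx], predictEnsemble(ens, nd),
                   tolerance = 1e-10)
    }
  }
})

test_that("suitability classes use half-open 20-point intervals", {
  g <- gridSpec(4, 4)
  vals <- c(0, 5, 19.99, 20, 25, 39.9, 40, 55, 60, 79, 80, 95, 100,
            10, 50, 90)
  out <- classifySuitability(gridRaster(matrix(vals, 4, 4), g))
  cls <- as.vector(rasterValues(out$classes))
  expect_equal(cls[vals == 20], 2)   # boundary joins the upper class
  expect_equal(cls[vals == 100], 5)
  expect_equal(cls[vals == 0], 1)
  uniform <- classifySuitability(gridRaster(matrix(85, 4, 4), g))
  expect_equal(uniform$areas$area_km2[5], 16)
  expect_equal(sum(uniform$areas$area_km2[-5]), 0)
  # histogram oracle on a random surface
  set.seed(9)
  rv <- matrix(runif(400, 0, 100), 20, 20)
  areas <- classifySuitability(gridRaster(rv, gridSpec(20, 20)))$areas
  brute <- vapply(1:5, function(k)
    sum(rv >= (k - 1) * 20 & (rv < k * 20 | (k == 5 & rv <= 100))),
    numeric(1))
  expect_equal(areas$n_cells, brute)
})

test_that("zonal summaries match a brute-force point-in-polygon count", {
  g <- gridSpec(20, 20)
  set.seed(10)
  sv <- matrix(runif(400, 0, 100), 20, 20)
  surf <- gridRaster(sv, g)
  zones <- list(rectPolygon(0, 20, 0, 20, id = 1, name = "all"),
                rectPolygon(2, 9, 3, 12, id = 2, name = "inner"))
  zs <- zonalSummary(surf, zones, pThreshold = 0.6)
  expect_equal(zs$suitable_area_km2[1], sum(sv / 100 > 0.6))
  ctr <- cellCenters(g)
  inz <- pointInPolygon(zones[[2]], ctr[, "x"], ctr[, "y"])
  expect_equal(zs$suitable_area_km2[2],
               sum(as.vector(sv)[inz] / 100 > 0.6))
  expect_equal(zonalSummary(surf, zones, pThreshold = 1)$suitable_area_km2,
               c(0, 0))
  hi <- gridRaster(matrix(90, 20, 20), g)
  zhi <- zonalSummary(hi, zones[2], pThreshold = 0.6)
  expect_equal(zhi$suitable_area_km2, zhi$zone_area_km2)
})
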