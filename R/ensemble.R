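# Six-algorithm habitat suitability ensemble: repeated stratified 80/20
# evaluation splits, AUC/KAPPA/TSS scoring, AUC-thresholded member
# selection, AUC-proportional weighting, weighted-mean prediction
# rescaled to 0-100, permutation variable importance, evaluation-strip
# response curves and equal-interval suitability classes.

.sdmAlgorithms <- c("GLM", "GAM", "GBM", "MARS", "RF", "MAXENT")

#' Fitted ensemble member
#'
#' One algorithm fitted on one replicate's training split, with its
#' held-out evaluation metrics.
#'
#' @slot algorithm one of GLM, GAM, GBM, MARS, RF, MAXENT.
#' @slot replicateId replicate number.
#' @slot fit opaque fitted state.
#' @slot vars covariate names used.
#' @slot metrics list with auc, kappa, tss, threshold_star.
#' @export
setClass("MemberModel",
  representation(
    algorithm = "character", replicateId = "integer", fit = "ANY",
    vars = "character", metrics = "list"
  )
)

setMethod("show", "MemberModel", function(object) {
  m <- object@metrics
  cat(sprintf(
    "MemberModel %s (replicate %d): AUC %.3f, TSS %.3f, KAPPA %.3f\n",
    object@algorithm, object@replicateId,
    m$auc %||% NA, m$tss %||% NA, m$kappa %||% NA
  ))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fitted suitability ensemble
#'
#' @slot members list of \linkS4class{MemberModel}s (all replicates of
#'   all algorithms).
#' @slot memberTable per-member metrics, selection flag and weight.
#' @slot vars covariate names.
#' @slot aucThreshold AUC cutoff used for selection.
#' @slot heldOut list of held-out (pred, label) pairs per member, for
#'   pooled ensemble metrics.
#' @export
setClass("SdmEnsemble",
  representation(
    members = "list", memberTable = "data.frame", vars = "character",
    aucThreshold = "numeric", heldOut = "list"
  )
)

setMethod("show", "SdmEnsemble", function(object) {
  tab <- object@memberTable
  cat(sprintf(
    "SdmEnsemble: %d members (%d selected at AUC > %.2f) on %s\n",
    nrow(tab), sum(tab$selected), object@aucThreshold,
    paste(object@vars, collapse = ", ")
  ))
  agg <- stats::aggregate(auc ~ algorithm, tab, mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-7s mean AUC %.3f\n", agg$algorithm[i], agg$auc[i]))
})

# ---- splits ----

#' Repeated stratified train/test splits
#'
#' Ten (by default) independent random 80/20 splits, stratified by
#' label, for the repeated split-sample evaluation of each algorithm.
#'
#' @param labels 0/1 vector.
#' @param nReplicates number of splits (default 10).
#' @param trainFraction fraction per class in training (default 0.8).
#' @param seed RNG seed.
#' @return List of integer train-index vectors; test = the complement.
#' @export
splitReplicates <- function(labels, nReplicates = 10, trainFraction = 0.8,
                            seed = 1) {
  set.seed(seed)
  idx1 <- which(labels == 1)
  idx0 <- which(labels == 0)
  lapply(seq_len(nReplicates), function(r) {
    sort(c(
      sample(idx1, round(trainFraction * length(idx1))),
      sample(idx0, round(trainFraction * length(idx0)))
    ))
  })
}

# ---- member fitters ----

# quantile knots for hinge features, interior and unique
.hingeKnots <- function(x, k) {
  unique(stats::quantile(x, probs = seq(1, k, by = 1) / (k + 1),
                         names = FALSE))
}

.hingeBasis <- function(x, knots) {
  cbind(
    vapply(knots, function(kn) pmax(x - kn, 0), numeric(length(x))),
    vapply(knots, function(kn) pmax(kn - x, 0), numeric(length(x)))
  )
}

# Forward-stagewise MARS-style fitter: hinge pairs at quantile knots are
# added greedily while the binomial deviance drop beats the AIC cost of
# two parameters, then the final basis is refit with glm.
.fitMars <- function(data, vars, maxPairs = 8, nKnots = 5) {
  y <- data$label
  cand <- do.call(rbind, lapply(vars, function(v) {
    kn <- .hingeKnots(data[[v]], nKnots)
    data.frame(var = v, knot = kn, stringsAsFactors = FALSE)
  }))
  basis <- matrix(1, nrow(data), 1)
  chosen <- cand[0, ]
  dev <- stats::glm.fit(basis, y, family = stats::binomial())$deviance
  for (step in seq_len(maxPairs)) {
    best <- NULL; bestDev <- dev
    for (ci in seq_len(nrow(cand))) {
      pr <- .hingeBasis(data[[cand$var[ci]]], cand$knot[ci])
      fit <- suppressWarnings(
        stats::glm.fit(cbind(basis, pr), y, family = stats::binomial())
      )
      if (fit$deviance < bestDev) { bestDev <- fit$deviance; best <- ci }
    }
    if (is.null(best) || dev - bestDev < 4) break  # AIC cost of 2 params
    basis <- cbind(basis, .hingeBasis(data[[cand$var[best]]],
                                      cand$knot[best]))
    chosen <- rbind(chosen, cand[best, ])
    dev <- bestDev
    cand <- cand[-best, , drop = FALSE]
  }
  fit <- suppressWarnings(
    stats::glm.fit(basis, y, family = stats::binomial())
  )
  list(coef = fit$coefficients, terms = chosen)
}

.predictMars <- function(fit, newdata) {
  basis <- matrix(1, nrow(newdata), 1)
  if (nrow(fit$terms)) {
    for (i in seq_len(nrow(fit$terms)))
      basis <- cbind(basis, .hingeBasis(newdata[[fit$terms$var[i]]],
                                        fit$terms$knot[i]))
  }
  co <- fit$coef
  co[is.na(co)] <- 0
  stats::plogis(drop(basis %*% co))
}

# MaxEnt as its penalized-logistic equivalence: linear + quadratic +
# hinge features, lasso penalty chosen by internal cross-validation,
# background observations down-weighted so both classes carry equal
# total weight.
.maxentFeatures <- function(data, vars, knots) {
  cols <- list()
  for (v in vars) {
    x <- data[[v]]
    cols[[paste0(v, "_lin")]] <- x
    cols[[paste0(v, "_sq")]] <- x^2
    kn <- knots[[v]]
    hb <- .hingeBasis(x, kn)
    colnames(hb) <- paste0(v, "_h", seq_len(ncol(hb)))
    for (j in seq_len(ncol(hb))) cols[[colnames(hb)[j]]] <- hb[, j]
  }
  do.call(cbind, cols)
}

.fitMaxent <- function(data, vars) {
  knots <- lapply(vars, function(v) .hingeKnots(data[[v]], 4))
  names(knots) <- vars
  X <- .maxentFeatures(data, vars, knots)
  y <- data$label
  w <- ifelse(y == 1, 1, sum(y == 1) / sum(y == 0))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", weights = w,
                          nfolds = 5, alpha = 1)
  list(cv = cv, knots = knots)
}

.fitQuadGlm <- function(data, vars) {
  rhs <- paste(
    c(vars, sprintf("I(%s^2)", vars)), collapse = " + "
  )
  suppressWarnings(stats::glm(
    stats::as.formula(paste("label ~", rhs)),
    family = stats::binomial(), data = data
  ))
}

.fitGam <- function(data, vars) {
  nu <- vapply(vars, function(v) length(unique(data[[v]])), integer(1))
  terms <- ifelse(nu >= 10, sprintf("s(%s, k = 5)", vars), vars)
  mgcv::gam(
    stats::as.formula(paste("label ~", paste(terms, collapse = " + "))),
    family = stats::binomial(), data = data
  )
}

.fitGbm <- function(data, vars, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(data[vars]),
                                 label = data$label)
  xgboost::xgb.train(
    params = list(
      objective = "binary:logistic", eta = 0.1, max_depth = 3,
      subsample = 0.8, nthread = 1
    ),
    data = dtrain, nrounds = 150, verbose = 0
  )
}

.fitRf <- function(data, vars, seed) {
  set.seed(seed)
  randomForest::randomForest(
    x = data[vars], y = factor(data$label, levels = c(0, 1)),
    ntree = 300
  )
}

#' Fit one ensemble member
#'
#' Probability-of-presence model per algorithm family: GLM is a
#' binomial-logit model with linear and quadratic terms; GAM uses
#' penalized smooths; GBM is stochastic gradient boosting with Bernoulli
#' loss; MARS is a forward-stagewise hinge-basis logit fit; RF a
#' probability forest; MAXENT the penalized-logistic maximum-entropy
#' equivalence with linear, quadratic and hinge features and
#' down-weighted background.
#'
#' @param algorithm one of GLM, GAM, GBM, MARS, RF, MAXENT.
#' @param data data.frame with \code{label} (0/1) and covariate columns.
#' @param vars covariate names (default: all non-label columns).
#' @param replicateId replicate number recorded on the model.
#' @param seed seed for the stochastic fitters.
#' @return A \linkS4class{MemberModel} (metrics empty until evaluated).
#' @export
fitMember <- function(algorithm, data, vars = setdiff(names(data), "label"),
                      replicateId = 1L, seed = 1) {
  algorithm <- match.arg(toupper(algorithm), .sdmAlgorithms)
  if (length(unique(data$label)) < 2)
    stop("single-class training data: cannot fit ", algorithm)
  constant <- vars[vapply(vars, function(v) stats::sd(data[[v]]) == 0,
                          logical(1))]
  if (length(constant)) {
    warning("dropping constant covariates: ",
            paste(constant, collapse = ", "))
    vars <- setdiff(vars, constant)
  }
  if (!length(vars)) stop("no non-constant covariates to fit")
  fit <- switch(algorithm,
    GLM = .fitQuadGlm(data, vars),
    GAM = .fitGam(data, vars),
    GBM = .fitGbm(data, vars, seed),
    MARS = .fitMars(data, vars),
    RF = .fitRf(data, vars, seed),
    MAXENT = .fitMaxent(data, vars)
  )
  new("MemberModel", algorithm = algorithm,
      replicateId = as.integer(replicateId), fit = fit, vars = vars,
      metrics = list())
}

#' Predict presence probability from a member
#'
#' @param model a \linkS4class{MemberModel}.
#' @param newdata data.frame containing the model's covariates.
#' @return Probabilities in [0, 1].
#' @export
predictMember <- function(model, newdata) {
  p <- switch(model@algorithm,
    GLM = stats::predict(model@fit, newdata = newdata, type = "response"),
    GAM = as.numeric(stats::predict(model@fit, newdata = newdata,
                                    type = "response")),
    GBM = stats::predict(model@fit,
                         xgboost::xgb.DMatrix(
                           as.matrix(newdata[model@vars]))),
    MARS = .predictMars(model@fit, newdata),
    RF = stats::predict(model@fit, newdata = newdata[model@vars],
                        type = "prob")[, "1"],
    MAXENT = {
      X <- .maxentFeatures(newdata, model@vars, model@fit$knots)
      as.numeric(stats::predict(model@fit$cv, newx = X, s = "lambda.min",
                                type = "response"))
    }
  )
  pmin(1, pmax(0, as.numeric(p)))
}

# ---- evaluation ----

#' Rank-statistic AUC
#'
#' Probability that a random presence outranks a random absence,
#' computed from the Wilcoxon rank sum (ties share credit).
#'
#' @param pred predicted probabilities.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
aucRank <- function(pred, labels) {
  np <- as.numeric(sum(labels == 1)); nn <- as.numeric(sum(labels == 0))
  if (np == 0 || nn == 0) stop("AUC needs both classes")
  r <- rank(pred)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Threshold-swept TSS and kappa
#'
#' Sensitivity, specificity, TSS and Cohen's kappa at each of
#' \code{nSteps} evenly spaced thresholds in [0, 1] (predicted presence
#' when probability >= threshold).
#'
#' @param pred predicted probabilities.
#' @param labels 0/1 labels.
#' @param nSteps number of thresholds (default 201).
#' @return data.frame with threshold, sens, spec, tss, kappa.
#' @export
thresholdSweep <- function(pred, labels, nSteps = 201) {
  thr <- seq(0, 1, length.out = nSteps)
  n <- as.numeric(length(labels))
  np <- as.numeric(sum(labels == 1)); nn <- n - np
  out <- vapply(thr, function(t) {
    pos <- pred >= t
    tp <- as.numeric(sum(pos & labels == 1))
    fp <- as.numeric(sum(pos & labels == 0))
    fn <- np - tp; tn <- nn - fp
    sens <- if (np) tp / np else 0
    spec <- if (nn) tn / nn else 0
    po <- (tp + tn) / n
    pe <- ((tp + fp) * np + (fn + tn) * nn) / n^2
    kap <- if (pe < 1) (po - pe) / (1 - pe) else 0
    c(sens, spec, sens + spec - 1, kap)
  }, numeric(4))
  data.frame(threshold = thr, sens = out[1, ], spec = out[2, ],
             tss = out[3, ], kappa = out[4, ])
}

#' Evaluate predictions against held-out labels
#'
#' AUC from the rank statistic; TSS and kappa maximized over the
#' threshold sweep; \code{threshold_star} is the (lowest)
#' TSS-maximizing threshold.
#'
#' @param pred predicted probabilities.
#' @param labels 0/1 labels.
#' @param nSteps sweep granularity (default 201).
#' @return List with auc, tss, kappa, threshold_star.
#' @export
evalMetrics <- function(pred, labels, nSteps = 201) {
  sw <- thresholdSweep(pred, labels, nSteps)
  list(
    auc = aucRank(pred, labels),
    tss = max(sw$tss),
    kappa = max(sw$kappa),
    threshold_star = sw$threshold[which.max(sw$tss)]
  )
}

#' Evaluate a member on test data
#'
#' @param model a \linkS4class{MemberModel}.
#' @param testData data.frame with label and covariates.
#' @return The model with its \code{metrics} slot filled.
#' @export
evaluateMember <- function(model, testData) {
  pred <- predictMember(model, testData)
  model@metrics <- evalMetrics(pred, testData$label)
  model
}

#' Select members and assign AUC-proportional weights
#'
#' Members with AUC above the threshold (default 0.79, about the top
#' half in the source analysis) are retained; each weight is its AUC
#' divided by the summed AUC of the selected set, so weights sum to 1.
#'
#' @param memberTable data.frame with at least an \code{auc} column.
#' @param aucThreshold selection cutoff (default 0.79).
#' @return The table with logical \code{selected} and numeric
#'   \code{weight} columns (weight 0 for unselected members).
#' @export
selectAndWeight <- function(memberTable, aucThreshold = 0.79) {
  sel <- memberTable$auc > aucThreshold
  if (!any(sel))
    stop("no member exceeds AUC ", aucThreshold,
         "; review the selection threshold or the training data")
  memberTable$selected <- sel
  memberTable$weight <- ifelse(sel, memberTable$auc / sum(memberTable$auc[sel]), 0)
  memberTable
}

#' Fit the full ensemble
#'
#' Runs every algorithm on every replicate split, evaluates each on its
#' held-out 20%, then selects and weights members by AUC.
#'
#' @param data data.frame with label and covariate columns (presences
#'   and pseudo-absences together).
#' @param algorithms algorithm subset (default all six).
#' @param nReplicates evaluation splits (default 10).
#' @param trainFraction training fraction (default 0.8).
#' @param aucThreshold member selection cutoff (default 0.79).
#' @param seed RNG seed governing splits and stochastic fitters.
#' @param quiet suppress progress messages.
#' @return An \linkS4class{SdmEnsemble}.
#' @export
fitEnsemble <- function(data, algorithms = .sdmAlgorithms,
                        nReplicates = 10, trainFraction = 0.8,
                        aucThreshold = 0.79, seed = 1, quiet = TRUE) {
  vars <- setdiff(names(data), "label")
  splits <- splitReplicates(data$label, nReplicates, trainFraction, seed)
  members <- list()
  heldOut <- list()
  rows <- list()
  k <- 0L
  for (alg in algorithms) {
    for (r in seq_len(nReplicates)) {
      k <- k + 1L
      if (!quiet) message("fitting ", alg, " replicate ", r)
      train <- data[splits[[r]], , drop = FALSE]
      test <- data[-splits[[r]], , drop = FALSE]
      m <- fitMember(alg, train, vars, replicateId = r,
                     seed = seed + 1000L * k)
      pred <- predictMember(m, test)
      m@metrics <- evalMetrics(pred, test$label)
      members[[k]] <- m
      heldOut[[k]] <- list(pred = pred, label = test$label)
      rows[[k]] <- data.frame(
        algorithm = alg, replicate = r, auc = m@metrics$auc,
        kappa = m@metrics$kappa, tss = m@metrics$tss,
        threshold_star = m@metrics$threshold_star,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- selectAndWeight(do.call(rbind, rows), aucThreshold)
  new("SdmEnsemble", members = members, memberTable = tab, vars = vars,
      aucThreshold = aucThreshold, heldOut = heldOut)
}

#' Pooled ensemble evaluation metrics
#'
#' AUC, TSS and kappa computed on the pooled held-out predictions of the
#' selected members.
#'
#' @param ensemble an \linkS4class{SdmEnsemble}.
#' @return List with auc, tss, kappa, threshold_star.
#' @export
ensembleMetrics <- function(ensemble) {
  sel <- which(ensemble@memberTable$selected)
  pred <- unlist(lapply(ensemble@heldOut[sel], `[[`, "pred"))
  lab <- unlist(lapply(ensemble@heldOut[sel], `[[`, "label"))
  evalMetrics(pred, lab)
}

#' Predict the 0-100 ensemble suitability surface
#'
#' Per cell, the weight-averaged probability of the selected members,
#' rescaled to 0-100. The ensemble value always lies within the member
#' prediction envelope.
#'
#' @param ensemble an \linkS4class{SdmEnsemble}.
#' @param covariates a \linkS4class{CovariateStack} (or a data.frame of
#'   covariate columns, in which case a vector is returned).
#' @param returnEnvelope also return per-cell min/max member predictions.
#' @return A \linkS4class{GridRaster} named "suitability" in [0, 100]
#'   (with attribute \code{envelope} if requested), or a numeric vector
#'   for data.frame input.
#' @export
predictEnsemble <- function(ensemble, covariates, returnEnvelope = FALSE) {
  isStack <- is(covariates, "CovariateStack")
  if (isStack) {
    g <- gridOf(covariates)
    mats <- lapply(ensemble@vars, function(v) as.vector(covariates[[v]]@values))
    newdata <- as.data.frame(stats::setNames(mats, ensemble@vars))
    ok <- stats::complete.cases(newdata)
  } else {
    newdata <- covariates
    ok <- rep(TRUE, nrow(newdata))
  }
  sel <- which(ensemble@memberTable$selected)
  w <- ensemble@memberTable$weight[sel]
  acc <- numeric(sum(ok))
  lo <- rep(Inf, sum(ok)); hi <- rep(-Inf, sum(ok))
  sub <- newdata[ok, , drop = FALSE]
  for (i in seq_along(sel)) {
    p <- predictMember(ensemble@members[[sel[i]]], sub)
    acc <- acc + w[i] * p
    if (returnEnvelope) { lo <- pmin(lo, p); hi <- pmax(hi, p) }
  }
  if (!isStack) {
    out <- rep(NA_real_, nrow(newdata)); out[ok] <- 100 * acc
    return(out)
  }
  v <- rep(NA_real_, g@nRows * g@nCols)
  v[ok] <- 100 * acc
  out <- gridRaster(matrix(v, g@nRows, g@nCols), g, "suitability")
  if (returnEnvelope) {
    lov <- rep(NA_real_, length(v)); hiv <- lov
    lov[ok] <- 100 * lo; hiv[ok] <- 100 * hi
    attr(out@values, "envelope") <- list(
      min = matrix(lov, g@nRows, g@nCols),
      max = matrix(hiv, g@nRows, g@nCols)
    )
  }
  out
}

#' Permutation variable importance
#'
#' For each selected member and variable: one minus the Pearson
#' correlation between predictions on the data and on the data with that
#' variable permuted, averaged over permutations; member scores are
#' weight-averaged and normalized to sum to 100.
#'
#' @param ensemble an \linkS4class{SdmEnsemble}.
#' @param data data.frame containing the covariate columns (label
#'   ignored).
#' @param nPermutations permutations per variable (default 3).
#' @param seed RNG seed.
#' @return data.frame with variable and importance (percent, sums to
#'   100).
#' @export
variableImportance <- function(ensemble, data, nPermutations = 3,
                               seed = 1) {
  set.seed(seed)
  vars <- ensemble@vars
  sel <- which(ensemble@memberTable$selected)
  w <- ensemble@memberTable$weight[sel]
  raw <- stats::setNames(numeric(length(vars)), vars)
  for (i in seq_along(sel)) {
    m <- ensemble@members[[sel[i]]]
    p0 <- predictMember(m, data)
    for (v in vars) {
      drops <- numeric(nPermutations)
      for (k in seq_len(nPermutations)) {
        perm <- data
        perm[[v]] <- sample(perm[[v]])
        pp <- predictMember(m, perm)
        r <- suppressWarnings(stats::cor(p0, pp))
        if (is.na(r)) r <- 1  # constant predictions: no dependence
        drops[k] <- 1 - r
      }
      raw[v] <- raw[v] + w[i] * mean(drops)
    }
  }
  raw[raw < 0] <- 0
  imp <- if (sum(raw) > 0) 100 * raw / sum(raw) else raw
  data.frame(variable = vars, importance = as.numeric(imp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluation-strip response curves
#'
#' For each variable, the weighted ensemble prediction along a sweep of
#' that variable with every other variable held at its mean.
#'
#' @param ensemble an \linkS4class{SdmEnsemble}.
#' @param data data.frame providing variable ranges and means.
#' @param nGrid sweep length (default 50).
#' @return Named list of data.frames (value, response) with response on
#'   the 0-100 suitability scale.
#' @export
responseCurves <- function(ensemble, data, nGrid = 50) {
  vars <- ensemble@vars
  means <- vapply(vars, function(v) mean(data[[v]]), numeric(1))
  out <- list()
  for (v in vars) {
    sweep <- seq(min(data[[v]]), max(data[[v]]), length.out = nGrid)
    nd <- as.data.frame(lapply(means, rep, nGrid))
    names(nd) <- vars
    nd[[v]] <- sweep
    out[[v]] <- data.frame(value = sweep,
                           response = predictEnsemble(ensemble, nd))
  }
  out
}

#' Five-class equal-interval suitability classification
#'
#' Half-open lower-inclusive intervals [0,20), [20,40), [40,60),
#' [60,80), [80,100]: class 1 "least potential" up to class 5 "highly
#' potential habitat". Returns the class raster and the per-class area.
#'
#' @param surface suitability \linkS4class{GridRaster} in [0, 100].
#' @return List with \code{classes} (GridRaster in 1..5) and
#'   \code{areas} (data.frame class, label, n_cells, area_km2).
#' @export
classifySuitability <- function(surface) {
  v <- surface@values
  if (any(v < 0 | v > 100, na.rm = TRUE))
    stop("suitability must lie in [0, 100]")
  cls <- pmin(floor(v / 20) + 1, 5)
  cellArea <- surface@grid@cellSize^2
  labels <- c("least potential", "moderately low potential",
              "moderate potential", "moderately high potential",
              "highly potential habitat")
  counts <- vapply(1:5, function(k) sum(cls == k, na.rm = TRUE),
                   numeric(1))
  list(
    classes = gridRaster(cls, surface@grid, "suitability_class"),
    areas = data.frame(
      class = 1:5, label = labels, n_cells = counts,
      area_km2 = counts * cellArea, stringsAsFactors = FALSE
    )
  )
}

#' Per-zone area above a suitability threshold
#'
#' @param surface suitability \linkS4class{GridRaster} in [0, 100].
#' @param zones list of \code{simplePolygon}s.
#' @param pThreshold probability threshold on suitability/100
#'   (default 0.6).
#' @return data.frame with id, name, zone_area_km2, suitable_area_km2,
#'   fraction.
#' @export
zonalSummary <- function(surface, zones, pThreshold = 0.6) {
  g <- surface@grid
  cellArea <- g@cellSize^2
  rows <- lapply(zones, function(z) {
    cells <- cellsInPolygon(z, g)
    vals <- surface@values[cells]
    nz <- sum(!is.na(vals))
    ns <- sum(vals / 100 > pThreshold, na.rm = TRUE)
    data.frame(
      id = z$id, name = z$name,
      zone_area_km2 = nz * cellArea,
      suitable_area_km2 = ns * cellArea,
      fraction = if (nz) ns / nz else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
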