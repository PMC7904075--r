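# Random-forest presence/pseudo-absence distribution modelling: occurrence
# deduplication onto the analysis grid, pseudo-absence generation with an
# exclusion zone, ensemble training, tree-path feature contributions, and
# extraction of the critical metabolic-index and depth thresholds.

# ---- grid cell bookkeeping -------------------------------------------------

grid_dims <- function(grid) c(nla = length(grid$lat), nlo = length(grid$lon))

cell_id_from_idx <- function(lat_idx, lon_idx, nlo) (lat_idx - 1L) * nlo + lon_idx

#' Deduplicate occurrence points onto the analysis grid
#'
#' Each point is assigned to its containing cell using half-open intervals
#' \[west, east) x \[south, north) (lower-edge inclusive, so a point on a
#' shared edge belongs to exactly one cell). Duplicates within a cell
#' collapse to one presence cell; points outside the grid extent or outside
#' `domain` are dropped and counted.
#'
#' @param points data.frame with lon, lat columns.
#' @param grid any [grid_stack()] defining the analysis grid.
#' @param domain optional logical lat x lon matrix (e.g. from
#'   [clip_depth_domain()]).
#' @return object of class `occurrence_set`: list with `cells` (data.frame
#'   cell_id, lat_idx, lon_idx, lon, lat, n_points), `n_points`,
#'   `n_out_of_domain`.
#' @export
dedupe_occurrences <- function(points, grid, domain = NULL) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  res_lon <- mean(diff(grid$lon)); res_lat <- mean(diff(grid$lat))
  west <- min(grid$lon) - abs(res_lon) / 2
  south <- min(grid$lat) - abs(res_lat) / 2
  nlo <- length(grid$lon); nla <- length(grid$lat)
  i_lon <- floor((points$lon - west) / abs(res_lon)) + 1L
  i_lat <- floor((points$lat - south) / abs(res_lat)) + 1L
  inside <- i_lon >= 1 & i_lon <= nlo & i_lat >= 1 & i_lat <= nla
  if (!is.null(domain)) {
    ok <- inside
    ok[inside] <- domain[cbind(i_lat[inside], i_lon[inside])]
    inside <- ok
  }
  id <- cell_id_from_idx(i_lat[inside], i_lon[inside], nlo)
  tab <- table(id)
  ids <- as.integer(names(tab))
  lat_idx <- (ids - 1L) %/% nlo + 1L
  lon_idx <- (ids - 1L) %% nlo + 1L
  structure(
    list(cells = data.frame(cell_id = ids, lat_idx = lat_idx,
                            lon_idx = lon_idx,
                            lon = grid$lon[lon_idx], lat = grid$lat[lat_idx],
                            n_points = as.integer(tab)),
         n_points = nrow(points),
         n_out_of_domain = sum(!inside)),
    class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d points -> %d unique cells (%d out of domain)\n",
              x$n_points, nrow(x$cells), x$n_out_of_domain))
  invisible(x)
}

#' Build the predictor table for the analysis domain
#'
#' One row per in-domain cell with the cell's aggregate predictor values.
#'
#' @param layers named list of single-slice [grid_stack()]s (e.g. min/mean/
#'   max phi aggregates and depth), all on the same grid.
#' @param domain logical lat x lon matrix; defaults to cells valid in every
#'   layer.
#' @return data.frame with cell_id, lat_idx, lon_idx, lon, lat and one
#'   column per layer.
#' @export
build_predictor_table <- function(layers, domain = NULL) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)))
  g <- layers[[1]]
  nla <- length(g$lat); nlo <- length(g$lon)
  mats <- lapply(layers, function(s) {
    stopifnot_aligned(s, g)
    matrix(s$data[1, , ], nla, nlo)
  })
  valid <- Reduce(`&`, lapply(mats, function(m) !is.na(m)))
  if (!is.null(domain)) valid <- valid & domain
  idx <- which(valid, arr.ind = TRUE)
  out <- data.frame(
    cell_id = cell_id_from_idx(idx[, 1], idx[, 2], nlo),
    lat_idx = idx[, 1], lon_idx = idx[, 2],
    lon = g$lon[idx[, 2]], lat = g$lat[idx[, 1]])
  for (nm in names(mats)) out[[nm]] <- mats[[nm]][idx]
  out[order(out$cell_id), , drop = FALSE]
}

neighbour_ids <- function(cells, nla, nlo) {
  # 8-neighbourhood (queen adjacency) of the given cell ids
  lat_idx <- (cells - 1L) %/% nlo + 1L
  lon_idx <- (cells - 1L) %% nlo + 1L
  out <- integer(0)
  for (di in -1:1) {
    for (dj in -1:1) {
      ii <- lat_idx + di; jj <- lon_idx + dj
      ok <- ii >= 1 & ii <= nla & jj >= 1 & jj <= nlo
      out <- c(out, cell_id_from_idx(ii[ok], jj[ok], nlo))
    }
  }
  unique(out)
}

#' Sample pseudo-absence cells
#'
#' Uniform sample without replacement over the domain cells, excluding the
#' presence cells and their 8-neighbours (queen adjacency).
#'
#' @param predictor_table from [build_predictor_table()] (defines the
#'   domain).
#' @param presence_cells integer cell ids.
#' @param n number of pseudo-absences.
#' @param nla,nlo grid dimensions.
#' @param seed optional RNG seed.
#' @return integer vector of cell ids.
#' @export
generate_pseudo_absences <- function(predictor_table, presence_cells, n,
                                     nla, nlo, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  excluded <- neighbour_ids(presence_cells, nla, nlo)
  eligible <- setdiff(predictor_table$cell_id, excluded)
  if (length(eligible) < n) {
    stop(sprintf("only %d eligible cells for %d pseudo-absences",
                 length(eligible), n))
  }
  sort(sample(eligible, n))
}

# ---- ensemble training -----------------------------------------------------

# Deterministic majority vote: presence when more than half the trees vote
# presence. predict.randomForest breaks exact vote ties at random, which
# would make accuracies and agreement maps depend on RNG state and model
# order; thresholding the vote fraction avoids that.
predict_class <- function(fit, x) {
  p <- stats::predict(fit, x, type = "prob")[, "presence"]
  factor(ifelse(p > 0.5, "presence", "absence"),
         levels = c("absence", "presence"))
}

stratified_split <- function(labels, train_frac) {
  train <- logical(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    n_tr <- round(train_frac * length(idx))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

permutation_importance <- function(model, test_x, test_y, n_perm = 3) {
  base_acc <- mean(predict_class(model, test_x) == test_y)
  drops <- vapply(names(test_x), function(v) {
    accs <- vapply(seq_len(n_perm), function(i) {
      px <- test_x
      px[[v]] <- px[[v]][sample.int(nrow(px))]
      mean(predict_class(model, px) == test_y)
    }, numeric(1))
    base_acc - mean(accs)
  }, numeric(1))
  drops
}

#' Train a random-forest presence/pseudo-absence ensemble
#'
#' Each of the `k` models gets its own freshly generated pseudo-absence set
#' (balanced with the presences), its own stratified 80/20 train/test split,
#' and a per-model seed derived from the master seed. Test accuracy is the
#' fraction of correctly classified test cells under majority vote, and
#' variable importance is the mean decrease in test accuracy under random
#' permutation of each predictor.
#'
#' @param predictor_table from [build_predictor_table()].
#' @param presence_cells integer cell ids of deduplicated presences.
#' @param predictors character vector of predictor column names.
#' @param nla,nlo grid dimensions of the analysis grid.
#' @param k ensemble size (default 10).
#' @param split training fraction (default 0.8).
#' @param ntree trees per forest (default 500).
#' @param mtry predictors tried per split (default floor(sqrt(p))).
#' @param seed master seed; model m uses seed + m.
#' @param n_perm permutations per predictor for the importance measure.
#' @return object of class `sdm_ensemble`.
#' @export
train_rf_ensemble <- function(predictor_table, presence_cells, predictors,
                              nla, nlo, k = 10, split = 0.8, ntree = 500,
                              mtry = max(1, floor(sqrt(length(predictors)))),
                              seed = 1, n_perm = 3) {
  stopifnot(all(predictors %in% names(predictor_table)))
  presence_cells <- intersect(presence_cells, predictor_table$cell_id)
  n_pres <- length(presence_cells)
  if (n_pres < 2) stop("need at least 2 presence cells")
  if (n_pres < 50) warning("fewer than 50 presence cells; accuracy estimates will be noisy")
  rownames(predictor_table) <- as.character(predictor_table$cell_id)
  models <- vector("list", k)
  for (m in seq_len(k)) {
    set.seed(seed + m)
    absences <- generate_pseudo_absences(predictor_table, presence_cells,
                                         n_pres, nla, nlo)
    cells <- c(presence_cells, absences)
    y <- factor(rep(c("presence", "absence"), each = n_pres),
                levels = c("absence", "presence"))
    x <- predictor_table[as.character(cells), predictors, drop = FALSE]
    rownames(x) <- NULL
    if (length(unique(y)) < 2) stop("degenerate single-class training data")
    is_train <- stratified_split(y, split)
    fit <- randomForest::randomForest(x[is_train, , drop = FALSE],
                                      y[is_train], ntree = ntree, mtry = mtry)
    test_x <- x[!is_train, , drop = FALSE]
    test_y <- y[!is_train]
    acc <- mean(predict_class(fit, test_x) == test_y)
    imp <- permutation_importance(fit, test_x, test_y, n_perm)
    models[[m]] <- list(fit = fit, seed = seed + m, accuracy = acc,
                        importance = imp,
                        train_x = x[is_train, , drop = FALSE],
                        train_y = y[is_train],
                        train_cells = cells[is_train])
  }
  structure(list(models = models, predictors = predictors, k = k,
                 split = split, ntree = ntree, mtry = mtry, seed = seed,
                 nla = nla, nlo = nlo),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  acc <- accuracies(x)
  cat(sprintf("sdm_ensemble: %d random forests (%d trees each) on {%s}\n",
              x$k, x$ntree, paste(x$predictors, collapse = ", ")))
  cat(sprintf("  test accuracy: mean %.3f (range %.3f-%.3f)\n",
              mean(acc), min(acc), max(acc)))
  invisible(x)
}

#' @export
summary.sdm_ensemble <- function(object, ...) {
  imp <- sapply(object$models, function(m) m$importance)
  out <- list(accuracies = accuracies(object),
              mean_importance = rowMeans(imp),
              top_ranked = apply(imp, 2, function(v) names(which.max(v))))
  class(out) <- "summary.sdm_ensemble"
  out
}

#' @export
print.summary.sdm_ensemble <- function(x, ...) {
  cat("ensemble test accuracies:\n")
  print(round(x$accuracies, 3))
  cat("mean permutation importance (accuracy drop):\n")
  print(round(x$mean_importance, 4))
  cat("top-ranked predictor per model:\n")
  print(table(x$top_ranked))
  invisible(x)
}

#' Per-model test accuracies of an ensemble
#' @param ensemble an `sdm_ensemble`.
#' @export
accuracies <- function(ensemble) {
  vapply(ensemble$models, function(m) m$accuracy, numeric(1))
}

#' Compare full and reduced predictor-set ensembles
#'
#' Two-sample t test on the per-model test accuracies; the reduced set is
#' recommended when the difference is not significant at `alpha`.
#'
#' @param full,reduced `sdm_ensemble` objects (or numeric accuracy vectors).
#' @param alpha significance level.
#' @return list with both means, `t`, `df`, `p`, and `use_reduced`.
#' @export
compare_full_vs_reduced <- function(full, reduced, alpha = 0.05) {
  a1 <- if (inherits(full, "sdm_ensemble")) accuracies(full) else full
  a2 <- if (inherits(reduced, "sdm_ensemble")) accuracies(reduced) else reduced
  if (length(a1) < 2 || length(a2) < 2) stop("need k >= 2 accuracies per ensemble")
  if (stats::sd(c(a1 - mean(a1), a2 - mean(a2))) < 1e-12) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(a1) + length(a2) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(a1, a2)
  }
  list(mean_full = mean(a1), mean_reduced = mean(a2),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, use_reduced = tt$p.value > alpha)
}

#' One-way comparison of predictor-set accuracies
#'
#' Standard one-way ANOVA across sets of per-model accuracies with Tukey HSD
#' pairwise adjusted p-values.
#'
#' @param acc_list named list of equal-length numeric accuracy vectors (e.g.
#'   phi, FAS, AAS, temperature ensembles).
#' @return list with `F`, `df`, `p`, the `aov` fit and the Tukey table.
#' @export
compare_predictor_sets <- function(acc_list) {
  stopifnot(length(acc_list) >= 2, !is.null(names(acc_list)))
  lens <- lengths(acc_list)
  if (length(unique(lens)) != 1) stop("accuracy vectors must have equal length")
  d <- data.frame(acc = unlist(acc_list),
                  set = factor(rep(names(acc_list), times = lens)))
  fit <- stats::aov(acc ~ set, data = d)
  an <- summary(fit)[[1]]
  list(F = an$`F value`[1], df = c(an$Df[1], an$Df[2]),
       p = an$`Pr(>F)`[1], aov = fit,
       tukey = stats::TukeyHSD(fit)$set)
}

# ---- feature contributions (tree-path decomposition) -----------------------

# Extract one tree of a randomForest as plain vectors.
tree_frame <- function(rf, k) {
  m <- randomForest::getTree(rf, k, labelVar = FALSE)
  list(left = m[, "left daughter"], right = m[, "right daughter"],
       splitvar = m[, "split var"], splitpoint = m[, "split point"],
       status = m[, "status"])
}

# Per-node presence probabilities from routing reference rows down the tree.
# Nodes no reference row reaches inherit the parent's probability (daughters
# always carry a higher index than their parent in getTree output).
tree_node_probs <- function(tree, x, y01) {
  nn <- length(tree$status)
  cnt <- numeric(nn); pres <- numeric(nn)
  n <- nrow(x)
  node <- rep(1L, n)
  cnt[1] <- n; pres[1] <- sum(y01)
  repeat {
    act <- which(tree$status[node] != -1)
    if (length(act) == 0) break
    cur <- node[act]
    v <- tree$splitvar[cur]
    xv <- x[cbind(act, v)]
    child <- ifelse(xv <= tree$splitpoint[cur], tree$left[cur], tree$right[cur])
    node[act] <- child
    cnt <- cnt + tabulate(child, nn)
    pres <- pres + tabulate(child[y01[act] == 1], nn)
  }
  prob <- ifelse(cnt > 0, pres / pmax(cnt, 1), NA_real_)
  parent <- integer(nn)
  parent[tree$left[tree$left > 0]] <- which(tree$left > 0)
  parent[tree$right[tree$right > 0]] <- which(tree$right > 0)
  for (j in seq_len(nn)[-1]) {
    if (is.na(prob[j])) prob[j] <- prob[parent[j]]
  }
  prob
}

# Path-walk contributions of each row of x under given node probabilities.
tree_contributions <- function(tree, prob, x) {
  n <- nrow(x); p <- ncol(x)
  contrib <- matrix(0, n, p)
  node <- rep(1L, n)
  repeat {
    act <- which(tree$status[node] != -1)
    if (length(act) == 0) break
    cur <- node[act]
    v <- tree$splitvar[cur]
    xv <- x[cbind(act, v)]
    child <- ifelse(xv <= tree$splitpoint[cur], tree$left[cur], tree$right[cur])
    contrib[cbind(act, v)] <- contrib[cbind(act, v)] + prob[child] - prob[cur]
    node[act] <- child
  }
  list(contrib = contrib, leaf_prob = prob[node], bias = prob[1])
}

#' Tree-path feature contributions of a random forest
#'
#' For every tree, each row's decision path is walked from the root; at each
#' split on predictor f the change in local presence probability (child
#' minus parent, probabilities computed by routing the reference rows down
#' the tree) is credited to f. Averaged over trees, the decomposition is
#' exactly additive: bias + sum of contributions = the forest's predicted
#' presence probability for the row (tree-averaged leaf presence fraction).
#'
#' @param model a fitted `randomForest` classification forest on numeric
#'   predictors.
#' @param newdata data.frame of rows to decompose (the model's predictors).
#' @param ref_x,ref_y reference rows defining the node probabilities:
#'   normally the model's training predictors and labels (factor or 0/1
#'   with 1/second level = presence).
#' @return list with `contributions` (rows x predictors matrix), `bias`
#'   (scalar) and `prediction` (per-row presence probability; equals
#'   bias + rowSums(contributions)).
#' @export
feature_contributions <- function(model, newdata, ref_x, ref_y) {
  if (!inherits(model, "randomForest")) stop("model must be a randomForest")
  vars <- rownames(model$importance)
  x_new <- as.matrix(newdata[, vars, drop = FALSE])
  x_ref <- as.matrix(ref_x[, vars, drop = FALSE])
  y01 <- if (is.factor(ref_y)) as.integer(ref_y == levels(ref_y)[2]) else
    as.integer(ref_y)
  ntree <- model$ntree
  total <- matrix(0, nrow(x_new), length(vars),
                  dimnames = list(NULL, vars))
  pred <- numeric(nrow(x_new)); bias <- 0
  for (k in seq_len(ntree)) {
    tr <- tree_frame(model, k)
    pr <- tree_node_probs(tr, x_ref, y01)
    tc <- tree_contributions(tr, pr, x_new)
    total <- total + tc$contrib
    pred <- pred + tc$leaf_prob
    bias <- bias + tc$bias
  }
  list(contributions = total / ntree, bias = bias / ntree,
       prediction = pred / ntree)
}

#' Pool training-row feature contributions across an ensemble
#'
#' Computes [feature_contributions()] of each model's own training rows
#' (with that model's training data as the reference set) and stacks them.
#'
#' @param ensemble an `sdm_ensemble`.
#' @return data.frame with one row per (model, training row): `model`, the
#'   predictor values, and `contrib_<predictor>` columns.
#' @export
pool_contributions <- function(ensemble) {
  out <- lapply(seq_along(ensemble$models), function(m) {
    mod <- ensemble$models[[m]]
    fc <- feature_contributions(mod$fit, mod$train_x, mod$train_x, mod$train_y)
    d <- cbind(data.frame(model = m), mod$train_x)
    for (v in ensemble$predictors) {
      d[[paste0("contrib_", v)]] <- fc$contributions[, v]
    }
    d
  })
  do.call(rbind, out)
}

# ---- threshold extraction --------------------------------------------------

#' Critical metabolic-index threshold from pooled contributions
#'
#' Binarises the sign of the minimum-phi feature contributions (positive ->
#' 1, otherwise 0) and fits a maximum-likelihood logistic regression of the
#' binary outcome on minimum phi; phi_crit is the value where the fitted
#' probability is 0.5, i.e. -beta0/beta1, with a Wald (delta-method)
#' confidence interval. Complete separation (likely on clean synthetic
#' data) falls back to the midpoint of the empirical transition and is
#' flagged.
#'
#' @param contrib numeric vector of pooled min-phi contributions.
#' @param values the matching minimum-phi values.
#' @param conf confidence level for the Wald interval.
#' @return object of class `threshold_estimate`: list with `phi_crit`,
#'   `ci`, `coef`, `separation`.
#' @export
estimate_phi_crit <- function(contrib, values, conf = 0.95) {
  stopifnot(length(contrib) == length(values))
  y <- as.integer(contrib > 0)
  if (all(y == 0) || all(y == 1)) {
    stop("contributions all of one sign; no threshold to estimate")
  }
  sep <- max(values[y == 0]) < min(values[y == 1])
  if (sep) {
    est <- (max(values[y == 0]) + min(values[y == 1])) / 2
    return(structure(list(phi_crit = est, ci = c(max(values[y == 0]),
                                                 min(values[y == 1])),
                          coef = NULL, separation = TRUE),
                     class = "threshold_estimate"))
  }
  fit <- suppressWarnings(stats::glm(y ~ values, family = stats::binomial()))
  b <- stats::coef(fit)
  est <- -b[1] / b[2]
  V <- stats::vcov(fit)
  # delta method on g(b) = -b0/b1
  grad <- c(-1 / b[2], b[1] / b[2]^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(phi_crit = unname(est), ci = unname(est + c(-1, 1) * z * se),
                 coef = b, separation = FALSE),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("phi_crit = %.3f (interval %.3f-%.3f)%s\n", x$phi_crit,
              x$ci[1], x$ci[2],
              if (x$separation) " [complete separation: midpoint fallback]" else ""))
  invisible(x)
}

#' Depth occurrence window from pooled contributions
#'
#' Bins depth (default 2 m bins), averages the pooled depth contributions
#' per bin, and reports the interpolated zero crossings bracketing the
#' positive region around the global-maximum bin. A side with no crossing
#' is returned as NA (open window) with a message.
#'
#' @param contrib pooled depth feature contributions.
#' @param depths matching depth values, m.
#' @param bin_width bin width, m.
#' @return list with `lower`, `upper` (m, NA if open) and the bin table.
#' @export
estimate_depth_thresholds <- function(contrib, depths, bin_width = 2) {
  stopifnot(length(contrib) == length(depths))
  br <- seq(floor(min(depths)), ceiling(max(depths)) + bin_width, by = bin_width)
  bin <- cut(depths, br, include.lowest = TRUE, right = FALSE)
  mid <- (br[-1] + br[-length(br)]) / 2
  mc <- tapply(contrib, bin, mean)
  keep <- !is.na(mc)
  mid <- mid[keep]; mc <- as.numeric(mc[keep])
  if (all(mc <= 0)) stop("no positive region in the depth contributions")
  imax <- which.max(mc)
  zero_cross <- function(i, j) {
    # linear interpolation between bin midpoints i (one sign) and j (other)
    mid[i] + (0 - mc[i]) * (mid[j] - mid[i]) / (mc[j] - mc[i])
  }
  lower <- NA_real_
  for (i in rev(seq_len(imax - 1))) {
    if (mc[i] <= 0) { lower <- zero_cross(i, i + 1); break }
  }
  upper <- NA_real_
  if (imax < length(mc)) {
    for (i in (imax + 1):length(mc)) {
      if (mc[i] <= 0) { upper <- zero_cross(i - 1, i); break }
    }
  }
  if (is.na(lower)) message("no lower zero crossing: window open below")
  if (is.na(upper)) message("no upper zero crossing: window open above")
  list(lower = unname(lower), upper = unname(upper),
       bins = data.frame(depth = mid, mean_contribution = mc))
}

# ---- projection ------------------------------------------------------------

#' Project an ensemble onto predictor layers
#'
#' Per cell, the number of models voting presence (majority vote within
#' each forest), scaled to 0-100; 100 means all models agree the cell is
#' suitable. Invariant to model ordering; the mask propagates.
#'
#' @param ensemble an `sdm_ensemble`.
#' @param predictor_table cells to project (from [build_predictor_table()],
#'   any period).
#' @param template optional [grid_stack()]; when given, the agreement is
#'   also returned as a single-slice stack on that grid.
#' @return list with `table` (predictor_table plus an `agreement` column)
#'   and, when `template` is supplied, `stack`.
#' @export
project_distribution <- function(ensemble, predictor_table, template = NULL) {
  missing <- setdiff(ensemble$predictors, names(predictor_table))
  if (length(missing) > 0) {
    stop("predictor table lacks layers: ", paste(missing, collapse = ", "))
  }
  x <- predictor_table[, ensemble$predictors, drop = FALSE]
  votes <- vapply(ensemble$models, function(m) {
    predict_class(m$fit, x) == "presence"
  }, logical(nrow(x)))
  agreement <- rowSums(votes) * (100 / ensemble$k)
  out <- predictor_table
  out$agreement <- agreement
  res <- list(table = out)
  if (!is.null(template)) {
    nla <- length(template$lat); nlo <- length(template$lon)
    mat <- matrix(NA_real_, nla, nlo)
    mat[cbind(out$lat_idx, out$lon_idx)] <- agreement
    res$stack <- grid_stack("agreement", "%", template$lon, template$lat,
                            template$time[1, , drop = FALSE],
                            array(mat, dim = c(1, nla, nlo)))
  }
  res
}

#' @rdname project_distribution
#' @param object an `sdm_ensemble`.
#' @param newdata a predictor table.
#' @param ... unused.
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  project_distribution(object, newdata)$table$agreement
}

# ---- end-to-end pipeline ---------------------------------------------------

#' Aggregate predictor layers for the distribution model
#'
#' Builds the min/mean/max phi aggregates and mean depth on the analysis
#' grid for one period of an environment set.
#'
#' @param env environment list as from [generate_environment()] (elements
#'   `contemporary`/`future` with temp, conc, sal stacks, plus `depth`).
#' @param params a [phi_params()] or `phi_fit`.
#' @param period `"contemporary"` or `"future"`.
#' @param mass reference projection mass, kg.
#' @return named list of single-slice stacks: min_phi, mean_phi, max_phi,
#'   depth.
#' @export
predictor_layers <- function(env, params, period = "contemporary", mass = 1) {
  blk <- env[[period]]
  po2 <- po2_layers(blk$conc, blk$temp, blk$sal, env$depth)
  ph <- compute_phi_layers(params, blk$temp, po2, mass = mass)
  agg <- aggregate_monthly(ph)
  list(min_phi = agg$min, mean_phi = agg$mean, max_phi = agg$max,
       depth = env$depth)
}

#' Full threshold-extraction pipeline
#'
#' From an environment set, calibrated parameters and raw occurrence points
#' to the critical phi and depth thresholds: builds predictor layers,
#' deduplicates occurrences, trains the reduced ensemble (min_phi + depth by
#' default), pools training-row feature contributions across the ensemble,
#' and extracts the thresholds.
#'
#' @param env environment list (see [predictor_layers()]).
#' @param params [phi_params()] or `phi_fit`.
#' @param points occurrence data.frame (lon, lat).
#' @param predictors predictor set for the ensemble.
#' @param k,ntree,seed forwarded to [train_rf_ensemble()].
#' @param depth_range domain depth clip, m.
#' @return list with `ensemble`, `phi_crit` ([estimate_phi_crit()] result),
#'   `depth_thresholds`, `occurrences`, `predictor_table`, `layers`.
#' @export
sdm_pipeline <- function(env, params, points,
                         predictors = c("min_phi", "depth"),
                         k = 10, ntree = 500, seed = 1,
                         depth_range = c(0, 100)) {
  layers <- predictor_layers(env, params)
  domain <- clip_depth_domain(env$depth, depth_range)
  ptab <- build_predictor_table(layers, domain)
  occ <- dedupe_occurrences(points, env$depth, domain)
  ens <- train_rf_ensemble(ptab, occ$cells$cell_id, predictors,
                           nla = length(env$depth$lat),
                           nlo = length(env$depth$lon),
                           k = k, ntree = ntree, seed = seed)
  pooled <- pool_contributions(ens)
  pc <- estimate_phi_crit(pooled$contrib_min_phi, pooled$min_phi)
  dt <- if ("depth" %in% predictors) {
    estimate_depth_thresholds(pooled$contrib_depth, pooled$depth)
  } else NULL
  list(ensemble = ens, phi_crit = pc, depth_thresholds = dt,
       occurrences = occ, predictor_table = ptab, layers = layers,
       pooled = pooled)
}
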