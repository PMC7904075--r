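# A compact synthetic world for the SDM unit tests: 20 x 20 grid, one-slice
# layers built directly (no ocean simulation), with a known suitability rule.
toy_world <- function(seed = 1, nla = 20, nlo = 20, threshold = 3,
                      depth_window = c(13, 75), informative_depth = TRUE,
                      n_presence = 60) {
  set.seed(seed)
  lon <- seq(0.25, by = 0.5, length.out = nlo)
  lat <- seq(-40 + 0.25, by = 0.5, length.out = nla)
  min_phi <- outer(rep(1, nla), seq(1, 5, length.out = nlo)) +
    matrix(rnorm(nla * nlo, 0, 0.05), nla, nlo)
  depth <- outer(seq(2, 98, length.out = nla), rep(1, nlo)) +
    matrix(rnorm(nla * nlo, 0, 0.5), nla, nlo)
  mk <- function(m, v) grid_stack(v, "1", lon, lat,
                                  data.frame(year = 2005, month = 1),
                                  array(m, dim = c(1, nla, nlo)))
  layers <- list(min_phi = mk(min_phi, "min_phi"), depth = mk(depth, "depth"))
  ptab <- build_predictor_table(layers)
  suitable <- min_phi >= threshold
  if (informative_depth) {
    suitable <- suitable & depth >= depth_window[1] & depth <= depth_window[2]
  }
  pres <- which(suitable, arr.ind = TRUE)
  pres_ids <- phimap:::cell_id_from_idx(pres[, 1], pres[, 2], nlo)
  pres_ids <- sort(sample(pres_ids, min(n_presence, length(pres_ids))))
  list(layers = layers, ptab = ptab, presence = pres_ids,
       nla = nla, nlo = nlo, min_phi = min_phi, depth = depth, grid = layers$min_phi)
}

test_that("occurrence deduplication assigns half-open cells with lower-edge inclusion", {
  g <- make_stack(matrix(0, 3, 4), lon = c(0.5, 1.5, 2.5, 3.5),
                  lat = c(10.5, 11.5, 12.5))
  pts <- data.frame(lon = c(0.2, 0.3, 0.9, 0.7, 0.1), lat = rep(10.2, 5))
  ded <- dedupe_occurrences(pts, g)
  expect_equal(nrow(ded$cells), 1)
  expect_equal(ded$cells$n_points, 5L)
  # a point exactly on the shared edge belongs to the cell east of it
  edge <- dedupe_occurrences(data.frame(lon = 1.0, lat = 10.5), g)
  expect_equal(edge$cells$lon, 1.5)
  expect_equal(edge$cells$lat, 10.5)
  # out-of-extent points are counted, not assigned
  out <- dedupe_occurrences(data.frame(lon = c(-1, 2.2), lat = c(10.2, 10.2)), g)
  expect_equal(out$n_out_of_domain, 1)
  expect_equal(nrow(out$cells), 1)
})

test_that("synthetic occurrences map to their exact generating cells", {
  w <- toy_world(2)
  set.seed(3)
  pick <- sample(w$presence, 40)
  lat_idx <- (pick - 1) %/% w$nlo + 1
  lon_idx <- (pick - 1) %% w$nlo + 1
  pts <- data.frame(lon = w$grid$lon[lon_idx] + runif(40, -0.24, 0.24),
                    lat = w$grid$lat[lat_idx] + runif(40, -0.24, 0.24))
  ded <- dedupe_occurrences(pts, w$grid)
  expect_setequal(ded$cells$cell_id, unique(pick))
})

test_that("pseudo-absences avoid presences and their 8-neighbourhood", {
  w <- toy_world(4)
  abs1 <- generate_pseudo_absences(w$ptab, w$presence, length(w$presence),
                                   w$nla, w$nlo, seed = 9)
  excl <- phimap:::neighbour_ids(w$presence, w$nla, w$nlo)
  expect_length(intersect(abs1, excl), 0)
  expect_length(abs1, length(w$presence))
  expect_identical(abs1, generate_pseudo_absences(w$ptab, w$presence,
                                                  length(w$presence),
                                                  w$nla, w$nlo, seed = 9))
  expect_error(generate_pseudo_absences(w$ptab, w$presence, 1e5, w$nla, w$nlo),
               "eligible")
})

test_that("ensembles separate threshold-labelled data and fail on shuffled labels", {
  w <- toy_world(5)
  ens <- train_rf_ensemble(w$ptab, w$presence, c("min_phi", "depth"),
                           w$nla, w$nlo, k = 5, ntree = 100, seed = 31)
  expect_gte(mean(accuracies(ens)), 0.95)
  # pure-noise predictors carry no signal: accuracy collapses to chance
  set.seed(77)
  w0 <- w
  w0$ptab$min_phi <- rnorm(nrow(w0$ptab))
  w0$ptab$depth <- rnorm(nrow(w0$ptab))
  fake <- sample(w$ptab$cell_id, 30)
  expect_warning(
    ens0 <- train_rf_ensemble(w0$ptab, fake, c("min_phi", "depth"),
                              w$nla, w$nlo, k = 10, ntree = 100, seed = 31),
    "fewer than 50")
  expect_lt(abs(mean(accuracies(ens0)) - 0.5), 0.12)
})

test_that("permutation importance ranks the planted driver first", {
  w <- toy_world(6, informative_depth = FALSE)   # only min_phi matters
  ens <- train_rf_ensemble(w$ptab, w$presence, c("min_phi", "depth"),
                           w$nla, w$nlo, k = 10, ntree = 100, seed = 13)
  top <- summary(ens)$top_ranked
  expect_gte(sum(top == "min_phi"), 9)
})

test_that("full vs reduced comparison reduces to the two-sample t test", {
  expect_equal(compare_full_vs_reduced(rep(0.9, 10), rep(0.9, 10))$t, 0)
  set.seed(2)
  a <- 0.9 + rnorm(10, 0, 0.01); b <- 0.6 + rnorm(10, 0, 0.01)
  r <- compare_full_vs_reduced(a, b)
  expect_lt(r$p, 0.01)
  expect_equal(r$mean_full, mean(a)); expect_equal(r$mean_reduced, mean(b))
  # closed-form Welch statistic
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 10 + var(b) / 10)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_error(compare_full_vs_reduced(0.9, 0.8), "k >= 2")
})

test_that("predictor-set comparison matches a brute-force ANOVA oracle", {
  v <- seq(0.85, 0.94, by = 0.01)
  sets <- list(phi = v, fas = v, aas = v, temp = v)
  expect_equal(compare_predictor_sets(sets)$F, 0)  # equal group means, nonzero spread
  set.seed(6)
  sets2 <- list(phi = rnorm(10, 0.93, 0.02), fas = rnorm(10, 0.90, 0.02),
                aas = rnorm(10, 0.82, 0.02), temp = rnorm(10, 0.91, 0.02))
  r <- compare_predictor_sets(sets2)
  # brute-force sums of squares
  all_v <- unlist(sets2); grp <- rep(names(sets2), each = 10)
  ssb <- sum(tapply(all_v, grp, function(v) 10 * (mean(v) - mean(all_v))^2))
  ssw <- sum(tapply(all_v, grp, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 3) / (ssw / 36)
  expect_equal(r$F, f_hand, tolerance = 1e-10)
  expect_equal(r$df, c(3, 36))
  # Tukey-adjusted p-values never fall below the pooled-MSE pairwise p
  mse <- ssw / 36
  t_pair <- (mean(sets2$phi) - mean(sets2$aas)) / sqrt(mse * 2 / 10)
  praw <- 2 * pt(-abs(t_pair), 36)
  expect_gte(r$tukey["phi-aas", "p adj"] + 1e-12, praw)
  expect_error(compare_predictor_sets(list(a = 1:3 / 10, b = 1:4 / 10)), "equal length")
})

test_that("tree-path contributions on hand-built trees follow the decomposition", {
  # one split on feature 1 at 0.5; reference rows put prob 0 left, 1 right
  tree <- list(left = c(2L, 0L, 0L), right = c(3L, 0L, 0L),
               splitvar = c(1L, 0L, 0L), splitpoint = c(0.5, 0, 0),
               status = c(1L, -1L, -1L))
  xref <- matrix(c(0.2, 0.8, 0.3, 0.9), 4, 1)
  prob <- phimap:::tree_node_probs(tree, xref, c(0, 1, 0, 1))
  expect_equal(prob, c(0.5, 0, 1))
  tc <- phimap:::tree_contributions(tree, prob, matrix(c(0.1, 0.7), 2, 1))
  expect_equal(tc$bias, 0.5)
  expect_equal(tc$contrib[, 1], c(-0.5, 0.5))   # leaf prob minus root prob
  expect_equal(tc$leaf_prob, c(0, 1))
  # a degenerate single-node tree contributes nothing
  stump <- list(left = 0L, right = 0L, splitvar = 0L, splitpoint = 0,
                status = -1L)
  pr2 <- phimap:::tree_node_probs(stump, xref, c(0, 1, 0, 1))
  tc2 <- phimap:::tree_contributions(stump, pr2, matrix(0.4, 1, 1))
  expect_equal(tc2$contrib[1, 1], 0)
  expect_equal(tc2$leaf_prob, tc2$bias)
})

test_that("contribution additivity holds to 1e-10 on a random forest", {
  set.seed(10)
  n <- 80
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- factor(ifelse(x$a + 0.5 * x$b + rnorm(n, 0, 0.5) > 0,
                     "presence", "absence"), levels = c("absence", "presence"))
  rf <- randomForest::randomForest(x, y, ntree = 10)
  fc <- feature_contributions(rf, x, x, y)
  gap <- abs(fc$bias + rowSums(fc$contributions) - fc$prediction)
  expect_lt(max(gap), 1e-10)
  # bias is the presence fraction of the reference rows
  expect_equal(fc$bias, mean(y == "presence"), tolerance = 1e-12)
})

test_that("phi_crit extraction inverts the logistic and handles separation", {
  # deterministic switch at 3.0: symmetric midpoint fallback
  x <- seq(2, 4, by = 0.01)
  contrib <- ifelse(x >= 3.0, 0.2, -0.2)
  est <- estimate_phi_crit(contrib, x)
  expect_true(est$separation)
  expect_equal(est$phi_crit, 3.0, tolerance = 0.02)
  # noisy logistic data: -b0/b1 matches a direct likelihood maximisation
  set.seed(14)
  xx <- runif(500, 2, 4)
  yy <- rbinom(500, 1, plogis((xx - 3) / 0.25))
  est2 <- estimate_phi_crit(ifelse(yy == 1, 0.1, -0.1), xx)
  expect_false(est2$separation)
  nll <- function(p) -sum(dbinom(yy, 1, plogis(p[1] + p[2] * xx), log = TRUE))
  op <- optim(c(0, 1), nll)
  expect_equal(est2$phi_crit, -op$par[1] / op$par[2], tolerance = 0.01)
  expect_true(est2$ci[1] < 3 & est2$ci[2] > 2.9)
  expect_error(estimate_phi_crit(rep(0.2, 5), 1:5), "one sign")
})

test_that("depth thresholds are the zero crossings around the positive region", {
  set.seed(15)
  d <- runif(3000, 0, 100)
  contrib <- ifelse(d >= 13 & d <= 75, 0.1, -0.1) + rnorm(3000, 0, 0.01)
  th <- estimate_depth_thresholds(contrib, d)
  expect_equal(th$lower, 13, tolerance = 2)
  expect_equal(th$upper, 75, tolerance = 2)
  # all-positive contributions: open window both sides
  expect_message(th2 <- estimate_depth_thresholds(rep(0.1, 100), runif(100, 0, 50)),
                 "open")
  expect_true(is.na(th2$lower) && is.na(th2$upper))
  # single sign change gives a one-sided window
  d3 <- seq(1, 99, by = 0.5)
  th3 <- estimate_depth_thresholds(ifelse(d3 < 40, 0.1, -0.1), d3)
  expect_true(is.na(th3$lower))
  expect_equal(th3$upper, 40, tolerance = 2)
  expect_error(estimate_depth_thresholds(rep(-1, 50), runif(50, 0, 90)),
               "no positive")
})

test_that("projection counts model votes and is invariant to model order", {
  w <- toy_world(16)
  ens <- train_rf_ensemble(w$ptab, w$presence, c("min_phi", "depth"),
                           w$nla, w$nlo, k = 5, ntree = 60, seed = 5)
  proj <- project_distribution(ens, w$ptab, template = w$grid)
  expect_true(all(proj$table$agreement %in% seq(0, 100, by = 20)))
  ens_r <- ens; ens_r$models <- rev(ens_r$models)
  expect_equal(project_distribution(ens_r, w$ptab)$table$agreement,
               proj$table$agreement)
  # suitable heartland agrees fully; far outside the window agrees ~never
  tab <- proj$table
  core <- tab$min_phi > 4 & tab$depth > 30 & tab$depth < 60
  expect_true(all(tab$agreement[core] == 100))
  off <- tab$min_phi < 2
  expect_lt(mean(tab$agreement[off]), 10)
  expect_error(project_distribution(ens, w$ptab[, -6]), "lacks")
})

test_that("pooled contributions recover a planted threshold end to end", {
  w <- toy_world(18)
  ens <- train_rf_ensemble(w$ptab, w$presence, c("min_phi", "depth"),
                           w$nla, w$nlo, k = 5, ntree = 100, seed = 3)
  pooled <- pool_contributions(ens)
  est <- estimate_phi_crit(pooled$contrib_min_phi, pooled$min_phi)
  expect_equal(est$phi_crit, 3.0, tolerance = 0.15)
  th <- estimate_depth_thresholds(pooled$contrib_depth, pooled$depth)
  expect_equal(th$lower, 13, tolerance = 4)
  expect_equal(th$upper, 75, tolerance = 4)
})
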