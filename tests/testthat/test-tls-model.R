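test_that("raw and adjusted TLS scores match pair-probability enumeration", {
  # 8 types, B = T = 0.5: raw = 0.5; the average distinct-pair probability
  # is enumerated over all 28 unordered pairs
  p <- matrix(0, 1, 8, dimnames = list("s1", c("B-cells", "T-cells",
                                               paste0("t", 1:6))))
  p[1, "B-cells"] <- 0.5; p[1, "T-cells"] <- 0.5
  s <- tls_score(p)
  expect_equal(s$raw, 0.5)
  pairs <- combn(8, 2)
  avg <- mean(apply(pairs, 2, function(ij) 2 * p[1, ij[1]] * p[1, ij[2]]))
  expect_equal(s$adjusted, 0.5 - avg)
  expect_equal(s$adjusted, 0.5 - 0.5 / 28)

  # B = T = 0 gives raw 0 and adjusted <= 0
  p2 <- random_props(20, 5, seed = 2,
                     types = c("B-cells", "T-cells", "a", "b", "c"))
  p2[, "B-cells"] <- 0; p2[, "T-cells"] <- 0
  p2 <- p2 / rowSums(p2)
  s2 <- tls_score(p2)
  expect_true(all(s2$raw == 0))
  expect_true(all(s2$adjusted <= 0))

  # raw is bounded by 0.5, attained only at the half/half composition
  p3 <- random_props(200, 8, seed = 3,
                     types = c("B-cells", "T-cells", paste0("t", 1:6)))
  s3 <- tls_score(p3)
  expect_true(all(s3$raw >= 0 & s3$raw <= 0.5))
  expect_true(all(s3$adjusted <= s3$raw))
})

test_that("the pair-sum identity 1 - sum(p^2) = sum of distinct-pair products holds", {
  p <- random_props(50, 7, seed = 5)
  lhs <- 1 - rowSums(p^2)
  rhs <- apply(p, 1, function(row) {
    tot <- 0
    for (u in 1:6) for (v in (u + 1):7) tot <- tot + 2 * row[u] * row[v]
    tot
  })
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # the same-type variant reduces to a constant shift
  s_incl <- tls_score(p, "t1", "t2", include_same_type = TRUE)
  expect_equal(s_incl$adjusted, s_incl$raw - 2 / (7 * 8), tolerance = 1e-12)
})

test_that("OLS recovers planted coefficients", {
  set.seed(8)
  n <- 300
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:5)))
  y <- 0.3 + 2 * x[, 1] - x[, 2]
  fit <- fit_tls_model(x, y)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[1:2]), c(2, -1), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[3:5]), rep(0, 3), tolerance = 1e-8)
  expect_equal(fit$fitted, as.numeric(y), tolerance = 1e-8)

  # pure noise: coefficients within 3 standard errors of zero
  set.seed(9)
  y2 <- rnorm(1000)
  x2 <- matrix(rnorm(1000 * 10), 1000, 10,
               dimnames = list(NULL, paste0("g", 1:10)))
  fit2 <- fit_tls_model(x2, y2)
  lmfit <- lm(y2 ~ x2)
  se <- summary(lmfit)$coefficients[-1, "Std. Error"]
  expect_true(all(abs(fit2$coefficients) < 3 * se))
  expect_equal(unname(fit2$coefficients), unname(coef(lmfit)[-1]),
               tolerance = 1e-10)

  # constant response
  fit3 <- fit_tls_model(x, rep(1.7, n))
  expect_equal(fit3$intercept, 1.7, tolerance = 1e-10)
  expect_equal(max(abs(fit3$coefficients)), 0, tolerance = 1e-10)
})

test_that("under-determined fits return the minimum-norm solution", {
  set.seed(10)
  x <- matrix(rnorm(10 * 25), 10, 25, dimnames = list(NULL, paste0("g", 1:25)))
  y <- rnorm(10)
  expect_warning(fit <- fit_tls_model(x, y), "minimum-norm")
  # interpolates the data...
  expect_equal(fit$fitted, as.numeric(y), tolerance = 1e-8)
  # ...and has minimal norm among least-squares solutions: any other
  # exact solution is longer
  beta <- c(fit$intercept, fit$coefficients)
  X <- cbind(1, x)
  qt <- qr(t(X))
  ns <- qr.Q(qt, complete = TRUE)[, (qt$rank + 1):26, drop = FALSE]
  for (k in seq_len(ncol(ns))) {
    alt <- beta + 0.1 * ns[, k]
    expect_equal(as.numeric(X %*% alt), as.numeric(y), tolerance = 1e-6)
    expect_gt(sum(alt^2), sum(beta^2))
  }
  expect_error(fit_tls_model(x[, 0], y), "empty gene set")
})

test_that("signature extraction locates a planted coefficient-curve elbow", {
  f <- planted_coefficient_curve(n = 1000, elbow = 170, seed = 1)
  sig <- extract_signature(f, sigma = 10)
  expect_lte(abs(sig$threshold_rank - 170), 15)
  expect_equal(length(sig$genes), sig$threshold_rank - 1)
  # members are exactly the genes ranked strictly above the threshold
  ranked <- sig$ranked
  expect_identical(sig$genes, ranked$gene[ranked$rank < sig$threshold_rank])

  # gene input order is irrelevant: sorting is the first step
  set.seed(2)
  sig2 <- extract_signature(f[sample(length(f))], sigma = 10)
  expect_identical(sig2$genes, sig$genes)
  expect_equal(sig2$threshold_rank, sig$threshold_rank)
})

test_that("a vanishing-sigma limit puts the threshold at a concave kink", {
  # piecewise-linear curve with dyadic slopes (exactly representable, so
  # the second difference is exactly zero off the kink and negative at it)
  n <- 100
  f <- numeric(n)
  f[1:50] <- 1 - (1:50) / 1024
  f[51:n] <- f[50] - (1:50) / 8
  names(f) <- paste0("g", 1:n)
  sig <- extract_signature(f, sigma = 0.05)
  expect_equal(sig$threshold_rank, 50)

  # convex curves (sign-flipped coefficients) have no concave crossing
  g <- -f; names(g) <- names(f)
  expect_error(extract_signature(g, sigma = 0.05), "no threshold")
  expect_error(extract_signature(f[1:20], sigma = 10), "at least")
})

test_that("prediction reproduces training fits and stratifies by quintile", {
  gen <- generate_dataset(synthetic_config(grid_rows = 12, grid_cols = 12,
                                           mask = "none", n_genes = 60,
                                           tls_foci = list(list(center = c(6, 6),
                                                                radius = 3)),
                                           seed = 19))
  scores <- tls_score(gen$truth$proportions)
  norm <- normalize_libsize_sd(gen$dataset)
  scores <- scores[match(rownames(norm$values), scores$spot), ]
  model <- fit_tls_model(norm, scores)
  pred <- predict_and_stratify(model, gen$dataset)
  expect_equal(pred$score, model$fitted, tolerance = 1e-9)

  # quintile arithmetic on scores 1..100
  set.seed(4)
  fake <- model
  fake$intercept <- 0
  fake$coefficients <- c(gA = 1)
  # craft samples whose predicted scores are strictly increasing
  q <- predict_and_stratify(fake,
    matrix(c(seq(1, 100), rep(50, 100)), 100, 2,
           dimnames = list(paste0("m", 1:100), c("gA", "gB"))),
    min_overlap = 0.5)
  expect_equal(q$stratum[order(q$score)],
               rep(c("low", "unassigned", "intermediate", "unassigned", "high"),
                   each = 20))

  # dropping a zero-coefficient, zero-count gene leaves predictions
  # unchanged (library sizes and the remaining genes' scaling are untouched)
  set.seed(6)
  m3 <- cbind(matrix(rpois(80, 20) + 1, 20, 4,
                     dimnames = list(paste0("m", 1:20), paste0("g", 1:4))),
              silent = 0)
  model0 <- list(intercept = 0.1,
                 coefficients = c(g1 = 1, g2 = -0.5, g3 = 0.2, g4 = 0,
                                  silent = 0),
                 normalization = "libsize_sd")
  class(model0) <- "tls_model"
  p_full <- suppressWarnings(predict_and_stratify(model0, m3))
  p_drop <- suppressMessages(predict_and_stratify(model0, m3[, 1:4]))
  expect_equal(p_drop$score, p_full$score, tolerance = 1e-9)

  # insufficient overlap errors with the measured fraction
  m2 <- as.matrix(gen$dataset$counts)
  expect_error(predict_and_stratify(model, m2[, 1:10]), "overlap")
})
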