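test_that("homology splits keep whole families together", {
  ids <- sprintf("t%03d", 1:100)
  fams <- rep(sprintf("f%02d", 1:10), each = 10L)
  sp <- homologySplit(ids, fams, c(0.8, 0.1, 0.1), seed = 1L)
  expect_equal(length(sp$train), 80L)
  expect_equal(length(sp$val), 10L)
  expect_equal(length(sp$test), 10L)
  famOf <- stats::setNames(fams, ids)
  expect_length(intersect(famOf[sp$train], famOf[sp$test]), 0L)
  expect_length(intersect(famOf[sp$train], famOf[sp$val]), 0L)

  sp2 <- homologySplit(ids, fams, seed = 2L)
  expect_false(identical(sp$train, sp2$train))
  expect_equal(length(sp2$train), 80L)
  expect_error(homologySplit(ids, fams, c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("no family straddles partitions over many seeded splits", {
  withr::with_seed(17, {
    ids <- sprintf("t%03d", 1:120)
    fams <- sample(sprintf("f%02d", 1:25), 120L, replace = TRUE)
    famOf <- stats::setNames(fams, ids)
    for (s in seq_len(200L)) {
      sp <- homologySplit(ids, fams, seed = s)
      expect_length(intersect(famOf[sp$train],
                              c(famOf[sp$val], famOf[sp$test])), 0L)
      expect_length(intersect(famOf[sp$val], famOf[sp$test]), 0L)
    }
  })
})

.syntheticProbeData <- function(n = 400L, d = 12L, seed = 1L) {
  withr::with_seed(seed, {
    emb <- matrix(rnorm(n * d), n, d,
                  dimnames = list(sprintf("t%04d", 1:n), NULL))
    beta <- rnorm(d)
    y <- drop(emb %*% beta)
    fams <- rep(sprintf("f%03d", seq_len(n / 4)), each = 4L)
    list(emb = emb, y = y, fams = stats::setNames(fams, rownames(emb)))
  })
}

test_that("linear probes recover realizable signals and reject noise", {
  dat <- .syntheticProbeData(1000L)
  task <- list(name = "lin", kind = "regression",
               labels = stats::setNames(dat$y, rownames(dat$emb)),
               family = dat$fams)
  sp <- homologySplit(rownames(dat$emb), dat$fams, seed = 3L)
  fit <- fitLinearProbe(dat$emb, task, sp, seed = 1L)
  expect_gte(fit$value, 0.999)

  taskPerm <- task
  taskPerm$labels <- stats::setNames(
    withr::with_seed(5, sample(dat$y)), rownames(dat$emb))
  fitP <- fitLinearProbe(dat$emb, taskPerm, sp, seed = 1L)
  expect_lt(abs(fitP$value), 0.1)

  taskConst <- task
  taskConst$labels[] <- 1
  expect_error(fitLinearProbe(dat$emb, taskConst, sp, seed = 1L),
               "constant")
})

test_that("classification probes reach near-perfect auPRC on separable classes", {
  withr::with_seed(9, {
    n <- 300L
    cls <- rep(c("A", "B", "C"), each = n / 3)
    centers <- matrix(c(5, 0, 0, 0, 5, 0, 0, 0, 5), 3, 3, byrow = TRUE)
    emb <- centers[as.integer(factor(cls)), ] + matrix(rnorm(n * 3, sd = .3),
                                                       n, 3)
    rownames(emb) <- sprintf("t%03d", 1:n)
    fams <- stats::setNames(rep(sprintf("f%02d", 1:30), length.out = n),
                            rownames(emb))
    task <- list(name = "cls", kind = "classification",
                 labels = stats::setNames(cls, rownames(emb)),
                 family = fams)
    sp <- homologySplit(rownames(emb), fams, seed = 2L)
    fit <- fitLinearProbe(emb, task, sp, seed = 1L)
    expect_gte(fit$value, 0.99)
  })
})

test_that("few-shot subsampling is uniform, seeded and bounded", {
  train <- sprintf("t%04d", 1:1000)
  s30 <- fewShotSubsample(train, 30L, seed = 1L)
  expect_length(unique(s30), 30L)
  expect_identical(s30, fewShotSubsample(train, 30L, seed = 1L))
  expect_false(identical(s30, fewShotSubsample(train, 30L, seed = 2L)))
  expect_identical(fewShotSubsample(train, 1000L, seed = 1L), train)
  expect_error(fewShotSubsample(train, 1001L), "exceeds")
})

test_that("the Fisher transform is arctanh", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.71), 0.8872, tolerance = 1e-4)
  expect_equal(fisherZ(-0.4), -fisherZ(0.4))
  expect_error(fisherZ(1), "< 1")
})

test_that("Z-score pooling normalizes to the hand-computed reference", {
  res <- data.frame(config = rep(c("cfgA", "cfgB"), each = 2L),
                    seed = c(1L, 2L, 1L, 2L),
                    value = c(0.6, 0.8, 0.2, 0.4))
  zn <- zscoreNormalize(res, kind = "classification")
  # hand pooling: mu = 0.5, population sigma = 0.2236
  expect_equal(zn$mu, 0.5)
  expect_equal(zn$sigma, 0.2236, tolerance = 1e-4)
  tab <- zn$table
  expect_equal(tab$meanZ[tab$config == "cfgA"], 0.8944, tolerance = 1e-4)
  expect_equal(tab$meanZ[tab$config == "cfgB"], -0.8944, tolerance = 1e-4)
  # scores at mu and mu + sigma
  expect_equal(((0.5 - zn$mu) / zn$sigma), 0)
  expect_equal(((zn$mu + zn$sigma - zn$mu) / zn$sigma), 1)
  # pooled reference is standardized to machine precision
  expect_lt(abs(mean(zn$z)), 1e-9)
  expect_lt(abs(mean(zn$z^2) - 1), 1e-9)
  expect_error(zscoreNormalize(res[res$config == "cfgA", ],
                               "classification"), "two configurations")
})

test_that("aggregate Z averages per-task Z with equal weights", {
  res <- rbind(
    data.frame(config = rep(c("a", "b"), each = 2L), task = "t1",
               kind = "classification", seed = 1:2,
               value = c(0.6, 0.8, 0.2, 0.4)),
    data.frame(config = rep(c("a", "b"), each = 2L), task = "t2",
               kind = "regression", seed = 1:2,
               value = c(0.5, 0.6, 0.1, 0.2)))
  agg <- aggregateZScores(res)
  expect_equal(nrow(agg$perTask), 4L)
  a <- agg$aggregate
  expect_equal(a$aggregateZ[a$config == "a"],
               mean(agg$perTask$meanZ[agg$perTask$config == "a"]))
  expect_equal(sum(a$aggregateZ), 0, tolerance = 1e-9)
})

test_that("one-sided Welch test behaves at the null and under separation", {
  same <- c(0.5, 0.6, 0.7)
  w <- welchOneSided(same, same)
  expect_equal(w$t, 0)
  expect_equal(w$p, 0.5)
  expect_true(w$topTier)

  ref <- rep(1, 10) + c(0.01, rep(0, 9))
  cand <- rep(0, 10) + c(0.01, rep(0, 9))
  w2 <- welchOneSided(ref, cand)
  expect_lt(w2$p, 1e-6)
  expect_false(w2$topTier)

  w3 <- welchOneSided(c(0, 0.1, 0.05), c(10, 10.1, 10.2))
  expect_gt(w3$p, 0.5)
  expect_true(w3$topTier)
  expect_error(welchOneSided(1, c(1, 2)), "two values")
  # matches stats::t.test on a generic case
  a <- c(1.2, 1.5, 1.1, 1.9); b <- c(0.8, 1.0, 1.4)
  expect_equal(welchOneSided(a, b)$p,
               stats::t.test(a, b, alternative = "greater")$p.value)
})
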